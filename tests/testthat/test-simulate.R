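test_that("the generated design has the full nested structure", {
  ex <- generate_experiment(seed = 7)
  expect_equal(nrow(ex$geochemistry), 72) # 2 species x 3 pH x 12 colonies
  expect_equal(nrow(ex$seawater), 36)
  expect_equal(nrow(ex$growth), 72)

  sw <- ex$seawater
  # 4 header tanks per treatment, 3 incubation tanks per header
  expect_equal(as.vector(tapply(sw$header_tank, sw$treatment,
                                function(x) length(unique(x)))),
               rep(4L, 3))
  expect_true(all(table(sw$header_tank) == 3))
  # one colony per species per incubation tank
  geo <- ex$geochemistry
  expect_true(all(table(geo$species, geo$incubation_tank) == 1))
  expect_true(all(table(geo$species, geo$treatment) == 12))
  # tank nesting consistent between tables
  m <- match(geo$incubation_tank, sw$tank_id)
  expect_identical(geo$header_tank, sw$header_tank[m])
  expect_identical(geo$treatment, sw$treatment[m])
  # growth ids match geochemistry ids
  expect_setequal(ex$growth$colony_id, geo$colony_id)
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_experiment(seed = 123)
  b <- generate_experiment(seed = 123)
  expect_identical(a$geochemistry, b$geochemistry)
  expect_identical(a$growth, b$growth)
  c <- generate_experiment(seed = 124)
  expect_false(identical(a$geochemistry$d11B_permil,
                         c$geochemistry$d11B_permil))
})

test_that("zero-noise parameters reproduce the generating regressions exactly", {
  p <- generator_params(
    ph_tank_sd = 0, alkalinity_sd = 0,
    d11B_analytical_sd = 0, BCa_analytical_sd = 0, tank_var_frac = 0,
    d11b_floor_sd = 0, bca_floor_sd = 0,
    species = list(a_youngei = list(
      d11b_slope = 2.37, d11b_intercept = 4.41,
      bca_slope = 31.6, bca_intercept = -124,
      calcification_mean = c(1.97, 1.65, 1.34),
      calcification_se = c(0, 0, 0),
      phcf_se = c(0, 0, 0), bca_se = c(0, 0, 0)
    ))
  )
  ex <- generate_experiment(p, seed = 1)
  geo <- ex$geochemistry
  ph <- ex$seawater$pH_total[match(geo$incubation_tank,
                                   ex$seawater$tank_id)]
  expect_equal(geo$d11B_permil, 2.37 * ph + 4.41, tolerance = 1e-12)
  expect_equal(geo$BCa_umol_mol, 31.6 * geo$d11B_permil - 124,
               tolerance = 1e-12)
  # growth records invert exactly through the calcification identities
  # (noise-free data makes the internal regressions exact fits, which lm
  # warns about)
  rates <- suppressWarnings(
    run_pipeline(geo, ex$growth, ex$seawater, mc = NULL))$colonies
  expect_equal(rates$calcification_mg_cm2_d,
               rep(c(1.97, 1.65, 1.34), each = 12), tolerance = 1e-9)
})

test_that("inconsistent design parameters raise config errors", {
  expect_error(generator_params(temperatures = c(21, 21)), "config error")
  expect_error(generator_params(n_header = 1), "config error")
  expect_error(
    generator_params(species = list(x = list(
      d11b_slope = 2, d11b_intercept = 1, bca_slope = 30, bca_intercept = 0,
      calcification_mean = c(1, 1), calcification_se = c(0.1, 0.1),
      phcf_se = c(0.01, 0.01), bca_se = c(6, 6)
    ))),
    "config error"
  )
})

test_that("per-treatment spreads are calibrated to the target standard errors", {
  # average observed SEs over seeds should sit near the configured targets
  seeds <- 1:8
  p <- generator_params()
  ses <- sapply(seeds, function(s) {
    ex <- generate_experiment(p, seed = s)
    res <- run_pipeline(ex$geochemistry, NULL, ex$seawater, mc = NULL)
    res$summary$pH_cf_se
  })
  target <- c(p$species$a_youngei$phcf_se, p$species$p_damicornis$phcf_se)
  # summary rows: species alphabetical, treatments descending pH
  obs <- rowMeans(ses)
  expect_true(all(obs / target > 0.5 & obs / target < 2))
})

test_that("experiments round-trip through CSV files", {
  ex <- generate_experiment(seed = 5)
  dir <- tempfile("exp")
  paths <- write_experiment(ex, dir)
  expect_true(all(file.exists(paths)))
  geo <- read.csv(file.path(dir, "geochemistry.csv"))
  expect_equal(geo$d11B_permil, ex$geochemistry$d11B_permil,
               tolerance = 1e-12)
  snap <- yaml::read_yaml(file.path(dir, "params.yaml"))
  expect_equal(snap$seed, 5)
  expect_equal(snap$salinity, 35.5)
  unlink(dir, recursive = TRUE)
})
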