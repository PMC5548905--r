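test_that("pH proxy hits pK_B at the fixed-point delta-11-B", {
  x0 <- oracle_d11b_fixed_point() # numerator == denominator
  k <- carb_constants(20.9, 35.5)
  expect_equal(x0, 25.6612, tolerance = 1e-4)
  expect_equal(phcf_from_d11b(x0, constants = k), -log10(k$KB),
               tolerance = 1e-12)
  expect_equal(d11b_from_phcf(-log10(k$KB), constants = k), x0,
               tolerance = 1e-12)
})

test_that("pH proxy reproduces treatment-mean fluid pH from the regressions", {
  # skeletal d11B evaluated from the species regressions at treatment pH
  expect_equal(phcf_from_d11b(2.37 * 8.09 + 4.41, 20.9, 35.5), 8.51,
               tolerance = 0.02 / 8.51)
  expect_equal(phcf_from_d11b(4.37 * 7.63 - 12.11, 21.0, 35.5), 8.35,
               tolerance = 0.02 / 8.35)
})

test_that("pH proxy domain errors are raised and named", {
  expect_error(phcf_from_d11b(39.7, 20.9, 35.5), "numerator")
  expect_error(phcf_from_d11b(40, 20.9, 35.5), "numerator")
  expect_error(phcf_from_d11b(11.9, 20.9, 35.5), "denominator")
})

test_that("forward and inverse pH proxy round-trip across the working range", {
  k <- carb_constants(21, 35.5)
  grid <- seq(15, 30, by = 0.25)
  ph <- phcf_from_d11b(grid, constants = k)
  expect_true(all(diff(ph) > 0)) # strictly increasing
  expect_equal(d11b_from_phcf(ph, constants = k), grid, tolerance = 1e-10)
  back <- d11b_from_phcf(seq(7.5, 9.5, by = 0.05), constants = k)
  expect_true(all(diff(back) > 0))
})

test_that("B/Ca proxy arithmetic matches an independent evaluation", {
  k <- carb_constants(20.9, 35.5)
  co3 <- co3cf_from_bca(618, 8.51, constants = k)
  expect_equal(co3, oracle_co3cf(618, 8.51, k), tolerance = 1e-12)
  expect_equal(co3 * 1e6, 880, tolerance = 0.05) # ~8.8e2 umol kg-1
  # nmol-exponent convention attenuates K_D by exp(-k_KD [H+] in nmol)
  b_nmol <- boron_constants(kd_h_unit = "nmol")
  co3_nmol <- co3cf_from_bca(618, 8.51, boron = b_nmol, constants = k)
  expect_equal(co3_nmol / co3, exp(-0.0202 * 10^-8.51 * 1e9) / exp(-0.0202 * 10^-8.51),
               tolerance = 1e-10)
  expect_error(co3cf_from_bca(-5, 8.51, constants = k), "BCa")
})

test_that("B/Ca proxy limits: vanishing at large B/Ca, increasing in pH_cf", {
  k <- carb_constants(20.9, 35.5)
  expect_lt(co3cf_from_bca(1e9, 8.51, constants = k), 1e-9)
  grid <- seq(7.8, 9.2, by = 0.05)
  co3 <- co3cf_from_bca(618, grid, constants = k)
  expect_true(all(diff(co3) > 0))
  co3n <- co3cf_from_bca(618, grid, boron = boron_constants(kd_h_unit = "nmol"),
                         constants = k)
  expect_true(all(diff(co3n) > 0))
})

test_that("full reconstruction reproduces published treatment means", {
  r1 <- resolve_calcifying_fluid(23.58, 618, 20.9, 35.5)
  expect_equal(r1$pH_cf, 8.51, tolerance = 0.05 / 8.51)
  expect_equal(r1$DIC_cf * 1e6, 3866, tolerance = 0.05)
  expect_equal(r1$omega_cf, 14.0, tolerance = 0.05)
  r2 <- resolve_calcifying_fluid(21.23, 649, 21.0, 35.5)
  expect_equal(r2$pH_cf, 8.35, tolerance = 0.05 / 8.35)
  expect_equal(r2$omega_cf, 10.2, tolerance = 0.05)
})

test_that("reconstruction satisfies the speciation and upregulation invariants", {
  set.seed(7)
  d <- runif(50, 19, 25)
  b <- runif(50, 450, 800)
  r <- resolve_calcifying_fluid(d, b, 21, 35.5)
  expect_true(all(r$DIC_cf / r$co3_cf > 1))
  expect_true(all(r$omega_cf > 0))
  expect_true(all(r$borate_cf > 0 & r$borate_cf < 4.4e-4))

  # the six treatment means: the fluid is always upregulated above seawater
  # pH (by 0.4 in ambient conditions, more under acidification) and carries
  # 1.5-2.1x the ambient seawater DIC
  ph_sw <- c(8.09, 7.81, 7.63)
  temps <- c(20.9, 20.9, 21.0)
  sw_dic <- carb_from_pH_alk(ph_sw, c(2358, 2358, 2357) * 1e-6,
                             constants = carb_constants(21, 35.5))$DIC
  for (sp in list(c(2.37, 4.41, 31.6, -124), c(4.37, -12.11, 25.8, 98.5))) {
    d11b <- sp[1] * ph_sw + sp[2]
    bca <- sp[3] * d11b + sp[4]
    for (j in 1:3) {
      r <- resolve_calcifying_fluid(d11b[j], bca[j], temps[j], 35.5)
      expect_gt(r$pH_cf - ph_sw[j], 0.3)
      expect_lt(r$pH_cf - ph_sw[j], 1.0)
      if (j == 1) { # ambient offset ~0.4
        expect_gt(r$pH_cf - ph_sw[j], 0.35)
        expect_lt(r$pH_cf - ph_sw[j], 0.5)
      }
      expect_gt(r$DIC_cf / sw_dic[j], 1.5)
      expect_lt(r$DIC_cf / sw_dic[j], 2.1)
    }
  }
})

test_that("reconstruction errors carry the offending colony id", {
  expect_error(
    resolve_calcifying_fluid(45, 618, 20.9, 35.5, colony_id = "AY_pH8.1_03"),
    "AY_pH8.1_03"
  )
})
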