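# analytic slope of the delta-11-B -> pH_cf map, used to calibrate
# colony-level noise from published standard errors of pH_cf
.dphcf_dd11b <- function(d11B, boron = boron_constants()) {
  a <- boron$alpha_B3_B4
  sw <- boron$d11B_seawater
  (1 / log(10)) * (1 / (sw - d11B) + a / (a * d11B - sw + 1000 * (a - 1)))
}

#' Parameters of the synthetic mesocosm experiment generator
#'
#' Describes a 2-species x 3-pH x 12-replicate coral acidification mesocosm:
#' three seawater-pH treatments held in quadruplicate header tanks, each
#' gravity-feeding three incubation tanks that hold one colony per species.
#' Per-colony skeletal geochemistry is generated from species-specific linear
#' responses of delta-11-B to seawater pH and of B/Ca to delta-11-B, with
#' biological (colony + tank) and analytical noise layered on top;
#' calcification rates are generated around per-treatment target means and
#' converted back into buoyant-weight records through the growth-module
#' identities.
#'
#' Colony-level standard deviations are calibrated so that per-treatment
#' standard errors at n = 12 match the `phcf_se`, `bca_se` and
#' `calcification_se` targets: the target SD (`se * sqrt(12)`) is decomposed
#' into analytical noise, the pH-jitter contribution, a header-tank effect
#' (`tank_var_frac` of the colony variance) and the residual colony variance,
#' with a small floor when the printed SE is tighter than the noise budget
#' allows.
#'
#' @param ph_targets Target total-scale pH of the three treatments.
#' @param temperatures Per-treatment temperature, degC.
#' @param ph_tank_sd SD of the realised header-tank pH around its target.
#' @param alkalinity_mean,alkalinity_sd Total alkalinity, umol kg-1.
#' @param salinity Practical salinity, shared by all tanks.
#' @param n_header Header tanks per treatment.
#' @param n_incubation Incubation tanks per header tank.
#' @param d11B_analytical_sd,BCa_analytical_sd Analytical measurement SDs
#'   (permil; umol mol-1).
#' @param tank_var_frac Header-tank variance as a fraction of colony variance.
#' @param species Named list of per-species parameter lists; each has
#'   `d11b_slope`, `d11b_intercept` (delta-11-B vs pH_sw), `bca_slope`,
#'   `bca_intercept` (B/Ca vs delta-11-B), `calcification_mean`,
#'   `calcification_se`, `phcf_se`, `bca_se` (per-treatment vectors).
#' @param allometric_a,allometric_b Surface-area power law used when
#'   back-computing growth records.
#' @param initial_weight_mean,initial_weight_sd Initial dry skeletal weight,
#'   g.
#' @param start_date Start of the incubation (ISO date string).
#' @param duration_days Length of the incubation (8 weeks = 56 d).
#' @param bca_floor_sd,d11b_floor_sd Lower bounds for the colony residual SDs.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(
    ph_targets = c(8.09, 7.81, 7.63),
    temperatures = c(20.9, 20.9, 21.0),
    ph_tank_sd = 0.05,
    alkalinity_mean = 2358, alkalinity_sd = 5,
    salinity = 35.5,
    n_header = 4, n_incubation = 3,
    d11B_analytical_sd = 0.17, BCa_analytical_sd = 18,
    tank_var_frac = 0.10,
    species = list(
      a_youngei = list(
        d11b_slope = 2.37, d11b_intercept = 4.41,
        bca_slope = 31.6, bca_intercept = -124,
        calcification_mean = c(1.97, 1.65, 1.34),
        calcification_se = c(0.13, 0.10, 0.09),
        phcf_se = c(0.01, 0.02, 0.02),
        bca_se = c(6, 8, 10)
      ),
      p_damicornis = list(
        d11b_slope = 4.37, d11b_intercept = -12.11,
        bca_slope = 25.8, bca_intercept = 98.5,
        calcification_mean = c(1.07, 1.00, 0.97),
        calcification_se = c(0.08, 0.08, 0.08),
        phcf_se = c(0.02, 0.02, 0.02),
        bca_se = c(10, 10, 11)
      )
    ),
    allometric_a = 5.2, allometric_b = 0.78,
    initial_weight_mean = 10, initial_weight_sd = 2,
    start_date = "2015-10-26", duration_days = 56,
    bca_floor_sd = 5, d11b_floor_sd = 0.05) {
  n_tr <- length(ph_targets)
  if (length(temperatures) != n_tr) {
    stop("config error: `temperatures` must match `ph_targets` in length",
         call. = FALSE)
  }
  if (n_header < 2 || n_incubation < 1) {
    stop("config error: need >= 2 header tanks per treatment and >= 1 incubation tank per header",
         call. = FALSE)
  }
  for (sp in names(species)) {
    p <- species[[sp]]
    lens <- vapply(p[c("calcification_mean", "calcification_se", "phcf_se",
                       "bca_se")], length, 1L)
    if (any(lens != n_tr)) {
      stop(sprintf("config error: per-treatment vectors of species '%s' must have length %d",
                   sp, n_tr), call. = FALSE)
    }
  }
  stopifnot(ph_tank_sd >= 0, alkalinity_sd >= 0, d11B_analytical_sd >= 0,
            BCa_analytical_sd >= 0, tank_var_frac >= 0)
  out <- as.list(environment())
  out <- out[!vapply(out, is.null, TRUE)]
  out$n_tr <- NULL; out$p <- NULL; out$lens <- NULL; out$sp <- NULL
  class(out) <- "generator_params"
  out
}

# variance partition for one species x treatment cell: returns the colony and
# tank SDs of the biological signal, given a target total SD and the known
# analytical and pH-jitter contributions
.partition_sd <- function(target_sd, analytical_sd, jitter_sd, tank_var_frac,
                          floor_sd) {
  v <- (target_sd^2 - analytical_sd^2 - jitter_sd^2) / (1 + tank_var_frac)
  colony_sd <- sqrt(max(v, floor_sd^2))
  c(colony = colony_sd, tank = sqrt(tank_var_frac) * colony_sd)
}

#' Generate a synthetic coral mesocosm experiment
#'
#' Draws a complete synthetic dataset with the nested tank structure described
#' in [generator_params()]: a seawater-conditions table (one row per
#' incubation tank), a skeletal-geochemistry table and a buoyant-weight growth
#' table (one row per colony). The same seed always yields the same dataset.
#'
#' @param params A [generator_params()] object.
#' @param seed Integer RNG seed.
#' @return A list of class `coral_experiment` with data frames `seawater`
#'   (`tank_id`, `header_tank`, `treatment`, `pH_total`,
#'   `alkalinity_umol_kg`, `temperature_C`, `salinity`), `geochemistry`
#'   (`colony_id`, `species`, `treatment`, `header_tank`, `incubation_tank`,
#'   `d11B_permil`, `BCa_umol_mol`), `growth` (`colony_id`,
#'   `buoyant_g_initial`, `buoyant_g_final`, `date_initial`, `date_final`,
#'   `surface_area_cm2`), plus `params` and `seed`.
#' @examples
#' ex <- generate_experiment(seed = 42)
#' nrow(ex$geochemistry)  # 72 colonies
#' @export
generate_experiment <- function(params = generator_params(), seed = 1) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(seed)
  n_tr <- length(params$ph_targets)
  tr_names <- sprintf("pH%.1f", round(params$ph_targets, 1))

  # header tanks (pH control units)
  header <- data.frame(
    header_tank = sprintf("H%02d", seq_len(n_tr * params$n_header)),
    treatment = rep(tr_names, each = params$n_header),
    tr_idx = rep(seq_len(n_tr), each = params$n_header)
  )
  header$pH_total <- params$ph_targets[header$tr_idx] +
    rnorm(nrow(header), 0, params$ph_tank_sd)
  header$temperature_C <- params$temperatures[header$tr_idx]

  # incubation tanks inherit their header-tank water
  inc <- header[rep(seq_len(nrow(header)), each = params$n_incubation), ]
  inc$tank_id <- sprintf("I%02d", seq_len(nrow(inc)))
  inc$alkalinity_umol_kg <- rnorm(nrow(inc), params$alkalinity_mean,
                                  params$alkalinity_sd)
  inc$salinity <- params$salinity
  seawater <- inc[, c("tank_id", "header_tank", "treatment", "pH_total",
                      "alkalinity_umol_kg", "temperature_C", "salinity")]
  rownames(seawater) <- NULL

  geo <- list()
  gro <- list()
  n_per_cell <- params$n_header * params$n_incubation
  for (sp in names(params$species)) {
    p <- params$species[[sp]]
    sp_tag <- toupper(paste0(substr(strsplit(sp, "_")[[1]], 1, 1),
                             collapse = ""))
    for (j in seq_len(n_tr)) {
      tanks <- inc[inc$tr_idx == j, ]
      temp <- params$temperatures[j]
      mean_d11b <- p$d11b_slope * params$ph_targets[j] + p$d11b_intercept
      deriv <- .dphcf_dd11b(mean_d11b)

      sd_d <- .partition_sd(p$phcf_se[j] * sqrt(n_per_cell) / deriv,
                            params$d11B_analytical_sd,
                            p$d11b_slope * params$ph_tank_sd,
                            params$tank_var_frac, params$d11b_floor_sd)
      bio_d11b_sd <- sqrt(max((p$phcf_se[j] * sqrt(n_per_cell) / deriv)^2 -
                                params$d11B_analytical_sd^2, 0))
      sd_b <- .partition_sd(p$bca_se[j] * sqrt(n_per_cell),
                            params$BCa_analytical_sd,
                            p$bca_slope * max(bio_d11b_sd, 0),
                            0, params$bca_floor_sd)
      sd_c <- .partition_sd(p$calcification_se[j] * sqrt(n_per_cell),
                            0, 0, params$tank_var_frac, 0)

      # header-tank random effects, shared by the 3 colonies of a header
      tank_eff_d <- rnorm(params$n_header, 0, sd_d["tank"])
      tank_eff_c <- rnorm(params$n_header, 0, sd_c["tank"])
      h_idx <- match(tanks$header_tank, unique(tanks$header_tank))

      d11b_true <- p$d11b_slope * tanks$pH_total + p$d11b_intercept +
        tank_eff_d[h_idx] + rnorm(nrow(tanks), 0, sd_d["colony"])
      d11b_meas <- d11b_true + rnorm(nrow(tanks), 0,
                                     params$d11B_analytical_sd)
      bca_true <- p$bca_slope * d11b_true + p$bca_intercept +
        rnorm(nrow(tanks), 0, sd_b["colony"])
      bca_meas <- bca_true + rnorm(nrow(tanks), 0, params$BCa_analytical_sd)
      calc <- p$calcification_mean[j] + tank_eff_c[h_idx] +
        rnorm(nrow(tanks), 0, sd_c["colony"])

      ids <- sprintf("%s_%s_%02d", sp_tag, tr_names[j], seq_len(nrow(tanks)))
      geo[[paste(sp, j)]] <- data.frame(
        colony_id = ids, species = sp, treatment = tr_names[j],
        header_tank = tanks$header_tank, incubation_tank = tanks$tank_id,
        d11B_permil = d11b_meas, BCa_umol_mol = bca_meas
      )

      # back-compute buoyant weights from the target rates
      w0 <- pmax(rnorm(nrow(tanks), params$initial_weight_mean,
                       params$initial_weight_sd),
                 params$initial_weight_mean / 3)
      sa <- allometric_surface_area(w0, params$allometric_a,
                                    params$allometric_b)
      rho <- seawater_density(temp, params$salinity)
      dry_gain <- calc * sa * params$duration_days / 1000 # g
      factor <- 1 - rho / 2.93
      gro[[paste(sp, j)]] <- data.frame(
        colony_id = ids,
        buoyant_g_initial = w0 * factor,
        buoyant_g_final = (w0 + dry_gain) * factor,
        date_initial = as.character(as.Date(params$start_date)),
        date_final = as.character(as.Date(params$start_date) +
                                    params$duration_days),
        surface_area_cm2 = sa
      )
    }
  }
  out <- list(seawater = seawater,
              geochemistry = do.call(rbind, c(geo, make.row.names = FALSE)),
              growth = do.call(rbind, c(gro, make.row.names = FALSE)),
              params = params, seed = seed)
  class(out) <- "coral_experiment"
  out
}

#' @export
print.coral_experiment <- function(x, ...) {
  cat(sprintf("Synthetic mesocosm experiment (seed %s): %d incubation tanks, %d colonies\n",
              format(x$seed), nrow(x$seawater), nrow(x$geochemistry)))
  cat("  treatments:", paste(unique(x$seawater$treatment), collapse = ", "),
      "\n  species:  ", paste(unique(x$geochemistry$species), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a synthetic experiment to CSV files
#'
#' Writes `seawater.csv`, `geochemistry.csv` and `growth.csv` plus a
#' `params.yaml` snapshot (including the seed) into a directory.
#'
#' @param experiment A `coral_experiment` from [generate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "coral_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("seawater.csv", "geochemistry.csv", "growth.csv",
                            "params.yaml"))
  write.csv(experiment$seawater, paths[1], row.names = FALSE)
  write.csv(experiment$geochemistry, paths[2], row.names = FALSE)
  write.csv(experiment$growth, paths[3], row.names = FALSE)
  snap <- unclass(experiment$params)
  snap$seed <- experiment$seed
  yaml::write_yaml(snap, paths[4])
  invisible(paths)
}
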