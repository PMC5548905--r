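.read_table <- function(x, what, required) {
  if (is.character(x)) {
    if (!file.exists(x)) {
      stop(sprintf("%s file not found: %s", what, x), call. = FALSE)
    }
    x <- read.csv(x, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x)) {
    stop(sprintf("%s input must be a data frame or CSV path", what),
         call. = FALSE)
  }
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s table is missing columns: %s", what,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x
}

.check_rows_finite <- function(tab, cols, what) {
  for (cc in cols) {
    bad <- which(!is.finite(tab[[cc]]))
    if (length(bad) > 0) {
      stop(sprintf("%s table: non-numeric or missing `%s` in row(s) %s",
                   what, cc, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Read a pipeline run configuration from YAML
#'
#' The configuration mirrors the arguments of [run_pipeline()]: file paths
#' (`seawater`, `geochemistry`, `growth`), `salinity_default`, a `constants`
#' block with formulation names ([carb_constants()]), a `boron` block
#' ([boron_constants()]), an `mc` block ([mc_spec()]), `out_dir` and `seed`.
#' Unknown formulation names are rejected here rather than mid-pipeline.
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (f in c("seawater", "geochemistry", "growth")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop(sprintf("config error: `%s` file does not exist: %s", f, cfg[[f]]),
           call. = FALSE)
    }
  }
  if (!is.null(cfg$constants)) {
    do.call(carb_constants, c(list(temperature = 21, salinity = 35.5),
                              cfg$constants)) # validates the names
  }
  if (!is.null(cfg$boron)) do.call(boron_constants, cfg$boron)
  if (!is.null(cfg$mc)) cfg$mc <- do.call(mc_spec, cfg$mc)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full proxy analysis pipeline
#'
#' End-to-end analysis of a mesocosm experiment: solves the seawater carbonate
#' chemistry per tank, reconstructs the per-colony calcifying fluid from
#' skeletal boron geochemistry (with optional Monte-Carlo uncertainties),
#' computes buoyant-weight calcification rates, summarises by species and
#' treatment, and applies the statistical design (header-tank gate, one-way
#' ANOVA + Tukey HSD, proxy regressions).
#'
#' @param geochemistry,growth,seawater Data frames or CSV paths with the
#'   column layouts produced by [generate_experiment()] /
#'   [write_experiment()]. `growth` may be `NULL` to skip calcification.
#' @param mc An [mc_spec()] for per-colony uncertainties, or `NULL` to skip
#'   the Monte-Carlo step.
#' @param boron A [boron_constants()] object.
#' @param constants_options Named list passed to [carb_constants()]
#'   (formulation choices).
#' @param salinity_default Salinity used where the seawater table lacks a
#'   `salinity` column.
#' @param seed RNG seed for the Monte-Carlo step.
#' @param out_dir Optional directory; when given, writes `colonies.csv`,
#'   `treatment_summary.csv`, `anova.csv`, `tukey.csv`, `regressions.csv`,
#'   `seawater_chemistry.csv` and `provenance.yaml`. Outputs are
#'   byte-identical across reruns with the same inputs, config and seed.
#' @return A list of class `coral_pipeline` with elements
#'   `seawater_chemistry` (per-tank solved CO2 system), `colonies`
#'   (per-colony reconstruction + rates + MC sds), `summary` (per species x
#'   treatment mean and SE of calcification, pH_cf, DIC_cf, omega_cf),
#'   `stats` (per-response tank gate, treatment test, Tukey), `regressions`
#'   (per-species linear fits of d11B and pH_cf on seawater pH), and
#'   `provenance`.
#' @examples
#' ex <- generate_experiment(seed = 42)
#' res <- run_pipeline(ex$geochemistry, ex$growth, ex$seawater, mc = NULL)
#' res$summary
#' @export
run_pipeline <- function(geochemistry, growth = NULL, seawater,
                         mc = mc_spec(), boron = boron_constants(),
                         constants_options = list(),
                         salinity_default = 35.5, seed = NULL,
                         out_dir = NULL) {
  geo <- .read_table(geochemistry, "geochemistry",
                     c("colony_id", "species", "treatment", "header_tank",
                       "incubation_tank", "d11B_permil", "BCa_umol_mol"))
  sw <- .read_table(seawater, "seawater",
                    c("tank_id", "pH_total", "alkalinity_umol_kg",
                      "temperature_C"))
  if (is.null(sw$salinity)) sw$salinity <- salinity_default
  .check_rows_finite(sw, c("pH_total", "alkalinity_umol_kg", "temperature_C",
                           "salinity"), "seawater")
  .check_rows_finite(geo, c("d11B_permil", "BCa_umol_mol"), "geochemistry")

  # per-tank seawater carbonate chemistry
  kw_list <- lapply(seq_len(nrow(sw)), function(i) {
    do.call(carb_constants, c(list(temperature = sw$temperature_C[i],
                                   salinity = sw$salinity[i]),
                              constants_options))
  })
  sw_chem <- do.call(rbind, lapply(seq_len(nrow(sw)), function(i) {
    sp <- carb_from_pH_alk(sw$pH_total[i], sw$alkalinity_umol_kg[i] * 1e-6,
                           constants = kw_list[[i]])
    data.frame(tank_id = sw$tank_id[i], pH_total = sw$pH_total[i],
               alkalinity_umol_kg = sw$alkalinity_umol_kg[i],
               temperature_C = sw$temperature_C[i],
               salinity = sw$salinity[i],
               DIC_umol_kg = sp$DIC * 1e6, pCO2_uatm = sp$pCO2_uatm,
               CO3_umol_kg = sp$CO3 * 1e6,
               omega_aragonite = sp$omega_aragonite)
  }))

  m <- match(geo$incubation_tank, sw$tank_id)
  if (anyNA(m)) {
    stop(sprintf("geochemistry table: incubation_tank not in seawater table in row(s) %s",
                 paste(utils::head(which(is.na(m)), 5), collapse = ", ")),
         call. = FALSE)
  }
  colonies <- cbind(geo, pH_sw = sw$pH_total[m],
                    temperature_C = sw$temperature_C[m],
                    salinity = sw$salinity[m])

  # calcifying-fluid reconstruction, grouped by (T, S) so constants are reused
  key <- paste(colonies$temperature_C, colonies$salinity)
  cf <- vector("list", nrow(colonies))
  for (kk in unique(key)) {
    idx <- which(key == kk)
    kset <- do.call(carb_constants,
                    c(list(temperature = colonies$temperature_C[idx[1]],
                           salinity = colonies$salinity[idx[1]]),
                      constants_options))
    cf[[idx[1]]] <- resolve_calcifying_fluid(
      colonies$d11B_permil[idx], colonies$BCa_umol_mol[idx],
      boron = boron, constants = kset,
      colony_id = colonies$colony_id[idx])
    cf[[idx[1]]]$.idx <- idx
  }
  cf <- do.call(rbind, cf[!vapply(cf, is.null, TRUE)])
  cf <- cf[order(cf$.idx), ]
  colonies$pH_cf <- cf$pH_cf
  colonies$co3_cf_umol_kg <- cf$co3_cf * 1e6
  colonies$DIC_cf_umol_kg <- cf$DIC_cf * 1e6
  colonies$omega_cf <- cf$omega_cf

  if (!is.null(mc)) {
    if (!is.null(seed)) set.seed(seed)
    mc_run <- mc
    mc_run$seed <- NULL # one RNG stream across colonies, seeded above
    un <- lapply(seq_len(nrow(colonies)), function(i) {
      kset <- do.call(carb_constants,
                      c(list(temperature = colonies$temperature_C[i],
                             salinity = colonies$salinity[i]),
                        constants_options))
      propagate_uncertainty(colonies$d11B_permil[i],
                            colonies$BCa_umol_mol[i],
                            spec = mc_run, boron = boron,
                            constants = kset)$summary
    })
    colonies$pH_cf_sd <- vapply(un, function(s) s$sd[s$quantity == "pH_cf"], 1)
    colonies$DIC_cf_sd_umol_kg <-
      vapply(un, function(s) s$sd[s$quantity == "DIC_cf"], 1) * 1e6
    colonies$omega_cf_sd <-
      vapply(un, function(s) s$sd[s$quantity == "omega_cf"], 1)
  }

  if (!is.null(growth)) {
    gr <- .read_table(growth, "growth",
                      c("colony_id", "buoyant_g_initial", "buoyant_g_final"))
    .check_rows_finite(gr, c("buoyant_g_initial", "buoyant_g_final"),
                       "growth")
    gm <- match(colonies$colony_id, gr$colony_id)
    if (anyNA(gm)) {
      stop(sprintf("growth table: no record for colony id(s) %s",
                   paste(utils::head(colonies$colony_id[is.na(gm)], 5),
                         collapse = ", ")), call. = FALSE)
    }
    gr <- gr[gm, ]
    rho <- seawater_density(colonies$temperature_C, colonies$salinity)
    days <- if (!is.null(gr$date_initial) && !is.null(gr$date_final)) {
      as.numeric(as.Date(gr$date_final) - as.Date(gr$date_initial))
    } else {
      56
    }
    colonies$calcification_mg_cm2_d <- net_calcification(
      gr$buoyant_g_initial, gr$buoyant_g_final,
      surface_area = gr$surface_area_cm2, days = days,
      seawater_density = rho)
  }

  resp_cols <- c(calcification = "calcification_mg_cm2_d", pH_cf = "pH_cf",
                 DIC_cf = "DIC_cf_umol_kg", omega_cf = "omega_cf")
  resp_cols <- resp_cols[resp_cols %in% names(colonies)]

  # per species x treatment summary (treatments ordered by descending pH)
  cell_means <- do.call(rbind, lapply(
    split(colonies, list(colonies$species, colonies$treatment),
          drop = TRUE),
    function(d) {
      row <- data.frame(species = d$species[1], treatment = d$treatment[1],
                        n = nrow(d))
      for (nm in names(resp_cols)) {
        x <- d[[resp_cols[nm]]]
        row[[paste0(nm, "_mean")]] <- mean(x)
        row[[paste0(nm, "_se")]] <- sd(x) / sqrt(length(x))
      }
      row
    }))
  # treatments are named pH8.1 > pH7.8 > pH7.6: descending lexicographic works
  cell_means <- cell_means[order(cell_means$species,
                                 cell_means$treatment,
                                 decreasing = c(FALSE, TRUE),
                                 method = "radix"), ]
  rownames(cell_means) <- NULL

  # statistical design per species and response
  stats_tabs <- list()
  for (sp in unique(colonies$species)) {
    d <- colonies[colonies$species == sp, ]
    for (nm in names(resp_cols)) {
      gate <- tank_effect_gate(d, resp_cols[nm])
      test <- treatment_test(d, resp_cols[nm])
      stats_tabs[[paste(sp, nm, sep = ".")]] <-
        list(species = sp, response = nm, gate = gate, test = test)
    }
  }

  regressions <- do.call(rbind, lapply(unique(colonies$species), function(sp) {
    d <- colonies[colonies$species == sp, ]
    fits <- list(d11B_vs_pHsw = linear_fit(d$pH_sw, d$d11B_permil),
                 pHcf_vs_pHsw = linear_fit(d$pH_sw, d$pH_cf))
    do.call(rbind, lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      data.frame(species = sp, fit = nm, slope = f$slope,
                 slope_se = f$slope_se, intercept = f$intercept,
                 intercept_se = f$intercept_se, p_value = f$p_value,
                 r_squared = f$r_squared)
    }))
  }))

  provenance <- list(
    package = "coralcarb",
    version = as.character(packageVersion("coralcarb")),
    seed = seed,
    salinity_default = salinity_default,
    constants = as.list(kw_list[[1]]$provenance),
    boron = unclass(boron),
    mc = if (!is.null(mc)) unclass(mc) else NULL,
    n_colonies = nrow(colonies)
  )

  out <- list(seawater_chemistry = sw_chem, colonies = colonies,
              summary = cell_means, stats = stats_tabs,
              regressions = regressions, provenance = provenance)
  class(out) <- "coral_pipeline"

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(sw_chem, file.path(out_dir, "seawater_chemistry.csv"),
              row.names = FALSE)
    write.csv(colonies, file.path(out_dir, "colonies.csv"),
              row.names = FALSE)
    write.csv(cell_means, file.path(out_dir, "treatment_summary.csv"),
              row.names = FALSE)
    anova_tab <- do.call(rbind, lapply(stats_tabs, function(s) {
      data.frame(species = s$species, response = s$response,
                 tank_p = s$gate$p_tank, tank_decision = s$gate$decision,
                 treatment_p = s$test$p_value,
                 treatment_p_over_tank = s$gate$p_treatment_over_tank)
    }))
    write.csv(anova_tab, file.path(out_dir, "anova.csv"), row.names = FALSE)
    tukey_tab <- do.call(rbind, lapply(stats_tabs, function(s) {
      cbind(species = s$species, response = s$response, s$test$tukey)
    }))
    write.csv(tukey_tab, file.path(out_dir, "tukey.csv"), row.names = FALSE)
    write.csv(regressions, file.path(out_dir, "regressions.csv"),
              row.names = FALSE)
    yaml::write_yaml(provenance, file.path(out_dir, "provenance.yaml"))
  }
  out
}

#' @export
print.coral_pipeline <- function(x, ...) {
  cat("Coral calcifying-fluid proxy pipeline\n")
  cat(sprintf("  %d tanks, %d colonies\n", nrow(x$seawater_chemistry),
              nrow(x$colonies)))
  cat("\nTreatment summary:\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
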