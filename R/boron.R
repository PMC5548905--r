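#' Boron proxy calibration constants
#'
#' Bundles the constants of the two skeletal boron proxies: the delta-11-B pH
#' proxy (seawater boron isotopic composition and the boric-acid/borate
#' fractionation factor) and the B/Ca carbonate-ion proxy (distribution
#' coefficient amplitude and its pH sensitivity from inorganic aragonite
#' precipitation experiments).
#'
#' The distribution coefficient is \eqn{K_D = K_{D,0} \exp(-k_{KD} [H^+])}.
#' `kd_h_unit` selects the unit of \eqn{[H^+]} inside the exponent: with
#' `"mol"` (the default) the exponential is effectively 1 at seawater-like pH,
#' which is the reading that reproduces published coral calcifying-fluid
#' reconstructions; with `"nmol"` the coefficient follows the
#' inorganic-calibration convention and K_D decreases by ~6% per 3 nmol kg-1
#' of \[H+\]. See the package vignette for the numerical consequences.
#'
#' @param d11B_seawater Seawater delta-11-B, permil (default 39.61).
#' @param alpha_B3_B4 Boric-acid/borate isotopic fractionation factor
#'   (default 1.0272; must exceed 1).
#' @param KD0 Distribution-coefficient amplitude, mol mol-1 scale
#'   (default 2.97e-3).
#' @param KD0_sd Optional 1-sigma uncertainty of `KD0` (default 0.17e-3 / 1.96,
#'   from the published 95% CI); not used unless requested by the Monte-Carlo
#'   layer.
#' @param k_KD Exponent coefficient (default 0.0202), per unit of \[H+\] in
#'   `kd_h_unit`.
#' @param kd_h_unit `"mol"` or `"nmol"`, unit of \[H+\] in the K_D exponent.
#' @return A list of class `boron_constants`.
#' @export
boron_constants <- function(d11B_seawater = 39.61,
                            alpha_B3_B4 = 1.0272,
                            KD0 = 2.97e-3,
                            KD0_sd = 0.17e-3 / 1.96,
                            k_KD = 0.0202,
                            kd_h_unit = c("mol", "nmol")) {
  stopifnot(d11B_seawater > 0, alpha_B3_B4 > 1, KD0 > 0, KD0_sd >= 0)
  out <- list(d11B_seawater = d11B_seawater, alpha_B3_B4 = alpha_B3_B4,
              KD0 = KD0, KD0_sd = KD0_sd, k_KD = k_KD,
              kd_h_unit = match.arg(kd_h_unit))
  class(out) <- "boron_constants"
  out
}

#' Calcifying-fluid pH from skeletal delta-11-B
#'
#' The boron-isotope pH proxy: assuming only the borate ion is incorporated
#' into skeletal aragonite, the fluid pH is
#' \deqn{pH_{cf} = pK_B - \log_{10}\!\left[\frac{\delta^{11}B_{sw} -
#'   \delta^{11}B}{\alpha\,\delta^{11}B - \delta^{11}B_{sw} +
#'   1000(\alpha - 1)}\right]}
#' with pK_B evaluated at the ambient temperature and salinity (Dickson 1990).
#'
#' @param d11B Skeletal delta-11-B, permil vs NIST 951. Vectorised. Must lie
#'   strictly between the value that zeroes the denominator
#'   (\eqn{(\delta^{11}B_{sw} - 1000(\alpha-1))/\alpha}) and
#'   `d11B_seawater`.
#' @param temperature,salinity Conditions for pK_B.
#' @param boron A [boron_constants()] object.
#' @param constants Optional [carb_constants()] object (for pK_B); computed
#'   from `temperature`/`salinity` when absent.
#' @return Total-scale calcifying-fluid pH. Strictly increasing in `d11B`.
#' @examples
#' phcf_from_d11b(23.58, temperature = 20.9, salinity = 35.5)  # ~8.51
#' @export
phcf_from_d11b <- function(d11B, temperature = NULL, salinity = NULL,
                           boron = boron_constants(), constants = NULL) {
  if (is.null(constants)) constants <- carb_constants(temperature, salinity)
  a <- boron$alpha_B3_B4
  sw <- boron$d11B_seawater
  num <- sw - d11B
  den <- a * d11B - sw + 1000 * (a - 1)
  if (any(num <= 0)) {
    stop("numerator non-positive: d11B must be below d11B_seawater",
         call. = FALSE)
  }
  if (any(den <= 0)) {
    stop(sprintf("denominator non-positive: d11B must exceed %.3f permil",
                 (sw - 1000 * (a - 1)) / a), call. = FALSE)
  }
  -log10(constants$KB) - log10(num / den)
}

#' Skeletal delta-11-B implied by a calcifying-fluid pH
#'
#' Algebraic inverse of [phcf_from_d11b()], used for round-trip checks and
#' for synthesising skeletal compositions from target fluid pH values.
#'
#' @param pH_cf Total-scale calcifying-fluid pH, in \[7, 10\]. Vectorised.
#' @inheritParams phcf_from_d11b
#' @return delta-11-B in permil; strictly increasing in `pH_cf`, and
#'   `phcf_from_d11b(d11b_from_phcf(p)) == p` to ~1e-12.
#' @export
d11b_from_phcf <- function(pH_cf, temperature = NULL, salinity = NULL,
                           boron = boron_constants(), constants = NULL) {
  if (is.null(constants)) constants <- carb_constants(temperature, salinity)
  .check_range(pH_cf, 7, 10, "pH_cf")
  a <- boron$alpha_B3_B4
  sw <- boron$d11B_seawater
  r <- 10^(-log10(constants$KB) - pH_cf) # (sw - x)/(a x - sw + 1000(a-1))
  (sw * (1 + r) - 1000 * r * (a - 1)) / (1 + r * a)
}

#' Calcifying-fluid carbonate ion from B/Ca and pH_cf
#'
#' The B/Ca carbonate-ion proxy from inorganic aragonite precipitation
#' experiments:
#' \deqn{[CO_3^{2-}]_{cf} = K_D \, [B(OH)_4^-]_{cf} / (B/Ca)}
#' where the fluid borate concentration follows from total (seawater-derived)
#' boron speciated at the fluid pH,
#' \eqn{[B(OH)_4^-]_{cf} = B_T / (1 + [H^+]_{cf}/K_B)}, and
#' \eqn{K_D = K_{D,0}\exp(-k_{KD}[H^+])} (see [boron_constants()] for the
#' \[H+\] unit convention).
#'
#' @param BCa Skeletal B/Ca in umol mol-1, positive. Vectorised.
#' @param pH_cf Total-scale calcifying-fluid pH. Vectorised.
#' @inheritParams phcf_from_d11b
#' @return Calcifying-fluid carbonate-ion concentration, mol kg-1.
#' @examples
#' co3cf_from_bca(618, 8.51, temperature = 20.9, salinity = 35.5) * 1e6
#' @export
co3cf_from_bca <- function(BCa, pH_cf, temperature = NULL, salinity = NULL,
                           boron = boron_constants(), constants = NULL) {
  if (is.null(constants)) constants <- carb_constants(temperature, salinity)
  if (any(!is.finite(BCa)) || any(BCa <= 0)) {
    stop("`BCa` must be positive (umol mol-1)", call. = FALSE)
  }
  h <- 10^(-pH_cf)
  borate <- constants$B_total / (1 + h / constants$KB)
  h_exp <- if (boron$kd_h_unit == "nmol") h * 1e9 else h
  KD <- boron$KD0 * exp(-boron$k_KD * h_exp)
  KD * borate / (BCa * 1e-6)
}

#' Full calcifying-fluid reconstruction from skeletal boron geochemistry
#'
#' Composes the proxy chain: delta-11-B -> pH_cf, then (B/Ca, pH_cf) ->
#' \[CO3\]_cf, then DIC_cf via the carbonic-acid speciation identity and
#' the aragonite saturation state Omega_cf.
#'
#' @param d11B Skeletal delta-11-B, permil. Vectorised.
#' @param BCa Skeletal B/Ca, umol mol-1. Vectorised (recycled with `d11B`).
#' @param temperature,salinity Ambient conditions; used for pK_B, the
#'   carbonic-acid constants and the solubility product.
#' @param boron A [boron_constants()] object.
#' @param constants Optional [carb_constants()] object.
#' @param colony_id Optional identifiers used to contextualise errors.
#' @return A `data.frame` of class `calcifying_fluid` with columns `d11B`,
#'   `BCa`, `pH_cf`, `borate_cf`, `co3_cf`, `DIC_cf` (mol kg-1) and
#'   `omega_cf`.
#' @examples
#' resolve_calcifying_fluid(23.58, 618, temperature = 20.9, salinity = 35.5)
#' @export
resolve_calcifying_fluid <- function(d11B, BCa, temperature = NULL,
                                     salinity = NULL,
                                     boron = boron_constants(),
                                     constants = NULL, colony_id = NULL) {
  if (is.null(constants)) constants <- carb_constants(temperature, salinity)
  res <- tryCatch({
    pH_cf <- phcf_from_d11b(d11B, boron = boron, constants = constants)
    co3 <- co3cf_from_bca(BCa, pH_cf, boron = boron, constants = constants)
    h <- 10^(-pH_cf)
    data.frame(
      d11B = d11B, BCa = BCa, pH_cf = pH_cf,
      borate_cf = constants$B_total / (1 + h / constants$KB),
      co3_cf = co3,
      DIC_cf = dic_from_pH_co3(pH_cf, co3, constants),
      omega_cf = omega_aragonite(co3, constants)
    )
  }, error = function(e) {
    if (!is.null(colony_id)) {
      stop(sprintf("calcifying-fluid reconstruction failed for colony %s: %s",
                   paste(colony_id, collapse = ","), conditionMessage(e)),
           call. = FALSE)
    }
    stop(e)
  })
  attr(res, "constants") <- constants
  attr(res, "boron") <- boron
  class(res) <- c("calcifying_fluid", class(res))
  res
}
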