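#' Solve the seawater CO2 system from pH and total alkalinity
#'
#' Computes the full carbonate speciation of a seawater sample from its
#' total-scale pH and total alkalinity, the measurement pair of mesocosm
#' pH-manipulation experiments. The alkalinity model is
#' \deqn{A_T = [HCO_3^-] + 2[CO_3^{2-}] + [B(OH)_4^-] + [OH^-] - [H^+]}
#' (phosphate, silicate and ammonia omitted, appropriate when nutrients are
#' not measured). pCO2 is the CO2(aq) concentration divided by the Weiss
#' solubility K0.
#'
#' @param pH_total Total-scale pH, in \[6, 9.5\]. Vectorised.
#' @param alkalinity Total alkalinity in mol kg-1 (e.g. 2358e-6). Vectorised.
#' @param temperature,salinity Conditions used to evaluate the constants when
#'   `constants` is not supplied.
#' @param constants Optional [carb_constants()] object; overrides
#'   `temperature`/`salinity`.
#' @return A `data.frame` of class `carb_speciation` with columns `pH_total`,
#'   `alkalinity`, `DIC`, `CO2aq`, `HCO3`, `CO3` (mol kg-1), `pCO2_uatm` and
#'   `omega_aragonite`; the constants are attached as attribute `"constants"`.
#' @examples
#' carb_from_pH_alk(8.09, 2358e-6, temperature = 20.9, salinity = 35.5)
#' @seealso [dic_from_pH_co3()], [omega_aragonite()], [alkalinity_from_speciation()]
#' @export
carb_from_pH_alk <- function(pH_total, alkalinity, temperature = NULL,
                             salinity = NULL, constants = NULL) {
  if (is.null(constants)) {
    constants <- carb_constants(temperature, salinity)
  }
  .check_seawater(constants$temperature, constants$salinity,
                  pH_total = pH_total, alkalinity = alkalinity)
  h <- 10^(-pH_total)
  borate <- constants$B_total / (1 + h / constants$KB)
  oh <- constants$Kw / h
  # carbonate alkalinity left once the non-carbonate terms are removed
  ca <- alkalinity - borate - oh + h
  if (any(ca <= 0)) {
    stop("no positive-DIC solution: carbonate alkalinity is non-positive",
         call. = FALSE)
  }
  hco3 <- ca / (1 + 2 * constants$K2 / h)
  co3 <- constants$K2 * hco3 / h
  co2 <- h * hco3 / constants$K1
  out <- data.frame(
    pH_total = pH_total,
    alkalinity = alkalinity,
    DIC = co2 + hco3 + co3,
    CO2aq = co2,
    HCO3 = hco3,
    CO3 = co3,
    pCO2_uatm = co2 / constants$K0 * 1e6,
    omega_aragonite = omega_aragonite(co3, constants)
  )
  attr(out, "constants") <- constants
  class(out) <- c("carb_speciation", class(out))
  out
}

#' Recompute total alkalinity from a solved speciation
#'
#' Conservation check for [carb_from_pH_alk()]: evaluates the alkalinity
#' balance from the returned species. Round-trips to the input alkalinity to
#' numerical precision.
#'
#' @param speciation A `carb_speciation` data frame.
#' @param constants The constants to use; defaults to those attached to
#'   `speciation`.
#' @return Total alkalinity in mol kg-1.
#' @export
alkalinity_from_speciation <- function(speciation,
                                       constants = attr(speciation, "constants")) {
  h <- 10^(-speciation$pH_total)
  borate <- constants$B_total / (1 + h / constants$KB)
  speciation$HCO3 + 2 * speciation$CO3 + borate + constants$Kw / h - h
}

#' DIC from pH and carbonate-ion concentration
#'
#' Converts a (pH, \[CO3^2-\]) pair into dissolved inorganic carbon using the
#' carbonic-acid dissociation constants:
#' \deqn{DIC = [CO_3^{2-}] (1 + [H^+]/K_2 + [H^+]^2/(K_1 K_2))}
#' This is the step that turns the proxy-reconstructed calcifying-fluid pH and
#' carbonate-ion concentration into DIC_cf.
#'
#' @param pH Total-scale pH. Vectorised.
#' @param co3 Carbonate-ion concentration, mol kg-1, non-negative. Vectorised.
#' @param constants A [carb_constants()] object.
#' @return DIC in mol kg-1.
#' @examples
#' k <- carb_constants(20.9, 35.5)
#' dic_from_pH_co3(8.51, 890e-6, k) * 1e6  # ~3824 umol kg-1
#' @export
dic_from_pH_co3 <- function(pH, co3, constants) {
  if (any(!is.finite(co3)) || any(co3 < 0)) {
    stop("`co3` must be non-negative (mol kg-1)", call. = FALSE)
  }
  h <- 10^(-pH)
  co3 * (1 + h / constants$K2 + h^2 / (constants$K1 * constants$K2))
}

#' Aragonite saturation state
#'
#' \deqn{\Omega_{arag} = [Ca^{2+}][CO_3^{2-}] / K_{sp}^{arag}} with calcium
#' proportional to salinity and the Mucci (1983) solubility product.
#'
#' @param co3 Carbonate-ion concentration, mol kg-1, non-negative. Vectorised.
#' @param constants A [carb_constants()] object.
#' @return Dimensionless saturation state; 0 iff `co3` is 0.
#' @export
omega_aragonite <- function(co3, constants) {
  if (any(!is.finite(co3)) || any(co3 < 0)) {
    stop("`co3` must be non-negative (mol kg-1)", call. = FALSE)
  }
  co3 * constants$Ca_total / constants$Ksp_aragonite
}
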