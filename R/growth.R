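#' Surface-pressure seawater density (EOS-80)
#'
#' International one-atmosphere equation of state of seawater (UNESCO 1983),
#' needed to convert buoyant weights to dry skeletal mass.
#'
#' @param temperature Temperature, degrees Celsius.
#' @param salinity Practical salinity.
#' @return Density in g cm-3 (about 1.0249 at 21 degC, S 35.5).
#' @export
seawater_density <- function(temperature, salinity) {
  .check_seawater(temperature, salinity)
  t <- temperature
  S <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  A <- 8.24493e-1 - 4.0899e-3 * t + 7.6438e-5 * t^2 -
    8.2467e-7 * t^3 + 5.3875e-9 * t^4
  B <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  C <- 4.8314e-4
  (rho_w + A * S + B * S^1.5 + C * S^2) / 1000
}

#' Dry skeletal mass change from a buoyant-weight change
#'
#' Archimedes: a submerged aragonite skeleton of dry mass m weighs
#' m (1 - rho_sw / rho_arag), so
#' \deqn{\Delta m_{dry} = \Delta m_{buoyant} / (1 - \rho_{sw}/\rho_{arag})}
#'
#' @param delta_buoyant Buoyant-weight change, g. Vectorised.
#' @param seawater_density Seawater density, g cm-3.
#' @param aragonite_density Skeletal density, g cm-3 (default 2.93, aragonite).
#' @return Dry-mass change in g (linear in `delta_buoyant`).
#' @examples
#' dry_from_buoyant(1, 1.025)  # 1.538 g
#' @export
dry_from_buoyant <- function(delta_buoyant, seawater_density,
                             aragonite_density = 2.93) {
  if (any(aragonite_density <= seawater_density)) {
    stop("aragonite_density must exceed seawater_density", call. = FALSE)
  }
  delta_buoyant / (1 - seawater_density / aragonite_density)
}

#' Net calcification rate from buoyant weights
#'
#' Converts initial/final buoyant weights into a surface-area-normalised net
#' calcification rate (mg CaCO3 cm-2 d-1). Negative rates (net dissolution)
#' are permitted.
#'
#' @param buoyant_initial,buoyant_final Buoyant weights, g (positive).
#' @param surface_area Tissue surface area, cm2 (positive).
#' @param date_initial,date_final `Date`s (or strings coercible to `Date`)
#'   bounding the incubation; alternatively give `days` directly.
#' @param days Elapsed time in days; overrides the dates when supplied.
#' @param seawater_density Seawater density, g cm-3 (default for 21 degC,
#'   S 35.5).
#' @param aragonite_density Skeletal density, g cm-3.
#' @return Net calcification, mg CaCO3 cm-2 d-1. Vectorised over all
#'   arguments.
#' @examples
#' net_calcification(50, 53.59, surface_area = 50, days = 56)  # ~1.97
#' @export
net_calcification <- function(buoyant_initial, buoyant_final, surface_area,
                              date_initial = NULL, date_final = NULL,
                              days = NULL,
                              seawater_density = coralcarb::seawater_density(21, 35.5),
                              aragonite_density = 2.93) {
  if (any(buoyant_initial <= 0) || any(buoyant_final <= 0)) {
    stop("buoyant weights must be positive", call. = FALSE)
  }
  if (any(surface_area <= 0)) {
    stop("`surface_area` must be positive (cm2)", call. = FALSE)
  }
  if (is.null(days)) {
    if (is.null(date_initial) || is.null(date_final)) {
      stop("give either `days` or both dates", call. = FALSE)
    }
    days <- as.numeric(as.Date(date_final) - as.Date(date_initial))
  }
  if (any(days <= 0)) {
    stop("elapsed time must be positive (date_final after date_initial)",
         call. = FALSE)
  }
  dry <- dry_from_buoyant(buoyant_final - buoyant_initial,
                          seawater_density, aragonite_density)
  dry * 1000 / surface_area / days
}

#' Allometric tissue surface area from dry skeletal weight
#'
#' Power-law relation surface_area = a * weight^b used to normalise
#' calcification when surface areas are not measured directly. The
#' coefficients are species- and site-specific and must be supplied (no
#' universal default exists).
#'
#' @param weight Dry skeletal weight, g.
#' @param a Coefficient (cm2 g-b), positive.
#' @param b Exponent, in (0, 1.5\].
#' @return Surface area, cm2.
#' @export
allometric_surface_area <- function(weight, a, b) {
  stopifnot(a > 0, b > 0, b <= 1.5)
  if (any(weight <= 0)) stop("`weight` must be positive (g)", call. = FALSE)
  a * weight^b
}
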