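#' Temperature-dependent parameters of the abiotic precipitation rate law
#'
#' The bio-inorganic calcification model treats skeletal growth as abiotic
#' aragonite precipitation from the calcifying fluid, with the empirical rate
#' law G = k_a (Omega_cf - 1)^n. Both parameters depend on temperature:
#' \deqn{k_a = -0.0177 T^2 + 1.47 T + 14.9, \qquad n = 0.0628 T + 0.0985}
#'
#' @param temperature Temperature, degrees Celsius (parameters positive over
#'   roughly 15-32 degC).
#' @return A list of class `iphrac_params` with elements `temperature`, `k_a`
#'   and `n`.
#' @examples
#' iphrac_params(21)  # k_a 37.964, n 1.4173
#' @export
iphrac_params <- function(temperature) {
  .check_range(temperature, -2, 40, "temperature")
  k_a <- -0.0177 * temperature^2 + 1.47 * temperature + 14.9
  n <- 0.0628 * temperature + 0.0985
  if (any(k_a <= 0) || any(n <= 0)) {
    stop("rate-law parameters non-positive at this temperature", call. = FALSE)
  }
  structure(list(temperature = temperature, k_a = k_a, n = n),
            class = "iphrac_params")
}

#' Abiotic precipitation rate at a calcifying-fluid saturation state
#'
#' Evaluates G = k_a (Omega_cf - 1)^n. The law is defined for supersaturated
#' fluid only (Omega >= 1); G(1) = 0 and G is strictly increasing in Omega.
#' Units are model rate units; use `scale` to align the curve with measured
#' calcification (mg cm-2 d-1) when plotting them together.
#'
#' @param omega_cf Calcifying-fluid aragonite saturation state, >= 1.
#'   Vectorised.
#' @param temperature Temperature, degrees Celsius.
#' @param scale Optional multiplicative factor applied to G (default 1).
#' @return Model precipitation rate.
#' @examples
#' iphrac_rate(14, 21) / iphrac_rate(10.2, 21)  # (13/9.2)^1.4173
#' @export
iphrac_rate <- function(omega_cf, temperature, scale = 1) {
  if (any(!is.finite(omega_cf)) || any(omega_cf < 1)) {
    stop("`omega_cf` must be >= 1: the rate law is undefined for undersaturated fluid",
         call. = FALSE)
  }
  p <- iphrac_params(temperature)
  scale * p$k_a * (omega_cf - 1)^p$n
}

#' Least-squares scaling of the rate curve onto measured calcification
#'
#' Finds the multiplicative factor that best aligns G(Omega, T) with observed
#' rates (ordinary least squares through the origin of the G-to-rate map).
#'
#' @param omega_cf Observed saturation states (>= 1).
#' @param rate Observed calcification rates, mg cm-2 d-1.
#' @param temperature Temperature, degrees Celsius.
#' @return The scalar scale factor.
#' @export
iphrac_scale_to_data <- function(omega_cf, rate, temperature) {
  g <- iphrac_rate(omega_cf, temperature)
  sum(g * rate) / sum(g^2)
}

#' Polynomial fit of calcification against saturation state
#'
#' Ordinary least-squares polynomial (default quadratic) of rate on Omega_cf,
#' as used to summarise the pooled relationship between calcification and the
#' reconstructed calcifying-fluid saturation state.
#'
#' @param omega_cf Saturation states (x). Duplicated values are allowed.
#' @param rate Calcification rates (y).
#' @param degree Polynomial degree (default 2); needs at least `degree + 2`
#'   points.
#' @return A list of class `omega_polyfit` with `coefficients` (named
#'   `c0`...`cdeg`, ascending powers), `r_squared`, `residuals` and the
#'   underlying `lm` fit.
#' @export
fit_calcification_vs_omega <- function(omega_cf, rate, degree = 2) {
  stopifnot(length(omega_cf) == length(rate))
  if (length(omega_cf) < degree + 2) {
    stop(sprintf("need at least %d points for a degree-%d fit",
                 degree + 2, degree), call. = FALSE)
  }
  if (length(unique(omega_cf)) < degree + 1) {
    stop("rank-deficient design: too few distinct omega_cf values",
         call. = FALSE)
  }
  fit <- lm(rate ~ poly(omega_cf, degree, raw = TRUE))
  cf <- setNames(coef(fit), paste0("c", 0:degree))
  structure(list(coefficients = cf,
                 r_squared = summary(fit)$r.squared,
                 residuals = residuals(fit),
                 fit = fit),
            class = "omega_polyfit")
}

#' @export
print.omega_polyfit <- function(x, ...) {
  deg <- length(x$coefficients) - 1
  terms <- paste(sprintf("%.4g*x^%d", x$coefficients, 0:deg), collapse = " + ")
  cat("Polynomial fit of calcification vs omega_cf:\n  y =", terms, "\n")
  cat(sprintf("  R-squared %.3f on %d points\n", x$r_squared,
              length(x$residuals)))
  invisible(x)
}
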