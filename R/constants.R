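#' Equilibrium constants of the seawater CO2 system
#'
#' Evaluates the thermodynamic constants needed to solve the marine CO2 system
#' on the total pH scale (mol kg-seawater-1 concentration units) at surface
#' pressure, plus the conservative total boron and calcium concentrations.
#'
#' Available formulations (selected by name):
#' \describe{
#'   \item{`k1k2`}{`"lueker2000"` (default) or `"roy1993"` for the first and
#'     second dissociation constants of carbonic acid, both on the total
#'     scale.}
#'   \item{`kb`}{`"dickson1990"` for boric acid.}
#'   \item{`ksp`}{`"mucci1983"` for the aragonite stoichiometric solubility
#'     product.}
#'   \item{`btot`}{`"lee2010"` (default) or `"uppstrom1974"` for total boron.}
#'   \item{`catot`}{`"riley1967"`, calcium proportional to salinity
#'     (0.010282 x S/35 mol kg-1).}
#' }
#' K0 (CO2 solubility) follows Weiss (1974) and Kw the DOE handbook fit; these
#' are not currently pluggable.
#'
#' @param temperature Temperature in degrees Celsius, in \[-2, 40\].
#' @param salinity Practical salinity, in \[1, 45\].
#' @param k1k2,kb,ksp,btot,catot Formulation names, see Details.
#' @return An object of class `carb_constants`: a list with elements `K0`,
#'   `K1`, `K2`, `KB`, `Kw`, `Ksp_aragonite` (all mol kg-1 scale, total pH
#'   scale), `B_total`, `Ca_total` (mol kg-1), `temperature`, `salinity`, and
#'   a `provenance` character vector naming the formulation behind each
#'   constant.
#' @examples
#' k <- carb_constants(25, 35)
#' -log10(k$KB)  # pK_B, ~8.597
#' @export
carb_constants <- function(temperature, salinity,
                           k1k2 = c("lueker2000", "roy1993"),
                           kb = "dickson1990",
                           ksp = "mucci1983",
                           btot = c("lee2010", "uppstrom1974"),
                           catot = "riley1967") {
  .check_seawater(temperature, salinity)
  k1k2 <- match.arg(k1k2)
  kb <- match.arg(kb)
  ksp <- match.arg(ksp)
  btot <- match.arg(btot)
  catot <- match.arg(catot)

  TK <- temperature + 273.15
  S <- salinity

  # Weiss (1974) CO2 solubility, mol kg-1 atm-1
  lnK0 <- -60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
    S * (0.023517 - 0.023656 * (TK / 100) + 0.0047036 * (TK / 100)^2)

  if (k1k2 == "lueker2000") {
    pK1 <- 3633.86 / TK - 61.2172 + 9.6777 * log(TK) -
      0.011555 * S + 0.0001152 * S^2
    pK2 <- 471.78 / TK + 25.9290 - 3.16967 * log(TK) -
      0.01781 * S + 0.0001122 * S^2
    K1 <- 10^-pK1
    K2 <- 10^-pK2
  } else { # roy1993 (total scale, mol kg-1)
    lnK1 <- 2.83655 - 2307.1266 / TK - 1.5529413 * log(TK) +
      (-0.20760841 - 4.0484 / TK) * sqrt(S) + 0.08468345 * S -
      0.00654208 * S^1.5 + log(1 - 0.001005 * S)
    lnK2 <- -9.226508 - 3351.6106 / TK - 0.2005743 * log(TK) +
      (-0.106901773 - 23.9722 / TK) * sqrt(S) + 0.1130822 * S -
      0.00846934 * S^1.5 + log(1 - 0.001005 * S)
    K1 <- exp(lnK1)
    K2 <- exp(lnK2)
  }

  # Dickson (1990) boric acid, total scale
  lnKB <- (-8966.90 - 2890.53 * sqrt(S) - 77.942 * S +
             1.728 * S^1.5 - 0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqrt(S) + 1.62142 * S -
    (24.4344 + 25.085 * sqrt(S) + 0.2474 * S) * log(TK) +
    0.053105 * sqrt(S) * TK

  # water dissociation (DOE handbook), total scale
  lnKw <- 148.9652 - 13847.26 / TK - 23.6521 * log(TK) +
    (118.67 / TK - 5.977 + 1.0495 * log(TK)) * sqrt(S) - 0.01615 * S

  # Mucci (1983) aragonite solubility product
  log10Ksp <- -171.945 - 0.077993 * TK + 2903.293 / TK +
    71.595 * log10(TK) +
    (-0.068393 + 0.0017276 * TK + 88.135 / TK) * sqrt(S) -
    0.10018 * S + 0.0059415 * S^1.5

  B_total <- switch(btot,
    lee2010 = 0.0004326 * S / 35,
    uppstrom1974 = 0.000416 * S / 35
  )
  Ca_total <- 0.010282 * S / 35

  out <- list(
    K0 = exp(lnK0), K1 = K1, K2 = K2, KB = exp(lnKB), Kw = exp(lnKw),
    Ksp_aragonite = 10^log10Ksp,
    B_total = B_total, Ca_total = Ca_total,
    temperature = temperature, salinity = salinity,
    provenance = c(K0 = "weiss1974", K1 = k1k2, K2 = k1k2, KB = kb,
                   Kw = "doe1994", Ksp_aragonite = ksp, B_total = btot,
                   Ca_total = catot)
  )
  stopifnot(out$K1 > out$K2)
  class(out) <- "carb_constants"
  out
}

#' @export
print.carb_constants <- function(x, ...) {
  cat(sprintf("Seawater CO2-system constants (total scale) at %g degC, S %g\n",
              x$temperature[1], x$salinity[1]))
  cat(sprintf("  pK1 %.4f  pK2 %.4f  pKB %.4f  pKw %.4f\n",
              -log10(x$K1[1]), -log10(x$K2[1]), -log10(x$KB[1]),
              -log10(x$Kw[1])))
  cat(sprintf("  K0 %.4e mol kg-1 atm-1  Ksp(arag) %.4e\n",
              x$K0[1], x$Ksp_aragonite[1]))
  cat(sprintf("  B_total %.4e  Ca_total %.4e mol kg-1\n",
              x$B_total[1], x$Ca_total[1]))
  invisible(x)
}
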