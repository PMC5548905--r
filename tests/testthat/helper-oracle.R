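# Independent-route CO2-system oracle used by the equivalence tests.
#
# The package solves the system directly from (pH, A_T). The oracle below
# takes (A_T, DIC) instead, expresses alkalinity as a function of [H+] through
# the DIC ionisation fractions, and root-finds [H+] with uniroot -- a
# different algebraic path through the equilibria. Speciation then follows
# from the DIC fractions, not from the carbonate-alkalinity partition the
# implementation uses.

oracle_alkalinity <- function(h, DIC, k) {
  denom <- h^2 + k$K1 * h + k$K1 * k$K2
  DIC * (k$K1 * h + 2 * k$K1 * k$K2) / denom +
    k$B_total / (1 + h / k$KB) + k$Kw / h - h
}

oracle_solve_alk_dic <- function(alkalinity, DIC, k) {
  root <- uniroot(function(h) oracle_alkalinity(h, DIC, k) - alkalinity,
                  lower = 10^-12, upper = 10^-4, tol = 1e-18)
  h <- root$root
  denom <- h^2 + k$K1 * h + k$K1 * k$K2
  list(pH = -log10(h),
       CO2aq = DIC * h^2 / denom,
       HCO3 = DIC * k$K1 * h / denom,
       CO3 = DIC * k$K1 * k$K2 / denom,
       pCO2_uatm = DIC * h^2 / denom / k$K0 * 1e6,
       omega_aragonite = DIC * k$K1 * k$K2 / denom * k$Ca_total /
         k$Ksp_aragonite)
}

# DIC from (pH, CO3) through the ionisation-fraction route
oracle_dic_from_ph_co3 <- function(pH, co3, k) {
  h <- 10^-pH
  frac_co3 <- k$K1 * k$K2 / (h^2 + k$K1 * h + k$K1 * k$K2)
  co3 / frac_co3
}

# The delta-11-B value at which the pH proxy's log argument equals 1, i.e.
# pH_cf = pK_B: solve (sw - x) = a x - sw + 1000(a - 1) for x.
oracle_d11b_fixed_point <- function(sw = 39.61, a = 1.0272) {
  (2 * sw - 1000 * (a - 1)) / (1 + a)
}

# Direct arithmetic evaluation of the B/Ca proxy, written out independently
oracle_co3cf <- function(BCa_umolmol, pH_cf, k, KD0 = 2.97e-3,
                         k_KD = 0.0202, h_unit = "mol") {
  h <- 10^-pH_cf
  borate <- k$B_total * k$KB / (k$KB + h) # equivalent speciation algebra
  h_in_exp <- if (h_unit == "nmol") h * 1e9 else h
  KD0 * exp(-k_KD * h_in_exp) * borate / (BCa_umolmol * 1e-6)
}
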