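#' Header-tank random-effect gate for the nested mesocosm design
#'
#' In the nested design (treatments fixed; header tanks nested in treatment;
#' organisms in incubation tanks fed by a header tank), the header tank is
#' first tested as a random factor. The tank mean square is tested over the
#' residual mean square; when the tank effect is non-significant at p > 0.25
#' the tank term is dropped and individual organisms are treated as
#' replicates. Both candidate F-tests for the treatment effect are reported:
#' over the tank mean square (the expected-mean-squares denominator while the
#' tank term is retained) and over the residual mean square (after dropping).
#'
#' @param data A data frame with at least the columns `treatment`,
#'   `header_tank` and the response.
#' @param response Name of the response column.
#' @return A list of class `tank_gate` with elements `decision`
#'   (`"drop_tank"` or `"keep_tank"`), `p_tank`, `anova` (data frame with
#'   rows treatment / header_tank / residuals: df, sum_sq, mean_sq),
#'   `p_treatment_over_tank`, `p_treatment_over_residual`, and `response`.
#' @export
tank_effect_gate <- function(data, response) {
  stopifnot(all(c("treatment", "header_tank", response) %in% names(data)))
  y <- data[[response]]
  treatment <- factor(data$treatment)
  # nested coding: tank labels are made unique within treatment
  tank <- factor(paste(treatment, data$header_tank, sep = ":"))
  tanks_per_tr <- tapply(tank, treatment, function(x) length(unique(x)))
  if (any(tanks_per_tr < 2)) {
    stop("design error: fewer than 2 header tanks in some treatment",
         call. = FALSE)
  }
  if (var(y) == 0) {
    # exactly constant response: no sums of squares, no tank evidence
    return(structure(list(
      decision = "drop_tank", p_tank = 1,
      anova = data.frame(term = c("treatment", "header_tank", "residuals"),
                         df = c(nlevels(treatment) - 1,
                                nlevels(tank) - nlevels(treatment),
                                length(y) - nlevels(tank)),
                         sum_sq = c(0, 0, 0), mean_sq = c(0, 0, 0)),
      p_treatment_over_tank = 1, p_treatment_over_residual = 1,
      response = response), class = "tank_gate"))
  }
  fit <- aov(y ~ treatment + tank)
  tab <- anova(fit)
  df <- tab$Df
  ss <- tab$`Sum Sq`
  ms <- tab$`Mean Sq`
  names(df) <- names(ss) <- names(ms) <- c("treatment", "header_tank",
                                           "residuals")
  f_tank <- ms[["header_tank"]] / ms[["residuals"]]
  p_tank <- pf(f_tank, df[["header_tank"]], df[["residuals"]],
               lower.tail = FALSE)
  # degenerate sums of squares (e.g. constant response) -> no tank evidence
  if (!is.finite(p_tank)) p_tank <- 1
  f_tr_tank <- ms[["treatment"]] / ms[["header_tank"]]
  p_tr_tank <- pf(f_tr_tank, df[["treatment"]], df[["header_tank"]],
                  lower.tail = FALSE)
  f_tr_res <- ms[["treatment"]] / ms[["residuals"]]
  p_tr_res <- pf(f_tr_res, df[["treatment"]], df[["residuals"]],
                 lower.tail = FALSE)
  structure(list(
    decision = if (p_tank > 0.25) "drop_tank" else "keep_tank",
    p_tank = p_tank,
    anova = data.frame(term = names(df), df = as.vector(df),
                       sum_sq = as.vector(ss), mean_sq = as.vector(ms)),
    p_treatment_over_tank = unname(p_tr_tank),
    p_treatment_over_residual = unname(p_tr_res),
    response = response
  ), class = "tank_gate")
}

#' @export
print.tank_gate <- function(x, ...) {
  cat(sprintf("Header-tank gate for '%s': %s (tank p = %.3g)\n",
              x$response, x$decision, x$p_tank))
  cat(sprintf("  treatment p over tank MS %.3g; over residual MS %.3g\n",
              x$p_treatment_over_tank, x$p_treatment_over_residual))
  invisible(x)
}

#' One-way treatment ANOVA with Tukey HSD pairwise comparisons
#'
#' Applied after the header-tank gate has dropped the tank term: individual
#' organisms are replicates and the pH treatments are compared with a one-way
#' ANOVA followed by Tukey honest significant differences.
#'
#' @param data A data frame with columns `treatment` and the response.
#' @param response Name of the response column.
#' @return A list of class `treatment_test` with `p_value` (treatment F-test),
#'   `anova` (the `aov` summary data frame) and `tukey` (data frame with one
#'   row per treatment pair: `diff`, `lwr`, `upr`, `p_adj`).
#' @export
treatment_test <- function(data, response) {
  stopifnot(all(c("treatment", response) %in% names(data)))
  treatment <- factor(data$treatment)
  if (any(table(treatment) == 0) || nlevels(treatment) < 2) {
    stop("design error: each treatment needs at least one observation",
         call. = FALSE)
  }
  y <- data[[response]]
  if (var(y) == 0) {
    # exactly constant response: every comparison is a tie
    pairs <- utils::combn(levels(treatment), 2,
                          function(p) paste(p[2], p[1], sep = "-"))
    return(structure(list(
      p_value = 1,
      anova = data.frame(term = c("treatment", "residuals"),
                         df = c(nlevels(treatment) - 1,
                                length(y) - nlevels(treatment)),
                         sum_sq = c(0, 0), mean_sq = c(0, 0)),
      tukey = data.frame(pair = pairs, diff = 0, lwr = 0, upr = 0,
                         p_adj = 1),
      response = response), class = "treatment_test"))
  }
  fit <- aov(y ~ treatment)
  tab <- anova(fit)
  p <- tab$`Pr(>F)`[1]
  if (!is.finite(p)) p <- 1
  tk <- TukeyHSD(fit)$treatment
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  # degenerate residual variance (identical groups) -> no evidence
  tukey$p_adj[!is.finite(tukey$p_adj)] <- 1
  structure(list(p_value = p,
                 anova = data.frame(term = c("treatment", "residuals"),
                                    df = tab$Df, sum_sq = tab$`Sum Sq`,
                                    mean_sq = tab$`Mean Sq`),
                 tukey = tukey,
                 response = response),
            class = "treatment_test")
}

#' @export
print.treatment_test <- function(x, ...) {
  cat(sprintf("One-way ANOVA for '%s': p = %.3g\n", x$response, x$p_value))
  print(x$tukey, row.names = FALSE)
  invisible(x)
}

#' Ordinary least-squares line with slope inference
#'
#' Thin wrapper around [stats::lm()] returning the quantities the proxy
#' regressions report: slope, intercept, their standard errors, the t-test
#' p-value on the slope and R-squared.
#'
#' @param x,y Numeric vectors (>= 3 points; `x` must vary).
#' @return A list of class `linear_fit` with `slope`, `intercept`,
#'   `slope_se`, `intercept_se`, `p_value`, `r_squared` and the `lm` object
#'   as `fit`.
#' @examples
#' linear_fit(1:5, 2 * (1:5) + 1)
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (var(x) == 0) stop("fit error: `x` is constant", call. = FALSE)
  fit <- lm(y ~ x)
  s <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 slope_se = s$coefficients[2, 2],
                 intercept_se = s$coefficients[1, 2],
                 p_value = s$coefficients[2, 4],
                 r_squared = s$r.squared,
                 fit = fit),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("y = %.4g x + %.4g  (slope p = %.3g, R2 = %.3f)\n",
              x$slope, x$intercept, x$p_value, x$r_squared))
  invisible(x)
}
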