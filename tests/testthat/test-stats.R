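# small helper: one balanced nested dataset (3 treatments x 4 header tanks x
# 3 organisms) with controllable tank and residual variance
sim_nested <- function(tank_sd, resid_sd, treat_effects = c(0, 0, 0)) {
  tr <- rep(c("pH8.1", "pH7.8", "pH7.6"), each = 12)
  tank <- rep(sprintf("H%02d", 1:12), each = 3)
  mu <- rep(treat_effects, each = 12)
  tank_eff <- rep(rnorm(12, 0, tank_sd), each = 3)
  data.frame(treatment = tr, header_tank = tank,
             y = mu + tank_eff + rnorm(36, 0, resid_sd))
}

test_that("the tank gate drops negligible tank effects and keeps strong ones", {
  # under a true null the tank p-value is uniform, so the p > 0.25 drop rule
  # retains ~75% of datasets; the simulated rate must sit in that band
  set.seed(21)
  null_decisions <- replicate(200, {
    tank_effect_gate(sim_nested(0, 1), "y")$decision
  })
  expect_gte(mean(null_decisions == "drop_tank"), 0.65)
  expect_lte(mean(null_decisions == "drop_tank"), 0.85)

  set.seed(22)
  strong_decisions <- replicate(50, {
    tank_effect_gate(sim_nested(5, 1), "y")$decision
  })
  expect_gte(mean(strong_decisions == "keep_tank"), 0.95)
})

test_that("the gate handles degenerate responses and reports both F routes", {
  d <- sim_nested(0, 1)
  d$y <- 3 # constant response: no sums of squares anywhere
  g <- tank_effect_gate(d, "y")
  expect_equal(g$decision, "drop_tank")
  expect_equal(g$p_tank, 1)

  set.seed(23)
  d2 <- sim_nested(1, 1, treat_effects = c(0, 1, 2))
  g2 <- tank_effect_gate(d2, "y")
  expect_true(is.finite(g2$p_treatment_over_tank))
  expect_true(is.finite(g2$p_treatment_over_residual))
  expect_named(g2$anova, c("term", "df", "sum_sq", "mean_sq"))
  expect_equal(g2$anova$df, c(2, 9, 24))

  d3 <- d2[d2$header_tank %in% sprintf("H%02d", c(1, 5, 9)), ]
  expect_error(tank_effect_gate(d3, "y"), "fewer than 2")
})

test_that("identical groups give p near 1 and no significant Tukey pairs", {
  d <- data.frame(treatment = rep(c("a", "b", "c"), each = 5),
                  y = rep(3, 15))
  t <- treatment_test(d, "y")
  expect_equal(t$p_value, 1)
  expect_true(all(t$tukey$p_adj > 0.99))
  expect_true(all(t$tukey$diff == 0))
  expect_error(treatment_test(d[0, ], "y"), "design error")
})

test_that("treatment tests recover the published power pattern on synthetic rates", {
  # per-treatment means/SEs of the two species, n = 12, colony SD = SE*sqrt(12)
  set.seed(31)
  reps <- 100
  sensitive <- replicate(reps, {
    d <- data.frame(
      treatment = rep(c("pH8.1", "pH7.8", "pH7.6"), each = 12),
      y = rnorm(36, rep(c(1.97, 1.65, 1.34), each = 12),
                rep(c(0.13, 0.10, 0.09) * sqrt(12), each = 12)))
    treatment_test(d, "y")$p_value
  })
  # simulation oracle at this effect size: P(p < 0.001) ~ 0.54,
  # P(p < 0.05) ~ 0.94
  expect_gte(mean(sensitive < 0.001), 0.40)
  expect_gte(mean(sensitive < 0.05), 0.85)

  tolerant <- replicate(reps, {
    d <- data.frame(
      treatment = rep(c("pH8.1", "pH7.8", "pH7.6"), each = 12),
      y = rnorm(36, rep(c(1.07, 1.00, 0.97), each = 12),
                rep(0.08 * sqrt(12), each = 12)))
    treatment_test(d, "y")$p_value
  })
  expect_gte(mean(tolerant > 0.05), 0.80)
})

test_that("Tukey intervals bracket the raw differences and control family-wise error", {
  set.seed(41)
  d <- data.frame(treatment = rep(c("a", "b", "c"), each = 12),
                  y = rnorm(36, rep(c(0, 0.5, 1), each = 12), 1))
  t <- treatment_test(d, "y")
  means <- tapply(d$y, d$treatment, mean)
  raw <- c(means["b"] - means["a"], means["c"] - means["a"],
           means["c"] - means["b"])
  expect_equal(unname(t$tukey$diff), unname(raw), tolerance = 1e-12)
  expect_true(all(t$tukey$lwr <= t$tukey$diff & t$tukey$diff <= t$tukey$upr))

  set.seed(42)
  fwe <- replicate(500, {
    d <- data.frame(treatment = rep(c("a", "b", "c"), each = 12),
                    y = rnorm(36))
    any(treatment_test(d, "y")$tukey$p_adj < 0.05)
  })
  expect_lte(mean(fwe), 0.05 + 2 * sqrt(0.05 * 0.95 / 500))
})

test_that("linear_fit returns exact coefficients on exact lines", {
  f <- suppressWarnings(linear_fit(1:10, 2 * (1:10) + 1)) # exact fit
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_error(linear_fit(rep(2, 5), 1:5), "constant")
  expect_error(linear_fit(1:2, 1:2), "3 points")
})
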