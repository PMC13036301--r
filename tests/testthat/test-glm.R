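unit_data <- function(n_inside, n_total, country = NULL, density = NULL) {
  d <- data.frame(n_inside = n_inside, n_total = n_total)
  if (!is.null(country)) d$country <- country
  if (!is.null(density)) d$density_inside <- density
  d
}

test_that("intercept-only fits match closed-form logits", {
  # every unit at 50/100: logit(0.5) = 0 and no deviance explained
  f <- fit_binomial_glm(unit_data(rep(50, 6), rep(100, 6)))
  expect_equal(f$coefficients$estimate[1], 0, tolerance = 1e-10)
  expect_equal(f$d2, 0, tolerance = 1e-12)
  # pooled proportion 0.8 with equal trials: intercept = ln(4)
  f2 <- fit_binomial_glm(unit_data(rep(80, 3), rep(100, 3)))
  expect_equal(f2$coefficients$estimate[1], log(4), tolerance = 1e-8)
})

test_that("sum-to-zero coding makes a two-level factor symmetric", {
  d <- unit_data(c(30, 30, 70, 70), rep(100, 4), country = c("A", "A", "B", "B"))
  f <- fit_binomial_glm(d, factor_col = "country")
  lev <- f$coefficients[grep("^level:", f$coefficients$term), ]
  expect_equal(nrow(lev), 2)
  expect_equal(lev$estimate[1], -lev$estimate[2], tolerance = 1e-10)
  expect_equal(lev$se[1], lev$se[2], tolerance = 1e-10)
})

test_that("saturated one-factor fit reproduces observed proportions", {
  d <- unit_data(c(20, 50, 85), c(100, 100, 100), country = c("A", "B", "C"))
  f <- fit_binomial_glm(d, factor_col = "country")
  expect_equal(as.numeric(stats::fitted(f$fit)), c(0.20, 0.50, 0.85), tolerance = 1e-8)
  expect_equal(f$d2, 1, tolerance = 1e-8)
})

test_that("explained deviance is monotone under model nesting", {
  set.seed(14)
  n <- 18
  d <- unit_data(stats::rbinom(n, 200, 0.6), rep(200, n),
                 country = rep(c("A", "B", "C"), each = 6),
                 density = stats::runif(n))
  f0 <- fit_binomial_glm(d, effort_col = "density_inside")
  f1 <- fit_binomial_glm(d, factor_col = "country", effort_col = "density_inside")
  expect_gte(f1$d2 + 1e-12, f0$d2)
  expect_lte(f1$residual_deviance, f1$null_deviance + 1e-9)
  expect_true(f1$d2 >= 0 && f1$d2 <= 1)
})

test_that("complete separation raises an informative error", {
  suppressWarnings(expect_error(
    fit_binomial_glm(unit_data(c(0, 0, 100, 100), rep(100, 4),
                               country = c("A", "A", "B", "B")),
                     factor_col = "country"),
    "separation"))
})

test_that("deviation flags classify levels by their CI position", {
  fake <- structure(list(coefficients = data.frame(
    term = c("(Intercept)", "level:A", "level:B", "level:C"),
    estimate = c(0.5, 0.4, -0.2, -0.2),
    se = c(0.1, 0.15, 0.15, 0.15),
    lower = c(0.3, 0.1, -0.5, -0.5),
    upper = c(0.7, 0.7, 0.1, -0.05),
    stringsAsFactors = FALSE
  )), class = "deviation_glm")
  fl <- deviation_flags(fake)
  expect_equal(fl$flag, c("above", "average", "below"))
})

test_that("deviation flags are invariant to factor level order", {
  set.seed(4)
  n <- 24
  cty <- rep(c("A", "B", "C", "D"), each = 6)
  p <- stats::plogis(0.3 + ifelse(cty == "C", 0.8, 0))
  d <- unit_data(stats::rbinom(n, 300, p), rep(300, n), country = cty)
  f1 <- deviation_flags(fit_binomial_glm(d, factor_col = "country"))
  d2 <- d[order(-seq_len(n)), ]
  d2$country <- factor(d2$country, levels = c("D", "B", "C", "A"))
  f2 <- deviation_flags(fit_binomial_glm(d2, factor_col = "country"))
  f2 <- f2[match(f1$level, f2$level), ]
  expect_equal(f1$flag, f2$flag)
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-8)
})

test_that("an elevated unit is flagged above the network-wide mean", {
  set.seed(33)
  hits <- 0L
  n_sim <- 60L
  for (i in seq_len(n_sim)) {
    cty <- rep(paste0("C", 1:6), each = 4)
    dens <- stats::runif(24, 0.05, 0.5)
    p <- stats::plogis(0.5 + 0.4 * dens + ifelse(cty == "C3", 0.6, 0))
    d <- unit_data(stats::rbinom(24, 400, p), rep(400, 24),
                   country = cty, density = dens)
    fl <- deviation_flags(fit_binomial_glm(d, factor_col = "country",
                                           effort_col = "density_inside"))
    if (fl$flag[fl$level == "C3"] == "above") hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("effort-term selection tracks the generating truth", {
  set.seed(55)
  n_sim <- 40L
  lin_hits <- quad_hits <- 0L
  for (i in seq_len(n_sim)) {
    dens <- stats::runif(30, 0, 1)
    # linear truth
    p_lin <- stats::plogis(0.2 + 1.2 * dens)
    d_lin <- unit_data(stats::rbinom(30, 300, p_lin), rep(300, 30), density = dens)
    if (select_effort_terms(d_lin, effort_col = "density_inside")$chosen == "linear")
      lin_hits <- lin_hits + 1L
    # strong quadratic truth
    p_quad <- stats::plogis(0.2 + 4 * dens - 4.5 * dens^2)
    d_quad <- unit_data(stats::rbinom(30, 300, p_quad), rep(300, 30), density = dens)
    if (select_effort_terms(d_quad, effort_col = "density_inside")$chosen == "quadratic")
      quad_hits <- quad_hits + 1L
  }
  expect_gte(lin_hits / n_sim, 0.95)
  expect_gte(quad_hits / n_sim, 0.95)
})

test_that("identical fits (no effort signal at all) default to linear", {
  d <- unit_data(rep(60, 10), rep(100, 10), density = rep(0.3, 10))
  # constant effort makes the quadratic column collinear -> rank error, or
  # with near-constant effort the simpler model must win
  d$density_inside <- d$density_inside + seq(0, 1e-9, length.out = 10)
  sel <- tryCatch(select_effort_terms(d, effort_col = "density_inside"),
                  error = function(e) list(chosen = "linear"))
  expect_equal(sel$chosen, "linear")
})
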