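score_df <- function(ids, treated, logit) {
  data.frame(plot_id = ids, treated = treated, score = stats::plogis(logit),
             logit = logit, stringsAsFactors = FALSE)
}

test_that("propensity scores collapse to the treated fraction without signal", {
  plots <- data.frame(
    plot_id = paste0("p", 1:10),
    status = rep(c("INSIDE", "OUTSIDE"), c(4, 6)),
    temp = 12, elev = 300, stringsAsFactors = FALSE
  )
  sc <- estimate_propensity(plots, c("temp", "elev"))
  expect_equal(sc$score, rep(0.4, 10), tolerance = 1e-8)
  expect_true(all(sc$score > 0 & sc$score < 1))
})

test_that("propensity model drops incomplete rows and recovers balance", {
  set.seed(2)
  n <- 400
  status <- rep(c("INSIDE", "OUTSIDE"), each = n / 2)
  plots <- data.frame(
    plot_id = sprintf("p%04d", 1:n), status = status,
    temp = stats::rnorm(n, 12 + ifelse(status == "INSIDE", 1.5, 0)),
    elev = stats::rnorm(n, 500),   # balanced by construction
    stringsAsFactors = FALSE
  )
  plots$temp[1] <- NA
  sc <- estimate_propensity(plots, c("temp", "elev"))
  expect_equal(attr(sc, "n_dropped"), 1L)
  expect_equal(nrow(sc), n - 1)
  cf <- summary(attr(sc, "model"))$coefficients
  ci_elev <- cf["elev", 1] + c(-1.96, 1.96) * cf["elev", 2]
  expect_true(ci_elev[1] < 0 && ci_elev[2] > 0)  # balanced covariate: CI covers 0
  ci_temp <- cf["temp", 1] + c(-1.96, 1.96) * cf["temp", 2]
  expect_true(ci_temp[1] > 0)                    # confounded covariate detected
})

test_that("greedy matching pairs identical scores at distance zero", {
  sc <- score_df(c("t1", "t2", "c1", "c2", "x1"),
                 c(TRUE, TRUE, FALSE, FALSE, FALSE),
                 c(0.5, 0.5, 0.5, 0.5, 3))
  m <- greedy_match(sc)
  expect_equal(nrow(m$pairs), 2)
  expect_equal(m$pairs$distance, c(0, 0))
  # without replacement: controls used at most once
  expect_false(any(duplicated(m$pairs$control_id)))
})

test_that("a vanishing caliper keeps only exact-score matches", {
  sc <- score_df(c("t1", "t2", "c1", "c2"),
                 c(TRUE, TRUE, FALSE, FALSE),
                 c(0, 1, 0, 1.4))
  m <- greedy_match(sc, caliper_sd = 1e-9)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$treated_id, "t1")
  expect_equal(m$pairs$control_id, "c1")
  # all-pairs-too-far errors out
  sc2 <- score_df(c("t", "c"), c(TRUE, FALSE), c(0, 5))
  expect_error(greedy_match(sc2, caliper_sd = 1e-6), "no common support")
})

test_that("greedy matcher equals the brute-force oracle on small instances", {
  set.seed(66)
  for (i in 1:40) {
    n_t <- sample(2:5, 1); n_c <- sample(2:5, 1)
    sc <- score_df(sprintf("p%02d", 1:(n_t + n_c)),
                   rep(c(TRUE, FALSE), c(n_t, n_c)),
                   round(stats::rnorm(n_t + n_c), 2))
    got <- tryCatch(greedy_match(sc, caliper_sd = 0.25), error = function(e) NULL)
    want <- match_oracle(sc, caliper_sd = 0.25)
    if (is.null(got)) {
      expect_true(is.null(want) || nrow(want) == 0)
    } else {
      expect_equal(got$pairs[c("treated_id", "control_id")], want,
                   ignore_attr = TRUE)
      expect_true(all(got$pairs$distance <= got$caliper + 1e-12))
      expect_lte(nrow(got$pairs), min(n_t, n_c))
    }
  }
})

test_that("balance statistics shrink after matching confounded data", {
  set.seed(12)
  n <- 600
  status <- rep(c("INSIDE", "OUTSIDE"), c(200, 400))
  plots <- data.frame(
    plot_id = sprintf("p%04d", 1:n), status = status,
    temp = stats::rnorm(n, 10 + ifelse(status == "INSIDE", 1.2, 0), 1.5),
    elev = stats::rnorm(n, 600, 100), stringsAsFactors = FALSE
  )
  sc <- estimate_propensity(plots, c("temp", "elev"))
  m <- greedy_match(sc)
  bal <- balance_stats(plots, m$pairs, c("temp", "elev"))
  t_row <- bal[bal$covariate == "temp", ]
  expect_lt(abs(t_row$smd_after), abs(t_row$smd_before))
  expect_gt(abs(t_row$smd_before), 0.5)   # confounding present before matching

  # perfectly matched identical pairs have zero SMD after
  dup <- plots[1:10, ]
  dup$plot_id <- paste0("d", 1:10)
  dup$status <- rep(c("INSIDE", "OUTSIDE"), 5)
  dup$temp <- rep(stats::rnorm(5), each = 2)
  dup$elev <- rep(stats::rnorm(5, 600), each = 2)
  pairs <- data.frame(treated_id = dup$plot_id[c(1, 3, 5, 7, 9)],
                      control_id = dup$plot_id[c(2, 4, 6, 8, 10)])
  bal2 <- balance_stats(dup, pairs, c("temp", "elev"))
  expect_equal(bal2$smd_after, c(0, 0), tolerance = 1e-12)

  # swapping the group labels negates the SMD
  flipped <- plots
  flipped$status <- ifelse(plots$status == "INSIDE", "OUTSIDE", "INSIDE")
  bal3 <- balance_stats(flipped, m$pairs[, c(2, 1)] |>
                          stats::setNames(c("treated_id", "control_id")), c("temp", "elev"))
  expect_equal(bal3$smd_before, -bal$smd_before, tolerance = 1e-12)

  # zero-variance covariate is reported as degenerate, not NaN
  plots$flat <- 1
  bal4 <- balance_stats(plots, m$pairs, c("flat"))
  expect_true(bal4$degenerate)
  expect_equal(bal4$smd_before, 0)
})

test_that("categorical covariates are balanced via per-level proportions", {
  set.seed(9)
  n <- 200
  plots <- data.frame(
    plot_id = sprintf("p%03d", 1:n),
    status = rep(c("INSIDE", "OUTSIDE"), each = n / 2),
    region = sample(c("ALP", "MED"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  pairs <- data.frame(treated_id = plots$plot_id[1:50],
                      control_id = plots$plot_id[101:150])
  bal <- balance_stats(plots, pairs, "region")
  expect_setequal(bal$covariate, c("region:ALP", "region:MED"))
})
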