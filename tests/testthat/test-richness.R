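test_that("incidence summaries count plots, not occurrence rows", {
  occ <- data.frame(
    plot_id = c("p1", "p2", "p3", "p1", "p1"),   # last row duplicates (p1, A)
    species_id = c("A", "A", "A", "B", "A"),
    native = TRUE, priority = FALSE, stringsAsFactors = FALSE
  )
  inc <- build_incidence(occ, c("p1", "p2", "p3"))
  expect_equal(inc$m, 3)
  expect_equal(inc$S_obs, 2)
  expect_equal(inc$Q1, 1)   # B in one plot
  expect_equal(inc$Q2, 0)
  expect_equal(unname(inc$freq[c("A", "B")]), c(3L, 1L))
  # freq total = number of distinct (plot, species) pairs
  expect_equal(sum(inc$freq), 4)
  expect_error(build_incidence(occ, character(0)), "empty stratum")
})

test_that("chao2 matches hand-evaluated values on both branches", {
  mk <- function(m, freq) {
    f <- stats::setNames(as.integer(freq), paste0("s", seq_along(freq)))
    structure(list(m = m, S_obs = length(f), Q1 = sum(f == 1L),
                   Q2 = sum(f == 2L), freq = f), class = "incidence_summary")
  }
  # no uniques: estimate equals the observed richness
  expect_equal(chao2(mk(10, rep(3, 20)))$estimate, 20)
  # classic branch: 5 + (3/4) * 2^2 / (2*1) = 6.5
  expect_equal(chao2(mk(4, c(4, 3, 2, 1, 1)))$estimate, 6.5)
  # bias-corrected branch (Q2 = 0): 8 + (4/5) * 3*2/2 = 10.4
  expect_equal(chao2(mk(5, c(1, 1, 1, 3, 3, 4, 5, 5)))$estimate, 10.4)
  expect_error(chao2(mk(1, c(1))), "fewer than 2")
})

test_that("chao2 agrees with vegan's incidence-based estimator", {
  set.seed(11)
  for (i in 1:10) {
    mat <- random_incidence_matrix(m = 8, s = 25, p = 0.25)
    mat <- mat[, colSums(mat) > 0, drop = FALSE]
    if (ncol(mat) < 2) next
    inc <- incidence_from_matrix(mat)
    ours <- chao2(inc)$estimate
    ref <- vegan::specpool(mat)$chao
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("chao2 never falls below observed richness, with exact equality cases", {
  set.seed(7)
  for (i in 1:50) {
    inc <- incidence_from_matrix(random_incidence_matrix(6, 15, stats::runif(1, 0.1, 0.8)))
    est <- chao2(inc)$estimate
    expect_gte(est, inc$S_obs)
    # the correction vanishes exactly when Q1 = 0, or Q1 = 1 on the
    # bias-corrected (Q2 = 0) branch
    eq <- inc$Q1 == 0 || (inc$Q1 == 1 && inc$Q2 == 0)
    if (eq) expect_equal(est, inc$S_obs) else expect_gt(est, inc$S_obs)
  }
})

test_that("rarefaction expectation matches brute-force subset enumeration", {
  set.seed(3)
  for (i in 1:5) {
    mat <- random_incidence_matrix(m = sample(4:6, 1), s = 12, p = 0.4)
    inc <- incidence_from_matrix(mat)
    for (t in seq_len(nrow(mat))) {
      expect_equal(rarefaction_expected(inc, t), rarefaction_bruteforce(mat, t),
                   tolerance = 1e-12)
    }
    # cross-check against vegan's exact accumulation curve
    ref <- suppressWarnings(vegan::specaccum(mat, method = "exact"))$richness
    expect_equal(rarefaction_expected(inc, seq_len(nrow(mat))), ref, tolerance = 1e-10)
  }
})

test_that("rarefaction endpoints and shape are correct", {
  mat <- rbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 0, 0, 1), c(0, 1, 1, 0))
  inc <- incidence_from_matrix(mat)
  expect_equal(rarefaction_expected(inc, inc$m), inc$S_obs)
  expect_equal(rarefaction_expected(inc, 1), mean(rowSums(mat)))
  expect_error(rarefaction_expected(inc, 0), "out of range")
  # non-decreasing and concave in t on random matrices
  set.seed(21)
  for (i in 1:10) {
    inc2 <- incidence_from_matrix(random_incidence_matrix(10, 30, 0.3))
    curve <- rarefaction_expected(inc2, 1:10)
    expect_true(all(diff(curve) >= -1e-10))
    expect_true(all(diff(diff(curve)) <= 1e-10))
  }
})

test_that("asymptote fits recover noiseless generating parameters exactly", {
  t <- 1:12
  mm <- 100 * t / (5 + t)
  expect_equal(fit_asymptote(t, mm, "michaelis_menten")$estimate, 100, tolerance = 1e-6)
  ar <- 80 - 60 * exp(-0.4 * t)
  expect_equal(fit_asymptote(t, ar, "asymptotic_regression")$estimate, 80, tolerance = 1e-6)
})

test_that("Michaelis-Menten asymptotes track Chao2 across simulated strata", {
  set.seed(42)
  chao_est <- mm_est <- numeric(24)
  for (i in 1:24) {
    pool <- 40 + 12 * i
    m <- 30
    # heterogeneous detection probabilities induce undetected species
    p <- stats::rbeta(pool, 0.8, 4)
    mat <- matrix(stats::rbinom(m * pool, 1, rep(p, each = m)), nrow = m)
    inc <- incidence_from_matrix(mat[, colSums(mat) > 0, drop = FALSE])
    chao_est[i] <- chao2(inc)$estimate
    tt <- unique(round(seq(1, m, length.out = 10)))
    mm_est[i] <- fit_asymptote(tt, rarefaction_expected(inc, tt), "michaelis_menten")$estimate
  }
  expect_gte(concordance(chao_est, mm_est), 0.9)
})

test_that("species partitions follow exact set algebra", {
  p <- partition_species(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(p$n_shared, 2)
  expect_equal(p$n_inside_only, 1)
  expect_equal(p$n_outside_only, 1)
  expect_equal(p$n_total, 4)
  expect_equal(p$pct_inside + p$pct_outside_only, 100)
  expect_equal(p$pct_outside + p$pct_inside_only, 100)

  # all species inside only
  p2 <- partition_species(c("a", "b"), character(0))
  expect_equal(p2$pct_inside_only, 100)

  # percentage identities hold on random partitions
  set.seed(5)
  for (i in 1:20) {
    ins <- sample(letters, sample(3:20, 1))
    outs <- sample(letters, sample(3:20, 1))
    pr <- partition_species(ins, outs)
    expect_equal(pr$n_inside_only + pr$n_outside_only + pr$n_shared, pr$n_total)
    expect_equal(pr$pct_inside + pr$pct_outside_only, 100)
    expect_equal(pr$pct_outside + pr$pct_inside_only, 100)
  }
})

test_that("priority mode uses the reference denominator and counts missing", {
  ref <- paste0("r", 1:10)
  p <- partition_species(c("r1", "r2", "r3"), c("r3", "r4"), reference = ref)
  expect_equal(p$n_missing, 6)
  expect_equal(p$pct_missing, 60)
  expect_equal(p$pct_inside, 30)
  expect_error(partition_species("a", "b", reference = character(0)), "non-empty")
})

test_that("concordance equals the product-moment correlation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(concordance(x, 2 * x + 1), 1)
  expect_equal(concordance(x, -x), -1)
  y <- c(2.0, 1.5, 3.5, 3.0, 5.5)
  # hand evaluation of the standard formula
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(concordance(x, y), r_hand)
  expect_error(concordance(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})
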