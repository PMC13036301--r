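# Incidence-based gamma-diversity estimation and species-set partitioning.
#
# Everything here works on incidence (presence across sampling units), never
# abundance: plots are the sampling units, a species' incidence frequency is
# the number of plots it was detected in.

#' Build an incidence summary for one stratum
#'
#' @param occurrences Occurrence data frame (`plot_id`, `species_id`, ...)
#'   already restricted to the stratum's plots, or not: only rows whose
#'   `plot_id` appears in `plot_ids` are counted.
#' @param plot_ids Character vector of the stratum's plots. Plots without
#'   occurrences still count towards `m`.
#' @return An `incidence_summary`: list with `m` (number of plots), `S_obs`,
#'   `Q1` (uniques), `Q2` (duplicates), and `freq` (named per-species
#'   incidence counts).
#' @export
build_incidence <- function(occurrences, plot_ids) {
  plot_ids <- unique(as.character(plot_ids))
  m <- length(plot_ids)
  if (m == 0) stop("empty stratum: no plots")
  occ <- occurrences[occurrences$plot_id %in% plot_ids, c("plot_id", "species_id")]
  occ <- occ[!duplicated(paste(occ$plot_id, occ$species_id, sep = "\r")), , drop = FALSE]
  freq <- table(occ$species_id)
  freq <- stats::setNames(as.integer(freq), names(freq))
  structure(
    list(m = m, S_obs = length(freq),
         Q1 = sum(freq == 1L), Q2 = sum(freq == 2L), freq = freq),
    class = "incidence_summary"
  )
}

#' @export
print.incidence_summary <- function(x, ...) {
  cat(sprintf("<incidence_summary m=%d S_obs=%d Q1=%d Q2=%d>\n",
              x$m, x$S_obs, x$Q1, x$Q2))
  invisible(x)
}

#' Chao2 incidence-based richness estimate
#'
#' Nonparametric lower-bound estimate of total richness from the counts of
#' species seen in exactly one (Q1) and exactly two (Q2) plots, with the
#' (m-1)/m small-sample factor. When Q2 = 0 the bias-corrected form
#' `S_obs + ((m-1)/m) * Q1*(Q1-1)/2` is used.
#'
#' @param inc An `incidence_summary`.
#' @return A one-row data frame (`estimator`, `estimate`, `S_obs`, `m`).
#' @export
chao2 <- function(inc) {
  stopifnot(inherits(inc, "incidence_summary"))
  if (inc$m < 2) stop("Chao2 estimator undefined for fewer than 2 plots")
  k <- (inc$m - 1) / inc$m
  est <- if (inc$Q2 > 0) {
    inc$S_obs + k * inc$Q1^2 / (2 * inc$Q2)
  } else {
    inc$S_obs + k * inc$Q1 * (inc$Q1 - 1) / 2
  }
  data.frame(estimator = "chao2", estimate = est, S_obs = inc$S_obs, m = inc$m,
             stringsAsFactors = FALSE)
}

#' Expected richness in a random subsample of plots (sample-based rarefaction)
#'
#' Exact hypergeometric expectation
#' `S_obs - sum_i C(m - f_i, t) / C(m, t)` over species with incidence
#' frequency `f_i`, evaluated via `lchoose` for numerical stability.
#'
#' @param inc An `incidence_summary`.
#' @param t Subsample size(s), each in `[1, m]`.
#' @return Numeric vector of expected richness values, one per `t`.
#' @export
rarefaction_expected <- function(inc, t) {
  stopifnot(inherits(inc, "incidence_summary"))
  if (any(t < 1 | t > inc$m)) stop("subsample size out of range [1, m]")
  f <- as.numeric(inc$freq)
  vapply(t, function(tt) {
    miss <- exp(lchoose(inc$m - f, tt) - lchoose(inc$m, tt))
    miss[inc$m - f < tt] <- 0
    inc$S_obs - sum(miss)
  }, 0)
}

#' Fit a saturating accumulation model and return its asymptote
#'
#' Robustness companions to Chao2: the Michaelis-Menten model
#' `S(t) = S_max * t / (B + t)` or the asymptotic-regression model
#' `S(t) = a - b * exp(-k * t)`; the asymptote (`S_max` or `a`) plays the
#' role of the richness estimate. Fitted by nonlinear least squares
#' (Levenberg-Marquardt) with heuristics: asymptote initialized just above
#' the last curve value, half-saturation from the curve.
#'
#' @param t Subsample sizes.
#' @param S Expected richness at each `t` (e.g. from
#'   [rarefaction_expected()]).
#' @param model `"michaelis_menten"` or `"asymptotic_regression"`.
#' @return One-row data frame (`estimator`, `estimate`, plus fitted
#'   parameters).
#' @export
fit_asymptote <- function(t, S, model = c("michaelis_menten", "asymptotic_regression")) {
  model <- match.arg(model)
  stopifnot(length(t) == length(S), length(t) >= 4)
  df <- data.frame(t = t, S = S)
  s_top <- max(S)
  if (model == "michaelis_menten") {
    half <- t[which.min(abs(S - s_top / 2))]
    fit <- tryCatch(
      minpack.lm::nlsLM(S ~ Smax * t / (B + t), data = df,
                        start = list(Smax = s_top * 1.1, B = max(half, 0.5)),
                        lower = c(Smax = 1e-8, B = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) stop("Michaelis-Menten fit failed: ", conditionMessage(e))
    )
    cf <- stats::coef(fit)
    data.frame(estimator = "michaelis_menten", estimate = unname(cf["Smax"]),
               B = unname(cf["B"]), stringsAsFactors = FALSE)
  } else {
    # a - b*exp(-k*t); initial decay rate from the first/last curve ratio
    k0 <- max(1 / max(t), 0.01)
    fit <- tryCatch(
      minpack.lm::nlsLM(S ~ a - b * exp(-k * t), data = df,
                        start = list(a = s_top * 1.05, b = s_top, k = k0),
                        lower = c(a = 1e-8, b = 1e-8, k = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) stop("asymptotic-regression fit failed: ", conditionMessage(e))
    )
    cf <- stats::coef(fit)
    data.frame(estimator = "asymptotic_regression", estimate = unname(cf["a"]),
               b = unname(cf["b"]), k = unname(cf["k"]), stringsAsFactors = FALSE)
  }
}

#' Partition species into exclusive and shared sets
#'
#' Set algebra between the species observed inside and outside the protected
#' network for one stratum. In native mode percentages are relative to the
#' union; in priority mode (when `reference` is supplied) they are relative
#' to the reference list and a missing-species count (reference species never
#' observed) is added.
#'
#' @param inside_set,outside_set Character vectors of species ids.
#' @param reference Optional reference species list (priority mode).
#' @param stratum Stratum label stored in the result.
#' @return One-row data frame with counts (`n_inside_only`, `n_outside_only`,
#'   `n_shared`, `n_total`, and `n_missing` in priority mode) and percentages
#'   (`pct_inside` includes shared, as does `pct_outside`).
#' @export
partition_species <- function(inside_set, outside_set, reference = NULL,
                              stratum = "all") {
  inside_set <- unique(as.character(inside_set))
  outside_set <- unique(as.character(outside_set))
  shared <- intersect(inside_set, outside_set)
  in_only <- setdiff(inside_set, outside_set)
  out_only <- setdiff(outside_set, inside_set)
  total <- length(shared) + length(in_only) + length(out_only)
  if (is.null(reference)) {
    denom <- total
    n_missing <- NA_integer_
  } else {
    reference <- unique(as.character(reference))
    denom <- length(reference)
    if (denom == 0) stop("priority mode requires a non-empty reference list")
    n_missing <- length(setdiff(reference, union(inside_set, outside_set)))
  }
  pct <- function(n) if (denom > 0) 100 * n / denom else NA_real_
  data.frame(
    stratum = stratum,
    n_inside_only = length(in_only), n_outside_only = length(out_only),
    n_shared = length(shared), n_total = total, n_missing = n_missing,
    pct_inside = pct(length(shared) + length(in_only)),
    pct_outside = pct(length(shared) + length(out_only)),
    pct_inside_only = pct(length(in_only)),
    pct_outside_only = pct(length(out_only)),
    pct_shared = pct(length(shared)),
    pct_missing = if (is.null(reference)) NA_real_ else pct(n_missing),
    stringsAsFactors = FALSE
  )
}

#' Pearson concordance between two estimate vectors
#'
#' @param x,y Paired finite numeric vectors, length >= 3.
#' @return Pearson product-moment correlation.
#' @export
concordance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values in estimates")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in estimates")
  stats::cor(x, y)
}
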