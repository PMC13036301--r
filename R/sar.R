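# Species-area relationship fitting, AICc model selection, bootstrap CIs and
# the inside-vs-outside parameter contrast.
#
# Area enters in units of 100 km^2 so that the power-model constant c is the
# expected richness of a 100 km^2 patch, the smallest scale at which the
# analysis units are comparable. Fits minimize squared error on the
# untransformed richness scale so that non-nested models (power, extended
# power, Kobayashi) are comparable by one AICc.

SAR_MODELS <- c("power", "extended_power", "kobayashi")

#' Evaluate a species-area model
#'
#' * power: `S = c * A^z`
#' * extended_power: `S = c * A^(z * A^(-d))` (reduces to power at `d = 0`)
#' * kobayashi: `S = c * ln(1 + A/z)`
#'
#' @param model One of `"power"`, `"extended_power"`, `"kobayashi"`.
#' @param A Area (in 100 km^2 units), > 0.
#' @param params Named vector/list with `c`, `z` and (extended power) `d`.
#' @return Predicted richness.
#' @export
sar_model <- function(model, A, params) {
  model <- match.arg(model, SAR_MODELS)
  stopifnot(all(A > 0))
  p <- as.list(params)
  if (is.null(p$c) || p$c <= 0) stop("parameter c must be positive")
  if (model == "kobayashi") {
    if (is.null(p$z) || p$z <= 0) stop("kobayashi half-saturation z must be positive")
    return(p$c * log(1 + A / p$z))
  }
  if (is.null(p$z) || p$z < 0) stop("scaling exponent z must be non-negative")
  if (model == "power") return(p$c * A^p$z)
  if (is.null(p$d)) stop("extended power model needs parameter d")
  p$c * A^(p$z * A^(-p$d))
}

sar_k <- function(model) switch(model, power = 2L, extended_power = 3L, kobayashi = 2L)

#' Small-sample corrected AIC from a least-squares fit
#'
#' `AICc = n*log(RSS/n) + 2K + 2K(K+1)/(n-K-1)` with `K = k + 1` counting the
#' error variance along with the k curve parameters.
#'
#' @param rss Residual sum of squares.
#' @param n Number of points.
#' @param k Number of curve parameters.
#' @return AICc value.
#' @export
aicc_ls <- function(rss, n, k) {
  K <- k + 1
  if (n - K - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

sar_start <- function(model, A, S) {
  # log-log OLS gives (c, z) for the power law; used to seed all models
  ols <- stats::lm(log(S) ~ log(A))
  c0 <- max(exp(stats::coef(ols)[1]), 1e-6)
  z0 <- min(max(stats::coef(ols)[2], 1e-3), 2)
  switch(model,
    power = list(c = c0, z = z0),
    extended_power = list(c = c0, z = z0, d = 0),
    kobayashi = list(c = max(S) / log(1 + max(A) / stats::median(A)),
                     z = stats::median(A))
  )
}

sar_fit_once <- function(A, S, model, start) {
  df <- data.frame(A = A, S = S)
  form <- switch(model,
    power = S ~ c * A^z,
    extended_power = S ~ c * A^(z * A^(-d)),
    kobayashi = S ~ c * log(1 + A / z)
  )
  lower <- switch(model,
    power = c(c = 1e-10, z = 0),
    extended_power = c(c = 1e-10, z = 0, d = -5),
    kobayashi = c(c = 1e-10, z = 1e-10)
  )
  minpack.lm::nlsLM(form, data = df, start = start, lower = lower,
                    control = minpack.lm::nls.lm.control(maxiter = 1000))
}

#' Fit a species-area model by nonlinear least squares
#'
#' Initialization comes from log-log OLS (power parameters), `d = 0`
#' (extended power) and the median area (Kobayashi half-saturation); a small
#' multi-start grid around these seeds is tried if the first fit fails.
#'
#' @param points Data frame with columns `A` (area in 100 km^2 units, > 0)
#'   and `S` (richness estimate, > 0); one group only.
#' @param model Model id.
#' @param group Optional group label carried into the result.
#' @return A `sar_fit` object: list with `model`, `params`, `rss`, `n`, `k`,
#'   `aicc`, `fitted`, `group`.
#' @export
fit_sar <- function(points, model = c("power", "extended_power", "kobayashi"),
                    group = NA_character_) {
  model <- match.arg(model)
  stopifnot(all(c("A", "S") %in% names(points)))
  A <- points$A; S <- points$S
  stopifnot(all(A > 0), all(S > 0))
  k <- sar_k(model)
  if (length(A) < k + 3) stop("need at least k + 3 points to fit ", model)
  start <- sar_start(model, A, S)
  fit <- NULL
  err <- NULL
  for (mult in list(1, 0.5, 2)) {
    st <- lapply(start, function(v) v * if (identical(mult, 1)) 1 else mult)
    if (model == "extended_power") st$d <- 0  # keep nesting seed
    fit <- tryCatch(sar_fit_once(A, S, model, st), error = function(e) {
      err <<- conditionMessage(e); NULL
    })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("SAR fit did not converge for ", model, ": ", err)
  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  structure(
    list(model = model, params = cf, rss = rss, n = length(A), k = k,
         aicc = aicc_ls(rss, length(A), k),
         fitted = as.numeric(stats::fitted(fit)), group = group),
    class = "sar_fit"
  )
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("<sar_fit %s%s n=%d RSS=%.4g AICc=%.4g>\n  params: %s\n",
              x$model, if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              x$n, x$rss, x$aicc,
              paste(names(x$params), signif(x$params, 5), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Select the best SAR model by AICc
#'
#' Minimum AICc wins; ties within `tol` go to the model with fewer
#' parameters, and between equally sized models to the plain power model.
#'
#' @param fits List of `sar_fit` objects (>= 1 converged).
#' @param tol Tie tolerance on AICc.
#' @return The selected `sar_fit`, with a `selection` attribute (data frame
#'   of model, k, AICc).
#' @export
select_sar_model <- function(fits, tol = 1e-9) {
  fits <- Filter(function(f) inherits(f, "sar_fit") && is.finite(f$aicc), fits)
  if (length(fits) == 0) stop("no converged SAR fits to select from")
  tab <- data.frame(
    model = vapply(fits, function(f) f$model, ""),
    k = vapply(fits, function(f) f$k, 0L),
    aicc = vapply(fits, function(f) f$aicc, 0)
  )
  best_aicc <- min(tab$aicc)
  cand <- which(tab$aicc <= best_aicc + tol)
  if (length(cand) > 1) {
    cand <- cand[tab$k[cand] == min(tab$k[cand])]
    if (length(cand) > 1) {
      pw <- cand[tab$model[cand] == "power"]
      cand <- if (length(pw) > 0) pw[1] else cand[1]
    }
  }
  out <- fits[[cand[1]]]
  attr(out, "selection") <- tab
  out
}

#' Nonparametric bootstrap CIs for SAR parameters
#'
#' Case (pairs) resampling with replacement, refit per replicate, percentile
#' 2.5/97.5 bounds. Replicates whose fit fails are dropped and counted.
#'
#' @param points Data frame with `A`, `S`.
#' @param model Model id.
#' @param B Number of replicates.
#' @param seed Integer seed.
#' @param strict Error (rather than warn) when more than 20% of replicates
#'   fail.
#' @return Data frame with one row per parameter: `param`, `point`, `lower`,
#'   `upper`; attributes `B_used`, `B_failed`, `boot` (replicate matrix).
#' @export
sar_bootstrap_ci <- function(points, model, B = 1000L, seed = 1L, strict = FALSE) {
  fit0 <- fit_sar(points, model)
  n <- nrow(points)
  set.seed(as.integer(seed))
  draws <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  reps <- matrix(NA_real_, nrow = B, ncol = length(fit0$params),
                 dimnames = list(NULL, names(fit0$params)))
  for (b in seq_len(B)) {
    idx <- draws[b, ]
    rep_fit <- tryCatch(fit_sar(points[idx, , drop = FALSE], model),
                        error = function(e) NULL)
    if (!is.null(rep_fit)) reps[b, ] <- rep_fit$params
  }
  ok <- stats::complete.cases(reps)
  n_fail <- sum(!ok)
  if (n_fail > 0.2 * B) {
    msg <- sprintf("%d of %d bootstrap replicates failed to converge", n_fail, B)
    if (strict) stop(msg) else warning(msg)
  }
  reps <- reps[ok, , drop = FALSE]
  ci <- apply(reps, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(
    param = names(fit0$params),
    point = as.numeric(fit0$params),
    lower = ci[1, ], upper = ci[2, ],
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "B_used") <- sum(ok)
  attr(out, "B_failed") <- n_fail
  attr(out, "boot") <- reps
  out
}

#' Contrast SAR parameters between the inside and outside groups
#'
#' @param ci_in,ci_out Bootstrap CI tables from [sar_bootstrap_ci()] for the
#'   same model.
#' @param model_in,model_out Model ids of the two fits (must match).
#' @return Data frame per parameter: point estimates, difference
#'   (inside - outside), both CIs and whether they overlap.
#' @export
contrast_sar_groups <- function(ci_in, ci_out,
                                model_in = "power", model_out = "power") {
  if (!identical(model_in, model_out)) {
    stop("cannot contrast different SAR models: ", model_in, " vs ", model_out)
  }
  stopifnot(identical(ci_in$param, ci_out$param))
  data.frame(
    param = ci_in$param,
    inside = ci_in$point, outside = ci_out$point,
    difference = ci_in$point - ci_out$point,
    in_lower = ci_in$lower, in_upper = ci_in$upper,
    out_lower = ci_out$lower, out_upper = ci_out$upper,
    ci_overlap = !(ci_in$lower > ci_out$upper | ci_out$lower > ci_in$upper),
    stringsAsFactors = FALSE
  )
}
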