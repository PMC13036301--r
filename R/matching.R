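# Propensity-score matching of plots inside vs outside the protected network,
# used to validate the inside/outside comparisons on an environmentally
# balanced subset. Greedy 1:1 nearest-neighbour matching without replacement,
# caliper on the logit of the propensity score.

#' Estimate propensity scores for network membership
#'
#' Logistic regression of INSIDE status on environmental covariates
#' (continuous covariates as-is, categoricals one-hot with the reference
#' level dropped). Rows with missing covariate values are dropped and
#' counted.
#'
#' @param plots Data frame with a `status` column (`"INSIDE"` is treatment)
#'   and the covariate columns.
#' @param covariates Character vector of covariate column names.
#' @return Data frame `plot_id`, `treated`, `score` (fitted probability),
#'   `logit`; attributes `n_dropped` and `model` (the `glm`).
#' @export
estimate_propensity <- function(plots, covariates) {
  stopifnot("status" %in% names(plots), "plot_id" %in% names(plots),
            all(covariates %in% names(plots)))
  keep <- stats::complete.cases(plots[, covariates, drop = FALSE]) &
    plots$status %in% c("INSIDE", "OUTSIDE")
  n_dropped <- sum(!keep)
  d <- plots[keep, , drop = FALSE]
  d$.treated <- as.integer(d$status == "INSIDE")
  for (cv in covariates) if (is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])
  form <- stats::as.formula(paste(".treated ~", paste(covariates, collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(), data = d,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  p <- stats::fitted(fit)
  if (any(p < 1e-10 | p > 1 - 1e-10)) {
    stop("separation in the propensity model; reduce or coarsen covariates")
  }
  out <- data.frame(plot_id = d$plot_id, treated = d$.treated == 1L,
                    score = as.numeric(p), logit = stats::qlogis(as.numeric(p)),
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "model") <- fit
  out
}

#' Greedy 1:1 propensity matching without replacement
#'
#' Treated plots are processed in decreasing-score order (ties broken by plot
#' id); each is paired with the nearest still-unmatched control by absolute
#' logit-score distance (ties again by plot id). Pairs farther apart than
#' `caliper_sd` standard deviations of the logit scores are discarded.
#'
#' @param scores Data frame from [estimate_propensity()].
#' @param caliper_sd Caliper in SD units of the logit scores (default 0.25).
#' @param ratio Controls per treated (only 1 supported).
#' @return A `match_result`: list with `pairs` (data frame `treated_id`,
#'   `control_id`, `distance`), `caliper` (absolute logit threshold),
#'   `retention` (matched plots / scored plots), `n_treated`, `n_control`.
#' @export
greedy_match <- function(scores, caliper_sd = 0.25, ratio = 1L) {
  stopifnot(caliper_sd > 0)
  if (ratio != 1L) stop("only 1:1 matching is supported")
  tr <- scores[scores$treated, , drop = FALSE]
  co <- scores[!scores$treated, , drop = FALSE]
  if (nrow(tr) == 0 || nrow(co) == 0) stop("both groups must be non-empty")
  caliper <- caliper_sd * stats::sd(scores$logit)
  ord <- order(-tr$score, tr$plot_id)
  tr <- tr[ord, , drop = FALSE]
  co <- co[order(co$plot_id), , drop = FALSE]  # stable tie-break by id
  used <- rep(FALSE, nrow(co))
  t_ids <- character(0); c_ids <- character(0); dists <- numeric(0)
  for (i in seq_len(nrow(tr))) {
    if (all(used)) break
    d <- abs(co$logit - tr$logit[i])
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= caliper) {
      used[j] <- TRUE
      t_ids <- c(t_ids, tr$plot_id[i])
      c_ids <- c(c_ids, co$plot_id[j])
      dists <- c(dists, d[j])
    }
  }
  if (length(t_ids) == 0) stop("no common support: zero pairs within the caliper")
  structure(
    list(pairs = data.frame(treated_id = t_ids, control_id = c_ids,
                            distance = dists, stringsAsFactors = FALSE),
         caliper = caliper,
         retention = 2 * length(t_ids) / nrow(scores),
         n_treated = nrow(tr), n_control = nrow(co)),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result pairs=%d retention=%.1f%% caliper=%.4g>\n",
              nrow(x$pairs), 100 * x$retention, x$caliper))
  invisible(x)
}

#' Covariate balance before and after matching
#'
#' Standardized mean difference (SMD) per continuous covariate:
#' `(mean_T - mean_C) / pooled SD`, where the pooled SD comes from the
#' pre-matching groups so before/after values are on the same scale.
#' Categorical covariates are expanded to per-level proportion differences.
#' Zero pooled SD yields SMD 0 with `degenerate = TRUE`.
#'
#' @param plots Plot data frame with `plot_id`, `status` and covariates.
#' @param pairs Pair data frame from [greedy_match()].
#' @param covariates Covariate column names.
#' @return Data frame `covariate`, `smd_before`, `smd_after`, `degenerate`.
#' @export
balance_stats <- function(plots, pairs, covariates) {
  expand <- function(df) {
    out <- list()
    for (cv in covariates) {
      v <- df[[cv]]
      if (is.numeric(v)) {
        out[[cv]] <- v
      } else {
        v <- as.character(v)
        for (lev in sort(unique(plots[[cv]]))) {
          out[[paste0(cv, ":", lev)]] <- as.numeric(v == lev)
        }
      }
    }
    as.data.frame(out, check.names = FALSE)
  }
  tr_all <- plots[plots$status == "INSIDE", , drop = FALSE]
  co_all <- plots[plots$status == "OUTSIDE", , drop = FALSE]
  Xt <- expand(tr_all); Xc <- expand(co_all)
  tr_m <- plots[match(pairs$treated_id, plots$plot_id), , drop = FALSE]
  co_m <- plots[match(pairs$control_id, plots$plot_id), , drop = FALSE]
  Xtm <- expand(tr_m); Xcm <- expand(co_m)
  smd <- function(a, b, s) if (s == 0) 0 else (mean(a) - mean(b)) / s
  res <- lapply(names(Xt), function(nm) {
    s_pool <- sqrt((stats::var(Xt[[nm]]) + stats::var(Xc[[nm]])) / 2)
    data.frame(covariate = nm,
               smd_before = smd(Xt[[nm]], Xc[[nm]], s_pool),
               smd_after = smd(Xtm[[nm]], Xcm[[nm]], s_pool),
               degenerate = s_pool == 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
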