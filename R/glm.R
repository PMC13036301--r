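# Binomial GLMs of the proportion of species recorded inside the protected
# network per analysis unit, with deviation (sum-to-zero) coding so each
# factor coefficient is a departure from the network-wide mean, and plot
# density inside the network as a sampling-effort covariate.

#' Fit a deviation-coded binomial GLM
#'
#' Response is `cbind(successes, trials - successes)` per unit (aggregated
#' binomial likelihood), the factor is sum-to-zero coded, and sampling effort
#' enters as a linear or linear + quadratic covariate. The implicit last
#' factor level's effect and Wald CI are derived as minus the sum of the
#' other level effects.
#'
#' @param data Data frame with the response and predictor columns.
#' @param successes,trials Column names of the binomial counts.
#' @param factor_col Column name of the grouping factor (country or
#'   bioregion), or `NULL` for no factor.
#' @param effort_col Column name of the effort covariate (plots per km^2
#'   inside the network), or `NULL`.
#' @param effort_terms `"linear"` or `"quadratic"` (linear + quadratic).
#' @return A `deviation_glm` object: list with `fit` (the `glm`),
#'   `coefficients` (data frame incl. the derived last level, SEs and 95%
#'   Wald CIs), `null_deviance`, `residual_deviance`, `aicc`, `d2`,
#'   `converged`, `levels`, `factor_col`.
#' @export
fit_binomial_glm <- function(data, successes = "n_inside", trials = "n_total",
                             factor_col = NULL, effort_col = NULL,
                             effort_terms = c("linear", "quadratic")) {
  effort_terms <- match.arg(effort_terms)
  stopifnot(all(c(successes, trials) %in% names(data)))
  s <- data[[successes]]; tr <- data[[trials]]
  stopifnot(all(tr >= 1), all(s >= 0), all(s <= tr))
  df <- data.frame(.s = s, .f = tr - s)
  rhs <- "1"
  lv <- NULL
  if (!is.null(factor_col)) {
    fac <- factor(data[[factor_col]])
    if (nlevels(fac) < 2) stop("factor '", factor_col, "' needs at least 2 levels")
    lv <- levels(fac)
    df$.g <- fac
    rhs <- c(rhs, ".g")
  }
  if (!is.null(effort_col)) {
    df$.e <- as.numeric(data[[effort_col]])
    rhs <- c(rhs, ".e")
    if (effort_terms == "quadratic") rhs <- c(rhs, "I(.e^2)")
  }
  form <- stats::as.formula(paste("cbind(.s, .f) ~", paste(rhs, collapse = " + ")))
  ctr <- if (!is.null(factor_col)) list(.g = stats::contr.sum(length(lv))) else NULL
  fit <- stats::glm(form, family = stats::binomial(), data = df, contrasts = ctr,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design matrix: ", paste(
      names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  mu <- stats::fitted(fit)
  sep <- mu < 1e-8 | mu > 1 - 1e-8
  if (any(sep)) {
    who <- if (!is.null(factor_col)) paste(unique(df$.g[sep]), collapse = ", ") else "some units"
    stop("separation: fitted probabilities at 0/1 for level(s) ", who)
  }
  cf <- summary(fit)$coefficients
  V <- stats::vcov(fit)
  coefs <- data.frame(
    term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
    lower = cf[, 1] - stats::qnorm(0.975) * cf[, 2],
    upper = cf[, 1] + stats::qnorm(0.975) * cf[, 2],
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(factor_col)) {
    gi <- grep("^\\.g", rownames(cf))
    # relabel sum-contrast columns .g1...g(L-1) with their level names
    coefs$term[gi] <- paste0("level:", lv[seq_along(gi)])
    # implicit last level: effect = -sum(others), var = 1' V 1 over the block
    eff <- -sum(cf[gi, 1])
    v_last <- sum(V[gi, gi])
    se_last <- sqrt(v_last)
    coefs <- rbind(coefs, data.frame(
      term = paste0("level:", lv[length(lv)]), estimate = eff, se = se_last,
      lower = eff - stats::qnorm(0.975) * se_last,
      upper = eff + stats::qnorm(0.975) * se_last,
      stringsAsFactors = FALSE
    ))
  }
  K <- length(stats::coef(fit))
  n <- nrow(df)
  aicc <- stats::AIC(fit) + if (n - K - 1 > 0) 2 * K * (K + 1) / (n - K - 1) else Inf
  structure(
    list(fit = fit, coefficients = coefs,
         null_deviance = fit$null.deviance,
         residual_deviance = fit$deviance,
         aicc = aicc,
         d2 = if (fit$null.deviance > 0) 1 - fit$deviance / fit$null.deviance else 0,
         converged = fit$converged, levels = lv, factor_col = factor_col,
         effort_terms = if (is.null(effort_col)) NA_character_ else effort_terms),
    class = "deviation_glm"
  )
}

#' @export
print.deviation_glm <- function(x, ...) {
  cat(sprintf("<deviation_glm D2=%.3f AICc=%.2f deviance %0.2f -> %0.2f>\n",
              x$d2, x$aicc, x$null_deviance, x$residual_deviance))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Choose linear vs linear+quadratic effort terms
#'
#' The quadratic term is kept only when it improves AICc by more than 2 AND
#' its 95% Wald CI excludes zero; otherwise the linear model is retained
#' (ties go to the simpler model).
#'
#' @inheritParams fit_binomial_glm
#' @return List with `chosen` (`"linear"` or `"quadratic"`), `fit` (the
#'   selected `deviation_glm`) and `comparison` (data frame of AICc, D2, and
#'   the quadratic term's CI).
#' @export
select_effort_terms <- function(data, successes = "n_inside", trials = "n_total",
                                factor_col = NULL, effort_col = "density_inside") {
  lin <- fit_binomial_glm(data, successes, trials, factor_col, effort_col, "linear")
  quad <- fit_binomial_glm(data, successes, trials, factor_col, effort_col, "quadratic")
  qrow <- quad$coefficients[quad$coefficients$term == "I(.e^2)", ]
  excl0 <- nrow(qrow) == 1 && (qrow$lower > 0 || qrow$upper < 0)
  keep_quad <- (quad$aicc < lin$aicc - 2) && excl0
  comparison <- data.frame(
    effort_terms = c("linear", "quadratic"),
    aicc = c(lin$aicc, quad$aicc),
    d2 = c(lin$d2, quad$d2),
    quad_lower = c(NA, qrow$lower), quad_upper = c(NA, qrow$upper)
  )
  list(chosen = if (keep_quad) "quadratic" else "linear",
       fit = if (keep_quad) quad else lin,
       comparison = comparison)
}

#' Flag factor levels deviating from the network-wide mean
#'
#' A level is `above` (`below`) when its 95% CI lies entirely above (below)
#' zero on the deviation-coded scale, `average` otherwise.
#'
#' @param fit A `deviation_glm` fitted with a factor.
#' @return Data frame with `level`, `estimate`, `lower`, `upper`, `flag`.
#' @export
deviation_flags <- function(fit) {
  stopifnot(inherits(fit, "deviation_glm"))
  cf <- fit$coefficients
  li <- grep("^level:", cf$term)
  if (length(li) == 0) stop("fit has no factor levels to flag")
  cf <- cf[li, ]
  flag <- ifelse(cf$lower > 0, "above", ifelse(cf$upper < 0, "below", "average"))
  data.frame(level = sub("^level:", "", cf$term),
             estimate = cf$estimate, lower = cf$lower, upper = cf$upper,
             flag = flag, stringsAsFactors = FALSE, row.names = NULL)
}
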