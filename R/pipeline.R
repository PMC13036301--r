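# End-to-end orchestration: filter -> classify -> assign units -> imbalance
# rule -> partitions & richness per level and mode -> species-area contrast
# inside vs outside -> deviation GLMs -> optional matching validation.

#' Run configuration
#'
#' @param synth A [synth_config()] describing the synthetic world, or `NULL`
#'   when `inputs` paths are given.
#' @param inputs Optional named list of file paths (`plots`, `occurrences`,
#'   `pa`, `regions`) read with the package readers instead of generating
#'   data.
#' @param policy A [filter_policy()].
#' @param levels Aggregation levels to partition at (any of `"unit"`,
#'   `"country"`, `"bioregion"`, `"eu"`).
#' @param modes `"native"` and/or `"priority"`.
#' @param priority_reference Reference priority list (character vector); for
#'   synthetic runs defaults to the generator's ground-truth priority list.
#' @param sar_models Candidate SAR models.
#' @param B Bootstrap replicates for SAR CIs.
#' @param glm_factor `"country"` or `"bioregion"`.
#' @param matching Run the propensity-matching validation?
#' @param imbalance_factor Maximum inside/outside plot-count ratio per unit.
#' @param seed Master seed fanned out to the generator and bootstrap.
#' @param out_dir Optional output directory for [write_results()].
#' @return A `run_config` list.
#' @export
run_config <- function(synth = synth_config(), inputs = NULL,
                       policy = filter_policy(),
                       levels = c("unit", "country", "bioregion", "eu"),
                       modes = c("native", "priority"),
                       priority_reference = NULL,
                       sar_models = c("power", "extended_power", "kobayashi"),
                       B = 1000L, glm_factor = "country", matching = TRUE,
                       imbalance_factor = 10, seed = 1L, out_dir = NULL) {
  if (!is.null(synth)) synth$seed <- as.integer(seed)
  structure(list(synth = synth, inputs = inputs, policy = policy,
                 levels = levels, modes = modes,
                 priority_reference = priority_reference,
                 sar_models = sar_models, B = as.integer(B),
                 glm_factor = glm_factor, matching = isTRUE(matching),
                 imbalance_factor = imbalance_factor,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

stratum_ids <- function(plots, level) {
  switch(level,
    unit = paste(plots$country, plots$bioregion, sep = ":"),
    country = plots$country,
    bioregion = plots$bioregion,
    eu = rep("EU", nrow(plots)),
    stop("unknown level: ", level)
  )
}

# species sets observed inside/outside per stratum of one level
species_sets <- function(occ, plots, level) {
  sid <- stratum_ids(plots, level)
  res <- list()
  for (s in sort(unique(sid))) {
    pin <- plots$plot_id[sid == s & plots$status == "INSIDE"]
    pout <- plots$plot_id[sid == s & plots$status == "OUTSIDE"]
    res[[s]] <- list(
      inside = unique(occ$species_id[occ$plot_id %in% pin]),
      outside = unique(occ$species_id[occ$plot_id %in% pout])
    )
  }
  res
}

partition_level <- function(occ, plots, level, reference = NULL) {
  sets <- species_sets(occ, plots, level)
  rows <- lapply(names(sets), function(s) {
    partition_species(sets[[s]]$inside, sets[[s]]$outside, reference, stratum = s)
  })
  out <- do.call(rbind, rows)
  out$level <- level
  out
}

richness_for_stratum <- function(occ, plot_ids) {
  inc <- build_incidence(occ, plot_ids)
  est <- data.frame(m = inc$m, S_obs = inc$S_obs,
                    chao2 = NA_real_, michaelis_menten = NA_real_,
                    asymptotic_regression = NA_real_)
  if (inc$m >= 2) est$chao2 <- chao2(inc)$estimate
  if (inc$m >= 5 && inc$S_obs >= 2) {
    tt <- unique(pmax(1, round(seq(1, inc$m, length.out = 12))))
    if (length(tt) >= 4) {
      curve <- rarefaction_expected(inc, tt)
      est$michaelis_menten <- tryCatch(
        fit_asymptote(tt, curve, "michaelis_menten")$estimate, error = function(e) NA_real_)
      est$asymptotic_regression <- tryCatch(
        fit_asymptote(tt, curve, "asymptotic_regression")$estimate, error = function(e) NA_real_)
    }
  }
  est
}

#' Run the full gap analysis
#'
#' Executes the pipeline described in the package vignette and returns a
#' result bundle; when `config$out_dir` is set, the tables plus a JSON
#' manifest are also written there. With a fixed seed the whole run is
#' reproducible.
#'
#' @param config A [run_config()].
#' @return A `gap_bundle` list: `units` (retained analysis units with
#'   densities), `partitions`, `richness` (per unit and group), `sar`
#'   (selected fits, CIs, contrast, selection table), `glm` (chosen effort
#'   terms, coefficients, flags), `matching` (balance, retention, matched
#'   partition; `NULL` when disabled), `counts` (stage bookkeeping), plus the
#'   inputs used (`plots`, `occurrences`) and ground `truth` when synthetic.
#' @export
run_gap_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  counts <- list()
  # --- data ------------------------------------------------------------------
  if (!is.null(config$inputs)) {
    plots <- read_plot_table(config$inputs$plots)
    occ <- read_occurrences(config$inputs$occurrences)
    pa <- read_polygon_layer(config$inputs$pa, role = "PROTECTED")
    regions <- read_polygon_layer(config$inputs$regions, role = "REGION")
    covariates <- if (!is.null(config$inputs$covariates)) {
      utils::read.csv(config$inputs$covariates, stringsAsFactors = FALSE,
                      colClasses = c(plot_id = "character"))
    } else NULL
    truth <- NULL
  } else {
    world <- generate_world(config$synth)
    plots <- world$plots; occ <- world$occurrences
    pa <- world$pa; regions <- world$regions
    covariates <- world$covariates
    truth <- world$truth
  }
  counts$plots_loaded <- nrow(plots)

  # --- filter, classify, assign ---------------------------------------------
  plots <- filter_plots(plots, config$policy)
  counts$plots_eligible <- nrow(plots)
  plots <- classify_plots(plots, pa, config$policy)
  plots <- assign_units(plots, regions)
  plots <- plots[plots$country != "UNASSIGNED", , drop = FALSE]
  units <- plot_density(build_units(plots, regions, pa))
  units <- imbalance_filter(units, config$imbalance_factor)
  counts$units_retained <- nrow(units)
  counts$units_excluded <- nrow(attr(units, "excluded"))
  unit_key <- paste(units$country, units$bioregion, sep = ":")
  plots <- plots[paste(plots$country, plots$bioregion, sep = ":") %in% unit_key, ,
                 drop = FALSE]
  occ <- occ[occ$plot_id %in% plots$plot_id, , drop = FALSE]
  counts$plots_analyzed <- nrow(plots)
  counts$occurrences_analyzed <- nrow(occ)

  # --- partitions per level and mode -----------------------------------------
  reference <- config$priority_reference
  if (is.null(reference) && !is.null(truth)) reference <- truth$priority_species
  partitions <- list()
  for (mode in config$modes) {
    occ_m <- if (mode == "priority") occ[occ$priority, , drop = FALSE] else occ
    ref_m <- if (mode == "priority") reference else NULL
    if (mode == "priority" && is.null(ref_m)) {
      stop("priority mode requires a reference species list")
    }
    for (lv in config$levels) {
      p <- partition_level(occ_m, plots, lv, ref_m)
      p$mode <- mode
      partitions[[paste(mode, lv)]] <- p
    }
  }
  partitions <- do.call(rbind, partitions)
  rownames(partitions) <- NULL

  # --- per-unit richness estimates -------------------------------------------
  rich <- list()
  for (u in seq_len(nrow(units))) {
    for (grp in c("INSIDE", "OUTSIDE")) {
      sel <- plots$country == units$country[u] &
        plots$bioregion == units$bioregion[u] & plots$status == grp
      if (!any(sel)) next
      est <- richness_for_stratum(occ, plots$plot_id[sel])
      est$country <- units$country[u]; est$bioregion <- units$bioregion[u]
      est$group <- grp
      est$area_km2 <- if (grp == "INSIDE") units$area_inside_km2[u] else units$area_outside_km2[u]
      rich[[length(rich) + 1L]] <- est
    }
  }
  richness <- do.call(rbind, rich)

  # --- species-area relationship ---------------------------------------------
  sar <- NULL
  sar_ok <- !is.na(richness$chao2) & richness$area_km2 > 0 & richness$chao2 > 0
  pts <- data.frame(A = richness$area_km2[sar_ok] / 100,
                    S = richness$chao2[sar_ok],
                    group = richness$group[sar_ok])
  n_min <- 3 + max(vapply(config$sar_models, sar_k, 0L))
  if (sum(pts$group == "INSIDE") >= n_min && sum(pts$group == "OUTSIDE") >= n_min) {
    fits <- list()
    sel_tab <- NULL
    for (grp in c("INSIDE", "OUTSIDE")) {
      gp <- pts[pts$group == grp, ]
      fg <- list()
      for (mdl in config$sar_models) {
        fg[[mdl]] <- tryCatch(fit_sar(gp, mdl, group = grp), error = function(e) NULL)
      }
      fg <- Filter(Negate(is.null), fg)
      fits[[grp]] <- fg
      st <- data.frame(group = grp,
                       model = vapply(fg, function(f) f$model, ""),
                       aicc = vapply(fg, function(f) f$aicc, 0))
      sel_tab <- rbind(sel_tab, st)
    }
    # one model for both groups: lowest summed AICc, ties to fewer parameters
    # then to the power model (mirrors choosing the simplest when differences
    # are negligible)
    shared_models <- intersect(names(fits$INSIDE), names(fits$OUTSIDE))
    tot <- vapply(shared_models, function(m) fits$INSIDE[[m]]$aicc + fits$OUTSIDE[[m]]$aicc, 0)
    pseudo <- lapply(shared_models, function(m) {
      structure(list(model = m, k = sar_k(m), aicc = tot[[m]], params = NULL),
                class = "sar_fit")
    })
    chosen <- select_sar_model(pseudo)$model
    ci_in <- sar_bootstrap_ci(pts[pts$group == "INSIDE", ], chosen,
                              B = config$B, seed = config$seed + 11L)
    ci_out <- sar_bootstrap_ci(pts[pts$group == "OUTSIDE", ], chosen,
                               B = config$B, seed = config$seed + 12L)
    sar <- list(model = chosen, selection = sel_tab,
                fit_inside = fits$INSIDE[[chosen]],
                fit_outside = fits$OUTSIDE[[chosen]],
                ci_inside = ci_in, ci_outside = ci_out,
                contrast = contrast_sar_groups(ci_in, ci_out, chosen, chosen),
                points = pts)
  }

  # --- deviation GLM ----------------------------------------------------------
  glm_res <- NULL
  pu <- partitions[partitions$level == "unit" & partitions$mode == "native", ]
  key <- match(paste(units$country, units$bioregion, sep = ":"), pu$stratum)
  glm_data <- data.frame(
    country = units$country, bioregion = units$bioregion,
    n_inside = pu$n_shared[key] + pu$n_inside_only[key],
    n_total = pu$n_total[key],
    density_inside = units$density_inside
  )
  glm_data <- glm_data[stats::complete.cases(glm_data), , drop = FALSE]
  if (nrow(glm_data) >= 4 && length(unique(glm_data[[config$glm_factor]])) >= 2) {
    sel <- select_effort_terms(glm_data, "n_inside", "n_total",
                               factor_col = config$glm_factor,
                               effort_col = "density_inside")
    glm_res <- list(effort_terms = sel$chosen, comparison = sel$comparison,
                    fit = sel$fit, coefficients = sel$fit$coefficients,
                    d2 = sel$fit$d2, aicc = sel$fit$aicc,
                    flags = deviation_flags(sel$fit))
  }

  # --- matching validation ----------------------------------------------------
  match_res <- NULL
  if (config$matching && !is.null(covariates)) {
    cov_cols <- c("mean_annual_temp", "annual_precip", "temp_seasonality",
                  "precip_seasonality", "elevation")
    md <- merge(plots, covariates, by = "plot_id")
    cats <- c("bioregion", "country")[c(length(unique(md$bioregion)) > 1,
                                        length(unique(md$country)) > 1)]
    covs <- c(cov_cols, cats)
    scores <- estimate_propensity(md, covs)
    mres <- greedy_match(scores, caliper_sd = 0.25, ratio = 1L)
    balance <- balance_stats(md, mres$pairs, covs)
    matched_ids <- c(mres$pairs$treated_id, mres$pairs$control_id)
    mp <- plots[plots$plot_id %in% matched_ids, , drop = FALSE]
    mocc <- occ[occ$plot_id %in% matched_ids, , drop = FALSE]
    matched_partition <- partition_level(mocc, mp, "eu")
    match_res <- list(pairs = mres$pairs, retention = mres$retention,
                      caliper = mres$caliper, balance = balance,
                      matched_partition = matched_partition)
  }

  bundle <- structure(
    list(units = units, partitions = partitions, richness = richness,
         sar = sar, glm = glm_res, matching = match_res, counts = counts,
         plots = plots, occurrences = occ, truth = truth,
         config = config),
    class = "gap_bundle"
  )

  if (!is.null(config$out_dir)) {
    tables <- list(units = units, partitions = partitions, richness = richness)
    if (!is.null(sar)) {
      tables$sar <- rbind(
        cbind(group = "INSIDE", model = sar$model, sar$ci_inside),
        cbind(group = "OUTSIDE", model = sar$model, sar$ci_outside)
      )
      tables$sar_contrast <- sar$contrast
    }
    if (!is.null(glm_res)) {
      tables$glm_coefficients <- glm_res$coefficients
      tables$glm_flags <- glm_res$flags
    }
    if (!is.null(match_res)) {
      tables$matching_balance <- match_res$balance
      tables$matched_partition <- match_res$matched_partition
    }
    cfg_clean <- config[setdiff(names(config), "out_dir")]
    write_results(tables, config$out_dir, config = cfg_clean, seed = config$seed)
  }
  bundle
}

#' One-page text summary of a result bundle
#'
#' @param bundle A `gap_bundle` from [run_gap_analysis()].
#' @return Character vector of markdown lines (also printed invisibly usable
#'   via `cat`).
#' @export
summarize_run <- function(bundle) {
  stopifnot(inherits(bundle, "gap_bundle"))
  lines <- c("# Protected-area gap analysis summary", "")
  eu <- bundle$partitions[bundle$partitions$level == "eu" &
                            bundle$partitions$mode == "native", ]
  if (nrow(eu) == 1) {
    lines <- c(lines, sprintf(
      paste0("Native species, network-wide: %d total; %.0f%% recorded inside ",
             "the network (incl. shared), %.0f%% outside; %.0f%% shared, ",
             "%.0f%% exclusively inside, %.0f%% exclusively outside."),
      eu$n_total, eu$pct_inside, eu$pct_outside, eu$pct_shared,
      eu$pct_inside_only, eu$pct_outside_only), "")
  }
  pr <- bundle$partitions[bundle$partitions$level == "eu" &
                            bundle$partitions$mode == "priority", ]
  if (nrow(pr) == 1) {
    lines <- c(lines, sprintf(
      paste0("Priority species: %.0f%% of the reference list recorded inside ",
             "the network, %.1f%% shared, %.0f%% missing from the data."),
      pr$pct_inside, pr$pct_shared, pr$pct_missing), "")
  } else {
    lines <- c(lines, "Priority mode: not run.", "")
  }
  if (!is.null(bundle$sar)) {
    ci <- function(tab, p) tab[tab$param == p, ]
    zi <- ci(bundle$sar$ci_inside, "z"); zo <- ci(bundle$sar$ci_outside, "z")
    lines <- c(lines, sprintf(
      "Species-area (%s model): z inside %.3f [%.3f, %.3f], z outside %.3f [%.3f, %.3f]%s.",
      bundle$sar$model, zi$point, zi$lower, zi$upper, zo$point, zo$lower, zo$upper,
      if (any(!bundle$sar$contrast$ci_overlap[bundle$sar$contrast$param == "z"]))
        " (non-overlapping CIs)" else ""), "")
  }
  if (!is.null(bundle$glm)) {
    fl <- bundle$glm$flags
    above <- fl$level[fl$flag == "above"]; below <- fl$level[fl$flag == "below"]
    lines <- c(lines, sprintf(
      "Deviation GLM (%s effort term, D2 = %.2f): above average: %s; below: %s.",
      bundle$glm$effort_terms, bundle$glm$d2,
      if (length(above)) paste(above, collapse = ", ") else "none",
      if (length(below)) paste(below, collapse = ", ") else "none"), "")
  }
  if (!is.null(bundle$matching)) {
    lines <- c(lines, sprintf(
      "Matching validation: %.0f%% of plots retained; matched-subset %% inside = %.1f.",
      100 * bundle$matching$retention,
      bundle$matching$matched_partition$pct_inside), "")
  }
  lines
}
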