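# Plot eligibility filters, inside/outside classification by buffer overlap,
# analysis-unit assignment, plot densities and the sampling-imbalance rule.

#' Plot eligibility policy
#'
#' Defaults follow the protected-area gap-analysis conventions: location
#' uncertainty at most 10 km, surveys from 1994 (the network's formal
#' establishment year) onward, human-made habitats (EUNIS level-1 class V)
#' excluded, and a strict >50% buffer-overlap rule for INSIDE status.
#'
#' @param max_uncertainty_m Maximum location uncertainty radius (m).
#' @param min_year Earliest eligible survey year.
#' @param excluded_habitat_classes Habitat classes to drop.
#' @param overlap_threshold Buffer-overlap fraction that must be *exceeded*
#'   for INSIDE status (strict inequality).
#' @param n_segments Vertices used to polygonize circular buffers.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(max_uncertainty_m = 10000, min_year = 1994,
                          excluded_habitat_classes = "V",
                          overlap_threshold = 0.5, n_segments = 64L) {
  stopifnot(overlap_threshold >= 0, overlap_threshold <= 1)
  structure(list(max_uncertainty_m = max_uncertainty_m, min_year = min_year,
                 excluded_habitat_classes = excluded_habitat_classes,
                 overlap_threshold = overlap_threshold,
                 n_segments = as.integer(n_segments)),
            class = "filter_policy")
}

#' Apply the plot-eligibility filters
#'
#' Retains plots with `uncertainty_m <= max_uncertainty_m`, `year >=
#' min_year`, and a habitat class outside the excluded set. Missing habitat
#' classes are retained (the exclusion rule names specific classes only) but
#' counted in the report.
#'
#' @param plots Plot data frame.
#' @param policy A [filter_policy()].
#' @return Filtered plot data frame with attribute `exclusions` (named counts
#'   per reason, plus `missing_habitat` among the retained).
#' @export
filter_plots <- function(plots, policy = filter_policy()) {
  too_uncertain <- plots$uncertainty_m > policy$max_uncertainty_m
  pre_establishment <- plots$year < policy$min_year
  bad_habitat <- !is.na(plots$habitat_class) &
    plots$habitat_class %in% policy$excluded_habitat_classes
  drop <- too_uncertain | pre_establishment | bad_habitat
  out <- plots[!drop, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("no plots left after filtering")
  attr(out, "exclusions") <- c(
    uncertainty = sum(too_uncertain),
    pre_establishment = sum(pre_establishment & !too_uncertain),
    habitat = sum(bad_habitat & !too_uncertain & !pre_establishment),
    missing_habitat = sum(is.na(out$habitat_class))
  )
  out
}

#' Fraction of a plot's uncertainty buffer inside the protected layer
#'
#' The buffer is the circle of radius `uncertainty_m` around the plot,
#' polygonized with `n_segments` vertices; the overlap fraction is the
#' intersection area with the protected features divided by the buffer area.
#' Protected features are assumed to have disjoint interiors (their
#' intersection areas are summed and capped at 1). A zero-radius buffer
#' degrades to a point-in-polygon test (fraction 1 or 0).
#'
#' @param x,y Plot coordinates.
#' @param uncertainty_m Buffer radius (>= 0).
#' @param pa A `polygon_layer` of protected features.
#' @param n_segments Circle polygonization count.
#' @return Overlap fraction in `[0, 1]`.
#' @export
buffer_overlap_fraction <- function(x, y, uncertainty_m, pa, n_segments = 64L) {
  stopifnot(uncertainty_m >= 0)
  if (uncertainty_m == 0) {
    return(if (point_in_layer(pa, x, y)) 1 else 0)
  }
  buf <- circle_ring(x, y, uncertainty_m, n_segments)
  buf_area <- abs(ring_area_signed(buf))
  r <- uncertainty_m
  inter <- 0
  for (f in pa$features) {
    for (poly in f$geometry) {
      bb <- poly[[1]]
      if (max(bb[, 1]) < x - r || min(bb[, 1]) > x + r ||
          max(bb[, 2]) < y - r || min(bb[, 2]) > y + r) next
      inter <- inter + intersection_area_convex(poly, buf)
    }
  }
  min(inter / buf_area, 1)
}

#' Classify plots inside/outside the protected network
#'
#' Computes each plot's buffer-overlap fraction and assigns
#' `status = "INSIDE"` iff the fraction strictly exceeds the policy
#' threshold (a buffer exactly half inside is OUTSIDE). The fraction is kept
#' in the `overlap_fraction` column for diagnostics.
#'
#' @param plots Filtered plot data frame.
#' @param pa Protected `polygon_layer`.
#' @param policy A [filter_policy()].
#' @return The plots with `overlap_fraction` and `status` filled in.
#' @export
classify_plots <- function(plots, pa, policy = filter_policy()) {
  n <- nrow(plots)
  frac <- numeric(n)
  for (i in seq_len(n)) {
    frac[i] <- buffer_overlap_fraction(plots$x[i], plots$y[i],
                                       plots$uncertainty_m[i], pa,
                                       policy$n_segments)
  }
  plots$overlap_fraction <- frac
  plots$status <- ifelse(frac > policy$overlap_threshold, "INSIDE", "OUTSIDE")
  plots
}

#' Assign plots to analysis units (country x bioregion)
#'
#' Plots that already carry both labels keep them (conflicts with the spatial
#' assignment are counted, not overwritten); otherwise the labels come from
#' the first region feature containing the plot centre (deterministic
#' tie-break for boundary points). Plots outside every region get
#' `UNASSIGNED` labels.
#'
#' @param plots Plot data frame.
#' @param regions Region `polygon_layer` whose feature properties carry
#'   `country` and `bioregion`.
#' @return Plots with `country`/`bioregion` filled; attributes `n_conflicts`
#'   and `n_unassigned`.
#' @export
assign_units <- function(plots, regions) {
  n_conflicts <- 0L
  n_unassigned <- 0L
  for (i in seq_len(nrow(plots))) {
    pre <- !is.na(plots$country[i]) && !is.na(plots$bioregion[i])
    fi <- first_containing_feature(regions, plots$x[i], plots$y[i])
    if (is.na(fi)) {
      if (!pre) {
        plots$country[i] <- "UNASSIGNED"
        plots$bioregion[i] <- "UNASSIGNED"
        n_unassigned <- n_unassigned + 1L
      }
      next
    }
    props <- regions$features[[fi]]$properties
    if (pre) {
      if (!identical(plots$country[i], props$country) ||
          !identical(plots$bioregion[i], props$bioregion)) {
        n_conflicts <- n_conflicts + 1L
      }
    } else {
      plots$country[i] <- props$country
      plots$bioregion[i] <- props$bioregion
    }
  }
  attr(plots, "n_conflicts") <- n_conflicts
  attr(plots, "n_unassigned") <- n_unassigned
  plots
}

#' Build the analysis-unit table
#'
#' One row per (country, bioregion) present in the region layer: inside and
#' outside land areas (km^2) and classified plot counts.
#'
#' @param plots Classified, unit-assigned plot data frame.
#' @param regions Region `polygon_layer` (properties `country`, `bioregion`).
#' @param pa Protected `polygon_layer`.
#' @param coord_unit_m Length of one coordinate unit in metres (areas are
#'   converted to km^2). Default 1 (coordinates in metres).
#' @return Data frame `country`, `bioregion`, `area_inside_km2`,
#'   `area_outside_km2`, `n_plots_inside`, `n_plots_outside`.
#' @export
build_units <- function(plots, regions, pa, coord_unit_m = 1) {
  to_km2 <- (coord_unit_m / 1000)^2
  rows <- lapply(regions$features, function(f) {
    a_tot <- sum(vapply(f$geometry, polygon_area, 0)) * to_km2
    # protected area within this region: intersect PA features with the
    # region's (convex, rectangular in the synthetic world) outer rings
    a_in <- 0
    for (poly in f$geometry) {
      for (pf in pa$features) {
        for (pp in pf$geometry) {
          a_in <- a_in + intersection_area_convex(pp, poly[[1]]) * to_km2
        }
      }
    }
    cty <- f$properties$country
    bio <- f$properties$bioregion
    sel <- plots$country == cty & plots$bioregion == bio
    data.frame(
      country = cty, bioregion = bio,
      area_inside_km2 = a_in,
      area_outside_km2 = max(a_tot - a_in, 0),
      n_plots_inside = sum(sel & plots$status == "INSIDE"),
      n_plots_outside = sum(sel & plots$status == "OUTSIDE"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Per-unit plot densities
#'
#' @param units Analysis-unit data frame from [build_units()].
#' @return `units` with `density_inside` and `density_outside` (plots per
#'   km^2; `NA` where the corresponding area is zero).
#' @export
plot_density <- function(units) {
  units$density_inside <- ifelse(units$area_inside_km2 > 0,
                                 units$n_plots_inside / units$area_inside_km2, NA_real_)
  units$density_outside <- ifelse(units$area_outside_km2 > 0,
                                  units$n_plots_outside / units$area_outside_km2, NA_real_)
  units
}

#' Exclude units with strong inside/outside sampling imbalance
#'
#' A unit is retained iff both strata contain plots and the larger plot count
#' is at most `factor` times the smaller one.
#'
#' @param units Analysis-unit data frame.
#' @param factor Maximum allowed imbalance ratio (default 10).
#' @return Retained units; attribute `excluded` holds the dropped rows with a
#'   `reason` column.
#' @export
imbalance_filter <- function(units, factor = 10) {
  lo <- pmin(units$n_plots_inside, units$n_plots_outside)
  hi <- pmax(units$n_plots_inside, units$n_plots_outside)
  keep <- lo > 0 & hi / lo <= factor
  excluded <- units[!keep, , drop = FALSE]
  if (nrow(excluded) > 0) {
    excluded$reason <- ifelse(lo[!keep] == 0, "empty stratum", "imbalance")
  }
  out <- units[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
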