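# Synthetic landscapes, plot networks and species occurrences with the
# statistical structure the gap analysis assumes: country x bioregion units
# on a rectangular grid, a protected strip covering a configurable share of
# each unit, species pools that scale with area by a power law (separate
# inside/outside truths), skewed abundance distributions, priority flags on
# the rarest species, and smooth climate/elevation fields for matching tests.
# Ground truth is returned alongside so recovery can be tested.

BIOREGION_CODES <- c("ALP", "CON", "MED", "ATL", "BOR", "PAN", "STE", "BLS", "MAC")
HABITAT_CODES <- c("C", "D", "E", "F", "G", "H")  # eligible EUNIS level-1 classes

#' Synthetic-world configuration
#'
#' Defaults emulate the structure of a continental vegetation-plot archive
#' overlaid on a protected-area network, scaled down so that the estimators
#' operate in their valid regime at test size: per-unit protected shares
#' spanning the reported national range (7-38%), species-area scaling
#' exponents set to the values reported inside (z = 0.33) and outside
#' (z = 0.22) the network with richness constants scaled to roughly 1/8 of
#' the continental ones while preserving their inside/outside ratio
#' (150 vs 125), a log-series abundance distribution, sampling densities
#' high enough for near-complete incidence coverage per unit, location
#' uncertainties with median 10 m, and priority flags on the rarest 4% of
#' the pool.
#'
#' @param n_units Number of country x bioregion units.
#' @param unit_area_km2 Length-2 range of unit areas (km^2), spread
#'   log-uniformly.
#' @param pa_fraction Protected share per unit: scalar or length-2 range.
#' @param gamma_per_unit Cap on any per-unit stratum pool size.
#' @param sad Abundance model: `list(family = "logseries", alpha = ...)` or
#'   `list(family = "lognormal", meanlog = ..., sdlog = ...)`.
#' @param richness_boost_inside Multiplier on expected plot richness inside
#'   the network (1 = no preferential sampling).
#' @param plots_per_unit_inside,plots_per_unit_outside Fixed plot counts per
#'   unit, or `NA` to derive counts from `plot_density_*`.
#' @param plot_density_inside,plot_density_outside Plots per km^2 when counts
#'   are density-driven (bounded by `plot_count_bounds`).
#' @param plot_count_bounds Lower/upper bounds on density-driven counts.
#' @param mean_plot_richness Expected species per plot (Poisson mean); `Inf`
#'   requests a complete census of the stratum pool in every plot.
#' @param uncertainty_dist `list(meanlog, sdlog)` of the log-normal
#'   uncertainty radius (m), capped at 10 km.
#' @param year_range Survey year range (inclusive).
#' @param priority_fraction Share of the global pool flagged priority (the
#'   rarest species).
#' @param sar_c,sar_z True power-law parameters scaling stratum pools with
#'   area in 100 km^2 units; scalars apply to both groups, or named vectors
#'   `c(inside = ..., outside = ...)`.
#' @param shared_pool_frac Shared fraction of the smaller of a unit's
#'   inside/outside pools.
#' @param neighbor_share Pool fraction shared between consecutive units.
#' @param label_missing_frac Share of plots emitted without country/bioregion
#'   labels (exercises spatial unit assignment).
#' @param confound_elevation_m Elevation offset added to inside plots
#'   (creates covariate confounding for matching tests; 0 = none).
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_units = 24L,
                         unit_area_km2 = c(500, 20000),
                         pa_fraction = c(0.07, 0.38),
                         gamma_per_unit = 5000L,
                         sad = list(family = "logseries", alpha = 1500),
                         richness_boost_inside = 1,
                         plots_per_unit_inside = NA_integer_,
                         plots_per_unit_outside = NA_integer_,
                         plot_density_inside = 0.15,
                         plot_density_outside = 0.05,
                         plot_count_bounds = c(30L, 300L),
                         mean_plot_richness = 25,
                         uncertainty_dist = list(meanlog = log(10), sdlog = 1.2),
                         year_range = c(1994L, 2020L),
                         priority_fraction = 0.04,
                         sar_c = c(inside = 150, outside = 125),
                         sar_z = c(inside = 0.33, outside = 0.22),
                         shared_pool_frac = 0.75,
                         neighbor_share = 0.3,
                         label_missing_frac = 0.1,
                         confound_elevation_m = 0,
                         seed = 1L) {
  pa <- if (length(pa_fraction) == 1) rep(pa_fraction, 2) else pa_fraction
  if (any(pa <= 0) || any(pa >= 1)) stop("pa_fraction must lie strictly in (0, 1)")
  stopifnot(n_units >= 1, gamma_per_unit >= 1)
  two <- function(v) {
    if (length(v) == 1) c(inside = unname(v), outside = unname(v))
    else c(inside = unname(v[["inside"]]), outside = unname(v[["outside"]]))
  }
  structure(list(
    n_units = as.integer(n_units), unit_area_km2 = unit_area_km2,
    pa_fraction = pa, gamma_per_unit = as.integer(gamma_per_unit), sad = sad,
    richness_boost_inside = richness_boost_inside,
    plots_per_unit_inside = plots_per_unit_inside,
    plots_per_unit_outside = plots_per_unit_outside,
    plot_density_inside = plot_density_inside,
    plot_density_outside = plot_density_outside,
    plot_count_bounds = plot_count_bounds,
    mean_plot_richness = mean_plot_richness,
    uncertainty_dist = uncertainty_dist,
    year_range = as.integer(year_range),
    priority_fraction = priority_fraction,
    sar_c = two(sar_c), sar_z = two(sar_z),
    shared_pool_frac = shared_pool_frac, neighbor_share = neighbor_share,
    label_missing_frac = label_missing_frac,
    confound_elevation_m = confound_elevation_m,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Log-series abundance sampler parameterized by Fisher's alpha: given the
# realized pool size S, the series parameter is x = 1 - exp(-S / alpha)
# (from S = -alpha * log(1 - x)), capped at 0.9999 so the inversion table
# stays finite. Sampling is exact inversion over the truncated support.
sample_sad <- function(n_species, sad) {
  if (sad$family == "lognormal") {
    return(stats::rlnorm(n_species, sad$meanlog, sad$sdlog))
  }
  if (sad$family != "logseries") stop("unknown SAD family: ", sad$family)
  x <- min(1 - exp(-n_species / sad$alpha), 0.9999)
  kmax <- 1000L
  repeat {
    k <- seq_len(kmax)
    pmf <- x^k / k
    if (pmf[kmax] / sum(pmf) < 1e-12 || kmax >= 200000L) break
    kmax <- kmax * 10L
  }
  cum <- cumsum(pmf) / sum(pmf)
  findInterval(stats::runif(n_species), cum) + 1
}

#' Generate the synthetic landscape
#'
#' Units are laid out on a grid (columns = countries, rows = bioregions) of
#' rectangles whose widths and heights are drawn log-uniformly so unit areas
#' span `unit_area_km2`. Each unit's protected area is the left vertical
#' strip covering its drawn protected share exactly. Coordinates are planar
#' metres.
#'
#' @param cfg A [synth_config()].
#' @return List with `regions` and `pa` (`polygon_layer`s) and `units` (data
#'   frame of per-unit geometry and true areas).
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_units
  n_rows <- if (n >= 9) 3L else if (n >= 4) 2L else 1L
  n_cols <- as.integer(ceiling(n / n_rows))
  lo <- sqrt(cfg$unit_area_km2[1]) * 1000  # edge lengths in m
  hi <- sqrt(cfg$unit_area_km2[2]) * 1000
  w <- exp(stats::runif(n_cols, log(lo), log(hi)))
  h <- exp(stats::runif(n_rows, log(lo), log(hi)))
  x0 <- c(0, cumsum(w))[seq_len(n_cols)]
  y0 <- c(0, cumsum(h))[seq_len(n_rows)]
  pa_frac <- stats::runif(n, cfg$pa_fraction[1], cfg$pa_fraction[2])
  units <- data.frame()
  region_feats <- list()
  pa_feats <- list()
  u <- 0L
  for (ci in seq_len(n_cols)) {
    for (ri in seq_len(n_rows)) {
      u <- u + 1L
      if (u > n) break
      cty <- sprintf("C%02d", ci)
      bio <- BIOREGION_CODES[ri]
      xmin <- x0[ci]; xmax <- x0[ci] + w[ci]
      ymin <- y0[ri]; ymax <- y0[ri] + h[ri]
      f <- pa_frac[u]
      pa_x1 <- xmin + f * w[ci]
      region_feats[[u]] <- list(
        geometry = list(list(rect_ring(xmin, ymin, xmax, ymax))),
        properties = list(country = cty, bioregion = bio)
      )
      pa_feats[[u]] <- list(
        geometry = list(list(rect_ring(xmin, ymin, pa_x1, ymax))),
        properties = list(site_id = sprintf("PA%02d", u))
      )
      a_tot <- w[ci] * h[ri] / 1e6
      units <- rbind(units, data.frame(
        country = cty, bioregion = bio,
        xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax, pa_x1 = pa_x1,
        pa_fraction = f, area_km2 = a_tot,
        area_inside_km2 = f * a_tot, area_outside_km2 = (1 - f) * a_tot,
        stringsAsFactors = FALSE
      ))
    }
  }
  list(regions = polygon_layer(region_feats, "REGION"),
       pa = polygon_layer(pa_feats, "PROTECTED"),
       units = units)
}

#' Generate plots, occurrences and ground truth
#'
#' Per unit, stratum species pools of size `round(c * (area/100 km^2)^z)`
#' (per-group truths, capped at `gamma_per_unit`, at least 5) are carved from
#' a global pool: consecutive units share `neighbor_share` of their pools,
#' and within a unit the inside and outside pools overlap by
#' `shared_pool_frac` of the smaller. Species weights come from the
#' configured abundance distribution; the `priority_fraction` rarest species
#' are flagged priority. Plots are placed uniformly in their stratum, and
#' each plot's species list is a weighted sample without replacement of
#' Poisson-distributed size (scaled by `richness_boost_inside` inside).
#'
#' @param cfg A [synth_config()].
#' @param landscape Output of [generate_landscape()] for the same config.
#' @return List: `plots` (header table, `status = "UNCLASSIFIED"`, labels
#'   missing for a `label_missing_frac` share), `covariates` (climate and
#'   elevation per plot), `occurrences` (long table), and `truth` (per-unit
#'   pool sizes inside/outside/shared, per-plot true status, SAR truths,
#'   priority reference list).
#' @export
generate_community <- function(cfg, landscape) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed((cfg$seed %% 1000000L) * 2L + 1L)
  units <- landscape$units
  n <- nrow(units)
  pool_size <- function(c0, z0, a_km2) {
    as.integer(pmin(pmax(round(c0 * (a_km2 / 100)^z0), 5), cfg$gamma_per_unit))
  }
  g_in <- pool_size(cfg$sar_c[["inside"]], cfg$sar_z[["inside"]], units$area_inside_km2)
  g_out <- pool_size(cfg$sar_c[["outside"]], cfg$sar_z[["outside"]], units$area_outside_km2)
  g_shared <- as.integer(round(cfg$shared_pool_frac * pmin(g_in, g_out)))
  g_unit <- g_in + g_out - g_shared
  # global pool as overlapping index windows: consecutive units share
  # neighbor_share of the earlier unit's pool
  start <- integer(n)
  start[1] <- 1L
  if (n > 1) {
    for (u in 2:n) {
      start[u] <- start[u - 1] + as.integer(round((1 - cfg$neighbor_share) * g_unit[u - 1]))
    }
  }
  s_global <- max(start + g_unit - 1L)
  species <- sprintf("sp%06d", seq_len(s_global))
  weights <- sample_sad(s_global, cfg$sad)
  n_priority <- as.integer(round(cfg$priority_fraction * s_global))
  priority_ids <- if (n_priority > 0) {
    species[order(weights, seq_len(s_global))[seq_len(n_priority)]]
  } else character(0)
  is_priority <- species %in% priority_ids

  pools_in <- vector("list", n)
  pools_out <- vector("list", n)
  for (u in seq_len(n)) {
    window <- seq.int(start[u], start[u] + g_unit[u] - 1L)
    pools_in[[u]] <- window[seq_len(g_in[u])]
    pools_out[[u]] <- window[seq.int(g_unit[u] - g_out[u] + 1L, g_unit[u])]
  }

  count_for <- function(fixed, dens, a_km2) {
    if (!is.na(fixed)) return(rep(as.integer(fixed), length(a_km2)))
    as.integer(pmin(pmax(round(dens * a_km2), cfg$plot_count_bounds[1]),
                    cfg$plot_count_bounds[2]))
  }
  n_in <- count_for(cfg$plots_per_unit_inside, cfg$plot_density_inside,
                    units$area_inside_km2)
  n_out <- count_for(cfg$plots_per_unit_outside, cfg$plot_density_outside,
                     units$area_outside_km2)

  plot_rows <- vector("list", 2L * n)
  occ_rows <- vector("list", 2L * n)
  capped <- 0L
  pid <- 0L
  Lx <- max(units$xmax); Ly <- max(units$ymax)
  for (u in seq_len(n)) {
    for (stratum in c("INSIDE", "OUTSIDE")) {
      np <- if (stratum == "INSIDE") n_in[u] else n_out[u]
      if (np == 0) next
      xr <- if (stratum == "INSIDE") c(units$xmin[u], units$pa_x1[u]) else c(units$pa_x1[u], units$xmax[u])
      px <- stats::runif(np, xr[1], xr[2])
      py <- stats::runif(np, units$ymin[u], units$ymax[u])
      ids <- sprintf("p%06d", pid + seq_len(np))
      pid <- pid + np
      unc <- pmin(stats::rlnorm(np, cfg$uncertainty_dist$meanlog,
                                cfg$uncertainty_dist$sdlog), 10000)
      labelled <- stats::runif(np) >= cfg$label_missing_frac
      pool <- if (stratum == "INSIDE") pools_in[[u]] else pools_out[[u]]
      wpool <- weights[pool]
      boost <- if (stratum == "INSIDE") cfg$richness_boost_inside else 1
      k <- if (is.infinite(cfg$mean_plot_richness)) {
        rep(length(pool), np)
      } else {
        stats::rpois(np, cfg$mean_plot_richness * boost)
      }
      over <- k > length(pool)
      capped <- capped + sum(over)
      k[over] <- length(pool)
      k[k < 1] <- 1L
      occ <- vector("list", np)
      for (i in seq_len(np)) {
        picked <- if (k[i] == length(pool)) pool else sample(pool, k[i], prob = wpool)
        occ[[i]] <- data.frame(plot_id = ids[i], species_id = species[picked],
                               native = TRUE, priority = is_priority[picked],
                               stringsAsFactors = FALSE)
      }
      idx <- 2L * (u - 1L) + if (stratum == "INSIDE") 1L else 2L
      occ_rows[[idx]] <- do.call(rbind, occ)
      plot_rows[[idx]] <- data.frame(
        plot_id = ids, x = px, y = py, uncertainty_m = unc,
        year = sample(seq(cfg$year_range[1], cfg$year_range[2]), np, replace = TRUE),
        habitat_class = sample(HABITAT_CODES, np, replace = TRUE),
        country = ifelse(labelled, units$country[u], NA_character_),
        bioregion = ifelse(labelled, units$bioregion[u], NA_character_),
        status = "UNCLASSIFIED", true_status = stratum,
        stringsAsFactors = FALSE
      )
    }
  }
  if (capped > 0) {
    warning(capped, " plot(s) requested more species than their pool holds; capped")
  }
  plots <- do.call(rbind, plot_rows[!vapply(plot_rows, is.null, TRUE)])
  occurrences <- do.call(rbind, occ_rows[!vapply(occ_rows, is.null, TRUE)])
  rownames(plots) <- rownames(occurrences) <- NULL

  # smooth climate/elevation fields over the landscape + observation noise
  ex <- plots$x / Lx; ey <- plots$y / Ly
  elevation <- pmax(150 + 1800 * ex * ey + stats::rnorm(nrow(plots), 0, 120), 0)
  if (cfg$confound_elevation_m != 0) {
    ins <- plots$true_status == "INSIDE"
    elevation[ins] <- elevation[ins] + cfg$confound_elevation_m
  }
  covariates <- data.frame(
    plot_id = plots$plot_id,
    mean_annual_temp = 18 - 6.5 * elevation / 1000 - 8 * ey + stats::rnorm(nrow(plots), 0, 0.5),
    annual_precip = 500 + 700 * ex + 0.25 * elevation + stats::rnorm(nrow(plots), 0, 50),
    temp_seasonality = 4000 + 3000 * ey + stats::rnorm(nrow(plots), 0, 200),
    precip_seasonality = 30 + 25 * ex + stats::rnorm(nrow(plots), 0, 3),
    elevation = elevation,
    stringsAsFactors = FALSE
  )

  truth_units <- data.frame(
    country = units$country, bioregion = units$bioregion,
    pool_inside = g_in, pool_outside = g_out, pool_shared = g_shared,
    area_inside_km2 = units$area_inside_km2,
    area_outside_km2 = units$area_outside_km2,
    stringsAsFactors = FALSE
  )
  plot_status <- data.frame(plot_id = plots$plot_id,
                            true_status = plots$true_status,
                            stringsAsFactors = FALSE)
  plots$true_status <- NULL
  list(
    plots = plots, covariates = covariates, occurrences = occurrences,
    truth = list(units = truth_units, plot_status = plot_status,
                 sar = list(c = cfg$sar_c, z = cfg$sar_z),
                 priority_species = priority_ids,
                 pools_inside = lapply(pools_in, function(ix) species[ix]),
                 pools_outside = lapply(pools_out, function(ix) species[ix]))
  )
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper running [generate_landscape()] and
#' [generate_community()] for one config.
#'
#' @param cfg A [synth_config()].
#' @return List combining the landscape and community outputs.
#' @export
generate_world <- function(cfg = synth_config()) {
  landscape <- generate_landscape(cfg)
  community <- generate_community(cfg, landscape)
  c(landscape["regions"], landscape["pa"], list(layout = landscape$units), community)
}
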