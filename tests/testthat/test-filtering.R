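base_plot <- function(...) {
  out <- data.frame(plot_id = "p1", x = 50, y = 50, uncertainty_m = 10,
                    year = 2000, habitat_class = "G", country = NA_character_,
                    bioregion = NA_character_, status = "UNCLASSIFIED",
                    stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) out[[nm]] <- mods[[nm]]
  out
}

test_that("eligibility filters apply the uncertainty, year and habitat rules", {
  plots <- rbind(
    base_plot(plot_id = "ok"),
    base_plot(plot_id = "pre", year = 1993),           # before network establishment
    base_plot(plot_id = "edge", uncertainty_m = 10000), # exactly at the bound: kept
    base_plot(plot_id = "far", uncertainty_m = 10001),
    base_plot(plot_id = "urban", habitat_class = "V"),
    base_plot(plot_id = "nohab", habitat_class = NA_character_)
  )
  kept <- filter_plots(plots, filter_policy())
  expect_setequal(kept$plot_id, c("ok", "edge", "nohab"))
  ex <- attr(kept, "exclusions")
  expect_equal(unname(ex["pre_establishment"]), 1)
  expect_equal(unname(ex["uncertainty"]), 1)
  expect_equal(unname(ex["habitat"]), 1)
  expect_equal(unname(ex["missing_habitat"]), 1)
})

test_that("buffer overlap fraction is exact on containment and near-exact on edges", {
  pa <- rect_layer(0, -50000, 100000, 50000)
  # buffer wholly inside
  expect_equal(buffer_overlap_fraction(50000, 0, 500, pa), 1.0)
  # wholly outside
  expect_equal(buffer_overlap_fraction(-5000, 0, 500, pa), 0.0)
  # disc centred on a long straight edge: analytic half-disc
  expect_equal(buffer_overlap_fraction(0, 0, 100, pa), 0.5, tolerance = 0.01)
  # zero uncertainty degrades to point-in-polygon
  expect_equal(buffer_overlap_fraction(1, 0, 0, pa), 1)
  expect_equal(buffer_overlap_fraction(-1, 0, 0, pa), 0)
})

test_that("overlap fraction is monotone in protected area for nested layers", {
  fractions <- vapply(seq(1000, 5000, by = 1000), function(half) {
    buffer_overlap_fraction(0, 0, 3000, rect_layer(-half, -half, half, half))
  }, 0)
  expect_true(all(diff(fractions) >= -1e-12))
})

test_that("classification uses a strict >50% rule and is translation invariant", {
  pa <- rect_layer(0, -50000, 100000, 50000)
  mk <- function(x, id) base_plot(plot_id = id, x = x, y = 0, uncertainty_m = 1000)
  plots <- rbind(mk(400, "in60"),   # >50% of buffer inside
                 mk(0, "half"),     # exactly 50%: OUTSIDE by strictness
                 mk(-5000, "out"))
  cl <- classify_plots(plots, pa, filter_policy())
  expect_gt(cl$overlap_fraction[1], 0.5)
  expect_equal(cl$overlap_fraction[2], 0.5, tolerance = 1e-12)
  expect_equal(cl$status, c("INSIDE", "OUTSIDE", "OUTSIDE"))

  # translate the whole scene: same classification away from the knife-edge
  # exactly-50% case (where rounding may tip either side of the threshold)
  dx <- 12345; dy <- -777
  pa2 <- rect_layer(0 + dx, -50000 + dy, 100000 + dx, 50000 + dy)
  plots2 <- plots; plots2$x <- plots2$x + dx; plots2$y <- plots2$y + dy
  cl2 <- classify_plots(plots2, pa2, filter_policy())
  expect_equal(cl2$status[c(1, 3)], cl$status[c(1, 3)])
  expect_equal(cl2$overlap_fraction, cl$overlap_fraction, tolerance = 1e-9)
})

test_that("unit assignment is spatial with pre-label precedence and tie rule", {
  regions <- polygon_layer(list(
    list(geometry = list(list(rect_ring(0, 0, 100, 100))),
         properties = list(country = "C1", bioregion = "ALP")),
    list(geometry = list(list(rect_ring(100, 0, 200, 100))),
         properties = list(country = "C2", bioregion = "MED"))
  ), role = "REGION")
  plots <- rbind(
    base_plot(plot_id = "a", x = 50, y = 50),
    base_plot(plot_id = "b", x = 150, y = 50),
    base_plot(plot_id = "pre", x = 150, y = 50, country = "C1", bioregion = "ALP"),
    base_plot(plot_id = "lost", x = 500, y = 500)
  )
  got <- assign_units(plots, regions)
  expect_equal(got$country, c("C1", "C2", "C1", "UNASSIGNED"))
  expect_equal(got$bioregion[1:2], c("ALP", "MED"))
  expect_equal(attr(got, "n_conflicts"), 1L)
  expect_equal(attr(got, "n_unassigned"), 1L)

  # point exactly on the shared boundary goes to exactly one unit,
  # deterministically (first containing feature in file order)
  bnd <- assign_units(base_plot(plot_id = "edge", x = 100, y = 50), regions)
  expect_true(bnd$country %in% c("C1", "C2"))
  bnd2 <- assign_units(base_plot(plot_id = "edge", x = 100, y = 50), regions)
  expect_identical(bnd$country, bnd2$country)
})

test_that("plot densities and the imbalance rule follow their definitions", {
  units <- data.frame(
    country = c("A", "B", "C"), bioregion = "ALP",
    area_inside_km2 = c(25, 10, 0), area_outside_km2 = c(100, 10, 50),
    n_plots_inside = c(50, 5, 0), n_plots_outside = c(90, 60, 40)
  )
  d <- plot_density(units)
  expect_equal(d$density_inside[1], 2.0)
  expect_true(is.na(d$density_inside[3]))
  nz <- !is.na(d$density_inside)
  expect_equal(d$density_inside[nz] * d$area_inside_km2[nz], d$n_plots_inside[nz])

  kept <- imbalance_filter(units, factor = 10)
  expect_equal(kept$country, "A")                     # ratio 90/50 = 1.8
  ex <- attr(kept, "excluded")
  expect_setequal(ex$country, c("B", "C"))            # ratio 12; empty stratum
  expect_equal(ex$reason[ex$country == "C"], "empty stratum")
  expect_equal(ex$reason[ex$country == "B"], "imbalance")
})

test_that("classification recovers ground-truth status on a synthetic world", {
  # tiny uncertainties relative to unit size: every buffer is far from edges
  # except a negligible sliver, so classified status must equal the truth
  cfg <- small_synth(seed = 12,
                     uncertainty_dist = list(meanlog = log(5), sdlog = 0.2))
  w <- generate_world(cfg)
  cl <- classify_plots(w$plots, w$pa, filter_policy())
  truth <- w$truth$plot_status$true_status[match(cl$plot_id, w$truth$plot_status$plot_id)]
  agree <- mean(cl$status == truth)
  expect_gte(agree, 0.995)
  # buffers well clear of any boundary must agree exactly
  clear <- cl$overlap_fraction %in% c(0, 1)
  expect_equal(cl$status[clear], truth[clear])
})
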