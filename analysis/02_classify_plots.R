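#!/usr/bin/env Rscript
# Eligibility filtering and inside/outside classification of the simulated
# plot network: applies the uncertainty/year/habitat rules, computes buffer
# overlap with the protected layer, assigns analysis units, and applies the
# factor-10 sampling-imbalance rule.

library(pagap)

world_dir <- file.path("results", "world")
out <- file.path("results", "classified")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

plots <- read_plot_table(file.path(world_dir, "plots.csv"))
pa <- read_polygon_layer(file.path(world_dir, "pa.geojson"), role = "PROTECTED")
regions <- read_polygon_layer(file.path(world_dir, "regions.geojson"), role = "REGION")

policy <- filter_policy()
plots <- filter_plots(plots, policy)
message("exclusions: ", paste(names(attr(plots, "exclusions")),
                              attr(plots, "exclusions"), collapse = ", "))
plots <- classify_plots(plots, pa, policy)
plots <- assign_units(plots, regions)
plots <- plots[plots$country != "UNASSIGNED", ]

units <- plot_density(build_units(plots, regions, pa))
units <- imbalance_filter(units)
message(sprintf("units retained: %d (excluded: %d)", nrow(units),
                nrow(attr(units, "excluded"))))
message(sprintf("plots inside: %d, outside: %d; intermediate overlap (50-75%%): %.1f%%",
                sum(plots$status == "INSIDE"), sum(plots$status == "OUTSIDE"),
                100 * mean(plots$overlap_fraction > 0.5 & plots$overlap_fraction < 0.75)))

write_plot_table(plots, file.path(out, "classified.csv"))
utils::write.csv(units, file.path(out, "units.csv"), row.names = FALSE)
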