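#!/usr/bin/env Rscript
# Generate the default synthetic study world and write its raw inputs:
# plot headers, occurrences, climate covariates, protected and region layers,
# and the ground truth used later for recovery checks.

library(pagap)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
out <- file.path("results", "world")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(seed = seed)
world <- generate_world(cfg)

write_plot_table(world$plots, file.path(out, "plots.csv"))
write_occurrences(world$occurrences, file.path(out, "occurrences.csv"))
utils::write.csv(world$covariates, file.path(out, "covariates.csv"), row.names = FALSE)
write_polygon_layer(world$pa, file.path(out, "pa.geojson"))
write_polygon_layer(world$regions, file.path(out, "regions.geojson"))
jsonlite::write_json(
  list(priority_species = world$truth$priority_species,
       units = world$truth$units, sar = world$truth$sar),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

message(sprintf("world: %d plots, %d occurrences, %d units, %d priority species",
                nrow(world$plots), nrow(world$occurrences),
                nrow(world$truth$units), length(world$truth$priority_species)))
message("written to ", out)
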