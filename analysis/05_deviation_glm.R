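#!/usr/bin/env Rscript
# Deviation analysis: binomial GLM of the proportion of species recorded
# inside the network per unit against the country factor (sum-to-zero coded)
# with inside plot density as sampling-effort covariate; linear vs quadratic
# effort terms compared by AICc and the quadratic term's CI; units deviating
# from the network-wide mean flagged by their 95% CI.

library(pagap)

units <- utils::read.csv(file.path("results", "classified", "units.csv"),
                         stringsAsFactors = FALSE)
partitions <- utils::read.csv(file.path("results", "richness", "partitions.csv"),
                              stringsAsFactors = FALSE)
out <- file.path("results", "glm")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pu <- partitions[partitions$level == "unit" & partitions$mode == "native", ]
key <- match(paste(units$country, units$bioregion, sep = ":"), pu$stratum)
d <- data.frame(country = units$country, bioregion = units$bioregion,
                n_inside = pu$n_shared[key] + pu$n_inside_only[key],
                n_total = pu$n_total[key],
                density_inside = units$density_inside)
d <- d[stats::complete.cases(d), ]

for (fac in c("country", "bioregion")) {
  if (length(unique(d[[fac]])) < 2) next
  sel <- select_effort_terms(d, factor_col = fac, effort_col = "density_inside")
  flags <- deviation_flags(sel$fit)
  utils::write.csv(sel$fit$coefficients,
                   file.path(out, paste0("coefficients_", fac, ".csv")), row.names = FALSE)
  utils::write.csv(flags, file.path(out, paste0("flags_", fac, ".csv")), row.names = FALSE)
  message(sprintf("%s model: %s effort term, D2 = %.2f, AICc = %.1f", fac,
                  sel$chosen, sel$fit$d2, sel$fit$aicc))
  message("  above average: ",
          paste(flags$level[flags$flag == "above"], collapse = ", "))
  message("  below average: ",
          paste(flags$level[flags$flag == "below"], collapse = ", "))
}
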