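# Shared fixtures and independent oracles used across the test files.

# incidence summary straight from a plots x species 0/1 matrix
incidence_from_matrix <- function(mat) {
  occ <- do.call(rbind, lapply(seq_len(nrow(mat)), function(i) {
    sp <- which(mat[i, ] > 0)
    if (length(sp) == 0) return(NULL)
    data.frame(plot_id = paste0("p", i), species_id = paste0("s", sp),
               native = TRUE, priority = FALSE, stringsAsFactors = FALSE)
  }))
  if (is.null(occ)) occ <- data.frame(plot_id = character(), species_id = character(),
                                      native = logical(), priority = logical())
  build_incidence(occ, paste0("p", seq_len(nrow(mat))))
}

random_incidence_matrix <- function(m, s, p = 0.3) {
  mat <- matrix(stats::rbinom(m * s, 1, p), nrow = m)
  # make sure at least one species is present somewhere
  if (all(mat == 0)) mat[1, 1] <- 1
  mat
}

# brute-force sample-based rarefaction: average richness over ALL t-subsets
rarefaction_bruteforce <- function(mat, t) {
  subs <- utils::combn(nrow(mat), t)
  mean(apply(subs, 2, function(ix) {
    sum(colSums(mat[ix, , drop = FALSE]) > 0)
  }))
}

# single-rectangle protected layer
rect_layer <- function(xmin, ymin, xmax, ymax, role = "PROTECTED", props = list()) {
  polygon_layer(list(list(geometry = list(list(rect_ring(xmin, ymin, xmax, ymax))),
                          properties = props)), role)
}

# small synthetic world that runs the full pipeline quickly
small_synth <- function(seed = 1, ...) {
  synth_config(n_units = 6L, unit_area_km2 = c(400, 4000),
               plot_density_inside = 0.3, plot_density_outside = 0.1,
               plot_count_bounds = c(25L, 80L),
               sar_c = c(inside = 80, outside = 65),
               mean_plot_richness = 18, seed = seed, ...)
}

# independent re-implementation of greedy nearest-neighbour matching used as
# an oracle on small instances: explicit distance matrix, explicit scans
match_oracle <- function(scores, caliper_sd = 0.25) {
  cal <- caliper_sd * stats::sd(scores$logit)
  tr <- scores[scores$treated, ]
  co <- scores[!scores$treated, ]
  tr <- tr[order(-tr$score, tr$plot_id), ]
  D <- outer(tr$logit, co$logit, function(a, b) abs(a - b))
  taken <- rep(FALSE, nrow(co))
  pairs <- NULL
  for (i in seq_len(nrow(tr))) {
    best <- NA; bestd <- Inf
    for (j in order(co$plot_id)) {   # id order makes ties deterministic
      if (taken[j]) next
      if (D[i, j] < bestd - 1e-15) { bestd <- D[i, j]; best <- j }
    }
    if (!is.na(best) && bestd <= cal) {
      taken[best] <- TRUE
      pairs <- rbind(pairs, data.frame(treated_id = tr$plot_id[i],
                                       control_id = co$plot_id[best],
                                       stringsAsFactors = FALSE))
    }
  }
  pairs
}

# simulate SAR points with multiplicative gaussian noise
sim_sar_points <- function(n, c0, z0, sigma = 0.05, model = "power",
                           a_range = c(1, 1000)) {
  A <- exp(stats::runif(n, log(a_range[1]), log(a_range[2])))
  S <- sar_model(model, A, list(c = c0, z = z0))
  S <- S * (1 + stats::rnorm(n, 0, sigma))
  data.frame(A = A, S = pmax(S, 1e-6))
}
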