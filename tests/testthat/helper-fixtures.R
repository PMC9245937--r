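# Shared fixtures and oracles for the test suite.

# Greedy one-to-one matching of detected punctum centroids to planted
# centroids within `radius` px; returns recall and precision.
match_puncta <- function(detected, planted, radius = 2.5) {
  if (nrow(detected) == 0L)
    return(c(recall = 0, precision = 1))
  d2 <- outer(detected[, 1], planted[, 1], "-")^2 +
        outer(detected[, 2], planted[, 2], "-")^2
  used <- rep(FALSE, nrow(planted))
  tp <- 0L
  for (i in order(apply(d2, 1, min))) {
    j <- which.min(ifelse(used, Inf, d2[i, ]))
    if (is.finite(d2[i, j]) && d2[i, j] <= radius^2) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  c(recall = tp / nrow(planted), precision = tp / nrow(detected))
}

detected_centroids <- function(ps) as.matrix(ps$puncta[, c("x", "y")])

# A filled disc mask of radius r_px centred in a side x side image.
disc_mask <- function(side, r_px) {
  ctr <- (side - 1) / 2
  g <- (seq_len(side) - 1) - ctr
  outer(g^2, g^2, "+") <= r_px^2
}

# Render a group of cases with a common planted mean and quantify it with
# the full pipeline; returns the per-case aggregate table.
quantify_group <- function(n_cases, neurons_per_case, coverage_mean,
                           soma_area_mean, seed, coverage_sd = 0.02,
                           soma_area_sd = 60, case_prefix = "g") {
  renders <- simulate_case_images(
    n_cases = n_cases, neurons_per_case = neurons_per_case,
    coverage_mean = coverage_mean, coverage_sd = coverage_sd,
    soma_area_mean = soma_area_mean, soma_area_sd = soma_area_sd,
    pixel_size = 0.2, seed = seed, case_prefix = case_prefix)
  per_neuron <- do.call(rbind, lapply(renders, function(r)
    process_image(r$image)))
  aggregate_case(per_neuron)
}
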