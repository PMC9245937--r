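square_mask <- function(side, sq, off = 5L) {
  m <- matrix(FALSE, side, side)
  m[off + seq_len(sq), off + seq_len(sq)] <- TRUE
  m
}

test_that("neuron size sums interior and boundary pixel areas", {
  # 10x10 solid square at 1 um/px: outline 36 px + interior 64 px = 100 um^2
  nm <- synapcover:::new_neuron_mask(square_mask(20, 10), pixel_size = 1)
  expect_equal(sum(nm$interior), 64)
  expect_equal(nrow(nm$boundary_coords), 36)
  expect_equal(compute_neuron_size(nm), 100)
  # 3x3 square at 0.2 um/px: 1 interior + 8 boundary = 9 x 0.04 um^2
  nm3 <- synapcover:::new_neuron_mask(square_mask(10, 3), pixel_size = 0.2)
  expect_equal(compute_neuron_size(nm3), 0.36)
  expect_equal(nm3$interior_area_um2, 0.04)
})

test_that("membrane synapse counting honours the band and counts each punctum once", {
  nm <- synapcover:::new_neuron_mask(square_mask(60, 20, off = 20L),
                                     pixel_size = 0.2)
  lab <- matrix(0L, 60, 60)
  lab[21:22, 21:22] <- 1L       # on the boundary corner
  lab[30:31, 30:31] <- 2L       # deep interior, > 0.5 um from boundary
  lab[55:56, 55:56] <- 3L       # > 3 um outside the boundary
  ps <- synapcover:::puncta_set_from_label(lab, matrix(1, 60, 60), 0.2)
  expect_equal(count_membrane_synapses(nm, ps, 0.5), 1L)
  expect_equal(count_membrane_synapses(nm, ps, 2.0), 2L)
  empty <- synapcover:::puncta_set_from_label(matrix(0L, 60, 60),
                                              matrix(0, 60, 60), 0.2)
  expect_equal(count_membrane_synapses(nm, empty, 0.5), 0L)
  small <- synapcover:::puncta_set_from_label(matrix(0L, 10, 10),
                                              matrix(0, 10, 10), 0.2)
  expect_error(count_membrane_synapses(nm, small, 0.5), "pairing")
})

test_that("coverage is synapse count over segmented area", {
  # square with object area exactly 2500 px x 0.04 = 100 um^2
  nm <- synapcover:::new_neuron_mask(square_mask(70, 50, off = 10L), 0.2)
  expect_equal(nm$interior_area_um2 + nm$boundary_area_um2, 100)
  lab <- matrix(0L, 70, 70)
  for (i in seq_len(30)) lab[10 + i, 10] <- i   # 30 puncta hugging the edge
  ps <- synapcover:::puncta_set_from_label(lab, matrix(1, 70, 70), 0.2)
  cr <- compute_coverage(nm, ps, band_halfwidth_um = 0.5)
  expect_equal(cr$n_synapses, 30L)
  expect_equal(cr$area_ad_um2, 100)
  expect_equal(cr$coverage, 0.300)
  expect_equal(cr$neuron_size_um2, cr$area_ad_um2)
  none <- compute_coverage(nm, synapcover:::puncta_set_from_label(
    matrix(0L, 70, 70), matrix(0, 70, 70), 0.2))
  expect_equal(none$coverage, 0)
})

test_that("planted membrane puncta all fall in the default counting band", {
  r <- render_neuron_image(450, 0.30, 0.2, noise_sd = 0, seed = 41)
  img <- normalize_intensity(r$image)
  nm <- segment_neuron(get_channel(img, "neurofilament"), 0.2)
  det <- detect_puncta(get_channel(img, "gad"), 0.2)
  ns <- count_membrane_synapses(nm, det, 0.5)
  expect_gte(ns, round(0.97 * r$truth$n_membrane_puncta))
  expect_lte(ns, r$truth$n_membrane_puncta)
})

test_that("qc_evaluate flags each planted defect and passes clean images", {
  expected <- c(poor_contrast = "poor_contrast",
                multi_process = "multi_process",
                two_neurons = "two_neurons",
                incorrect_neuron = "incorrect_neuron")
  for (k in names(expected)) {
    d <- render_degenerate_image(k, seed = 8)
    expect_identical(process_image(d$image)$qc_status, expected[[k]],
                     label = k)
  }
  clean <- render_neuron_image(450, 0.3, 0.2, seed = 8)
  expect_identical(process_image(clean$image)$qc_status, "pass")
})

test_that("QC-failed neurons carry NA measurements but are retained", {
  d <- render_degenerate_image("poor_contrast", seed = 12)
  row <- process_image(d$image)
  expect_true(is.na(row$coverage))
  expect_identical(row$qc_status, "poor_contrast")
  expect_s3_class(row, "coverage_result")
})

test_that("QC bookkeeping satisfies its conservation invariants", {
  rep1 <- summarize_qc(c(total_deleted = 239), n_photographed = 883)
  expect_equal(rep1$n_retained, 644L)
  expect_equal(round(rep1$percent_deleted), 27)

  rep2 <- summarize_qc(rep(c("pass", "poor_contrast"), c(10, 0)))
  expect_equal(rep2$n_retained, 10L)
  expect_equal(rep2$percent_deleted, 0)

  rep3 <- summarize_qc(c(a = 2, b = 3), n_photographed = 10)
  expect_equal(rep3$n_deleted, 5L)
  expect_equal(rep3$percent_deleted, 50)

  # property: random status mixes always conserve counts
  set.seed(7)
  for (i in 1:20) {
    st <- sample(c("pass", "poor_contrast", "multi_process",
                   "incorrect_neuron", "two_neurons"), 50, replace = TRUE)
    rp <- summarize_qc(st)
    expect_equal(rp$n_deleted, sum(unlist(rp$deleted_by_reason)))
    expect_equal(rp$n_retained + rp$n_deleted, rp$n_photographed)
    expect_equal(rp$percent_deleted, 100 * rp$n_deleted / 50)
  }
  expect_error(summarize_qc(data.frame()), "empty")
})

test_that("case aggregation averages passing neurons only and flags empty cases", {
  res <- rbind(
    synapcover:::coverage_result("c1", "i1", 20, 100, 0.2, 100, "pass"),
    synapcover:::coverage_result("c1", "i2", 40, 100, 0.4, 120, "pass"),
    synapcover:::coverage_result("c1", "i3", NA, NA, NA, NA, "poor_contrast"),
    synapcover:::coverage_result("c2", "i4", NA, NA, NA, NA, "multi_process"))
  agg <- aggregate_case(res, "c1")
  expect_equal(agg$mean_coverage, 0.3)
  expect_equal(agg$mean_neuron_size, 110)
  expect_equal(agg$n_pass, 2L)
  expect_error(aggregate_case(res, "c2"),
               class = "synapcover_case_excluded")
  expect_warning(all_cases <- aggregate_case(res), "excluded")
  expect_equal(nrow(all_cases), 1L)
})

test_that("coverage doubles when the planted punctum count doubles", {
  cov1 <- cov2 <- numeric(3)
  for (s in 1:3) {
    r1 <- render_neuron_image(400, 0.15, 0.2, seed = 200 + s)
    r2 <- render_neuron_image(400, 0.30, 0.2, seed = 200 + s)
    cov1[s] <- process_image(r1$image)$coverage
    cov2[s] <- process_image(r2$image)$coverage
  }
  expect_lt(abs(mean(cov2) / mean(cov1) - 2), 2 * 0.05)
})

test_that("recovered coverage is stable under pixel-size refinement", {
  r1 <- render_neuron_image(450, 0.3, pixel_size = 0.2, seed = 55)
  r2 <- render_neuron_image(450, 0.3, pixel_size = 0.1, seed = 55)
  c1 <- process_image(r1$image)$coverage
  c2 <- process_image(r2$image)$coverage
  expect_lt(abs(c2 - c1) / c1, 0.03)
})
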