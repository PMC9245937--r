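make_stack <- function(ch, role = "neurofilament", ps = 0.2) {
  image_stack(setNames(list(ch), role), pixel_size = ps)
}

test_that("percentile normalization removes multiplicative intensity drift", {
  set.seed(1)
  ch <- matrix(runif(10000, 0.05, 0.6), 100)
  a <- normalize_intensity(make_stack(ch))
  b <- normalize_intensity(make_stack(0.5 * ch))
  expect_equal(a$channels[[1]], b$channels[[1]], tolerance = 1e-12)
  # already spanning its anchor percentiles: renormalizing changes nothing
  once <- normalize_intensity(make_stack(ch))
  twice <- normalize_intensity(once)
  expect_lt(max(abs(once$channels[[1]] - twice$channels[[1]])), 1 / 255)
})

test_that("a constant channel raises a degenerate-channel error", {
  expect_error(normalize_intensity(make_stack(matrix(0.4, 50, 50))),
               class = "synapcover_degenerate_channel")
})

test_that("segmentation recovers a disc of known area", {
  set.seed(3)
  # radius 11.3 um at 0.2 um/px: area pi * 11.3^2 = 401 um^2
  mask <- disc_mask(160, 11.3 / 0.2)
  red <- mask * 0.85 + matrix(rnorm(160^2, 0, 0.02), 160)
  red <- pmin(pmax(red, 0), 1)
  nm <- segment_neuron(red, 0.2)
  expect_equal(nm$component_count, 1L)
  expect_lt(abs(compute_neuron_size(nm) - 401) / 401, 0.03)
  expect_lt(abs(nm$interior_area_um2 + nm$boundary_area_um2 -
                  sum(mask) * 0.04) / (sum(mask) * 0.04), 0.02)
})

test_that("a blank noise-only channel raises no-neuron-found", {
  set.seed(4)
  red <- matrix(abs(rnorm(120^2, 0, 0.03)), 120)
  expect_error(segment_neuron(red / max(red), 0.2),
               class = "synapcover_no_neuron")
})

test_that("two disjoint somata yield component_count 2", {
  d <- render_degenerate_image("two_neurons", seed = 21)
  img <- normalize_intensity(d$image)
  nm <- segment_neuron(get_channel(img, "neurofilament"), 0.2)
  expect_equal(nm$component_count, 2L)
})

test_that("segmentation and detection are invariant to translation and rotation", {
  r <- render_neuron_image(420, 0.3, 0.2, seed = 9)
  img <- normalize_intensity(r$image)
  red <- get_channel(img, "neurofilament")
  g <- get_channel(img, "gad")
  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m)))]
  pad <- function(m, k = 7) {
    out <- matrix(0, nrow(m) + k, ncol(m) + k)
    out[(k + 1):(nrow(m) + k), (k + 1):(ncol(m) + k)] <- m
    out
  }
  s0 <- segment_neuron(red, 0.2)
  for (tf in list(rot90, pad)) {
    st <- segment_neuron(tf(red), 0.2)
    expect_equal(compute_neuron_size(st), compute_neuron_size(s0))
    expect_equal(st$component_count, s0$component_count)
  }
  n0 <- n_puncta(detect_puncta(g, 0.2))
  expect_equal(n_puncta(detect_puncta(rot90(g), 0.2)), n0)
  expect_equal(n_puncta(detect_puncta(pad(g), 0.2)), n0)
})

test_that("well-separated noise-free puncta are recovered exactly", {
  r <- render_neuron_image(2000, 0.06, 0.2, noise_sd = 0, seed = 13,
                           min_sep_um = 0.9)
  expect_equal(r$truth$n_membrane_puncta, 120)
  img <- normalize_intensity(r$image)
  ps <- detect_puncta(get_channel(img, "gad"), 0.2)
  expect_equal(n_puncta(ps), 120)
})

test_that("punctum count under default noise stays within 5 of the planted 120", {
  for (s in 1:6) {
    r <- render_neuron_image(400, 0.30, 0.2, seed = 100 + s)
    expect_equal(r$truth$n_membrane_puncta, 120)
    img <- normalize_intensity(r$image)
    n <- n_puncta(detect_puncta(get_channel(img, "gad"), 0.2))
    expect_lte(abs(n - 120), 5)
  }
})

test_that("an empty channel yields an empty puncta set", {
  ps <- detect_puncta(matrix(0, 80, 80), 0.2)
  expect_equal(n_puncta(ps), 0)
  expect_equal(nrow(ps$puncta), 0)
})

test_that("punctum count is monotone non-increasing in the threshold", {
  r <- render_neuron_image(420, 0.3, 0.2, seed = 31)
  g <- get_channel(normalize_intensity(r$image), "gad")
  counts <- sapply(c(0.1, 0.22, 0.4, 0.6, 0.9), function(th)
    n_puncta(detect_puncta(g, 0.2, punctum_params(threshold = th))))
  expect_true(all(diff(counts) <= 0))
})

test_that("punctum masks are disjoint with areas in the admissible range", {
  r <- render_neuron_image(450, 0.35, 0.2, seed = 17)
  ps <- detect_puncta(get_channel(normalize_intensity(r$image), "gad"), 0.2)
  max_px <- round(pi * (1.5 / 2 / 0.2)^2)
  expect_true(all(ps$puncta$area_px >= 3 & ps$puncta$area_px <= max_px))
  # label matrix partitions pixels: punctum areas sum to labelled pixels
  expect_equal(sum(ps$puncta$area_px), sum(ps$label > 0))
})

test_that("DAB extraction recovers planted fractions and units", {
  full <- render_dab_image(1, area_mm2 = 0.0025, pixel_size = 0.2, seed = 2)
  q <- quantify_dab(full$image, assessed_area_mm2 = 0.0025)
  expect_equal(q$positive_pixels, full$truth$n_pixels)
  expect_equal(q$expression, full$truth$n_pixels / 1e6 / 0.0025)

  none <- render_dab_image(0, area_mm2 = 0.0025, seed = 2)
  expect_equal(quantify_dab(none$image)$expression, 0)

  quarter <- render_dab_image(0.25, area_mm2 = 0.0025, seed = 5)
  qq <- quantify_dab(quarter$image)
  frac <- qq$positive_pixels / quarter$truth$n_pixels
  expect_lt(abs(frac - 0.25) / 0.25, 0.03)

  expect_error(quantify_dab(make_stack(matrix(0.5, 10, 10))), "rgb")
})
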