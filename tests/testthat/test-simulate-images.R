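test_that("planted punctum count equals round(coverage x area) for any seed", {
  cases <- list(c(400, 0.30, 120), c(531, 0.348, 185), c(250, 0, 0),
                c(403, 0.299, 120))
  for (cs in cases) {
    r <- render_neuron_image(soma_area_um2 = cs[1], coverage = cs[2],
                             pixel_size = 0.2, seed = 11)
    expect_identical(r$truth$n_membrane_puncta, round(cs[2] * cs[1]))
    expect_equal(nrow(r$truth$puncta_centroids), cs[3])
    expect_equal(r$truth$planted_coverage * cs[1],
                 r$truth$n_membrane_puncta)
  }
})

test_that("zero coverage leaves the green channel noise-only", {
  r <- render_neuron_image(coverage = 0, noise_sd = 0, seed = 2)
  expect_equal(sum(get_channel(r$image, "gad")), 0)
  r2 <- render_neuron_image(coverage = 0, noise_sd = 0.03, seed = 2)
  expect_lt(max(get_channel(r2$image, "gad")), 0.2)
})

test_that("rendering is bit-identical under a fixed seed", {
  a <- render_neuron_image(450, 0.32, seed = 77)
  b <- render_neuron_image(450, 0.32, seed = 77)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$puncta_centroids, b$truth$puncta_centroids)
  c <- render_neuron_image(450, 0.32, seed = 78)
  expect_false(identical(a$image$channels, c$image$channels))
})

test_that("rasterized soma area matches the requested area and refines with pixel size", {
  r <- render_neuron_image(531, 0.2, pixel_size = 0.2, seed = 4)
  expect_lt(abs(r$truth$raster_area_um2 - 531) / 531, 0.02)
  # mean relative error shrinks monotonically as pixels get finer
  rel_err <- sapply(c(0.4, 0.2, 0.1), function(ps) {
    mean(sapply(1:5, function(s) {
      r <- render_neuron_image(450, 0, pixel_size = ps, noise_sd = 0,
                               seed = s)
      abs(r$truth$raster_area_um2 - 450) / 450
    }))
  })
  expect_true(all(diff(rel_err) < 0))
})

test_that("invalid render parameters are rejected", {
  expect_error(render_neuron_image(soma_area_um2 = -5), "soma_area_um2")
  expect_error(render_neuron_image(pixel_size = 0), "pixel_size")
  expect_error(render_neuron_image(coverage = -0.1), "coverage")
  # far beyond the packing limit of the membrane band
  expect_error(render_neuron_image(400, coverage = 5, seed = 1),
               "placement failure.*2000")
})

test_that("degenerate renders carry their planted defect and reject unknown kinds", {
  for (k in c("poor_contrast", "multi_process", "two_neurons",
              "incorrect_neuron")) {
    d <- render_degenerate_image(k, seed = 5)
    expect_identical(d$truth$degenerate_kind, k)
  }
  expect_error(render_degenerate_image("blurry", seed = 1), "kind")
  pc <- render_degenerate_image("poor_contrast", seed = 6)
  red <- get_channel(pc$image, "neurofilament")
  expect_lt(diff(quantile(red, c(0.01, 0.99))), 0.15)
})

test_that("DAB renders plant an exact positive pixel count", {
  z <- render_dab_image(0, area_mm2 = 0.001, seed = 3)
  expect_identical(z$truth$n_positive_pixels, 0)
  full <- render_dab_image(1, area_mm2 = 0.04, pixel_size = 0.2, seed = 3)
  expect_identical(full$truth$n_positive_pixels, 1000000)
  expect_error(render_dab_image(1.2), "positive_fraction")
  expect_error(render_dab_image(0.5, area_mm2 = -1), "area_mm2")
})
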