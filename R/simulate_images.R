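# ---- geometry helpers -------------------------------------------------------

# Irregular convex-ish polygon approximating a pyramidal soma profile.
# Vertices at sorted angles with radial jitter; radii rescaled so the exact
# (shoelace) polygon area equals `area_px2`.  Returns an n x 2 matrix of
# 0-based pixel coordinates centred on `centre`.
soma_polygon <- function(area_px2, centre = c(0, 0), n_vertices = NULL,
                         radial_jitter = 0.25) {
  if (is.null(n_vertices)) n_vertices <- sample(8:12, 1L)
  # equally spaced angles with bounded jitter keep the polygon star-shaped
  # around the centre (i.i.d. angles can cluster into a degenerate sliver)
  step <- 2 * pi / n_vertices
  ang <- sort((seq_len(n_vertices) - 1) * step +
                stats::runif(n_vertices, -0.4, 0.4) * step +
                stats::runif(1, 0, 2 * pi))
  rad <- 1 + stats::runif(n_vertices, -radial_jitter, radial_jitter)
  x <- rad * cos(ang)
  y <- rad * sin(ang)
  a <- polygon_area(cbind(x, y))
  s <- sqrt(area_px2 / a)
  cbind(x = centre[1] + s * x, y = centre[2] + s * y)
}

# Shoelace area of a polygon given as n x 2 matrix (any orientation).
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Rasterize a polygon onto a width x height grid: TRUE where the pixel
# centre (0-based coordinates) falls inside.
rasterize_polygon <- function(poly, width, height) {
  grid <- cbind(rep(seq_len(width) - 1, times = height),
                rep(seq_len(height) - 1, each = width))
  inside <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), grid)
  matrix(inside, nrow = width, ncol = height)
}

# Additive rendering of isotropic Gaussian blobs onto `img` ([x, y] layout).
# centres: n x 2 matrix of 0-based continuous coords; peak: length-n vector.
add_gaussian_blobs <- function(img, centres, peak, sigma_px) {
  if (NROW(centres) == 0L) return(img)
  w <- nrow(img); h <- ncol(img)
  r <- ceiling(4 * sigma_px)
  for (i in seq_len(NROW(centres))) {
    cx <- centres[i, 1]; cy <- centres[i, 2]
    xi <- max(1L, floor(cx - r) + 1L):min(w, ceiling(cx + r) + 1L)
    yi <- max(1L, floor(cy - r) + 1L):min(h, ceiling(cy + r) + 1L)
    gx <- exp(-((xi - 1 - cx)^2) / (2 * sigma_px^2))
    gy <- exp(-((yi - 1 - cy)^2) / (2 * sigma_px^2))
    img[xi, yi] <- img[xi, yi] + peak[i] * outer(gx, gy)
  }
  img
}

# Pixels within `band_px` (Euclidean) of the mask outline, inside or out.
membrane_band_mask <- function(mask, band_px) {
  b <- mask_boundary(mask)
  d <- EBImage::distmap(EBImage::Image(1 - b))
  img_data(d) <= band_px
}

# 8-connected outline: object pixels with at least one background neighbour
# (pixels beyond the image edge count as background).  Separable 3x3
# neighbourhood sum on a zero-padded copy; a pixel is boundary when the sum
# of its 9-neighbourhood is below 9.
mask_boundary <- function(mask) {
  w <- nrow(mask); h <- ncol(mask)
  p <- matrix(0, w + 2L, h + 2L)
  p[2:(w + 1L), 2:(h + 1L)] <- mask
  a <- p[1:w, ] + p[2:(w + 1L), ] + p[3:(w + 2L), ]
  s <- a[, 1:h] + a[, 2:(h + 1L)] + a[, 3:(h + 2L)]
  mask & s < 9
}

# Sample `n` points uniformly over TRUE pixels of `region`, with pairwise
# minimum separation `min_sep_px`, plus sub-pixel jitter.  Errors if the
# requested count cannot be placed.
place_points <- function(region, n, min_sep_px, max_stall = 5000L) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  idx <- which(region, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("placement failure: membrane band is empty", call. = FALSE)
  # random sequential adsorption jams near 55% disc coverage; refuse
  # outright when the request exceeds that capacity
  capacity <- 0.6 * nrow(idx) / (pi * (min_sep_px / 2)^2)
  if (min_sep_px > 0 && n > 1.5 * capacity)
    stop(sprintf(paste0("placement failure: could not place %d puncta at ",
                        "minimum separation %.2f px (band capacity ~%d)"),
                 n, min_sep_px, floor(capacity)), call. = FALSE)
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  stall <- 0L
  sep <- min_sep_px
  while (placed < n) {
    if (stall > max_stall) {
      # near the jamming limit: relax the separation slightly rather than
      # fail; the planted count stays exact, a few pairs pack tighter
      sep <- sep * 0.85
      stall <- 0L
      if (sep < 1)
        stop(sprintf(paste0("placement failure: could not place %d puncta ",
                            "at minimum separation %.2f px (placed %d)"),
                     n, min_sep_px, placed), call. = FALSE)
    }
    k <- idx[sample.int(nrow(idx), 1L), ]
    cand <- c(k[1] - 1 + stats::runif(1, -0.5, 0.5),
              k[2] - 1 + stats::runif(1, -0.5, 0.5))
    if (placed > 0L) {
      d2 <- (pts[seq_len(placed), 1] - cand[1])^2 +
            (pts[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < sep^2) {
        stall <- stall + 1L
        next
      }
    }
    placed <- placed + 1L
    stall <- 0L
    pts[placed, ] <- cand
  }
  pts
}

# ---- neuron image generator -------------------------------------------------

#' Render a synthetic confocal-like neuron image with planted ground truth
#'
#' Emulates a single layer-5 pyramidal soma (neurofilament, red channel)
#' ringed by GAD+ puncta (green channel) at a requested membrane coverage,
#' with a DAPI nuclear disc (blue channel).  The planted punctum count is
#' exactly `round(coverage * soma_area_um2)`; punctum centroids are drawn
#' uniformly on the membrane band (soma outline dilated by
#' `band_halfwidth_um`).  Both fluorescence channels are multiplied by
#' `intensity_scale` (emulating per-case staining/illumination drift),
#' clipped to `[0, 1]`, and degraded with additive Gaussian noise.
#'
#' @param soma_area_um2 target soma area in µm² (> 0).
#' @param coverage planted coverage in puncta per µm² of soma area (>= 0).
#' @param pixel_size µm per pixel (> 0).
#' @param noise_sd additive Gaussian noise SD in full-scale units.
#' @param intensity_scale multiplicative intensity factor (applied before
#'   noise).
#' @param seed integer seed; the render is bit-reproducible given the seed.
#' @param band_halfwidth_um half-width of the membrane band on which puncta
#'   are planted, µm.  Slightly wider than the default counting band
#'   half-width (0.5 µm): a punctum centred up to ~0.75 µm from the
#'   boundary still extends into the counting band, and the extra width
#'   eases packing at high planted densities.
#' @param punctum_fwhm_um full width at half maximum of a rendered punctum.
#' @param min_sep_um minimum separation between planted punctum centres, µm.
#'   The default (1.2 x FWHM, about 2.8 sigma) is the smallest separation
#'   at which two rendered puncta of unequal brightness still present two
#'   distinct intensity maxima, so the planted count remains recoverable.
#' @param margin_um blank margin around the soma, µm.
#' @param include_dapi include the nuclear (blue) channel.
#' @param case_id,image_id identifiers carried into the stack.
#' @return a list with elements `image` (an [image_stack()]) and `truth`
#'   (a `ground_truth` record: `soma_polygon`, `soma_area_um2`,
#'   `raster_area_um2`, `puncta_centroids`, `n_membrane_puncta`,
#'   `planted_coverage`, `intensity_scale`, `degenerate_kind`).
#' @export
render_neuron_image <- function(soma_area_um2 = 400, coverage = 0.30,
                                pixel_size = 0.2, noise_sd = 0.03,
                                intensity_scale = 1, seed = NULL,
                                band_halfwidth_um = 0.6,
                                punctum_fwhm_um = 0.5,
                                min_sep_um = 1.2 * punctum_fwhm_um,
                                margin_um = 4, include_dapi = TRUE,
                                case_id = "", image_id = "") {
  if (!is.finite(soma_area_um2) || soma_area_um2 <= 0)
    stop("`soma_area_um2` must be > 0", call. = FALSE)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be > 0", call. = FALSE)
  if (!is.finite(coverage) || coverage < 0)
    stop("`coverage` must be >= 0", call. = FALSE)
  with_seed(seed, {
    area_px2 <- soma_area_um2 / pixel_size^2
    r_eq <- sqrt(area_px2 / pi)
    margin_px <- margin_um / pixel_size
    side <- ceiling(2 * (1.3 * r_eq + margin_px))
    ctr <- c(side - 1, side - 1) / 2
    poly <- soma_polygon(area_px2, centre = ctr)
    mask <- rasterize_polygon(poly, side, side)

    n_puncta <- round(coverage * soma_area_um2)
    band <- membrane_band_mask(mask, band_halfwidth_um / pixel_size)
    centres <- place_points(band, n_puncta, min_sep_um / pixel_size)

    sigma_px <- punctum_fwhm_um / (2 * sqrt(2 * log(2))) / pixel_size
    peaks <- stats::runif(n_puncta, 0.6, 1.0)

    red <- matrix(0, side, side)
    red[mask] <- 0.85
    green <- add_gaussian_blobs(matrix(0, side, side), centres, peaks,
                                sigma_px)
    channels <- list(neurofilament = red, gad = green)
    if (include_dapi) {
      cen <- polygon_centroid(poly)
      gx <- (seq_len(side) - 1) - cen[1]
      gy <- (seq_len(side) - 1) - cen[2]
      nucleus <- outer(gx^2, gy^2, "+") <= (0.45 * r_eq)^2
      blue <- matrix(0, side, side)
      blue[nucleus] <- 0.8
      channels$dapi <- blue
    }
    channels <- lapply(channels, function(ch) {
      ch <- pmin(pmax(ch * intensity_scale, 0), 1)
      pmin(pmax(ch + stats::rnorm(length(ch), 0, noise_sd), 0), 1)
    })
    truth <- structure(
      list(soma_polygon = poly,
           soma_area_um2 = soma_area_um2,
           raster_area_um2 = sum(mask) * pixel_size^2,
           puncta_centroids = centres,
           n_membrane_puncta = n_puncta,
           planted_coverage = n_puncta / soma_area_um2,
           intensity_scale = intensity_scale,
           degenerate_kind = "none"),
      class = "ground_truth")
    list(image = image_stack(channels, pixel_size, case_id, image_id),
         truth = truth)
  })
}

#' Render a synthetic image exhibiting one of the QC deletion defects
#'
#' Produces images that should be flagged by [qc_evaluate()]:
#' `poor_contrast` (red-channel dynamic range compressed below the QC
#' contrast threshold), `multi_process` (thin elongated processes attached
#' to the soma, driving solidity below threshold), `two_neurons` (two
#' disjoint somata each above the minimum soma area), and
#' `incorrect_neuron` (a fragment below the minimum soma area).
#'
#' @param kind one of `"poor_contrast"`, `"multi_process"`,
#'   `"two_neurons"`, `"incorrect_neuron"`.
#' @param seed integer seed.
#' @param pixel_size µm per pixel.
#' @param ... further arguments passed to [render_neuron_image()].
#' @return as [render_neuron_image()]; `truth$degenerate_kind` records the
#'   planted defect.
#' @export
render_degenerate_image <- function(kind, seed = NULL, pixel_size = 0.2,
                                    ...) {
  kinds <- c("poor_contrast", "multi_process", "two_neurons",
             "incorrect_neuron")
  if (length(kind) != 1L || !kind %in% kinds)
    stop("`kind` must be one of: ", paste(kinds, collapse = ", "),
         call. = FALSE)
  out <- with_seed(seed, switch(kind,
    poor_contrast = {
      r <- render_neuron_image(pixel_size = pixel_size, ...)
      red <- get_channel(r$image, "neurofilament")
      # compress dynamic range well below the QC contrast threshold
      r$image$channels$neurofilament <- 0.45 + 0.08 * red
      r
    },
    multi_process = {
      r <- render_neuron_image(pixel_size = pixel_size, margin_um = 18, ...)
      red <- get_channel(r$image, "neurofilament")
      side <- nrow(red)
      cen <- polygon_centroid(r$truth$soma_polygon)
      len_px <- 15 / pixel_size
      w_px <- 0.8 / pixel_size
      for (ang in stats::runif(3, 0, 2 * pi)) {
        t_seq <- seq(0, 1.3 * sqrt(r$truth$soma_area_um2 / pi) / pixel_size +
                       len_px, by = 0.5)
        px <- round(cen[1] + t_seq * cos(ang))
        py <- round(cen[2] + t_seq * sin(ang))
        for (dx in seq(-ceiling(w_px / 2), ceiling(w_px / 2))) {
          xi <- px + dx
          ok <- xi >= 0 & xi < side & py >= 0 & py < side
          red[cbind(xi[ok] + 1, py[ok] + 1)] <- 0.85
        }
      }
      r$image$channels$neurofilament <-
        pmin(pmax(red + stats::rnorm(length(red), 0, 0.01), 0), 1)
      r
    },
    two_neurons = {
      a <- render_neuron_image(soma_area_um2 = 250, pixel_size = pixel_size,
                               margin_um = 3, ...)
      b <- render_neuron_image(soma_area_um2 = 250, pixel_size = pixel_size,
                               margin_um = 3, ...)
      da <- dim(get_channel(a$image, "neurofilament"))
      db <- dim(get_channel(b$image, "neurofilament"))
      gap <- ceiling(4 / pixel_size)
      w <- da[1] + db[1] + gap; h <- max(da[2], db[2])
      ch <- lapply(names(a$image$channels), function(role) {
        m <- matrix(0, w, h)
        m[seq_len(da[1]), seq_len(da[2])] <- a$image$channels[[role]]
        m[da[1] + gap + seq_len(db[1]), seq_len(db[2])] <-
          b$image$channels[[role]]
        m
      })
      names(ch) <- names(a$image$channels)
      a$image <- image_stack(ch, pixel_size)
      a$truth$degenerate_kind <- "two_neurons"
      a
    },
    incorrect_neuron = {
      render_neuron_image(soma_area_um2 = 50, coverage = 0,
                          pixel_size = pixel_size, ...)
    }))
  out$truth$degenerate_kind <- kind
  out
}

#' Render a synthetic DAB-stained RGB image with an exact positive fraction
#'
#' Emulates a brightfield field of view of DAB immunohistochemistry with
#' haematoxylin counterstain.  Exactly `round(positive_fraction * n_pixels)`
#' pixels are coloured with a DAB-brown absorbance spectrum; the remainder
#' are haematoxylin-blue or near-white background.  Colours follow the
#' Beer-Lambert model under the standard haematoxylin/DAB stain vectors, so
#' colour-deconvolution extraction can recover the planted fraction.
#'
#' @param positive_fraction fraction of DAB-positive pixels in `[0, 1]`.
#' @param area_mm2 physical area of the field, mm².
#' @param pixel_size µm per pixel.
#' @param seed integer seed.
#' @param noise_sd RGB additive noise SD.
#' @return list with `image` (an [image_stack()] with an `rgb` channel) and
#'   `truth` (`n_positive_pixels`, `n_pixels`, `positive_fraction`).
#' @export
render_dab_image <- function(positive_fraction, area_mm2 = 0.04,
                             pixel_size = 0.2, seed = NULL,
                             noise_sd = 0.005) {
  if (!is.finite(positive_fraction) || positive_fraction < 0 ||
      positive_fraction > 1)
    stop("`positive_fraction` must be in [0, 1]", call. = FALSE)
  if (!is.finite(area_mm2) || area_mm2 <= 0)
    stop("`area_mm2` must be > 0", call. = FALSE)
  with_seed(seed, {
    n_px <- round(area_mm2 * 1e6 / pixel_size^2)
    side <- floor(sqrt(n_px))
    w <- side; h <- ceiling(n_px / side)
    n_tot <- w * h
    n_pos <- round(positive_fraction * n_tot)
    pos <- logical(n_tot)
    if (n_pos > 0) pos[sample.int(n_tot, n_pos)] <- TRUE

    od_h <- od_d <- numeric(n_tot)
    od_d[pos] <- stats::runif(n_pos, 0.6, 1.1)
    od_h[pos] <- stats::runif(n_pos, 0, 0.10)
    neg <- which(!pos)
    hema <- neg[stats::runif(length(neg)) < 0.5]
    bg <- setdiff(neg, hema)
    od_h[hema] <- stats::runif(length(hema), 0.3, 0.8)
    od_d[hema] <- stats::runif(length(hema), 0, 0.05)
    od_h[bg] <- stats::runif(length(bg), 0, 0.04)
    od_d[bg] <- stats::runif(length(bg), 0, 0.03)

    sv <- hdab_stain_vectors()
    od_rgb <- cbind(od_h, od_d) %*% sv[1:2, ]
    rgb <- 10^(-od_rgb)
    rgb <- rgb + stats::rnorm(length(rgb), 0, noise_sd)
    rgb <- pmin(pmax(rgb, 0), 1)
    arr <- array(rgb, dim = c(w, h, 3))
    truth <- structure(
      list(n_positive_pixels = n_pos, n_pixels = n_tot,
           positive_fraction = n_pos / n_tot,
           degenerate_kind = "none"),
      class = "ground_truth")
    list(image = image_stack(list(rgb = arr), pixel_size),
         truth = truth)
  })
}

#' Simulate an imaging experiment for a set of cases
#'
#' Renders `neurons_per_case` neuron images for each of `n_cases` cases.
#' Per-neuron soma areas and coverages are drawn around the case means
#' (Gaussian, truncated at zero), and each case receives a multiplicative
#' intensity-drift factor drawn uniformly from `scale_range`, emulating
#' between-case staining variation.
#'
#' @param n_cases number of cases.
#' @param neurons_per_case neurons imaged per case.
#' @param coverage_mean,coverage_sd per-neuron planted coverage
#'   distribution (puncta/µm²).
#' @param soma_area_mean,soma_area_sd per-neuron soma area distribution
#'   (µm²).
#' @param pixel_size µm per pixel.
#' @param noise_sd additive noise SD.
#' @param scale_range range of the per-case intensity drift factor.
#' @param seed integer seed.
#' @param case_prefix prefix for case identifiers.
#' @return list of per-neuron records, each as returned by
#'   [render_neuron_image()].
#' @export
simulate_case_images <- function(n_cases = 1, neurons_per_case = 30,
                                 coverage_mean = 0.30, coverage_sd = 0.02,
                                 soma_area_mean = 450, soma_area_sd = 60,
                                 pixel_size = 0.2, noise_sd = 0.03,
                                 scale_range = c(0.6, 1.4), seed = NULL,
                                 case_prefix = "case") {
  with_seed(seed, {
    out <- vector("list", n_cases * neurons_per_case)
    k <- 0L
    for (ci in seq_len(n_cases)) {
      scl <- stats::runif(1, scale_range[1], scale_range[2])
      for (ni in seq_len(neurons_per_case)) {
        # symmetric +/- 2 SD truncation: keeps the planted group mean
        # while avoiding unpackable extreme draws
        rtrunc <- function(m, s) {
          if (s <= 0) return(m)
          repeat {
            v <- stats::rnorm(1, m, s)
            if (abs(v - m) <= 2 * s) return(v)
          }
        }
        a <- max(rtrunc(soma_area_mean, soma_area_sd), 50)
        cv <- max(rtrunc(coverage_mean, coverage_sd), 0)
        k <- k + 1L
        out[[k]] <- render_neuron_image(
          soma_area_um2 = a, coverage = cv, pixel_size = pixel_size,
          noise_sd = noise_sd, intensity_scale = scl,
          case_id = sprintf("%s%02d", case_prefix, ci),
          image_id = sprintf("%s%02d_n%03d", case_prefix, ci, ni))
      }
    }
    out
  })
}
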