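# Image processing: intensity normalization, soma segmentation, punctum
# detection, DAB colour extraction.

#' Percentile-based light-intensity normalization
#'
#' Post-mortem confounders (time in formalin, post-mortem interval, tissue
#' pH) shift absolute immunofluorescence intensity between cases.  Each
#' fluorescence channel is linearly rescaled so that its `low_pct`
#' percentile maps to 0 and its `high_pct` percentile maps to 1, then
#' clipped to `[0, 1]`.  The transform is invariant to multiplicative
#' intensity drift in the clipping-free regime.  An `rgb` channel is left
#' untouched.
#'
#' In a punctate channel the brightest structures (the puncta) occupy well
#' under 1% of pixels, so anchoring the top of the scale at the 99th
#' percentile would saturate punctum cores into flat plateaus and make
#' touching puncta inseparable.  The `gad` and `synaptophysin` channels
#' therefore use `puncta_high_pct` (default 99.9) as their upper anchor.
#'
#' @param image an [image_stack()].
#' @param low_pct,high_pct percentiles in `[0, 100]`, `low_pct < high_pct`.
#' @param puncta_high_pct upper anchor percentile for punctate channels.
#' @return the normalized [image_stack()].
#' @export
normalize_intensity <- function(image, low_pct = 1, high_pct = 99,
                                puncta_high_pct = 99.9) {
  stopifnot(inherits(image, "image_stack"))
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100))
    stop("need 0 <= low_pct < high_pct <= 100", call. = FALSE)
  for (role in names(image$channels)) {
    if (role == "rgb") next
    hp <- if (role %in% c("gad", "synaptophysin")) puncta_high_pct
          else high_pct
    ch <- image$channels[[role]]
    q <- stats::quantile(ch, c(low_pct, hp) / 100, names = FALSE)
    if (q[2] - q[1] <= .Machine$double.eps) {
      cond <- structure(
        class = c("synapcover_degenerate_channel", "error", "condition"),
        list(message = sprintf(
               "channel '%s' is degenerate (no dynamic range between the %g and %g percentiles)",
               role, low_pct, hp),
             call = sys.call(-1), role = role))
      stop(cond)
    }
    image$channels[[role]] <- pmin(pmax((ch - q[1]) / (q[2] - q[1]), 0), 1)
  }
  image
}

#' Segmentation parameters for the soma boundary
#'
#' @param threshold fixed intensity threshold on the normalized red
#'   channel; `NULL` selects Otsu's threshold per image.
#' @param r_open_um radius of the despeckling morphological opening
#'   applied before closing, µm; removes isolated suprathreshold noise
#'   pixels without affecting a solid soma.
#' @param r_close_um radius of the morphological closing element, µm.
#' @param min_soma_area_um2 components smaller than this are discarded
#'   before the largest surviving component is retained, µm².
#' @return parameter list.
#' @export
seg_params <- function(threshold = NULL, r_open_um = 0.2,
                       r_close_um = 0.6, min_soma_area_um2 = 100) {
  list(threshold = threshold, r_open_um = r_open_um,
       r_close_um = r_close_um, min_soma_area_um2 = min_soma_area_um2)
}

# Odd-sized disc brush of radius `r_px` (>= 1 pixel).
disc_brush <- function(r_px) {
  size <- max(3L, 2L * as.integer(ceiling(r_px)) + 1L)
  EBImage::makeBrush(size, shape = "disc")
}

no_neuron_error <- function(msg) {
  stop(structure(
    class = c("synapcover_no_neuron", "error", "condition"),
    list(message = msg, call = NULL)))
}

#' Segment the neuronal perikaryon boundary
#'
#' Part (i) of the coverage algorithm.  The normalized neurofilament (red)
#' channel is thresholded (Otsu by default), morphologically closed, holes
#' are filled, components below `min_soma_area_um2` are removed, and the
#' largest surviving component is retained as the soma.  The boundary is
#' the 8-connected outline of the retained object (object pixels with a
#' background 8-neighbour); the interior is the object minus its boundary.
#'
#' @param red_channel normalized red-channel matrix (`[x, y]` layout).
#' @param pixel_size µm per pixel.
#' @param params see [seg_params()].
#' @return a `neuron_mask`: `interior` (logical matrix), `boundary_coords`
#'   (m x 2, 0-based `(x, y)`), `object` (interior + boundary mask),
#'   `interior_area_um2`, `boundary_area_um2`, `component_count` (number of
#'   components surviving the size filter), `solidity` (object area over
#'   convex-hull area), `pixel_size`.
#' @export
segment_neuron <- function(red_channel, pixel_size, params = seg_params()) {
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be > 0", call. = FALSE)
  thr <- params$threshold
  if (is.null(thr))
    thr <- EBImage::otsu(EBImage::Image(red_channel), range = c(0, 1))
  bw <- EBImage::Image((red_channel > thr) * 1)
  if (params$r_open_um > 0)
    bw <- EBImage::opening(bw, disc_brush(params$r_open_um / pixel_size))
  bw <- EBImage::closing(bw, disc_brush(params$r_close_um / pixel_size))
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(as.integer(lab))
  min_px <- params$min_soma_area_um2 / pixel_size^2
  keep <- which(sizes >= min_px)
  if (length(keep) == 0L)
    no_neuron_error(sprintf(
      "no component reaches the minimum soma area (%.0f um^2)",
      params$min_soma_area_um2))
  largest <- keep[which.max(sizes[keep])]
  obj <- img_data(lab) == largest
  new_neuron_mask(obj, pixel_size, component_count = length(keep))
}

# Build a neuron_mask from a segmented object mask.
new_neuron_mask <- function(obj, pixel_size, component_count = 1L) {
  boundary <- mask_boundary(obj)
  interior <- obj & !boundary
  bc <- which(boundary, arr.ind = TRUE) - 1L
  structure(
    list(interior = interior,
         boundary_coords = unname(bc),
         object = obj,
         interior_area_um2 = sum(interior) * pixel_size^2,
         boundary_area_um2 = sum(boundary) * pixel_size^2,
         component_count = component_count,
         solidity = mask_solidity(obj),
         pixel_size = pixel_size),
    class = "neuron_mask")
}

#' @export
print.neuron_mask <- function(x, ...) {
  cat(sprintf(
    "<neuron_mask> interior %.1f um^2 + boundary %.1f um^2, %d component(s), solidity %.2f\n",
    x$interior_area_um2, x$boundary_area_um2, x$component_count, x$solidity))
  invisible(x)
}

# Object pixel count over the area of the convex hull of the pixel centres
# (hull area corrected outward by half the hull perimeter + 1 so that a
# convex pixel set scores ~1).
mask_solidity <- function(obj) {
  pix <- which(obj, arr.ind = TRUE)
  if (nrow(pix) < 3L) return(1)
  h <- grDevices::chull(pix)
  hull <- pix[h, , drop = FALSE]
  a <- polygon_area(hull)
  j <- c(seq_len(nrow(hull))[-1], 1L)
  per <- sum(sqrt(rowSums((hull[j, , drop = FALSE] - hull)^2)))
  min(nrow(pix) / (a + per / 2 + 1), 1)
}

#' Punctum detection parameters
#'
#' @param threshold intensity threshold applied to the background-
#'   suppressed channel.
#' @param r_tophat_um radius of the white top-hat structuring element, µm.
#' @param blur_sigma_px Gaussian pre-smoothing SD in pixels.
#' @param min_punctum_px minimum punctum area, pixels.
#' @param max_punctum_diam_um diameter of the largest plausible single
#'   punctum; components above the corresponding disc area are split by
#'   watershed.
#' @param ws_tolerance minimum intensity drop between neighbouring local
#'   maxima for the watershed to keep them as separate puncta.
#' @return parameter list.
#' @export
punctum_params <- function(threshold = 0.22, r_tophat_um = 1.2,
                           blur_sigma_px = 0.4, min_punctum_px = 3,
                           max_punctum_diam_um = 1.5, ws_tolerance = 0.01) {
  list(threshold = threshold, r_tophat_um = r_tophat_um,
       blur_sigma_px = blur_sigma_px, min_punctum_px = min_punctum_px,
       max_punctum_diam_um = max_punctum_diam_um,
       ws_tolerance = ws_tolerance)
}

#' Detect synaptic puncta in the GAD (or synaptophysin) channel
#'
#' Part (ii) of the coverage algorithm.  The normalized channel is lightly
#' smoothed, background is suppressed with a white top-hat, and the
#' suprathreshold intensity surface is partitioned by a local-maximum
#' watershed, so that merged components of touching puncta are split into
#' one object per intensity peak (at membrane punctum densities of
#' 0.25-0.40/µm², neighbouring puncta routinely touch, so the watershed is
#' applied to the whole surface rather than only to oversize components).
#' Components outside the admissible pixel-area range are discarded; each
#' retained component is one punctum.
#'
#' @param green_channel normalized channel matrix (`[x, y]` layout).
#' @param pixel_size µm per pixel.
#' @param params see [punctum_params()].
#' @return a `puncta_set`: `puncta` (data.frame with `x`, `y` centroid in
#'   0-based pixels, `area_px`, `peak_intensity`), `label` (integer label
#'   matrix, 0 = background), `pixel_size`.
#' @export
detect_puncta <- function(green_channel, pixel_size,
                          params = punctum_params()) {
  g <- green_channel
  if (params$blur_sigma_px > 0)
    g <- blur_separable(g, params$blur_sigma_px)
  th <- EBImage::whiteTopHat(EBImage::Image(g),
                             disc_brush(params$r_tophat_um / pixel_size))
  thm <- img_data(th)
  max_px <- round(pi * (params$max_punctum_diam_um / 2 / pixel_size)^2)

  surf <- thm
  surf[thm <= params$threshold] <- 0
  lab <- img_data(EBImage::watershed(EBImage::Image(surf),
                                      tolerance = params$ws_tolerance,
                                      ext = 1))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= params$min_punctum_px & sizes <= max_px)
  pix <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  sel <- ids %in% keep
  pix <- pix[sel, , drop = FALSE]; ids <- ids[sel]
  lab[] <- 0L
  if (length(ids)) lab[pix] <- match(ids, sort(unique(ids)))
  puncta_set_from_label(lab, green_channel, pixel_size)
}

# Build a puncta_set from an integer label matrix (0 = background) and the
# intensity channel it was derived from.
puncta_set_from_label <- function(lab, intensity, pixel_size) {
  pix <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  if (length(ids)) {
    puncta <- data.frame(
      x = as.vector(tapply(pix[, 1] - 1, ids, mean)),
      y = as.vector(tapply(pix[, 2] - 1, ids, mean)),
      area_px = as.integer(tabulate(ids)),
      peak_intensity = as.vector(tapply(intensity[pix], ids, max)),
      row.names = NULL)
  } else {
    puncta <- data.frame(x = numeric(0), y = numeric(0),
                         area_px = integer(0), peak_intensity = numeric(0))
  }
  structure(list(puncta = puncta, label = lab, pixel_size = pixel_size),
            class = "puncta_set")
}

# Small separable Gaussian blur (replicated edges); radius 2 px suffices
# for the sub-pixel smoothing scales used here.
blur_separable <- function(m, sigma, r = 2L) {
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  w <- nrow(m); h <- ncol(m)
  out <- matrix(0, w, h)
  for (d in -r:r)
    out <- out + k[d + r + 1] * m[pmin(pmax(seq_len(w) + d, 1L), w), ]
  m2 <- out
  out <- matrix(0, w, h)
  for (d in -r:r)
    out <- out + k[d + r + 1] * m2[, pmin(pmax(seq_len(h) + d, 1L), h)]
  out
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %d puncta\n", nrow(x$puncta)))
  invisible(x)
}

#' Number of detected puncta
#' @param x a `puncta_set`.
#' @return integer count.
#' @export
n_puncta <- function(x) nrow(x$puncta)

# ---- DAB colour extraction --------------------------------------------------

# Normalized haematoxylin / DAB / residual absorbance vectors
# (Ruifrok-Johnston colour deconvolution).
hdab_stain_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.872)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  m <- rbind(h / sqrt(sum(h^2)), d / sqrt(sum(d^2)), r / sqrt(sum(r^2)))
  rownames(m) <- c("haematoxylin", "dab", "residual")
  m
}

#' DAB extraction parameters
#' @param dab_od_threshold optical-density threshold on the unmixed DAB
#'   channel above which a pixel is called positive.
#' @return parameter list.
#' @export
dab_params <- function(dab_od_threshold = 0.15) {
  list(dab_od_threshold = dab_od_threshold)
}

#' Quantify DAB-positive pixels by colour deconvolution
#'
#' Semi-automatic colour-based extraction of DAB immunoreactivity: RGB
#' intensities are converted to optical densities (Beer-Lambert), unmixed
#' into haematoxylin/DAB/residual stain space with the standard stain
#' matrix, and pixels whose DAB optical density exceeds the threshold are
#' counted as positive.  Expression is reported in millions of positive
#' pixels per mm² of assessed tissue.
#'
#' @param image an [image_stack()] with an `rgb` channel.
#' @param assessed_area_mm2 assessed physical area; defaults to the image
#'   area implied by its pixel size.
#' @param params see [dab_params()].
#' @return a `dab_quant`: `positive_pixels`, `assessed_area_mm2`,
#'   `expression` (millions of pixels/mm²).
#' @export
quantify_dab <- function(image, assessed_area_mm2 = NULL,
                         params = dab_params()) {
  stopifnot(inherits(image, "image_stack"))
  if (!"rgb" %in% names(image$channels))
    stop("`image` has no rgb channel", call. = FALSE)
  arr <- image$channels$rgb
  if (is.null(assessed_area_mm2))
    assessed_area_mm2 <- prod(dim(arr)[1:2]) * image$pixel_size^2 / 1e6
  if (assessed_area_mm2 <= 0)
    stop("`assessed_area_mm2` must be > 0", call. = FALSE)
  od <- -log10(pmax(matrix(arr, ncol = 3L), 1 / 255))
  unmix <- od %*% solve(hdab_stain_vectors())
  pos <- sum(unmix[, 2] > params$dab_od_threshold)
  structure(
    list(positive_pixels = pos,
         assessed_area_mm2 = assessed_area_mm2,
         expression = pos / 1e6 / assessed_area_mm2),
    class = "dab_quant")
}

#' @export
print.dab_quant <- function(x, ...) {
  cat(sprintf(
    "<dab_quant> %d positive px over %.3f mm^2 = %.3f million px/mm^2\n",
    x$positive_pixels, x$assessed_area_mm2, x$expression))
  invisible(x)
}
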