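# Part (iii) of the algorithm: combine neuron and puncta segmentations into
# the coverage statistic C', neuron size, and QC bookkeeping.

#' QC thresholds
#'
#' @param contrast_min minimum robust contrast (99th minus 1st percentile
#'   of the raw red channel, full-scale units) below which an image is
#'   deleted as `poor_contrast`.
#' @param solidity_min minimum solidity of the retained soma component;
#'   below it the segmentation is deemed to have captured multiple
#'   processes (`multi_process`).
#' @param min_soma_area_um2 minimum soma area, µm² (shared with
#'   [seg_params()]).
#' @return parameter list.
#' @export
qc_params <- function(contrast_min = 0.15, solidity_min = 0.80,
                      min_soma_area_um2 = 100) {
  list(contrast_min = contrast_min, solidity_min = solidity_min,
       min_soma_area_um2 = min_soma_area_um2)
}

qc_statuses <- function() {
  c("pass", "poor_contrast", "multi_process", "incorrect_neuron",
    "two_neurons")
}

#' Image quality-control status
#'
#' Reproduces the deletion rules applied after segmentation: in priority
#' order, `poor_contrast` (raw red-channel robust contrast below
#' `contrast_min`), `two_neurons` (two or more components above the
#' minimum soma area), `multi_process` (retained component solidity below
#' `solidity_min`), `incorrect_neuron` (no component reaching the minimum
#' soma area), otherwise `pass`.
#'
#' @param image the raw (pre-normalization) [image_stack()].
#' @param neuron a `neuron_mask` from [segment_neuron()], or the
#'   no-neuron-found condition it signalled, or `NULL` if segmentation was
#'   not attempted.
#' @param params see [qc_params()].
#' @return a single status string; always returns, never errors.
#' @export
qc_evaluate <- function(image, neuron = NULL, params = qc_params()) {
  red <- get_channel(image, "neurofilament")
  q <- stats::quantile(red, c(0.01, 0.99), names = FALSE)
  if (q[2] - q[1] < params$contrast_min) return("poor_contrast")
  if (is.null(neuron) || inherits(neuron, "condition") ||
      inherits(neuron, "synapcover_no_neuron"))
    return("incorrect_neuron")
  stopifnot(inherits(neuron, "neuron_mask"))
  if (neuron$component_count >= 2L) return("two_neurons")
  if (neuron$solidity < params$solidity_min) return("multi_process")
  "pass"
}

#' Neuron size
#'
#' The area within the segmented neuronal boundary summed with the area of
#' the delineated boundary itself: (interior pixel count + boundary pixel
#' count) x pixel_size², in µm².
#'
#' @param neuron a `neuron_mask`.
#' @return size in µm².
#' @export
compute_neuron_size <- function(neuron) {
  stopifnot(inherits(neuron, "neuron_mask"))
  neuron$interior_area_um2 + neuron$boundary_area_um2
}

#' Count puncta overlapping the neuronal membrane
#'
#' A punctum counts (once) if any of its pixels falls within the membrane
#' band: the segmented boundary dilated by `band_halfwidth_um` on both
#' sides.
#'
#' @param neuron a `neuron_mask`.
#' @param puncta a `puncta_set` from the same image.
#' @param band_halfwidth_um band half-width, µm (>= 0).
#' @return integer count N_s.
#' @export
count_membrane_synapses <- function(neuron, puncta,
                                    band_halfwidth_um = 0.5) {
  stopifnot(inherits(neuron, "neuron_mask"),
            inherits(puncta, "puncta_set"))
  if (!identical(dim(neuron$interior), dim(puncta$label)))
    stop("invalid pairing: neuron mask and puncta label dimensions differ",
         call. = FALSE)
  if (band_halfwidth_um < 0)
    stop("`band_halfwidth_um` must be >= 0", call. = FALSE)
  if (nrow(puncta$puncta) == 0L) return(0L)
  b <- matrix(FALSE, nrow(neuron$interior), ncol(neuron$interior))
  b[neuron$boundary_coords + 1L] <- TRUE
  d <- img_data(EBImage::distmap(EBImage::Image(1 - b)))
  band <- d <= band_halfwidth_um / neuron$pixel_size
  length(unique(puncta$label[band & puncta$label > 0]))
}

#' Inhibitory synaptic coverage of one neuron
#'
#' Computes C' = N_s / A(d), where N_s is the number of puncta overlapping
#' the neuronal membrane and A(d) is the area of the segmented neuron.
#' A(d) is taken as interior plus boundary area (identical to the neuron
#' size): the source method prints coverage "per µm² neuronal membrane"
#' while defining A(d) as the area of the segmented neuron, and this
#' package resolves that ambiguity by using the full segmented area.
#'
#' @param neuron a `neuron_mask`.
#' @param puncta a `puncta_set` from the same image.
#' @param band_halfwidth_um membrane band half-width, µm.
#' @param qc_status QC status to record (from [qc_evaluate()]).
#' @param case_id,image_id identifiers.
#' @return a `coverage_result` one-row data.frame: `case_id`, `image_id`,
#'   `n_synapses`, `area_ad_um2`, `coverage` (puncta/µm²),
#'   `neuron_size_um2`, `qc_status`.
#' @export
compute_coverage <- function(neuron, puncta, band_halfwidth_um = 0.5,
                             qc_status = "pass", case_id = "",
                             image_id = "") {
  size <- compute_neuron_size(neuron)
  if (size <= 0) no_neuron_error("segmented neuron has zero area")
  ns <- count_membrane_synapses(neuron, puncta, band_halfwidth_um)
  coverage_result(case_id, image_id, ns, size, ns / size, size, qc_status)
}

coverage_result <- function(case_id, image_id, n_synapses, area_ad_um2,
                            coverage, neuron_size_um2, qc_status) {
  stopifnot(qc_status %in% qc_statuses())
  structure(
    data.frame(case_id = case_id, image_id = image_id,
               n_synapses = n_synapses, area_ad_um2 = area_ad_um2,
               coverage = coverage, neuron_size_um2 = neuron_size_um2,
               qc_status = qc_status, stringsAsFactors = FALSE),
    class = c("coverage_result", "data.frame"))
}

#' Quantify one image end to end
#'
#' Runs the full per-neuron pipeline: QC contrast check on the raw image,
#' intensity normalization, soma segmentation, punctum detection, QC
#' status resolution, and the coverage computation.  QC-failed neurons are
#' retained in the output with their status and `NA` measurements, so
#' deletion bookkeeping stays reproducible.
#'
#' @param image a raw [image_stack()] with `neurofilament` and a puncta
#'   channel (`gad` or `synaptophysin`).
#' @param band_halfwidth_um membrane band half-width, µm.
#' @param seg,det,qc parameter lists ([seg_params()], [punctum_params()],
#'   [qc_params()]).
#' @param low_pct,high_pct,puncta_high_pct normalization percentiles.
#' @return a `coverage_result` row (see [compute_coverage()]).
#' @export
process_image <- function(image, band_halfwidth_um = 0.5,
                          seg = seg_params(), det = punctum_params(),
                          qc = qc_params(), low_pct = 1, high_pct = 99,
                          puncta_high_pct = 99.9) {
  stopifnot(inherits(image, "image_stack"))
  failed <- function(status)
    coverage_result(image$case_id, image$image_id, NA_integer_, NA_real_,
                    NA_real_, NA_real_, status)
  red_raw <- get_channel(image, "neurofilament")
  q <- stats::quantile(red_raw, c(0.01, 0.99), names = FALSE)
  if (q[2] - q[1] < qc$contrast_min) return(failed("poor_contrast"))

  norm <- tryCatch(
    normalize_intensity(image, low_pct, high_pct, puncta_high_pct),
    synapcover_degenerate_channel = function(e) e)
  if (inherits(norm, "condition")) return(failed("poor_contrast"))

  seg$min_soma_area_um2 <- qc$min_soma_area_um2
  neuron <- tryCatch(
    segment_neuron(get_channel(norm, "neurofilament"), image$pixel_size,
                   seg),
    synapcover_no_neuron = function(e) e)
  status <- qc_evaluate(image, neuron, qc)
  if (status != "pass") return(failed(status))

  role <- if ("gad" %in% names(image$channels)) "gad" else "synaptophysin"
  puncta <- detect_puncta(get_channel(norm, role), image$pixel_size, det)
  compute_coverage(neuron, puncta, band_halfwidth_um, status,
                   image$case_id, image$image_id)
}

#' QC deletion bookkeeping
#'
#' @param results a `coverage_result` data.frame (rows for every
#'   photographed neuron, QC-failed ones included), or a character vector
#'   of QC statuses, or a named vector of deletion-reason counts together
#'   with `n_photographed`.
#' @param n_photographed total photographed; defaults to `nrow(results)`
#'   when `results` carries per-neuron rows.
#' @return a `qc_report`: `n_photographed`, `n_deleted`,
#'   `deleted_by_reason` (named vector), `n_retained`, `percent_deleted`
#'   (stored unrounded; printed rounded to the nearest integer).
#' @export
summarize_qc <- function(results, n_photographed = NULL) {
  if (is.data.frame(results)) {
    if (nrow(results) == 0L) stop("empty results", call. = FALSE)
    status <- results$qc_status
  } else if (is.character(results) && length(results) > 0) {
    status <- results
  } else if (is.numeric(results) && !is.null(names(results))) {
    if (is.null(n_photographed))
      stop("`n_photographed` required with reason counts", call. = FALSE)
    by_reason <- results
    n_del <- sum(by_reason)
    return(qc_report(n_photographed, n_del, by_reason))
  } else stop("empty or unrecognised input", call. = FALSE)
  if (is.null(n_photographed)) n_photographed <- length(status)
  reasons <- setdiff(qc_statuses(), "pass")
  by_reason <- vapply(reasons, function(r) sum(status == r), integer(1))
  qc_report(n_photographed, sum(status != "pass"), by_reason)
}

qc_report <- function(n_photographed, n_deleted, by_reason) {
  stopifnot(n_deleted == sum(by_reason), n_photographed >= n_deleted)
  structure(
    list(n_photographed = as.integer(n_photographed),
         n_deleted = as.integer(n_deleted),
         deleted_by_reason = by_reason,
         n_retained = as.integer(n_photographed - n_deleted),
         percent_deleted = 100 * n_deleted / n_photographed),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d photographed, %d deleted (%d%%), %d retained\n",
              x$n_photographed, x$n_deleted, round(x$percent_deleted),
              x$n_retained))
  for (r in names(x$deleted_by_reason))
    if (x$deleted_by_reason[[r]] > 0)
      cat(sprintf("  %s: %d\n", r, x$deleted_by_reason[[r]]))
  invisible(x)
}

#' Per-case aggregation of passing neurons
#'
#' Unweighted means over neurons with `qc_status == "pass"` only.
#'
#' @param results a `coverage_result` data.frame.
#' @param case_id case to aggregate; `NULL` aggregates every case present.
#' @return data.frame with `case_id`, `mean_coverage`, `mean_neuron_size`,
#'   `n_pass`.  A case with zero passing neurons signals a
#'   `synapcover_case_excluded` condition (when named explicitly) or is
#'   dropped with a warning (when aggregating all).
#' @export
aggregate_case <- function(results, case_id = NULL) {
  stopifnot(is.data.frame(results))
  if (is.null(case_id)) {
    out <- lapply(unique(results$case_id), function(ci) {
      tryCatch(aggregate_case(results, ci),
               synapcover_case_excluded = function(e) {
                 warning(conditionMessage(e), call. = FALSE)
                 NULL
               })
    })
    return(do.call(rbind, out))
  }
  rows <- results[results$case_id == case_id &
                    results$qc_status == "pass", , drop = FALSE]
  if (nrow(rows) == 0L)
    stop(structure(
      class = c("synapcover_case_excluded", "error", "condition"),
      list(message = sprintf(
             "case '%s' excluded: no neuron passed quality control",
             case_id),
           call = NULL)))
  data.frame(case_id = case_id,
             mean_coverage = mean(rows$coverage),
             mean_neuron_size = mean(rows$neuron_size_um2),
             n_pass = nrow(rows), stringsAsFactors = FALSE)
}
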