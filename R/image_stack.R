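#' Calibrated multi-channel image
#'
#' An `image_stack` bundles one or more co-registered 2D channels with a
#' physical pixel-size calibration and case/image identifiers.  Channels are
#' named by biological role.  Fluorescence channels are numeric matrices on
#' the unit interval; the `rgb` role holds a width x height x 3 array.
#'
#' Pixel coordinates throughout the package are 0-based `(x, y)` =
#' (column, row), with `x` running along the first matrix dimension, so pixel
#' `(x, y)` is `channel[x + 1, y + 1]`.
#'
#' @param channels named list of 2D numeric matrices (or, for role `"rgb"`,
#'   a 3D array with third dimension 3).  Names must come from
#'   [channel_roles()].
#' @param pixel_size pixel edge length in micrometres (µm/pixel), > 0.
#' @param case_id,image_id identifier strings carried through to results.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size, case_id = "", image_id = "") {
  if (!is.list(channels) || length(channels) == 0L)
    stop("`channels` must be a non-empty named list", call. = FALSE)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("every channel must be named by its role", call. = FALSE)
  bad <- setdiff(names(channels), channel_roles())
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "),
         "; valid roles are ", paste(channel_roles(), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (µm/pixel)",
         call. = FALSE)
  dims <- lapply(channels, function(ch) dim(ch)[1:2])
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all channels must share the same height and width", call. = FALSE)
  structure(
    list(channels = channels, pixel_size = pixel_size,
         case_id = as.character(case_id), image_id = as.character(image_id)),
    class = "image_stack")
}

#' Recognised channel roles
#' @return character vector of valid channel role names.
#' @export
channel_roles <- function() {
  c("neurofilament", "gad", "synaptophysin", "dapi", "rgb")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %dx%d px @ %.3g um/px, channels: %s\n",
              d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  if (nzchar(x$case_id) || nzchar(x$image_id))
    cat(sprintf("  case '%s', image '%s'\n", x$case_id, x$image_id))
  invisible(x)
}

#' Retrieve one channel of an image stack
#'
#' @param image an [image_stack()].
#' @param role channel role name.
#' @return the channel matrix (or array for `rgb`).
#' @export
get_channel <- function(image, role) {
  stopifnot(inherits(image, "image_stack"))
  if (!role %in% names(image$channels))
    stop("channel role '", role, "' not present (have: ",
         paste(names(image$channels), collapse = ", "), ")", call. = FALSE)
  image$channels[[role]]
}

#' Write an image stack as multi-page TIFF with a role sidecar
#'
#' Each channel is written as one 8-bit TIFF page.  Because baseline TIFF
#' page description tags are not reliably round-tripped by available
#' writers, channel roles, pixel size and identifiers are stored in a JSON
#' sidecar (`<path>.json`) which [read_image_stack()] resolves
#' automatically.  An `rgb` channel is written as a single RGB page.
#'
#' @param image an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(image, path) {
  stopifnot(inherits(image, "image_stack"))
  pages <- lapply(image$channels, function(ch) {
    # tiff expects [row, col(, channel)]; internal layout is [x = col, y = row]
    if (length(dim(ch)) == 3L) aperm(ch, c(2, 1, 3)) else t(ch)
  })
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 8L,
                  compression = "none")
  meta <- list(roles = as.list(names(image$channels)),
               pixel_size = image$pixel_size,
               case_id = image$case_id, image_id = image$image_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' Channel roles are resolved from the JSON sidecar written by
#' [write_image_stack()] when present, otherwise from the `roles` argument
#' (one role per page, in page order).
#'
#' @param path TIFF path.
#' @param roles optional character vector of channel roles overriding or
#'   replacing the sidecar mapping.
#' @param pixel_size required if no sidecar is present.
#' @param case_id,image_id identifier overrides.
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path, roles = NULL, pixel_size = NULL,
                             case_id = NULL, image_id = NULL) {
  if (!file.exists(path))
    stop("cannot read image: no such file '", path, "'", call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("failed to read TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  if (is.null(roles)) roles <- unlist(meta$roles)
  if (is.null(roles))
    stop("channel roles unresolvable: no sidecar for '", path,
         "' and no `roles` given", call. = FALSE)
  if (length(roles) != length(pages))
    stop("role mapping names ", length(roles), " channels but TIFF has ",
         length(pages), " pages", call. = FALSE)
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size
  if (is.null(pixel_size))
    stop("pixel_size unresolvable for '", path, "'", call. = FALSE)
  channels <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) aperm(p, c(2, 1, 3)) else t(p)
  })
  names(channels) <- roles
  image_stack(channels, pixel_size,
              case_id = case_id %||% meta$case_id %||% "",
              image_id = image_id %||% meta$image_id %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strip the EBImage Image class, returning the bare 2D numeric matrix
# (avoids S4 Ops dispatch on hot paths).
img_data <- function(x) {
  d <- EBImage::imageData(x)
  if (length(dim(d)) > 2L) dim(d) <- dim(d)[1:2]
  d
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}
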