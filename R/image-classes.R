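#' Calibrated single-channel intensity image
#'
#' A lightweight container for one fluorescence channel: a numeric matrix of
#' finite, non-negative intensities with a physical pixel size and a semantic
#' role. All package operations preserve the calibration attributes.
#'
#' @param pixels Numeric matrix of finite values >= 0.
#' @param pixel_size_um Pixel pitch in micrometers (> 0).
#' @param channel_role One of `"nuclei"`, `"membrane"`, `"organelle"`,
#'   `"content"`.
#' @return An `intensity_image`: the matrix with `pixel_size_um` and
#'   `channel_role` attributes.
#' @examples
#' img <- intensity_image(matrix(runif(100), 10), 0.1, "nuclei")
#' pixel_size(img)
#' @export
intensity_image <- function(pixels, pixel_size_um, channel_role) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!all(is.finite(pixels))) stop("pixel values must be finite")
  if (any(pixels < 0)) stop("pixel values must be >= 0")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  channel_role <- match.arg(channel_role, c("nuclei", "membrane", "organelle", "content"))
  structure(pixels,
            pixel_size_um = pixel_size_um,
            channel_role = channel_role,
            class = c("intensity_image", "matrix", "array"))
}

#' @rdname intensity_image
#' @param img An `intensity_image`.
#' @export
pixel_size <- function(img) attr(img, "pixel_size_um")

#' @rdname intensity_image
#' @export
channel_role <- function(img) attr(img, "channel_role")

# rebuild an intensity_image around new pixels, keeping calibration
reimage <- function(pixels, template, clamp = TRUE) {
  if (clamp) pixels[pixels < 0] <- 0
  intensity_image(unclass(pixels), pixel_size(template), channel_role(template))
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d px, %.4g um/px, role: %s, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), pixel_size(x), channel_role(x), min(x), max(x)))
  invisible(x)
}

#' Multi-channel calibrated image
#'
#' Bundles the semantic channels of one field of view. Roles `nuclei`,
#' `membrane` and `organelle` are required; `content` is optional and enables
#' the organelle-content quantification.
#'
#' @param channels Named list of [intensity_image()] objects; names are roles.
#' @param image_id Character scalar identifying the field (e.g. file name).
#' @return A `multichannel_image` (list with elements `channels`, `image_id`).
#' @export
multichannel_image <- function(channels, image_id = "image") {
  required <- c("nuclei", "membrane", "organelle")
  if (!all(required %in% names(channels)))
    stop("channels must include roles: ", paste(required, collapse = ", "))
  dims <- vapply(channels, dim, integer(2))
  if (!all(dims == dims[, 1])) stop("all channels must share dimensions")
  ps <- vapply(channels, pixel_size, numeric(1))
  if (max(ps) - min(ps) > 1e-12) stop("all channels must share pixel_size_um")
  structure(list(channels = channels, image_id = as.character(image_id)),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multichannel_image> '%s': %d x %d px, %.4g um/px, channels: %s\n",
              x$image_id, d[1], d[2], pixel_size(x$channels[[1]]),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.multichannel_image <- function(x) dim(x$channels[[1]])

#' Rescale an image to the full [0, 1] range
#'
#' Linearly maps the observed `[min, max]` to `[0, 1]`. A constant image maps
#' to all zeros. The operation is idempotent on its own output.
#'
#' @param img An [intensity_image()] or plain numeric matrix.
#' @return Image of the same class/calibration with `min = 0`, `max = 1`
#'   (unless constant).
#' @examples
#' m <- intensity_image(matrix(c(2, 4, 6, 2), 2), 0.1, "organelle")
#' range(rescale_full_range(m))
#' @export
rescale_full_range <- function(img) {
  lo <- min(img); hi <- max(img)
  out <- if (hi - lo <= 0) {
    array(0, dim(img))
  } else {
    (unclass(img) - lo) / (hi - lo)
  }
  out <- matrix(out, nrow(img), ncol(img))
  if (inherits(img, "intensity_image")) reimage(out, img, clamp = FALSE) else out
}

#' Label image constructor
#'
#' Integer object-label matrix; 0 is background, positive labels identify
#' objects of the stated kind.
#'
#' @param labels Integer matrix >= 0.
#' @param kind One of `"nucleus"`, `"cell"`, `"membrane"`, `"organelle"`,
#'   `"organelle_expanded"`.
#' @return A `label_image`.
#' @export
label_image <- function(labels, kind) {
  stopifnot(is.matrix(labels))
  kind <- match.arg(kind, c("nucleus", "cell", "membrane", "organelle", "organelle_expanded"))
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("labels must be >= 0")
  structure(labels, kind = kind, class = c("label_image", "matrix", "array"))
}

#' @rdname label_image
#' @param x A `label_image`.
#' @export
label_kind <- function(x) attr(x, "kind")

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image> %d x %d px, kind: %s, %d object(s)\n",
              nrow(x), ncol(x), label_kind(x), length(setdiff(unique(as.integer(x)), 0L))))
  invisible(x)
}

# plain integer matrix view
as_label_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "kind") <- NULL
  storage.mode(m) <- "integer"
  m
}
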