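#' Segmentation parameters for one object class
#'
#' @param threshold_method `"otsu"`, `"robust_background"` or `"manual"`.
#' @param threshold_correction Multiplier applied to the automatic threshold.
#' @param threshold_bounds Two values in `[0, 1]`; the corrected threshold is
#'   clipped into this interval.
#' @param threshold_value Manual threshold (required when method is
#'   `"manual"`).
#' @param diameter_range_px Objects with equivalent diameter outside
#'   `[d_min, d_max]` are removed.
#' @param declump `"none"` or `"shape"` (distance-transform watershed).
#' @param discard_border Drop objects touching the image border.
#' @return A `seg_params` list.
#' @export
seg_params <- function(threshold_method = c("otsu", "robust_background", "manual"),
                       threshold_correction = 1,
                       threshold_bounds = c(0, 1),
                       threshold_value = NULL,
                       diameter_range_px = c(2, Inf),
                       declump = c("none", "shape"),
                       discard_border = FALSE) {
  threshold_method <- match.arg(threshold_method)
  declump <- match.arg(declump)
  stopifnot(threshold_correction > 0,
            length(threshold_bounds) == 2, threshold_bounds[1] <= threshold_bounds[2],
            length(diameter_range_px) == 2, diameter_range_px[1] < diameter_range_px[2])
  structure(list(threshold_method = threshold_method,
                 threshold_correction = threshold_correction,
                 threshold_bounds = threshold_bounds,
                 threshold_value = threshold_value,
                 diameter_range_px = diameter_range_px,
                 declump = declump,
                 discard_border = discard_border),
            class = "seg_params")
}

#' Global threshold of an image in [0, 1]
#'
#' Computes an automatic threshold (Otsu over a 256-bin histogram, or a
#' robust-background estimate: mean + 2 SD after trimming the brightest and
#' dimmest 5%), multiplies it by `correction`, clips into `bounds`, and
#' returns the binary mask `img > t`.
#'
#' @param img Image with values in `[0, 1]`.
#' @param method `"otsu"`, `"robust_background"` or `"manual"`.
#' @param correction Positive multiplier on the automatic threshold.
#' @param bounds Clipping interval for the corrected threshold.
#' @param value Manual threshold when `method = "manual"`.
#' @return Logical matrix; the threshold used is attached as attribute
#'   `"threshold"`.
#' @export
threshold_global <- function(img, method = c("otsu", "robust_background", "manual"),
                             correction = 1, bounds = c(0, 1), value = NULL) {
  method <- match.arg(method)
  m <- as_plain_matrix(img)
  if (min(m) < -1e-9 || max(m) > 1 + 1e-9) stop("img must be in [0, 1]")
  t0 <- switch(method,
    otsu = EBImage::otsu(m, range = c(0, 1), levels = 256),
    robust_background = {
      v <- sort(as.vector(m))
      n <- length(v)
      keep <- v[max(1, floor(0.05 * n)):min(n, ceiling(0.95 * n))]
      mean(keep) + 2 * sd(keep)
    },
    manual = {
      if (is.null(value)) stop("manual threshold method requires a value")
      value
    })
  t <- min(max(t0 * correction, bounds[1]), bounds[2])
  mask <- m > t
  attr(mask, "threshold") <- t
  mask
}

equivalent_diameter <- function(area_px) 2 * sqrt(area_px / pi)

# renumber positive labels 1..N in raster (row-major) order of first pixel
renumber_raster <- function(lab) {
  nr <- nrow(lab)
  pos <- which(lab > 0L)
  if (!length(pos)) return(lab)
  # raster rank: rows first, then columns
  r <- (pos - 1L) %% nr
  cc <- (pos - 1L) %/% nr
  rank <- r * ncol(lab) + cc
  first <- tapply(rank, lab[pos], min)
  old <- as.integer(names(first))
  new <- integer(max(old))
  new[old[order(first)]] <- seq_along(old)
  out <- lab
  out[pos] <- new[lab[pos]]
  out
}

#' Identify primary objects (nuclei, organelles)
#'
#' Threshold, fill holes, optionally split touching objects by watershed on
#' the smoothed distance transform, label 8-connected components, remove
#' objects whose equivalent diameter falls outside `diameter_range_px`, and
#' optionally remove border-touching objects. Labels are renumbered 1..N in
#' raster order of each object's first pixel, so the result is deterministic.
#'
#' @param img Image in `[0, 1]` (already smoothed / enhanced as appropriate).
#' @param params A [seg_params()] object.
#' @param kind Label kind for the result (`"nucleus"` or `"organelle"`).
#' @return A [label_image()]. Zero objects is a valid outcome.
#' @export
identify_primary <- function(img, params = seg_params(), kind = "nucleus") {
  mask <- threshold_global(img, params$threshold_method, params$threshold_correction,
                           params$threshold_bounds, params$threshold_value)
  mask <- EBImage::fillHull(mask * 1L)
  storage.mode(mask) <- "integer"
  if (params$declump == "shape" && any(mask > 0L)) {
    d_min <- params$diameter_range_px[1]
    dt <- EBImage::distmap(mask)
    dts <- smooth_image(dt, 1)
    ws <- EBImage::watershed(dts * (mask > 0L), tolerance = 1,
                             ext = max(1L, floor(if (is.finite(d_min)) d_min / 2 else 1)))
    lab <- matrix(as.integer(ws), nrow(ws), ncol(ws))
  } else {
    lab <- label_components(mask, 8L)
  }
  lab <- filter_labels(lab, params)
  label_image(renumber_raster(lab), kind)
}

filter_labels <- function(lab, params) {
  if (!any(lab > 0L)) return(lab)
  counts <- tabulate(lab[lab > 0L])
  eqd <- equivalent_diameter(counts)
  drop <- which(eqd < params$diameter_range_px[1] | eqd > params$diameter_range_px[2])
  if (isTRUE(params$discard_border)) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, border[border > 0L])
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab
}

#' Identify cells by seeded propagation from nuclear seeds
#'
#' Grows each seed outward over the foreground: every foreground pixel takes
#' the label of the seed with minimal accumulated path cost, where a step
#' between 8-neighbors costs `sqrt(dI^2 + lambda^2 * s^2)` (`dI` = absolute
#' membrane-guide intensity difference, `s` = Euclidean step length). Small
#' `lambda` makes boundaries follow membrane ridges; large `lambda`
#' approaches a Voronoi partition of the seeds. Equidistant ties resolve to
#' the lower seed label.
#'
#' @param seeds Nucleus [label_image()] (non-empty).
#' @param guide Smoothed membrane-channel image.
#' @param lambda Regularization (>= 0); default 0.05.
#' @param foreground `"all"` (confluent monolayer: the whole field is cell)
#'   or a logical matrix restricting the cells' support.
#' @return Cell [label_image()]; cell labels equal their seed labels.
#' @export
identify_secondary_propagation <- function(seeds, guide, lambda = 0.05,
                                           foreground = "all") {
  s <- as_label_matrix(seeds)
  if (!any(s > 0L)) stop("no seeds: at least one nucleus is required")
  if (!is.numeric(lambda) || lambda < 0) stop("lambda must be >= 0")
  g <- as_plain_matrix(guide)
  if (!identical(dim(g), dim(s))) stop("seeds and guide dimensions differ")
  fg <- if (identical(foreground, "all")) {
    matrix(TRUE, nrow(g), ncol(g))
  } else {
    if (!identical(dim(foreground), dim(g))) stop("foreground dimensions differ")
    foreground | (s > 0L)  # seeds always belong to their cells
  }
  lab <- propagate_dijkstra(g, s, fg, lambda)
  label_image(lab, "cell")
}

#' Identify the tertiary membrane object
#'
#' For each cell, the membrane band is the set of cell pixels within
#' `width_px` of that cell's boundary: the cell minus its erosion by a disk
#' of radius `width_px`. Membrane labels equal their cell labels.
#'
#' @param cells Cell [label_image()].
#' @param width_px Band width in pixels (>= 1).
#' @return Membrane [label_image()].
#' @export
identify_tertiary_membrane <- function(cells, width_px = 3L) {
  if (width_px < 1) stop("width_px must be >= 1")
  l <- as_label_matrix(cells)
  offs <- disk_offsets(width_px)
  # erosion of each cell: pixel stays interior if the whole disk lies in the
  # same cell; pixels near the image border are boundary by convention
  nr <- nrow(l); nc <- ncol(l)
  interior <- matrix(TRUE, nr, nc)
  for (t in seq_len(nrow(offs))) {
    dr <- offs$dr[t]; dc <- offs$dc[t]
    if (dr == 0 && dc == 0) next
    shifted <- matrix(-1L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    shifted[rs - dr, cs - dc] <- l[rs, cs]
    interior <- interior & (shifted == l)
  }
  mem <- l
  mem[interior] <- 0L
  mem[l == 0L] <- 0L
  label_image(mem, "membrane")
}

#' Expand labels into the background
#'
#' Each background pixel within Euclidean distance `n_px` of an object takes
#' the label of the nearest object (ties go to the lower label). Existing
#' labels are never overwritten and expansion never merges objects.
#'
#' @param labels A [label_image()].
#' @param n_px Expansion distance in pixels (>= 0); `0` is the identity.
#' @return A [label_image()] of kind `organelle_expanded` (or the input kind
#'   if not an organelle image).
#' @export
expand_labels <- function(labels, n_px = 2) {
  if (n_px < 0) stop("n_px must be >= 0")
  l <- as_label_matrix(labels)
  out <- expand_labels_cpp(l, as.numeric(n_px))
  kind <- if (label_kind(labels) %in% c("organelle", "organelle_expanded"))
    "organelle_expanded" else label_kind(labels)
  label_image(out, kind)
}
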