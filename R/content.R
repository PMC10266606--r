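#' Split each cell into inside- and outside-organelle masks
#'
#' `inside(cell)` = expanded-organelle pixels intersected with the cell;
#' `outside(cell)` = the rest of the cell (optionally minus the nucleus).
#' The two masks are disjoint and, with nucleus exclusion off, partition the
#' cell's pixel set. Expansion crossing a cell border is clipped to the
#' owning cell by the intersection.
#'
#' @param organelles_expanded [label_image()] from [expand_labels()]
#'   (default 2 px expansion captures membrane-bound markers hugging the
#'   organelle surface).
#' @param cells Cell [label_image()].
#' @param nuclei Optional nucleus [label_image()] for `exclude_nucleus`.
#' @param exclude_nucleus Remove nucleus pixels from the outside mask
#'   (`FALSE` by default: the cytoplasmic reference is the whole cell minus
#'   expanded organelles).
#' @return Tibble with `cell_label` and list-columns `inside_idx`,
#'   `outside_idx` of linear pixel indices.
#' @export
split_in_out <- function(organelles_expanded, cells, nuclei = NULL,
                         exclude_nucleus = FALSE) {
  oe <- as_label_matrix(organelles_expanded)
  cl <- as_label_matrix(cells)
  if (!identical(dim(oe), dim(cl))) stop("label image dimensions differ")
  excl <- if (exclude_nucleus) {
    if (is.null(nuclei)) stop("exclude_nucleus = TRUE requires nuclei")
    as_label_matrix(nuclei) > 0L
  } else matrix(FALSE, nrow(cl), ncol(cl))
  ids <- sort(setdiff(unique(as.integer(cl)), 0L))
  res <- lapply(ids, function(cell) {
    cidx <- which(cl == cell)
    inorg <- oe[cidx] > 0L
    tibble(cell_label = cell,
           inside_idx = list(cidx[inorg]),
           outside_idx = list(cidx[!inorg & !excl[cidx]]))
  })
  dplyr::bind_rows(res)
}

#' Per-cell content-channel means inside vs outside organelles
#'
#' Mean secondary-marker intensity over the inside and outside masks, and
#' the cytoplasm-corrected value `corrected = mean_in - mean_out` (may be
#' negative; never clipped). Intensities are in the channel's normalized
#' units (A.U.). Empty masks yield missing means.
#'
#' @param content_img Content-channel [intensity_image()] (dtype-normalized,
#'   not full-range rescaled: rescaling is for QC display only).
#' @param masks Tibble from [split_in_out()].
#' @return Tibble with `cell_label`, `mean_in`, `mean_out`, `corrected`,
#'   `in_pixel_count`, `out_pixel_count`.
#' @export
content_means <- function(content_img, masks) {
  m <- as_plain_matrix(content_img)
  mean_of <- function(idx) if (length(idx)) mean(m[idx]) else NA_real_
  masks |>
    dplyr::mutate(
      mean_in = vapply(.data$inside_idx, mean_of, numeric(1)),
      mean_out = vapply(.data$outside_idx, mean_of, numeric(1)),
      corrected = .data$mean_in - .data$mean_out,
      in_pixel_count = lengths(.data$inside_idx),
      out_pixel_count = lengths(.data$outside_idx)) |>
    dplyr::select("cell_label", "mean_in", "mean_out", "corrected",
                  "in_pixel_count", "out_pixel_count")
}

#' Local-ring variant of the outside mask
#'
#' Replaces the whole-cell outside reference by a ring of width
#' `ring_width_px` directly surrounding each cell's expanded organelles,
#' which tracks local background gradients better than the whole-cell mean.
#'
#' @inheritParams split_in_out
#' @param ring_width_px Ring width in pixels.
#' @return Same shape as [split_in_out()].
#' @export
split_in_ring <- function(organelles_expanded, cells, ring_width_px = 5) {
  oe <- as_label_matrix(organelles_expanded)
  cl <- as_label_matrix(cells)
  ring_all <- expand_labels_cpp(oe, as.numeric(ring_width_px))
  ids <- sort(setdiff(unique(as.integer(cl)), 0L))
  res <- lapply(ids, function(cell) {
    cidx <- which(cl == cell)
    inorg <- oe[cidx] > 0L
    inring <- ring_all[cidx] > 0L & !inorg
    tibble(cell_label = cell,
           inside_idx = list(cidx[inorg]),
           outside_idx = list(cidx[inring]))
  })
  dplyr::bind_rows(res)
}
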