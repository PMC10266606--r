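#' Read a multi-channel TIFF and map channels to semantic roles
#'
#' Reads a single- or multi-page TIFF, splits its planes into channels, and
#' attaches the physical pixel size. Integer images are normalized by their
#' bit-depth maximum on load (so thresholds are dtype-independent); float
#' TIFFs are taken as-is. If the file holds a z-stack, planes are grouped per
#' channel (all z of channel 1, then channel 2, ...) and collapsed by
#' per-pixel maximum projection.
#'
#' @param path Path to a TIFF file.
#' @param channel_map Named integer vector mapping role -> plane index
#'   (1-based), e.g. `c(nuclei = 1, membrane = 2, organelle = 3)`. Roles
#'   `nuclei`, `membrane`, `organelle` are required; `content` optional.
#' @param pixel_size_um Pixel pitch in micrometers, or `"from-metadata"` to
#'   use the TIFF resolution tags. There is no silent default: missing
#'   calibration is an error, because all reported lengths/areas are in
#'   physical units.
#' @param n_z Number of z-planes per channel (default 1, i.e. 2D).
#' @param projection Projection for z-stacks; only `"max"` is supported.
#' @param image_id Identifier for the field; defaults to the file name.
#' @return A [multichannel_image()].
#' @export
read_image <- function(path, channel_map, pixel_size_um = "from-metadata",
                       n_z = 1L, projection = "max", image_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  projection <- match.arg(projection, "max")
  if (is.null(names(channel_map)) || any(!nzchar(names(channel_map))))
    stop("channel_map must be a named vector (role = plane index)")
  bad <- setdiff(names(channel_map), c("nuclei", "membrane", "organelle", "content"))
  if (length(bad)) stop("unknown channel roles: ", paste(bad, collapse = ", "))

  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  planes <- list()
  for (p in pages) {
    if (length(dim(p)) == 3) {
      for (k in seq_len(dim(p)[3])) planes[[length(planes) + 1L]] <- p[, , k]
    } else {
      planes[[length(planes) + 1L]] <- p
    }
  }
  # attributes (resolution tags) live on the first page
  info <- attributes(pages[[1]])

  ps <- resolve_pixel_size(pixel_size_um, info, path)

  n_z <- as.integer(n_z)
  if (n_z < 1) stop("n_z must be >= 1")
  n_ch <- length(planes) / n_z
  if (n_ch != floor(n_ch))
    stop("plane count (", length(planes), ") is not a multiple of n_z (", n_z, ")")
  if (any(channel_map > n_ch) || any(channel_map < 1))
    stop("channel index out of range: file provides ", n_ch, " channel(s)")

  channels <- lapply(seq_along(channel_map), function(i) {
    ci <- channel_map[[i]]
    zplanes <- planes[((ci - 1L) * n_z + 1L):(ci * n_z)]
    plane <- Reduce(pmax, zplanes)
    plane[plane < 0] <- 0
    intensity_image(plane, ps, names(channel_map)[i])
  })
  names(channels) <- names(channel_map)
  multichannel_image(channels, image_id %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_pixel_size <- function(pixel_size_um, info, path) {
  if (is.numeric(pixel_size_um)) {
    if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
    return(pixel_size_um)
  }
  if (!identical(pixel_size_um, "from-metadata"))
    stop("pixel_size_um must be a number or \"from-metadata\"")
  xres <- info$x.resolution
  if (is.null(xres) || !is.finite(xres) || xres <= 0)
    stop("no resolution metadata in ", path,
         "; pass pixel_size_um explicitly (no silent default)")
  unit <- info$resolution.unit %||% "inch"
  unit_um <- switch(unit, inch = 25400, cm = 10000,
                    stop("unsupported resolution unit: ", unit))
  unit_um / xres
}

#' Write the per-image / per-cell / per-organelle result tables
#'
#' Writes three CSV files with stable column order and full float precision;
#' missing values are written as empty fields. Re-running on identical inputs
#' produces byte-identical files.
#'
#' @param per_image,per_cell,per_organelle Tibbles as produced by
#'   [summarize_objects()] / [run_op()].
#' @param out_dir Output directory (created if needed).
#' @return (Invisibly) the paths written.
#' @export
write_tables <- function(per_image, per_cell, per_organelle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("per_image.csv", "per_cell.csv", "per_organelle.csv"))
  readr::write_csv(per_image, paths[1], na = "")
  readr::write_csv(per_cell, paths[2], na = "")
  readr::write_csv(per_organelle, paths[3], na = "")
  invisible(paths)
}

# boundary pixels of a label image: labeled pixels with a 4-neighbor of a
# different value (or on the image edge)
label_boundaries <- function(labels) {
  l <- as_label_matrix(labels)
  nr <- nrow(l); nc <- ncol(l)
  pad <- matrix(-1L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- l
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  diff <- (pad[1:nr, 2:(nc + 1L)] != ctr) | (pad[3:(nr + 2L), 2:(nc + 1L)] != ctr) |
          (pad[2:(nr + 1L), 1:nc] != ctr) | (pad[2:(nr + 1L), 3:(nc + 2L)] != ctr)
  (ctr > 0L) & diff
}

# 3x5 bitmaps for digits 0-9, used to stamp cell numbers on QC overlays
digit_glyphs <- local({
  rows <- list(
    "0" = c("111", "101", "101", "101", "111"),
    "1" = c("010", "110", "010", "010", "111"),
    "2" = c("111", "001", "111", "100", "111"),
    "3" = c("111", "001", "111", "001", "111"),
    "4" = c("101", "101", "111", "001", "001"),
    "5" = c("111", "100", "111", "001", "111"),
    "6" = c("111", "100", "111", "101", "111"),
    "7" = c("111", "001", "010", "010", "010"),
    "8" = c("111", "101", "111", "101", "111"),
    "9" = c("111", "101", "111", "001", "111"))
  lapply(rows, function(r) do.call(rbind, lapply(strsplit(r, ""), as.integer)))
})

stamp_number <- function(rgb, number, at_rc, color = c(1, 1, 1), scale = 2L) {
  digits <- strsplit(as.character(number), "")[[1]]
  gw <- 3L * scale + scale  # glyph + 1 unit spacing
  total_w <- length(digits) * gw - scale
  r0 <- round(at_rc[1]) - (5L * scale) %/% 2L
  c0 <- round(at_rc[2]) - total_w %/% 2L
  nr <- dim(rgb)[1]; nc <- dim(rgb)[2]
  for (d in seq_along(digits)) {
    g <- digit_glyphs[[digits[d]]]
    g <- g[rep(seq_len(5), each = scale), rep(seq_len(3), each = scale), drop = FALSE]
    for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
      if (g[i, j] == 1L) {
        ri <- r0 + i - 1L; ci <- c0 + (d - 1L) * gw + j - 1L
        if (ri >= 1 && ri <= nr && ci >= 1 && ci <= nc) rgb[ri, ci, ] <- color
      }
    }
  }
  rgb
}

#' Write a quality-control overlay image
#'
#' Draws object outlines over the (rescaled) organelle channel: nuclei in
#' blue, cells in red, organelles in green, and stamps each cell with its
#' label number at the cell centroid so outliers can be traced back. The
#' overlay is a pure sink: it never feeds back into measurements.
#'
#' @param img Background [intensity_image()] (typically the organelle
#'   channel).
#' @param nuclei,cells,organelles [label_image()]s sharing `img`'s
#'   dimensions; `organelles` may be `NULL`.
#' @param out_path PNG path to write.
#' @return (Invisibly) `out_path`.
#' @export
write_overlay <- function(img, nuclei, cells, organelles, out_path) {
  for (l in list(nuclei, cells, organelles)) {
    if (!is.null(l) && !identical(dim(l)[1:2], dim(img)[1:2]))
      stop("label image dimensions must match the background image")
  }
  base <- rescale_full_range(unclass(img))
  rgb <- array(rep(base, 3L), c(dim(base), 3L))
  paint <- function(rgb, labels, color) {
    if (is.null(labels)) return(rgb)
    b <- label_boundaries(labels)
    for (k in 1:3) {
      ch <- rgb[, , k]
      ch[b] <- color[k]
      rgb[, , k] <- ch
    }
    rgb
  }
  rgb <- paint(rgb, cells, c(1, 0, 0))
  rgb <- paint(rgb, nuclei, c(0, 0, 1))
  rgb <- paint(rgb, organelles, c(0, 1, 0))
  cl <- as_label_matrix(cells)
  for (lbl in sort(setdiff(unique(as.integer(cl)), 0L))) {
    idx <- which(cl == lbl, arr.ind = TRUE)
    rgb <- stamp_number(rgb, lbl, colMeans(idx), color = c(1, 1, 1))
  }
  dir.create(dirname(out_path), showWarnings = FALSE, recursive = TRUE)
  png::writePNG(rgb, out_path)
  invisible(out_path)
}
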