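#' Per-object size and shape measurements
#'
#' For every label: area (pixel count scaled by the pixel size squared),
#' intensity-unweighted centroid, eccentricity of the ellipse with identical
#' second central moments, equivalent diameter, and the maximum Feret
#' diameter computed as the largest pairwise distance between convex-hull
#' vertices of the object's pixel centers.
#'
#' Conventions: pixel centers sit at integer (row, col) coordinates, so a
#' 1 x N segment has Feret diameter `(N - 1)` px. Second moments treat each
#' pixel as a unit square (adds 1/12 per axis), so eccentricity is always
#' `< 1`, even for single-pixel-wide segments.
#'
#' @param labels A [label_image()].
#' @param pixel_size_um Pixel pitch in micrometers.
#' @return Tibble with columns `label`, `area_px`, `area_um2`, `centroid_r`,
#'   `centroid_c`, `eccentricity`, `max_feret_um`, `equivalent_diameter_px`.
#' @export
measure_shape <- function(labels, pixel_size_um) {
  l <- as_label_matrix(labels)
  ids <- sort(setdiff(unique(as.integer(l)), 0L))
  if (!length(ids)) {
    return(tibble(label = integer(), area_px = integer(), area_um2 = numeric(),
                  centroid_r = numeric(), centroid_c = numeric(),
                  eccentricity = numeric(), max_feret_um = numeric(),
                  equivalent_diameter_px = numeric()))
  }
  idx <- which(l > 0L)
  nr <- nrow(l)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  labs <- l[idx]
  res <- lapply(ids, function(id) {
    sel <- labs == id
    r <- rows[sel]; cc <- cols[sel]
    n <- length(r)
    mr <- mean(r); mc <- mean(cc)
    # central second moments, pixel-as-unit-square model
    mu_rr <- sum((r - mr)^2) / n + 1 / 12
    mu_cc <- sum((cc - mc)^2) / n + 1 / 12
    mu_rc <- sum((r - mr) * (cc - mc)) / n
    tr <- mu_rr + mu_cc
    det <- mu_rr * mu_cc - mu_rc^2
    disc <- sqrt(max(0, tr^2 / 4 - det))
    l1 <- tr / 2 + disc  # major-axis variance
    l2 <- tr / 2 - disc
    ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
    tibble(label = id, area_px = n,
           area_um2 = n * pixel_size_um^2,
           centroid_r = mr, centroid_c = mc,
           eccentricity = ecc,
           max_feret_um = max_feret_px(r, cc) * pixel_size_um,
           equivalent_diameter_px = equivalent_diameter(n))
  })
  dplyr::bind_rows(res)
}

# max pairwise distance between pixel centers, via convex hull vertices
max_feret_px <- function(r, cc) {
  n <- length(r)
  if (n == 1) return(0)
  pts <- cbind(cc, r)  # chull expects (x, y)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  m <- nrow(hp)
  if (m == 1) return(0)
  d2 <- outer(hp[, 1], hp[, 1], "-")^2 + outer(hp[, 2], hp[, 2], "-")^2
  sqrt(max(d2))
}

#' Per-object intensity measurements
#'
#' Mean and integrated intensity of a channel over each label's pixels, in
#' the channel's normalized units (arbitrary units, A.U.).
#'
#' @param labels A [label_image()].
#' @param img An [intensity_image()] (or matrix) with matching dimensions.
#' @return Tibble with `label`, `mean_intensity`, `integrated_intensity`,
#'   `pixel_count`.
#' @export
measure_intensity <- function(labels, img) {
  l <- as_label_matrix(labels)
  m <- as_plain_matrix(img)
  if (!identical(dim(l), dim(m))) stop("labels and image dimensions differ")
  ids <- sort(setdiff(unique(as.integer(l)), 0L))
  if (!length(ids)) {
    return(tibble(label = integer(), mean_intensity = numeric(),
                  integrated_intensity = numeric(), pixel_count = integer()))
  }
  idx <- which(l > 0L)
  sums <- tapply(m[idx], l[idx], sum)
  cnts <- tapply(m[idx], l[idx], length)
  tibble(label = as.integer(names(sums)),
         mean_intensity = as.numeric(sums / cnts),
         integrated_intensity = as.numeric(sums),
         pixel_count = as.integer(cnts)) |>
    dplyr::arrange(.data$label)
}

#' Relative distance between nucleus and cell edge
#'
#' `100 * d_nuc / (d_nuc + d_mem)`: 0% at the nucleus edge, 100% at the cell
#' edge. When both distances are zero the position is undefined and `NA` is
#' returned (excluded from aggregation).
#'
#' @param d_nuc_um,d_mem_um Non-negative distances (vectorized).
#' @return Percentages in `[0, 100]` (or `NA`).
#' @examples
#' relative_distance(c(0, 5, 3), c(5, 5, 1))  # 0, 50, 75
#' @export
relative_distance <- function(d_nuc_um, d_mem_um) {
  if (any(d_nuc_um < 0, na.rm = TRUE) || any(d_mem_um < 0, na.rm = TRUE))
    stop("distances must be >= 0")
  out <- 100 * d_nuc_um / (d_nuc_um + d_mem_um)
  out[!is.na(d_nuc_um) & !is.na(d_mem_um) & d_nuc_um == 0 & d_mem_um == 0] <- NA_real_
  out
}

#' Organelle distances to nucleus and cell edge
#'
#' For each organelle assigned to a cell containing exactly one nucleus,
#' measures the Euclidean distance from the organelle centroid to the nearest
#' pixel of that cell's nucleus (0 if the centroid lies inside the nucleus)
#' and to the nearest pixel of the cell's outer boundary, both in
#' micrometers, plus the relative distance. Distances are computed per cell
#' in isolation, so neighboring cells' nuclei never interfere. Organelles in
#' cells with 0 or >= 2 nuclei are flagged and get missing distances.
#'
#' @param organelle_shape Tibble from [measure_shape()] on the organelles.
#' @param relations Tibble from [assign_parents()].
#' @param nuclei,cells [label_image()]s.
#' @param pixel_size_um Pixel pitch in micrometers.
#' @return `relations` with `d_nuc_um`, `d_mem_um`, `rel_dist_pct` and
#'   logical `flag_multi_nucleus` filled in.
#' @export
edge_distances <- function(organelle_shape, relations, nuclei, cells, pixel_size_um) {
  nl <- as_label_matrix(nuclei)
  cl <- as_label_matrix(cells)
  nr <- nrow(cl)
  # map each nucleus to its cell (cell label under the nucleus' pixels)
  nuc_idx <- which(nl > 0L)
  nuc_cell <- tapply(cl[nuc_idx], nl[nuc_idx], function(v) {
    v <- v[v > 0L]
    if (!length(v)) return(0L)
    as.integer(names(which.max(table(v))))
  })
  cells_present <- sort(setdiff(unique(as.integer(cl)), 0L))
  n_nuc_per_cell <- table(factor(nuc_cell, levels = cells_present))

  boundary <- label_boundaries(cells)

  per_cell_sets <- new.env(parent = emptyenv())
  get_sets <- function(cell) {
    key <- as.character(cell)
    if (!is.null(per_cell_sets[[key]])) return(per_cell_sets[[key]])
    cidx <- which(cl == cell)
    crow <- ((cidx - 1L) %% nr) + 1L
    ccol <- ((cidx - 1L) %/% nr) + 1L
    bsel <- boundary[cidx]
    nuc_of_cell <- as.integer(names(nuc_cell)[nuc_cell == cell])
    nsel <- nl[cidx] %in% nuc_of_cell & nl[cidx] > 0L
    out <- list(brow = crow[bsel], bcol = ccol[bsel],
                nrow_ = crow[nsel], ncol_ = ccol[nsel])
    per_cell_sets[[key]] <- out
    out
  }

  res <- relations
  res$d_nuc_um <- NA_real_
  res$d_mem_um <- NA_real_
  res$flag_multi_nucleus <- FALSE
  shape <- organelle_shape[match(res$organelle_label, organelle_shape$label), ]
  for (i in seq_len(nrow(res))) {
    cell <- res$cell_label[i]
    if (cell == 0L) next
    n_nuc <- n_nuc_per_cell[as.character(cell)]
    if (is.na(n_nuc) || n_nuc != 1L) {
      res$flag_multi_nucleus[i] <- TRUE
      next
    }
    s <- get_sets(cell)
    if (!length(s$nrow_) || !length(s$brow)) {
      res$flag_multi_nucleus[i] <- TRUE
      next
    }
    cr <- shape$centroid_r[i]; cc <- shape$centroid_c[i]
    # inside the nucleus? nearest-pixel-center test at the rounded centroid
    rr <- min(max(round(cr), 1L), nr)
    rc <- min(max(round(cc), 1L), ncol(cl))
    inside <- nl[rr, rc] > 0L && cl[rr, rc] == cell
    d_nuc <- if (inside) 0 else sqrt(min((s$nrow_ - cr)^2 + (s$ncol_ - cc)^2))
    d_mem <- sqrt(min((s$brow - cr)^2 + (s$bcol - cc)^2))
    res$d_nuc_um[i] <- d_nuc * pixel_size_um
    res$d_mem_um[i] <- d_mem * pixel_size_um
  }
  res$rel_dist_pct <- relative_distance(res$d_nuc_um, res$d_mem_um)
  res
}
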