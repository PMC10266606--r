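#' Assign organelles to parent cells
#'
#' The parent is the cell label under the organelle's centroid pixel; if that
#' pixel is background, the cell with maximal pixel overlap (ties to the
#' lower label); if the organelle overlaps no cell, parent 0 (excluded from
#' per-cell statistics but counted in the QC log, never silently dropped).
#'
#' @param organelles,cells [label_image()]s with identical dimensions.
#' @return Tibble with `organelle_label`, `cell_label` (0 = unassigned).
#' @export
assign_parents <- function(organelles, cells) {
  ol <- as_label_matrix(organelles)
  cl <- as_label_matrix(cells)
  if (!identical(dim(ol), dim(cl))) stop("label image dimensions differ")
  ids <- sort(setdiff(unique(as.integer(ol)), 0L))
  if (!length(ids)) return(tibble(organelle_label = integer(), cell_label = integer()))
  nr <- nrow(ol)
  idx <- which(ol > 0L)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  labs <- ol[idx]
  parent <- vapply(ids, function(id) {
    sel <- labs == id
    r <- rows[sel]; cc <- cols[sel]
    pr <- min(max(round(mean(r)), 1L), nr)
    pc <- min(max(round(mean(cc)), 1L), ncol(ol))
    p <- cl[pr, pc]
    if (p > 0L) return(as.integer(p))
    ov <- cl[cbind(r, cc)]
    ov <- ov[ov > 0L]
    if (!length(ov)) return(0L)
    tab <- table(ov)
    cand <- as.integer(names(tab)[tab == max(tab)])
    min(cand)  # ties -> lower label
  }, integer(1))
  tibble(organelle_label = ids, cell_label = parent)
}

#' Summarize organelle measurements per cell and per image
#'
#' Produces the two reporting levels used for group comparisons: per-cell
#' means over assigned organelles (the default statistical unit) and a
#' per-image row; the pooled per-organelle table doubles as the
#' single-organelle view. Missing values are excluded from means; cells with
#' zero organelles keep missing means.
#'
#' @param relations Tibble from [assign_parents()] + [edge_distances()]
#'   (columns `organelle_label`, `cell_label`, optionally `d_nuc_um`,
#'   `d_mem_um`, `rel_dist_pct`).
#' @param organelle_shape Tibble from [measure_shape()] on organelles.
#' @param cell_shape Tibble from [measure_shape()] on cells.
#' @param image_id Identifier copied into every row.
#' @return List of tibbles: `per_organelle`, `per_cell`, `per_image`, and a
#'   `qc` list (unassigned organelle count, multi-nucleus flags).
#' @export
summarize_objects <- function(relations, organelle_shape, cell_shape,
                              image_id = "image") {
  per_org <- relations |>
    dplyr::left_join(organelle_shape |>
                       dplyr::select("label", "area_um2", "eccentricity",
                                     "max_feret_um"),
                     by = c(organelle_label = "label")) |>
    dplyr::mutate(image_id = image_id, .before = 1)

  assigned <- per_org |> dplyr::filter(.data$cell_label > 0L)
  cell_stats <- assigned |>
    dplyr::group_by(.data$cell_label) |>
    dplyr::summarise(
      organelle_count = dplyr::n(),
      mean_length_um = mean_or_na(.data$max_feret_um),
      mean_eccentricity = mean_or_na(.data$eccentricity),
      mean_rel_dist_pct = if ("rel_dist_pct" %in% names(assigned))
        mean_or_na(.data$rel_dist_pct) else NA_real_,
      .groups = "drop")

  per_cell <- cell_shape |>
    dplyr::transmute(cell_label = .data$label,
                     cell_area_um2 = .data$area_um2) |>
    dplyr::left_join(cell_stats, by = "cell_label") |>
    dplyr::mutate(organelle_count = dplyr::coalesce(.data$organelle_count, 0L),
                  image_id = image_id, .before = 1)

  n_unassigned <- sum(per_org$cell_label == 0L)
  per_image <- tibble(
    image_id = image_id,
    cell_count = nrow(cell_shape),
    organelle_count_total = nrow(per_org),
    organelle_count_assigned = nrow(assigned),
    organelle_count_unassigned = n_unassigned,
    mean_cell_area_um2 = mean_or_na(per_cell$cell_area_um2),
    mean_organelles_per_cell = mean_or_na(per_cell$organelle_count))

  qc <- list(image_id = image_id,
             unassigned_organelles = n_unassigned,
             multi_nucleus_flags = if ("flag_multi_nucleus" %in% names(relations))
               sum(relations$flag_multi_nucleus) else 0L)

  list(per_organelle = per_org, per_cell = per_cell, per_image = per_image, qc = qc)
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) NA_real_ else mean(x)
}
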