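#' Pipeline configuration
#'
#' Builds the fully-resolved configuration for a batch run. One config
#' applies to every image of a batch (acquisition and analysis parameters
#' must be constant across compared images), and a run can write the
#' resolved config back to YAML for exact reruns.
#'
#' @param ... Named overrides of the defaults, nested lists merged deeply,
#'   e.g. `op_config(organelles = list(diameter_range_px = c(2, 30)))`.
#' @return A nested `op_config` list with all defaults materialized.
#' @export
op_config <- function(...) {
  defaults <- list(
    channels = list(nuclei = 1L, membrane = 2L, organelle = 3L),
    pixel_size_um = "from-metadata",
    enhancement = list(
      smooth_sigma_px = list(nuclei = 2, membrane = 2),
      speckle_radius_px = 5,
      neurite_length_px = 11,
      neurite_angle_step_deg = 15),
    nuclei = list(threshold_method = "otsu", threshold_correction = 1,
                  threshold_bounds = c(0, 1), diameter_range_px = c(10, 80),
                  declump = "shape", discard_border = FALSE),
    cells = list(lambda = 0.05, foreground = "all"),
    membrane = list(width_px = 3L),
    organelles = list(threshold_method = "otsu", threshold_correction = 1.2,
                      threshold_bounds = c(0, 1), diameter_range_px = c(3, 40),
                      declump = "none", discard_border = FALSE),
    content = list(expand_px = 2, mode = "mask_mean", ring_width_px = 5,
                   exclude_nucleus = FALSE),
    output = list(overlay = TRUE))
  structure(deep_merge(defaults, list(...)), class = "op_config")
}

deep_merge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Write / read a resolved configuration as YAML
#'
#' @param config An [op_config()].
#' @param path YAML file path.
#' @return `write_config` the path (invisibly); `read_config` an
#'   `op_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(op_config, yaml::read_yaml(path))
}

seg_params_from <- function(block) {
  seg_params(threshold_method = block$threshold_method,
             threshold_correction = block$threshold_correction,
             threshold_bounds = block$threshold_bounds,
             threshold_value = block$threshold_value,
             diameter_range_px = block$diameter_range_px,
             declump = block$declump,
             discard_border = block$discard_border)
}

resolve_input <- function(x, config) {
  if (inherits(x, "synthetic_field")) return(x$image)
  if (inherits(x, "multichannel_image")) return(x)
  if (is.character(x) && length(x) == 1) {
    cm <- unlist(config$channels)
    return(read_image(x, cm, pixel_size_um = config$pixel_size_um))
  }
  stop("unsupported input: pass file paths, multichannel_image or synthetic_field objects")
}

#' Segment and measure one multi-channel image
#'
#' The core single-image pass: smooth and threshold the nuclei channel
#' (primary objects), propagate cells from the nuclear seeds over the
#' smoothed membrane channel (secondary), derive the membrane band
#' (tertiary), rescale and enhance the organelle channel (speckle + neurite
#' top-hats) and identify organelles, then measure shape, intensity,
#' parent-cell assignment and nucleus/edge distances, and summarize per cell
#' and per image.
#'
#' @param img A [multichannel_image()] (or `synthetic_field`, or file path).
#' @param config An [op_config()].
#' @param content Also run the organelle-content quantification (requires a
#'   `content` channel).
#' @return List: tables `per_image`, `per_cell`, `per_organelle`, `qc`, and
#'   `labels` (list of nuclei / cells / membrane / organelles
#'   [label_image()]s) plus the input `image`.
#' @export
profile_image <- function(img, config = op_config(), content = FALSE) {
  img <- resolve_input(img, config)
  ps <- pixel_size(img$channels[[1]])

  nuc_s <- smooth_image(img$channels$nuclei,
                        config$enhancement$smooth_sigma_px$nuclei)
  nuclei <- identify_primary(rescale_full_range(nuc_s),
                             seg_params_from(config$nuclei), kind = "nucleus")

  guide <- smooth_image(img$channels$membrane,
                        config$enhancement$smooth_sigma_px$membrane)
  if (any(as_label_matrix(nuclei) > 0L)) {
    fg <- config$cells$foreground
    if (identical(fg, "auto"))
      fg <- threshold_global(rescale_full_range(guide), "otsu") |
        (as_label_matrix(nuclei) > 0L)
    cells <- identify_secondary_propagation(nuclei, guide,
                                            lambda = config$cells$lambda,
                                            foreground = fg)
    membrane <- identify_tertiary_membrane(cells, config$membrane$width_px)
  } else {
    # empty field: no seeds, hence no cells; still a valid (empty) result
    cells <- label_image(matrix(0L, nrow(guide), ncol(guide)), "cell")
    membrane <- label_image(matrix(0L, nrow(guide), ncol(guide)), "membrane")
  }

  org_res <- rescale_full_range(img$channels$organelle)
  step <- config$enhancement$neurite_angle_step_deg
  enhanced <- enhance_organelles(org_res,
                                 radius_px = config$enhancement$speckle_radius_px,
                                 length_px = config$enhancement$neurite_length_px,
                                 angles_deg = seq(0, 180 - step, by = step))
  organelles <- identify_primary(rescale_full_range(enhanced),
                                 seg_params_from(config$organelles),
                                 kind = "organelle")

  org_shape <- measure_shape(organelles, ps)
  org_int <- measure_intensity(organelles, img$channels$organelle)
  org_shape <- dplyr::left_join(
    org_shape,
    dplyr::select(org_int, "label", mean_intensity_organelle = "mean_intensity"),
    by = "label")
  cell_shape <- measure_shape(cells, ps)
  nuc_shape <- measure_shape(nuclei, ps)

  rel <- assign_parents(organelles, cells)
  rel <- edge_distances(org_shape, rel, nuclei, cells, ps)
  out <- summarize_objects(rel, org_shape, cell_shape, image_id = img$image_id)
  out$per_image$nucleus_count <- nrow(nuc_shape)

  if (content) {
    if (is.null(img$channels$content))
      stop("content quantification requested but no 'content' channel is mapped")
    expanded <- expand_labels(organelles, config$content$expand_px)
    masks <- switch(config$content$mode,
      mask_mean = split_in_out(expanded, cells, nuclei,
                               exclude_nucleus = config$content$exclude_nucleus),
      local_ring = split_in_ring(expanded, cells, config$content$ring_width_px),
      signal_objects = split_in_out_signal(img$channels$content, expanded, cells),
      stop("unknown content mode: ", config$content$mode))
    cm <- content_means(img$channels$content, masks)
    out$per_cell <- dplyr::left_join(
      out$per_cell,
      dplyr::transmute(cm, cell_label = .data$cell_label,
                       content_mean_in = .data$mean_in,
                       content_mean_out = .data$mean_out,
                       content_corrected = .data$corrected,
                       content_channel_name = "content"),
      by = "cell_label")
  }

  c(out, list(labels = list(nuclei = nuclei, cells = cells,
                            membrane = membrane, organelles = organelles),
              image = img))
}

# thresholded variant: re-identify signal objects on the masked channel
# before measuring (optional mode; adds a threshold dependence)
split_in_out_signal <- function(content_img, organelles_expanded, cells) {
  oe <- as_label_matrix(organelles_expanded)
  cl <- as_label_matrix(cells)
  m <- rescale_full_range(as_plain_matrix(content_img))
  ids <- sort(setdiff(unique(as.integer(cl)), 0L))
  inmask <- m > attr(threshold_global(m, "otsu"), "threshold")
  res <- lapply(ids, function(cell) {
    cidx <- which(cl == cell)
    inorg <- oe[cidx] > 0L
    sig <- inmask[cidx]
    tibble(cell_label = cell,
           inside_idx = list(cidx[inorg & sig]),
           outside_idx = list(cidx[!inorg & sig]))
  })
  dplyr::bind_rows(res)
}

run_pipeline <- function(images, config, content, out_dir = NULL) {
  results <- list()
  failures <- character()
  for (i in seq_along(images)) {
    res <- tryCatch(profile_image(images[[i]], config, content = content),
                    error = function(e) e)
    if (inherits(res, "error")) {
      id <- if (is.character(images[[i]])) images[[i]] else sprintf("input %d", i)
      warning("image skipped: ", id, " (", conditionMessage(res), ")",
              call. = FALSE)
      failures <- c(failures, paste0(id, ": ", conditionMessage(res)))
      next
    }
    results[[length(results) + 1L]] <- res
  }
  per_image <- dplyr::bind_rows(lapply(results, `[[`, "per_image"))
  per_cell <- dplyr::bind_rows(lapply(results, `[[`, "per_cell"))
  per_org <- dplyr::bind_rows(lapply(results, `[[`, "per_organelle"))
  qc <- list(images = lapply(results, `[[`, "qc"), failures = failures)
  if (!is.null(out_dir)) {
    write_tables(per_image, per_cell, per_org, out_dir)
    write_config(config, file.path(out_dir, "resolved_config.yaml"))
    if (isTRUE(config$output$overlay)) {
      for (res in results) {
        write_overlay(res$image$channels$organelle,
                      res$labels$nuclei, res$labels$cells, res$labels$organelles,
                      file.path(out_dir, paste0("overlay_", res$image$image_id, ".png")))
      }
    }
  }
  structure(list(per_image = per_image, per_cell = per_cell,
                 per_organelle = per_org, qc = qc, config = config,
                 results = results),
            class = "op_batch")
}

#' Run the organelle-profiling pipeline over a batch of images
#'
#' Applies the identical configuration to every image (read, segment,
#' measure, relate, summarize), binds the per-image / per-cell /
#' per-organelle tables, and optionally writes CSV exports, QC overlays and
#' the resolved config. Per-image failures are logged and skipped so one
#' corrupt tile cannot destroy a batch; failures are listed in `$qc$failures`.
#'
#' @param images Character vector of TIFF paths, or a list of
#'   [multichannel_image()] / `synthetic_field` objects.
#' @param config An [op_config()].
#' @param out_dir Optional export directory.
#' @return An `op_batch` list: `per_image`, `per_cell`, `per_organelle`,
#'   `qc`, `config`, and the per-image `results`.
#' @export
run_op <- function(images, config = op_config(), out_dir = NULL) {
  run_pipeline(images, config, content = FALSE, out_dir = out_dir)
}

#' Run the organelle-content pipeline over a batch of images
#'
#' Everything [run_op()] does, plus: expand organelles (default 2 px), split
#' every cell into inside/outside-organelle masks, and append the content
#' means and the cytoplasm-corrected value to `per_cell`. Requires a
#' `content` channel; organelle segmentation is identical to [run_op()].
#'
#' @inheritParams run_op
#' @return An `op_batch` with content columns in `per_cell`.
#' @export
run_ocp <- function(images, config = op_config(), out_dir = NULL) {
  run_pipeline(images, config, content = TRUE, out_dir = out_dir)
}

#' @export
print.op_batch <- function(x, ...) {
  cat(sprintf("<op_batch> %d image(s), %d cell(s), %d organelle(s)\n",
              nrow(x$per_image), nrow(x$per_cell), nrow(x$per_organelle)))
  if (length(x$qc$failures)) cat(" failures:", length(x$qc$failures), "\n")
  invisible(x)
}
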