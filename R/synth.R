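#' Parameters for the synthetic-field generator
#'
#' The generator emulates a confluent endothelial monolayer: a Voronoi-like
#' tessellation of cells each holding one elliptical nucleus, a membrane
#' ridge along cell borders, rod-shaped (capsule) organelles placed at a
#' controllable radial position, and an optional content channel with set
#' inside/outside intensity levels; everything is blurred by a Gaussian PSF
#' and corrupted with additive Gaussian noise. Defaults reproduce the
#' group-1 regime used throughout the tests: per-organelle length
#' Normal(1.38, 0.21) um truncated above 0.3 um, mean organelle
#' eccentricity 0.78, and content levels 0.08 (inside) / 0.05 (outside)
#' A.U.
#'
#' @param field_px Field size `(rows, cols)` in pixels.
#' @param pixel_size_um Pixel pitch (default 0.1 um/px, a typical 63x
#'   confocal sampling).
#' @param n_cells Number of cells tiling the field.
#' @param nucleus_axes_um Ellipse semi-axes of nuclei, micrometers.
#' @param membrane_width_px Width of the rendered membrane ridge.
#' @param organelles_per_cell `list(mean, dispersion)`; `dispersion = 0`
#'   gives exactly `round(mean)` per cell, otherwise a negative-binomial
#'   count with `size = mean / dispersion`.
#' @param length_um `list(mean, sd, min)`: truncated-normal organelle length.
#' @param eccentricity `list(mean, sd)`: per-organelle true eccentricity is
#'   drawn from this (truncated) normal and each capsule's width is derived
#'   from its own length and eccentricity, so the population's true mean
#'   eccentricity tracks the stated target.
#' @param width_um Fixed capsule width; overrides `eccentricity` sampling.
#' @param radial_fraction Range of the uniform placement fraction along the
#'   nucleus-center-to-cell-boundary ray (0 = at nucleus, 1 = at border).
#' @param content_levels `c(mu_in, mu_out)` content-channel levels, or
#'   `NULL` to omit the content channel.
#' @param psf_sigma_px Gaussian PSF sigma (0 disables blur).
#' @param noise_sigma Additive Gaussian noise SD (clipped to `>= 0` after).
#' @param crowded Allow organelle-organelle contact (tests under-segmentation
#'   behavior); by default placements keep at least a 1-px gap.
#' @param rng_seed Integer seed; fully determines the field.
#' @return A `synth_params` list.
#' @export
synth_params <- function(field_px = c(256, 256),
                         pixel_size_um = 0.1,
                         n_cells = 12,
                         nucleus_axes_um = c(1.6, 1.1),
                         membrane_width_px = 2,
                         organelles_per_cell = list(mean = 6, dispersion = 0),
                         length_um = list(mean = 1.38, sd = 0.21, min = 0.3),
                         eccentricity = list(mean = 0.78, sd = 0.04),
                         width_um = NULL,
                         radial_fraction = c(0.2, 0.9),
                         content_levels = c(mu_in = 0.08, mu_out = 0.05),
                         psf_sigma_px = 1,
                         noise_sigma = 0.01,
                         crowded = FALSE,
                         rng_seed = 1L) {
  stopifnot(length(field_px) == 2, pixel_size_um > 0, n_cells >= 1,
            length_um$min > 0, is.null(width_um) || width_um > 0)
  structure(list(field_px = as.integer(field_px), pixel_size_um = pixel_size_um,
                 n_cells = as.integer(n_cells), nucleus_axes_um = nucleus_axes_um,
                 membrane_width_px = membrane_width_px,
                 organelles_per_cell = organelles_per_cell,
                 length_um = length_um, eccentricity = eccentricity,
                 width_um = width_um,
                 radial_fraction = radial_fraction,
                 content_levels = content_levels,
                 psf_sigma_px = psf_sigma_px, noise_sigma = noise_sigma,
                 crowded = isTRUE(crowded), rng_seed = as.integer(rng_seed)),
            class = "synth_params")
}

#' Closed-form eccentricity of a capsule
#'
#' A capsule (rectangle with semicircular caps; total tip-to-tip length `L`,
#' width `w`) has analytic second central moments; the moment-equivalent
#' ellipse eccentricity is `sqrt(1 - I_trans / I_long)` over the area-scaled
#' axis variances. This is the generator's stored ground truth for rendered
#' rods.
#'
#' @param length Total capsule length (tip to tip), any unit.
#' @param width Capsule width (same unit); must satisfy `width <= length`.
#' @return Eccentricity in `[0, 1)`.
#' @export
capsule_eccentricity <- function(length, width) {
  r <- width / 2
  ell <- pmax(length - width, 0)
  A <- 2 * r * ell + pi * r^2
  i_trans <- 2 * ell * r^3 / 3 + pi * r^4 / 4
  # each cap: parallel-axis shift of a half-disk by ell/2 along the long axis
  i_long <- r * ell^3 / 6 +
    2 * ((ell / 2)^2 * (pi * r^2 / 2) + 2 * (ell / 2) * (2 * r^3 / 3) +
           pi * r^4 / 8)
  l1 <- i_long / A
  l2 <- i_trans / A
  sqrt(pmax(0, 1 - l2 / l1))
}

#' @rdname capsule_eccentricity
#' @param ecc Target eccentricity in (0, 1).
#' @return `capsule_width_for_eccentricity`: the width giving the target
#'   eccentricity at the stated length.
#' @export
capsule_width_for_eccentricity <- function(length, ecc) {
  stopifnot(ecc > 0, ecc < 1)
  uniroot(function(w) capsule_eccentricity(length, w) - ecc,
          lower = 1e-3 * length, upper = length * (1 - 1e-6), tol = 1e-9)$root
}

with_preserved_seed <- function(code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

rnorm_trunc <- function(n, mean, sd, lower) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x > lower])
  }
  out[seq_len(n)]
}

# dart-throwing Poisson-disk sampling; relaxes the radius if needed
poisson_disk <- function(n, nr, nc, margin = 12) {
  dmin <- 0.8 * sqrt(nr * nc / n)
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n) {
    p <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
    ok <- nrow(pts) == 0 ||
      min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= dmin^2
    if (ok) pts <- rbind(pts, p)
    tries <- tries + 1L
    if (tries %% 600L == 0L) dmin <- dmin * 0.85  # relax if packing stalls
    if (tries > 20000L) stop("could not place cell centers")
  }
  pts
}

point_segment_dist <- function(pr, pc, a, b) {
  # distance from points (pr, pc) to segment a-b; a, b are c(row, col)
  vr <- b[1] - a[1]; vc <- b[2] - a[2]
  vv <- vr^2 + vc^2
  t <- if (vv == 0) rep(0, length(pr)) else
    pmin(1, pmax(0, ((pr - a[1]) * vr + (pc - a[2]) * vc) / vv))
  sqrt((pr - (a[1] + t * vr))^2 + (pc - (a[2] + t * vc))^2)
}

#' Generate a synthetic multi-channel field with ground truth
#'
#' Renders the channels described in [synth_params()] and records the true
#' cell and organelle parameters before blur and noise, so pipeline output
#' can be scored against known truth. The same seed always yields the
#' bit-identical field.
#'
#' @param params A [synth_params()] object.
#' @return List of class `synthetic_field`: `image` (a
#'   [multichannel_image()]), `cells` [label_image()] of true cell regions,
#'   and `truth` (list of tibbles `cells`, `organelles`, plus
#'   `content_levels` and the parameters used).
#' @export
generate_field <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  with_preserved_seed({
    set.seed(params$rng_seed)
    gen_field_impl(params)
  })
}

gen_field_impl <- function(p) {
  nr <- p$field_px[1]; nc <- p$field_px[2]
  ps <- p$pixel_size_um
  # keep nuclei clear of the field border so no cell is degenerate
  centers <- poisson_disk(p$n_cells, nr, nc,
                          margin = max(12, ceiling(p$nucleus_axes_um[1] / ps) + 4))

  # Voronoi-like tessellation: nearest center, ties to the lower cell label
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2 <- sapply(seq_len(p$n_cells), function(k)
    as.vector((rr - centers[k, 1])^2 + (cc - centers[k, 2])^2))
  cells <- matrix(max.col(-d2, ties.method = "first"), nr, nc)
  storage.mode(cells) <- "integer"

  nuc_ch <- matrix(0, nr, nc)
  a_px <- p$nucleus_axes_um[1] / ps
  b_px <- p$nucleus_axes_um[2] / ps
  cell_rows <- vector("list", p$n_cells)
  for (k in seq_len(p$n_cells)) {
    phi <- runif(1, 0, pi)
    cr <- centers[k, 1]; ccol <- centers[k, 2]
    ext <- ceiling(a_px) + 1L
    ri <- max(1, floor(cr - ext)):min(nr, ceiling(cr + ext))
    ci <- max(1, floor(ccol - ext)):min(nc, ceiling(ccol + ext))
    g <- expand.grid(r = ri, c = ci)
    xr <- (g$r - cr) * cos(phi) + (g$c - ccol) * sin(phi)
    xc <- -(g$r - cr) * sin(phi) + (g$c - ccol) * cos(phi)
    inside <- (xr / a_px)^2 + (xc / b_px)^2 <= 1
    sel <- cbind(g$r[inside], g$c[inside])
    sel <- sel[cells[sel] == k, , drop = FALSE]  # clip to owning cell
    nuc_ch[sel] <- 0.9
    cell_rows[[k]] <- tibble(cell_label = k, center_r = cr, center_c = ccol,
                             area_px = sum(cells == k),
                             nucleus_a_um = p$nucleus_axes_um[1],
                             nucleus_b_um = p$nucleus_axes_um[2],
                             nucleus_phi = phi)
  }

  # membrane ridge along cell boundaries
  bmask <- label_boundaries(label_image(cells, "cell"))
  mem_bin <- matrix(0L, nr, nc)
  mem_bin[bmask] <- 1L
  if (p$membrane_width_px > 1)
    mem_bin <- (expand_labels_cpp(mem_bin, (p$membrane_width_px - 1) / 2 + 0.01) > 0) * 1L
  mem_ch <- mem_bin * 0.8

  # organelles: anti-aliased capsules placed on the nucleus->boundary ray
  org_ch <- matrix(0, nr, nc)
  footprint <- matrix(0L, nr, nc)
  org_rows <- list()
  oid <- 0L
  for (k in seq_len(p$n_cells)) {
    n_org <- if (p$organelles_per_cell$dispersion == 0) {
      round(p$organelles_per_cell$mean)
    } else {
      rnbinom(1, mu = p$organelles_per_cell$mean,
              size = p$organelles_per_cell$mean / p$organelles_per_cell$dispersion)
    }
    for (j in seq_len(n_org)) {
      # size and shape are drawn once per organelle; retries normally only
      # move it, so placement rejection cannot bias the realized size
      # distribution (sizes are resampled only as a last resort below)
      draw_size <- function() {
        L_um <- rnorm_trunc(1, p$length_um$mean, p$length_um$sd, p$length_um$min)
        # lengths are stated in the pixel-center Feret convention, which
        # reads one pixel short of the geometric extent: render accordingly
        L_render_um <- L_um + ps
        w_um <- if (!is.null(p$width_um)) p$width_um else {
          e_i <- min(0.97, max(0.15, rnorm(1, p$eccentricity$mean, p$eccentricity$sd)))
          capsule_width_for_eccentricity(L_render_um, e_i)
        }
        list(L_um = L_um, L_px = L_render_um / ps, w_um = w_um, w_px = w_um / ps)
      }
      sz <- draw_size()
      placed <- FALSE
      for (try in seq_len(500L)) {
        # in cramped cells, fall back late: first drop the clearance from
        # 1.5 to 1.0 px, then allow a fresh size draw
        clearance <- if (p$crowded) 0 else if (try <= 300L) 1.5 else 1
        if (try > 400L) sz <- draw_size()
        L_um <- sz$L_um; L_px <- sz$L_px; w_um <- sz$w_um; w_px <- sz$w_px
        theta <- runif(1, 0, pi)
        tfrac <- runif(1, p$radial_fraction[1], p$radial_fraction[2])
        alpha <- runif(1, 0, 2 * pi)
        dir <- c(cos(alpha), sin(alpha))
        # walk the ray from the cell center: note where it exits the nucleus
        # and where it leaves the cell; the radial fraction runs from the
        # nucleus edge (0) to the cell border (1)
        s <- 1; s_nuc <- 0
        while (TRUE) {
          q <- round(centers[k, ] + s * dir)
          if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc ||
              cells[q[1], q[2]] != k) break
          if (nuc_ch[q[1], q[2]] > 0) s_nuc <- s
          s <- s + 1
        }
        ray_len <- s - 1
        if (ray_len - s_nuc < w_px) next
        ctr <- centers[k, ] + (s_nuc + tfrac * (ray_len - s_nuc)) * dir
        u <- c(cos(theta), sin(theta))
        half <- max(0, (L_px - w_px) / 2)
        p1 <- ctr - half * u; p2 <- ctr + half * u
        ext <- ceiling(L_px / 2 + w_px / 2) + 2L
        ri <- max(1, floor(ctr[1] - ext)):min(nr, ceiling(ctr[1] + ext))
        ci <- max(1, floor(ctr[2] - ext)):min(nc, ceiling(ctr[2] + ext))
        g <- expand.grid(r = ri, c = ci)
        d <- point_segment_dist(g$r, g$c, p1, p2)
        core <- d <= w_px / 2
        # clearance rules out diagonal (8-connected) contact between rendered
        # footprints, keeping ground-truth counts unambiguous
        margin <- d <= w_px / 2 + clearance
        sel_core <- cbind(g$r[core], g$c[core])
        sel_margin <- cbind(g$r[margin], g$c[margin])
        if (!nrow(sel_core)) next
        if (any(cells[sel_margin] != k)) next          # stay inside the cell
        if (any(footprint[sel_margin] > 0L)) next      # no organelle overlap
        if (any(nuc_ch[sel_core] > 0)) next            # cytoplasmic: not on the nucleus
        aa <- pmin(1, pmax(0, w_px / 2 + 0.5 - d))
        sub <- matrix(org_ch[cbind(g$r, g$c)], nrow = length(ri))
        org_ch[cbind(g$r, g$c)] <- pmax(as.vector(sub), 0.9 * aa)
        footprint[sel_core] <- 1L
        oid <- oid + 1L
        org_rows[[oid]] <- tibble(
          organelle_id = oid, cell_label = k,
          center_r = ctr[1], center_c = ctr[2], orientation = theta,
          true_length_um = L_um, true_width_um = w_um,
          true_eccentricity = capsule_eccentricity(L_um + ps, w_um),
          radial_fraction = tfrac)
        placed <- TRUE
        break
      }
      if (!placed) stop("infeasible organelle packing in cell ", k,
                        " after bounded retries")
    }
  }

  channels <- list(
    nuclei = nuc_ch,
    membrane = mem_ch,
    organelle = org_ch)
  if (!is.null(p$content_levels)) {
    halo <- expand_labels_cpp(footprint, 2) > 0
    channels$content <- matrix(p$content_levels[["mu_out"]], nr, nc)
    channels$content[halo] <- p$content_levels[["mu_in"]]
  }
  channels <- lapply(channels, function(ch) {
    if (p$psf_sigma_px > 0) ch <- conv_sep_reflect(ch, gauss_kernel(p$psf_sigma_px))
    if (p$noise_sigma > 0) ch <- ch + rnorm(length(ch), 0, p$noise_sigma)
    ch[ch < 0] <- 0
    ch
  })
  img <- multichannel_image(
    mapply(function(ch, role) intensity_image(matrix(ch, nr, nc), ps, role),
           channels, names(channels), SIMPLIFY = FALSE),
    image_id = sprintf("synthetic_seed%d", p$rng_seed))

  structure(list(
    image = img,
    cells = label_image(cells, "cell"),
    truth = list(cells = dplyr::bind_rows(cell_rows),
                 organelles = if (oid > 0) dplyr::bind_rows(org_rows) else
                   tibble(organelle_id = integer(), cell_label = integer(),
                          center_r = numeric(), center_c = numeric(),
                          orientation = numeric(), true_length_um = numeric(),
                          true_width_um = numeric(),
                          true_eccentricity = numeric(),
                          radial_fraction = numeric()),
                 content_levels = p$content_levels,
                 params = p)),
    class = "synthetic_field")
}

gauss_kernel <- function(sigma) {
  h <- ceiling(3 * sigma)
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("<synthetic_field> %s: %d cells, %d organelles\n",
              x$image$image_id, nrow(x$truth$cells), nrow(x$truth$organelles)))
  invisible(x)
}

#' Generate a two-group synthetic experiment
#'
#' Builds `n_images` independent fields per group from two parameter sets
#' that differ only in declared fields (e.g. organelle length and
#' eccentricity), with deterministic per-image seeds, and concatenates the
#' ground truth with group tags. This mirrors the two-population design used
#' for group contrasts (distinct length/shape regimes, or content levels).
#'
#' @param group_a,group_b [synth_params()] for the two conditions.
#' @param n_images Fields per group.
#' @param seed Base seed; image `i` of group A uses `seed + i`, of group B
#'   `seed + 1000 + i`.
#' @return List with `fields_a`, `fields_b` (lists of `synthetic_field`) and
#'   `truth`: the pooled per-organelle truth tibble with `group` and
#'   `image_id` columns.
#' @export
make_two_group_experiment <- function(group_a, group_b, n_images = 5, seed = 1L) {
  gen_group <- function(params, tag, offset) {
    lapply(seq_len(n_images), function(i) {
      pi_ <- params
      pi_$rng_seed <- as.integer(seed + offset + i)
      f <- generate_field(pi_)
      f$image$image_id <- sprintf("%s_img%02d", tag, i)
      f
    })
  }
  fa <- gen_group(group_a, "groupA", 0L)
  fb <- gen_group(group_b, "groupB", 1000L)
  truth <- dplyr::bind_rows(
    purrr::map2_dfr(fa, seq_len(n_images), function(f, i)
      dplyr::mutate(f$truth$organelles, group = "A",
                    image_id = f$image$image_id, .before = 1)),
    purrr::map2_dfr(fb, seq_len(n_images), function(f, i)
      dplyr::mutate(f$truth$organelles, group = "B",
                    image_id = f$image$image_id, .before = 1)))
  list(fields_a = fa, fields_b = fb, truth = truth)
}
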