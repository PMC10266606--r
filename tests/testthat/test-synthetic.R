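test_that("generated fields match their declared construction", {
  p <- synth_params(field_px = c(300, 300), n_cells = 20,
                    organelles_per_cell = list(mean = 3, dispersion = 0),
                    rng_seed = 41)
  f <- generate_field(p)
  expect_equal(nrow(f$truth$cells), 20)
  # each cell holds exactly one nucleus (rendered at its center)
  expect_equal(anyDuplicated(f$truth$cells$cell_label), 0)
  expect_named(f$image$channels, c("nuclei", "membrane", "organelle", "content"))
  expect_true(all(f$truth$organelles$cell_label %in% f$truth$cells$cell_label))
  # every organelle center lies inside its owning cell
  cl <- unclass(f$cells)
  ctr <- round(cbind(f$truth$organelles$center_r, f$truth$organelles$center_c))
  expect_true(all(cl[ctr] == f$truth$organelles$cell_label))
})

test_that("the same seed reproduces the field bit for bit", {
  p <- synth_params(field_px = c(128, 128), n_cells = 5,
                    organelles_per_cell = list(mean = 3, dispersion = 0),
                    rng_seed = 42)
  f1 <- generate_field(p)
  f2 <- generate_field(p)
  for (ch in names(f1$image$channels))
    expect_identical(unclass(f1$image$channels[[ch]]),
                     unclass(f2$image$channels[[ch]]))
  expect_identical(f1$truth$organelles, f2$truth$organelles)
  # a different seed gives a different field
  f3 <- generate_field(synth_params(field_px = c(128, 128), n_cells = 5,
                                    organelles_per_cell = list(mean = 3, dispersion = 0),
                                    rng_seed = 43))
  expect_false(identical(unclass(f1$image$channels$nuclei),
                         unclass(f3$image$channels$nuclei)))
})

test_that("sampled organelle lengths follow the stated truncated normal", {
  lens <- unlist(lapply(44:50, function(s) {
    p <- synth_params(psf_sigma_px = 0, noise_sigma = 0, rng_seed = s)
    generate_field(p)$truth$organelles$true_length_um
  }))
  expect_gte(length(lens), 480)
  se <- 0.21 / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 1.38), 3 * se + 0.01)  # small truncation shift
  expect_true(all(lens > 0.3))
})

test_that("capsule eccentricity closed form behaves at its limits", {
  expect_equal(capsule_eccentricity(2, 2), 0)               # disk
  expect_gt(capsule_eccentricity(2, 0.2), 0.99)             # thin rod
  # monotone: wider capsules are rounder
  e <- capsule_eccentricity(2, c(0.4, 0.8, 1.2, 1.6, 2))
  expect_true(all(diff(e) < 0))
  # width solver inverts the closed form
  w <- capsule_width_for_eccentricity(1.38, 0.78)
  expect_equal(capsule_eccentricity(1.38, w), 0.78, tolerance = 1e-6)
})

test_that("measured eccentricity matches stored truth on clean renders", {
  # noiseless, unblurred renders: per-population agreement within 0.05
  p <- synth_params(field_px = c(256, 256), n_cells = 12,
                    organelles_per_cell = list(mean = 6, dispersion = 0),
                    psf_sigma_px = 0, noise_sigma = 0, rng_seed = 45)
  f <- generate_field(p)
  lab <- identify_primary(rescale_full_range(f$image$channels$organelle),
                          seg_params(threshold_method = "manual",
                                     threshold_value = 0.5,
                                     diameter_range_px = c(2, 60)),
                          kind = "organelle")
  s <- measure_shape(lab, p$pixel_size_um)
  expect_equal(nrow(s), nrow(f$truth$organelles))
  expect_lt(abs(mean(s$eccentricity) - mean(f$truth$organelles$true_eccentricity)),
            0.05)
})

test_that("placement radial fraction tracks the measured relative distance", {
  p <- synth_params(field_px = c(256, 256), n_cells = 10,
                    organelles_per_cell = list(mean = 6, dispersion = 0),
                    radial_fraction = c(0.05, 0.95),
                    psf_sigma_px = 0, noise_sigma = 0, rng_seed = 46)
  f <- generate_field(p)
  res <- profile_image(f)
  po <- res$per_organelle
  tr <- f$truth$organelles
  # match measured organelles to truth by nearest centroid
  sh <- measure_shape(res$labels$organelles, 1)
  m <- vapply(seq_len(nrow(sh)), function(i) {
    which.min((tr$center_r - sh$centroid_r[i])^2 + (tr$center_c - sh$centroid_c[i])^2)
  }, integer(1))
  keep <- !is.na(po$rel_dist_pct)
  rho <- suppressWarnings(
    cor(tr$radial_fraction[m][keep], po$rel_dist_pct[keep], method = "spearman"))
  expect_gt(rho, 0.9)
})

test_that("two-group experiments tag truth and respect per-image seeds", {
  ga <- synth_params(field_px = c(128, 128), n_cells = 4,
                     organelles_per_cell = list(mean = 3, dispersion = 0),
                     length_um = list(mean = 1.38, sd = 0.21, min = 0.3))
  gb <- synth_params(field_px = c(128, 128), n_cells = 4,
                     organelles_per_cell = list(mean = 3, dispersion = 0),
                     length_um = list(mean = 1.10, sd = 0.27, min = 0.3))
  ex <- make_two_group_experiment(ga, gb, n_images = 3, seed = 7)
  expect_length(ex$fields_a, 3)
  expect_length(ex$fields_b, 3)
  tm <- ex$truth |> dplyr::group_by(group) |>
    dplyr::summarise(len = mean(true_length_um))
  expect_gt(tm$len[tm$group == "A"], tm$len[tm$group == "B"])
  # rebuilding with the same seed reproduces the experiment
  ex2 <- make_two_group_experiment(ga, gb, n_images = 3, seed = 7)
  expect_identical(ex$truth, ex2$truth)
})
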