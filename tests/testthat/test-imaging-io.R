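test_that("multi-channel TIFF reading maps roles and is lossless", {
  set.seed(1)
  planes <- lapply(1:3, function(i) matrix(runif(20 * 30), 20, 30))
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  img <- read_image(path, c(nuclei = 1, membrane = 2, organelle = 3),
                    pixel_size_um = 0.1)
  expect_s3_class(img, "multichannel_image")
  expect_named(img$channels, c("nuclei", "membrane", "organelle"))
  expect_equal(vapply(img$channels, pixel_size, numeric(1)),
               c(nuclei = 0.1, membrane = 0.1, organelle = 0.1))
  # channel separation is lossless (up to float32 storage precision)
  for (i in 1:3)
    expect_equal(unclass(img$channels[[i]]), planes[[i]],
                 ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("z-stacks collapse by per-pixel maximum projection", {
  set.seed(2)
  # 2 channels x 3 z-planes, grouped per channel
  planes <- lapply(1:6, function(i) matrix(runif(12 * 10), 12, 10))
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  img <- read_image(path, c(nuclei = 1, membrane = 2, organelle = 2),
                    pixel_size_um = 0.2, n_z = 3)
  expect_equal(unclass(img$channels$nuclei),
               Reduce(pmax, planes[1:3]), ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(unclass(img$channels$membrane),
               Reduce(pmax, planes[4:6]), ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("read errors are hard: missing file, bad index, missing calibration", {
  expect_error(read_image("no/such/file.tif", c(nuclei = 1, membrane = 2, organelle = 3), 0.1),
               "not found")
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(1:3, function(i) matrix(0.5, 5, 5)), path,
                  bits.per.sample = 32L)
  expect_error(read_image(path, c(nuclei = 1, membrane = 2, organelle = 9), 0.1),
               "out of range")
  # no resolution tags in the file and no explicit pixel size -> no silent default
  expect_error(read_image(path, c(nuclei = 1, membrane = 2, organelle = 3)),
               "pixel_size_um")
  expect_error(read_image(path, c(nuclei = 1, membrane = 2, organelle = 3),
                          pixel_size_um = -1), "> 0")
})

test_that("resolution metadata converts to micrometers per pixel", {
  # 10000 px/cm -> 1 um/px; 25400 px/inch -> 1 um/px
  expect_equal(organellaR:::resolve_pixel_size(
    "from-metadata", list(x.resolution = 10000, resolution.unit = "cm"), "x"), 1)
  expect_equal(organellaR:::resolve_pixel_size(
    "from-metadata", list(x.resolution = 25400, resolution.unit = "inch"), "x"), 1)
  expect_equal(organellaR:::resolve_pixel_size(
    "from-metadata", list(x.resolution = 25400), "x"), 1)  # inch is the TIFF default
})

test_that("rescale_full_range stretches, handles constants, and is idempotent", {
  m <- intensity_image(matrix(c(2, 4, 6, 2), 2), 0.1, "organelle")
  r <- rescale_full_range(m)
  expect_equal(sort(unique(as.vector(r))), c(0, 0.5, 1))
  const <- intensity_image(matrix(7, 4, 4), 0.1, "organelle")
  expect_true(all(rescale_full_range(const) == 0))
  expect_equal(unclass(rescale_full_range(r)), unclass(r))
  set.seed(3)
  x <- intensity_image(matrix(runif(100), 10), 0.1, "nuclei")
  r1 <- rescale_full_range(x)
  expect_equal(range(r1), c(0, 1))
  expect_equal(unclass(rescale_full_range(r1)), unclass(r1))
})

test_that("write_tables produces stable, rerun-identical CSVs", {
  per_image <- tibble::tibble(image_id = "a", cell_count = 2L)
  per_cell <- tibble::tibble(image_id = "a", cell_label = 1:2,
                             mean_length_um = c(1.234567890123, NA))
  per_org <- tibble::tibble(image_id = "a", organelle_label = 1:3, cell_label = c(1L, 1L, 2L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_tables(per_image, per_cell, per_org, d1)
  write_tables(per_image, per_cell, per_org, d2)
  for (f in c("per_image.csv", "per_cell.csv", "per_organelle.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  pc <- readLines(file.path(d1, "per_cell.csv"))
  expect_length(pc, 3)                     # header + 2 cells
  expect_match(pc[3], ",$")                # NA written as empty field
  expect_length(readLines(file.path(d1, "per_organelle.csv")), 4)
  # empty table -> header only
  d3 <- withr::local_tempdir()
  write_tables(per_image[0, ], per_cell[0, ], per_org[0, ], d3)
  expect_length(readLines(file.path(d3, "per_organelle.csv")), 1)
})

test_that("overlay outlines match brute-force boundary sets and cells are numbered", {
  nuc <- label_image(mk_disk(60, 60, 30, 30, 6), "nucleus")
  cells <- label_image(matrix(1L, 60, 60), "cell")
  org <- label_image(mk_disk(60, 60, 15, 45, 3), "organelle")
  bg <- img01(matrix(0.2, 60, 60))
  path <- withr::local_tempfile(fileext = ".png")
  write_overlay(bg, nuc, cells, org, path)
  rgb <- png::readPNG(path)
  # organelle boundary pixels painted green
  b <- oracle_boundary(unclass(org))
  expect_true(all(rgb[, , 2][b] == 1 & rgb[, , 1][b] == 0))
  # nucleus boundary painted blue
  bn <- oracle_boundary(unclass(nuc))
  expect_true(all(rgb[, , 3][bn] == 1))
  # a white label digit appears near the cell centroid
  ctr <- round(colMeans(which(unclass(cells) == 1L, arr.ind = TRUE)))
  win_r <- max(1, ctr[1] - 8):min(60, ctr[1] + 8)
  win_c <- max(1, ctr[2] - 8):min(60, ctr[2] + 8)
  white <- rgb[win_r, win_c, 1] == 1 & rgb[win_r, win_c, 2] == 1 & rgb[win_r, win_c, 3] == 1
  expect_true(any(white))
  # zero organelles still works
  empty <- label_image(matrix(0L, 60, 60), "organelle")
  expect_no_error(write_overlay(bg, nuc, cells, empty,
                                withr::local_tempfile(fileext = ".png")))
  expect_error(write_overlay(bg, label_image(matrix(0L, 10, 10), "nucleus"),
                             cells, org, path), "dimensions")
})
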