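test_that("global threshold agrees with an exhaustive Otsu oracle", {
  set.seed(8)
  m <- matrix(c(rnorm(200, 0.1, 0.01), rnorm(200, 0.9, 0.01)), 20, 20)
  m <- pmin(pmax(m, 0), 1)
  mask <- threshold_global(m, "otsu")
  # exhaustive Otsu over a 256-bin histogram
  bins <- floor(pmin(as.vector(m), 1 - 1e-9) * 256)
  h <- tabulate(bins + 1L, nbins = 256)
  best <- -Inf; bt <- 0
  for (k in 1:255) {
    w0 <- sum(h[1:k]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    mids <- (seq_len(256) - 0.5) / 256
    m0 <- sum(h[1:k] * mids[1:k]) / w0
    m1 <- sum(h[(k + 1):256] * mids[(k + 1):256]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; bt <- k / 256 }
  }
  expect_equal(unclass(mask), m > bt, ignore_attr = TRUE)
  expect_true(all(m[mask] > 0.5) && all(m[!mask] < 0.5))
  # correction and clipping
  mask2 <- threshold_global(m, "otsu", correction = 10, bounds = c(0, 0.5))
  expect_equal(attr(mask2, "threshold"), 0.5)
  expect_false(any(threshold_global(matrix(0, 5, 5), "otsu")))
  expect_error(threshold_global(m, "manual"), "value")
})

test_that("primary identification counts, declumps and filters by size", {
  two <- mk_disk(60, 90, 30, 25, 10) | mk_disk(60, 90, 30, 65, 10)
  lab <- identify_primary(img01(two * 0.9), seg_params(diameter_range_px = c(10, 40)))
  expect_equal(max(lab), 2L)
  # two disks of diameter 20 overlapping by 4 px, shape declump -> 2 labels
  ov <- mk_disk(60, 90, 30, 30, 10) | mk_disk(60, 90, 30, 46, 10)
  lab2 <- identify_primary(img01(ov * 0.9),
                           seg_params(diameter_range_px = c(10, 40), declump = "shape"))
  expect_equal(max(lab2), 2L)
  # a 3-px speck outside the diameter range is removed
  sp <- two; sp[5, 5] <- 1; sp[5, 6] <- 1; sp[6, 5] <- 1
  lab3 <- identify_primary(img01(sp * 0.9), seg_params(diameter_range_px = c(10, 40)))
  expect_equal(max(lab3), 2L)
  # all-zero image: zero objects is a valid result
  lab4 <- identify_primary(img01(matrix(0, 30, 30)), seg_params())
  expect_equal(max(lab4), 0L)
  # border discard
  bd <- mk_disk(40, 40, 2, 20, 6) | mk_disk(40, 40, 25, 20, 6)
  lab5 <- identify_primary(img01(bd * 0.9),
                           seg_params(diameter_range_px = c(5, 30), discard_border = TRUE))
  expect_equal(max(lab5), 1L)
})

test_that("labels are 8-connected and renumbered in raster order", {
  m <- matrix(0, 10, 10)
  m[2, 2] <- 1; m[3, 3] <- 1          # diagonal touch: one 8-connected object
  m[8, 8] <- 1
  m[2, 8] <- 1
  lab <- identify_primary(img01(m * 0.9), seg_params(diameter_range_px = c(0.5, 10)))
  l <- as.matrix(unclass(lab))
  expect_equal(l[2, 2], l[3, 3])      # 8-connectivity joins the diagonal pair
  # raster order: (2,2) block first, then (2,8), then (8,8)
  expect_equal(l[2, 2], 1L)
  expect_equal(l[2, 8], 2L)
  expect_equal(l[8, 8], 3L)
})

test_that("propagation matches the exhaustive relaxation oracle", {
  set.seed(9)
  # single seed, uniform guide: everything becomes label 1
  s <- matrix(0L, 12, 12); s[6, 6] <- 1L
  lab <- identify_secondary_propagation(label_image(s, "nucleus"),
                                        img01(matrix(0.5, 12, 12)), lambda = 0.05)
  expect_true(all(unclass(lab) == 1L))
  # two seeds, constant guide: Voronoi-like split with lower-label ties
  s2 <- matrix(0L, 20, 31); s2[10, 8] <- 1L; s2[10, 24] <- 2L
  g2 <- matrix(0.3, 20, 31)
  lab2 <- identify_secondary_propagation(label_image(s2, "nucleus"), img01(g2), 0.05)
  want2 <- oracle_propagate(g2, s2, 0.05)
  expect_identical(unclass(as_plain_int(lab2)), want2)
  expect_true(all(lab2[, 1:15] == 1L) && all(lab2[, 17:31] == 2L))
  expect_true(all(lab2[, 16] == 1L))  # equidistant column -> lower label
  # bright ridge: boundary settles on the ridge crest
  g3 <- matrix(0.1, 24, 41); g3[, 20:22] <- 0.9; g3[, 21] <- 1
  s3 <- matrix(0L, 24, 41); s3[12, 6] <- 1L; s3[12, 36] <- 2L
  lab3 <- identify_secondary_propagation(label_image(s3, "nucleus"), img01(g3), 0.01)
  bcol <- vapply(seq_len(24), function(i) max(which(lab3[i, ] == 1L)), integer(1))
  expect_true(all(abs(bcol - 21) <= 1))
  expect_identical(unclass(as_plain_int(lab3)), oracle_propagate(g3, s3, 0.01))
  # random guides, several seeds: pixel-for-pixel oracle agreement
  for (trial in 1:6) {
    nr <- sample(14:22, 1); nc <- sample(14:22, 1)
    g <- matrix(runif(nr * nc), nr, nc)
    s <- matrix(0L, nr, nc)
    k <- sample(2:4, 1)
    pos <- sample(nr * nc, k)
    s[pos] <- seq_len(k)
    got <- identify_secondary_propagation(label_image(s, "nucleus"), img01(g), 0.05)
    expect_identical(unclass(as_plain_int(got)), oracle_propagate(g, s, 0.05))
  }
  expect_error(identify_secondary_propagation(
    label_image(matrix(0L, 5, 5), "nucleus"), img01(matrix(0, 5, 5))), "seed")
  expect_error(identify_secondary_propagation(
    label_image(s2, "nucleus"), img01(g2), lambda = -1), ">= 0")
})

test_that("cells partition the foreground with one cell per seed", {
  f <- generate_field(synth_params(field_px = c(96, 96), n_cells = 4,
                                   organelles_per_cell = list(mean = 2, dispersion = 0),
                                   rng_seed = 5))
  res <- profile_image(f)
  cl <- unclass(res$labels$cells)
  expect_true(all(cl > 0L))                                   # full partition
  expect_equal(length(unique(as.integer(cl))), res$per_image$nucleus_count)
  # each cell region is connected and contains its seed
  nl <- unclass(res$labels$nuclei)
  for (k in unique(as.integer(cl)))
    expect_true(any(nl[cl == k] == k))
})

test_that("tertiary membrane is the cell minus its erosion", {
  sq <- matrix(0L, 30, 30); sq[6:25, 6:25] <- 1L
  cells <- label_image(sq, "cell")
  mem <- identify_tertiary_membrane(cells, 1)
  expect_equal(sum(mem > 0), 76)                 # 20x20 frame
  expect_true(all(unclass(mem)[sq == 0L] == 0L)) # membrane within the cell
  # width >= inradius: the whole cell becomes membrane
  mem2 <- identify_tertiary_membrane(cells, 12)
  expect_equal(sum(mem2 > 0), sum(sq > 0))
  # set identity: cell minus membrane is the eroded interior
  interior <- sq == 1L & unclass(mem) == 0L
  expect_true(all(which(interior) %in% which(sq == 1L)))
  expect_equal(sum(interior), 18 * 18)
})

test_that("label expansion is Euclidean, tie-broken low, and never merges", {
  one <- matrix(0L, 11, 11); one[6, 6] <- 1L
  e2 <- expand_labels(label_image(one, "organelle"), 2)
  # lattice points with squared distance <= 4: a 13-pixel diamond-disk
  expect_equal(sum(e2 > 0), 13)
  offs <- expand.grid(dr = -2:2, dc = -2:2)
  offs <- offs[offs$dr^2 + offs$dc^2 <= 4, ]
  expect_setequal(which(unclass(e2) == 1L),
                  (6 + offs$dc - 1) * 11 + 6 + offs$dr)
  # n = 0 is the identity
  expect_identical(as_plain_int(expand_labels(label_image(one, "organelle"), 0)), one)
  # two objects 3 px apart expand to abut but never merge
  two <- matrix(0L, 9, 13); two[5, 4] <- 1L; two[5, 8] <- 2L
  e <- unclass(expand_labels(label_image(two, "organelle"), 2))
  expect_setequal(setdiff(unique(as.integer(e)), 0L), 1:2)
  expect_equal(e[5, 6], 1L)      # equidistant tie -> lower label
  expect_equal(e[5, 5], 1L); expect_equal(e[5, 7], 2L)
  # nearest-label oracle on a random configuration
  set.seed(10)
  l <- matrix(0L, 15, 15)
  l[sample(225, 4)] <- 1:4
  got <- unclass(expand_labels(label_image(l, "organelle"), 3))
  pos <- which(l > 0L)
  pr <- (pos - 1L) %% 15L + 1L; pc <- (pos - 1L) %/% 15L + 1L
  for (i in 1:15) for (j in 1:15) {
    if (l[i, j] > 0L) { expect_equal(got[i, j], l[i, j]); next }
    d2 <- (pr - i)^2 + (pc - j)^2
    if (min(d2) <= 9) {
      cands <- l[pos[d2 == min(d2)]]
      expect_equal(got[i, j], min(cands))
    } else expect_equal(got[i, j], 0L)
  }
  # iterated expansion support identity for unit steps
  ea <- expand_labels(expand_labels(label_image(one, "organelle"), 1), 1)
  eb <- expand_labels(label_image(one, "organelle"), 2)
  expect_identical(unclass(ea) > 0L, unclass(eb) > 0L)
})
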