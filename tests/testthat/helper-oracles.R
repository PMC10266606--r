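# Independent brute-force oracles. These deliberately re-derive results from
# definitions (loops, exhaustive relaxation, all-pairs scans) and never call
# the package's own compiled kernels.

reflect1 <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

oracle_minmax <- function(img, offs, take_min) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  f <- if (take_min) min else max
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- mapply(function(dr, dc) img[reflect1(i + dr, nr), reflect1(j + dc, nc)],
                   offs$dr, offs$dc)
    out[i, j] <- f(vals)
  }
  out
}

oracle_tophat <- function(img, offs) {
  er <- oracle_minmax(img, offs, TRUE)
  refl <- data.frame(dr = -offs$dr, dc = -offs$dc)
  op <- oracle_minmax(er, refl, FALSE)
  th <- img - op
  th[th < 0] <- 0
  th
}

oracle_disk_offsets <- function(radius) {
  g <- expand.grid(dr = -floor(radius):floor(radius),
                   dc = -floor(radius):floor(radius))
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

oracle_line_offsets <- function(length_px, angle_deg) {
  h <- (length_px - 1) / 2
  t <- seq(-h, h, by = 1)
  a <- angle_deg * pi / 180
  unique(data.frame(dr = round(-t * sin(a)), dc = round(t * cos(a))))
}

# Exhaustive (Jacobi) relaxation of the propagation fixpoint:
# value(q) = lexicographic min over neighbors p of (dist(p) + step(p,q), lab(p)),
# step = sqrt(dI^2 + lambda^2 * s^2).  Same tie rule as the implementation.
oracle_propagate <- function(guide, seeds, lambda, mask = NULL) {
  nr <- nrow(guide); nc <- ncol(guide)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  dist <- matrix(Inf, nr, nc)
  lab <- matrix(0L, nr, nc)
  sel <- seeds > 0L & mask
  dist[sel] <- 0
  lab[sel] <- seeds[sel]
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!mask[i, j] || lab[i, j] == 0L || !is.finite(dist[i, j])) next
      for (t in seq_len(nrow(nb))) {
        qi <- i + nb$dr[t]; qj <- j + nb$dc[t]
        if (qi < 1 || qi > nr || qj < 1 || qj > nc || !mask[qi, qj]) next
        s2 <- if (nb$dr[t] != 0 && nb$dc[t] != 0) 2 else 1
        dI <- abs(guide[qi, qj] - guide[i, j])
        cand <- dist[i, j] + sqrt(dI * dI + lambda * lambda * s2)
        if (cand < dist[qi, qj] ||
            (cand == dist[qi, qj] && lab[i, j] < lab[qi, qj])) {
          dist[qi, qj] <- cand
          lab[qi, qj] <- lab[i, j]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

oracle_feret_all_pairs <- function(rows, cols) {
  if (length(rows) < 2) return(0)
  d2 <- outer(rows, rows, "-")^2 + outer(cols, cols, "-")^2
  sqrt(max(d2))
}

oracle_boundary <- function(labels) {
  l <- labels
  nr <- nrow(l); nc <- ncol(l)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (l[i, j] == 0) next
    nbv <- c(if (i > 1) l[i - 1, j] else -1, if (i < nr) l[i + 1, j] else -1,
             if (j > 1) l[i, j - 1] else -1, if (j < nc) l[i, j + 1] else -1)
    out[i, j] <- any(nbv != l[i, j])
  }
  out
}

# --- shape renderers for fixtures -------------------------------------------

mk_disk <- function(nr, nc, cr, cc, r) {
  m <- matrix(0L, nr, nc)
  m[(row(m) - cr)^2 + (col(m) - cc)^2 <= r^2] <- 1L
  m
}

mk_ellipse <- function(nr, nc, cr, cc, a, b, phi = 0) {
  m <- matrix(0L, nr, nc)
  xr <- (row(m) - cr) * cos(phi) + (col(m) - cc) * sin(phi)
  xc <- -(row(m) - cr) * sin(phi) + (col(m) - cc) * cos(phi)
  m[(xr / a)^2 + (xc / b)^2 <= 1] <- 1L
  m
}

# binary capsule: tip-to-tip length L, width w, orientation theta (radians)
mk_capsule <- function(nr, nc, cr, cc, L, w, theta) {
  u <- c(cos(theta), sin(theta))
  half <- max(0, (L - w) / 2)
  a <- c(cr, cc) - half * u
  b <- c(cr, cc) + half * u
  m <- matrix(0L, nr, nc)
  pr <- as.vector(row(m)); pc <- as.vector(col(m))
  vr <- b[1] - a[1]; vc <- b[2] - a[2]
  vv <- vr^2 + vc^2
  t <- if (vv == 0) rep(0, length(pr)) else
    pmin(1, pmax(0, ((pr - a[1]) * vr + (pc - a[2]) * vc) / vv))
  d <- sqrt((pr - (a[1] + t * vr))^2 + (pc - (a[2] + t * vc))^2)
  m[d <= w / 2] <- 1L
  m
}

img01 <- function(m, ps = 0.1, role = "organelle") {
  intensity_image(matrix(as.numeric(m), nrow(m), ncol(m)), ps, role)
}

as_plain_int <- function(x) {
  m <- unclass(x)
  attr(m, "kind") <- NULL
  storage.mode(m) <- "integer"
  m
}
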