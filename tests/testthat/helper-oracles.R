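# Shared fixtures and independent oracles used across the suite.

# A small, quick default phantom (noise-free unless stated).
quickSpec <- function(...) {
  args <- utils::modifyList(
    list(semiAxisLR = 120, semiAxisAP = 85,
         vertebraCenter = c(5, 18), vertebraRadius = 12,
         processLength = 45, pixelSpacing = c(1.5, 1.5),
         imageShape = c(224L, 224L), noiseSD = 0),
    list(...))
  do.call(phantomSpec, args)
}

# Pixel-counting oracle for quadrant fractions of an analytic phantom
# contour: a regular grid of `h`-mm cells, each counted by whether its
# centre lies inside the contour (radial test), split by the cross-hair
# through `center`. Independent of the polygon-clipping implementation.
pixelCountQuadrants <- function(spec, center, h = 0.1) {
  R <- max(contourRadius(seq(0, 2 * pi, length.out = 3600), spec)) + h
  g <- seq(-R, R, by = h) + h / 2
  left <- g >= center[1L]
  counts <- c(0, 0, 0, 0)
  for (y in g) {                       # row by row to bound memory
    inside <- sqrt(g^2 + y^2) <= contourRadius(atan2(y, g), spec)
    post <- y >= center[2L]
    nl <- sum(inside & left); nr <- sum(inside & !left)
    if (post) counts <- counts + c(0, 0, nl, nr)   # a3, a4
    else counts <- counts + c(nr, nl, 0, 0)        # a1, a2
  }
  counts / sum(counts)
}

# Random star-shaped polygon about the origin (always simple). Jittered
# equally-spaced angles bound the angular gaps, so the origin (and a
# small neighbourhood of it) stays strictly inside every edge chord.
randomStarPolygon <- function(n, rmin = 0.4, rmax = 1) {
  th <- 2 * pi * (seq_len(n) - 1) / n +
    stats::runif(n, 0, 0.8 * 2 * pi / n)
  r <- stats::runif(n, rmin, rmax)
  cbind(r * cos(th), r * sin(th))
}

# Random convex polygon via the convex hull of random points,
# recentred on its area centroid so the origin is strictly interior.
randomConvexPolygon <- function(n) {
  p <- matrix(stats::rnorm(2L * n), ncol = 2L)
  v <- p[grDevices::chull(p), , drop = FALSE]
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  cen <- c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * A)
  sweep(v, 2L, cen)
}

# Brute-force re-aggregation of a cohort, written independently of the
# package's aggregation path: collects raw (patient, level) values per
# group and applies mean()/sd() directly.
bruteForceTable <- function(records, grouping) {
  grp <- vapply(records, function(r) switch(grouping,
    none = "all", gender = r$gender,
    severity = classifySeverity(max(r$curves$angle)),
    region = classifyRegion(r$curves)), character(1L))
  out <- list()
  for (g in unique(grp)) {
    meas <- do.call(rbind, lapply(records[grp == g],
                                  function(r) r$measurements))
    for (lev in unique(meas$level)) {
      x12 <- meas$L12_mm[meas$level == lev]
      x13 <- meas$L13_mm[meas$level == lev]
      x12 <- x12[!is.na(x12)]
      out[[paste(g, lev)]] <- list(
        group = g, level = lev,
        n12 = length(x12), m12 = mean(x12),
        s12 = if (length(x12) >= 2) sd(x12) else NA_real_,
        n13 = length(x13), m13 = mean(x13),
        s13 = if (length(x13) >= 2) sd(x13) else NA_real_)
    }
  }
  out
}

# Brute-force regional pooling from raw values.
bruteForceRegion <- function(records, grouping, levels) {
  grp <- vapply(records, function(r) switch(grouping,
    none = "all", gender = r$gender,
    severity = classifySeverity(max(r$curves$angle)),
    region = classifyRegion(r$curves)), character(1L))
  out <- list()
  for (g in unique(grp)) {
    meas <- do.call(rbind, lapply(records[grp == g],
                                  function(r) r$measurements))
    sel <- meas[meas$level %in% levels, , drop = FALSE]
    x13 <- sel$L13_mm[!is.na(sel$L13_mm)]
    x12 <- sel$L12_mm[!is.na(sel$L12_mm)]
    out[[g]] <- list(m12 = mean(x12),
                     s12 = if (length(x12) >= 2) sd(x12) else NA_real_,
                     m13 = mean(x13),
                     s13 = if (length(x13) >= 2) sd(x13) else NA_real_)
  }
  out
}
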