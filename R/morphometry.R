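#' Euclidean distance between two pixel positions in mm
#'
#' Distance between two (row, col) pixel positions under anisotropic
#' per-axis pixel spacing: each index difference is scaled by its axis
#' spacing before the Pythagorean sum.
#'
#' @param p,q numeric(2) (row, col) pixel positions.
#' @param spacing numeric(2) (row, col) spacing, mm.
#' @return length in mm.
#' @examples
#' euclideanMM(c(100, 100), c(100, 160), c(0.7, 0.7))  # 42 mm
#' @export
euclideanMM <- function(p, q, spacing) {
  if (any(spacing <= 0)) stop("pixel spacing must be positive")
  sqrt(((p[1L] - q[1L]) * spacing[1L])^2 +
       ((p[2L] - q[2L]) * spacing[2L])^2)
}

# Convert a 0-based (row, col) pixel position to the package mm frame
# (x = col * col-spacing = patient-left, y = row * row-spacing =
# posterior).
pxToMM <- function(p, spacing) {
  c(x = p[2L] * spacing[2L], y = p[1L] * spacing[1L])
}

#' Skin-crossing point of the spinous axis
#'
#' Intersects the ray from the vertebral-body centre \code{m1} through
#' the spinous tip \code{m2} with the body contour and returns the
#' first crossing beyond the tip: the ray is parametrized as
#' \code{p(t) = m1 + t (m2 - m1)} and the intersection with the
#' smallest \code{t > 1} over all polygon edges is returned — the
#' nearest point where the spinous axis meets the skin on the
#' posterior side.
#'
#' @param m1,m2 numeric(2) (x, y) mm points, both interior to the
#'   contour, \code{m1 != m2}.
#' @param contour a \linkS4class{ContourPolygon}.
#' @return numeric(2) (x, y) mm crossing point.
#' @export
skinCrossing <- function(m1, m2, contour) {
  d <- m2 - m1
  if (all(d == 0)) stop("m1 and m2 must differ")
  v <- contour@vertices
  a <- v
  b <- v[c(seq_len(nrow(v))[-1L], 1L), , drop = FALSE]
  # solve m1 + t d = a + s (b - a), 0 <= s <= 1, per edge
  ex <- b[, 1L] - a[, 1L]; ey <- b[, 2L] - a[, 2L]
  den <- d[1L] * ey - d[2L] * ex
  wx <- a[, 1L] - m1[1L]; wy <- a[, 2L] - m1[2L]
  t <- (wx * ey - wy * ex) / den
  s <- (wx * d[2L] - wy * d[1L]) / den
  ok <- is.finite(t) & s >= 0 & s <= 1 & t > 1
  if (!any(ok))
    stop("spinous axis does not cross the contour beyond the tip; ",
         "markers inconsistent with the body contour")
  tmin <- min(t[ok])
  m1 + tmin * d
}

#' Polygon area by the shoelace (Surveyor's) formula
#'
#' Absolute area of a simple closed polygon from its Cartesian vertex
#' coordinates, \code{|1/2 sum(x_i y_{i+1} - x_{i+1} y_i)|} over the
#' closed vertex cycle.
#'
#' @param contour a \linkS4class{ContourPolygon}, or an n x 2 vertex
#'   matrix.
#' @return area in mm^2.
#' @examples
#' polygonArea(contourPolygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))  # 1
#' @export
polygonArea <- function(contour) {
  v <- if (is(contour, "ContourPolygon")) contour@vertices else
    as.matrix(contour)
  if (nrow(v) < 3L) stop("a polygon needs at least 3 vertices")
  abs(signedArea(v))
}

# Clip a polygon (vertex matrix) against the half-plane keep(p) >= 0,
# Sutherland-Hodgman step. `value` returns the signed coordinate used
# for the linear interpolation of crossing points.
clipHalfPlane <- function(v, axis, bound, keepAbove) {
  n <- nrow(v)
  if (n == 0L) return(v)
  s <- if (keepAbove) v[, axis] - bound else bound - v[, axis]
  out <- matrix(numeric(0), 0L, 2L)
  res <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ci <- s[i] >= 0; cj <- s[j] >= 0
    if (ci) { k <- k + 1L; res[[k]] <- v[i, ] }
    if (xor(ci, cj)) {
      t <- s[i] / (s[i] - s[j])
      k <- k + 1L
      res[[k]] <- v[i, ] + t * (v[j, ] - v[i, ])
    }
  }
  if (k == 0L) return(out)
  do.call(rbind, res[seq_len(k)])
}

#' Quadrant areas of the contour-enclosed region about a point
#'
#' Cuts the region enclosed by the body contour with the two
#' axis-parallel lines through \code{center} (the cross-hair through
#' the vertebral-body centre) and returns the four quadrant areas by
#' Sutherland-Hodgman clipping followed by the shoelace formula, plus
#' the total area and the four normalized fractions.
#'
#' Quadrant labels follow the anatomical convention used throughout:
#' \code{a1} anterior-right, \code{a2} anterior-left, \code{a3}
#' posterior-left, \code{a4} posterior-right (+x patient-left, +y
#' posterior). Degenerate clipped slivers below 1e-9 mm^2 count as
#' zero.
#'
#' @param contour a \linkS4class{ContourPolygon}.
#' @param center numeric(2) (x, y) mm, strictly interior.
#' @return list with \code{areas} (named a1..a4, mm^2), \code{total}
#'   (mm^2) and \code{fractions} (areas / total).
#' @examples
#' sq <- contourPolygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' quadrantAreas(sq, c(0.25, 0.25))$areas
#' @export
quadrantAreas <- function(contour, center) {
  v <- contour@vertices
  if (!pointInPolygon(center, v))
    stop("cross-hair centre must lie strictly inside the contour")
  piece <- function(keepLeft, keepPost) {
    w <- clipHalfPlane(v, 1L, center[1L], keepLeft)
    if (nrow(w) >= 3L) w <- clipHalfPlane(w, 2L, center[2L], keepPost)
    if (nrow(w) < 3L) return(0)
    a <- abs(signedArea(w))
    if (a < 1e-9) 0 else a
  }
  a1 <- piece(FALSE, FALSE)   # anterior-right: x < cx, y < cy
  a2 <- piece(TRUE, FALSE)    # anterior-left
  a3 <- piece(TRUE, TRUE)     # posterior-left
  a4 <- piece(FALSE, TRUE)    # posterior-right
  areas <- c(a1 = a1, a2 = a2, a3 = a3, a4 = a4)
  total <- sum(areas)
  list(areas = areas, total = total, fractions = areas / total)
}

# Even-odd (crossing number) point-in-polygon test.
pointInPolygon <- function(p, v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- ((y > p[2L]) != (yn > p[2L]))
  if (!any(cross)) return(FALSE)
  xc <- x[cross] + (p[2L] - y[cross]) / (yn[cross] - y[cross]) *
    (xn[cross] - x[cross])
  sum(xc > p[1L]) %% 2L == 1L
}

#' Back-to-front and left-to-right area aspects
#'
#' Collapses the four quadrant areas into the two normalized aspects
#' that locate the vertebral body within the body contour:
#' \code{f_back}, the posterior-half fraction (a3 + a4) / total, and
#' \code{f_left}, the left-half fraction (a2 + a3) / total.
#'
#' @param q result of \code{\link{quadrantAreas}}.
#' @return numeric(2) c(f_back, f_left), each strictly in (0, 1) for an
#'   interior centre.
#' @export
areaAspects <- function(q) {
  if (q$total <= 0) stop("total area must be positive")
  c(f_back = unname((q$areas["a3"] + q$areas["a4"]) / q$total),
    f_left = unname((q$areas["a2"] + q$areas["a3"]) / q$total))
}

#' Measure one vertebra on an axial slice
#'
#' Composition of the per-vertebra pipeline: converts the annotated
#' pixel markers to mm, computes the body-to-spinous distance L12 (when
#' the spinous tip m2 was identifiable), intersects the spinous axis
#' with the body contour to obtain the skin crossing m3 and the
#' body-to-skin distance L13, and partitions the contour area into
#' quadrants and aspects about the vertebral-body centre.
#'
#' When m2 is missing, L12 is recorded as \code{NA}; L13 is also
#' \code{NA} unless a substitute axis direction is supplied, since the
#' spinous axis is otherwise undefined. Quadrant areas and aspects are
#' always computed from m1 alone.
#'
#' @param slice the \linkS4class{CTSlice} the markers were set on.
#' @param markers list with elements \code{level}, \code{m1_px},
#'   \code{m2_px} (each 0-based (row, col); \code{m2_px} may be NULL),
#'   and optionally \code{slice}.
#' @param contour the \linkS4class{ContourPolygon} extracted from the
#'   same slice (mm frame of the slice raster).
#' @param substituteDirection optional numeric(2) (x, y) mm-frame
#'   direction used for the skin crossing when m2 is missing.
#' @return one-row data.frame: level, L12_mm, L13_mm, a1..a4_mm2,
#'   total_mm2, f_back, f_left.
#' @export
measureVertebra <- function(slice, markers, contour,
                            substituteDirection = NULL) {
  sp <- slice@spacing
  m1 <- pxToMM(markers$m1_px, sp)
  hasM2 <- !is.null(markers$m2_px) && !anyNA(markers$m2_px)
  if (hasM2) {
    m2 <- pxToMM(markers$m2_px, sp)
    L12 <- euclideanMM(markers$m1_px, markers$m2_px, sp)
    m3 <- skinCrossing(m1, m2, contour)
    L13 <- sqrt(sum((m3 - m1)^2))
  } else if (!is.null(substituteDirection)) {
    d <- substituteDirection / sqrt(sum(substituteDirection^2))
    L12 <- NA_real_
    # a nominal point along the substitute axis plays the role of m2
    m3 <- skinCrossing(m1, m1 + 1e-6 * d, contour)
    L13 <- sqrt(sum((m3 - m1)^2))
  } else {
    L12 <- NA_real_
    L13 <- NA_real_
  }
  q <- quadrantAreas(contour, m1)
  asp <- areaAspects(q)
  data.frame(level = markers$level,
             L12_mm = L12, L13_mm = L13,
             a1_mm2 = unname(q$areas["a1"]), a2_mm2 = unname(q$areas["a2"]),
             a3_mm2 = unname(q$areas["a3"]), a4_mm2 = unname(q$areas["a4"]),
             total_mm2 = q$total,
             f_back = unname(asp["f_back"]), f_left = unname(asp["f_left"]),
             stringsAsFactors = FALSE)
}
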