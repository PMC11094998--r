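#' Area fraction of an ellipse beyond a chord
#'
#' Fraction of the total ellipse area lying on the side of a chord with
#' normalized coordinate \code{>= t}, where \code{t} is the chord
#' offset divided by the semi-axis perpendicular to the chord. Because
#' area fractions are invariant under the affine map that turns any
#' ellipse into the unit circle, the fraction is independent of both
#' semi-axes:
#' \deqn{F(t) = 1/2 - (t \sqrt{1 - t^2} + \arcsin t)/\pi.}
#' F is strictly decreasing with F(-1) = 1, F(0) = 1/2, F(1) = 0.
#'
#' @param t chord offset(s) in [-1, 1].
#' @return area fraction(s) in [0, 1].
#' @examples
#' ellipseAreaFraction(0)    # 0.5
#' ellipseAreaFraction(0.5)  # 0.1955011
#' @export
ellipseAreaFraction <- function(t) {
  if (any(abs(t) > 1)) stop("chord offset must lie in [-1, 1]")
  0.5 - (t * sqrt(1 - t^2) + asin(t)) / pi
}

#' Invert the ellipse chord-area relation
#'
#' Finds the unique normalized chord offset \code{t} in [-1, 1] whose
#' beyond-chord area fraction equals \code{f}, by bisection on the
#' strictly decreasing \code{\link{ellipseAreaFraction}}. Bisection is
#' used (rather than a derivative method) because F has vanishing slope
#' at |t| = 1.
#'
#' @param f target area fraction(s), each strictly in (0, 1).
#' @param tol convergence tolerance on |F(t) - f|.
#' @return chord offset(s) t, vectorized over \code{f}.
#' @examples
#' invertAreaFraction(0.5)  # 0
#' @export
invertAreaFraction <- function(f, tol = 1e-10) {
  if (any(f <= 0 | f >= 1)) stop("area fraction must lie strictly in (0, 1)")
  lo <- rep(-1, length(f))   # F(lo) = 1 > f
  hi <- rep(1, length(f))    # F(hi) = 0 < f
  for (k in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- ellipseAreaFraction(mid)
    high <- fm > f           # fraction still too large: move chord up
    lo[high] <- mid[high]
    hi[!high] <- mid[!high]
    if (max(abs(fm - f)) < tol && max(hi - lo) < tol) break
  }
  (lo + hi) / 2
}

#' Map area aspects to a position in the generalized ellipse
#'
#' Places a vertebral body inside a generalized ellipse by the
#' equal-area chord construction: the horizontal chord at normalized
#' posterior coordinate \code{v} is chosen so that the ellipse fraction
#' posterior of it equals the measured posterior-half aspect
#' \code{f_back}, and likewise the vertical chord \code{u} for the
#' left-half aspect \code{f_left}. The crossing point (u, v) of the two
#' chords is the normalized vertebral position, comparable across
#' patients regardless of individual body shape — the ellipse is never
#' fitted to any contour, and the construction is independent of its
#' semi-axes.
#'
#' The two chords are computed independently, so for extreme aspect
#' pairs the crossing point may fall outside the inscribed ellipse;
#' each coordinate individually always lies strictly in (-1, 1).
#'
#' For a vertebra exactly at the contour centroid of an elliptical
#' body, both aspects are 0.5 and the position degenerates to the
#' ellipse centre (0, 0). A posteriorly shifted vertebra has a small
#' posterior remainder (small \code{f_back}), hence a posterior
#' (positive v) position.
#'
#' @param aspects numeric(2) c(f_back, f_left), each strictly in (0, 1).
#' @param tol inversion tolerance.
#' @return numeric(2) c(u, v): +u patient-left, +v posterior.
#' @examples
#' mapToEllipse(c(0.5, 0.5))  # centre (0, 0)
#' @export
mapToEllipse <- function(aspects, tol = 1e-10) {
  v <- invertAreaFraction(aspects[[1L]], tol)
  u <- invertAreaFraction(aspects[[2L]], tol)
  c(u = unname(u), v = unname(v))
}
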