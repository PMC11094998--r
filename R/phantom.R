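#' Construct a synthetic torso phantom specification
#'
#' Defines the geometry of a synthetic axial CT slice of a torso: an
#' elliptical soft-tissue body contour, optionally deformed by a
#' Gaussian radial bulge that emulates the posterior rib hump seen on
#' the convex side in scoliosis, with an embedded high-intensity
#' vertebral-body disk and a spinous-process bar, on an air background.
#'
#' Tissue intensities are fixed at -1000 HU (air), +40 HU (soft tissue)
#' and +1000 HU (bone) so that a single threshold around -300 HU
#' separates body from air robustly even under noise.
#'
#' @param semiAxisLR,semiAxisAP ellipse semi-axes (left-right half-width
#'   and anterior-posterior half-depth), mm.
#' @param humpAmplitude peak radial elevation of the rib hump, mm.
#' @param humpCenter angular position of the hump peak, rad
#'   (0 = patient-left, pi/2 = posterior).
#' @param humpWidth Gaussian angular width of the hump, rad.
#' @param vertebraCenter (x, y) mm position of the vertebral-body centre
#'   relative to the contour centroid (+x patient-left, +y posterior).
#' @param vertebraRadius radius of the vertebral-body disk, mm.
#' @param processLength distance from the vertebral-body centre to the
#'   spinous-process end tip, mm.
#' @param processAngle spinous-axis angle measured from straight
#'   posterior, positive towards patient-left, rad.
#' @param pixelSpacing (row, col) pixel spacing, mm.
#' @param sliceStep slice step along the scan direction, mm.
#' @param noiseSD additive Gaussian noise SD, HU.
#' @param imageShape (rows, cols) of the raster.
#'
#' @return a validated \linkS4class{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(vertebraCenter = c(0, 25), humpAmplitude = 15)
#' spec
#' @export
phantomSpec <- function(semiAxisLR = 150, semiAxisAP = 100,
                        humpAmplitude = 0, humpCenter = pi / 2 + 0.6,
                        humpWidth = 0.5,
                        vertebraCenter = c(0, 20), vertebraRadius = 15,
                        processLength = 55, processAngle = 0,
                        pixelSpacing = c(1.5, 1.5), sliceStep = 5,
                        noiseSD = 15, imageShape = c(256L, 256L)) {
  new("PhantomSpec",
      semiAxisLR = as.numeric(semiAxisLR),
      semiAxisAP = as.numeric(semiAxisAP),
      humpAmplitude = as.numeric(humpAmplitude),
      humpCenter = as.numeric(humpCenter),
      humpWidth = as.numeric(humpWidth),
      vertebraCenter = as.numeric(vertebraCenter),
      vertebraRadius = as.numeric(vertebraRadius),
      processLength = as.numeric(processLength),
      processAngle = as.numeric(processAngle),
      pixelSpacing = as.numeric(pixelSpacing),
      sliceStep = as.numeric(sliceStep),
      noiseSD = as.numeric(noiseSD),
      imageShape = as.integer(imageShape))
}

#' Radial body-contour model of the phantom
#'
#' Radius of the phantom body contour at polar angle \code{theta}
#' (0 = patient-left, pi/2 = posterior, about the contour centroid):
#' the ellipse radius for the two semi-axes plus a Gaussian bump of
#' amplitude \code{humpAmplitude} centred at \code{humpCenter}, using
#' the wrapped angular distance. Smooth, strictly positive and
#' 2*pi-periodic.
#'
#' @param theta polar angle(s), rad.
#' @param spec a \linkS4class{PhantomSpec} (its validity is not
#'   re-checked here; this function is used inside the validity check).
#' @return radius (mm), vectorized over \code{theta}.
#' @examples
#' spec <- phantomSpec()
#' contourRadius(0, spec)        # semiAxisLR
#' contourRadius(pi / 2, spec)   # semiAxisAP
#' @export
contourRadius <- function(theta, spec) {
  a <- spec@semiAxisLR
  b <- spec@semiAxisAP
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  if (spec@humpAmplitude > 0) {
    d <- (theta - spec@humpCenter) %% (2 * pi)
    d <- pmin(d, 2 * pi - d)   # wrapped angular distance
    r <- r + spec@humpAmplitude * exp(-d^2 / (2 * spec@humpWidth^2))
  }
  r
}

# Distance from `origin` (inside the contour) to the analytic contour
# along direction angle(s) `angles`, by vectorized bisection on
# g(t) = |origin + t e(theta)| - r(.). Assumes the contour is
# star-shaped about `origin` (one crossing per ray), which holds for
# vertebral centres well inside the torso.
rayContourDistance <- function(origin, angles, spec, iter = 60L) {
  ex <- cos(angles); ey <- sin(angles)
  g <- function(t) {
    px <- origin[1L] + t * ex
    py <- origin[2L] + t * ey
    sqrt(px^2 + py^2) - contourRadius(atan2(py, px), spec)
  }
  lo <- rep(0, length(angles))
  hi <- rep(2 * (spec@semiAxisLR + spec@semiAxisAP + spec@humpAmplitude),
            length(angles))
  if (g(0)[1L] >= 0) stop("ray origin lies outside the body contour")
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    neg <- g(mid) < 0
    lo[neg] <- mid[neg]
    hi[!neg] <- mid[!neg]
  }
  (lo + hi) / 2
}

# Quadrant area fractions of the analytic phantom contour about
# `center`, by polar integration: each quadrant about the cross-hair
# centre corresponds to a quarter-turn of local directions, and its
# area is 1/2 * integral of rho(theta)^2 over that quarter, with
# rho(theta) the ray-to-contour distance from `center`. Composite
# Simpson with `n` intervals per quadrant; the integrand is smooth
# within each quadrant. This is the analytic ground-truth oracle that
# the polygon-clipping implementation is tested against.
analyticQuadrantFractions <- function(spec, center, n = 1024L) {
  simpsonQuad <- function(th0, th1) {
    th <- seq(th0, th1, length.out = n + 1L)
    rho <- rayContourDistance(center, th, spec)
    h <- (th1 - th0) / n
    w <- rep(c(4, 2), length.out = n - 1L)
    (h / 3) * sum(c(1, w, 1) * rho^2) / 2
  }
  # local direction quarters in the (+x left, +y posterior) frame
  a3 <- simpsonQuad(0, pi / 2)            # posterior-left
  a4 <- simpsonQuad(pi / 2, pi)           # posterior-right
  a1 <- simpsonQuad(pi, 3 * pi / 2)       # anterior-right
  a2 <- simpsonQuad(3 * pi / 2, 2 * pi)   # anterior-left
  tot <- a1 + a2 + a3 + a4
  c(a1, a2, a3, a4) / tot
}

#' Generate a synthetic axial CT phantom with analytic ground truth
#'
#' Rasterizes the phantom described by \code{spec} into one or more
#' axial slices (air -1000 HU, soft tissue +40 HU, vertebral body and
#' spinous process +1000 HU) with additive Gaussian noise truncated at
#' +/- 4 SD, and computes the analytic ground truth for every
#' downstream stage: the densely sampled contour polygon, the three
#' markers (vertebral-body centre m1, spinous tip m2, skin crossing m3
#' on the ray m1 -> m2), the distances L12 and L13, and the quadrant
#' area fractions about m1 from the polar integration oracle.
#'
#' @param spec a valid \linkS4class{PhantomSpec}.
#' @param seed integer RNG seed; the same seed yields a bit-identical
#'   volume and truth.
#' @param nSlices number of identical-geometry slices to stack (noise
#'   differs per slice).
#' @param contourSamples vertices of the truth contour polygon.
#' @return list with elements \code{volume} (\linkS4class{CTVolume})
#'   and \code{truth} (\linkS4class{PhantomTruth}). Truth coordinates
#'   are mm relative to the contour centroid, which sits at the
#'   geometric centre of the image raster.
#' @examples
#' ph <- makePhantom(phantomSpec(noiseSD = 0), seed = 1)
#' truthDistances(ph$truth)
#' @export
makePhantom <- function(spec, seed, nSlices = 1L, contourSamples = 3600L) {
  validObject(spec)
  nr <- spec@imageShape[1L]; nc <- spec@imageShape[2L]
  spr <- spec@pixelSpacing[1L]; spc <- spec@pixelSpacing[2L]
  cy <- (nr - 1) / 2 * spr     # contour centroid at the raster centre
  cx <- (nc - 1) / 2 * spc
  y <- (seq_len(nr) - 1) * spr - cy          # +row = posterior
  x <- (seq_len(nc) - 1) * spc - cx          # +col = patient-left
  X <- matrix(x, nr, nc, byrow = TRUE)
  Y <- matrix(y, nr, nc)
  R <- sqrt(X^2 + Y^2)
  inside <- R <= contourRadius(atan2(Y, X), spec)

  m1 <- spec@vertebraCenter
  dirv <- c(sin(spec@processAngle), cos(spec@processAngle))
  m2 <- m1 + spec@processLength * dirv
  # vertebral-body disk plus a 2-3 px wide spinous bar from m1 to m2
  disk <- (X - m1[1L])^2 + (Y - m1[2L])^2 <= spec@vertebraRadius^2
  px <- X - m1[1L]; py <- Y - m1[2L]
  t <- pmax(0, pmin(1, (px * dirv[1L] + py * dirv[2L]) /
                       spec@processLength))
  dseg <- sqrt((px - t * spec@processLength * dirv[1L])^2 +
               (py - t * spec@processLength * dirv[2L])^2)
  bar <- dseg <= 1.25 * max(spec@pixelSpacing)
  base <- matrix(-1000, nr, nc)
  base[inside] <- 40
  base[inside & (disk | bar)] <- 1000

  set.seed(as.integer(seed))
  vol <- array(0, dim = c(nr, nc, nSlices))
  for (s in seq_len(nSlices)) {
    noise <- if (spec@noiseSD > 0) {
      z <- stats::rnorm(nr * nc, sd = spec@noiseSD)
      pmax(pmin(z, 4 * spec@noiseSD), -4 * spec@noiseSD)
    } else 0
    vol[, , s] <- base + noise
  }
  volume <- new("CTVolume", data = vol,
                spacing = c(spec@pixelSpacing, spec@sliceStep))

  th <- seq(0, 2 * pi, length.out = contourSamples + 1L)[-(contourSamples + 1L)]
  rr <- contourRadius(th, spec)
  poly <- ensureCCW(new("ContourPolygon",
                        vertices = cbind(x = rr * cos(th),
                                         y = rr * sin(th))))
  dirAngle <- atan2(dirv[2L], dirv[1L])
  L13 <- rayContourDistance(m1, dirAngle, spec)
  m3 <- m1 + L13 * c(cos(dirAngle), sin(dirAngle))
  qf <- analyticQuadrantFractions(spec, m1)
  truth <- new("PhantomTruth", contour = poly,
               m1 = m1, m2 = m2, m3 = m3,
               L12 = spec@processLength, L13 = L13,
               quadrantFractions = qf,
               aspects = c(f_back = qf[3L] + qf[4L],
                           f_left = qf[2L] + qf[3L]))
  list(volume = volume, truth = truth)
}

#' Ground-truth markers of a phantom in pixel coordinates
#'
#' Converts the analytic truth markers of a phantom (mm, relative to
#' the contour centroid) into the 0-based (row, col) pixel coordinates
#' of its raster, as a marker annotation consumes them.
#'
#' @param spec the \linkS4class{PhantomSpec} used to build the phantom.
#' @param truth the matching \linkS4class{PhantomTruth}.
#' @param slice 0-based slice index to annotate.
#' @param level vertebral level label for the annotation entry.
#' @return a one-entry marker list suitable for
#'   \code{\link{runPipeline}} / \code{\link{writeMarkers}}.
#' @export
phantomMarkers <- function(spec, truth, slice = 0L, level = "T7") {
  nr <- spec@imageShape[1L]; nc <- spec@imageShape[2L]
  cy <- (nr - 1) / 2; cx <- (nc - 1) / 2
  toPx <- function(p) c(row = p[2L] / spec@pixelSpacing[1L] + cy,
                        col = p[1L] / spec@pixelSpacing[2L] + cx)
  list(list(level = level, slice = as.integer(slice),
            m1_px = unname(toPx(truth@m1)),
            m2_px = unname(toPx(truth@m2))))
}
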