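#' @import methods
NULL

#' CTSlice: one axial CT image
#'
#' A single transverse CT slice. Intensities are in Hounsfield units (HU)
#' and the per-axis pixel spacing is in mm. The array convention used
#' throughout the package is 0-based \code{(row, col)} indexing with
#' \code{+col} pointing to the patient's left and \code{+row} pointing
#' posterior (supine LPS orientation); physical mm coordinates are index
#' times per-axis spacing.
#'
#' @slot data numeric matrix of HU values, rows indexing the
#'   anterior-to-posterior direction and columns right-to-left.
#' @slot spacing numeric(2), pixel spacing in mm as (row, col).
#'
#' @export
setClass("CTSlice", representation(data = "matrix", spacing = "numeric"))

setValidity("CTSlice", function(object) {
  if (length(object@spacing) != 2L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("'spacing' must be two positive finite mm values (row, col)")
  if (!is.numeric(object@data) || any(dim(object@data) < 2L))
    return("'data' must be a numeric matrix with at least 2 rows and columns")
  TRUE
})

#' CTVolume: a stack of axial CT slices
#'
#' @slot data numeric 3-d array (row, col, slice) of HU values.
#' @slot spacing numeric(3), (row, col) pixel spacing and slice step, mm.
#'
#' @export
setClass("CTVolume", representation(data = "array", spacing = "numeric"))

setValidity("CTVolume", function(object) {
  if (length(dim(object@data)) != 3L)
    return("'data' must be a 3-d array (row, col, slice)")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("'spacing' must be three positive mm values (row, col, slice)")
  TRUE
})

#' ContourPolygon: closed outer body contour
#'
#' An ordered, closed list of vertices in physical mm coordinates. The
#' stored coordinate frame is \code{(x, y)} with \code{+x} patient-left
#' (column direction) and \code{+y} patient-posterior (row direction);
#' orientation is normalized to counter-clockwise in that frame. The
#' vertex list is open-stored (first vertex not repeated) with the
#' closure implied.
#'
#' @slot vertices numeric matrix, n x 2, columns \code{x}, \code{y} (mm).
#'
#' @export
setClass("ContourPolygon", representation(vertices = "matrix"))

setValidity("ContourPolygon", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L)
    return("'vertices' must be an n x 2 numeric matrix")
  if (nrow(v) < 3L)
    return("a polygon needs at least 3 vertices")
  if (any(!is.finite(v)))
    return("vertices must be finite")
  TRUE
})

#' PhantomSpec: parameters of the synthetic torso slice
#'
#' Geometry of a synthetic axial torso slice: an elliptical soft-tissue
#' body contour with an optional Gaussian posterior bulge emulating a
#' rib hump, an embedded high-intensity vertebral body with a spinous
#' process bar, air background, and anisotropic pixel spacing.
#'
#' Angles follow the slice frame: theta = 0 points to the patient's left
#' (+x) and theta = pi/2 posterior (+y). The spinous-process axis angle
#' is measured from straight posterior, positive towards patient-left.
#'
#' @slot semiAxisLR half-width of the base ellipse, left-right, mm.
#' @slot semiAxisAP half-depth, anterior-posterior, mm.
#' @slot humpAmplitude peak radial elevation of the rib hump, mm (>= 0).
#' @slot humpCenter angular position of the hump peak, rad.
#' @slot humpWidth Gaussian angular width of the hump, rad (> 0).
#' @slot vertebraCenter numeric(2) (x, y) mm of the vertebral-body centre
#'   relative to the contour centroid.
#' @slot vertebraRadius radius of the vertebral-body disk, mm.
#' @slot processLength length of the spinous process bar from the body
#'   centre to its end tip, mm.
#' @slot processAngle spinous-axis angle from straight posterior, rad.
#' @slot pixelSpacing numeric(2), (row, col) spacing, mm.
#' @slot sliceStep slice step along the scan direction, mm (default 5).
#' @slot noiseSD additive Gaussian HU noise standard deviation (>= 0).
#' @slot imageShape integer(2), (rows, cols) of the slice raster.
#'
#' @export
setClass("PhantomSpec", representation(
  semiAxisLR = "numeric", semiAxisAP = "numeric",
  humpAmplitude = "numeric", humpCenter = "numeric", humpWidth = "numeric",
  vertebraCenter = "numeric", vertebraRadius = "numeric",
  processLength = "numeric", processAngle = "numeric",
  pixelSpacing = "numeric", sliceStep = "numeric",
  noiseSD = "numeric", imageShape = "integer"))

setValidity("PhantomSpec", function(object) {
  pos <- function(x) length(x) == 1L && is.finite(x) && x > 0
  if (!pos(object@semiAxisLR) || !pos(object@semiAxisAP))
    return("semi-axes must be positive lengths")
  if (object@humpAmplitude < 0) return("humpAmplitude must be >= 0")
  if (object@humpAmplitude >= object@semiAxisAP)
    return("humpAmplitude must be smaller than semiAxisAP")
  if (!pos(object@humpWidth)) return("humpWidth must be positive")
  if (length(object@vertebraCenter) != 2L)
    return("vertebraCenter must be an (x, y) pair in mm")
  if (!pos(object@vertebraRadius)) return("vertebraRadius must be positive")
  if (!pos(object@processLength)) return("processLength must be positive")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    return("pixelSpacing must be two positive mm values (row, col)")
  if (!pos(object@sliceStep)) return("sliceStep must be positive")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  if (length(object@imageShape) != 2L || any(object@imageShape < 16L))
    return("imageShape must be two integers >= 16")
  # vertebral body plus full process must lie strictly inside the contour
  d <- c(sin(object@processAngle), cos(object@processAngle))
  tip <- object@vertebraCenter + object@processLength * d
  probe <- rbind(
    tip,
    sweep(cbind(cos(seq(0, 2 * pi, length.out = 17L)[-17L]),
                sin(seq(0, 2 * pi, length.out = 17L)[-17L])) *
            object@vertebraRadius, 2L, object@vertebraCenter, "+"))
  r <- sqrt(rowSums(probe^2))
  rc <- contourRadius(atan2(probe[, 2L], probe[, 1L]), object)
  if (any(r >= rc))
    return("vertebral body and spinous process must lie strictly inside the body contour")
  TRUE
})

#' PhantomTruth: analytic ground truth of a phantom slice
#'
#' @slot contour the analytic body contour sampled as a
#'   \linkS4class{ContourPolygon}.
#' @slot m1,m2,m3 numeric(2) (x, y) mm: vertebral-body centre, spinous
#'   tip, and skin crossing along the spinous axis.
#' @slot L12,L13 Euclidean distances m1-m2 and m1-m3, mm.
#' @slot quadrantFractions numeric(4), area fractions of the four
#'   quadrants (anterior-right, anterior-left, posterior-left,
#'   posterior-right) about m1, summing to 1.
#' @slot aspects numeric(2), (f_back, f_left): posterior-half and
#'   left-half area fractions.
#'
#' @export
setClass("PhantomTruth", representation(
  contour = "ContourPolygon",
  m1 = "numeric", m2 = "numeric", m3 = "numeric",
  L12 = "numeric", L13 = "numeric",
  quadrantFractions = "numeric", aspects = "numeric"))

setValidity("PhantomTruth", function(object) {
  if (object@L12 >= object@L13)
    return("L12 must be smaller than L13 (the skin lies beyond the spinous tip)")
  q <- object@quadrantFractions
  if (length(q) != 4L || any(q <= 0) || any(q >= 1) ||
      abs(sum(q) - 1) > 1e-9)
    return("quadrantFractions must be four values in (0,1) summing to 1")
  TRUE
})

#' CohortTable: per-level / regional mean and SD summary
#'
#' Aggregated morphometry of a cohort: per group and per vertebral level
#' (and, after \code{\link{regionalMeans}}, per region) the count, the
#' arithmetic mean and the sample standard deviation of the
#' body-to-spinous distance L12 and the body-to-skin distance L13, mm.
#'
#' @slot table data.frame with columns \code{group}, \code{row},
#'   \code{rowType} ("level" or "region"), \code{nL12}, \code{meanL12},
#'   \code{sdL12}, \code{nL13}, \code{meanL13}, \code{sdL13}.
#' @slot grouping one of "severity", "region", "gender", "none".
#'
#' @export
setClass("CohortTable",
         representation(table = "data.frame", grouping = "character"))

setValidity("CohortTable", function(object) {
  need <- c("group", "row", "rowType", "nL12", "meanL12", "sdL12",
            "nL13", "meanL13", "sdL13")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  bad <- !is.na(object@table$sdL12) & object@table$nL12 < 2L
  if (any(bad)) return("SD may only be present when count >= 2")
  TRUE
})
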