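#' Accessors for vertemetry data classes
#'
#' @param object a vertemetry S4 object.
#' @name accessors
NULL

#' @describeIn accessors HU matrix of a \linkS4class{CTSlice} (or the 3-d
#'   array of a \linkS4class{CTVolume}).
#' @export
setGeneric("sliceData", function(object) standardGeneric("sliceData"))
#' @export
setMethod("sliceData", "CTSlice", function(object) object@data)
#' @export
setMethod("sliceData", "CTVolume", function(object) object@data)

#' @describeIn accessors per-axis spacing in mm.
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @export
setMethod("pixelSpacing", "CTSlice", function(object) object@spacing)
#' @export
setMethod("pixelSpacing", "CTVolume", function(object) object@spacing)
#' @export
setMethod("pixelSpacing", "PhantomSpec", function(object) object@pixelSpacing)

#' @describeIn accessors extract axial slice \code{i} (0-based) from a
#'   volume as a \linkS4class{CTSlice}.
#' @param i 0-based slice index.
#' @export
setGeneric("getSlice", function(object, i) standardGeneric("getSlice"))
#' @export
setMethod("getSlice", "CTVolume", function(object, i) {
  ns <- dim(object@data)[3L]
  if (i < 0L || i >= ns)
    stop("slice index ", i, " outside volume (0..", ns - 1L, ")")
  new("CTSlice", data = object@data[, , i + 1L, drop = TRUE],
      spacing = object@spacing[1:2])
})

#' @describeIn accessors n x 2 vertex matrix (x = patient-left,
#'   y = posterior, mm) of a \linkS4class{ContourPolygon}.
#' @export
setGeneric("contourVertices",
           function(object) standardGeneric("contourVertices"))
#' @export
setMethod("contourVertices", "ContourPolygon", function(object)
  object@vertices)
#' @export
setMethod("contourVertices", "PhantomTruth", function(object)
  object@contour@vertices)

#' @describeIn accessors ground-truth marker positions of a
#'   \linkS4class{PhantomTruth} as a 3 x 2 matrix (rows m1, m2, m3).
#' @export
setGeneric("truthMarkers", function(object) standardGeneric("truthMarkers"))
#' @export
setMethod("truthMarkers", "PhantomTruth", function(object) {
  m <- rbind(object@m1, object@m2, object@m3)
  dimnames(m) <- list(c("m1", "m2", "m3"), c("x", "y"))
  m
})

#' @describeIn accessors ground-truth distances of a
#'   \linkS4class{PhantomTruth} as c(L12, L13), mm.
#' @export
setGeneric("truthDistances",
           function(object) standardGeneric("truthDistances"))
#' @export
setMethod("truthDistances", "PhantomTruth", function(object)
  c(L12 = object@L12, L13 = object@L13))

#' @describeIn accessors ground-truth quadrant area fractions
#'   (anterior-right, anterior-left, posterior-left, posterior-right).
#' @export
setGeneric("truthQuadrantFractions",
           function(object) standardGeneric("truthQuadrantFractions"))
#' @export
setMethod("truthQuadrantFractions", "PhantomTruth", function(object)
  object@quadrantFractions)

#' @describeIn accessors ground-truth area aspects c(f_back, f_left).
#' @export
setGeneric("truthAspects", function(object) standardGeneric("truthAspects"))
#' @export
setMethod("truthAspects", "PhantomTruth", function(object) object@aspects)

#' @describeIn accessors summary data.frame of a
#'   \linkS4class{CohortTable}.
#' @export
setGeneric("cohortSummary", function(object) standardGeneric("cohortSummary"))
#' @export
setMethod("cohortSummary", "CohortTable", function(object) object@table)

#' @describeIn accessors grouping variable of a
#'   \linkS4class{CohortTable}.
#' @export
setGeneric("cohortGrouping",
           function(object) standardGeneric("cohortGrouping"))
#' @export
setMethod("cohortGrouping", "CohortTable", function(object) object@grouping)

setMethod("show", "CTSlice", function(object) {
  d <- dim(object@data)
  cat("CTSlice: ", d[1L], " x ", d[2L], " px, spacing ",
      sprintf("%.3g x %.3g", object@spacing[1L], object@spacing[2L]),
      " mm, HU range [", sprintf("%.0f", min(object@data)), ", ",
      sprintf("%.0f", max(object@data)), "]\n", sep = "")
})

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat("CTVolume: ", d[1L], " x ", d[2L], " px x ", d[3L], " slices, ",
      "spacing ", sprintf("%.3g x %.3g", object@spacing[1L],
                          object@spacing[2L]),
      " mm, step ", sprintf("%.3g", object@spacing[3L]), " mm\n", sep = "")
})

setMethod("show", "ContourPolygon", function(object) {
  cat("ContourPolygon: ", nrow(object@vertices), " vertices, area ",
      sprintf("%.1f", polygonArea(object)), " mm^2\n", sep = "")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec: body ellipse ", object@semiAxisLR, " x ",
      object@semiAxisAP, " mm", sep = "")
  if (object@humpAmplitude > 0)
    cat(", rib hump ", object@humpAmplitude, " mm", sep = "")
  cat("; vertebra at (", object@vertebraCenter[1L], ", ",
      object@vertebraCenter[2L], ") mm, process ", object@processLength,
      " mm\n", sep = "")
})

setMethod("show", "PhantomTruth", function(object) {
  cat("PhantomTruth: L12 = ", sprintf("%.2f", object@L12),
      " mm, L13 = ", sprintf("%.2f", object@L13),
      " mm, aspects (back, left) = (",
      sprintf("%.3f", object@aspects[1L]), ", ",
      sprintf("%.3f", object@aspects[2L]), ")\n", sep = "")
})

setMethod("show", "CohortTable", function(object) {
  cat("CohortTable (grouping: ", object@grouping, "), ",
      nrow(object@table), " rows\n", sep = "")
  print(utils::head(object@table, 10L), row.names = FALSE)
  if (nrow(object@table) > 10L) cat("...\n")
})
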