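#' Create a contour polygon from a vertex matrix
#'
#' @param vertices n x 2 numeric matrix of (x, y) mm vertices
#'   (+x patient-left, +y posterior); an explicitly repeated closing
#'   vertex is dropped. Orientation is normalized to counter-clockwise.
#' @return a \linkS4class{ContourPolygon}.
#' @export
contourPolygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  n <- nrow(vertices)
  if (n >= 2L && isTRUE(all(vertices[1L, ] == vertices[n, ])))
    vertices <- vertices[-n, , drop = FALSE]
  colnames(vertices) <- c("x", "y")
  ensureCCW(new("ContourPolygon", vertices = vertices))
}

# Normalize vertex order to counter-clockwise (positive shoelace sign)
# in the (+x left, +y posterior) frame.
ensureCCW <- function(poly) {
  v <- poly@vertices
  if (signedArea(v) < 0)
    poly@vertices <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  poly
}

signedArea <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Extract the outer body contour from an axial slice
#'
#' Traces iso-contours of the HU image at \code{thresholdHU} with a
#' marching-squares algorithm (sub-pixel linear interpolation along
#' cell edges, via \code{grDevices::contourLines}) and returns, among
#' all closed contours, the one enclosing the largest area — the outer
#' body contour, robust to internal bone or air contours. Vertex
#' indices are converted to mm through the pixel spacing and the
#' orientation is normalized to counter-clockwise.
#'
#' The default threshold of -300 HU lies midway between air
#' (about -1000 HU) and soft tissue (about 0 to 60 HU), so the traced
#' polygon is insensitive to moderate threshold changes and image
#' noise. No smoothing is applied to the polygon.
#'
#' @param slice a \linkS4class{CTSlice}.
#' @param thresholdHU iso-level, HU.
#' @return a \linkS4class{ContourPolygon} in mm image coordinates
#'   (x = column direction, y = row direction, origin at pixel (0, 0)).
#' @examples
#' ph <- makePhantom(phantomSpec(noiseSD = 0), seed = 1)
#' poly <- extractBodyContour(getSlice(ph$volume, 0))
#' polygonArea(poly)
#' @export
extractBodyContour <- function(slice, thresholdHU = -300) {
  z <- slice@data
  nr <- nrow(z); nc <- ncol(z)
  rowmm <- (seq_len(nr) - 1) * slice@spacing[1L]
  colmm <- (seq_len(nc) - 1) * slice@spacing[2L]
  cl <- grDevices::contourLines(x = rowmm, y = colmm, z = z,
                                levels = thresholdHU)
  if (length(cl) == 0L)
    stop("no body contour at threshold ", thresholdHU, " HU")
  # contourLines returns x along rows, y along columns; repackage into
  # the package frame (x = col mm = patient-left, y = row mm = posterior)
  polys <- lapply(cl, function(co)
    cbind(x = co$y, y = co$x))
  closed <- vapply(polys, function(v)
    all(v[1L, ] == v[nrow(v), ]), logical(1L))
  areas <- vapply(polys, function(v) abs(signedArea(v)), numeric(1L))
  if (!any(closed)) {
    # open traces clipped at the domain edge: the body leaves the image
    stop("body truncated by field of view")
  }
  if (any(!closed) && max(areas[!closed]) > max(areas[closed]))
    stop("body truncated by field of view")
  best <- which(closed)[which.max(areas[closed])]
  contourPolygon(polys[[best]])
}

#' Pick the transverse slice closest to the vertical centre of a vertebra
#'
#' Given the first and last slice index spanned by a vertebra, returns
#' the index nearest to the midpoint; an exact tie is broken toward the
#' smaller index.
#'
#' @param levelRanges data.frame with columns \code{level},
#'   \code{first}, \code{last} (0-based slice indices), or a named list
#'   of \code{c(first, last)} pairs.
#' @param level vertebral level label to look up.
#' @return 0-based slice index.
#' @examples
#' selectCenterSlice(data.frame(level = "T7", first = 10, last = 21), "T7")
#' @export
selectCenterSlice <- function(levelRanges, level) {
  if (is.data.frame(levelRanges)) {
    i <- match(level, levelRanges$level)
    if (is.na(i)) stop("level ", level, " absent from annotation")
    rng <- c(levelRanges$first[i], levelRanges$last[i])
  } else {
    if (is.null(levelRanges[[level]]))
      stop("level ", level, " absent from annotation")
    rng <- levelRanges[[level]]
  }
  if (rng[2L] < rng[1L]) stop("invalid slice range for level ", level)
  mid <- (rng[1L] + rng[2L]) / 2
  as.integer(floor(mid + 0.5 - (mid %% 1 == 0.5) * 0.5))
}

#' Write contour vertices to CSV
#'
#' @param poly a \linkS4class{ContourPolygon}.
#' @param path output file.
#' @export
writeContourCSV <- function(poly, path) {
  v <- contourVertices(poly)
  utils::write.csv(data.frame(x_mm = fmtNum(v[, 1L]),
                              y_mm = fmtNum(v[, 2L])),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
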