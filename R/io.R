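# fixed 6-significant-digit float formatting for reproducible CSV diffs
fmtNum <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))

#' Write a CT volume as NIfTI
#'
#' Stores the HU array with the per-axis spacing (row, col, slice step)
#' in the header pixdim. Axis 1 of the array is the row (posterior)
#' direction, axis 2 the column (patient-left) direction.
#'
#' Single-slice volumes are stored as 2-D images (the file format drops
#' trailing singleton dimensions), so their slice step is not preserved;
#' \code{\link{readCTVolume}} restores it as 1 mm.
#'
#' @param volume a \linkS4class{CTVolume}.
#' @param path output file (.nii or .nii.gz).
#' @export
writeCTVolume <- function(volume, path) {
  # spacing goes through the header: pixdim<- on an image whose
  # trailing singleton dimension was squeezed would silently drop it
  img <- RNifti::asNifti(volume@data,
                         list(pixdim = c(-1, volume@spacing,
                                         0, 0, 0, 0)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a CT volume from NIfTI
#'
#' @param path .nii / .nii.gz file with spacing in the header.
#' @return a \linkS4class{CTVolume}.
#' @export
readCTVolume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  sp <- RNifti::pixdim(img)
  if (length(d) == 2L) {   # single-slice volumes come back squeezed
    d <- c(d, 1L)
    sp <- c(sp[1:2], 1)
  }
  arr <- array(as.numeric(img), dim = d[1:3])
  new("CTVolume", data = arr, spacing = as.numeric(sp[1:3]))
}

#' Read a per-vertebra marker annotation file
#'
#' Markers arrive as the JSON an annotator produces:
#' \code{\{"patient": id, "vertebrae": [\{"level": "T7", "slice": 123,
#' "m1_px": [r, c], "m2_px": [r, c] | null\}]\}} with 0-based (row, col)
#' pixel positions; \code{m2_px} is null when no clear spinous-process
#' end tip could be identified.
#'
#' @param path JSON file.
#' @return list with \code{patient} and \code{vertebrae} (a list of
#'   marker entries).
#' @export
readMarkers <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  m$vertebrae <- lapply(m$vertebrae, function(v) {
    v$slice <- as.integer(v$slice)
    v$m1_px <- as.numeric(unlist(v$m1_px))
    v$m2_px <- if (is.null(v$m2_px)) NULL else as.numeric(unlist(v$m2_px))
    v
  })
  m
}

#' Write a per-vertebra marker annotation file
#'
#' @param vertebrae list of marker entries (level, slice, m1_px, m2_px).
#' @param path output JSON file.
#' @param patient patient identifier.
#' @export
writeMarkers <- function(vertebrae, path, patient = "anonymous") {
  jsonlite::write_json(list(patient = patient, vertebrae = vertebrae),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a phantom specification from YAML
#'
#' Field names follow the \code{\link{phantomSpec}} arguments.
#'
#' @param path YAML file.
#' @return a \linkS4class{PhantomSpec}.
#' @export
readPhantomSpec <- function(path) {
  do.call(phantomSpec, yaml::read_yaml(path))
}

#' Write ground truth of a phantom as JSON
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @param path output JSON file.
#' @export
writePhantomTruth <- function(truth, path) {
  jsonlite::write_json(list(
    m1_mm = truth@m1, m2_mm = truth@m2, m3_mm = truth@m3,
    L12_mm = truth@L12, L13_mm = truth@L13,
    quadrant_fractions = truth@quadrantFractions,
    aspects = list(f_back = truth@aspects[[1L]],
                   f_left = truth@aspects[[2L]]),
    contour = truth@contour@vertices), path, digits = NA)
  invisible(path)
}

# md5 of an arbitrary R object (via its serialization) or of a file.
md5Of <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(unname(tools::md5sum(x)))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(x, NULL, version = 2L), tmp)
  unname(tools::md5sum(tmp))
}

# header comment lines carried by every output file: tool version,
# config hash, input hashes.
outputHeader <- function(config = NULL, inputs = character()) {
  ver <- as.character(utils::packageVersion("vertemetry"))
  lines <- c(sprintf("# vertemetry %s", ver))
  if (!is.null(config))
    lines <- c(lines, sprintf("# config md5: %s", md5Of(config)))
  for (f in inputs)
    lines <- c(lines, sprintf("# input %s md5: %s", basename(f), md5Of(f)))
  lines
}

# write a data.frame as CSV with header comment lines and fixed float
# formatting (byte-identical across runs for identical inputs).
writeTableCSV <- function(df, path, config = NULL, inputs = character()) {
  num <- vapply(df, is.numeric, logical(1L)) &
    !vapply(df, is.integer, logical(1L))
  df[num] <- lapply(df[num], fmtNum)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(outputHeader(config, inputs), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort table as CSV
#'
#' Mirrors the structure of a per-level / regional summary table: one
#' row per group x level (and region), columns for count, mean and SD
#' of L12 and L13 in mm. Carries a header comment with the tool version.
#'
#' @param table a \linkS4class{CohortTable}.
#' @param path output CSV.
#' @param config optional configuration object hashed into the header.
#' @export
writeCohortTable <- function(table, path, config = NULL) {
  writeTableCSV(cohortSummary(table), path, config = config)
}
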