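#' Simulate a morphometry cohort with known structure
#'
#' Generates a cohort of patient records carrying per-level L12/L13
#' measurements, Cobb angles, curve apexes and gender, for exercising
#' the classification, aggregation and reporting stages. The default
#' composition mirrors a typical adult scoliosis case mix: 20 patients
#' split 4 mild / 10 medium / 6 strong by Cobb angle and
#' 4 thoracic / 3 thoraco-lumbar / 10 lumbar / 3 combined by curve
#' region, with levels T1-L5 (C7 in about a third of patients).
#'
#' The distance model follows the physiological level trend: L12 is
#' minimal around T7 and rises towards both the lumbar and the upper
#' thoracic ends; L13 adds a patient-specific soft-tissue offset. The
#' across-patient scatter of L13 grows with severity and is largest at
#' the levels of the patient's own curve region, so the qualitative
#' regularities probed by \code{\link{findingsReport}} are present by
#' construction. Occasionally (5\%) the spinous tip is unidentifiable
#' and L12 is missing.
#'
#' @param nPatients number of patients.
#' @param seed RNG seed.
#' @param severityCounts named integer vector (mild, medium, strong);
#'   recycled/truncated to \code{nPatients}.
#' @param regionCounts named integer vector (thoracic, thoraco-lumbar,
#'   lumbar, combined).
#' @param missingL12Rate probability that a level has no identifiable
#'   spinous tip.
#' @return list of patient records as consumed by
#'   \code{\link{aggregateLevels}}.
#' @export
simulateCohort <- function(nPatients = 20L, seed = 1L,
                           severityCounts = c(mild = 4L, medium = 10L,
                                              strong = 6L),
                           regionCounts = c(thoracic = 4L,
                                            `thoraco-lumbar` = 3L,
                                            lumbar = 10L, combined = 3L),
                           missingL12Rate = 0.05) {
  set.seed(as.integer(seed))
  sev <- rep(rep(names(severityCounts), severityCounts),
             length.out = nPatients)
  reg <- rep(rep(names(regionCounts), regionCounts),
             length.out = nPatients)
  levels <- c(paste0("T", 1:12), paste0("L", 1:5))
  idx <- levelIndex(levels)
  # physiological level trend for L12: minimum near T7, mm
  base12 <- 55 + 0.55 * (idx - levelIndex("T7"))^2 * 0.2
  base12 <- pmin(base12, 73)
  sdWide <- c(mild = 4, medium = 8, strong = 12)
  apexPool <- list(thoracic = paste0("T", c(6:10)),
                   `thoraco-lumbar` = c("T12", "L1"),
                   lumbar = paste0("L", 2:4))
  regionLevels <- list(thoracic = paste0("T", 2:11),
                       `thoraco-lumbar` = c("T12", "L1"),
                       lumbar = paste0("L", 2:5))
  records <- vector("list", nPatients)
  for (i in seq_len(nPatients)) {
    s <- sev[i]; r <- reg[i]
    gender <- if (i %% 2L == 0L) "female" else "male"
    cobb <- switch(s, mild = stats::runif(1, 10, 19.5),
                   medium = stats::runif(1, 20, 40),
                   strong = stats::runif(1, 40.5, 75))
    if (r == "combined") {
      curves <- data.frame(
        angle = c(cobb, max(10, cobb - stats::runif(1, 2, 10))),
        apex = c(sample(apexPool$thoracic, 1L),
                 sample(apexPool$lumbar, 1L)))
    } else {
      curves <- data.frame(angle = cobb, apex = sample(apexPool[[r]], 1L))
    }
    lev <- if (stats::runif(1) < 0.33) c("C7", levels) else levels
    ii <- levelIndex(lev)
    b12 <- c(57, base12)[match(ii, c(levelIndex("C7"), idx))]
    L12 <- b12 + stats::rnorm(length(lev), 0, 3)
    tissue <- stats::runif(1, 10, 25)
    # curve-region levels of the patient carry the severity-scaled
    # extra scatter of the skin distance
    inCurve <- if (r == "combined")
      lev %in% c(regionLevels$thoracic, regionLevels$lumbar) else
      lev %in% regionLevels[[r]]
    L13 <- L12 + tissue + stats::rnorm(length(lev), 0, 2) +
      ifelse(inCurve, stats::rnorm(length(lev), 0, sdWide[[s]]), 0)
    L13 <- pmax(L13, L12 + 1)
    miss <- stats::runif(length(lev)) < missingL12Rate
    L12[miss] <- NA_real_
    records[[i]] <- list(
      patient_id = sprintf("P%02d", i), gender = gender,
      curves = curves,
      measurements = data.frame(level = lev, L12_mm = L12,
                                L13_mm = L13, stringsAsFactors = FALSE))
  }
  records
}

#' Read a cohort metadata table
#'
#' @param path CSV with columns \code{patient_id}, \code{gender},
#'   \code{curves}; curves encoded as \code{"angle@apex;angle@apex"}.
#' @return list of records (without measurements).
#' @export
readCohortMeta <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  lapply(seq_len(nrow(meta)), function(i) {
    parts <- strsplit(meta$curves[i], ";", fixed = TRUE)[[1L]]
    av <- strsplit(parts, "@", fixed = TRUE)
    list(patient_id = as.character(meta$patient_id[i]),
         gender = meta$gender[i],
         curves = data.frame(
           angle = vapply(av, function(p) as.numeric(p[1L]), numeric(1L)),
           apex = vapply(av, `[`, character(1L), 2L),
           stringsAsFactors = FALSE),
         measurements = NULL)
  })
}

#' Write a cohort metadata table
#'
#' @param records list of patient records.
#' @param path output CSV path.
#' @export
writeCohortMeta <- function(records, path) {
  meta <- data.frame(
    patient_id = vapply(records, `[[`, character(1L), "patient_id"),
    gender = vapply(records, `[[`, character(1L), "gender"),
    curves = vapply(records, function(r)
      paste(sprintf("%.6g@%s", r$curves$angle, r$curves$apex),
            collapse = ";"), character(1L)))
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
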