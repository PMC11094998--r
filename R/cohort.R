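#' Vertebral level labels in cranio-caudal order
#'
#' @return character vector C7, T1..T12, L1..L5.
#' @export
vertebralLevels <- function() c("C7", paste0("T", 1:12), paste0("L", 1:5))

levelIndex <- function(level) {
  i <- match(level, vertebralLevels())
  if (anyNA(i)) stop("unknown vertebral level: ",
                     paste(level[is.na(i)], collapse = ", "))
  i
}

# Region of a single apex level, or NA for C7/T1.
apexRegion <- function(apex) {
  i <- levelIndex(apex)
  ifelse(i >= levelIndex("T2") & i <= levelIndex("T11"), "thoracic",
  ifelse(i %in% levelIndex(c("T12", "L1")), "thoraco-lumbar",
  ifelse(i >= levelIndex("L2"), "lumbar", NA_character_)))
}

#' Classify scoliosis severity from the Cobb angle
#'
#' Severity classes follow the conventional Cobb-angle grading: mild
#' below 20 degrees, strong above 40 degrees, and medium for everything
#' in between (the boundary values 20 and 40 are medium).
#'
#' @param maxCobbDeg largest Cobb angle of the patient, degrees (>= 0).
#' @return one of "mild", "medium", "strong"; vectorized.
#' @examples
#' classifySeverity(c(15, 20, 40, 41))
#' @export
classifySeverity <- function(maxCobbDeg) {
  if (any(maxCobbDeg < 0)) stop("Cobb angle must be non-negative")
  ifelse(maxCobbDeg < 20, "mild",
         ifelse(maxCobbDeg > 40, "strong", "medium"))
}

#' Classify the affected spinal region from curve apexes
#'
#' The region is decided by the apex of the main curve (the one with
#' the largest Cobb angle; ties break toward the more cranial apex):
#' thoracic for an apex between T2 and T11, thoraco-lumbar around T12
#' and L1, lumbar from L2 to L5. When the recorded curves contain both
#' a thoracic-range and a lumbar-range apex the deformity is combined;
#' thoraco-lumbar apexes do not trigger "combined" on their own.
#'
#' @param curves data.frame with columns \code{angle} (deg) and
#'   \code{apex} (level label), one row per curve.
#' @return one of "thoracic", "thoraco-lumbar", "lumbar", "combined".
#' @examples
#' classifyRegion(data.frame(angle = c(30, 28), apex = c("T7", "L3")))
#' @export
classifyRegion <- function(curves) {
  if (nrow(curves) == 0L) stop("at least one curve is required")
  regions <- apexRegion(curves$apex)
  if (any(regions %in% "thoracic") && any(regions %in% "lumbar"))
    return("combined")
  ord <- order(-curves$angle, levelIndex(curves$apex))
  main <- regions[ord[1L]]
  if (is.na(main))
    stop("unclassifiable region: main apex ", curves$apex[ord[1L]],
         " outside T2-L5")
  main
}

groupOfRecord <- function(record, grouping) {
  switch(grouping,
         none = "all",
         gender = record$gender,
         severity = classifySeverity(max(record$curves$angle)),
         region = classifyRegion(record$curves),
         stop("unknown grouping: ", grouping))
}

meanSD <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  c(n = n,
    mean = if (n >= 1L) mean(x) else NA_real_,
    sd = if (n >= 2L) stats::sd(x) else NA_real_)
}

#' Aggregate per-vertebra measurements into a per-level cohort table
#'
#' For every group under the chosen grouping and every vertebral level
#' measured, computes the count, arithmetic mean and sample standard
#' deviation (n - 1 denominator) of the body-to-spinous distance L12
#' and the body-to-skin distance L13. Missing L12 values (no
#' identifiable spinous tip) are excluded from both the mean and the
#' count.
#'
#' @param records list of patient records; each a list with
#'   \code{patient_id}, \code{gender}, \code{curves} (data.frame
#'   \code{angle}, \code{apex}) and \code{measurements} (data.frame
#'   with at least \code{level}, \code{L12_mm}, \code{L13_mm}).
#' @param grouping one of "severity", "region", "gender", "none".
#' @return a \linkS4class{CohortTable} with one row per group x level.
#' @export
aggregateLevels <- function(records, grouping = c("none", "severity",
                                                  "region", "gender")) {
  grouping <- match.arg(grouping)
  if (length(records) == 0L) stop("at least one patient record required")
  groups <- vapply(records, groupOfRecord, character(1L),
                   grouping = grouping)
  rows <- list()
  for (g in unique(groups)) {
    meas <- do.call(rbind, lapply(records[groups == g],
                                  function(r) r$measurements))
    for (lev in vertebralLevels()) {
      m <- meas[meas$level == lev, , drop = FALSE]
      if (nrow(m) == 0L) next
      s12 <- meanSD(m$L12_mm); s13 <- meanSD(m$L13_mm)
      if (s13[["n"]] == 0L && s12[["n"]] == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, row = lev, rowType = "level",
        nL12 = as.integer(s12[["n"]]), meanL12 = s12[["mean"]],
        sdL12 = s12[["sd"]],
        nL13 = as.integer(s13[["n"]]), meanL13 = s13[["mean"]],
        sdL13 = s13[["sd"]], stringsAsFactors = FALSE)
    }
  }
  new("CohortTable", table = do.call(rbind, rows), grouping = grouping)
}

# Pool per-level cells (counts, means, sample SDs) into one cell over
# all underlying (patient, level) values: the pooled mean is the
# count-weighted mean and the pooled sum of squares recombines the
# within-cell and between-cell parts.
poolCells <- function(n, m, s) {
  keep <- n > 0L
  n <- n[keep]; m <- m[keep]; s <- s[keep]
  N <- sum(n)
  if (N == 0L) return(c(n = 0, mean = NA_real_, sd = NA_real_))
  M <- sum(n * m) / N
  ss <- sum(ifelse(n >= 2L, (n - 1) * s^2, 0) + n * (m - M)^2)
  c(n = N, mean = M,
    sd = if (N >= 2L) sqrt(ss / (N - 1)) else NA_real_)
}

#' Append regional mean/SD rows to a per-level cohort table
#'
#' Adds, per group, the pooled rows "T2...T11", "T12/L1", "L2...L5" and
#' "all" (every measured level, including C7 and T1 when present).
#' Pooling is over all underlying (patient, level) values, not over
#' per-level means, recombined exactly from the per-level counts,
#' means and sample SDs.
#'
#' @param table a per-level \linkS4class{CohortTable} from
#'   \code{\link{aggregateLevels}}.
#' @return the table with regional rows appended (rowType "region").
#' @export
regionalMeans <- function(table) {
  tab <- table@table[table@table$rowType == "level", , drop = FALSE]
  regions <- list("all" = vertebralLevels(),
                  "T2...T11" = paste0("T", 2:11),
                  "T12/L1" = c("T12", "L1"),
                  "L2...L5" = paste0("L", 2:5))
  rows <- list()
  for (g in unique(tab$group)) {
    tg <- tab[tab$group == g, , drop = FALSE]
    for (rn in names(regions)) {
      sel <- tg[tg$row %in% regions[[rn]], , drop = FALSE]
      if (nrow(sel) == 0L) next
      p12 <- poolCells(sel$nL12, sel$meanL12, sel$sdL12)
      p13 <- poolCells(sel$nL13, sel$meanL13, sel$sdL13)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, row = rn, rowType = "region",
        nL12 = as.integer(p12[["n"]]), meanL12 = p12[["mean"]],
        sdL12 = p12[["sd"]],
        nL13 = as.integer(p13[["n"]]), meanL13 = p13[["mean"]],
        sdL13 = p13[["sd"]], stringsAsFactors = FALSE)
    }
  }
  new("CohortTable",
      table = rbind(table@table[table@table$rowType == "level", ,
                                drop = FALSE],
                    do.call(rbind, rows)),
      grouping = table@grouping)
}

regionCell <- function(tab, g, rn, col) {
  v <- tab[tab$group == g & tab$row == rn & tab$rowType == "region",
           col]
  if (length(v) == 0L) NA_real_ else v
}

poolLevels <- function(tab, g, levels, pre) {
  sel <- tab[tab$group == g & tab$rowType == "level" &
               tab$row %in% levels, , drop = FALSE]
  if (nrow(sel) == 0L) return(NA_real_)
  poolCells(sel[[paste0("n", pre)]], sel[[paste0("mean", pre)]],
            sel[[paste0("sd", pre)]])[["mean"]]
}

#' Qualitative findings report over cohort tables
#'
#' Evaluates, as a diagnostics report (no hypothesis tests), the
#' descriptive regularities expected of transverse vertebral
#' morphometry: per severity group, (i) whether the across-patient
#' variation of the body-to-skin distance exceeds that of the
#' body-to-spinous distance, SD(L13) > SD(L12) over all levels;
#' (ii) whether SD(L13) increases from mild through medium to strong;
#' (iii) whether the upper-thoracic rise is more pronounced for L13
#' than L12, i.e. mean L12(T1..T4)/mean L12(T5..T9) < mean
#' L13(T1..T4)/mean L13(T5..T9); and per curve-region group (iv) which
#' of the three spinal regions carries the maximal SD(L13) and whether
#' it coincides with the classified curve region.
#'
#' @param severityTable \linkS4class{CohortTable} grouped by severity,
#'   with regional rows (\code{\link{regionalMeans}} applied).
#' @param regionTable \linkS4class{CohortTable} grouped by curve
#'   region, with regional rows; optional.
#' @return nested list of booleans/values; entries that cannot be
#'   evaluated (missing groups) are \code{NA}.
#' @export
findingsReport <- function(severityTable, regionTable = NULL) {
  st <- severityTable@table
  sevs <- c("mild", "medium", "strong")
  sdGt <- sapply(sevs, function(g) {
    s13 <- regionCell(st, g, "all", "sdL13")
    s12 <- regionCell(st, g, "all", "sdL12")
    # relative guard so exact ties are not decided by rounding noise
    if (is.na(s13) || is.na(s12)) NA else
      s13 - s12 > 1e-9 * (s13 + s12)
  }, simplify = FALSE)
  sd13 <- vapply(sevs, function(g) regionCell(st, g, "all", "sdL13"),
                 numeric(1L))
  ordering <- if (anyNA(sd13)) NA else
    sd13[["mild"]] < sd13[["medium"]] && sd13[["medium"]] < sd13[["strong"]]
  upper <- paste0("T", 1:4); mid <- paste0("T", 5:9)
  ratio <- sapply(sevs, function(g) {
    r12 <- poolLevels(st, g, upper, "L12") / poolLevels(st, g, mid, "L12")
    r13 <- poolLevels(st, g, upper, "L13") / poolLevels(st, g, mid, "L13")
    if (is.na(r12) || is.na(r13)) NA else r12 < r13
  }, simplify = FALSE)
  out <- list(sd_L13_gt_sd_L12 = sdGt,
              sd_L13_ordered_by_severity = ordering,
              upper_thoracic_rise_stronger_for_L13 = ratio)
  if (!is.null(regionTable)) {
    rt <- regionTable@table
    regionRow <- c(thoracic = "T2...T11", `thoraco-lumbar` = "T12/L1",
                   lumbar = "L2...L5")
    maxSD <- sapply(names(regionRow), function(g) {
      v <- vapply(unname(regionRow), function(rn)
        regionCell(rt, g, rn, "sdL13"), numeric(1L))
      names(v) <- names(regionRow)
      if (all(is.na(v))) NA_character_ else names(v)[which.max(v)]
    }, simplify = FALSE)
    out$max_sd_region <- maxSD
    out$max_sd_matches_curve_region <- lapply(names(regionRow),
      function(g) if (is.na(maxSD[[g]])) NA else maxSD[[g]] == g)
    names(out$max_sd_matches_curve_region) <- names(regionRow)
  }
  out
}
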