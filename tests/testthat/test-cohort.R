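test_that("severity classification follows the Cobb-angle boundaries", {
  expect_identical(classifySeverity(15), "mild")
  expect_identical(classifySeverity(19.9), "mild")
  expect_identical(classifySeverity(20), "medium")
  expect_identical(classifySeverity(40), "medium")
  expect_identical(classifySeverity(41), "strong")
  expect_error(classifySeverity(-1), "non-negative")
  # monotone in the angle under mild < medium < strong
  ord <- c(mild = 1L, medium = 2L, strong = 3L)
  a <- seq(0, 80, by = 0.5)
  expect_true(all(diff(ord[classifySeverity(a)]) >= 0))
})

test_that("curve-region classification follows the apex ranges", {
  expect_identical(classifyRegion(data.frame(angle = 50, apex = "T8")),
                   "thoracic")
  expect_identical(classifyRegion(data.frame(angle = 35, apex = "T12")),
                   "thoraco-lumbar")
  expect_identical(classifyRegion(data.frame(angle = 35, apex = "L1")),
                   "thoraco-lumbar")
  expect_identical(classifyRegion(data.frame(angle = 30, apex = "L3")),
                   "lumbar")
  expect_identical(classifyRegion(
    data.frame(angle = c(30, 28), apex = c("T7", "L3"))), "combined")
  # thoraco-lumbar apexes alone never yield combined
  expect_identical(classifyRegion(
    data.frame(angle = c(30, 25), apex = c("T12", "L1"))),
    "thoraco-lumbar")
  # main curve = largest angle; cranial tie-break
  expect_identical(classifyRegion(
    data.frame(angle = c(20, 35), apex = c("T5", "T12"))),
    "thoraco-lumbar")
  expect_identical(classifyRegion(
    data.frame(angle = c(30, 30), apex = c("T12", "T4"))), "thoracic")
  expect_error(classifyRegion(data.frame(angle = 25, apex = "C7")),
               "unclassifiable")
})

mkRecord <- function(id, levels, L12, L13, angle = 30, apex = "T8",
                     gender = "female") {
  list(patient_id = id, gender = gender,
       curves = data.frame(angle = angle, apex = apex),
       measurements = data.frame(level = levels, L12_mm = L12,
                                 L13_mm = L13, stringsAsFactors = FALSE))
}

test_that("per-level aggregation: hand-checked means, SDs and missing exclusion", {
  recs <- list(mkRecord("a", "T5", 62, 62),
               mkRecord("b", "T5", NA, 58),
               mkRecord("c", "T5", 60, 60))
  tab <- cohortSummary(aggregateLevels(recs, "none"))
  row <- tab[tab$row == "T5", ]
  expect_equal(row$meanL13, 60)
  expect_equal(row$sdL13, 2)
  expect_identical(row$nL12, 2L)         # missing L12 excluded
  expect_equal(row$meanL12, 61)
  # single value: mean = value, SD undefined
  one <- cohortSummary(aggregateLevels(list(mkRecord("a", "L2", 70, 85)),
                                       "none"))
  expect_equal(one$meanL13, 85)
  expect_true(is.na(one$sdL13))
  expect_identical(one$nL13, 1L)
})

test_that("regional pooling is over raw (patient, level) values", {
  recs <- list(mkRecord("a", c("T12", "L1"), c(60, 60), c(60, 60)),
               mkRecord("b", c("T12", "L1"), c(80, 80), c(80, 80)))
  tab <- regionalMeans(aggregateLevels(recs, "none"))
  row <- cohortSummary(tab)
  tl <- row[row$row == "T12/L1", ]
  expect_equal(tl$meanL13, 70)
  expect_equal(tl$sdL13, sd(c(60, 60, 80, 80)))  # 11.547
  # single patient constant over T2..T11
  rec <- mkRecord("c", paste0("T", 2:11), rep(70, 10), rep(70, 10))
  r2 <- cohortSummary(regionalMeans(aggregateLevels(list(rec), "none")))
  th <- r2[r2$row == "T2...T11", ]
  expect_equal(th$meanL13, 70)
  expect_equal(th$sdL13, 0)
})

test_that("duplicating a patient preserves means and doubles counts", {
  recs <- simulateCohort(6, seed = 3)
  tab1 <- cohortSummary(aggregateLevels(recs, "severity"))
  tab2 <- cohortSummary(aggregateLevels(c(recs, recs), "severity"))
  m <- merge(tab1, tab2, by = c("group", "row"))
  expect_equal(m$meanL13.x, m$meanL13.y)
  expect_equal(m$meanL12.x, m$meanL12.y)
  expect_identical(m$nL13.y, 2L * m$nL13.x)
})

test_that("aggregation agrees with a brute-force recomputation", {
  for (s in 1:10) {
    recs <- simulateCohort(sample(4:12, 1), seed = s,
                           missingL12Rate = 0.2)
    for (grouping in c("none", "severity", "gender")) {
      tab <- cohortSummary(aggregateLevels(recs, grouping))
      bf <- bruteForceTable(recs, grouping)
      for (key in names(bf)) {
        b <- bf[[key]]
        row <- tab[tab$group == b$group & tab$row == b$level, ]
        expect_identical(nrow(row), 1L)
        expect_identical(row$nL12, b$n12)
        expect_equal(row$meanL13, b$m13, tolerance = 1e-12)
        expect_equal(row$sdL13, b$s13, tolerance = 1e-12)
        expect_equal(row$sdL12, b$s12, tolerance = 1e-12)
      }
    }
  }
})

test_that("regional rows agree with brute-force pooling of raw values", {
  recs <- simulateCohort(10, seed = 21, missingL12Rate = 0.15)
  tab <- cohortSummary(regionalMeans(aggregateLevels(recs, "severity")))
  for (rn in list(c("T2...T11", paste0("T", 2:11)),
                  c("L2...L5", paste0("L", 2:5)))) {
    bf <- bruteForceRegion(recs, "severity", rn[-1])
    for (g in names(bf)) {
      row <- tab[tab$group == g & tab$row == rn[1], ]
      expect_equal(row$meanL13, bf[[g]]$m13, tolerance = 1e-12)
      expect_equal(row$sdL13, bf[[g]]$s13, tolerance = 1e-12)
      expect_equal(row$sdL12, bf[[g]]$s12, tolerance = 1e-12)
    }
  }
})

test_that("findings report flags constructed equalities and orderings", {
  # L13 = L12 + constant per patient => SD(L13) == SD(L12), not greater
  lv <- paste0("T", 2:11)
  recs <- lapply(1:6, function(i) {
    x <- rnorm(10, 55, 4)
    mkRecord(paste0("p", i), lv, x, x + 20,
             angle = c(15, 30, 30, 30, 50, 50)[i])
  })
  tabs <- regionalMeans(aggregateLevels(recs, "severity"))
  rep1 <- findingsReport(tabs)
  expect_false(rep1$sd_L13_gt_sd_L12$medium)
  # extra L13 scatter confined to each group's own curve region puts
  # the max SD in the matching regional rows (generator-controlled)
  regionLv <- list(thoracic = paste0("T", 2:11),
                   `thoraco-lumbar` = c("T12", "L1"),
                   lumbar = paste0("L", 2:5))
  apexes <- c(thoracic = "T8", `thoraco-lumbar` = "T12", lumbar = "L3")
  allLv <- c(paste0("T", 1:12), paste0("L", 1:5))
  recs2 <- unlist(lapply(names(apexes), function(rg)
    lapply(1:4, function(i) {
      L13 <- rep(80, length(allLv)) +
        ifelse(allLv %in% regionLv[[rg]], i * 8, i * 0.5)
      mkRecord(paste0(rg, i), allLv, rep(60, length(allLv)), L13,
               angle = 45 + i, apex = apexes[[rg]])
    })), recursive = FALSE)
  rtab <- regionalMeans(aggregateLevels(recs2, "region"))
  rep2 <- findingsReport(regionalMeans(aggregateLevels(recs2, "severity")),
                         rtab)
  expect_identical(rep2$max_sd_region,
                   list(thoracic = "thoracic",
                        `thoraco-lumbar` = "thoraco-lumbar",
                        lumbar = "lumbar"))
  expect_true(all(unlist(rep2$max_sd_matches_curve_region)))
  # deterministic on identical inputs
  expect_identical(rep2,
                   findingsReport(
                     regionalMeans(aggregateLevels(recs2, "severity")),
                     rtab))
})

test_that("cohort metadata round-trips through CSV", {
  recs <- simulateCohort(5, seed = 2)
  path <- tempfile(fileext = ".csv")
  writeCohortMeta(recs, path)
  back <- readCohortMeta(path)
  expect_identical(vapply(back, `[[`, character(1), "patient_id"),
                   vapply(recs, `[[`, character(1), "patient_id"))
  expect_equal(back[[3]]$curves$angle, recs[[3]]$curves$angle,
               tolerance = 1e-5)
  expect_identical(back[[3]]$curves$apex, recs[[3]]$curves$apex)
})
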