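test_that("category rubric lookups are deterministic and boundary-correct", {
  expect_equal(scoreCategory("necrosis", 0), 0L)
  expect_equal(scoreCategory("necrosis", 5), 1L)
  expect_equal(scoreCategory("necrosis", 20), 2L)
  expect_equal(scoreCategory("necrosis", 45), 3L)
  # boundary percentages take the higher score
  expect_equal(scoreCategory("necrosis", 10), 2L)
  expect_equal(scoreCategory("necrosis", 30), 3L)
  expect_equal(scoreCategory("neutrophil", "none"), 0L)
  expect_equal(scoreCategory("neutrophil", "sparse-focal"), 1L)
  expect_equal(scoreCategory("neutrophil", "diffuse"), 3L)
  expect_equal(scoreCategory("congestion", "moderate"), 2L)
  expect_equal(scoreCategory("oedema", "severe"), 3L)
  # most severe observation wins across multiple fields
  expect_equal(scoreCategory("necrosis", c(5, 25, 8)), 2L)
  expect_equal(scoreCategory("oedema", c("none", "moderate", "mild")), 2L)
  expect_error(scoreCategory("necrosis", 120), "percentage")
  expect_error(scoreCategory("oedema", "weird"), "unknown")
})

test_that("composite score is the category sum with a ceiling of 12", {
  expect_equal(compositeScore(c(0, 0, 0, 0)), 0)
  expect_equal(compositeScore(c(3, 3, 3, 3)), 12)
  expect_equal(compositeScore(c(2.9, 3, 3, 3)), 11.9)
  expect_error(compositeScore(c(4, 0, 0, 0)), "\\[0, 3\\]")
  expect_error(compositeScore(c(1, 1, 1)), "four")
})

test_that("group summaries reproduce the reference composite means by linearity", {
  ref <- histologyReferenceMeans()
  # composite mean = sum of category means, for every reference row
  comps <- apply(ref[, c("neutrophil", "necrosis", "congestion", "oedema")],
                 1, compositeScore)
  expect_equal(comps, c(6.3, 6.6, 8.4, 11.9))
  # simulated biopsies at zero jitter recover the stated means at large n
  tab <- simulateHistology(ref, dispersion = 0, nBiopsies = 2000, seed = 9)
  s <- summarizeGroups(tab)
  key <- paste(s$group, s$timepoint)
  comp <- s$composite_mean[match(paste(ref$group, ref$timepoint), key)]
  expect_equal(comp, comps, tolerance = 0.03)
  # linearity: mean of composites equals sum of category means exactly
  expect_equal(s$composite_mean,
               rowSums(s[, c("neutrophil", "necrosis", "congestion", "oedema")]))
  # single record: means equal that record
  one <- tab[1, ]
  s1 <- summarizeGroups(one)
  expect_equal(s1$composite_mean, one$composite)
  expect_error(summarizeGroups(tab[0, ]), "non-empty")
})

test_that("group comparison: t test with normality and variance diagnostics", {
  mk <- function(g, tp, comps) data.frame(
    group = g, timepoint = tp, biopsy_id = seq_along(comps),
    neutrophil = 0L, necrosis = 0L, congestion = 0L, oedema = 0L,
    composite = comps)
  # identical groups: t = 0, p = 1
  same <- rbind(mk("A", "30 min", c(4, 6, 5, 7)), mk("B", "30 min", c(4, 6, 5, 7)))
  r <- compareGroups(same, "30 min")
  expect_equal(r$t, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)
  expect_true(all(is.finite(r$shapiro_p)))
  # one record per group: error
  expect_error(compareGroups(rbind(mk("A", "30 min", 5), mk("B", "30 min", 9)),
                             "30 min"), "two records")
  # power: 3-point separation, sd 0.5, n = 4 detects the difference
  set.seed(17)
  hits <- mean(replicate(400, {
    tab <- rbind(mk("A", "30 min", rnorm(4, 8.5, 0.5)),
                 mk("B", "30 min", rnorm(4, 11.5, 0.5)))
    compareGroups(tab, "30 min")$p < 0.05
  }))
  expect_gte(hits, 0.95)
})

test_that("histology CSV round-trips and validates the composite invariant", {
  tab <- simulateHistology(dispersion = 0.3, nBiopsies = 3, seed = 2)
  expect_true(all(tab$composite ==
                  rowSums(tab[, c("neutrophil", "necrosis", "congestion",
                                  "oedema")])))
  f <- tempfile(fileext = ".csv")
  writeHistologyCsv(tab, f)
  back <- readHistologyCsv(f)
  expect_equal(back$composite, tab$composite)
  bad <- tab
  bad$composite[1] <- bad$composite[1] + 1
  fb <- tempfile(fileext = ".csv")
  writeHistologyCsv(bad, fb)
  expect_error(readHistologyCsv(fb), "composite")
})
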