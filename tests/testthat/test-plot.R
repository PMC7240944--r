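plotFixture <- function() {
  fs <- FeatureSet(data.frame(
    feature_id = c("f1", "f2", "f3"), mz = c(148.06, 170.04, 500.1),
    rt = c(114, 114, 600), p_value = 0.01,
    mid = c(100, 50, 10), late = c(300, 80, 10),
    stationary = c(150, 60, 10)))
  m <- mzFBA:::normalizeMatches(data.frame(
    compound_name = "L-Glutamate", feature_id = c("f1", "f2"),
    observed_mz = c(148.06, 170.04), rt = 114,
    adduct = c("[M+H]+", "[M+Na]+"), ppm_error = 0.1,
    source = "pyfba_model"))
  list(fs = fs, m = m)
}

test_that("3D scatter sidecar has two points per feature with the phase deltas", {
  fx <- plotFixture()
  path <- tempfile(fileext = ".png")
  side <- plotMatches3D(fx$fs, fx$m, which = "matched", path = path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".tsv")))
  expect_equal(nrow(side), 4L)            # 2 matched features x 2 contrasts
  d <- phaseDeltas(fx$fs)
  lm <- side[side$contrast == "late_minus_mid", ]
  expect_equal(lm$delta[match(c("f1", "f2"), lm$feature_id)],
               d$late_minus_mid[match(c("f1", "f2"), d$feature_id)])
  sl <- side[side$contrast == "stationary_minus_late", ]
  expect_equal(sl$delta[match("f1", sl$feature_id)], -150)
  # sidecar on disk equals the returned coordinates
  back <- read.delim(paste0(path, ".tsv"))
  expect_equal(back$delta, side$delta)
})

test_that("unmatched selection of a fully matched set is empty but plots", {
  fx <- plotFixture()
  fully <- fx$fs
  fully@features <- fully@features[1:2, ]
  path <- tempfile(fileext = ".png")
  expect_warning(side <- plotMatches3D(fully, fx$m, "unmatched", path),
                 "nothing to plot")
  expect_equal(nrow(side), 0L)
  expect_true(file.exists(path))
  all3 <- plotMatches3D(fx$fs, NULL, "all", tempfile(fileext = ".png"))
  expect_equal(nrow(all3), 6L)
})

test_that("phase box plot sidecar carries the five-number summaries", {
  set.seed(8)
  reps <- list(mid = 1e4 + rnorm(5, 0, 100), late = 5e4 + rnorm(5, 0, 100),
               stationary = 2e4 + rnorm(5, 0, 100))
  path <- tempfile(fileext = ".png")
  side <- plotPhaseBoxplot(reps, path, feature_id = "M148T115")
  expect_equal(side$phase, c("mid", "late", "stationary"))
  expect_equal(side$median, vapply(reps, median, 0)[side$phase],
               ignore_attr = TRUE)
  # rise then fall, as for a metabolite produced then consumed
  expect_gt(side$median[2], side$median[1])
  expect_lt(side$median[3], side$median[2])
  # one replicate per phase collapses the summary to the value
  one <- plotPhaseBoxplot(list(mid = 5, late = 6, stationary = 4),
                          tempfile(fileext = ".png"))
  expect_true(all(one$min == one$max))
  expect_error(plotPhaseBoxplot(list(mid = 1, late = 2,
                                     stationary = numeric(0)),
                                tempfile(fileext = ".png")), "stationary")
})
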