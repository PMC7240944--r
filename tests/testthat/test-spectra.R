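toyScans <- function() {
  list(
    list(rt = 110, mz = c(100.5, 148.0604, 149.0638),
         intensity = c(10, 1e5, 5.9e3)),
    list(rt = 112, mz = c(148.0604, 149.0638), intensity = c(9e4, 5.4e3)),
    list(rt = 114, mz = c(148.0604, 149.0638), intensity = c(1.1e5, 6.5e3)),
    list(rt = 150, mz = c(300.1, 301.1), intensity = c(5e3, 100)),
    list(rt = 200, mz = 500.25, intensity = 2e3))
}

test_that("hand-written mzXML round-trips through the reader", {
  path <- tempfile(fileext = ".mzXML")
  writeMzXML(toyScans(), path, polarity = "positive")
  sp <- readSpectra(path, "positive")
  expect_s4_class(sp, "SpectrumCollection")
  expect_equal(length(sp), 5L)
  expect_equal(polarity(sp), "positive")
  near <- nearestScans(sp, 114)
  expect_equal(length(near), 1L)
  scan <- near[[1]][[1]]
  expect_equal(scan$rt, 114)
  expect_equal(scan$mz, c(148.0604, 149.0638), tolerance = 1e-4)
  expect_equal(scan$intensity, c(1.1e5, 6.5e3), tolerance = 1e-3)
})

test_that("mzML and mzXML encodings of the same scans agree", {
  p1 <- tempfile(fileext = ".mzXML")
  p2 <- tempfile(fileext = ".mzML")
  writeMzXML(toyScans(), p1, polarity = "positive")
  writeMzML(toyScans(), p2, polarity = "positive")
  a <- readSpectra(p1, "positive")
  b <- readSpectra(p2, "positive")
  expect_equal(length(a), length(b))
  for (i in seq_len(length(a))) {
    # mzXML stores 32-bit floats, mzML 64-bit: agreement to float precision
    expect_equal(a@scans[[i]]$mz, b@scans[[i]]$mz, tolerance = 1e-6)
    expect_equal(a@scans[[i]]$intensity, b@scans[[i]]$intensity,
                 tolerance = 1e-6)
    expect_equal(a@rt[i], b@rt[i], tolerance = 1e-3)
  }
})

test_that("files without MS1 scans are rejected", {
  path <- tempfile(fileext = ".mzXML")
  writeMzXML(toyScans()[1:2], path, polarity = "positive", ms_level = 2L)
  expect_error(readSpectra(path, "positive"), "no MS1")
  expect_error(readSpectra(tempfile(fileext = ".mzXML"), "positive"),
               "not found")
})

test_that("nearest-scan query minimizes RT distance (vs linear scan)", {
  path <- tempfile(fileext = ".mzXML")
  set.seed(5)
  rts <- round(sort(runif(40, 0, 1000)), 3)  # writer stores RT to 0.1 ms
  scans <- lapply(rts, function(t)
    list(rt = t, mz = 100 + t / 1000, intensity = 1))
  writeMzXML(scans, path, polarity = "positive")
  sp <- readSpectra(path, "positive")
  for (q in runif(20, 0, 1000)) {
    got <- nearestScans(sp, q, n = 1, rt_radius = Inf)[[1]][[1]]$rt
    expect_equal(abs(got - q), min(abs(rts - q)), tolerance = 1e-6)
  }
  # radius excludes far queries entirely
  expect_length(nearestScans(sp, max(rts) + 100, rt_radius = 30), 0L)
})

test_that("multiple files become samples keyed by file name", {
  p1 <- file.path(tempdir(), "repA.mzXML")
  p2 <- file.path(tempdir(), "repB.mzXML")
  writeMzXML(toyScans()[1:3], p1)
  writeMzXML(toyScans()[1:3], p2)
  sp <- readSpectra(c(p1, p2), "positive")
  expect_setequal(unique(sp@sample_id), c("repA", "repB"))
  near <- nearestScans(sp, 112, n = 2)
  expect_setequal(names(near), c("repA", "repB"))
  expect_equal(length(near$repA), 2L)
})

test_that("windowed intensity sums what falls inside the ppm window", {
  scan <- list(mz = c(148.0604, 148.0630, 149.0638),
               intensity = c(1e5, 2e4, 5.9e3))
  expect_equal(windowIntensity(scan, 148.0604, ppm = 5), 1e5)    # 26 mDa away: out
  expect_equal(windowIntensity(scan, 148.0617, ppm = 10), 1.2e5) # both inside
  expect_equal(windowIntensity(scan, 200, ppm = 5), 0)
})
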