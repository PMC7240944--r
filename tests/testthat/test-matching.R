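mkFeatures <- function(mz, rt = seq_along(mz) * 100, p = 0.01) {
  FeatureSet(data.frame(
    feature_id = sprintf("f%02d", seq_along(mz)), mz = mz, rt = rt,
    p_value = rep_len(p, length(mz)), mid = rep(1, length(mz)),
    late = rep(2, length(mz)), stationary = rep(1.5, length(mz))))
}

test_that("significance filter is strict and order-preserving", {
  fs <- mkFeatures(c(100, 200, 300), p = 1)
  fs@features$p_value <- c(0.01, 0.05, 0.2)
  kept <- filterSignificant(fs, 0.05)
  expect_equal(features(kept)$feature_id, "f01")   # 0.05 itself excluded
  expect_equal(length(filterSignificant(fs, 1.0)), 3L)
  expect_equal(length(filterSignificant(mkFeatures(numeric(0)))), 0L)
  fs2 <- mkFeatures(c(1, 2, 3) * 100)
  fs2@features$p_value <- c(0.04, 0.001, 0.03)
  expect_equal(features(filterSignificant(fs2))$feature_id,
               c("f01", "f02", "f03"))
})

test_that("detectability filter removes small inorganics, keeps metabolites", {
  cs <- CompoundSet(data.frame(
    compound_id = c("co2", "nh3", "glc", "fe", "big"),
    name = c("CO2", "NH3", "D-Glucose", "iron-ish", "polymer"),
    formula = c("CO2", "NH3", "C6H12O6", "FeH2O", "C70H120N10O30")))
  kept <- compounds(filterDetectableCompounds(cs))
  expect_setequal(kept$compound_id, "glc")  # CO2/NH3 below range, Fe no C, big over
  # carbon requirement can be lifted
  kept2 <- compounds(filterDetectableCompounds(cs, require_carbon = FALSE))
  expect_true("fe" %in% kept2$compound_id)
  # Ca/Cl two-letter symbols don't count as carbon
  cs2 <- CompoundSet(data.frame(compound_id = "cacl", name = "salt",
                                formula = "CaCl2H10O5"))
  expect_equal(length(filterDetectableCompounds(cs2)), 0L)
})

test_that("peak grouping is single-linkage on RT and partitions features", {
  fs <- mkFeatures(c(100, 101, 102), rt = c(110.0, 110.5, 140.0))
  g <- groupPeaksRT(fs, rt_window = 2)
  expect_equal(g$peak_group[match(c("f01", "f02", "f03"), g$feature_id)],
               c(1L, 1L, 2L))
  # chaining: equal gaps link transitively into one group
  fs2 <- mkFeatures(c(100, 101, 102, 103), rt = c(0, 2, 4, 6))
  g2 <- groupPeaksRT(fs2, rt_window = 2)
  expect_equal(unique(g2$peak_group), 1L)
  expect_equal(nrow(groupPeaksRT(mkFeatures(numeric(0)))), 0L)
})

test_that("peak groups satisfy the span bound on random instances", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:80, 1)
    w <- runif(1, 1, 20)
    fs <- mkFeatures(runif(n, 50, 1000), rt = runif(n, 0, 1500))
    g <- groupPeaksRT(fs, w)
    expect_setequal(g$feature_id, features(fs)$feature_id)
    spans <- tapply(g$rt, g$peak_group, function(r) diff(range(r)))
    sizes <- tapply(g$rt, g$peak_group, length)
    expect_true(all(spans <= (sizes - 1) * w + 1e-9))
    # gap between consecutive groups exceeds the window
    ord <- order(g$rt)
    gaps <- diff(g$rt[ord])
    boundary <- diff(g$peak_group[ord]) != 0
    expect_true(all(gaps[boundary] > w))
  }
})

test_that("exact-mass features match with zero ppm error", {
  comp <- CompoundSet(data.frame(compound_id = "cpd00023",
                                 name = "L-Glutamate", formula = "C5H9NO4"))
  ad <- defaultAdducts("positive")
  fs <- mkFeatures(adductMz("C5H9NO4", ad[1, ]))
  m <- matchFeatures(fs, comp, ad, 5)
  expect_equal(nrow(m), 1L)
  expect_identical(m$adduct, "[M+H]+")
  expect_identical(m$ppm_error, 0)
  expect_identical(m$isotope_pass, "not_evaluated")
  expect_error(matchFeatures(fs, comp, ad[0, ], 5), "empty")
})

test_that("matching equals the exhaustive oracle on random instances", {
  for (seed in 1:12) {
    inst <- randomInstance(sample(20:200, 1), sample(10:60, 1), seed = seed)
    m <- matchFeatures(inst$features, inst$compounds, inst$adducts, 5)
    o <- oracleMatch(features(inst$features), compounds(inst$compounds),
                     inst$adducts, 5)
    expect_identical(matchKey(m), matchKey(o))
  }
})

test_that("matches grow monotonically with tolerance and adduct list", {
  inst <- randomInstance(150, 50, seed = 404)
  m5 <- matchFeatures(inst$features, inst$compounds, inst$adducts, 5)
  m10 <- matchFeatures(inst$features, inst$compounds, inst$adducts, 10)
  expect_true(all(matchKey(m5) %in% matchKey(m10)))
  sub <- inst$adducts[1:3, ]
  msub <- matchFeatures(inst$features, inst$compounds, sub, 5)
  expect_true(all(matchKey(msub) %in% matchKey(m5)))
})

test_that("stored match records are self-consistent", {
  inst <- randomInstance(150, 50, seed = 77)
  m <- matchFeatures(inst$features, inst$compounds, inst$adducts, 5)
  expect_true(all(abs(m$ppm_error) <= 5))
  expect_equal(ppmError(m$observed_mz, m$theoretical_mz), m$ppm_error,
               tolerance = 1e-9)
  # ordered by feature then |ppm|
  expect_false(is.unsorted(m$feature_id))
  for (id in unique(m$feature_id))
    expect_false(is.unsorted(abs(m$ppm_error[m$feature_id == id])))
})

test_that("ranking puts isotope-confirmed matches first", {
  m <- mzFBA:::normalizeMatches(data.frame(
    compound_name = c("a", "b", "c"), feature_id = c("f1", "f2", "f3"),
    observed_mz = c(100, 200, 300), rt = 1, adduct = "[M+H]+",
    ppm_error = c(0.1, 2.0, 1.0), source = "pyfba_model",
    isotope_pass = c("false", "true", "not_evaluated")))
  r <- rankMatches(m)
  expect_equal(r$feature_id, c("f2", "f3", "f1"))
})

test_that("phase deltas report rise-then-fall patterns", {
  fs <- FeatureSet(data.frame(feature_id = c("a", "b"), mz = c(100, 200),
                              rt = c(1, 2), p_value = 0.01,
                              mid = c(100, 5), late = c(300, 5),
                              stationary = c(150, 5)))
  d <- phaseDeltas(fs)
  expect_equal(d$late_minus_mid, c(200, 0))
  expect_equal(d$stationary_minus_late, c(-150, 0))
  expect_gt(d$late_minus_mid[1], 0)     # produced during growth...
  expect_lt(d$stationary_minus_late[1], 0)  # ...consumed at stationary
})

test_that("summary counts are conserved and split by source", {
  inst <- randomInstance(100, 40, seed = 55)
  m <- matchFeatures(inst$features, inst$compounds, inst$adducts, 5)
  s <- summarizeMatches(m, inst$features)
  expect_lte(s$n_isotope_matched, s$n_features_matched)
  expect_lte(s$n_features_matched, s$n_features_significant)
  expect_equal(s$n_features_matched, length(unique(m$feature_id)))
  expect_equal(s$n_compounds_matched, length(unique(m$compound_id)))
  expect_equal(s$per_source$n_features_matched, s$n_features_matched)
  out <- capture.output(print(s))
  expect_match(out[2], "significant features")
})

test_that("run comparison reports exclusive and shared compounds", {
  mk <- function(ids) mzFBA:::normalizeMatches(data.frame(
    compound_name = ids, feature_id = paste0("f", seq_along(ids)),
    observed_mz = 100, rt = 1, adduct = "[M+H]+", ppm_error = 0,
    compound_id = ids, source = "pyfba_model"))
  cmp <- compareRuns(mk(c("A", "B", "C")), mk(c("B", "C", "D")))
  expect_equal(cmp$exclusive_a, "A")
  expect_equal(cmp$exclusive_b, "D")
  expect_setequal(cmp$shared, c("B", "C"))
  expect_equal(unname(cmp$totals), c(3L, 3L, 2L, 4L))
  same <- compareRuns(mk(c("A", "B")), mk(c("A", "B")))
  expect_setequal(same$shared, c("A", "B"))
  expect_length(same$exclusive_a, 0L)
  bad <- mk("A"); bad$source <- "modelseed_db"
  expect_error(compareRuns(mk("A"), bad), "different compound sources")
})
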