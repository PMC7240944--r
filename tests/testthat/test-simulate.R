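test_that("identical seeds produce byte-identical datasets", {
  d1 <- file.path(tempdir(), "gen-det-1")
  d2 <- file.path(tempdir(), "gen-det-2")
  unlink(c(d1, d2), recursive = TRUE)
  generateDataset(d1, n_compounds = 20, n_planted = 8, n_noise = 20,
                  n_samples = 2, seed = 7)
  generateDataset(d2, n_compounds = 20, n_planted = 8, n_noise = 20,
                  n_samples = 2, seed = 7)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # a different seed changes the data
  d3 <- file.path(tempdir(), "gen-det-3")
  unlink(d3, recursive = TRUE)
  generateDataset(d3, n_compounds = 20, n_planted = 8, n_noise = 20,
                  n_samples = 2, seed = 8)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "features.tsv"))),
                         unname(tools::md5sum(file.path(d3, "features.tsv")))))
})

test_that("zero mass noise means every planted feature matches exactly", {
  g <- generateDataset(file.path(tempdir(), "gen-exact"),
                       n_compounds = 25, n_planted = 10, n_noise = 10,
                       ppm_noise_sd = 0, n_samples = 1, seed = 13)
  expect_true(all(g$truth$mass_error_ppm == 0))
  feat <- filterSignificant(readFeatureTable(g$feature_path,
                                             dialect = "generic"))
  comp <- readCompoundTable(g$compound_path)
  m <- matchFeatures(feat, comp, defaultAdducts("positive"), 5)
  planted <- paste(g$truth$compound_id, g$truth$adduct, g$truth$feature_id)
  got <- paste(m$compound_id, m$adduct, m$feature_id)
  expect_true(all(planted %in% got))
  err <- m$ppm_error[match(planted, got)]
  expect_true(all(abs(err) < 1e-2))  # limited by 6-decimal table formatting
})

test_that("planted truth is recovered and withheld adducts never match", {
  g <- generateDataset(file.path(tempdir(), "gen-recover"),
                       n_compounds = 30, n_planted = 12, n_noise = 30,
                       n_samples = 1, seed = 31)
  feat <- filterSignificant(readFeatureTable(g$feature_path,
                                             dialect = "generic"))
  comp <- readCompoundTable(g$compound_path)
  ad <- defaultAdducts("positive")
  m <- matchFeatures(feat, comp, ad, 5)
  planted <- paste(g$truth$compound_id, g$truth$adduct, g$truth$feature_id)
  got <- paste(m$compound_id, m$adduct, m$feature_id)
  expect_true(all(planted %in% got))
  # no noise feature matches anything (exclusion zone by construction)
  expect_false(any(m$feature_id %in% g$noise_feature_ids))
  # withhold one planted adduct from the search list: its features vanish
  victim <- g$truth$adduct[1]
  m2 <- matchFeatures(feat, comp, ad[ad$name != victim, ], 5)
  lost <- g$truth$feature_id[g$truth$adduct == victim]
  expect_false(any(paste(m2$feature_id, m2$adduct) %in%
                     paste(lost, victim)))
})

test_that("planted spectra yield isotope ratios near prediction", {
  g <- generateDataset(file.path(tempdir(), "gen-iso"),
                       n_compounds = 20, n_planted = 10, n_noise = 5,
                       isotope_noise_rel_sd = 0.05, n_samples = 3, seed = 53)
  sp <- readSpectra(g$spectra_paths, "positive")
  obs <- vapply(seq_len(nrow(g$truth)), function(i)
    observedM1Ratio(g$truth$observed_mz[i], g$truth$rt[i], sp), 0)
  relerr <- abs(obs - g$truth$planted_m1_ratio) / g$truth$planted_m1_ratio
  expect_true(all(is.finite(relerr)))
  expect_true(mean(relerr < 0.20) >= 0.95)
})

test_that("infeasible noise space is detected", {
  expect_error(
    generateDataset(file.path(tempdir(), "gen-bad"),
                    n_compounds = 30, n_planted = 5, n_noise = 200,
                    noise_exclusion_ppm = 5e5, n_samples = 1, seed = 1),
    "exhausted")
})

test_that("glutamate fixture builds the six-species peak group", {
  fx <- glutamateFixture(file.path(tempdir(), "glu-fx"))
  expect_equal(nrow(fx$species), 6L)
  expect_equal(fx$species$mz[fx$species$species == "[M+H]+"], 148.0604,
               tolerance = 1e-4)
  feat <- readFeatureTable(fx$feature_path, dialect = "generic")
  expect_equal(length(feat), 6L)
  g <- groupPeaksRT(filterSignificant(feat), 10)
  expect_equal(unique(g$peak_group), 1L)   # all six co-elute
  sp <- readSpectra(fx$spectra_paths, "positive")
  expect_equal(length(sp), 5L)
})
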