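# Synthetic LC-MS dataset generator with planted ground truth.  Stands
# in for a real timed-extraction bacterial metabolomics experiment so
# the whole annotation pipeline is testable without any downloads; the
# emitted files use the same formats the real workflow consumes.

#' Bundled metabolite formula pool
#'
#' About a hundred real small-molecule metabolite formulas (amino
#' acids, sugars, nucleotides, organic acids, cofactors, fatty acids)
#' used by the dataset generator.  Real formulas give a realistic mass
#' distribution and genuine isomer collisions (e.g. the hexoses, leucine
#' and isoleucine), which exercises the one-feature-many-compounds path.
#'
#' @return data.frame with `compound_id`, `name`, `formula`.
#' @export
metabolitePool <- function() {
  raw <- c(
    "Glycine|C2H5NO2", "L-Alanine|C3H7NO2", "L-Serine|C3H7NO3",
    "L-Proline|C5H9NO2", "L-Valine|C5H11NO2", "L-Threonine|C4H9NO3",
    "L-Cysteine|C3H7NO2S", "L-Leucine|C6H13NO2", "L-Isoleucine|C6H13NO2",
    "L-Asparagine|C4H8N2O3", "L-Aspartate|C4H7NO4", "L-Glutamine|C5H10N2O3",
    "L-Glutamate|C5H9NO4", "L-Lysine|C6H14N2O2", "L-Methionine|C5H11NO2S",
    "L-Histidine|C6H9N3O2", "L-Phenylalanine|C9H11NO2",
    "L-Arginine|C6H14N4O2", "L-Tyrosine|C9H11NO3", "L-Tryptophan|C11H12N2O2",
    "D-Glucose|C6H12O6", "D-Fructose|C6H12O6", "myo-Inositol|C6H12O6",
    "D-Ribose|C5H10O5", "D-Xylose|C5H10O5", "2-Deoxyribose|C5H10O4",
    "Sucrose|C12H22O11", "Trehalose|C12H22O11", "Maltose|C12H22O11",
    "N-Acetylglucosamine|C8H15NO6", "Glucosamine|C6H13NO5",
    "Glycerol|C3H8O3", "Ribitol|C5H12O5", "Sorbitol|C6H14O6",
    "Pyruvate|C3H4O3", "L-Lactate|C3H6O3", "Acetate|C2H4O2",
    "Citrate|C6H8O7", "Isocitrate|C6H8O7", "cis-Aconitate|C6H6O6",
    "2-Oxoglutarate|C5H6O5", "Succinate|C4H6O4", "Fumarate|C4H4O4",
    "L-Malate|C4H6O5", "Oxaloacetate|C4H4O5", "Glyoxylate|C2H2O3",
    "Glycolate|C2H4O3", "Formate|CH2O2", "Propionate|C3H6O2",
    "Shikimate|C7H10O5", "Chorismate|C10H10O6", "Quinate|C7H12O6",
    "Glucose-6-phosphate|C6H13O9P", "Fructose-6-phosphate|C6H13O9P",
    "Fructose-1,6-bisphosphate|C6H14O12P2",
    "Glyceraldehyde-3-phosphate|C3H7O6P", "3-Phosphoglycerate|C3H7O7P",
    "Phosphoenolpyruvate|C3H5O6P", "Ribose-5-phosphate|C5H11O8P",
    "Glycerol-3-phosphate|C3H9O6P",
    "Adenine|C5H5N5", "Guanine|C5H5N5O", "Cytosine|C4H5N3O",
    "Uracil|C4H4N2O2", "Thymine|C5H6N2O2", "Hypoxanthine|C5H4N4O",
    "Xanthine|C5H4N4O2", "Adenosine|C10H13N5O4", "Guanosine|C10H13N5O5",
    "Cytidine|C9H13N3O5", "Uridine|C9H12N2O6", "Inosine|C10H12N4O5",
    "AMP|C10H14N5O7P", "GMP|C10H14N5O8P", "UMP|C9H13N2O9P",
    "CMP|C9H14N3O8P", "ADP|C10H15N5O10P2", "ATP|C10H16N5O13P3",
    "NAD|C21H27N7O14P2", "NADP|C21H28N7O17P3", "FAD|C27H33N9O15P2",
    "FMN|C17H21N4O9P", "Coenzyme-A|C21H36N7O16P3S",
    "Thiamine|C12H17N4OS", "Riboflavin|C17H20N4O6",
    "Nicotinamide|C6H6N2O", "Pyridoxal|C8H9NO3", "Pyridoxine|C8H11NO3",
    "Pantothenate|C9H17NO5", "Biotin|C10H16N2O3S", "Folate|C19H19N7O6",
    "4-Aminobenzoate|C7H7NO2", "Glutathione|C10H17N3O6S",
    "Spermidine|C7H19N3", "Putrescine|C4H12N2", "L-Ornithine|C5H12N2O2",
    "L-Citrulline|C6H13N3O3", "L-Homoserine|C4H9NO3",
    "L-Cystathionine|C7H14N2O4S", "Taurine|C2H7NO3S",
    "Ethanolamine|C2H7NO", "Betaine|C5H11NO2", "L-Carnitine|C7H15NO3",
    "Creatine|C4H9N3O2", "Urea|CH4N2O",
    "Laurate|C12H24O2", "Myristate|C14H28O2", "Palmitate|C16H32O2",
    "Stearate|C18H36O2", "Oleate|C18H34O2")
  parts <- strsplit(raw, "|", fixed = TRUE)
  data.frame(
    compound_id = sprintf("cpd%05d", seq_along(parts)),
    name = vapply(parts, `[`, "", 1),
    formula = vapply(parts, `[`, "", 2),
    stringsAsFactors = FALSE)
}

# truncated normal in ppm
rppm <- function(n, sd, max_abs) {
  if (sd == 0) return(rep(0, n))
  x <- stats::rnorm(n, 0, sd)
  while (any(bad <- abs(x) > max_abs))
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
  x
}

.phasePatterns <- c("rise_fall", "monotone_up", "monotone_down")

phaseMeans <- function(pattern, base) {
  switch(pattern,
         rise_fall = c(mid = base, late = 3 * base, stationary = 1.5 * base),
         monotone_up = c(mid = base, late = 2 * base, stationary = 4 * base),
         monotone_down = c(mid = 4 * base, late = 2 * base, stationary = base))
}

#' Generate a synthetic annotation dataset with known ground truth
#'
#' Emulates the inputs of a timed-extraction untargeted metabolomics
#' experiment run against a model-predicted compound list: a compound
#' TSV, a significant-feature table, per-replicate raw MS1 spectra
#' (mzXML), and a ground-truth manifest.  Planted features carry the
#' theoretical m/z of a (compound, adduct) pair perturbed by a
#' truncated-normal ppm error; each planted compound may emit a small
#' co-eluting adduct cluster; per-phase class means follow a
#' rise-fall / monotone-up / monotone-down pattern; spectra contain M
#' and M+1 centroids whose ratio is the predicted ion isotope ratio
#' perturbed by relative noise.  Noise features avoid an exclusion zone
#' around every theoretical compound-adduct m/z so the expected match
#' set is known exactly.  Fully reproducible from `seed`.
#'
#' @param dir Output directory (created).
#' @param n_compounds Compounds drawn from [metabolitePool()].
#' @param n_planted Planted (compound, adduct, feature) triples, one
#'   primary per chosen compound.
#' @param n_noise Unmatched noise features.
#' @param ppm_noise_sd Mass-error SD in ppm (default 1.5, typical
#'   calibrated QTOF accuracy).
#' @param ppm_noise_max Truncation bound in ppm (default 4, inside the
#'   5 ppm match tolerance).
#' @param isotope_noise_rel_sd Relative SD of the planted M+1/M ratio
#'   (default 0.05).
#' @param rt_range Two seconds values, elution window (default 60-1200).
#' @param n_samples Biological replicates / raw files (default 5).
#' @param polarity Ionization mode of the planted adducts.
#' @param adducts Adduct table to plant from (default
#'   [defaultAdducts()] of `polarity`).
#' @param cluster_prob Probability that a planted compound emits one
#'   additional co-eluting adduct feature (default 0.3).
#' @param noise_exclusion_ppm Half-width of the m/z exclusion zone
#'   around every theoretical compound-adduct m/z that noise features
#'   must avoid (default 15 ppm).
#' @param spectra_format `"mzXML"` or `"mzML"`.
#' @param seed Integer seed; same seed, same bytes.
#' @return List with `dir`, file paths (`compound_path`, `feature_path`,
#'   `spectra_paths`, `truth_path`, `manifest_path`) and the `truth`
#'   data.frame plus `noise_feature_ids`.
#' @export
generateDataset <- function(dir,
                            n_compounds = 50, n_planted = 20, n_noise = 100,
                            ppm_noise_sd = 1.5, ppm_noise_max = 4,
                            isotope_noise_rel_sd = 0.05,
                            rt_range = c(60, 1200), n_samples = 5,
                            polarity = "positive",
                            adducts = defaultAdducts(polarity),
                            cluster_prob = 0.3, noise_exclusion_ppm = 15,
                            spectra_format = c("mzXML", "mzML"),
                            seed) {
  spectra_format <- match.arg(spectra_format)
  stopifnot(n_planted <= n_compounds, length(rt_range) == 2,
            rt_range[1] < rt_range[2])
  pool <- metabolitePool()
  stopifnot(n_compounds <= nrow(pool))
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  cmp <- pool[sample.int(nrow(pool), n_compounds), , drop = FALSE]
  cmp <- cmp[order(cmp$compound_id), ]
  compound_path <- file.path(dir, "compounds.tsv")
  writeTsv(data.frame(id = cmp$compound_id, name = cmp$name,
                      formula = cmp$formula), compound_path)

  masses <- vapply(cmp$formula, monoisotopicMass, 0)
  m1 <- vapply(cmp$formula, function(f) predictM1Ratio(f)$m1_ratio, 0)
  theo <- (rep(adducts$multimer, times = n_compounds) * rep(masses, each = nrow(adducts)) +
             rep(adducts$delta_mass, times = n_compounds)) /
    rep(adducts$charge, times = n_compounds)
  theo <- theo[theo > 0]

  # ---- plant features -------------------------------------------------
  pick <- sample.int(n_compounds, n_planted)
  rows <- list()
  for (k in seq_len(n_planted)) {
    ci <- pick[k]
    rt <- stats::runif(1, rt_range[1], rt_range[2])
    pattern <- sample(.phasePatterns, 1)
    ai <- sample.int(nrow(adducts), 1)
    nAdd <- if (stats::runif(1) < cluster_prob && nrow(adducts) > 1) 1L else 0L
    ais <- c(ai, if (nAdd) sample(setdiff(seq_len(nrow(adducts)), ai), nAdd))
    for (j in seq_along(ais)) {
      a <- adducts[ais[j], ]
      tmz <- (a$multimer * masses[ci] + a$delta_mass) / a$charge
      err <- rppm(1, ppm_noise_sd, ppm_noise_max)
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = cmp$compound_id[ci], compound_name = cmp$name[ci],
        adduct = a$name, true_mz = tmz,
        observed_mz = tmz * (1 + err * 1e-6), mass_error_ppm = err,
        rt = rt + if (j > 1) stats::runif(1, -3, 3) else 0,
        planted_m1_ratio = m1[ci] * a$multimer,
        phase_pattern = pattern, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  truth$feature_id <- make.unique(
    sprintf("M%dT%d", round(truth$observed_mz), round(truth$rt)), sep = "_")

  # ---- noise features avoid every theoretical adduct m/z --------------
  mz_lo <- max(50, min(truth$observed_mz) * 0.8)
  mz_hi <- min(1000, max(truth$observed_mz) * 1.2)
  noise_mz <- numeric(0)
  tries <- 0L
  theo_sorted <- sort(theo)
  while (length(noise_mz) < n_noise) {
    tries <- tries + 1L
    if (tries > 1000L * n_noise)
      stop("noise m/z space exhausted; loosen noise_exclusion_ppm")
    cand <- stats::runif(1, mz_lo, mz_hi)
    i <- findInterval(cand, theo_sorted)
    nearest <- min(abs(cand - theo_sorted[pmax(i, 1L)]),
                   abs(cand - theo_sorted[pmin(i + 1L, length(theo_sorted))]))
    if (nearest / cand * 1e6 > noise_exclusion_ppm)
      noise_mz <- c(noise_mz, cand)
  }
  noise <- data.frame(
    mz = noise_mz,
    rt = stats::runif(n_noise, rt_range[1], rt_range[2]),
    pattern = sample(.phasePatterns, n_noise, replace = TRUE))
  noise$feature_id <- make.unique(
    sprintf("M%dT%d", round(noise$mz), round(noise$rt)), sep = "_")
  # disambiguate against planted ids
  clash <- noise$feature_id %in% truth$feature_id
  noise$feature_id[clash] <- paste0(noise$feature_id[clash], "_n")

  # ---- feature table --------------------------------------------------
  mkRow <- function(id, mz, rt, pattern, base, p_value) {
    pm <- phaseMeans(pattern, base)
    data.frame(feature_id = id, mz = mz, rt = rt, p_value = p_value,
               mid = pm[["mid"]], late = pm[["late"]],
               stationary = pm[["stationary"]])
  }
  # planted features are all significant; ~30% of noise features are not,
  # so the significance filter has something to remove
  noise_p <- ifelse(stats::runif(n_noise) < 0.3,
                    stats::runif(n_noise, 0.06, 0.9),
                    stats::runif(n_noise, 1e-4, 0.049))
  feat <- rbind(
    do.call(rbind, lapply(seq_len(nrow(truth)), function(i)
      mkRow(truth$feature_id[i], truth$observed_mz[i], truth$rt[i],
            truth$phase_pattern[i], stats::rlnorm(1, log(1e5), 0.5),
            stats::runif(1, 1e-4, 0.04)))),
    do.call(rbind, lapply(seq_len(n_noise), function(i)
      mkRow(noise$feature_id[i], noise$mz[i], noise$rt[i],
            noise$pattern[i], stats::rlnorm(1, log(3e4), 0.7),
            noise_p[i]))))
  feature_path <- file.path(dir, "features.tsv")
  writeTsv(data.frame(feature_id = feat$feature_id,
                      mz = sprintf("%.6f", feat$mz),
                      rt = sprintf("%.2f", feat$rt),
                      p_value = sprintf("%.6f", feat$p_value),
                      mid = sprintf("%.1f", feat$mid),
                      late = sprintf("%.1f", feat$late),
                      stationary = sprintf("%.1f", feat$stationary)),
           feature_path)

  # ---- raw spectra: M and M+1 centroids around each planted RT --------
  spectra_paths <- character(n_samples)
  offsets <- c(-2, -1, 0, 1, 2)
  for (s in seq_len(n_samples)) {
    scan_rts <- sort(unique(round(as.vector(outer(truth$rt, offsets, `+`)), 3)))
    scans <- lapply(scan_rts, function(t) {
      memb <- which(abs(truth$rt - t) <= 3)
      if (!length(memb)) return(NULL)
      iM <- stats::rlnorm(length(memb), log(1e5), 0.3)
      ratio <- truth$planted_m1_ratio[memb] *
        (1 + stats::rnorm(length(memb), 0, isotope_noise_rel_sd))
      ratio <- pmax(ratio, 0)
      mz <- c(truth$observed_mz[memb], truth$observed_mz[memb] + C13_SPACING)
      it <- c(iM, iM * ratio)
      ord <- order(mz)
      mz <- mz[ord]; it <- it[ord]
      dup <- c(FALSE, diff(mz) <= 1e-9)
      list(rt = t, mz = mz[!dup], intensity = it[!dup])
    })
    scans <- scans[!vapply(scans, is.null, TRUE)]
    ext <- if (spectra_format == "mzXML") "mzXML" else "mzML"
    spectra_paths[s] <- file.path(dir, sprintf("sample%d.%s", s, ext))
    writer <- if (spectra_format == "mzXML") writeMzXML else writeMzML
    writer(scans, spectra_paths[s], polarity = polarity)
  }

  # ---- truth + manifest ----------------------------------------------
  truth_path <- file.path(dir, "truth.tsv")
  writeTsv(truth[, c("compound_id", "compound_name", "adduct", "feature_id",
                     "true_mz", "observed_mz", "mass_error_ppm", "rt",
                     "planted_m1_ratio", "phase_pattern")], truth_path)
  noise_path <- file.path(dir, "noise_features.tsv")
  writeTsv(noise[, c("feature_id", "mz", "rt")], noise_path)
  manifest <- list(
    seed = seed,
    parameters = list(n_compounds = n_compounds, n_planted = n_planted,
                      n_noise = n_noise, ppm_noise_sd = ppm_noise_sd,
                      ppm_noise_max = ppm_noise_max,
                      isotope_noise_rel_sd = isotope_noise_rel_sd,
                      rt_range = rt_range, n_samples = n_samples,
                      polarity = polarity, cluster_prob = cluster_prob,
                      noise_exclusion_ppm = noise_exclusion_ppm,
                      spectra_format = spectra_format),
    expected = list(
      n_features = nrow(feat),
      n_features_significant = sum(feat$p_value < 0.05),
      n_features_matched = length(unique(truth$feature_id)),
      # isomer-aware: every compound in the emitted list with some
      # adduct within 5 ppm of a planted feature m/z will be annotated,
      # not just the compound that generated the feature
      n_compounds_matched = local({
        hit <- logical(n_compounds)
        for (ci in seq_len(n_compounds)) {
          tmz <- (adducts$multimer * masses[ci] + adducts$delta_mass) /
            adducts$charge
          tmz <- tmz[tmz > 0]
          hit[ci] <- any(vapply(tmz, function(t)
            any(abs(1e6 * (truth$observed_mz - t) / t) <= 5), TRUE))
        }
        sum(hit)
      })))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(dir = dir, compound_path = compound_path, feature_path = feature_path,
       spectra_paths = spectra_paths, truth_path = truth_path,
       manifest_path = manifest_path, truth = truth,
       noise_feature_ids = noise$feature_id)
}

#' The canonical glutamic-acid worked example
#'
#' Builds the six-species co-eluting peak group observed for glutamic
#' acid in a reverse-phase positive-mode run: the protonated molecule,
#' the carboxyl neutral loss, the water neutral loss, the sodium
#' adduct, the dimer and the trimer, all at the theoretical m/z for
#' C5H9NO4 and one retention time (114 s, i.e. eluting at 1.9 min).
#' With the default positive adduct list, accurate-mass matching
#' annotates four of the six (the carboxyl loss and the trimer are not
#' in the preset list).  The spectrum file carries M and M+1 centroids
#' at the predicted ion isotope ratios.
#'
#' @param dir Output directory.
#' @param rt Elution time in seconds.
#' @return List with `dir`, `feature_path`, `compound_path`,
#'   `spectra_paths` and the `species` table (name, m/z, in the default
#'   list or not).
#' @export
glutamateFixture <- function(dir, rt = 114) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  glu <- "C5H9NO4"
  M <- monoisotopicMass(glu)
  r1 <- predictM1Ratio(glu)$m1_ratio
  cooh <- monoisotopicMass(c(C = 1L, H = 1L, O = 2L))
  h2o <- monoisotopicMass(c(H = 2L, O = 1L))
  species <- data.frame(
    species = c("[M+H]+", "[M-COOH+H]+", "[M-H2O+H]+", "[M+Na]+",
                "[2M+H]+", "[3M+H]+"),
    mz = c(M + PROTON_MASS,
           M - cooh + PROTON_MASS,
           M - h2o + PROTON_MASS,
           M + MONOISOTOPIC_MASS[["Na"]] - ELECTRON_MASS,
           2 * M + PROTON_MASS,
           3 * M + PROTON_MASS),
    multimer = c(1L, 1L, 1L, 1L, 2L, 3L),
    in_default_list = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  species$m1_ratio <- r1 * species$multimer

  feature_path <- file.path(dir, "features.tsv")
  pm <- phaseMeans("rise_fall", 1e5)
  writeTsv(data.frame(
    feature_id = sprintf("M%dT%d", round(species$mz), round(rt)),
    mz = sprintf("%.6f", species$mz),
    rt = sprintf("%.2f", rt),
    p_value = "0.001000",
    mid = pm[["mid"]], late = pm[["late"]], stationary = pm[["stationary"]]),
    feature_path)

  compound_path <- file.path(dir, "compounds.tsv")
  writeTsv(data.frame(id = "cpd00023", name = "L-Glutamate", formula = glu),
           compound_path)

  scans <- lapply(rt + c(-2, -1, 0, 1, 2), function(t) {
    iM <- rep(1e5, nrow(species))
    mz <- c(species$mz, species$mz + C13_SPACING)
    it <- c(iM, iM * species$m1_ratio)
    ord <- order(mz)
    list(rt = t, mz = mz[ord], intensity = it[ord])
  })
  spectra_path <- file.path(dir, "sampleL5.mzXML")
  writeMzXML(scans, spectra_path, polarity = "positive")
  list(dir = dir, feature_path = feature_path, compound_path = compound_path,
       spectra_paths = spectra_path, species = species, rt = rt)
}
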