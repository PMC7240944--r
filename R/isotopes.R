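#' Measure the M+1/M isotope ratio of a feature in the raw data
#'
#' For each sample, takes the `n_scans` MS1 scans nearest the feature's
#' retention time, sums intensity within `mz_tol_ppm` of the feature m/z
#' (the monoisotopic channel) and of m/z + 1.00335/charge (the M+1
#' channel), and forms the per-sample ratio of the two sums.  The
#' median across samples is returned — robust to single-sample dropouts
#' where the M+1 peak falls below the signal-to-noise limit.
#'
#' @param mz,rt Feature m/z and retention time (seconds).
#' @param spectra A [SpectrumCollection-class].
#' @param n_scans Scans per sample to pool (default 3).
#' @param mz_tol_ppm Extraction window half-width in ppm (default 10;
#'   wider than the match tolerance so the full centroid is captured).
#' @param charge Ion charge (isotope spacing is 1.00335/charge).
#' @param rt_radius Seconds; samples whose nearest scan is farther than
#'   this are skipped.
#' @return The median M+1/M ratio, or `NA` when the M+1 peak is
#'   undetected in every sample (or no scan covers the RT).
#' @export
observedM1Ratio <- function(mz, rt, spectra, n_scans = 3L, mz_tol_ppm = 10,
                            charge = 1L, rt_radius = 30) {
  stopifnot(is(spectra, "SpectrumCollection"), n_scans >= 1L)
  near <- nearestScans(spectra, rt, n = n_scans, rt_radius = rt_radius)
  if (!length(near)) {
    mzfbaLog("DEBUG", sprintf("no scan within %.0f s of RT %.1f", rt_radius, rt))
    return(NA_real_)
  }
  m1mz <- mz + C13_SPACING / charge
  ratios <- vapply(near, function(scans) {
    iM <- sum(vapply(scans, windowIntensity, 0, mz = mz, ppm = mz_tol_ppm))
    iM1 <- sum(vapply(scans, windowIntensity, 0, mz = m1mz, ppm = mz_tol_ppm))
    if (iM <= 0 || iM1 <= 0) NA_real_ else iM1 / iM
  }, 0)
  if (all(is.na(ratios))) return(NA_real_)
  stats::median(ratios, na.rm = TRUE)
}

#' Apply the isotope-ratio criteria to a match table
#'
#' Fills the isotope columns of a match table: the isotope ratio
#' difference (observed minus predicted M+1/M, reported as an absolute
#' difference) and the pass flag.  A match passes when an observed
#' ratio is available and the absolute difference is within `rel_tol`
#' times the predicted ratio; matches without a measurable M+1 peak are
#' `not_evaluated`, never failed.
#'
#' @param matches Match data.frame from [matchFeatures()].
#' @param observed Named numeric vector of observed M+1/M ratios keyed
#'   by `feature_id` (NA = undetected), e.g. assembled with
#'   [observedM1Ratio()].
#' @param rel_tol Relative pass tolerance on the predicted ratio
#'   (default 0.20, typical QTOF isotope-ratio accuracy).
#' @return The match data.frame with `observed_m1_ratio`,
#'   `isotope_ratio_difference` and `isotope_pass` filled.
#' @export
validateIsotopes <- function(matches, observed, rel_tol = 0.20) {
  stopifnot(rel_tol > 0)
  if (!nrow(matches)) return(matches)
  obs <- observed[matches$feature_id]
  matches$observed_m1_ratio <- as.numeric(obs)
  matches$isotope_ratio_difference <- matches$observed_m1_ratio -
    matches$predicted_m1_ratio
  pass <- !is.na(matches$observed_m1_ratio) &
    abs(matches$isotope_ratio_difference) <=
      rel_tol * matches$predicted_m1_ratio
  matches$isotope_pass <- ifelse(is.na(matches$observed_m1_ratio),
                                 "not_evaluated",
                                 ifelse(pass, "true", "false"))
  matches
}
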