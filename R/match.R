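#' Keep significantly changing features
#'
#' Retains features whose differential p-value is strictly below
#' `alpha`, preserving input order.
#'
#' @param x A [FeatureSet-class].
#' @param alpha Significance threshold, in (0, 1]; default 0.05.
#' @return A [FeatureSet-class] of the significant features.
#' @export
filterSignificant <- function(x, alpha = 0.05) {
  stopifnot(is(x, "FeatureSet"), alpha > 0, alpha <= 1)
  FeatureSet(features(x)[features(x)$p_value < alpha, , drop = FALSE])
}

#' Keep compounds an LC-MS system could plausibly detect
#'
#' Restricts a compound list to species within reach of the acquisition
#' mass range, removing what an electrospray LC-MS run will not report
#' as a molecular feature: metal ions, and low-molecular-weight
#' inorganics such as CO2 and NH3.  Compounds must contain carbon (when
#' `require_carbon`) and have a neutral monoisotopic mass within
#' `[mz_min - margin, mz_max]`; the lower margin (25 Da) admits species
#' observed only through mass-shifting adducts.
#'
#' @param x A [CompoundSet-class].
#' @param mz_min,mz_max Acquisition mass range, default 50-1000 m/z.
#' @param require_carbon Drop carbon-free species (metal ions, small
#'   inorganics); default TRUE.
#' @param margin Da subtracted from `mz_min` for the mass cut; the
#'   default (5) admits compounds shifted into range by electron/proton
#'   transfer while still excluding the small inorganics.
#' @return A filtered [CompoundSet-class].
#' @export
filterDetectableCompounds <- function(x, mz_min = 50, mz_max = 1000,
                                      require_carbon = TRUE, margin = 5) {
  stopifnot(is(x, "CompoundSet"), mz_min < mz_max)
  df <- compounds(x)
  keep <- df$mono_mass >= (mz_min - margin) & df$mono_mass <= mz_max
  if (require_carbon && nrow(df))
    keep <- keep & grepl("C(?![a-z])", df$formula, perl = TRUE)
  out <- x
  out@compounds <- df[keep, , drop = FALSE]
  mzfbaLog("INFO", sprintf("detectability filter kept %d of %d compounds",
                           sum(keep), nrow(df)))
  out
}

#' Group co-eluting features into peak groups
#'
#' Features eluting within the same retention-time window indicate
#' potential adducts or co-eluting species of one metabolite.  Grouping
#' is single-linkage on RT: features are sorted by RT and a new group
#' starts whenever the gap to the previous feature exceeds `rt_window`.
#' The result partitions the feature set.
#'
#' @param x A [FeatureSet-class].
#' @param rt_window Link threshold in seconds (default 10).
#' @return data.frame with `feature_id`, `rt`, `peak_group`, plus an
#'   attribute `"groups"` holding per-group `group_id`, `rt_center`
#'   (mean member RT) and `n_members`.
#' @export
groupPeaksRT <- function(x, rt_window = 10) {
  stopifnot(is(x, "FeatureSet"), rt_window > 0)
  df <- features(x)
  if (nrow(df) == 0L) {
    out <- data.frame(feature_id = character(0), rt = numeric(0),
                      peak_group = integer(0))
    attr(out, "groups") <- data.frame(group_id = integer(0),
                                      rt_center = numeric(0),
                                      n_members = integer(0))
    return(out)
  }
  ord <- order(df$rt, df$feature_id)
  rt <- df$rt[ord]
  grp <- cumsum(c(1L, as.integer(diff(rt) > rt_window)))
  out <- data.frame(feature_id = df$feature_id[ord], rt = rt,
                    peak_group = grp)
  out <- out[match(df$feature_id, out$feature_id), ]
  rownames(out) <- NULL
  centers <- tapply(rt, grp, mean)
  attr(out, "groups") <- data.frame(
    group_id = as.integer(names(centers)),
    rt_center = as.numeric(centers),
    n_members = as.integer(table(grp)))
  out
}

#' Accurate-mass adduct matching of features against a compound list
#'
#' Emits one match record for every (feature, compound, adduct)
#' combination whose theoretical adduct m/z lies within `ppm_tol` of the
#' observed feature m/z.  A feature may match several compounds (mass
#' isomers) and a compound several features; nothing is collapsed.
#' Records carry the signed ppm error, the compound's predicted M+1
#' ratio, and the feature's peak group when a grouping is supplied;
#' isotope fields start as `not_evaluated` (see [validateIsotopes()]).
#'
#' Implemented by sorting the compound-by-adduct theoretical m/z grid
#' and range-searching each feature with [findInterval()]; equivalent to
#' the exhaustive scan over all triples.
#'
#' @param x A [FeatureSet-class] (typically already significance
#'   filtered).
#' @param comp A [CompoundSet-class] (typically detectability filtered).
#' @param adducts Adduct table of one polarity ([defaultAdducts()]).
#' @param ppm_tol Mass tolerance in ppm (default 5).
#' @param groups Optional result of [groupPeaksRT()] used to stamp
#'   `peak_group`.
#' @return Match data.frame ordered by (feature_id, |ppm_error|); see
#'   [writeMatchTable()] for columns.
#' @export
matchFeatures <- function(x, comp, adducts, ppm_tol = 5, groups = NULL) {
  stopifnot(is(x, "FeatureSet"), is(comp, "CompoundSet"), ppm_tol > 0)
  validateAdducts(adducts)
  if (length(unique(adducts$polarity)) > 1L)
    stop("adduct table mixes polarities; match one polarity per run")
  fdf <- features(x)
  cdf <- compounds(comp)

  # theoretical m/z grid: one row per compound x adduct
  nA <- nrow(adducts)
  nC <- nrow(cdf)
  grid <- data.frame(
    ci = rep(seq_len(nC), each = nA),
    ai = rep(seq_len(nA), times = nC))
  grid$mz <- (adducts$multimer[grid$ai] * cdf$mono_mass[grid$ci] +
                adducts$delta_mass[grid$ai]) / adducts$charge[grid$ai]
  grid <- grid[grid$mz > 0, , drop = FALSE]
  grid <- grid[order(grid$mz), , drop = FALSE]

  res <- vector("list", nrow(fdf))
  for (i in seq_len(nrow(fdf))) {
    mz <- fdf$mz[i]
    tol <- mz * ppm_tol * 1e-6
    lo <- findInterval(mz - tol, grid$mz) + 1L
    hi <- findInterval(mz + tol, grid$mz)
    if (hi < lo) next
    hit <- grid[lo:hi, , drop = FALSE]
    err <- ppmError(mz, hit$mz)
    inside <- abs(err) <= ppm_tol
    if (!any(inside)) next
    hit <- hit[inside, , drop = FALSE]
    res[[i]] <- data.frame(
      compound_name = cdf$name[hit$ci],
      feature_id = fdf$feature_id[i],
      observed_mz = mz,
      rt = fdf$rt[i],
      peak_group = NA_integer_,
      isotope_ratio_difference = NA_real_,
      isotope_pass = "not_evaluated",
      adduct = adducts$name[hit$ai],
      ppm_error = err[inside],
      source = cdf$source[hit$ci],
      compound_id = cdf$compound_id[hit$ci],
      theoretical_mz = hit$mz,
      # the ion carries multimer copies of the molecule, so its M+1
      # ratio scales with the multimer (adduct atoms contribute ~0)
      predicted_m1_ratio = cdf$m1_ratio[hit$ci] * adducts$multimer[hit$ai],
      observed_m1_ratio = NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- if (any(!vapply(res, is.null, TRUE)))
    do.call(rbind, res[!vapply(res, is.null, TRUE)])
  else normalizeMatches(data.frame())
  if (!is.null(groups) && nrow(out))
    out$peak_group <- groups$peak_group[match(out$feature_id,
                                              groups$feature_id)]
  out <- out[order(out$feature_id, abs(out$ppm_error)), , drop = FALSE]
  rownames(out) <- NULL
  normalizeMatches(out)
}

#' Rank a match table for reporting
#'
#' Isotope-validated matches first, then by increasing absolute mass
#' error.
#'
#' @param matches Match data.frame.
#' @return Reordered match data.frame.
#' @export
rankMatches <- function(matches) {
  ord <- order(factor(matches$isotope_pass,
                      levels = c("true", "not_evaluated", "false")),
               abs(matches$ppm_error))
  out <- matches[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Growth-phase intensity differences of features
#'
#' The two successive class-mean differences along the growth curve:
#' late-exponential minus mid-exponential, and stationary minus
#' late-exponential.  A metabolite produced during growth and then
#' consumed by salvage pathways shows a positive first and negative
#' second delta.
#'
#' @param x A [FeatureSet-class].
#' @return data.frame with `feature_id`, `late_minus_mid`,
#'   `stationary_minus_late`.
#' @export
phaseDeltas <- function(x) {
  df <- features(x)
  data.frame(feature_id = df$feature_id,
             late_minus_mid = df$late - df$mid,
             stationary_minus_late = df$stationary - df$late)
}

#' Summary counts of an annotation run
#'
#' Mirrors the run-report layout: features entering the match, features
#' matched by accurate mass, features additionally passing the
#' isotope-ratio criteria, and distinct compounds matched — overall and
#' per compound source.  Compound counts can exceed feature counts when
#' isomers share a mass.
#'
#' @param matches Match data.frame.
#' @param x The [FeatureSet-class] that was matched (after significance
#'   filtering).
#' @return List of class `mzfba_summary` with `n_features_significant`,
#'   `n_features_matched`, `n_isotope_matched`, `n_compounds_matched`,
#'   `per_source` (data.frame).
#' @export
summarizeMatches <- function(matches, x) {
  stopifnot(is(x, "FeatureSet"))
  n_sig <- length(x)
  bySource <- function(df) {
    data.frame(
      n_features_matched = length(unique(df$feature_id)),
      n_isotope_matched = length(unique(df$feature_id[df$isotope_pass == "true"])),
      n_compounds_matched = length(unique(df$compound_id)))
  }
  per <- do.call(rbind, lapply(split(matches, matches$source), bySource))
  per <- cbind(source = rownames(per), per)
  rownames(per) <- NULL
  tot <- bySource(matches)
  structure(list(
    n_features_significant = n_sig,
    n_features_matched = tot$n_features_matched,
    n_isotope_matched = tot$n_isotope_matched,
    n_compounds_matched = tot$n_compounds_matched,
    per_source = per), class = "mzfba_summary")
}

#' @export
print.mzfba_summary <- function(x, ...) {
  cat("Annotation summary\n")
  cat(sprintf("  significant features        %d\n", x$n_features_significant))
  cat(sprintf("  matched by accurate mass    %d\n", x$n_features_matched))
  cat(sprintf("  isotope-ratio confirmed     %d\n", x$n_isotope_matched))
  cat(sprintf("  distinct compounds matched  %d\n", x$n_compounds_matched))
  if (nrow(x$per_source) > 1L) {
    cat("  by source:\n")
    print(x$per_source, row.names = FALSE)
  }
  invisible(x)
}

#' Compound overlap between two annotation runs
#'
#' Compares the distinct compounds matched in two runs (e.g. a
#' reverse-phase positive-mode and a HILIC negative-mode run of the
#' same cultures) by compound ID.
#'
#' @param matches_a,matches_b Match data.frames of the two runs.
#' @return List with `exclusive_a`, `exclusive_b`, `shared` (character
#'   vectors of compound IDs) and integer `totals`.
#' @export
compareRuns <- function(matches_a, matches_b) {
  sa <- unique(matches_a$source)
  sb <- unique(matches_b$source)
  if (length(sa) && length(sb) && !any(sa %in% sb))
    stop("runs matched against different compound sources: ",
         paste(sa, collapse = ","), " vs ", paste(sb, collapse = ","))
  a <- unique(matches_a$compound_id)
  b <- unique(matches_b$compound_id)
  list(exclusive_a = setdiff(a, b),
       exclusive_b = setdiff(b, a),
       shared = intersect(a, b),
       totals = c(a = length(a), b = length(b),
                  shared = length(intersect(a, b)),
                  union = length(union(a, b))))
}
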