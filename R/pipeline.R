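#' Run configuration for a full annotation pass
#'
#' Bundles every tunable of one annotation run: the ionization
#' polarity, the mass tolerance, the significance threshold, the
#' co-elution window, the isotope-ratio pass tolerance and extraction
#' settings, the acquisition mass range, the adduct table and the
#' input/output paths.  The configuration round-trips through JSON (the
#' run log), so a finished run can be reproduced exactly from its own
#' output directory.
#'
#' @slot polarity "positive" or "negative".
#' @slot ppm_tol Mass tolerance in ppm.
#' @slot alpha Significance threshold on the feature p-value.
#' @slot rt_window Peak-group link window, seconds.
#' @slot isotope_rel_tol Relative isotope-ratio pass tolerance.
#' @slot n_scans Scans per sample pooled for the M+1 measurement.
#' @slot mz_min,mz_max Acquisition mass range (m/z).
#' @slot adducts Adduct table data.frame.
#' @slot feature_path,compound_paths,spectra_paths,out_dir Input and
#'   output locations; `compound_paths` is named by source
#'   (`pyfba_model`, `modelseed_db`).
#' @slot feature_dialect Feature-table dialect for [readFeatureTable()].
#' @export
setClass("MzFbaParams", representation(
  polarity = "character", ppm_tol = "numeric", alpha = "numeric",
  rt_window = "numeric", isotope_rel_tol = "numeric", n_scans = "integer",
  mz_min = "numeric", mz_max = "numeric", adducts = "data.frame",
  feature_path = "character", compound_paths = "character",
  spectra_paths = "character", out_dir = "character",
  feature_dialect = "character"))

setValidity("MzFbaParams", function(object) {
  if (!object@polarity %in% c("positive", "negative"))
    return("polarity must be 'positive' or 'negative'")
  for (s in c("ppm_tol", "alpha", "rt_window", "isotope_rel_tol"))
    if (slot(object, s) <= 0) return(paste(s, "must be > 0"))
  if (object@alpha > 1) return("alpha must be in (0, 1]")
  if (object@mz_min >= object@mz_max) return("mz_min must be < mz_max")
  if (object@n_scans < 1L) return("n_scans must be >= 1")
  if (length(object@compound_paths) == 0L)
    return("at least one compound list is required")
  if (is.null(names(object@compound_paths)) ||
      !all(names(object@compound_paths) %in% c("pyfba_model", "modelseed_db")))
    return("compound_paths must be named 'pyfba_model' and/or 'modelseed_db'")
  TRUE
})

#' @rdname MzFbaParams-class
#' @param feature_path Significant-feature table path.
#' @param compound_paths Named character vector of compound lists
#'   (names `pyfba_model` / `modelseed_db`).
#' @param out_dir Output directory for the run.
#' @param polarity,ppm_tol,alpha,rt_window,isotope_rel_tol,n_scans
#'   Pipeline tunables (see slots); defaults: 5 ppm, 0.05, 10 s, 0.20,
#'   3 scans.
#' @param mz_min,mz_max Acquisition mass range, default 50-1000 m/z.
#' @param spectra_paths Optional raw mzXML/mzML files for isotope
#'   validation.
#' @param adducts Adduct table; default the built-in list for
#'   `polarity`.
#' @param feature_dialect `"generic"` or `"xcms_diffreport"`.
#' @export
MzFbaParams <- function(feature_path, compound_paths, out_dir,
                        polarity = "positive", ppm_tol = 5, alpha = 0.05,
                        rt_window = 10, isotope_rel_tol = 0.20,
                        n_scans = 3L, mz_min = 50, mz_max = 1000,
                        spectra_paths = character(0),
                        adducts = defaultAdducts(polarity),
                        feature_dialect = "generic") {
  new("MzFbaParams", polarity = polarity, ppm_tol = ppm_tol, alpha = alpha,
      rt_window = rt_window, isotope_rel_tol = isotope_rel_tol,
      n_scans = as.integer(n_scans), mz_min = mz_min, mz_max = mz_max,
      adducts = validateAdducts(adducts), feature_path = feature_path,
      compound_paths = compound_paths, spectra_paths = spectra_paths,
      out_dir = out_dir, feature_dialect = feature_dialect)
}

setMethod("show", "MzFbaParams", function(object) {
  cat(sprintf(
    "MzFbaParams: %s mode, %g ppm, alpha %g, RT window %g s, %d compound list(s), %d raw file(s)\n",
    object@polarity, object@ppm_tol, object@alpha, object@rt_window,
    length(object@compound_paths), length(object@spectra_paths)))
})

paramsToList <- function(p) {
  list(polarity = p@polarity, ppm_tol = p@ppm_tol, alpha = p@alpha,
       rt_window = p@rt_window, isotope_rel_tol = p@isotope_rel_tol,
       n_scans = p@n_scans, mz_min = p@mz_min, mz_max = p@mz_max,
       adducts = p@adducts, feature_path = p@feature_path,
       compound_paths = as.list(p@compound_paths),
       spectra_paths = p@spectra_paths, out_dir = p@out_dir,
       feature_dialect = p@feature_dialect)
}

#' Reload a run configuration from a run log
#'
#' @param path `params.json` written by [runMatch()].
#' @return An [MzFbaParams-class] object equal to the original.
#' @export
readParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  MzFbaParams(feature_path = x$feature_path,
              compound_paths = unlist(x$compound_paths),
              out_dir = x$out_dir, polarity = x$polarity,
              ppm_tol = x$ppm_tol, alpha = x$alpha,
              rt_window = x$rt_window, isotope_rel_tol = x$isotope_rel_tol,
              n_scans = x$n_scans, mz_min = x$mz_min, mz_max = x$mz_max,
              spectra_paths = if (length(x$spectra_paths))
                as.character(x$spectra_paths) else character(0),
              adducts = as.data.frame(x$adducts),
              feature_dialect = x$feature_dialect)
}

#' Run the full annotation pipeline
#'
#' Orchestrates one annotation pass: load the feature table and the
#' compound list(s); keep significant features; restrict compounds to
#' the detectable range; group co-eluting features; match every
#' compound source by accurate mass; if raw spectra are supplied,
#' measure M+1/M ratios and apply the isotope criteria; then write per
#' source a ranked match TSV, an overall summary (TSV and JSON), the 3D
#' overview plots with sidecars, and a `params.json` run log holding
#' every effective parameter.
#'
#' @param params An [MzFbaParams-class].
#' @return Invisibly, a list with `matches` (named by source),
#'   `summaries`, `features_significant` and the output directory.
#' @export
runMatch <- function(params) {
  stopifnot(is(params, "MzFbaParams"))
  validObject(params)
  dir.create(params@out_dir, recursive = TRUE, showWarnings = FALSE)

  feat <- readFeatureTable(params@feature_path,
                           dialect = params@feature_dialect)
  sig <- filterSignificant(feat, params@alpha)
  mzfbaLog("INFO", sprintf("%d of %d features significant at alpha %g",
                           length(sig), length(feat), params@alpha))
  groups <- groupPeaksRT(sig, params@rt_window)

  spectra <- NULL
  if (length(params@spectra_paths))
    spectra <- readSpectra(params@spectra_paths, params@polarity)

  matches <- list()
  summaries <- list()
  for (src in names(params@compound_paths)) {
    comp <- readCompoundTable(params@compound_paths[[src]], source = src)
    comp <- filterDetectableCompounds(comp, params@mz_min, params@mz_max)
    m <- matchFeatures(sig, comp, params@adducts, params@ppm_tol,
                       groups = groups)
    if (!is.null(spectra) && nrow(m)) {
      fids <- unique(m$feature_id)
      fdf <- features(sig)
      obs <- vapply(fids, function(id) {
        i <- match(id, fdf$feature_id)
        observedM1Ratio(fdf$mz[i], fdf$rt[i], spectra,
                        n_scans = params@n_scans)
      }, 0)
      m <- validateIsotopes(m, obs, params@isotope_rel_tol)
    }
    if (nrow(m) == 0L)
      warning("no matches for source ", src)
    matches[[src]] <- m
    writeMatchTable(m, file.path(params@out_dir,
                                 sprintf("matches_%s.tsv", src)))
    summaries[[src]] <- summarizeMatches(m, sig)
  }

  sumDf <- do.call(rbind, lapply(names(summaries), function(src) {
    s <- summaries[[src]]
    data.frame(source = src,
               n_features_significant = s$n_features_significant,
               n_features_matched = s$n_features_matched,
               n_isotope_matched = s$n_isotope_matched,
               n_compounds_matched = s$n_compounds_matched)
  }))
  writeTsv(sumDf, file.path(params@out_dir, "summary.tsv"))
  jsonlite::write_json(sumDf, file.path(params@out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  allMatches <- do.call(rbind, matches)
  for (w in c("matched", "all", "unmatched"))
    plotMatches3D(sig, allMatches, which = w,
                  path = file.path(params@out_dir,
                                   sprintf("features_%s.png", w)))
  jsonlite::write_json(paramsToList(params),
                       file.path(params@out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(matches = matches, summaries = summaries,
                 features_significant = sig, out_dir = params@out_dir))
}

#' Compare the compounds annotated by two runs
#'
#' Reads the match tables of two finished [runMatch()] output
#' directories (e.g. a reverse-phase positive run and a HILIC negative
#' run) and reports, per common compound source, the compounds
#' exclusive to each run and shared by both.  Written to
#' `overlap.json` in `out_path` when given.
#'
#' @param dir_a,dir_b Run output directories.
#' @param source Compound source to compare (default `pyfba_model`).
#' @param out_path Optional JSON report path.
#' @return The [compareRuns()] list.
#' @export
runCompare <- function(dir_a, dir_b, source = "pyfba_model",
                       out_path = NULL) {
  pa <- file.path(dir_a, sprintf("matches_%s.tsv", source))
  pb <- file.path(dir_b, sprintf("matches_%s.tsv", source))
  for (p in c(pa, pb))
    if (!file.exists(p)) stop("no match table for source '", source,
                              "' in run: ", dirname(p))
  cmp <- compareRuns(readMatchTable(pa), readMatchTable(pb))
  if (!is.null(out_path))
    jsonlite::write_json(cmp, out_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  cmp
}
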