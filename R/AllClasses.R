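#' @import methods
NULL

#' FeatureSet: significant untargeted LC-MS features
#'
#' Container for one run's feature table: one row per (m/z, retention
#' time) feature with its differential-significance p-value and the mean
#' intensity in each growth-phase sample class (mid-, late-exponential,
#' stationary).  Retention times are stored in seconds.
#'
#' @slot features data.frame with columns `feature_id`, `mz`, `rt`
#'   (seconds), `p_value`, `mid`, `late`, `stationary`, `max_intensity`.
#' @seealso [readFeatureTable()], [filterSignificant()], [groupPeaksRT()]
#' @export
setClass("FeatureSet", representation(features = "data.frame"))

.featureCols <- c("feature_id", "mz", "rt", "p_value",
                  "mid", "late", "stationary", "max_intensity")

setValidity("FeatureSet", function(object) {
  df <- object@features
  miss <- setdiff(.featureCols, names(df))
  if (length(miss))
    return(paste("missing feature column(s):", paste(miss, collapse = ", ")))
  if (nrow(df)) {
    if (anyDuplicated(df$feature_id)) return("feature_id values must be unique")
    if (any(df$mz <= 0 | df$mz >= 10000)) return("mz must be in (0, 10000)")
    if (any(df$rt < 0)) return("rt must be >= 0")
    if (any(df$p_value < 0 | df$p_value > 1)) return("p_value must be in [0, 1]")
  }
  TRUE
})

#' Construct a FeatureSet from a data.frame
#'
#' @param features data.frame holding at least `feature_id`, `mz`, `rt`,
#'   `p_value`, `mid`, `late`, `stationary`; `max_intensity` is derived
#'   from the class means when absent.
#' @return A [FeatureSet-class] object.
#' @export
FeatureSet <- function(features) {
  features <- as.data.frame(features)
  if (!"max_intensity" %in% names(features) && nrow(features))
    features$max_intensity <- pmax(features$mid, features$late,
                                   features$stationary)
  if (!"max_intensity" %in% names(features))
    features$max_intensity <- numeric(0)
  features$feature_id <- as.character(features$feature_id)
  new("FeatureSet", features = features[, .featureCols, drop = FALSE])
}

#' CompoundSet: a model or database metabolite list
#'
#' Metabolites from a flux-balance-model export or a compound database,
#' with the monoisotopic mass and predicted M+1 isotope ratio derived
#' from each molecular formula at load time.  Rows whose formulas could
#' not be interpreted are kept aside in `skipped` with the reason.
#'
#' @slot compounds data.frame with columns `compound_id`, `name`,
#'   `formula`, `mono_mass`, `m1_ratio`, `source`.
#' @slot skipped data.frame of rows dropped at load (columns
#'   `compound_id`, `name`, `formula`, `reason`).
#' @seealso [readCompoundTable()], [filterDetectableCompounds()]
#' @export
setClass("CompoundSet",
         representation(compounds = "data.frame", skipped = "data.frame"))

.compoundCols <- c("compound_id", "name", "formula", "mono_mass",
                   "m1_ratio", "source")

setValidity("CompoundSet", function(object) {
  df <- object@compounds
  miss <- setdiff(.compoundCols, names(df))
  if (length(miss))
    return(paste("missing compound column(s):", paste(miss, collapse = ", ")))
  if (nrow(df)) {
    if (any(df$mono_mass <= 0)) return("mono_mass must be > 0")
    if (any(df$m1_ratio < 0)) return("m1_ratio must be >= 0")
    if (anyDuplicated(paste(df$source, df$compound_id)))
      return("compound_id must be unique within a source")
  }
  TRUE
})

#' Construct a CompoundSet, deriving masses and isotope ratios
#'
#' @param compounds data.frame with `compound_id`, `name`, `formula`
#'   columns (formula strings); `mono_mass`/`m1_ratio` are computed.
#' @param source Provenance label, e.g. `"pyfba_model"` or
#'   `"modelseed_db"`.
#' @param skipped Optional data.frame of unparsable rows.
#' @return A [CompoundSet-class] object.
#' @export
CompoundSet <- function(compounds, source = "pyfba_model",
                        skipped = NULL) {
  compounds <- as.data.frame(compounds)
  if (nrow(compounds)) {
    if (!"mono_mass" %in% names(compounds))
      compounds$mono_mass <- vapply(compounds$formula, monoisotopicMass, 0)
    if (!"m1_ratio" %in% names(compounds))
      compounds$m1_ratio <- vapply(compounds$formula,
                                   function(f) predictM1Ratio(f)$m1_ratio, 0)
    compounds$source <- source
    compounds$compound_id <- as.character(compounds$compound_id)
  } else {
    for (col in c("mono_mass", "m1_ratio")) compounds[[col]] <- numeric(0)
    compounds$source <- character(0)
  }
  if (is.null(skipped))
    skipped <- data.frame(compound_id = character(0), name = character(0),
                          formula = character(0), reason = character(0))
  new("CompoundSet", compounds = compounds[, .compoundCols, drop = FALSE],
      skipped = skipped)
}

#' SpectrumCollection: MS1 centroid scans indexed by sample and RT
#'
#' Holds the centroided MS1 scans of one or more raw files, queryable by
#' retention time within a sample.  Each scan is a list with `rt`
#' (seconds), `sample_id`, `mz` (strictly increasing) and `intensity`.
#'
#' @slot scans list of scan records.
#' @slot rt numeric vector of scan retention times (seconds).
#' @slot sample_id character vector of per-scan sample labels.
#' @slot polarity `"positive"` or `"negative"`.
#' @seealso [readSpectra()], [nearestScans()]
#' @export
setClass("SpectrumCollection",
         representation(scans = "list", rt = "numeric",
                        sample_id = "character", polarity = "character"))

setValidity("SpectrumCollection", function(object) {
  n <- length(object@scans)
  if (length(object@rt) != n || length(object@sample_id) != n)
    return("rt and sample_id must parallel the scan list")
  if (!object@polarity %in% c("positive", "negative"))
    return("polarity must be 'positive' or 'negative'")
  for (s in object@scans) {
    if (length(s$mz) != length(s$intensity))
      return("mz and intensity arrays must have equal length")
    if (is.unsorted(s$mz, strictly = TRUE))
      return("scan m/z arrays must be strictly increasing")
    if (any(s$intensity < 0)) return("intensities must be >= 0")
  }
  TRUE
})

SpectrumCollection <- function(scans, polarity) {
  new("SpectrumCollection", scans = scans,
      rt = vapply(scans, `[[`, 0, "rt"),
      sample_id = vapply(scans, `[[`, "", "sample_id"),
      polarity = polarity)
}
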