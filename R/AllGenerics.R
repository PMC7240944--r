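#' Accessors for mzFBA containers
#'
#' `features()` and `compounds()` return the underlying data.frame of a
#' [FeatureSet-class] or [CompoundSet-class]; `skippedCompounds()` the
#' load report of rows dropped for unparsable formulas; `polarity()` the
#' ionization mode of a [SpectrumCollection-class].
#'
#' @param x A package container object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname accessors
#' @export
setGeneric("compounds", function(x) standardGeneric("compounds"))

#' @rdname accessors
#' @export
setGeneric("skippedCompounds", function(x) standardGeneric("skippedCompounds"))

#' @rdname accessors
#' @export
setGeneric("polarity", function(x) standardGeneric("polarity"))

#' @rdname accessors
setMethod("features", "FeatureSet", function(x) x@features)

#' @rdname accessors
setMethod("compounds", "CompoundSet", function(x) x@compounds)

#' @rdname accessors
setMethod("skippedCompounds", "CompoundSet", function(x) x@skipped)

#' @rdname accessors
setMethod("polarity", "SpectrumCollection", function(x) x@polarity)

#' @describeIn accessors number of features
setMethod("length", "FeatureSet", function(x) nrow(x@features))

#' @describeIn accessors number of compounds
setMethod("length", "CompoundSet", function(x) nrow(x@compounds))

#' @describeIn accessors number of scans
setMethod("length", "SpectrumCollection", function(x) length(x@scans))

setMethod("show", "FeatureSet", function(object) {
  df <- object@features
  cat(sprintf("FeatureSet with %d features", nrow(df)))
  if (nrow(df))
    cat(sprintf("; m/z %.4f-%.4f, RT %.1f-%.1f s, %d with p < 0.05",
                min(df$mz), max(df$mz), min(df$rt), max(df$rt),
                sum(df$p_value < 0.05)))
  cat("\n")
})

setMethod("show", "CompoundSet", function(object) {
  cat(sprintf("CompoundSet with %d compounds (%s)%s\n",
              nrow(object@compounds),
              paste(unique(object@compounds$source), collapse = ", "),
              if (nrow(object@skipped))
                sprintf("; %d rows skipped at load", nrow(object@skipped))
              else ""))
})

setMethod("show", "SpectrumCollection", function(object) {
  cat(sprintf(
    "SpectrumCollection: %d MS1 scans, %d sample(s), %s mode, RT %.1f-%.1f s\n",
    length(object@scans), length(unique(object@sample_id)), object@polarity,
    if (length(object@rt)) min(object@rt) else NA,
    if (length(object@rt)) max(object@rt) else NA))
})

#' @describeIn accessors features data.frame
#' @param row.names,optional,... passed through (unused)
setMethod("as.data.frame", "FeatureSet",
          function(x, row.names = NULL, optional = FALSE, ...) x@features)

#' @describeIn accessors compounds data.frame
setMethod("as.data.frame", "CompoundSet",
          function(x, row.names = NULL, optional = FALSE, ...) x@compounds)
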