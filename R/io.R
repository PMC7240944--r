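#' Read an untargeted feature table
#'
#' Loads a delimited significant-feature export into a
#' [FeatureSet-class].  Two dialects are supported: `xcms_diffreport`
#' (columns `name`/`featureidx`, `mzmed`, `rtmed`, `pvalue` and one mean
#' intensity column per sample class) and `generic` (`feature_id`, `mz`,
#' `rt`, `p_value` and the class columns).  All rows are retained
#' regardless of p-value; significance filtering is a separate step
#' ([filterSignificant()]).
#'
#' Retention times are normalized to seconds.  With `rt_units = "auto"`
#' files whose largest RT is below 60 are taken to be in minutes (an
#' LC run shorter than one minute is not plausible, one shorter than
#' 60 s of seconds is); the decision is logged.  Pass `"minutes"` or
#' `"seconds"` to override.
#'
#' @param path Delimited text file with a header (separator sniffed).
#' @param dialect `"xcms_diffreport"` or `"generic"`.
#' @param rt_units `"auto"`, `"seconds"` or `"minutes"`.
#' @param class_map Named character vector mapping the internal phase
#'   names `mid`, `late`, `stationary` to the file's column names.
#' @return A [FeatureSet-class].
#' @export
readFeatureTable <- function(path,
                             dialect = c("xcms_diffreport", "generic"),
                             rt_units = c("auto", "seconds", "minutes"),
                             class_map = c(mid = "mid", late = "late",
                                           stationary = "stationary")) {
  dialect <- match.arg(dialect)
  rt_units <- match.arg(rt_units)
  stopifnot(all(c("mid", "late", "stationary") %in% names(class_map)))
  tab <- utils::read.table(path, header = TRUE, sep = sniffSep(path),
                           stringsAsFactors = FALSE, quote = "\"",
                           check.names = FALSE)
  cols <- if (dialect == "xcms_diffreport") {
    idcol <- intersect(c("name", "featureidx"), names(tab))[1]
    if (is.na(idcol)) idcol <- "name"
    c(feature_id = idcol, mz = "mzmed", rt = "rtmed", p_value = "pvalue",
      class_map)
  } else {
    c(feature_id = "feature_id", mz = "mz", rt = "rt", p_value = "p_value",
      class_map)
  }
  miss <- setdiff(unname(cols), names(tab))
  if (length(miss))
    stop(sprintf("feature table %s is missing required column(s): %s",
                 path, paste(miss, collapse = ", ")))
  df <- stats::setNames(tab[, unname(cols), drop = FALSE], names(cols))
  for (col in c("mz", "rt", "p_value", "mid", "late", "stationary")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("unparsable numeric value in column '%s', row %d of %s",
                   col, bad[1], path))
    df[[col]] <- v
  }
  if (rt_units == "minutes" ||
      (rt_units == "auto" && nrow(df) > 0 && max(df$rt) < 60)) {
    df$rt <- df$rt * 60
    mzfbaLog("INFO", "retention times interpreted as minutes; converted to seconds")
  }
  if ("maxint" %in% names(tab)) df$max_intensity <- as.numeric(tab$maxint)
  FeatureSet(df)
}

#' Read a model or database compound list
#'
#' Loads a TSV/CSV metabolite export (a flux-balance model's predicted
#' metabolite list, or a ModelSEED-style database dump) into a
#' [CompoundSet-class].  Requires id, name and formula columns
#' (`compound_id`/`id`, `name`, `formula`).  Monoisotopic mass and the
#' predicted M+1 isotope ratio are derived from each formula.
#'
#' Database dumps store formulas at physiological charge.  When a
#' `charge` column is present (and `adjust_charge = TRUE`) the neutral
#' form is recovered by adding `-charge` hydrogens before computing the
#' mass; without a charge column the formula is used as-is and a caveat
#' is logged.  Rows with missing, `"null"` or uninterpretable formulas
#' (R-groups, parentheses, charge notation) are skipped and reported in
#' the load report ([skippedCompounds()]).
#'
#' @param path Delimited file; separator sniffed from the header.
#' @param source `"pyfba_model"` or `"modelseed_db"`.
#' @param adjust_charge Recover neutral formulas via a `charge` column.
#' @param strict Error (instead of warn) when more than half the rows
#'   are skipped.
#' @return A [CompoundSet-class].
#' @export
readCompoundTable <- function(path,
                              source = c("pyfba_model", "modelseed_db"),
                              adjust_charge = TRUE, strict = FALSE) {
  source <- match.arg(source)
  tab <- utils::read.table(path, header = TRUE, sep = sniffSep(path),
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (nrow(tab) == 0L) stop("compound file has no rows: ", path)
  names(tab) <- tolower(names(tab))
  idcol <- intersect(c("compound_id", "id"), names(tab))[1]
  miss <- c(if (is.na(idcol)) "id", setdiff(c("name", "formula"), names(tab)))
  if (length(miss))
    stop(sprintf("compound table %s is missing required column(s): %s",
                 path, paste(miss, collapse = ", ")))
  hasCharge <- "charge" %in% names(tab) && adjust_charge
  if (!hasCharge && source == "modelseed_db")
    mzfbaLog("INFO", "no charge column: formulas matched as stored, ",
             "which may be the ionized form")

  keep <- vector("list", nrow(tab))
  skip <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    ftxt <- as.character(tab$formula[i])
    rec <- list(compound_id = as.character(tab[[idcol]][i]),
                name = as.character(tab$name[i]), formula = ftxt)
    if (is.na(ftxt) || !nzchar(ftxt) || tolower(ftxt) %in% c("null", "none")) {
      skip[[i]] <- c(rec, reason = "missing formula"); next
    }
    counts <- tryCatch(parseFormula(ftxt), error = function(e) e)
    if (inherits(counts, "error")) {
      skip[[i]] <- c(rec, reason = conditionMessage(counts)); next
    }
    if (hasCharge) {
      z <- suppressWarnings(as.integer(tab$charge[i]))
      if (!is.na(z) && z != 0L) {
        h <- if ("H" %in% names(counts)) counts[["H"]] else 0L
        h <- h - z
        if (h < 0L) {
          skip[[i]] <- c(rec, reason = "charge adjustment yields negative H")
          next
        }
        counts <- counts[names(counts) != "H"]
        if (h > 0L) counts <- c(counts, c(H = h))
        rec$formula <- formatFormula(counts)
      }
    }
    rec$mono_mass <- monoisotopicMass(counts)
    rec$m1_ratio <- predictM1Ratio(counts)$m1_ratio
    keep[[i]] <- rec
  }
  keep <- keep[!vapply(keep, is.null, TRUE)]
  skip <- skip[!vapply(skip, is.null, TRUE)]
  skipped <- if (length(skip))
    do.call(rbind, lapply(skip, function(x) as.data.frame(x)))
  else NULL
  if (length(skip) > nrow(tab) / 2) {
    msg <- sprintf("%d of %d compound rows skipped (unparsable formulas) in %s",
                   length(skip), nrow(tab), path)
    if (strict) stop(msg) else warning(msg)
  }
  if (!length(keep)) stop("no usable compounds in ", path)
  cmp <- do.call(rbind, lapply(keep, as.data.frame))
  if (anyDuplicated(cmp$compound_id))
    stop("duplicate compound_id values in ", path)
  mzfbaLog("INFO", sprintf("loaded %d compounds from %s (%d skipped)",
                           nrow(cmp), basename(path), length(skip)))
  CompoundSet(cmp, source = source, skipped = skipped)
}

.matchCols <- c("compound_name", "feature_id", "observed_mz", "rt",
                "peak_group", "isotope_ratio_difference", "isotope_pass",
                "adduct", "ppm_error", "source",
                "compound_id", "theoretical_mz", "predicted_m1_ratio",
                "observed_m1_ratio")

#' Write and read the ranked match table
#'
#' The annotation report: one row per (feature, compound, adduct) match,
#' leading with the compound name, the feature ID from the upstream
#' feature-detection results, the observed m/z, retention time, peak
#' group, the isotope ratio difference (observed minus predicted
#' M+1/M), whether the match met the isotope-ratio criteria, and the
#' identified adduct, followed by the signed ppm error, the compound
#' source and diagnostic columns.  Rows are ordered by feature ID then
#' absolute ppm error; a write/read cycle is the identity up to float
#' formatting.
#'
#' @param matches Match data.frame (from [matchFeatures()] /
#'   [validateIsotopes()]).
#' @param path Output TSV path.
#' @return `writeMatchTable` returns `path` invisibly; `readMatchTable`
#'   the match data.frame.
#' @export
writeMatchTable <- function(matches, path) {
  matches <- normalizeMatches(matches)
  ord <- order(matches$feature_id, abs(matches$ppm_error))
  writeTsv(format(matches[ord, .matchCols, drop = FALSE],
                  digits = 10, scientific = FALSE, trim = TRUE), path)
}

#' @rdname writeMatchTable
#' @export
readMatchTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "\"",
                           na.strings = "NA",
                           colClasses = c(isotope_pass = "character",
                                          feature_id = "character",
                                          compound_id = "character"))
  normalizeMatches(tab)
}

# canonical column set/order and types for a match data.frame
normalizeMatches <- function(matches) {
  matches <- as.data.frame(matches)
  for (col in setdiff(.matchCols, names(matches)))
    matches[[col]] <- switch(col,
      isotope_pass = rep("not_evaluated", nrow(matches)),
      peak_group = rep(NA_integer_, nrow(matches)),
      rep(NA_real_, nrow(matches)))
  num <- c("observed_mz", "rt", "isotope_ratio_difference", "ppm_error",
           "theoretical_mz", "predicted_m1_ratio", "observed_m1_ratio")
  for (col in num) matches[[col]] <- as.numeric(matches[[col]])
  matches$peak_group <- as.integer(matches$peak_group)
  matches[, .matchCols, drop = FALSE]
}
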