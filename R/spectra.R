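#' Read raw MS1 centroid spectra from mzXML/mzML files
#'
#' Opens each raw file through `mzR`, keeps MS1 scans, and returns a
#' [SpectrumCollection-class] queryable by sample and retention time.
#' One file is one sample; the sample label is the file name without
#' extension.  Profile-mode scans are rejected by default or reduced to
#' local maxima when `centroid = TRUE`.
#'
#' @param paths Character vector of mzXML/mzML paths.
#' @param polarity `"positive"` or `"negative"`; scans carrying an
#'   explicit opposite polarity flag are dropped.
#' @param centroid Pick local maxima from profile scans instead of
#'   rejecting them.
#' @return A [SpectrumCollection-class].
#' @export
readSpectra <- function(paths, polarity = c("positive", "negative"),
                        centroid = FALSE) {
  polarity <- match.arg(polarity)
  scans <- list()
  for (path in paths) {
    if (!file.exists(path)) stop("raw file not found: ", path)
    sample_id <- sub("\\.(mzXML|mzML|mzxml|mzml)$", "", basename(path))
    handle <- tryCatch(mzR::openMSfile(path),
                       error = function(e)
                         stop("cannot read raw file ", path, ": ",
                              conditionMessage(e)))
    on.exit(mzR::close(handle), add = TRUE)
    hdr <- mzR::header(handle)
    ms1 <- which(hdr$msLevel == 1L)
    if (!length(ms1)) stop("no MS1 scans in ", path)
    want <- if (polarity == "positive") 1L else 0L
    flagged <- !is.na(hdr$polarity[ms1]) & hdr$polarity[ms1] >= 0
    ms1 <- ms1[!flagged | hdr$polarity[ms1] == want]
    if (!length(ms1))
      stop("no MS1 scans of polarity '", polarity, "' in ", path)
    for (i in ms1) {
      pk <- mzR::peaks(handle, i)
      centroided <- hdr$centroided[i]
      if (!is.na(centroided) && !centroided && nrow(pk) > 0L) {
        if (!centroid)
          stop("profile-mode scan in ", path,
               " (set centroid = TRUE to pick local maxima)")
        pk <- pickLocalMaxima(pk)
      }
      ord <- order(pk[, 1])
      pk <- pk[ord, , drop = FALSE]
      dup <- duplicated(pk[, 1])
      pk <- pk[!dup, , drop = FALSE]
      scans[[length(scans) + 1L]] <-
        list(rt = hdr$retentionTime[i], sample_id = sample_id,
             mz = unname(pk[, 1]), intensity = unname(pk[, 2]))
    }
  }
  mzfbaLog("INFO", sprintf("read %d MS1 scans from %d file(s)",
                           length(scans), length(paths)))
  SpectrumCollection(scans, polarity)
}

pickLocalMaxima <- function(pk) {
  n <- nrow(pk)
  if (n <= 2L) return(pk)
  y <- pk[, 2]
  keep <- c(y[1] > y[2], y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n],
            y[n] > y[n - 1]) & y > 0
  pk[keep, , drop = FALSE]
}

#' Scans nearest a retention time
#'
#' Returns, per sample, the `n` scans whose retention times are closest
#' to `rt` (verified minimal-distance selection), skipping samples with
#' no scan inside `rt_radius`.
#'
#' @param x A [SpectrumCollection-class].
#' @param rt Query retention time, seconds.
#' @param n Scans per sample.
#' @param rt_radius Maximum |scan RT - rt| in seconds for the nearest
#'   scan of a sample to count as covering the query.
#' @return Named list (by sample) of lists of scan records; samples with
#'   no coverage are omitted.
#' @export
nearestScans <- function(x, rt, n = 3L, rt_radius = 30) {
  stopifnot(is(x, "SpectrumCollection"), n >= 1L)
  out <- list()
  for (sid in unique(x@sample_id)) {
    idx <- which(x@sample_id == sid)
    d <- abs(x@rt[idx] - rt)
    if (!length(idx) || min(d) > rt_radius) next
    sel <- idx[order(d)][seq_len(min(n, length(idx)))]
    out[[sid]] <- x@scans[sel]
  }
  out
}

#' Summed intensity in a narrow m/z window of one scan
#'
#' @param scan A scan record (`mz`, `intensity`).
#' @param mz Window center.
#' @param ppm Half-width in ppm.
#' @return Summed intensity (0 when nothing falls in the window).
#' @keywords internal
windowIntensity <- function(scan, mz, ppm) {
  tol <- mz * ppm * 1e-6
  lo <- findInterval(mz - tol, scan$mz) + 1L
  hi <- findInterval(mz + tol, scan$mz)
  if (hi < lo) 0 else sum(scan$intensity[lo:hi])
}
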