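# Graphical outputs.  Every plot writes a machine-readable TSV sidecar
# with the exact plotted coordinates next to the image, so tests and
# downstream scripts assert numbers rather than pixels; plotting never
# mutates analysis state.

#' 3D scatter of features over m/z, retention time and intensity change
#'
#' The run overview: x = m/z, y = retention time, z = growth-phase
#' intensity difference, with two points per plotted feature — the
#' late-minus-mid difference in red and the stationary-minus-late
#' difference in blue.  `which` selects the matched features, all
#' significant features, or the unmatched remainder.
#'
#' @param x A [FeatureSet-class] (the significant features).
#' @param matches Match data.frame (needed for `"matched"` /
#'   `"unmatched"`).
#' @param which `"matched"`, `"all"` or `"unmatched"`.
#' @param path Output image path (`.png` or `.svg` by extension); the
#'   sidecar is written at `paste0(path, ".tsv")`.
#' @return Invisibly, the sidecar data.frame (`feature_id`, `mz`, `rt`,
#'   `delta`, `contrast`).
#' @export
plotMatches3D <- function(x, matches = NULL,
                          which = c("matched", "all", "unmatched"), path) {
  which <- match.arg(which)
  stopifnot(is(x, "FeatureSet"))
  df <- features(x)
  if (which != "all") {
    if (is.null(matches)) stop("matches required for which = '", which, "'")
    hit <- df$feature_id %in% unique(matches$feature_id)
    df <- df[if (which == "matched") hit else !hit, , drop = FALSE]
  }
  deltas <- phaseDeltas(FeatureSet(df))
  n <- nrow(deltas)
  side <- rbind(
    data.frame(feature_id = deltas$feature_id, mz = df$mz, rt = df$rt,
               delta = deltas$late_minus_mid,
               contrast = rep("late_minus_mid", n)),
    data.frame(feature_id = deltas$feature_id, mz = df$mz, rt = df$rt,
               delta = deltas$stationary_minus_late,
               contrast = rep("stationary_minus_late", n)))
  writeTsv(side, paste0(path, ".tsv"))
  openDevice(path)
  if (nrow(side) == 0L) {
    warning("nothing to plot for which = '", which, "'")
    graphics::plot.new()
    graphics::title(main = sprintf("%s features (none)", which))
  } else {
    print(lattice::cloud(
      delta ~ mz * rt, data = side,
      groups = factor(side$contrast,
                      levels = c("late_minus_mid", "stationary_minus_late")),
      col = c("red", "blue"), pch = 16, cex = 0.6,
      xlab = "m/z", ylab = "RT (s)", zlab = "intensity difference",
      main = sprintf("%s features (n = %d)", which, nrow(side) / 2),
      auto.key = list(text = c("late - mid", "stationary - late"),
                      points = TRUE, col = c("red", "blue"))))
  }
  grDevices::dev.off()
  invisible(side)
}

openDevice <- function(path, width = 7, height = 6) {
  if (grepl("\\.svg$", path)) grDevices::svg(path, width = width, height = height)
  else grDevices::png(path, width = width * 120, height = height * 120, res = 120)
}

#' Growth-phase box plot of one feature
#'
#' Box-and-whisker plot of the per-replicate intensities of a feature
#' across the mid-exponential, late-exponential and stationary phases,
#' as used to inspect the production-then-consumption pattern of a
#' matched metabolite.  The sidecar TSV carries the five-number summary
#' per phase.
#'
#' @param intensities Named list with numeric vectors `mid`, `late`,
#'   `stationary` (one value per biological replicate; at least one
#'   each).
#' @param path Output image path; sidecar at `paste0(path, ".tsv")`.
#' @param feature_id Label for the plot title.
#' @return Invisibly, the sidecar data.frame (`phase`, `min`, `q1`,
#'   `median`, `q3`, `max`, `n`).
#' @export
plotPhaseBoxplot <- function(intensities, path, feature_id = "") {
  phases <- c("mid", "late", "stationary")
  for (p in phases)
    if (is.null(intensities[[p]]) || length(intensities[[p]]) == 0L)
      stop("no replicate intensities for phase '", p, "'")
  side <- do.call(rbind, lapply(phases, function(p) {
    v <- intensities[[p]]
    fv <- stats::fivenum(v)
    data.frame(phase = p, min = fv[1], q1 = fv[2], median = fv[3],
               q3 = fv[4], max = fv[5], n = length(v))
  }))
  writeTsv(side, paste0(path, ".tsv"))
  openDevice(path, width = 5, height = 5)
  graphics::boxplot(intensities[phases], names = phases,
                    col = c("grey80", "grey60", "grey40"),
                    ylab = "intensity", main = feature_id)
  grDevices::dev.off()
  invisible(side)
}
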