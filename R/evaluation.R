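# ROI-based accuracy metrics, the detection criterion and sample-level
# aggregation.

#' ROI accuracy metrics of a reconstruction
#'
#' Evaluates a fine-grid estimate inside a spherical region of interest
#' (default 60 mm diameter) centered at the true source position:
#' amplitude-weighted center of mass versus the true position, the angle
#' between the net (vector-summed) ROI moment and the true orientation,
#' the log10 ratio of the net moment norm to the true amplitude, and the
#' relative maximum (max ROI amplitude over max global amplitude). The
#' source counts as detected when the relative maximum strictly exceeds
#' the threshold (default 0.1).
#'
#' @param x numeric length-3K estimate on the fine grid.
#' @param space the [SourceSpace-class].
#' @param truth a [DipoleSource-class] (its position is the ROI center
#'   unless `center` is given).
#' @param diameter ROI diameter in mm (default 60).
#' @param threshold detection cutoff on the relative maximum, in (0, 1)
#'   (default 0.1).
#' @param center optional ROI center override (mm).
#' @return one-row `data.frame` with columns `positionError` (mm),
#'   `angleError` (degrees, NA for an all-zero ROI), `log10AmpError`,
#'   `relativeMaximum`, `detected`, and `scalarAmplitudeSum` (the scalar
#'   sum of ROI amplitudes, exported for sensitivity checks).
#' @export
roiMetrics <- function(x, space, truth, diameter = 60, threshold = 0.1,
                       center = NULL) {
  stopifnot(is(space, "SourceSpace"), is(truth, "DipoleSource"))
  if (diameter <= 0) stop("diameter must be positive")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  if (length(x) != 3L * nSources(space))
    stop("estimate does not match the source space", call. = FALSE)
  if (is.null(center)) center <- truth@position
  d <- sqrt(colSums((t(space@positions) - center)^2))
  inRoi <- d <= diameter / 2
  if (!any(inRoi))
    stop("ROI contains no source position", call. = FALSE)
  amp <- sourceAmplitudes(x)
  maxGlobal <- max(amp)
  ampRoi <- amp[inRoi]
  relMax <- if (maxGlobal > 0) max(ampRoi) / maxGlobal else 0
  moments <- matrix(x, nrow = 3L)[, inRoi, drop = FALSE]
  net <- rowSums(moments)
  netNorm <- .vnorm(net)
  if (sum(ampRoi) > 0) {
    com <- colSums(space@positions[inRoi, , drop = FALSE] * ampRoi) /
      sum(ampRoi)
    posErr <- .vnorm(com - truth@position)
  } else {
    posErr <- NA_real_
  }
  angErr <- if (netNorm > 0) {
    cosA <- sum(net / netNorm * truth@direction)
    acos(pmin(1, pmax(-1, cosA))) * 180 / pi
  } else NA_real_
  ampErr <- if (truth@amplitude > 0 && netNorm > 0) {
    log10(netNorm / truth@amplitude)
  } else NA_real_
  data.frame(positionError = posErr, angleError = angErr,
             log10AmpError = ampErr, relativeMaximum = relMax,
             detected = relMax > threshold,
             scalarAmplitudeSum = sum(ampRoi))
}

#' Aggregate per-realization ROI metrics
#'
#' Medians and 90% intervals (5th to 95th percentile, linear
#' interpolation) of each metric, plus the percentage of realizations
#' satisfying the detection criterion.
#'
#' @param metrics `data.frame` with one [roiMetrics()] row per
#'   realization.
#' @return `data.frame` with columns `metric`, `median`, `q05`, `q95`,
#'   and an attached `detectionPercentage` attribute also present as a
#'   row of the column `metric == "detected"` expressed in percent.
#' @export
summarizeMetrics <- function(metrics) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0L)
    stop("metrics must be a non-empty data.frame", call. = FALSE)
  cols <- c("positionError", "angleError", "log10AmpError",
            "relativeMaximum")
  rows <- lapply(cols, function(cn) {
    v <- metrics[[cn]]
    v <- v[is.finite(v)]
    if (length(v) == 0L)
      return(data.frame(metric = cn, median = NA_real_, q05 = NA_real_,
                        q95 = NA_real_))
    q <- quantile(v, c(0.05, 0.95), names = FALSE, type = 7)
    data.frame(metric = cn, median = median(v), q05 = q[1L], q95 = q[2L])
  })
  out <- do.call(rbind, rows)
  pct <- 100 * mean(metrics$detected)
  out <- rbind(out, data.frame(metric = "detected", median = pct,
                               q05 = NA_real_, q95 = NA_real_))
  attr(out, "detectionPercentage") <- pct
  out
}

#' Detection percentage of a metrics table
#' @param metrics `data.frame` of [roiMetrics()] rows.
#' @return numeric percentage in [0, 100].
#' @export
detectionPercentage <- function(metrics) 100 * mean(metrics$detected)

#' Fixed-width histogram table of the ROI metrics
#'
#' @param metrics `data.frame` of [roiMetrics()] rows.
#' @param bins integer, bin count per metric (default 20).
#' @return `data.frame` with columns `metric`, `binStart`, `binEnd`,
#'   `count`; counts per metric sum to the number of finite values.
#' @export
histogramTable <- function(metrics, bins = 20L) {
  bins <- .assertCount(bins, "bins")
  cols <- c("positionError", "angleError", "log10AmpError",
            "relativeMaximum")
  rows <- lapply(cols, function(cn) {
    v <- metrics[[cn]]
    v <- v[is.finite(v)]
    if (length(v) == 0L) return(NULL)
    rng <- range(v)
    if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1L], rng[2L], length.out = bins + 1L)
    idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                bins)
    data.frame(metric = cn, binStart = edges[-(bins + 1L)],
               binEnd = edges[-1L], count = tabulate(idx, bins))
  })
  do.call(rbind, rows)
}
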