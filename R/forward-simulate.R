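#' Simulate sensor data from dipole sources
#'
#' Each dipole is matched to the nearest source-space position (a warning
#' is issued above 5 mm mismatch); the noiseless data are the
#' amplitude-weighted superposition of the corresponding lead-field
#' columns. Zero-mean Gaussian white noise with standard deviation
#' `noisePct` percent of the maximal clean signal amplitude is added, and
#' the result is max-normalized to one. The noise standard deviation is
#' recorded on the same normalized scale.
#'
#' @param lead a [LeadField-class].
#' @param space the [SourceSpace-class] the lead field was built on.
#' @param dipoles a [DipoleSource-class] or list thereof.
#' @param noisePct numeric, noise level in percent (default 3).
#' @param seed optional integer seed for the noise draw.
#' @return a [MeasurementSet-class] with `max(abs(y)) == 1`.
#' @examples
#' head <- headModel()
#' sp <- buildSourceSpace(200, seed = 1)
#' L <- eegLeadfield(sp, electrodeArray(head, 32), head)
#' simulateData(L, sp, defaultDipoles(10, 5), noisePct = 3, seed = 2)
#' @export
simulateData <- function(lead, space, dipoles, noisePct = 3, seed = NULL) {
  stopifnot(is(lead, "LeadField"), is(space, "SourceSpace"))
  if (is(dipoles, "DipoleSource")) dipoles <- list(dipoles)
  dipoles <- Filter(function(d) d@amplitude > 0, dipoles)
  if (length(dipoles) == 0L && noisePct == 0)
    stop("degenerate data: no active dipole and no noise", call. = FALSE)
  if (nSources(lead) != nSources(space))
    stop("lead field and source space disagree on the position count",
         call. = FALSE)
  m <- nrow(lead@matrix)
  clean <- numeric(m)
  for (d in dipoles) {
    d2 <- colSums((t(space@positions) - d@position)^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) > 5)
      warning(sprintf(
        "dipole at (%.1f, %.1f, %.1f) mm is %.1f mm from its nearest source position",
        d@position[1], d@position[2], d@position[3], sqrt(d2[j])))
    clean <- clean +
      d@amplitude * drop(lead@matrix[, .componentCols(j)] %*% d@direction)
  }
  maxClean <- max(abs(clean))
  if (maxClean == 0 && noisePct == 0)
    stop("degenerate data: clean signal is identically zero", call. = FALSE)
  sdRaw <- noisePct / 100 * maxClean
  .withSeed(seed, {
    yRaw <- clean + rnorm(m, 0, sdRaw)
    f <- max(abs(yRaw))
    if (f == 0)
      stop("degenerate data: simulated measurement is identically zero",
           call. = FALSE)
    new("MeasurementSet", y = yRaw / f, sigma = sdRaw / f,
        cleanY = clean / f, normalizationFactor = f)
  })
}

#' Fuse EEG and MEG into a combined E/MEG system
#'
#' Stacks the two systems row-wise after multiplying the MEG lead field
#' and data by c = ||L_EEG||_F / ||L_MEG||_F, so both blocks carry equal
#' Frobenius norm. The scaling is applied on the raw (pre-normalization)
#' scale — the two separately max-normalized datasets imply different
#' source magnitudes, so they are first mapped back via their recorded
#' normalization factors — and the stacked data vector is then
#' max-normalized jointly. The pooled noise level is the
#' row-count-weighted RMS of the per-block (scaled) noise standard
#' deviations, on the joint normalized scale.
#'
#' @param leadEEG,leadMEG [LeadField-class] objects over the same source
#'   space.
#' @param measEEG,measMEG matching [MeasurementSet-class] objects.
#' @return list with elements `lead` (modality `"EMEG"`) and
#'   `measurement` (with `max(abs(y)) == 1`).
#' @export
combineEMEG <- function(leadEEG, measEEG, leadMEG, measMEG) {
  stopifnot(is(leadEEG, "LeadField"), is(leadMEG, "LeadField"),
            is(measEEG, "MeasurementSet"), is(measMEG, "MeasurementSet"))
  if (ncol(leadEEG@matrix) != ncol(leadMEG@matrix))
    stop("dimension error: EEG and MEG lead fields must share one source space",
         call. = FALSE)
  if (length(measEEG@y) != nrow(leadEEG@matrix) ||
      length(measMEG@y) != nrow(leadMEG@matrix))
    stop("dimension error: measurements do not match their lead fields",
         call. = FALSE)
  cc <- norm(leadEEG@matrix, "F") / norm(leadMEG@matrix, "F")
  fe <- measEEG@normalizationFactor
  fm <- measMEG@normalizationFactor
  yRaw <- c(measEEG@y * fe, cc * measMEG@y * fm)
  cleanRaw <- c(measEEG@cleanY * fe, cc * measMEG@cleanY * fm)
  f <- max(abs(yRaw))
  me <- length(measEEG@y)
  mm <- length(measMEG@y)
  sigma <- sqrt((me * (measEEG@sigma * fe)^2 +
                 mm * (cc * measMEG@sigma * fm)^2) / (me + mm)) / f
  lead <- new("LeadField",
              matrix = rbind(leadEEG@matrix, cc * leadMEG@matrix),
              modality = "EMEG", units = "Ohm/m; 1/m^2 (Frobenius-scaled)")
  meas <- new("MeasurementSet",
              y = yRaw / f, sigma = sigma, cleanY = cleanRaw / f,
              normalizationFactor = f)
  list(lead = lead, measurement = meas)
}

#' Scale a lead field to unit mean column norm
#'
#' Divides the matrix by the mean of its column 2-norms — a single
#' global scalar, so the operation is depth-, resolution- and
#' decomposition-invariant and introduces no source weighting. On this
#' normalized scale the hyperprior scale parameter of the hierarchical
#' model becomes comparable across forward models and modalities.
#'
#' @param lead a [LeadField-class].
#' @return list with `lead` (the scaled [LeadField-class]) and `scale`
#'   (the divisor applied).
#' @export
normalizeLeadField <- function(lead) {
  stopifnot(is(lead, "LeadField"))
  a <- mean(sqrt(colSums(lead@matrix^2)))
  if (a == 0) stop("lead field is identically zero", call. = FALSE)
  list(lead = new("LeadField", matrix = lead@matrix / a,
                  modality = lead@modality,
                  units = paste0(lead@units, " / ", format(a))),
       scale = a)
}
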