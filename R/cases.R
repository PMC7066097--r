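# Configuration-driven replication of the two-dipole validation cases.

# Case matrix for the spherical-head experiments: modality, sparsity
# factor, decomposition count, hyperprior family and the deep /
# superficial dipole amplitudes.
.CASE_TABLE <- data.frame(
  caseId = LETTERS[1:9],
  modality = c("EEG", "EEG", "EEG", "EEG", "EEG", "EEG", "EEG",
               "EMEG", "EMEG"),
  sparsity = c(8, 8, 8, 8, 5, 8, 8, 8, 8),
  nDecompositions = c(100L, 100L, 100L, 100L, 100L, 20L, 100L, 100L, 100L),
  hyperprior = c("IG", "IG", "IG", "IG", "IG", "IG", "G", "IG", "IG"),
  deepAmplitude = c(10, 10, 0, 10, 10, 10, 10, 10, 10),
  superficialAmplitude = c(5, 0, 5, 7, 7, 7, 5, 5, 7),
  stringsAsFactors = FALSE)

#' The validation case matrix
#'
#' One row per spherical-head case (A)-(I): measurement modality,
#' sparsity factor s, decomposition count D, hyperprior family and the
#' deep / superficial dipole amplitudes. All cases use 3% noise and 50
#' noise realizations unless overridden.
#'
#' @return a `data.frame` with nine rows.
#' @export
caseTable <- function() .CASE_TABLE

#' Build a validation case configuration
#'
#' `scaleFactor < 1` shrinks the decomposition count and the realization
#' count proportionally (floor, minimum 5) for reduced desk-scale runs;
#' such runs are labeled as scaled in every serialized output. The
#' single-step (minimum-norm) and coarse-level-only variants are exposed
#' through `nIter = 1` and `nLevels = 1`.
#'
#' @param caseId one of `"A"`..`"I"` (see [caseTable()]).
#' @param scaleFactor numeric in (0, 1].
#' @param noisePct noise level in percent (default 3; 5 reproduces the
#'   high-noise variant).
#' @param nRealizations independent noise realizations (default 50).
#' @param nLevels resolution levels (default 3).
#' @param nIter IAS iterations per level (default 10; 1 gives the
#'   minimum-norm variant).
#' @param seed master seed.
#' @return a [CaseConfig-class].
#' @examples
#' caseConfig("A", scaleFactor = 0.25, seed = 1)
#' @export
caseConfig <- function(caseId, scaleFactor = 1, noisePct = 3,
                       nRealizations = 50L, nLevels = 3L, nIter = 10L,
                       seed = NULL) {
  row <- .CASE_TABLE[.CASE_TABLE$caseId == toupper(caseId), ]
  if (nrow(row) != 1L)
    stop(sprintf("config error: unknown case id '%s'", caseId),
         call. = FALSE)
  scaled <- function(n) max(5L, as.integer(floor(n * scaleFactor)))
  new("CaseConfig", caseId = row$caseId, modality = row$modality,
      sparsity = row$sparsity,
      nDecompositions = scaled(row$nDecompositions),
      hyperprior = row$hyperprior, deepAmplitude = row$deepAmplitude,
      superficialAmplitude = row$superficialAmplitude,
      noisePct = noisePct, nRealizations = scaled(nRealizations),
      nLevels = as.integer(nLevels), nIter = as.integer(nIter),
      scaleFactor = scaleFactor,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Forward assets shared by the validation cases
#'
#' Builds the source space, electrode and magnetometer arrays and both
#' lead fields once; every case and realization reuses them.
#'
#' @param K source position count.
#' @param nSensors sensors per modality (default 102).
#' @param head a [HeadModel-class] (default Ary).
#' @param seed seed for the source-space draw.
#' @param meg also build the MEG lead field (default TRUE).
#' @param rMax outer source-shell radius in mm (default 86.5, so the
#'   near-cortex test dipole has candidate positions on all sides while
#'   staying strictly inside the 87 mm brain sphere).
#' @return list with `space`, `head`, `electrodes`, `magnetometers`,
#'   `leadEEG`, `leadMEG`.
#' @export
makeCaseAssets <- function(K, nSensors = 102L, head = headModel(),
                           seed = NULL, meg = TRUE, rMax = 86.5) {
  space <- buildSourceSpace(K, 0, rMax, seed = seed)
  electrodes <- electrodeArray(head, nSensors)
  leadEEG <- eegLeadfield(space, electrodes, head)
  magnetometers <- NULL
  leadMEG <- NULL
  if (meg) {
    magnetometers <- magnetometerArray(electrodes)
    leadMEG <- megLeadfield(space, magnetometers, head)
  }
  list(space = space, head = head, electrodes = electrodes,
       magnetometers = magnetometers, leadEEG = leadEEG,
       leadMEG = leadMEG)
}

#' Run one validation case
#'
#' For each realization: a fresh noise vector is drawn (independently
#' per modality for combined E/MEG), the RAMUS reconstruction is
#' computed, and both 60 mm ROIs (deep and superficial) are evaluated —
#' a dipole with zero amplitude is omitted from the simulation but its
#' ROI is still scored, which is how false positives are counted.
#'
#' @param cfg a [CaseConfig-class].
#' @param assets forward assets from [makeCaseAssets()].
#' @param keepReconstructions logical, retain the final estimate of each
#'   realization (default FALSE to save memory).
#' @return list with `config`, `deep` and `superficial` per-realization
#'   metric `data.frame`s, matching `summaryDeep` / `summarySuperficial`
#'   tables, and `scaled` flag.
#' @export
runCase <- function(cfg, assets, keepReconstructions = FALSE) {
  stopifnot(is(cfg, "CaseConfig"))
  seed <- if (is.na(cfg@seed)) NULL else cfg@seed
  dipDeep <- dipoleSource(c(7, 0, 5), angleDeg = 68, amplitude = 1)
  dipSup <- dipoleSource(c(-50, 7, 71), angleDeg = 1, amplitude = 1)
  active <- defaultDipoles(cfg@deepAmplitude, cfg@superficialAmplitude)
  hp <- if (cfg@hyperprior == "IG") igHyperprior() else gammaHyperprior()
  .withSeed(seed, {
    n <- cfg@nRealizations
    seedsNoise <- .drawSeeds(n)
    seedsNoiseMeg <- .drawSeeds(n)
    seedsDecomp <- .drawSeeds(n)
    deepRows <- vector("list", n)
    supRows <- vector("list", n)
    recs <- if (keepReconstructions) vector("list", n) else NULL
    for (i in seq_len(n)) {
      measE <- simulateData(assets$leadEEG, assets$space, active,
                            noisePct = cfg@noisePct,
                            seed = seedsNoise[i])
      if (cfg@modality == "EMEG") {
        if (is.null(assets$leadMEG))
          stop("assets lack a MEG lead field for an E/MEG case")
        measM <- simulateData(assets$leadMEG, assets$space, active,
                              noisePct = cfg@noisePct,
                              seed = seedsNoiseMeg[i])
        sys <- combineEMEG(assets$leadEEG, measE, assets$leadMEG, measM)
        lead <- sys$lead
        meas <- sys$measurement
      } else {
        lead <- assets$leadEEG
        meas <- measE
      }
      rcfg <- ramusConfig(nLevels = cfg@nLevels, sparsity = cfg@sparsity,
                          nDecompositions = cfg@nDecompositions,
                          hyperprior = hp, nIter = cfg@nIter,
                          seed = seedsDecomp[i])
      fit <- ramusReconstruct(lead, meas, assets$space, rcfg)
      x <- currentEstimate(fit)
      # truth amplitudes on the normalized data scale of the inversion
      f <- measE@normalizationFactor
      deepRows[[i]] <- roiMetrics(
        x, assets$space,
        dipoleSource(dipDeep@position, direction = dipDeep@direction,
                     amplitude = cfg@deepAmplitude / f))
      supRows[[i]] <- roiMetrics(
        x, assets$space,
        dipoleSource(dipSup@position, direction = dipSup@direction,
                     amplitude = cfg@superficialAmplitude / f))
      if (keepReconstructions) recs[[i]] <- x
    }
    deep <- do.call(rbind, deepRows)
    sup <- do.call(rbind, supRows)
    deep$realization <- seq_len(n)
    sup$realization <- seq_len(n)
    list(config = cfg, deep = deep, superficial = sup,
         summaryDeep = summarizeMetrics(deep),
         summarySuperficial = summarizeMetrics(sup),
         scaled = cfg@scaleFactor < 1,
         reconstructions = recs)
  })
}

#' Run a suite of validation cases
#'
#' @param caseIds character vector of case ids (possibly empty).
#' @param assets forward assets from [makeCaseAssets()].
#' @param scaleFactor passed to [caseConfig()].
#' @param seed master seed; each case gets a derived sub-seed.
#' @param ... further arguments to [caseConfig()].
#' @return list with `detectionMatrix` (one row per case, deep and
#'   superficial detection percentages) and `results` (per-case
#'   [runCase()] output).
#' @export
runSuite <- function(caseIds, assets, scaleFactor = 1, seed = NULL, ...) {
  caseIds <- toupper(caseIds)
  if (length(caseIds) == 0L)
    return(list(detectionMatrix = data.frame(caseId = character(),
                                             deepPct = numeric(),
                                             superficialPct = numeric()),
                results = list()))
  .withSeed(seed, {
    caseSeeds <- .drawSeeds(length(caseIds))
    results <- vector("list", length(caseIds))
    names(results) <- caseIds
    for (i in seq_along(caseIds)) {
      cfg <- caseConfig(caseIds[i], scaleFactor = scaleFactor,
                        seed = caseSeeds[i], ...)
      results[[i]] <- runCase(cfg, assets)
    }
    detectionMatrix <- data.frame(
      caseId = caseIds,
      deepPct = vapply(results, function(r)
        detectionPercentage(r$deep), numeric(1)),
      superficialPct = vapply(results, function(r)
        detectionPercentage(r$superficial), numeric(1)),
      scaled = scaleFactor < 1)
    rownames(detectionMatrix) <- NULL
    list(detectionMatrix = detectionMatrix, results = results)
  })
}
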