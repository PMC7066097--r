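# The RAMUS algorithm: coarse-to-fine IAS MAP estimation over D random
# nested multiresolution decompositions with chained initial guesses,
# normalized level means, and the final decomposition mean.

#' RAMUS configuration
#'
#' @param nLevels resolution level count L (default 3).
#' @param sparsity sparsity factor s (default 8).
#' @param nDecompositions decomposition count D (default 100).
#' @param hyperprior a [HyperpriorSpec-class] (default inverse gamma,
#'   beta 1.5, theta0 1e-10).
#' @param nIter IAS iterations per level (default 10).
#' @param seed optional master seed.
#' @param chain chain initial guesses across levels and decompositions
#'   (default TRUE, the standard scheme).
#' @param restriction `"subsample"` (default) or `"aggregate"`; see
#'   [RamusConfig-class].
#' @return a [RamusConfig-class].
#' @export
ramusConfig <- function(nLevels = 3L, sparsity = 8,
                        nDecompositions = 100L,
                        hyperprior = igHyperprior(), nIter = 10L,
                        seed = NULL, chain = TRUE,
                        restriction = c("subsample", "aggregate")) {
  new("RamusConfig", nLevels = as.integer(nLevels),
      sparsity = as.numeric(sparsity),
      nDecompositions = as.integer(nDecompositions),
      hyperprior = hyperprior, nIter = as.integer(nIter),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
      chain = chain, restriction = match.arg(restriction))
}

#' Normalized mean of prolongated level estimates
#'
#' Elementwise sum of the L level estimates (all on the fine grid)
#' divided by `sum_l s^(L-l)`, the factor that balances the multiplied
#' source count introduced by interpolating coarse estimates onto denser
#' levels (for L = 3, s = 8 the denominator is 64 + 8 + 1 = 73).
#'
#' @param levelEstimates list of numeric fine-grid vectors, coarsest
#'   first.
#' @param s numeric sparsity factor.
#' @return numeric fine-grid vector.
#' @export
normalizedLevelMean <- function(levelEstimates, s) {
  L <- length(levelEstimates)
  if (L == 0L)
    stop("parameter error: no level estimates supplied", call. = FALSE)
  len <- lengths(levelEstimates)
  if (any(len != len[1L]))
    stop("all level estimates must live on the same (fine) grid",
         call. = FALSE)
  Reduce(`+`, levelEstimates) / sum(s^(L - seq_len(L)))
}

#' RAMUS reconstruction
#'
#' For each of D randomized nested decompositions, runs the IAS MAP
#' optimizer coarse-to-fine. The level-l system restricts the source
#' space to the K_l selected positions (their own lead-field columns
#' under the default `"subsample"` restriction — regularization by
#' discretization), and the initial guess is the subset-mean restriction
#' of the previous estimate (zeros at the very start; the previous
#' decomposition's normalized level mean at level 1 of decompositions
#' k > 1; the level-(l-1) estimate at finer levels). Each level estimate
#' is mapped to the fine grid by nearest-neighbor copy — which multiplies
#' the represented source count by about s^(L-l), the factor the
#' normalized-mean denominator balances — and the levels are combined by
#' [normalizedLevelMean()]; the final reconstruction is the arithmetic
#' mean over decompositions.
#'
#' @param lead a [LeadField-class] (or numeric matrix) on the fine grid.
#' @param measurement a [MeasurementSet-class] (or numeric data vector;
#'   then `sigma` must be given).
#' @param space the [SourceSpace-class] behind the lead field.
#' @param cfg a [RamusConfig-class].
#' @param sigma optional noise standard deviation override.
#' @param normalize scale the lead field to unit mean column norm for
#'   the inversion (default TRUE; see [normalizeLeadField()]). The
#'   returned estimates are rescaled back to the units of the input
#'   lead field, so only the interpretation of the hyperprior scale
#'   parameter depends on this switch.
#' @return a [RamusResult-class].
#' @examples
#' head <- headModel()
#' sp <- buildSourceSpace(150, seed = 1)
#' L <- eegLeadfield(sp, electrodeArray(head, 32), head)
#' y <- simulateData(L, sp, defaultDipoles(10, 5), 3, seed = 2)
#' fit <- ramusReconstruct(L, y, sp, ramusConfig(nDecompositions = 3, seed = 3))
#' @export
ramusReconstruct <- function(lead, measurement, space, cfg = ramusConfig(),
                             sigma = NULL, normalize = TRUE) {
  M <- if (is(lead, "LeadField")) lead@matrix else lead
  y <- if (is(measurement, "MeasurementSet")) measurement@y
       else as.numeric(measurement)
  columnScale <- 1
  if (normalize) {
    columnScale <- mean(sqrt(colSums(M^2)))
    if (columnScale == 0) stop("lead field is identically zero")
    M <- M / columnScale
  }
  if (is.null(sigma)) {
    if (!is(measurement, "MeasurementSet"))
      stop("supply 'sigma' when 'measurement' is a plain vector")
    sigma <- measurement@sigma
  }
  stopifnot(is(space, "SourceSpace"), is(cfg, "RamusConfig"))
  K <- nSources(space)
  if (ncol(M) != 3L * K)
    stop("lead field does not match the source space", call. = FALSE)
  icfg <- iasConfig(cfg@nIter, sigma)
  D <- cfg@nDecompositions
  seed <- if (is.na(cfg@seed)) NULL else cfg@seed
  .withSeed(seed, {
    decompSeeds <- .drawSeeds(D)
    perDec <- matrix(0, 3L * K, D)
    xbarPrev <- NULL
    for (k in seq_len(D)) {
      dec <- buildDecomposition(space, L = cfg@nLevels, s = cfg@sparsity,
                                seed = decompSeeds[k])
      fineEstimates <- vector("list", cfg@nLevels)
      for (l in seq_len(cfg@nLevels)) {
        level <- dec@levels[[l]]
        Ll <- if (cfg@restriction == "subsample") {
          M[, .componentCols(level@centers), drop = FALSE]
        } else {
          restrictLeadfield(M, level)
        }
        x0 <- if (l == 1L) {
          if (is.null(xbarPrev) || !cfg@chain) {
            numeric(3L * length(level@centers))
          } else {
            restrictEstimate(xbarPrev, level)
          }
        } else {
          restrictEstimate(fineEstimates[[l - 1L]], level)
        }
        st <- tryCatch(iasMap(Ll, y, cfg@hyperprior, icfg, xInit = x0),
                       error = function(e)
                         stop(sprintf("decomposition %d, level %d: %s",
                                      k, l, conditionMessage(e)),
                              call. = FALSE))
        fineEstimates[[l]] <- prolongate(st@x, level)
      }
      xbar <- normalizedLevelMean(fineEstimates, cfg@sparsity)
      perDec[, k] <- xbar
      if (cfg@chain) xbarPrev <- xbar
    }
    perDec <- perDec / columnScale     # back to input lead-field units
    new("RamusResult", xFinal = rowMeans(perDec), perDecomposition = perDec,
        provenance = list(
          columnScale = columnScale,
          nLevels = cfg@nLevels, sparsity = cfg@sparsity,
          nDecompositions = D, nIter = cfg@nIter,
          hyperprior = list(family = cfg@hyperprior@family,
                            beta = cfg@hyperprior@beta,
                            theta0 = cfg@hyperprior@theta0),
          sigma = sigma, chain = cfg@chain,
          restriction = cfg@restriction,
          seed = if (is.null(seed)) NA_real_ else seed,
          decompositionSeeds = decompSeeds))
  })
}
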