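#' @import methods
#' @importFrom stats rnorm runif median quantile
#' @importFrom utils read.csv write.csv read.table write.table
#' @importFrom Matrix sparseMatrix
NULL

#' Three-shell spherical head model
#'
#' Concentric-sphere conductor geometry used by the analytic forward
#' solvers. The default is the classical Ary three-shell head: 87, 92 and
#' 100 mm spheres representing brain, skull and scalp with conductivities
#' 0.33, 0.0042 and 0.33 S/m.
#'
#' @slot radii numeric, layer outer radii in mm, strictly increasing
#'   (innermost first).
#' @slot conductivities numeric, one conductivity per layer in S/m.
#' @slot maxDegree integer, maximum Legendre degree of the EEG potential
#'   series.
#' @slot seriesTol numeric, relative tail tolerance at which the series is
#'   truncated early.
#' @seealso [headModel()]
#' @exportClass HeadModel
setClass("HeadModel",
  slots = c(radii = "numeric", conductivities = "numeric",
            maxDegree = "integer", seriesTol = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@radii) < 1L ||
        length(object@radii) != length(object@conductivities))
      msg <- c(msg, "radii and conductivities must have equal length >= 1")
    if (any(diff(object@radii) <= 0) || any(object@radii <= 0))
      msg <- c(msg, "radii must be positive and strictly increasing")
    if (any(object@conductivities <= 0))
      msg <- c(msg, "conductivities must be positive")
    if (object@maxDegree < 1L)
      msg <- c(msg, "maxDegree must be >= 1")
    if (object@seriesTol <= 0)
      msg <- c(msg, "seriesTol must be positive")
    if (length(msg)) msg else TRUE
  })

#' Sensor array on or above the scalp
#'
#' Either point electrodes on the outermost sphere surface or radial
#' magnetometers outside it.
#'
#' @slot kind character, `"electrode"` or `"radial_magnetometer"`.
#' @slot positions numeric matrix, n x 3 sensor coordinates in mm.
#' @slot radius numeric, the nominal sphere radius (mm) the sensors sit on.
#' @seealso [electrodeArray()], [magnetometerArray()]
#' @exportClass SensorArray
setClass("SensorArray",
  slots = c(kind = "character", positions = "matrix", radius = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("electrode", "radial_magnetometer"))
      msg <- c(msg, "kind must be 'electrode' or 'radial_magnetometer'")
    if (ncol(object@positions) != 3L)
      msg <- c(msg, "positions must have 3 columns")
    nrm <- .rowNorms(object@positions)
    if (object@kind == "electrode" &&
        any(abs(nrm - object@radius) > 1e-6 * object@radius))
      msg <- c(msg, "electrodes must lie on the sphere of the given radius")
    if (length(msg)) msg else TRUE
  })

#' Volumetric source space
#'
#' K candidate source positions sampled in a spherical shell strictly
#' inside the innermost conductor. Each position carries three Cartesian
#' current components, so source vectors have length 3K with component c of
#' position j stored at entry 3*(j-1)+c.
#'
#' @slot positions numeric matrix, K x 3 coordinates in mm.
#' @slot rMin,rMax numeric, shell bounds in mm.
#' @seealso [buildSourceSpace()]
#' @exportClass SourceSpace
setClass("SourceSpace",
  slots = c(positions = "matrix", rMin = "numeric", rMax = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@positions) != 3L)
      msg <- c(msg, "positions must have 3 columns")
    if (object@rMin < 0 || object@rMax <= object@rMin)
      msg <- c(msg, "need 0 <= rMin < rMax")
    nrm <- .rowNorms(object@positions)
    if (any(nrm > object@rMax + 1e-9) || any(nrm < object@rMin - 1e-9))
      msg <- c(msg, "all positions must lie inside the [rMin, rMax] shell")
    if (length(msg)) msg else TRUE
  })

#' Lead field matrix
#'
#' Linear forward map from the flattened 3K source vector to the m sensor
#' measurements (y = L x + n). EEG entries are average-referenced scalp
#' potentials in Ohm/m; MEG entries are radial magnetic fields divided by
#' mu0, in 1/m^2.
#'
#' @slot matrix numeric, m x 3K.
#' @slot modality character, `"EEG"`, `"MEG"` or `"EMEG"`.
#' @slot units character tag.
#' @seealso [eegLeadfield()], [megLeadfield()], [combineEMEG()]
#' @exportClass LeadField
setClass("LeadField",
  slots = c(matrix = "matrix", modality = "character", units = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@modality %in% c("EEG", "MEG", "EMEG"))
      msg <- c(msg, "modality must be EEG, MEG or EMEG")
    if (ncol(object@matrix) %% 3L != 0L)
      msg <- c(msg, "column count must be a multiple of 3")
    if (!all(is.finite(object@matrix)))
      msg <- c(msg, "lead field entries must be finite")
    if (length(msg)) msg else TRUE
  })

#' Current dipole source
#'
#' A point dipole with unit moment direction and a dimensionless amplitude
#' (the validation experiments use arbitrary units, e.g. 10 for the deep
#' thalamic and 5 for the superficial somatosensory component).
#'
#' @slot position numeric length-3, mm.
#' @slot direction numeric length-3 unit vector.
#' @slot amplitude numeric scalar >= 0.
#' @seealso [dipoleSource()], [defaultDipoles()]
#' @exportClass DipoleSource
setClass("DipoleSource",
  slots = c(position = "numeric", direction = "numeric",
            amplitude = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@position) != 3L || !all(is.finite(object@position)))
      msg <- c(msg, "position must be a finite 3-vector")
    if (length(object@direction) != 3L ||
        abs(.vnorm(object@direction) - 1) > 1e-8)
      msg <- c(msg, "direction must be a unit 3-vector")
    if (length(object@amplitude) != 1L || object@amplitude < 0)
      msg <- c(msg, "amplitude must be a single non-negative number")
    if (length(msg)) msg else TRUE
  })

#' Measurement set
#'
#' Sensor data simulated from dipoles: noiseless superposition plus
#' Gaussian white noise, max-normalized to one. `sigma` is the noise
#' standard deviation expressed on the normalized data scale.
#'
#' @slot y numeric, length-m data vector.
#' @slot sigma numeric, noise sd on the normalized scale.
#' @slot cleanY numeric, noiseless data on the same normalized scale.
#' @slot normalizationFactor numeric, max|clean + noise| before scaling.
#' @seealso [simulateData()]
#' @exportClass MeasurementSet
setClass("MeasurementSet",
  slots = c(y = "numeric", sigma = "numeric", cleanY = "numeric",
            normalizationFactor = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(is.finite(object@y)))
      msg <- c(msg, "y must be finite")
    if (length(object@cleanY) != length(object@y))
      msg <- c(msg, "cleanY must match y in length")
    if (object@sigma < 0)
      msg <- c(msg, "sigma must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Hyperprior specification
#'
#' Gamma or inverse-gamma hyperprior on the per-component prior variances
#' theta of the current density. The inverse-gamma family with beta = 1.5
#' and theta0 = 1e-10 is the depth-robust default.
#'
#' @slot family character, `"inverse_gamma"` or `"gamma"`.
#' @slot beta numeric shape parameter (dimensionless).
#' @slot theta0 numeric scale parameter (variance units of x^2).
#' @seealso [igHyperprior()], [gammaHyperprior()]
#' @exportClass HyperpriorSpec
setClass("HyperpriorSpec",
  slots = c(family = "character", beta = "numeric", theta0 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@family %in% c("inverse_gamma", "gamma"))
      msg <- c(msg, "family must be 'inverse_gamma' or 'gamma'")
    if (object@theta0 <= 0)
      msg <- c(msg, "theta0 must be positive")
    if (object@beta < 1.5)
      msg <- c(msg, "beta must be >= 1.5")
    if (length(msg)) msg else TRUE
  })

#' IAS optimizer configuration
#'
#' @slot nIter integer, number of alternating iterations (default 10).
#' @slot sigma numeric, noise standard deviation on the data scale used in
#'   the likelihood term.
#' @seealso [iasConfig()], [iasMap()]
#' @exportClass IASConfig
setClass("IASConfig",
  slots = c(nIter = "integer", sigma = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nIter < 1L) msg <- c(msg, "nIter must be >= 1")
    if (object@sigma <= 0) msg <- c(msg, "sigma must be positive")
    if (length(msg)) msg else TRUE
  })

#' IAS iterate state
#'
#' Final state of the alternating optimizer: current-density iterate x,
#' hypervariances theta, and the history of the joint negative log
#' posterior recorded after every half-step (theta-step, then x-step).
#'
#' @slot x numeric, length-3K iterate.
#' @slot theta numeric, length-3K positive hypervariances.
#' @slot objective numeric, objective history (2 entries per iteration).
#' @exportClass IASState
setClass("IASState",
  slots = c(x = "numeric", theta = "numeric", objective = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@theta) != length(object@x))
      msg <- c(msg, "theta must match x in length")
    if (any(object@theta <= 0))
      msg <- c(msg, "theta entries must be positive")
    if (!all(is.finite(object@objective)))
      msg <- c(msg, "objective history must be finite")
    if (length(msg)) msg else TRUE
  })

#' One resolution level of a multiresolution decomposition
#'
#' A subset of source positions acting as centers, plus the
#' nearest-neighbor assignment of every fine position to its center's
#' subset.
#'
#' @slot index integer, level index (1 = coarsest).
#' @slot centers integer, indices (into the source-space positions) of the
#'   K_l centers.
#' @slot assignment integer length-K, subset label (1..K_l) of each fine
#'   position.
#' @slot sizes integer length-K_l, subset cardinalities.
#' @exportClass ResolutionLevel
setClass("ResolutionLevel",
  slots = c(index = "integer", centers = "integer",
            assignment = "integer", sizes = "integer"),
  validity = function(object) {
    msg <- character()
    kl <- length(object@centers)
    if (kl < 1L) msg <- c(msg, "need at least one center")
    if (anyDuplicated(object@centers))
      msg <- c(msg, "centers must be distinct")
    if (any(object@assignment < 1L) || any(object@assignment > kl))
      msg <- c(msg, "assignment labels out of range")
    if (!all(tabulate(object@assignment, kl) == object@sizes))
      msg <- c(msg, "sizes inconsistent with assignment")
    if (any(object@sizes < 1L))
      msg <- c(msg, "subsets must be non-empty (exhaustive partition)")
    # each center belongs to its own subset
    if (any(object@assignment[object@centers] != seq_len(kl)))
      msg <- c(msg, "each center must belong to its own subset")
    if (length(msg)) msg else TRUE
  })

#' Randomized nested multiresolution decomposition
#'
#' Ordered resolution levels l = 1..L with K_l = round(K * s^(l-L))
#' centers; level-l centers are a subset of level-(l+1) centers and the
#' finest level is the full source space with singleton subsets.
#'
#' @slot levels list of [ResolutionLevel-class] objects, coarsest first.
#' @slot sparsity numeric, sparsity factor s (>= 1).
#' @slot seed integer or NA, RNG seed used to draw the centers.
#' @seealso [buildDecomposition()]
#' @exportClass MultiresDecomposition
setClass("MultiresDecomposition",
  slots = c(levels = "list", sparsity = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    L <- length(object@levels)
    if (L < 1L) msg <- c(msg, "need at least one level")
    if (object@sparsity < 1)
      msg <- c(msg, "sparsity must be >= 1")
    for (l in seq_len(L)) {
      if (!is(object@levels[[l]], "ResolutionLevel"))
        msg <- c(msg, "levels must contain ResolutionLevel objects")
    }
    if (L > 1L) {
      for (l in seq_len(L - 1L)) {
        if (!all(object@levels[[l]]@centers %in%
                 object@levels[[l + 1L]]@centers))
          msg <- c(msg, sprintf("level %d centers not nested in level %d",
                                l, l + 1L))
      }
    }
    if (length(msg)) msg else TRUE
  })

#' RAMUS configuration
#'
#' Defaults follow the main validation cases: three resolution levels,
#' sparsity factor 8, 100 decompositions, inverse-gamma hyperprior
#' (beta 1.5, theta0 1e-10) and ten IAS iterations per level.
#'
#' @slot nLevels integer, resolution level count L.
#' @slot sparsity numeric, sparsity factor s.
#' @slot nDecompositions integer, decomposition count D.
#' @slot hyperprior a [HyperpriorSpec-class].
#' @slot nIter integer, IAS iterations per level.
#' @slot seed numeric, master seed (NA = use current RNG stream).
#' @slot chain logical, chain initial guesses across levels and
#'   decompositions (the standard scheme); FALSE restarts every
#'   decomposition from zero (diagnostic).
#' @slot restriction character, how the level-l system is built:
#'   `"subsample"` (default) takes the lead-field columns of the selected
#'   center positions — regularization by discretization, with the
#'   nearest-neighbor copy on interpolation multiplying the source count
#'   that the normalized level mean balances out; `"aggregate"` sums the
#'   member columns per subset (constant-in-subset model, diagnostic).
#' @seealso [ramusConfig()], [ramusReconstruct()]
#' @exportClass RamusConfig
setClass("RamusConfig",
  slots = c(nLevels = "integer", sparsity = "numeric",
            nDecompositions = "integer", hyperprior = "HyperpriorSpec",
            nIter = "integer", seed = "numeric", chain = "logical",
            restriction = "character"),
  validity = function(object) {
    msg <- character()
    if (object@nLevels < 1L) msg <- c(msg, "nLevels must be >= 1")
    if (object@sparsity < 1) msg <- c(msg, "sparsity must be >= 1")
    if (object@nDecompositions < 1L)
      msg <- c(msg, "nDecompositions must be >= 1")
    if (object@nIter < 1L) msg <- c(msg, "nIter must be >= 1")
    if (!object@restriction %in% c("subsample", "aggregate"))
      msg <- c(msg, "restriction must be 'subsample' or 'aggregate'")
    if (length(msg)) msg else TRUE
  })

#' RAMUS reconstruction result
#'
#' Stores the per-decomposition normalized level means (fine grid) and
#' their arithmetic mean, the final reconstruction.
#'
#' @slot xFinal numeric length-3K, final estimate.
#' @slot perDecomposition numeric matrix, 3K x D, one normalized level
#'   mean per decomposition.
#' @slot provenance list, configuration echo and the seeds used.
#' @exportClass RamusResult
setClass("RamusResult",
  slots = c(xFinal = "numeric", perDecomposition = "matrix",
            provenance = "list"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@perDecomposition) != length(object@xFinal))
      msg <- c(msg, "perDecomposition rows must match xFinal length")
    if (max(abs(object@xFinal - rowMeans(object@perDecomposition))) >
        1e-12 * max(1, max(abs(object@xFinal))))
      msg <- c(msg, "xFinal must equal the mean over decompositions")
    if (length(msg)) msg else TRUE
  })

#' Validation case configuration
#'
#' One row of the experiment matrix: modality, sparsity factor,
#' decomposition count, hyperprior family and the two dipole amplitudes,
#' plus run-size controls.
#'
#' @slot caseId character, e.g. `"A"`.
#' @slot modality character, `"EEG"` or `"EMEG"`.
#' @slot sparsity numeric.
#' @slot nDecompositions integer.
#' @slot hyperprior character, `"IG"` or `"G"`.
#' @slot deepAmplitude,superficialAmplitude numeric.
#' @slot noisePct numeric, noise level in percent of the maximal clean
#'   signal amplitude (default 3).
#' @slot nRealizations integer, independent noise realizations (default 50).
#' @slot nLevels,nIter integer, resolution levels and IAS iterations.
#' @slot scaleFactor numeric in (0, 1], shrinks nDecompositions and
#'   nRealizations for reduced runs.
#' @slot seed numeric, master seed.
#' @seealso [caseConfig()], [runCase()]
#' @exportClass CaseConfig
setClass("CaseConfig",
  slots = c(caseId = "character", modality = "character",
            sparsity = "numeric", nDecompositions = "integer",
            hyperprior = "character", deepAmplitude = "numeric",
            superficialAmplitude = "numeric", noisePct = "numeric",
            nRealizations = "integer", nLevels = "integer",
            nIter = "integer", scaleFactor = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@modality %in% c("EEG", "EMEG"))
      msg <- c(msg, "modality must be EEG or EMEG")
    if (!object@hyperprior %in% c("IG", "G"))
      msg <- c(msg, "hyperprior must be IG or G")
    if (object@scaleFactor <= 0 || object@scaleFactor > 1)
      msg <- c(msg, "scaleFactor must be in (0, 1]")
    if (object@deepAmplitude < 0 || object@superficialAmplitude < 0)
      msg <- c(msg, "amplitudes must be non-negative")
    if (object@noisePct < 0)
      msg <- c(msg, "noisePct must be non-negative")
    if (length(msg)) msg else TRUE
  })
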