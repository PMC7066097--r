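#' Sample a volumetric source space
#'
#' Draws `K` source positions uniformly from the spherical shell
#' `rMin <= ||p|| <= rMax` (mm). Uniformity in volume is obtained by
#' inverse-transform sampling of the radius (cube-root law) together with
#' isotropic directions. The default shell [0, 85] mm keeps every
#' candidate strictly inside the 87 mm brain sphere while leaving nearby
#' candidates for both a ~9 mm-deep and a near-cortex dipole.
#'
#' @param K integer, number of source positions.
#' @param rMin,rMax numeric shell bounds in mm, `0 <= rMin < rMax`.
#' @param seed optional integer for reproducible sampling.
#' @return a [SourceSpace-class] with K positions (3K source components).
#' @examples
#' sp <- buildSourceSpace(500, seed = 1)
#' range(sqrt(rowSums(coordinatesMm(sp)^2)))
#' @export
buildSourceSpace <- function(K, rMin = 0, rMax = 85, seed = NULL) {
  K <- .assertCount(K, "K")
  if (!is.finite(rMin) || !is.finite(rMax) || rMin < 0 || rMax <= rMin)
    stop("invalid shell bounds: need 0 <= rMin < rMax", call. = FALSE)
  .withSeed(seed, {
    r <- (rMin^3 + runif(K) * (rMax^3 - rMin^3))^(1 / 3)
    dir <- matrix(rnorm(3L * K), ncol = 3L)
    dir <- dir / .rowNorms(dir)
    new("SourceSpace", positions = dir * r, rMin = rMin, rMax = rMax)
  })
}

#' Construct a current dipole
#'
#' The moment direction may be given either as a 3-vector (normalized
#' internally) or through `angleDeg`, the elevation of the moment out of
#' the local tangential plane, measured within the plane spanned by the
#' radial direction and the z-axis (0 degrees = tangential, 90 degrees =
#' radial).
#'
#' @param position numeric length-3, mm.
#' @param direction numeric length-3 moment direction (any norm), or NULL.
#' @param angleDeg numeric, elevation from tangential in degrees (used
#'   when `direction` is NULL).
#' @param amplitude numeric, dimensionless source strength.
#' @return a [DipoleSource-class].
#' @examples
#' dipoleSource(c(7, 0, 5), angleDeg = 68, amplitude = 10)
#' @export
dipoleSource <- function(position, direction = NULL, angleDeg = NULL,
                         amplitude = 1) {
  position <- as.numeric(position)
  if (is.null(direction)) {
    if (is.null(angleDeg))
      stop("supply either 'direction' or 'angleDeg'")
    direction <- .tiltedDirection(position, angleDeg)
  } else {
    nrm <- .vnorm(direction)
    if (nrm == 0) stop("direction must be non-zero")
    direction <- as.numeric(direction) / nrm
  }
  new("DipoleSource", position = position, direction = direction,
      amplitude = as.numeric(amplitude))
}

# Unit moment elevated `angleDeg` out of the tangential plane at
# `position`, within the plane spanned by the radial direction and z-hat
# (0 degrees = tangential, 90 = radial). A near-tangential superficial
# source models the somatosensory P20/N20 component; a near-radial deep
# one models the thalamic P14/N14.
.tiltedDirection <- function(position, angleDeg) {
  rhat <- position / .vnorm(position)
  zhat <- c(0, 0, 1)
  u <- zhat - sum(zhat * rhat) * rhat
  if (.vnorm(u) < 1e-12) {           # position on the z-axis: use x-hat
    u <- c(1, 0, 0) - rhat[1] * rhat
  }
  u <- u / .vnorm(u)
  a <- angleDeg * pi / 180
  sin(a) * rhat + cos(a) * u
}

#' Default deep and superficial test dipoles
#'
#' The two-dipole configuration used throughout the validation cases: a
#' deep, thalamus-like dipole at (7, 0, 5) mm elevated 68 degrees from
#' the tangential plane (near-radial, modeling the P14/N14 component) and
#' a superficial, somatosensory-cortex-like dipole at (-50, 7, 71) mm at
#' 1 degree (near-tangential, P20/N20, matching the tangential character
#' of the somatosensory source). An amplitude of zero drops that dipole
#' from the returned list; the names `"deep"`/`"superficial"` identify
#' the survivors.
#'
#' @param deepAmplitude,superficialAmplitude numeric source strengths.
#' @return named list of [DipoleSource-class] objects.
#' @export
defaultDipoles <- function(deepAmplitude = 10, superficialAmplitude = 5) {
  out <- list()
  if (deepAmplitude > 0)
    out$deep <- dipoleSource(c(7, 0, 5), angleDeg = 68,
                             amplitude = deepAmplitude)
  if (superficialAmplitude > 0)
    out$superficial <- dipoleSource(c(-50, 7, 71), angleDeg = 1,
                                    amplitude = superficialAmplitude)
  out
}

#' Per-position amplitudes of a flattened source vector
#'
#' @param x numeric length-3K current-density vector.
#' @return numeric length-K vector of Euclidean moment norms.
#' @export
sourceAmplitudes <- function(x) {
  m <- matrix(x, nrow = 3L)
  sqrt(colSums(m^2))
}
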