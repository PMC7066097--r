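#' Construct a concentric-spheres head model
#'
#' Defaults to the Ary three-shell head: brain, skull and scalp spheres of
#' 87, 92 and 100 mm radius with conductivities 0.33, 0.0042 and 0.33 S/m.
#'
#' @param radii numeric, layer outer radii in mm, innermost first.
#' @param conductivities numeric, layer conductivities in S/m.
#' @param maxDegree integer, maximum Legendre degree for the EEG potential
#'   series (default 160, which brings the relative tail below 1e-8 even
#'   for sources at 85 mm depth inside the Ary geometry).
#' @param seriesTol numeric, relative tail tolerance for early truncation
#'   of the series (default 1e-8).
#' @return a [HeadModel-class] object.
#' @examples
#' headModel()
#' @export
headModel <- function(radii = c(87, 92, 100),
                      conductivities = c(0.33, 0.0042, 0.33),
                      maxDegree = 160L, seriesTol = 1e-8) {
  new("HeadModel", radii = as.numeric(radii),
      conductivities = as.numeric(conductivities),
      maxDegree = as.integer(maxDegree), seriesTol = seriesTol)
}

#' Inner (brain) radius of a head model, in mm
#' @param head a [HeadModel-class].
#' @return numeric scalar.
#' @export
innerRadius <- function(head) head@radii[1L]

#' Outer (scalp) radius of a head model, in mm
#' @param head a [HeadModel-class].
#' @return numeric scalar.
#' @export
outerRadius <- function(head) head@radii[length(head@radii)]

# Deterministic quasi-uniform spiral layout on the upper hemisphere
# (z >= 0) of a sphere with the given radius. The golden-angle spiral
# needs no RNG, so the same count always yields the same coordinates.
.fibonacciHemisphere <- function(n, radius) {
  i <- seq_len(n)
  z <- (i - 0.5) / n                 # uniform in (0, 1): upper hemisphere
  phi <- i * pi * (3 - sqrt(5))      # golden angle
  rho <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

#' Electrode array on the scalp
#'
#' Places `n` point electrodes quasi-uniformly over the upper hemisphere
#' of the outermost sphere using a deterministic golden-angle spiral.
#'
#' @param head a [HeadModel-class].
#' @param n integer, electrode count (default 102).
#' @return a [SensorArray-class] of kind `"electrode"`.
#' @examples
#' electrodeArray(headModel(), 102)
#' @export
electrodeArray <- function(head, n = 102L) {
  n <- .assertCount(n, "n")
  R <- outerRadius(head)
  new("SensorArray", kind = "electrode",
      positions = .fibonacciHemisphere(n, R), radius = R)
}

#' Radial magnetometer array
#'
#' Magnetometer positions are the electrode positions scaled radially
#' outward by a constant factor (default 1.2, i.e. 120 mm for a 100 mm
#' scalp).
#'
#' @param electrodes a [SensorArray-class] of kind `"electrode"`.
#' @param scale numeric scaling factor > 1.
#' @return a [SensorArray-class] of kind `"radial_magnetometer"`.
#' @export
magnetometerArray <- function(electrodes, scale = 1.2) {
  stopifnot(is(electrodes, "SensorArray"))
  if (electrodes@kind != "electrode")
    stop("magnetometer positions are derived from an electrode array")
  if (scale <= 1)
    stop("scale must exceed 1 so magnetometers sit outside the scalp")
  new("SensorArray", kind = "radial_magnetometer",
      positions = electrodes@positions * scale,
      radius = electrodes@radius * scale)
}
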