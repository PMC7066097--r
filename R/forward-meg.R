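# Radial magnetometer forward solution (Sarvas formula).
#
# In a spherically symmetric conductor the magnetic field outside the
# head has the closed form B = mu0/(4 pi F^2) (F q x r0 - (q x r0 . r)
# grad F); volume currents contribute nothing to the radial component,
# and dipoles with a radial moment are magnetically silent.

#' MEG radial lead field
#'
#' Computes the m x 3K matrix of radial magnetic field components (per
#' unit dipole moment, divided by mu0, hence 1/m^2) of three Cartesian
#' unit dipoles at each source position, using the Sarvas closed form for
#' a spherically symmetric conductor.
#'
#' @param space a [SourceSpace-class].
#' @param sensors a radial-magnetometer [SensorArray-class] strictly
#'   outside the conductor.
#' @param head optional [HeadModel-class]; when supplied, sensor radii are
#'   checked against the scalp radius.
#' @return a [LeadField-class] with modality `"MEG"`.
#' @examples
#' head <- headModel()
#' sp <- buildSourceSpace(20, seed = 1)
#' mags <- magnetometerArray(electrodeArray(head, 32))
#' megLeadfield(sp, mags, head)
#' @export
megLeadfield <- function(space, sensors, head = NULL) {
  stopifnot(is(space, "SourceSpace"), is(sensors, "SensorArray"))
  if (sensors@kind != "radial_magnetometer")
    stop("MEG lead field requires a radial magnetometer array",
         call. = FALSE)
  sens <- sensors@positions / 1000
  pos <- space@positions / 1000
  rn <- .rowNorms(sens)
  lim <- if (is.null(head)) max(.rowNorms(pos)) else outerRadius(head) / 1000
  if (any(rn <= lim + 1e-12))
    stop("geometry error: magnetometer inside the conductor", call. = FALSE)
  m <- nrow(sens)
  K <- nrow(pos)
  rhat <- sens / rn
  L <- matrix(0, m, 3L * K)
  for (j in seq_len(K)) {
    r0 <- pos[j, ]
    a <- sweep(sens, 2L, r0)                       # r - r0, m x 3
    an <- .rowNorms(a)
    adotr <- rowSums(a * sens)
    # F = a (r a + r^2 - r0 . r)
    Fv <- an * (rn * an + rn^2 - drop(sens %*% r0))
    cf <- an^2 / rn + adotr / an + 2 * an + 2 * rn
    cg <- an + 2 * rn + adotr / an
    gradF <- sens * cf - matrix(r0, m, 3L, byrow = TRUE) * cg
    gdotr <- rowSums(gradF * rhat)
    # rows of Qx: q_k x r0 for the three Cartesian unit moments
    Qx <- rbind(c(0, -r0[3L], r0[2L]),
                c(r0[3L], 0, -r0[1L]),
                c(-r0[2L], r0[1L], 0))
    for (k in 1:3) {
      qxr0 <- Qx[k, ]
      L[, 3L * (j - 1L) + k] <-
        (Fv * drop(rhat %*% qxr0) - drop(sens %*% qxr0) * gdotr) /
        (4 * pi * Fv^2)
    }
  }
  new("LeadField", matrix = L, modality = "MEG", units = "1/m^2")
}
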