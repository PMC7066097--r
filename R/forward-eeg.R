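# Analytic EEG forward solution for concentric conducting spheres.
#
# Per Legendre degree n the potential in each layer is a combination of
# r^n and r^-(n+1) harmonics; the dipole enters through its free-medium
# expansion in the innermost layer. Interface continuity of potential and
# normal current plus the insulating outer boundary give one small linear
# system per degree. All basis functions are scaled per layer so every
# matrix entry is a radius ratio <= 1, which keeps the system
# well-conditioned at high degree.

# Layer response coefficients g~_n for a unit source coefficient, n =
# 1..nmax. Radii in meters. For a homogeneous sphere this reduces to
# (2n+1)/n * (R1/RN)^(n+1) (single-layer: (2n+1)/n).
.sphereSeriesCoefficients <- function(Rm, sig, nmax) {
  N <- length(Rm)
  n <- seq_len(nmax)
  if (N == 1L) return((2 * n + 1) / n)
  rho <- Rm[-N] / Rm[-1L]            # rho[i] = R_i / R_{i+1}
  iu <- function(i) if (i == 1L) 1L else 2L * i - 2L
  iv <- function(i) 2L * i - 1L
  g <- numeric(nmax)
  dim <- 2L * N - 1L
  for (nn in n) {
    M <- matrix(0, dim, dim)
    rhs <- numeric(dim)
    # interface at R_1 between the source layer and layer 2
    M[1L, iu(1L)] <- 1
    M[1L, iu(2L)] <- -rho[1L]^nn
    M[1L, iv(2L)] <- -1
    rhs[1L] <- -1
    M[2L, iu(1L)] <- sig[1L] * nn
    M[2L, iu(2L)] <- -sig[2L] * nn * rho[1L]^nn
    M[2L, iv(2L)] <- sig[2L] * (nn + 1)
    rhs[2L] <- sig[1L] * (nn + 1)
    row <- 3L
    if (N > 2L) {
      for (i in 2L:(N - 1L)) {       # interface at R_i
        M[row, iu(i)] <- 1
        M[row, iv(i)] <- rho[i - 1L]^(nn + 1)
        M[row, iu(i + 1L)] <- -rho[i]^nn
        M[row, iv(i + 1L)] <- -1
        row <- row + 1L
        M[row, iu(i)] <- sig[i] * nn
        M[row, iv(i)] <- -sig[i] * (nn + 1) * rho[i - 1L]^(nn + 1)
        M[row, iu(i + 1L)] <- -sig[i + 1L] * nn * rho[i]^nn
        M[row, iv(i + 1L)] <- sig[i + 1L] * (nn + 1)
        row <- row + 1L
      }
    }
    # insulating scalp surface at R_N
    M[row, iu(N)] <- nn
    M[row, iv(N)] <- -(nn + 1) * rho[N - 1L]^(nn + 1)
    sol <- solve(M, rhs)
    g[nn] <- sol[iu(N)] + sol[iv(N)] * rho[N - 1L]^(nn + 1)
  }
  g
}

#' EEG lead field for a concentric-spheres head
#'
#' Computes the m x 3K matrix of average-referenced scalp potentials
#' (Ohm/m, i.e. V per unit dipole moment in A m) for three Cartesian unit
#' dipoles at each source position, via the multilayer-sphere Legendre
#' series. The series is truncated at `head@maxDegree` or once the
#' relative tail drops below `head@seriesTol`, whichever comes first.
#'
#' @param space a [SourceSpace-class]; all positions must be strictly
#'   inside the innermost sphere.
#' @param sensors an electrode [SensorArray-class] on the outer surface.
#' @param head a [HeadModel-class].
#' @return a [LeadField-class] with modality `"EEG"`.
#' @examples
#' head <- headModel()
#' sp <- buildSourceSpace(20, seed = 1)
#' L <- eegLeadfield(sp, electrodeArray(head, 32), head)
#' max(abs(colSums(leadMatrix(L))))   # average reference
#' @export
eegLeadfield <- function(space, sensors, head) {
  stopifnot(is(space, "SourceSpace"), is(sensors, "SensorArray"),
            is(head, "HeadModel"))
  if (sensors@kind != "electrode")
    stop("EEG lead field requires an electrode array", call. = FALSE)
  if (abs(sensors@radius - outerRadius(head)) > 1e-6 * outerRadius(head))
    stop("electrode radius does not match the outer sphere", call. = FALSE)
  Rm <- head@radii / 1000
  sig <- head@conductivities
  pos <- space@positions / 1000
  elec <- sensors@positions / 1000
  m <- nrow(elec)
  K <- nrow(pos)
  b <- .rowNorms(pos)
  if (any(b >= Rm[1L]))
    stop("geometry error: source position on or outside the innermost sphere",
         call. = FALSE)
  # radial unit vectors; a central dipole keeps only the degree-1 term,
  # for which any axis choice yields the same potential
  bSafe <- ifelse(b > 0, b, 1)
  rhat0 <- pos / bSafe
  rhat0[b == 0, ] <- rep(c(0, 0, 1), each = sum(b == 0))
  rehat <- elec / .rowNorms(elec)
  cosg <- pmin(1, pmax(-1, rehat %*% t(rhat0)))     # m x K

  gtil <- .sphereSeriesCoefficients(Rm, sig, head@maxDegree)
  invden <- 1 / (4 * pi * sig[1L] * Rm[1L]^2)
  bratio <- b / Rm[1L]

  Pprev <- matrix(1, m, K)          # P_0
  Pcur <- cosg                      # P_1
  dPprev <- matrix(0, m, K)         # P_0'
  dPcur <- matrix(1, m, K)          # P_1'
  A <- matrix(0, m, K)              # sum_n w_n n P_n
  B <- matrix(0, m, K)              # sum_n w_n P_n'
  bpow <- rep(1, K)                 # (b/R1)^(n-1)
  total <- 0
  converged <- FALSE
  for (nn in seq_len(head@maxDegree)) {
    w <- gtil[nn] * bpow * invden
    W <- matrix(w, m, K, byrow = TRUE)
    A <- A + (nn * W) * Pcur
    B <- B + W * dPcur
    termMag <- max(abs(w)) * nn * (nn + 1) / 2   # |P_n|<=1, |P_n'|<=n(n+1)/2
    total <- total + termMag
    if (nn >= 10L && termMag < head@seriesTol * total) {
      converged <- TRUE
      break
    }
    # recurrences to degree n+1
    Pnext <- ((2 * nn + 1) * cosg * Pcur - nn * Pprev) / (nn + 1)
    dPnext <- dPprev + (2 * nn + 1) * Pcur
    Pprev <- Pcur; Pcur <- Pnext
    dPprev <- dPcur; dPcur <- dPnext
    bpow <- bpow * bratio
  }
  if (!converged)
    stop(sprintf(
      "numeric error: potential series not converged to tol %g at degree %d",
      head@seriesTol, head@maxDegree), call. = FALSE)

  L <- matrix(0, m, 3L * K)
  cols <- 3L * (seq_len(K) - 1L)
  for (k in 1:3) {
    Qr <- matrix(rhat0[, k], m, K, byrow = TRUE)
    Tang <- rehat[, k] - cosg * Qr  # e_k . (rhat_e - cos(g) rhat_0)
    L[, cols + k] <- A * Qr + Tang * B
  }
  L <- sweep(L, 2L, colMeans(L))    # average reference
  new("LeadField", matrix = L, modality = "EEG", units = "Ohm/m")
}
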