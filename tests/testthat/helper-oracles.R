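# Shared fixtures and independent oracle implementations used across the
# test files. Oracles are deliberately naive (grid search, dense solves,
# term-by-term series) and never call the code paths they check.

aryHead <- headModel()

# Small assets reused by several files (built once per test run).
tinyAssets <- local({
  sp <- buildSourceSpace(150, 10, 80, seed = 421)
  el <- electrodeArray(aryHead, 32)
  list(space = sp, electrodes = el,
       lead = eegLeadfield(sp, el, aryHead))
})

# Closed-form surface potential of a dipole inside a homogeneous
# conducting sphere (insulating boundary), via the Legendre series with
# explicit coefficients (2n+1)/n * b^(n-1) / (4 pi sigma R^(n+1)).
homogeneousSphereOracle <- function(posMm, q, elecMm, radiusMm, sigma,
                                    nmax = 300) {
  pos <- posMm / 1000
  elec <- elecMm / 1000
  R <- radiusMm / 1000
  b <- sqrt(sum(pos^2))
  rhat0 <- if (b > 0) pos / b else c(0, 0, 1)
  v <- vapply(seq_len(nrow(elec)), function(i) {
    re <- elec[i, ]
    rehat <- re / sqrt(sum(re^2))
    cg <- sum(rehat * rhat0)
    qr <- sum(q * rhat0)
    tang <- sum(q * (rehat - cg * rhat0))
    acc <- 0
    Pm1 <- 1; P <- cg; dPm1 <- 0; dP <- 1
    for (n in seq_len(nmax)) {
      acc <- acc + (2 * n + 1) / n * b^(n - 1) / R^(n + 1) *
        (n * qr * P + tang * dP)
      Pn1 <- ((2 * n + 1) * cg * P - n * Pm1) / (n + 1)
      dPn1 <- dPm1 + (2 * n + 1) * P
      Pm1 <- P; P <- Pn1
      dPm1 <- dP; dP <- dPn1
    }
    acc / (4 * pi * sigma)
  }, numeric(1))
  v - mean(v)   # average reference
}

# Radial component of the free-space magnetic field of the primary
# current dipole alone (no volume currents), per unit mu0: in a sphere
# the volume currents contribute nothing radial, so this must equal the
# full Sarvas solution's radial component.
freeSpaceRadialOracle <- function(posMm, q, sensMm) {
  r0 <- posMm / 1000
  sens <- sensMm / 1000
  vapply(seq_len(nrow(sens)), function(i) {
    rs <- sens[i, ]
    d <- rs - r0
    cr <- c(q[2] * d[3] - q[3] * d[2],
            q[3] * d[1] - q[1] * d[3],
            q[1] * d[2] - q[2] * d[1])
    sum(cr * rs / sqrt(sum(rs^2))) / (4 * pi * sum(d^2)^1.5)
  }, numeric(1))
}

# Scalar brute-force maximizer of the conditional posterior of one
# hypervariance: theta | x ~ argmax of hyperprior(theta) * N(x; 0, theta).
bruteForceTheta <- function(x, hp) {
  negLog <- if (hp@family == "inverse_gamma") {
    function(t) x^2 / (2 * t) + hp@theta0 / t + (hp@beta + 1.5) * log(t)
  } else {
    eta <- max(hp@beta - 1.5, 0)
    function(t) x^2 / (2 * t) + t / hp@theta0 - eta * log(t)
  }
  span <- max(hp@theta0, x^2) * c(1e-6, 1e6)
  opt <- stats::optimize(negLog, interval = span, tol = 1e-14)
  # refine on a tight log-grid around the optimum
  g <- exp(seq(log(opt$minimum) - 0.01, log(opt$minimum) + 0.01,
               length.out = 4001))
  g[which.min(vapply(g, negLog, numeric(1)))]
}

# Dense source-space solve of the x half-step quadratic.
denseXStep <- function(L, y, theta, sigma) {
  A <- crossprod(L) / sigma^2 + diag(1 / theta, length(theta))
  drop(solve(A, crossprod(L, y) / sigma^2))
}

expect_rel_equal <- function(got, want, tol) {
  scale <- max(abs(want), .Machine$double.eps)
  expect_lt(max(abs(got - want)) / scale, tol)
}
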