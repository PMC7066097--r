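# IAS optimizer: hypervariance and current-density half-steps, full
# alternating iteration, limiting behaviors.

test_that("theta updates match the brute-force scalar maximizer", {
  for (hp in list(igHyperprior(beta = 1.5, theta0 = 1e-10),
                  igHyperprior(beta = 2.5, theta0 = 1e-6),
                  gammaHyperprior(beta = 2, theta0 = 1e-4),
                  gammaHyperprior(beta = 3, theta0 = 1e-8))) {
    xs <- c(0, sqrt(hp@theta0) * 10^seq(-1, 3, length.out = 9))
    got <- updateTheta(xs, hp)
    want <- vapply(xs, bruteForceTheta, numeric(1), hp = hp)
    expect_rel_equal(got, want, 1e-6)
  }
})

test_that("theta update reproduces the closed-form reference points", {
  # frozen values from the grid-search oracle
  expect_equal(updateTheta(0, igHyperprior(1.5, 1e-10)), 1e-10 / 3)
  expect_equal(updateTheta(1, igHyperprior(1.5, 1e-10)),
               (1e-10 + 0.5) / 3, tolerance = 1e-12)
  expect_equal(updateTheta(0, gammaHyperprior(beta = 2, theta0 = 1e-4)),
               5e-5)
})

test_that("x update solves the ridge system via the data-space formula", {
  expect_equal(updateX(diag(2), c(1, 0), c(1, 1), 1), c(0.5, 0))
  # vanishing prior variance pins the component at zero
  x <- updateX(diag(2), c(1, 1), c(1, 1e-300), 1)
  expect_lt(abs(x[2]), 1e-12)
  set.seed(31)
  for (dims in list(c(4, 6), c(20, 90), c(50, 300))) {
    L <- matrix(rnorm(dims[1] * dims[2]), dims[1], dims[2])
    y <- rnorm(dims[1])
    theta <- rexp(dims[2]) + 0.05
    sigma <- 0.7
    expect_rel_equal(updateX(L, y, theta, sigma),
                     denseXStep(L, y, theta, sigma), 1e-8)
  }
})

test_that("a single IAS step from zero is the constant-theta minimum norm
           estimate", {
  set.seed(12)
  L <- matrix(rnorm(8 * 30), 8, 30)
  y <- rnorm(8)
  hp <- igHyperprior(beta = 1.5, theta0 = 1e-4)
  st <- iasMap(L, y, hp, iasConfig(1, 0.5))
  th <- hp@theta0 / (hp@beta + 1.5)
  mne <- th * drop(crossprod(L, solve(th * tcrossprod(L) +
                                        0.25 * diag(8), y)))
  expect_rel_equal(currentEstimate(st), mne, 1e-10)
})

test_that("the joint objective is non-increasing at every half-step", {
  set.seed(13)
  L <- matrix(rnorm(12 * 40), 12, 40)
  y <- rnorm(12)
  for (hp in list(igHyperprior(theta0 = 1e-6),
                  gammaHyperprior(theta0 = 1e-6))) {
    st <- iasMap(L, y, hp, iasConfig(15, 0.1))
    obj <- objectiveHistory(st)
    expect_true(all(diff(obj) <= 1e-8 * (abs(obj[-length(obj)]) + 1)))
  }
})

test_that("IAS recovers the support of a noiseless single-column signal", {
  set.seed(14)
  # well-conditioned 6 x 9 system
  L <- qr.Q(qr(matrix(rnorm(81), 9, 9)))[, 1:6]
  L <- t(L) + 0.1 * matrix(rnorm(54), 6, 9)
  for (jTrue in c(2, 7)) {
    y <- L[, jTrue] * 3
    st <- iasMap(L, y, igHyperprior(theta0 = 1e-8),
                 iasConfig(10, 0.01))
    # brute-force single-column least squares as the support oracle
    res <- vapply(seq_len(9), function(j) {
      b <- sum(L[, j] * y) / sum(L[, j]^2)
      sum((y - b * L[, j])^2)
    }, numeric(1))
    expect_equal(which.min(res), jTrue)
    expect_equal(which.max(abs(currentEstimate(st))), jTrue)
  }
})

test_that("joint rescaling of y, sigma and theta0 rescales the
           single-step estimate linearly", {
  set.seed(15)
  L <- matrix(rnorm(6 * 20), 6, 20)
  y <- rnorm(6)
  cc <- 3.7
  x1 <- currentEstimate(iasMap(L, y, igHyperprior(theta0 = 1e-4),
                               iasConfig(1, 0.2)))
  x2 <- currentEstimate(iasMap(L, cc * y,
                               igHyperprior(theta0 = cc^2 * 1e-4),
                               iasConfig(1, cc * 0.2)))
  expect_rel_equal(x2, cc * x1, 1e-10)
})

test_that("gamma hyperprior with beta = 1.5 is degenerate from a zero
           start but usable from a warm start", {
  set.seed(16)
  L <- matrix(rnorm(5 * 12), 5, 12)
  y <- rnorm(5)
  hp <- gammaHyperprior(beta = 1.5, theta0 = 1e-6)
  cold <- iasMap(L, y, hp, iasConfig(5, 0.1))
  expect_lt(max(abs(currentEstimate(cold))), 1e-200)
  warm <- iasMap(L, y, hp, iasConfig(5, 0.1), xInit = rep(1, 12))
  expect_gt(max(abs(currentEstimate(warm))), 0)
})

test_that("hyperprior validation rejects invalid parameters", {
  expect_error(igHyperprior(theta0 = 0), "theta0")
  expect_error(igHyperprior(beta = 1), "beta")
  expect_error(iasConfig(0, 1), "nIter")
  expect_error(iasConfig(5, -1), "sigma")
})
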