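# Spherical forward simulator: geometry, EEG series, Sarvas MEG,
# measurement simulation and E/MEG fusion.

test_that("source space sampling respects the shell and is reproducible", {
  sp <- buildSourceSpace(500, 20, 70, seed = 1)
  r <- sqrt(rowSums(coordinatesMm(sp)^2))
  expect_true(all(r >= 20 - 1e-9 & r <= 70 + 1e-9))
  sp2 <- buildSourceSpace(500, 20, 70, seed = 1)
  expect_identical(coordinatesMm(sp), coordinatesMm(sp2))
  expect_error(buildSourceSpace(10, 50, 40), "shell")
  expect_error(buildSourceSpace(0, 0, 85), "integer")
})

test_that("uniform ball sampling has mean radius 3R/4", {
  R <- 85
  sp <- buildSourceSpace(50000, 0, R, seed = 7)
  r <- sqrt(rowSums(coordinatesMm(sp)^2))
  # Var(r) = 3R^2/80 for a uniform ball
  se <- sqrt(3 * R^2 / 80 / 50000)
  expect_lt(abs(mean(r) - 3 * R / 4), 3 * se)
})

test_that("electrodes sit on the scalp, magnetometers at 1.2x", {
  el <- electrodeArray(aryHead, 102)
  r <- sqrt(rowSums(coordinatesMm(el)^2))
  expect_true(all(abs(r - 100) < 1e-6 * 100))
  expect_true(all(coordinatesMm(el)[, 3] >= 0))   # upper hemisphere
  mg <- magnetometerArray(el)
  expect_equal(coordinatesMm(mg), coordinatesMm(el) * 1.2)
  expect_error(magnetometerArray(el, scale = 0.9), "outside")
})

test_that("a central dipole produces a pure cos(polar angle) pattern", {
  sp0 <- new("SourceSpace", positions = matrix(0, 1, 3), rMin = 0,
             rMax = 1)
  el <- electrodeArray(aryHead, 102)
  L <- leadMatrix(eegLeadfield(sp0, el, aryHead))
  cosTheta <- coordinatesMm(el)[, 3] / 100
  expect_gt(cor(L[, 3], cosTheta), 1 - 1e-12)
})

test_that("EEG columns are average-referenced", {
  L <- leadMatrix(tinyAssets$lead)
  colNorm <- sqrt(colSums(L^2))
  expect_lt(max(abs(colSums(L)) / colNorm), 1e-10)
})

test_that("EEG matches the homogeneous-sphere closed form when all
           conductivities are equal", {
  hm <- headModel(conductivities = c(0.33, 0.33, 0.33))
  sp <- buildSourceSpace(4, 15, 75, seed = 11)
  el <- electrodeArray(hm, 40)
  L <- leadMatrix(eegLeadfield(sp, el, hm))
  for (j in seq_len(4)) {
    for (k in 1:3) {
      want <- homogeneousSphereOracle(coordinatesMm(sp)[j, ], diag(3)[k, ],
                                      coordinatesMm(el), 100, 0.33)
      expect_rel_equal(L[, 3 * (j - 1) + k], want, 1e-8)
    }
  }
})

test_that("EEG series is converged at the default truncation", {
  sp <- new("SourceSpace",
            positions = rbind(c(60, 10, 20), c(0, 0, 80)),
            rMin = 0, rMax = 85)
  el <- electrodeArray(aryHead, 40)
  L1 <- leadMatrix(eegLeadfield(sp, el, aryHead))
  L2 <- leadMatrix(eegLeadfield(sp, el, headModel(maxDegree = 400)))
  expect_rel_equal(L1, L2, 1e-8)
})

test_that("EEG forward is linear and rejects out-of-brain sources", {
  L <- leadMatrix(tinyAssets$lead)
  q <- c(0.3, -1.2, 0.5)
  col <- L[, 1:3] %*% q
  expect_equal(L[, 1:3] %*% (2 * q), 2 * col)
  bad <- new("SourceSpace", positions = matrix(c(88, 0, 0), 1, 3),
             rMin = 0, rMax = 90)
  expect_error(eegLeadfield(bad, tinyAssets$electrodes, aryHead),
               "geometry")
})

test_that("radial dipoles are magnetically silent; tangential ones match
           the free-space primary field", {
  sp <- buildSourceSpace(5, 20, 80, seed = 3)
  mg <- magnetometerArray(electrodeArray(aryHead, 60))
  L <- leadMatrix(megLeadfield(sp, mg, aryHead))
  pos <- coordinatesMm(sp)
  for (j in seq_len(5)) {
    rhat <- pos[j, ] / sqrt(sum(pos[j, ]^2))
    radial <- L[, 3 * (j - 1) + 1:3] %*% rhat
    expect_lt(max(abs(radial)), 1e-12 * max(abs(L)))
    tq <- c(-pos[j, 2], pos[j, 1], 0)
    tq <- tq / sqrt(sum(tq^2))
    got <- drop(L[, 3 * (j - 1) + 1:3] %*% tq)
    want <- freeSpaceRadialOracle(pos[j, ], tq, coordinatesMm(mg))
    expect_rel_equal(got, want, 1e-12)
  }
  expect_error(megLeadfield(sp, electrodeArray(aryHead, 10), aryHead),
               "magnetometer")
  inside <- new("SensorArray", kind = "radial_magnetometer",
                positions = matrix(c(50, 0, 0), 1, 3), radius = 50)
  expect_error(megLeadfield(sp, inside, aryHead), "geometry")
})

test_that("noiseless simulation reproduces the normalized dipole
           superposition exactly", {
  sp <- tinyAssets$space
  L <- tinyAssets$lead
  dip <- dipoleSource(coordinatesMm(sp)[5, ], direction = c(0, 0, 1),
                      amplitude = 2)
  meas <- simulateData(L, sp, dip, noisePct = 0)
  want <- 2 * drop(leadMatrix(L)[, 13:15] %*% c(0, 0, 1))
  expect_equal(measurements(meas), want / max(abs(want)))
  expect_equal(max(abs(measurements(meas))), 1)
  expect_equal(noiseSigma(meas), 0)
  expect_error(simulateData(L, sp, list(), noisePct = 0), "degenerate")
})

test_that("simulated noise has sd 3% of the maximal clean amplitude", {
  sp <- tinyAssets$space
  L <- tinyAssets$lead
  dip <- dipoleSource(coordinatesMm(sp)[5, ], direction = c(0, 0, 1))
  n <- 3000
  e1 <- vapply(seq_len(n), function(i) {
    m <- simulateData(L, sp, dip, noisePct = 3, seed = 5000 + i)
    m@y[1] * m@normalizationFactor        # raw-scale entry
  }, numeric(1))
  clean <- simulateData(L, sp, dip, noisePct = 0)
  cleanRaw <- clean@cleanY * clean@normalizationFactor
  sdWant <- 0.03 * max(abs(cleanRaw))
  se <- sdWant / sqrt(2 * (n - 1))
  expect_lt(abs(sd(e1 - cleanRaw[1]) - sdWant), 3 * se)
})

test_that("simulation is bit-reproducible under a fixed seed and warns on
           distant dipoles", {
  sp <- tinyAssets$space
  L <- tinyAssets$lead
  dip <- dipoleSource(c(0, 0, 30), direction = c(1, 0, 0))
  m1 <- suppressWarnings(simulateData(L, sp, dip, 3, seed = 99))
  m2 <- suppressWarnings(simulateData(L, sp, dip, 3, seed = 99))
  expect_identical(measurements(m1), measurements(m2))
  far <- dipoleSource(c(0, 0, 5), direction = c(1, 0, 0))
  expect_warning(simulateData(L, sp, far, 3, seed = 1), "mm from")
})

test_that("E/MEG fusion equalizes block Frobenius norms and scales the
           data consistently", {
  m <- 8; p <- 12
  set.seed(42)
  Le <- new("LeadField", matrix = matrix(rnorm(m * p), m, p),
            modality = "EEG", units = "Ohm/m")
  Lm <- new("LeadField", matrix = matrix(rnorm(m * p), m, p) / 2,
            modality = "MEG", units = "1/m^2")
  mkMeas <- function(y) new("MeasurementSet", y = y / max(abs(y)),
                            sigma = 0.03, cleanY = y / max(abs(y)),
                            normalizationFactor = max(abs(y)))
  ye <- rnorm(m); ym <- rnorm(m)
  sys <- combineEMEG(Le, mkMeas(ye), Lm, mkMeas(ym))
  cc <- norm(Le@matrix, "F") / norm(Lm@matrix, "F")
  M <- leadMatrix(sys$lead)
  expect_equal(norm(M[1:m, ], "F"), norm(M[(m + 1):(2 * m), ], "F"))
  expect_equal(M[(m + 1):(2 * m), ], cc * Lm@matrix)
  # data blocks: same c applied to the raw MEG data, joint max-normalization
  yRaw <- c(ye, cc * ym)
  expect_equal(measurements(sys$measurement), yRaw / max(abs(yRaw)))
  expect_equal(max(abs(measurements(sys$measurement))), 1)
  # identical systems: c = 1, plain stacking
  sysId <- combineEMEG(Le, mkMeas(ye), Le, mkMeas(ye))
  expect_equal(leadMatrix(sysId$lead), rbind(Le@matrix, Le@matrix))
  expect_error(combineEMEG(Le, mkMeas(ye),
                           new("LeadField", matrix = matrix(0, m, 6),
                               modality = "MEG", units = ""),
                           mkMeas(ym)),
               "dimension")
})

test_that("tilted directions interpolate between tangential and radial", {
  p <- c(30, -40, 50)
  rhat <- p / sqrt(sum(p^2))
  d0 <- dipoleSource(p, angleDeg = 0)@direction
  d90 <- dipoleSource(p, angleDeg = 90)@direction
  expect_lt(abs(sum(d0 * rhat)), 1e-12)        # tangential
  expect_equal(drop(d90), rhat, tolerance = 1e-12)  # radial
  expect_equal(sqrt(sum(d0^2)), 1)
})
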