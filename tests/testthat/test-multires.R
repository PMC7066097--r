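# Randomized nested decompositions and the transfer operators.

test_that("nearest-center partition matches an exhaustive search and
           breaks ties toward the lowest index", {
  set.seed(21)
  pos <- cbind(matrix(rnorm(12), 6, 2), 0)
  cen <- c(2L, 5L)
  got <- partitionNearest(pos, cen)
  want <- apply(as.matrix(dist(pos))[, cen], 1, which.min)
  expect_equal(got, unname(want))
  # exact tie: equidistant point goes to the first center
  tie <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, 0, 0))
  expect_equal(partitionNearest(tie, c(1L, 2L))[3], 1L)
  expect_equal(partitionNearest(tie, seq_len(3L)), 1:3)
  expect_equal(partitionNearest(tie, 2L), rep(1L, 3))
})

test_that("decomposition level sizes follow K * s^(l - L) and the levels
           nest", {
  sp <- buildSourceSpace(10000, 0, 85, seed = 22)
  dec <- buildDecomposition(sp, L = 3, s = 8, seed = 23)
  kl <- vapply(resolutionLevels(dec), function(l) length(l@centers),
               integer(1))
  expect_equal(kl, c(156L, 1250L, 10000L))
  levs <- resolutionLevels(dec)
  for (l in 1:2) {
    expect_true(all(levs[[l]]@centers %in% levs[[l + 1]]@centers))
  }
  # partition invariants on every level
  for (lev in levs) {
    expect_equal(sort(unique(lev@assignment)),
                 seq_along(lev@centers))
    expect_equal(sum(lev@sizes), 10000L)
    expect_equal(lev@assignment[lev@centers],
                 seq_along(lev@centers))
  }
  # mean subset size ~ s^(L - l) within 20%
  for (l in 1:2) {
    expect_lt(abs(mean(levs[[l]]@sizes) / 8^(3 - l) - 1), 0.2)
  }
})

test_that("degenerate decompositions collapse to the full space", {
  sp <- buildSourceSpace(200, 0, 85, seed = 24)
  one <- buildDecomposition(sp, L = 1, s = 8, seed = 1)
  expect_equal(length(resolutionLevels(one)), 1L)
  expect_equal(resolutionLevels(one)[[1]]@assignment, 1:200)
  flat <- buildDecomposition(sp, L = 3, s = 1, seed = 1)
  for (lev in resolutionLevels(flat)) {
    expect_equal(length(lev@centers), 200L)
  }
  expect_error(buildDecomposition(sp, L = 3, s = 0.5), "sparsity")
})

test_that("restriction, prolongation and estimate restriction are
           mutually consistent", {
  sp <- buildSourceSpace(300, 0, 85, seed = 25)
  dec <- buildDecomposition(sp, L = 2, s = 6, seed = 26)
  lev <- resolutionLevels(dec)[[1]]
  fine <- resolutionLevels(dec)[[2]]
  L <- leadMatrix(eegLeadfield(sp, electrodeArray(aryHead, 20), aryHead))
  Lc <- restrictLeadfield(L, lev)
  # singleton subsets: coarse = fine
  expect_equal(restrictLeadfield(L, fine), L)
  # L_coarse x_c = L_fine P(x_c)
  set.seed(27)
  xc <- rnorm(ncol(Lc))
  expect_rel_equal(drop(Lc %*% xc), drop(L %*% prolongate(xc, lev)),
                   1e-12)
  # column-mass conservation per component
  comp <- rep(1:3, length.out = ncol(L))
  for (k in 1:3) {
    expect_rel_equal(rowSums(Lc[, rep(1:3, length(lev@centers)) == k]),
                     rowSums(L[, comp == k]), 1e-12)
  }
  # prolongate copies, restrictEstimate averages, and they round-trip
  xf <- rnorm(ncol(L))
  expect_equal(prolongate(xf, fine), xf)
  expect_equal(restrictEstimate(xf, fine), xf)
  expect_rel_equal(restrictEstimate(prolongate(xc, lev), lev), xc, 1e-12)
  # constant fields are preserved both ways
  expect_equal(prolongate(rep(2, ncol(Lc)), lev), rep(2, ncol(L)))
  expect_rel_equal(restrictEstimate(rep(2, ncol(L)), lev),
                   rep(2, ncol(Lc)), 1e-12)
  # adjoint consistency: <P xc, xf> = <xc, |B| restrict(xf)>
  lhs <- sum(prolongate(xc, lev) * xf)
  rhs <- sum(xc * (rep(lev@sizes, each = 3) * restrictEstimate(xf, lev)))
  expect_rel_equal(lhs, rhs, 1e-12)
})

test_that("subset means are computed per component", {
  pos <- rbind(c(0, 0, 10), c(0, 0, 11), c(0, 0, 50))
  sp <- new("SourceSpace", positions = pos, rMin = 0, rMax = 60)
  lev <- new("ResolutionLevel", index = 1L, centers = c(1L, 3L),
             assignment = c(1L, 1L, 2L), sizes = c(2L, 1L))
  xf <- c(1, 0, 0, 3, 0, 0, 9, 9, 9)
  expect_equal(restrictEstimate(xf, lev), c(2, 0, 0, 9, 9, 9))
})

test_that("decomposition JSON export replays exactly", {
  sp <- buildSourceSpace(150, 0, 85, seed = 28)
  dec <- buildDecomposition(sp, L = 3, s = 5, seed = 29)
  path <- tempfile(fileext = ".json")
  writeDecompositionJSON(dec, path)
  dec2 <- readDecompositionJSON(path, sp)
  for (l in 1:3) {
    expect_identical(resolutionLevels(dec2)[[l]]@assignment,
                     resolutionLevels(dec)[[l]]@assignment)
  }
})
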