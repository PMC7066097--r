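# ROI metrics, detection criterion, aggregation, histograms.

# small deterministic space: a line of positions along z plus outliers
evalSpace <- local({
  pos <- rbind(c(0, 0, 40), c(0, 10, 40), c(0, -10, 40),
               c(0, 0, 60), c(50, 50, 30), c(-60, 20, 10))
  new("SourceSpace", positions = pos, rMin = 0, rMax = 85)
})

impulse <- function(j, moment, K = 6) {
  x <- numeric(3 * K)
  x[3 * (j - 1) + 1:3] <- moment
  x
}

test_that("an exact unit impulse at the truth scores perfectly", {
  truth <- dipoleSource(c(0, 0, 40), direction = c(0, 1, 0),
                        amplitude = 2)
  m <- roiMetrics(impulse(1, c(0, 2, 0)), evalSpace, truth)
  expect_equal(m$positionError, 0)
  expect_equal(m$angleError, 0)
  expect_equal(m$log10AmpError, 0)
  expect_equal(m$relativeMaximum, 1)
  expect_true(m$detected)
})

test_that("symmetric equal amplitudes center on the ROI center", {
  truth <- dipoleSource(c(0, 0, 40), direction = c(1, 0, 0))
  x <- impulse(2, c(1, 0, 0)) + impulse(3, c(1, 0, 0))
  m <- roiMetrics(x, evalSpace, truth)
  expect_equal(m$positionError, 0)
})

test_that("detection requires strictly exceeding the threshold", {
  truth <- dipoleSource(c(0, 0, 40), direction = c(1, 0, 0))
  # global max 1 far outside the ROI, ROI maximum exactly 0.100 / 0.101
  at <- roiMetrics(impulse(1, c(0.100, 0, 0)) + impulse(6, c(1, 0, 0)),
                   evalSpace, truth)
  expect_equal(at$relativeMaximum, 0.1)
  expect_false(at$detected)
  above <- roiMetrics(impulse(1, c(0.101, 0, 0)) + impulse(6, c(1, 0, 0)),
                      evalSpace, truth)
  expect_true(above$detected)
})

test_that("metrics are invariant under positive rescaling except the
           amplitude error, which shifts by log10 of the scale", {
  truth <- dipoleSource(c(0, 0, 40), direction = c(0, 0, 1),
                        amplitude = 1)
  x <- impulse(1, c(0.2, 0, 0.9)) + impulse(4, c(0, 0.1, 0.2)) +
    impulse(5, c(0.5, 0, 0))
  m1 <- roiMetrics(x, evalSpace, truth)
  m2 <- roiMetrics(10 * x, evalSpace, truth)
  expect_equal(m2$positionError, m1$positionError)
  expect_equal(m2$angleError, m1$angleError)
  expect_equal(m2$relativeMaximum, m1$relativeMaximum)
  expect_equal(m2$log10AmpError, m1$log10AmpError + 1)
})

test_that("adding amplitude inside the ROI never revokes detection", {
  truth <- dipoleSource(c(0, 0, 40), direction = c(1, 0, 0))
  base <- impulse(1, c(0.3, 0, 0)) + impulse(6, c(1, 0, 0))
  expect_true(roiMetrics(base, evalSpace, truth)$detected)
  for (extra in c(0.1, 1, 10)) {
    x <- base + impulse(2, c(extra, 0, 0))
    expect_true(roiMetrics(x, evalSpace, truth)$detected)
  }
})

test_that("degenerate estimates are flagged rather than erroring", {
  truth <- dipoleSource(c(0, 0, 40), direction = c(1, 0, 0),
                        amplitude = 0)
  m <- roiMetrics(numeric(18), evalSpace, truth)
  expect_equal(m$relativeMaximum, 0)
  expect_true(is.na(m$angleError))
  expect_false(m$detected)
  far <- dipoleSource(c(200, 200, 200), direction = c(1, 0, 0))
  expect_error(roiMetrics(numeric(18), evalSpace, far), "ROI")
})

test_that("relative maximum is 1 exactly when the global maximizer lies
           in the ROI", {
  truth <- dipoleSource(c(0, 0, 40), direction = c(1, 0, 0))
  inRoi <- roiMetrics(impulse(1, c(2, 0, 0)) + impulse(6, c(1, 0, 0)),
                      evalSpace, truth)
  expect_equal(inRoi$relativeMaximum, 1)
  outRoi <- roiMetrics(impulse(1, c(1, 0, 0)) + impulse(6, c(2, 0, 0)),
                       evalSpace, truth)
  expect_lt(outRoi$relativeMaximum, 1)
})

test_that("aggregation reproduces direct percentile computation", {
  df <- data.frame(positionError = as.numeric(1:50),
                   angleError = NA_real_, log10AmpError = NA_real_,
                   relativeMaximum = runif(50),
                   detected = rep(c(TRUE, FALSE), 25))
  s <- summarizeMetrics(df)
  row <- s[s$metric == "positionError", ]
  expect_equal(row$median, 25.5)
  expect_equal(row$q05, 3.45)
  expect_equal(row$q95, 47.55)
  expect_equal(detectionPercentage(df), 50)
  one <- summarizeMetrics(df[1, ])
  expect_equal(one$median[one$metric == "positionError"], 1)
  expect_true(attr(one, "detectionPercentage") %in% c(0, 100))
})

test_that("histogram tables match a naive counting pass", {
  set.seed(61)
  df <- data.frame(positionError = rnorm(40, 10, 3),
                   angleError = runif(40, 0, 90),
                   log10AmpError = rnorm(40),
                   relativeMaximum = runif(40),
                   detected = TRUE)
  h <- histogramTable(df, bins = 7)
  for (cn in unique(h$metric)) {
    sub <- h[h$metric == cn, ]
    expect_equal(sum(sub$count), 40)
    v <- df[[cn]]
    naive <- vapply(seq_len(nrow(sub)), function(i) {
      lo <- sub$binStart[i]; hi <- sub$binEnd[i]
      if (i == nrow(sub)) sum(v >= lo & v <= hi) else sum(v >= lo & v < hi)
    }, numeric(1))
    expect_equal(sub$count, naive)
  }
  const <- data.frame(positionError = rep(5, 9), angleError = NA_real_,
                      log10AmpError = NA_real_, relativeMaximum = 0.5,
                      detected = TRUE)
  hc <- histogramTable(const, bins = 5)
  expect_equal(sum(hc$count[hc$metric == "positionError"] > 0), 1L)
})
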