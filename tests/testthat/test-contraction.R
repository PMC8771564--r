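# Kymograms, wall tracking, fractional shortening, area change and the
# calcium-contraction delay.

ringFrame <- function(nr, nc, ctr, a, b, wall = 6, edge = 2, amp = 1000) {
  r <- matrix(seq_len(nr), nr, nc)
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  rho <- sqrt(((c_ - ctr[2]) / a)^2 + ((r - ctr[1]) / b)^2)
  outer_ <- pmin(pmax((1 - rho) * a / edge + 0.5, 0), 1)
  inner <- pmin(pmax((rho - (1 - wall / a)) * a / edge + 0.5, 0), 1)
  amp * outer_ * inner
}

test_that("kymograms of uniform frames are constant and axis-aligned lines are lookups", {
  s <- constantStack(7, n = 4, nr = 10, nc = 20)
  line <- MeasurementLine(c(5, 2), c(5, 18), 1L)
  ky <- buildKymogram(s, line)
  expect_true(all(ky@intensities == 7))
  expect_equal(dim(ky@intensities), c(4L, 17L))

  img <- blobImage()
  s2 <- stackFromFrames(img, img * 2)
  line2 <- MeasurementLine(c(12, 3), c(12, 30), 1L)
  ky2 <- buildKymogram(s2, line2)
  expect_equal(ky2@intensities[1, ], img[12, 3:30])
  expect_equal(ky2@intensities[2, ], 2 * img[12, 3:30])
  expect_equal(spatialStep(ky2), 1.45)

  lineOut <- MeasurementLine(c(5, -3), c(5, 18), 1L)
  expect_error(buildKymogram(s, lineOut), "exits the frame")
})

test_that("a synthetic ring of known outer diameter is tracked within a pixel", {
  px <- 1.45
  aPx <- 100 / px / 2            # outer diameter 100 um -> 69.0 px
  frame <- ringFrame(96, 96, c(48, 48), aPx, aPx)
  s <- ChannelStack(array(rep(frame, 3), dim = c(96, 96, 3))
                    |> aperm(c(3, 1, 2)), 0.02, px)
  ky <- buildKymogram(s, MeasurementLine(c(48, 4), c(48, 93), 1L))
  dtr <- trackOuterWalls(ky)
  expect_true(all(abs(traceValues(dtr) - 100) <= px))
  expect_true(all(trackedMask(dtr)))
})

test_that("tracking is invariant to a global intensity scale", {
  px <- 1.45
  frame <- ringFrame(64, 64, c(32, 32), 20, 20)
  mk <- function(f) {
    arr <- array(0, dim = c(2, 64, 64)); arr[1, , ] <- f; arr[2, , ] <- f
    ChannelStack(arr, 0.02, px)
  }
  line <- MeasurementLine(c(32, 4), c(32, 61), 1L)
  d1 <- traceValues(trackOuterWalls(buildKymogram(mk(frame), line)))
  d2 <- traceValues(trackOuterWalls(buildKymogram(mk(frame * 7.3), line)))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("static frames give a constant diameter and no contraction cycles", {
  px <- 1.45
  frame <- ringFrame(64, 64, c(32, 32), 20, 20)
  arr <- array(0, dim = c(60, 64, 64))
  for (i in 1:60) arr[i, , ] <- frame
  s <- ChannelStack(arr, 0.02, px)
  dtr <- trackOuterWalls(buildKymogram(s, MeasurementLine(c(32, 4), c(32, 61), 1L)))
  expect_lt(diff(range(traceValues(dtr))), 1e-9)
  expect_equal(nrow(contractionCycles(dtr)), 0)
})

test_that("FS and FAC follow their defining formulas", {
  # oscillating diameter: EDD 100, ESD 75 -> FS 0.25
  dt <- 0.01
  t <- seq(0, 3, by = dt)
  d <- 100 - 25 * (0.5 - 0.5 * cos(2 * pi * 2 * t))
  dtr <- new("DiameterTrace", time = t, diameter = d,
             tracked = rep(TRUE, length(t)), frameInterval = dt)
  cc <- contractionCycles(dtr)
  expect_gt(nrow(cc), 2)
  expect_equal(cc$EDD_um, rep(100, nrow(cc)), tolerance = 1e-6)
  expect_equal(cc$ESD_um, rep(75, nrow(cc)), tolerance = 1e-6)
  expect_equal(cc$FS, rep(0.25, nrow(cc)), tolerance = 1e-6)

  a <- 10000 - 2500 * (0.5 - 0.5 * cos(2 * pi * 2 * t))
  attr(a, "frameInterval") <- dt
  fac <- fractionalAreaChange(a)
  expect_equal(fac$FAC, rep(0.25, nrow(fac)), tolerance = 1e-6)
})

test_that("area trace of a pulsating filled ellipse matches pi*a*b analytically", {
  nr <- 80; nc <- 80; px <- 1.45
  dt <- 0.02
  n <- 100
  t <- (seq_len(n) - 1) * dt
  scale <- 1 - 0.15 * (0.5 - 0.5 * cos(2 * pi * 2 * t))
  r <- matrix(seq_len(nr), nr, nc)
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  arr <- array(0, dim = c(n, nr, nc))
  a0 <- 22; b0 <- 18
  for (i in seq_len(n)) {
    a <- a0 * scale[i]; b <- b0 * scale[i]
    arr[i, , ] <- 900 * (((c_ - 40) / a)^2 + ((r - 40) / b)^2 <= 1)
  }
  s <- ChannelStack(arr, dt, px)
  area <- ventricleAreaTrace(s)
  analytic <- pi * a0 * b0 * scale^2 * px^2
  expect_true(all(abs(area - analytic) / analytic < 0.05))
  fac <- fractionalAreaChange(area)
  expect_equal(mean(fac$FAC), 1 - min(scale)^2 / max(scale)^2,
               tolerance = 0.02)
})

test_that("the calcium-contraction delay is zero for an inverted copy and recovers a known lag", {
  dt <- 0.01
  t <- seq(0, 6, by = dt)
  x <- 1 + 0.3 * pmax(0, sin(2 * pi * 2 * t))^4
  rt <- RatioTrace(x, dt, "ventricle")
  dtr0 <- new("DiameterTrace", time = t, diameter = 100 - 20 * (x - 1),
              tracked = rep(TRUE, length(t)), frameInterval = dt)
  del0 <- caContractionDelay(rt, dtr0)
  expect_equal(del0$mean_s, 0, tolerance = 1e-9)

  # diameter minimum lagging the ratio peak by 40 ms
  lag <- 0.04
  xl <- 1 + 0.3 * pmax(0, sin(2 * pi * 2 * (t - lag)))^4
  dtrL <- new("DiameterTrace", time = t, diameter = 100 - 20 * (xl - 1),
              tracked = rep(TRUE, length(t)), frameInterval = dt)
  delL <- caContractionDelay(rt, dtrL)
  expect_lt(abs(delL$mean_s - lag), dt / 2 + 2e-3)
})

test_that("untracked rows are filled and excessive failure is an error", {
  px <- 1.45
  frame <- ringFrame(64, 64, c(32, 32), 20, 20)
  arr <- array(0, dim = c(10, 64, 64))
  for (i in 1:10) arr[i, , ] <- frame
  arr[4, , ] <- 5                       # one frame with no wall signal
  s <- ChannelStack(arr, 0.02, px)
  ky <- buildKymogram(s, MeasurementLine(c(32, 4), c(32, 61), 1L))
  dtr <- trackOuterWalls(ky)
  expect_false(trackedMask(dtr)[4])
  expect_equal(traceValues(dtr)[4], traceValues(dtr)[3], tolerance = 1e-6)

  arrBad <- array(5, dim = c(10, 64, 64))
  for (i in 1:2) arrBad[i, , ] <- frame
  sBad <- ChannelStack(arrBad, 0.02, px)
  kyBad <- buildKymogram(sBad, MeasurementLine(c(32, 4), c(32, 61), 1L))
  expect_error(trackOuterWalls(kyBad), "different measurement line")
})
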