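# Pixel-wise ratioing, clipping, intensity-weighted ROI traces and the
# motion-artifact index.

test_that("ratio stack applies the clipping rule exactly", {
  D <- matrix(100, 4, 4)
  F1 <- matrix(100, 4, 4)
  s <- computeRatioStack(stackFromFrames(F1), stackFromFrames(D),
                         displayRange = c(0.5, 2))
  expect_true(all(ratios(s) == 1))

  # pixel ratios 0.1 and 10 under display range (0.5, 2.0) clip to
  # 0.5/4 = 0.125 and 2*4 = 8
  F2 <- matrix(c(10, 1000, 100, 100), 2, 2)
  D2 <- matrix(100, 2, 2)
  s2 <- computeRatioStack(stackFromFrames(F2), stackFromFrames(D2),
                          displayRange = c(0.5, 2))
  expect_equal(ratios(s2)[1, 1, 1], 0.125)
  expect_equal(ratios(s2)[1, 2, 1], 8)
  expect_equal(ratios(s2)[1, 1, 2], 1)

  # zero donor clips to the upper bound
  D3 <- matrix(c(0, 100), 1, 2)
  F3 <- matrix(c(50, 100), 1, 2)
  s3 <- computeRatioStack(stackFromFrames(F3), stackFromFrames(D3),
                          displayRange = c(0.5, 2))
  expect_equal(ratios(s3)[1, 1, 1], 8)
  expect_error(computeRatioStack(stackFromFrames(F3), stackFromFrames(D3),
                                 displayRange = c(2, 0.5)), "minimum")
})

test_that("clipping is idempotent", {
  img <- blobImage()
  fret <- stackFromFrames(img * 2)
  donor <- stackFromFrames(img)
  dr <- c(0.5, 2)
  r1 <- ratios(computeRatioStack(fret, donor, dr))
  # feeding the clipped ratios back through (donor = 1) changes nothing
  r2 <- ratios(computeRatioStack(stackFromFrames(r1[1, , ]),
                                 stackFromFrames(matrix(1, 32, 32)), dr))
  expect_equal(r2[1, , ], r1[1, , ])
})

test_that("weighted ROI ratio reproduces hand-computed values", {
  # uniform ROI: D = 100, F = 150 everywhere -> 1.5
  roi <- ROI("all", matrix(TRUE, 2, 2))
  tr <- weightedRoiRatio(stackFromFrames(matrix(150, 2, 2)),
                         stackFromFrames(matrix(100, 2, 2)), roi,
                         displayRange = c(0.5, 2.5))
  expect_equal(traceValues(tr), 1.5)

  # two pixels {D=100,F=200}, {D=10,F=10}: weights (150, 10),
  # ratio = (2.0*150 + 1.0*10) / 160 = 1.9375
  D <- matrix(c(100, 10, 0, 0), 1, 4)
  F1 <- matrix(c(200, 10, 0, 0), 1, 4)
  roi2 <- ROI("pair", matrix(c(TRUE, TRUE, FALSE, FALSE), 1, 4))
  tr2 <- weightedRoiRatio(stackFromFrames(F1), stackFromFrames(D), roi2,
                          displayRange = c(0.5, 2.5))
  expect_equal(traceValues(tr2), 1.9375)

  # single-pixel ROI equals that pixel's clipped ratio:
  # raw 200/100 = 2 clips to the upper bound 0.4 * 4 = 1.6
  roi3 <- ROI("px", matrix(c(TRUE, FALSE, FALSE, FALSE), 1, 4))
  tr3 <- weightedRoiRatio(stackFromFrames(F1), stackFromFrames(D), roi3,
                          displayRange = c(0.1, 0.4))
  expect_equal(traceValues(tr3), 1.6)
})

test_that("zero-weight frames are flagged missing with a warning", {
  D <- array(0, dim = c(2, 2, 2)); D[1, , ] <- 100
  F1 <- array(0, dim = c(2, 2, 2)); F1[1, , ] <- 150
  roi <- ROI("all", matrix(TRUE, 2, 2))
  expect_warning(
    tr <- weightedRoiRatio(ChannelStack(F1, 0.02, 1.45),
                           ChannelStack(D, 0.02, 1.45), roi,
                           displayRange = c(0.5, 2)),
    "zero total ROI weight")
  expect_equal(traceValues(tr), c(1.5, NA))
})

test_that("weighted ROI ratio is exactly invariant to common-mode scaling", {
  set.seed(42)
  n <- 8; nr <- 10; nc <- 10
  D <- array(stats::runif(n * nr * nc, 50, 500), dim = c(n, nr, nc))
  F1 <- D * array(stats::runif(n * nr * nc, 0.8, 2.5), dim = c(n, nr, nc))
  m <- stats::runif(n, 0.3, 3)                   # arbitrary per-frame factor
  Dm <- D * m; Fm <- F1 * m
  roi <- ROI("box", matrix(TRUE, nr, nc))
  dr <- c(0.5, 3)
  base <- traceValues(weightedRoiRatio(ChannelStack(F1, 0.02, 1.45),
                                       ChannelStack(D, 0.02, 1.45), roi, dr))
  mod <- traceValues(weightedRoiRatio(ChannelStack(Fm, 0.02, 1.45),
                                      ChannelStack(Dm, 0.02, 1.45), roi, dr))
  expect_equal(mod, base, tolerance = 1e-12)
})

test_that("motion-artifact index behaves at its fixed points", {
  osc <- RatioTrace(1 + 0.2 * sin(seq(0, 20, by = 0.1)), 0.02, "test")
  flat <- RatioTrace(rep(1.5, length(traceValues(osc))), 0.02, "control")
  expect_equal(motionArtifactIndex(osc, flat), 0)
  expect_equal(motionArtifactIndex(osc, osc), 1)
  expect_error(motionArtifactIndex(flat, osc), "zero variance")
})

test_that("motion-only construct shows far less ratio variance than the sensor", {
  test <- smallRender("3dpf", durationS = 3, seed = 5)
  ctrl <- smallRender("motion_only", durationS = 3, seed = 5)
  trTest <- weightedRoiRatio(test$fret, test$donor, test$truth$roiVentricle)
  trCtrl <- weightedRoiRatio(ctrl$fret, ctrl$donor, ctrl$truth$roiVentricle)
  idx <- motionArtifactIndex(trTest, trCtrl)
  expect_lt(idx, 0.1)
})

test_that("pseudo-color rendering is deterministic and intensity-gated", {
  r <- matrix(c(0.5, 2), 2, 2)
  zero <- renderRatioImage(r, matrix(0, 2, 2), c(0.5, 2))
  expect_true(all(zero == 0))
  i <- matrix(1, 2, 2)
  lo <- renderRatioImage(matrix(0.5, 2, 2), i, c(0.5, 2))
  hi <- renderRatioImage(matrix(2, 2, 2), i, c(0.5, 2))
  expect_equal(lo[1, 1, ], c(0, 0, 1))   # hue endpoint blue
  expect_equal(hi[1, 1, ], c(1, 0, 0))   # hue endpoint red
  a <- renderRatioImage(r, i, c(0.5, 2))
  b <- renderRatioImage(r, i, c(0.5, 2))
  expect_identical(a, b)
})

test_that("polygon ROIs rasterize with the even-odd rule", {
  # unit square polygon covering pixels (2..4, 2..4)
  sq <- rbind(c(1.5, 1.5), c(1.5, 4.5), c(4.5, 4.5), c(4.5, 1.5))
  roi <- roiFromPolygon(sq, c(6, 6), "sq")
  expect_equal(sum(roiMask(roi)), 9)
  expect_true(all(roiMask(roi)[2:4, 2:4]))
  # JSON round trip
  path <- file.path(tempdir(), "rois.json")
  writeRoiJSON(list(sq = sq), path)
  back <- readRoiJSON(path, c(6, 6))
  expect_identical(roiMask(back$sq), roiMask(roi))
})
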