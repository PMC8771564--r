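# Stack IO, dual-view splitting and channel registration.

test_that("TIFF write/read round trip is the identity on integer stacks", {
  s <- constantStack(0, n = 3, nr = 4, nc = 4)
  path <- file.path(tempdir(), "zeros.tif")
  writeStack(s, path)
  back <- readStack(path, 0.02, 1.45)
  expect_identical(dim(frames(back)), c(3L, 4L, 4L))
  expect_true(all(frames(back) == 0))

  img <- blobImage()
  s2 <- stackFromFrames(img, img * 2, pmin(img * 3, 65535))
  path2 <- file.path(tempdir(), "blobs.tif")
  writeStack(s2, path2)
  back2 <- readStack(path2)         # metadata from the JSON sidecar
  expect_equal(frames(back2), frames(s2))
  expect_equal(frameInterval(back2), 0.02)
  expect_equal(pixelSize(back2), 1.45)
})

test_that("a directory of per-frame TIFFs reads back in lexicographic order", {
  d <- file.path(tempdir(), "framedir")
  dir.create(d, showWarnings = FALSE)
  img <- blobImage()
  for (i in 1:3)
    tiff::writeTIFF(img * i / 65535, file.path(d, sprintf("frame_%02d.tif", i)),
                    bits.per.sample = 16L)
  s <- readStack(d, 0.01, 1.45)
  expect_equal(nFrames(s), 3L)
  expect_equal(s@frames[2, , ], img * 2)
})

test_that("stack readers reject broken inputs by name", {
  expect_error(readStack(file.path(tempdir(), "nope.tif")), "no such file")
  d <- file.path(tempdir(), "badshapes")
  dir.create(d, showWarnings = FALSE)
  tiff::writeTIFF(matrix(0, 4, 4), file.path(d, "a.tif"), bits.per.sample = 16L)
  tiff::writeTIFF(matrix(0, 4, 5), file.path(d, "b.tif"), bits.per.sample = 16L)
  expect_error(readStack(d, 0.02, 1.45), "b\\.tif")
  f <- file.path(tempdir(), "meta.tif")
  tiff::writeTIFF(matrix(0, 4, 4), f, bits.per.sample = 16L)
  expect_error(readStack(f, -0.02, 1.45), "frameInterval")
})

test_that("splitDualView separates halves with forced geometry", {
  arr <- array(0, dim = c(10, 8, 16))
  arr[, , 1:8] <- 1; arr[, , 9:16] <- 2
  s <- ChannelStack(arr, 0.02, 1.45)
  halves <- splitDualView(s, "left-right", "left")
  expect_identical(dim(frames(halves$donor)), c(10L, 8L, 8L))
  expect_true(all(frames(halves$donor) == 1))
  expect_true(all(frames(halves$fret) == 2))
  expect_identical(channelLabel(halves$donor), "donor")

  arrTB <- array(0, dim = c(10, 16, 8))
  arrTB[, 1:8, ] <- 3; arrTB[, 9:16, ] <- 4
  sTB <- ChannelStack(arrTB, 0.02, 1.45)
  hTB <- splitDualView(sTB, "top-bottom", "top")
  expect_identical(dim(frames(hTB$donor)), c(10L, 8L, 8L))
  expect_true(all(frames(hTB$donor) == 3))

  sOdd <- ChannelStack(array(0, dim = c(2, 4, 7)), 0.02, 1.45)
  expect_error(splitDualView(sOdd, "left-right"), "odd")
})

test_that("split-view render halves equal the generator's channel stacks", {
  p <- heartPreset("3dpf", EDDum = 40, ESDum = 30)
  vid <- renderHeartVideo(p, durationS = 0.5, frameRateHz = 50,
                          frameDim = c(64L, 64L), seed = 3, splitView = TRUE)
  halves <- splitDualView(vid$splitView, "left-right", "left")
  expect_identical(frames(halves$donor), frames(vid$donor))
  expect_identical(frames(halves$fret), frames(vid$fret))
})

test_that("registration returns (0,0) for identical stacks and is self-inverse", {
  img <- blobImage()
  s <- stackFromFrames(img, img)
  reg <- registerChannels(s, s)
  expect_identical(shiftDy(reg$shift), 0L)
  expect_identical(shiftDx(reg$shift), 0L)
  expect_identical(frames(reg$fret), frames(s))
})

test_that("registration recovers injected integer shifts (exhaustive oracle)", {
  img <- blobImage()
  base <- stackFromFrames(img, img)
  # independent oracle: direct overlap cross-correlation over all shifts
  oracleShift <- function(a, b, maxShift) {
    best <- c(NA, NA); bestv <- -Inf
    a0 <- a - mean(a); b0 <- b - mean(b)
    for (dy in -maxShift:maxShift) for (dx in -maxShift:maxShift) {
      ra <- max(1, 1 + dy):min(nrow(a), nrow(a) + dy)
      ca <- max(1, 1 + dx):min(ncol(a), ncol(a) + dx)
      v <- sum(a0[ra - dy, ca - dx] * b0[ra, ca])
      if (v > bestv) { bestv <- v; best <- c(dy, dx) }
    }
    best
  }
  shifts <- list(c(2L, -1L), c(-3L, 4L), c(0L, 5L), c(-5L, -5L))
  for (s in shifts) {
    shifted <- array(0, dim = c(2, 32, 32))
    ri <- pmin(pmax(seq_len(32) - s[1], 1), 32)
    ci <- pmin(pmax(seq_len(32) - s[2], 1), 32)
    for (i in 1:2) shifted[i, , ] <- img[ri, ci]
    fretS <- ChannelStack(shifted, 0.02, 1.45, "fret")
    reg <- registerChannels(base, fretS, maxShift = 6)
    expect_identical(c(shiftDy(reg$shift), shiftDx(reg$shift)), s)
    # oracle agreement: average images, same answer
    avgF <- apply(frames(fretS), c(2, 3), mean)
    expect_identical(oracleShift(img, avgF, 6), s)
    # aligned stack matches the donor away from replicated edges
    inner <- 7:26
    expect_equal(frames(reg$fret)[1, inner, inner], img[inner, inner])
  }
})

test_that("registration rejects uniform frames and warns at the search boundary", {
  expect_error(registerChannels(constantStack(5), constantStack(5)),
               "registration signal")
  img <- blobImage()
  base <- stackFromFrames(img, img)
  shifted <- img[pmin(pmax(seq_len(32) - 4, 1), 32), ]
  fretS <- stackFromFrames(shifted, shifted)
  expect_warning(registerChannels(base, fretS, maxShift = 4), "boundary")
})

test_that("ChannelStack validity enforces metadata and intensity invariants", {
  expect_error(ChannelStack(array(-1, dim = c(1, 2, 2)), 0.02, 1.45),
               "non-negative")
  expect_error(ChannelStack(array(0, dim = c(1, 2, 2)), 0, 1.45), "positive")
  expect_error(ChannelStack(array(0, dim = c(1, 2, 2)), 0.02, 1.45, "odd"),
               "channelLabel")
})
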