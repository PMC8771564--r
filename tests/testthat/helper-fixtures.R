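# Fixtures generated in code: small stacks, traces and renders shared
# across test files.

# A reproducible non-degenerate "heart-like" image: two Gaussian blobs on a
# low background.
blobImage <- function(nr = 32, nc = 32) {
  r <- matrix(seq_len(nr), nr, nc)
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  img <- 50 + 800 * exp(-((r - 12)^2 + (c_ - 10)^2) / 18) +
    600 * exp(-((r - 22)^2 + (c_ - 24)^2) / 30)
  round(img)
}

stackFromFrames <- function(..., fi = 0.02, px = 1.45, label = "generic") {
  ChannelStack(list(...), frameInterval = fi, pixelSize = px,
               channelLabel = label)
}

constantStack <- function(value, n = 3, nr = 4, nc = 4, fi = 0.02, px = 1.45) {
  ChannelStack(array(value, dim = c(n, nr, nc)), fi, px)
}

# Small, fast synthetic render used by several files (compact geometry so a
# 64x64 frame fits the whole heart).
smallRender <- function(preset = "3dpf", durationS = 3, rate = 50, seed = 1,
                        ...) {
  p <- heartPreset(preset, EDDum = 40, ESDum = 40 * (1 - 0.259), ...)
  renderHeartVideo(p, durationS = durationS, frameRateHz = rate,
                   frameDim = c(64L, 64L), seed = seed)
}

# Noiseless single-cycle pulse trace: linear rise, exponential decay.
pulseTrace <- function(n = 200, dt = 0.005) {
  t <- (seq_len(n) - 1) * dt
  x <- rep(1, n)
  rise <- t >= 0.2 & t < 0.3
  x[rise] <- 1 + (t[rise] - 0.2) / 0.1
  dec <- t >= 0.3
  x[dec] <- 1 + exp(-(t[dec] - 0.3) / 0.15)
  x
}
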