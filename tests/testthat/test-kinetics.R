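# Transient detection and per-cycle kinetics.

# Noiseless periodic pulse train with linear rise and exponential decay,
# plus the exact event times.
pulseTrain <- function(hr = 4, dur = 5, dt = 0.005, riseDur = 0.05,
                       tauDecay = 0.06, base = 1, amp = 1, t0 = 0.1) {
  t <- seq(0, dur - dt, by = dt)
  x <- rep(base, length(t))
  onsets <- seq(t0, dur - 1e-9, by = 1 / hr)
  for (o in onsets) {
    rise <- t >= o & t < o + riseDur
    x[rise] <- pmax(x[rise], base + amp * (t[rise] - o) / riseDur)
    dec <- t >= o + riseDur & t < o + 1 / hr
    x[dec] <- pmax(x[dec], base + amp * exp(-(t[dec] - o - riseDur) / tauDecay))
  }
  list(t = t, x = x, onsets = onsets, peaks = onsets + riseDur)
}

test_that("detector finds every interior cycle of a clean train and nothing in noise-free flats", {
  expect_equal(nrow(detectTransients(rep(2, 500), frameInterval = 0.005)), 0)
  tr <- pulseTrain()
  cyc <- detectTransients(tr$x, frameInterval = 0.005)
  # 20 events in 5 s; first and last peaks are boundary cycles
  interior <- tr$peaks[tr$peaks > 0.3 & tr$peaks < 4.7]
  expect_equal(nrow(cyc), length(interior) - 1)
  pkT <- (cyc$peak - 1) * 0.005
  matched <- sapply(pkT, function(p) min(abs(tr$peaks - p)))
  expect_true(all(matched <= 0.005 + 1e-9))
})

test_that("detection is robust to 1% amplitude noise", {
  tr <- pulseTrain()
  clean <- detectTransients(tr$x, frameInterval = 0.005)
  set.seed(0)
  noisy <- detectTransients(tr$x + stats::rnorm(length(tr$x), 0, 0.01),
                            frameInterval = 0.005)
  expect_equal(nrow(noisy), nrow(clean))
  expect_true(all(abs(noisy$peak - clean$peak) <= 2))
})

test_that("detector agrees with an exhaustive local-maximum oracle", {
  # oracle: scan all local maxima above the same rolling mid-level
  # threshold, enforcing the refractory spacing
  oraclePeaks <- function(x, dt, minInt = 0.1, pf = 0.5, winS = 1) {
    w <- max(3L, round(winS / dt)); h <- w %/% 2
    n <- length(x)
    thr <- sapply(seq_len(n), function(i) {
      seg <- x[max(1, i - h):min(n, i + h)]
      min(seg) + pf * (max(seg) - min(seg))
    })
    cand <- which(x > thr)
    cand <- cand[cand > 1 & cand < n]
    cand <- cand[x[cand] >= x[cand - 1] & x[cand] >= x[cand + 1]]
    keep <- integer(0)
    for (i in cand)
      if (!length(keep) || (i - keep[length(keep)]) * dt >= minInt)
        keep <- c(keep, i)
    keep
  }
  for (hr in c(2, 3, 4)) {
    tr <- pulseTrain(hr = hr, dur = 6)
    cyc <- detectTransients(tr$x, frameInterval = 0.005)
    orc <- oraclePeaks(tr$x, 0.005)
    # every detected interior peak is an oracle peak
    expect_true(all(cyc$peak %in% orc))
    # counts differ only by the boundary cycles the detector excludes
    expect_lte(length(orc) - nrow(cyc), 3)
  }
})

test_that("kinetics of a linear ramp with instantaneous reset are analytic", {
  # ramp 1.0 -> 2.0 over 100 ms: 10-90% crossings at 10 and 90 ms,
  # rise time 80 ms, rise slope 0.8/0.08 = 10 /s
  dt <- 0.001
  t <- seq(0, 0.3, by = dt)
  x <- rep(1, length(t))
  ramp <- t >= 0.1 & t <= 0.2
  x[ramp] <- 1 + (t[ramp] - 0.1) / 0.1
  x[t > 0.2 & t <= 0.25] <- 1 + (0.25 - t[t > 0.2 & t <= 0.25]) / 0.05
  cyc <- data.frame(onset = which(t == 0.05), peak = which(t == 0.2),
                    end = which(t == 0.28))
  k <- cycleKinetics(x, cyc, frameInterval = dt)
  expect_equal(k$rise_time_s, 0.08, tolerance = 1e-9)
  expect_equal(k$rise_slope, 10, tolerance = 1e-9)
  expect_equal(k$diastolic_ratio, 1)
  expect_equal(k$systolic_ratio, 2)
  expect_equal(k$amplitude, 1)
})

test_that("exponential decay yields decay time tau*ln(9)", {
  # decay from 2 to 1 with tau = 0.5 s; 90->10% crossing interval is
  # tau*(ln(10) - ln(10/9)) = tau*ln(9)
  dt <- 0.002
  t <- seq(0, 6, by = dt)
  x <- 1 + exp(-pmax(t - 0.5, 0) / 0.5)
  x[t < 0.5] <- 1 + t[t < 0.5] / 0.5 * 1   # fast rise to the peak
  cyc <- data.frame(onset = 1L, peak = which.max(x), end = length(x))
  k <- cycleKinetics(x, cyc, frameInterval = dt)
  expect_lt(abs(k$decay_time_s - 0.5 * log(9)), 2 * dt)
  # dense numeric root-finding oracle
  f <- function(lev) stats::uniroot(function(u) 1 + exp(-u / 0.5) - lev,
                                    c(0, 5), tol = 1e-10)$root
  expect_lt(abs(k$decay_time_s - (f(1.1) - f(1.9))), 2 * dt)
})

test_that("a symmetric triangular pulse has equal rise and decay kinetics", {
  dt <- 0.001
  t <- seq(0, 1, by = dt)
  x <- 1 + pmax(0, 0.3 - abs(t - 0.5)) / 0.3
  cyc <- data.frame(onset = 1L, peak = which.max(x), end = length(t))
  k <- cycleKinetics(x, cyc, frameInterval = dt)
  expect_equal(k$rise_time_s, k$decay_time_s, tolerance = 1e-9)
  expect_equal(k$rise_slope, k$decay_slope, tolerance = 1e-9)
})

test_that("heart rate follows the median peak interval", {
  cyc <- data.frame(onset = c(1, 26, 51), peak = c(13, 38, 63),
                    end = c(26, 51, 76))
  expect_equal(heartRate(cyc, frameInterval = 0.01), 240)  # peaks every 0.25 s
  expect_equal(heartRate(cyc, frameInterval = 0.04), 60)   # peaks every 1.0 s
  expect_warning(hr1 <- heartRate(cyc[1, ], frameInterval = 0.01), "fewer than 2")
  expect_true(is.na(hr1))
})

test_that("time-shift equivariance and amplitude-scale behavior hold", {
  tr <- pulseTrain(dur = 4)
  dt <- 0.005
  cyc <- detectTransients(tr$x, frameInterval = dt)
  k <- cycleKinetics(tr$x, cyc, frameInterval = dt)
  # shift by 40 frames
  shift <- 40L
  xs <- c(rep(tr$x[1], shift), tr$x)
  cycS <- detectTransients(xs, frameInterval = dt)
  kS <- cycleKinetics(xs, cycS, frameInterval = dt)
  m <- min(nrow(k), nrow(kS))
  # the shifted trace may admit one extra leading cycle; align on the tail
  kT <- k[(nrow(k) - m + 1):nrow(k), ]; kT$idx <- NULL
  kST <- kS[(nrow(kS) - m + 1):nrow(kS), ]
  expect_equal(kST$t_peak, kT$t_peak + shift * dt, tolerance = 1e-9)
  expect_equal(kST$rise_time_s, kT$rise_time_s, tolerance = 1e-9)
  expect_equal(kST$amplitude, kT$amplitude, tolerance = 1e-9)
  # scaling by c > 0 scales levels and slopes, leaves times and HR alone
  cfac <- 3.7
  cyc2 <- detectTransients(tr$x * cfac, frameInterval = dt)
  k2 <- cycleKinetics(tr$x * cfac, cyc2, frameInterval = dt)
  expect_equal(k2$amplitude, k$amplitude * cfac, tolerance = 1e-9)
  expect_equal(k2$rise_slope, k$rise_slope * cfac, tolerance = 1e-9)
  expect_equal(k2$rise_time_s, k$rise_time_s, tolerance = 1e-9)
  expect_equal(heartRate(cyc2, dt), heartRate(cyc, dt), tolerance = 1e-12)
})

test_that("Savitzky-Golay smoothing reproduces polynomials and reduces noise", {
  t <- seq(0, 1, length.out = 101)
  cubic <- 1 + 2 * t - 3 * t^2 + 0.5 * t^3
  expect_equal(savgolSmooth(cubic, 7, 3), cubic, tolerance = 1e-10)
  expect_equal(savgolSmooth(rep(2.5, 50), 7, 3), rep(2.5, 50))
  expect_error(savgolSmooth(cubic, 6, 3), "odd")
  expect_error(savgolSmooth(cubic[1:5], 7, 3), "longer than")
  tr <- pulseTrain()
  set.seed(1)
  noisy <- tr$x + stats::rnorm(length(tr$x), 0, 0.05)
  sm <- savgolSmooth(noisy, 7, 3)
  expect_lt(sqrt(mean((sm - tr$x)^2)), sqrt(mean((noisy - tr$x)^2)))
})

test_that("normalization to the lowest diastolic ratio is idempotent", {
  x <- c(2.5, 1.25, 3, 1.9)
  n1 <- normalizeToDiastole(x)
  expect_equal(min(n1), 1)
  expect_equal(normalizeToDiastole(n1), n1)
  expect_equal(normalizeToDiastole(rep(4, 5)), rep(1, 5))
  expect_error(normalizeToDiastole(c(-1, 2)), "positive")
})

test_that("recording summaries average per-cycle parameters", {
  tr <- pulseTrain(dur = 5)
  cyc <- detectTransients(tr$x, frameInterval = 0.005)
  k <- cycleKinetics(tr$x, cyc, frameInterval = 0.005)
  s <- summarizeRecording(k, cyc, durationS = 5)
  expect_equal(s$n_cycles, nrow(k))
  expect_equal(s$mean_amplitude, mean(k$amplitude))
  expect_equal(s$heart_rate_bpm, 240)
  one <- summarizeRecording(k[1, ], cyc[1, ], durationS = 5)
  expect_equal(one$mean_rise_time_s, k$rise_time_s[1])
  two <- data.frame(k[1:2, ])
  two$amplitude <- c(0.2, 0.4)
  expect_equal(summarizeRecording(two, cyc[1:2, ])$mean_amplitude, 0.3)
})
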