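analyticBandpassGain <- function(f, f1 = 250, f2 = 500, N = 2) {
  1 / sqrt(1 + ((f^2 - f1 * f2) / (f * (f2 - f1)))^(2 * N))
}

steadyAmplitude <- function(y, fs) {
  ss <- y[round(length(y) / 2):length(y)]
  (max(ss) - min(ss)) / 2
}

test_that("band-pass blocks DC and matches the analytic Butterworth response", {
  fs <- 35000
  dc <- bandpassFilter(rep(2, 2 * fs), fs)
  expect_lt(max(abs(dc[(fs):(2 * fs)])), 1e-6 * 2)
  t <- seq(0, 1, by = 1 / fs)
  for (f in c(300, 375, 450)) {
    y <- bandpassFilter(sin(2 * pi * f * t), fs)
    expect_equal(steadyAmplitude(y, fs), analyticBandpassGain(f),
                 tolerance = 5e-3)
  }
  # -3 dB at both band edges by the Butterworth definition
  for (f in c(250, 500)) {
    y <- bandpassFilter(sin(2 * pi * f * t), fs)
    expect_equal(steadyAmplitude(y, fs), 1 / sqrt(2), tolerance = 0.02)
  }
})

test_that("band-pass rejects a band edge at or above Nyquist", {
  expect_error(bandpassFilter(rnorm(100), fs = 1000), "Nyquist")
  expect_error(bandpassFilter(rnorm(100), fs = 2000, low = 500, high = 250),
               "low < high")
})

test_that("filtering is linear and time invariant", {
  fs <- 2000
  set.seed(3)
  x <- rnorm(fs)
  expect_equal(bandpassFilter(3.7 * x, fs), 3.7 * bandpassFilter(x, fs))
  # shift by k samples: outputs agree away from the edges
  k <- 100
  y <- bandpassFilter(x, fs)
  yShift <- bandpassFilter(c(rep(0, k), x), fs)
  expect_equal(yShift[(k + 500):(k + 1500)], y[500:1500], tolerance = 1e-10)
})

test_that("baseline equals the amplitude for a pure sinusoid", {
  fs <- 2000
  x <- 4.2 * sin(2 * pi * 300 * seq(0, 1.2, by = 1 / fs))
  bl <- estimateBaseline(x, fs)
  expect_equal(bl$amplitude, 4.2, tolerance = 1e-3)
  expect_length(bl$subMaxima, 20)
})

test_that("baseline is the mean of the lowest quartile of sub-window maxima", {
  fs <- 2000
  nSub <- 100                              # 50 ms at 2 kHz
  # construct a signal whose 20 sub-window maxima are exactly 1..20
  x <- numeric(20 * nSub)
  for (b in 1:20) x[(b - 1) * nSub + 50] <- b
  expect_equal(estimateBaseline(x, fs)$amplitude, mean(1:5))
  expect_error(estimateBaseline(x[1:100], fs), "shorter")
})

test_that("baseline matches the brute-force recomputation on noise", {
  fs <- 2000
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(2.5 * fs)
    bl <- estimateBaseline(x, fs)
    m <- vapply(1:20, function(b) max(abs(x[((b - 1) * 100 + 1):(b * 100)])), 0)
    expect_equal(bl$amplitude, mean(sort(m)[1:5]))
    expect_lte(bl$amplitude, max(m))
    expect_gte(bl$amplitude, min(m))
    # scale equivariance
    expect_equal(estimateBaseline(3.3 * x, fs)$amplitude, 3.3 * bl$amplitude)
  }
})

test_that("delta threshold is half the baseline and flags flat channels", {
  expect_equal(deltaThreshold(2), 1)
  bl <- estimateBaseline(sin(2 * pi * 300 * seq(0, 1, by = 5e-4)), 2000)
  expect_equal(deltaThreshold(bl), 0.5 * bl$amplitude)
  expect_equal(deltaThreshold(7 * 2) / deltaThreshold(2), 7)  # homogeneity
  err <- tryCatch(deltaThreshold(0), condition = identity)
  expect_s3_class(err, "snnHFO_degenerate_channel")
})
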