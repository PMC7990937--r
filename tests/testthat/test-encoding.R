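test_that("upsampling interpolates through the original samples", {
  set.seed(4)
  x <- rnorm(100)
  up <- upsampleSignal(x, 2000, 10000)     # integer ratio 5
  expect_equal(up[seq(1, length(up), by = 5)], x)
  # affine signals are reproduced exactly
  ramp <- 0.5 + 2 * (0:99)
  upr <- upsampleSignal(ramp, 2000, 35000)
  tOut <- seq(0, 99 / 2000, by = 1 / 35000)
  expect_equal(upr, 0.5 + 2 * tOut * 2000, tolerance = 1e-12)
  expect_error(upsampleSignal(x, 2000, 2000), "exceed")
})

test_that("upsampling a sinusoid respects the linear-interpolation error bound", {
  fsIn <- 2000; fsOut <- 35000; f <- 300; A <- 1
  tIn <- seq(0, 0.5, by = 1 / fsIn)
  up <- upsampleSignal(A * sin(2 * pi * f * tIn), fsIn, fsOut)
  tOut <- seq(0, max(tIn), by = 1 / fsOut)
  bound <- A * pi^2 * f^2 / (2 * fsIn^2)
  expect_lt(max(abs(up - A * sin(2 * pi * f * tOut))), bound * 1.01)
})

test_that("constant signals produce no spikes", {
  st <- admEncode(rep(3.2, 1000), 35000, threshold = 0.5)
  expect_length(upTimes(st), 0)
  expect_length(dnTimes(st), 0)
  expect_error(admEncode(rnorm(10), 35000, threshold = -1), "positive")
})

test_that("ramp encoding matches the closed-form inter-spike interval", {
  # grid-aligned, integer-valued ramp: fs 10 kHz, slope fs uV/s (one unit
  # per sample), delta = 10 units (= 10 samples to cross), refractory = 3
  # samples; the tracking rules then give ISI = r + delta/s exactly
  fs <- 10000; s <- fs; delta <- 10; r <- 3 / fs
  Tdur <- 2
  x <- as.numeric(0:(Tdur * fs))
  st <- admEncode(x, fs, delta, r)
  expect_length(dnTimes(st), 0)
  isi <- diff(upTimes(st))
  expect_equal(max(abs(isi - (r + delta / s))), 0)
  expect_length(upTimes(st), floor((Tdur - delta / s) / (r + delta / s)) + 1)
  # falling ramp swaps the streams exactly
  stNeg <- admEncode(-x, fs, delta, r)
  expect_identical(dnTimes(stNeg), upTimes(st))
  expect_identical(upTimes(stNeg), dnTimes(st))
})

test_that("encoding is scale invariant and respects the shared refractory", {
  fs <- 35000
  set.seed(9)
  x <- cumsum(rnorm(2 * fs))               # smooth-ish random walk
  st <- admEncode(x, fs, threshold = 2)
  stScaled <- admEncode(6.25 * x, fs, threshold = 6.25 * 2)
  expect_identical(upTimes(st), upTimes(stScaled))
  expect_identical(dnTimes(st), dnTimes(stScaled))
  merged <- sort(c(upTimes(st), dnTimes(st)))
  expect_true(length(merged) > 10)
  expect_gte(min(diff(merged)), 3e-4 - 1e-12)
  expect_true(all(merged >= 0 & merged < duration(st)))
})

test_that("spike count is non-increasing in the threshold for monotone input", {
  fs <- 10000
  x <- (seq_len(fs))^1.3 / fs              # monotone, convex
  counts <- vapply(c(0.5, 1, 2, 4, 8),
                   function(d) length(upTimes(admEncode(x, fs, d))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("spike trains survive the TSV round trip", {
  st <- hfoSpikeTrain()
  p <- file.path(tempdir(), "train.tsv")
  writeSpikeTrain(st, p)
  back <- readSpikeTrain(p, duration = duration(st))
  expect_equal(upTimes(back), upTimes(st))
  expect_equal(dnTimes(back), dnTimes(st))
})
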