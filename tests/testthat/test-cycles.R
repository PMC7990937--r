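test_that("cycle extraction follows the burst definition", {
  # UP,UP,DN,DN,UP,DN -> two cycles
  st <- SpikeTrain(up = c(1, 2, 5) * 1e-3, dn = c(3, 4, 6) * 1e-3,
                   duration = 0.01, refractory = 0)
  cyc <- extractCycles(st)
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$n_up, c(2, 1))
  expect_equal(cyc$duration_s, c(3e-3, 1e-3))
  # UP-only trains close no cycle
  expect_equal(nrow(extractCycles(SpikeTrain(up = (1:5) * 1e-3, dn = numeric(0),
                                             duration = 0.01, refractory = 0))), 0)
  # strict alternation: one cycle per UP-DN pair
  alt <- SpikeTrain(up = (0:5) * 2e-3, dn = (0:5) * 2e-3 + 1e-3,
                    duration = 0.02, refractory = 0)
  expect_equal(nrow(extractCycles(alt)), 6)
  # leading DN burst is ignored
  lead <- SpikeTrain(up = c(3, 5) * 1e-3, dn = c(1, 4, 6) * 1e-3,
                     duration = 0.01, refractory = 0)
  expect_equal(nrow(extractCycles(lead)), 2)
})

test_that("cycle extraction equals the run-length oracle on random trains", {
  for (seed in 1:60) {
    st <- randomTrain(sample(2:60, 1), seed = seed)
    expect_equal(nrow(extractCycles(st)),
                 oracleCycles(upTimes(st), dnTimes(st)))
  }
})

test_that("trailing unmatched UP spikes do not change the cycle count", {
  st <- hfoSpikeTrain()
  n0 <- nrow(extractCycles(st))
  more <- SpikeTrain(up = c(upTimes(st), max(dnTimes(st)) + c(1, 2) * 1e-3),
                     dn = dnTimes(st), duration = duration(st))
  expect_equal(nrow(extractCycles(more)), n0)
})

test_that("the calibration fixture trains carry the published snippet statistics", {
  h <- snippetStats(list(hfoSpikeTrain()))
  expect_equal(h$median_train_duration_ms, 24, tolerance = 0.01)
  expect_equal(h$median_n_cycles, 6)
  expect_equal(h$median_cycle_duration_ms, 2.6, tolerance = 0.01)
  tr <- snippetStats(list(transientSpikeTrain()))
  expect_equal(tr$median_train_duration_ms, 9, tolerance = 0.01)
  expect_equal(tr$median_n_cycles, 2)
  expect_equal(tr$median_cycle_duration_ms, 3.2, tolerance = 0.01)
  expect_gt(tr$median_isi_ms, h$median_isi_ms)
  expect_error(snippetStats(list()), "at least one")
})

test_that("encoded synthetic snippets separate oscillations from transients", {
  set.seed(11)
  enc <- function(sig) {
    filt <- bandpassFilter(sig, 2000)
    admEncode(upsampleSignal(filt, 2000, 35000), 35000, 0.5)
  }
  silent <- Recording(matrix(0, 1, 2000), fs = 2000)
  hts <- lapply(1:12, function(i) {
    d <- max(10, rnorm(1, 24, 4)); f <- runif(1, 250, 500)
    enc(samples(injectHfo(silent, 1, 0.3, d, f, 3,
                          baselineAmp = 1)$recording)[1, ])
  })
  tts <- lapply(1:12, function(i) {
    w <- runif(1, 2, 3)
    enc(samples(injectTransient(silent, 1, 0.3, w, 6,
                                baselineAmp = 1)$recording)[1, ])
  })
  h <- snippetStats(hts); t <- snippetStats(tts)
  expect_gt(h$median_n_cycles, t$median_n_cycles)
  expect_gt(h$median_train_duration_ms, t$median_train_duration_ms)
  expect_gte(h$median_n_cycles, 4)
  expect_lte(t$median_n_cycles, 3)
  expect_lte(t$median_train_duration_ms, 12)
})
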