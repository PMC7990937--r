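test_that("background generation is deterministic with the documented spectrum", {
  spec0 <- syntheticSpec(duration = 4, nChannels = 2, backgroundRms = 0)
  expect_true(all(samples(generateBackground(spec0)) == 0))
  spec <- syntheticSpec(duration = 20, nChannels = 1, seed = 5)
  a <- generateBackground(spec)
  b <- generateBackground(spec)
  expect_identical(samples(a), samples(b))
  expect_equal(sd(samples(a)[1, ]), spec$backgroundRms, tolerance = 1e-6)
  sp <- spec.pgram(ts(samples(a)[1, ], frequency = spec$fs), plot = FALSE,
                   taper = 0.1)
  keep <- sp$freq > 1 & sp$freq < 900
  slope <- unname(coef(lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2])
  expect_equal(slope, -1, tolerance = 0.2)
})

test_that("HFO injection is local, validated and baseline-scaled", {
  spec <- syntheticSpec(duration = 4, nChannels = 1, seed = 2)
  rec <- generateBackground(spec)
  expect_error(injectHfo(rec, 1, 1, 24, 600, 3), "fast-ripple")
  expect_error(injectHfo(rec, 1, 3.99, 24, 375, 3), "fit inside")
  unchanged <- injectHfo(rec, 1, 1, 24, 375, 0)
  expect_identical(samples(unchanged$recording), samples(rec))
  res <- injectHfo(rec, 1, 1, 24, 375, 3)
  x0 <- samples(rec)[1, ]; x1 <- samples(res$recording)[1, ]
  changed <- which(x0 != x1)
  fs <- samplingRate(rec)
  expect_gte(min(changed), 1 * fs)
  expect_lte(max(changed), (1 + 0.024) * fs + 1)
  expect_equal(res$truth$kind, "hfo")
})

test_that("transient injection is local and reproducible", {
  spec <- syntheticSpec(duration = 4, nChannels = 1, seed = 2)
  rec <- generateBackground(spec)
  expect_identical(samples(injectTransient(rec, 1, 1, 2, 0)$recording),
                   samples(rec))
  r1 <- injectTransient(rec, 1, 1, 2, 6)
  r2 <- injectTransient(rec, 1, 1, 2, 6)
  expect_identical(samples(r1$recording), samples(r2$recording))
  changed <- which(samples(rec)[1, ] != samples(r1$recording)[1, ])
  expect_lte(diff(range(changed)), 0.002 * samplingRate(rec) + 1)
  expect_equal(r1$truth$kind, "transient")
})

test_that("the benchmark fixture is reproducible with a consistent manifest", {
  spec <- syntheticSpec(duration = 30, nChannels = 2, nHfo = 6, nTransient = 6,
                        seed = 3)
  bm1 <- makeBenchmark(spec)
  bm2 <- makeBenchmark(spec)
  expect_identical(bm1$truth, bm2$truth)
  expect_identical(samples(bm1$recording), samples(bm2$recording))
  expect_equal(sum(bm1$truth$kind == "hfo"), 6)
  expect_equal(sum(bm1$truth$kind == "transient"), 6)
  # manifest arithmetic: per-channel true rate = injected / duration
  for (ch in channelLabels(bm1$recording)) {
    nH <- sum(bm1$truth$kind == "hfo" & bm1$truth$channel == ch)
    expect_equal(nH / (spec$duration / 60),
                 nH / (duration(bm1$recording) / 60))
  }
  # events on one channel never overlap
  for (ch in unique(bm1$truth$channel)) {
    tr <- bm1$truth[bm1$truth$channel == ch, ]
    if (nrow(tr) > 1)
      expect_true(all(tr$start_s[-1] >= tr$end_s[-nrow(tr)]))
  }
  # manifest TSV round trip
  p <- file.path(tempdir(), "truth.tsv")
  writeManifest(bm1$truth, p)
  expect_equal(readManifest(p), bm1$truth)
})
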