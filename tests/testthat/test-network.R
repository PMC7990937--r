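test_that("the network topology matches the published wiring", {
  cfg <- defaultNetworkConfig()
  net <- buildNetwork(cfg)
  n <- cfg@nSecondLayer
  expect_equal(nrow(net@connections), 3 * n + 4)
  pol <- function(from, to) unique(net@connections$polarity[
    net@connections$from == from & grepl(to, net@connections$to)])
  expect_equal(pol("UP", "^SL"), "exc")
  expect_equal(pol("DN", "^SL"), "inh")
  expect_equal(pol("UP", "^DI$"), "exc")
  expect_equal(pol("DN", "^DI$"), "exc")
  expect_equal(pol("DI", "^GI$"), "inh")
  expect_equal(pol("Poisson", "^GI$"), "exc")
  expect_equal(pol("GI", "^SL"), "inh")
  # published strengths for the fixed synapses
  expect_equal(unique(net@connections$strength_fA[net@connections$to == "DI"]), 21)
  expect_equal(net@connections$strength_fA[net@connections$from == "DI"], 17.5)
  expect_equal(unique(net@connections$strength_fA[net@connections$from == "GI"]), 24.5)
})

test_that("a minimal single-neuron network simulates without error", {
  cfg <- defaultNetworkConfig(nSecondLayer = 1, nW = 1, nTau = 1)
  act <- simulateNetwork(buildNetwork(cfg), hfoSpikeTrain(), 0.06, seed = 1)
  expect_length(act$slSpikes, 1)
})

test_that("parameters outside the published ranges are rejected unless overridden", {
  cfg <- defaultNetworkConfig()
  cfg@wUp[1] <- 20
  expect_error(buildNetwork(cfg), "range")
  cfg@validateRanges <- FALSE
  expect_s4_class(buildNetwork(cfg), "Network")
  cfg2 <- defaultNetworkConfig()
  cfg2@tauDnMs <- cfg2@tauUpMs - 2        # offset outside [0.1, 1] ms
  expect_error(buildNetwork(cfg2), "range")
})

test_that("the Poisson generator follows the Poisson law and the seed", {
  expect_length(poissonTrain(0, 10, seed = 1), 0)
  expect_identical(poissonTrain(500, 2, seed = 42), poissonTrain(500, 2, seed = 42))
  rate <- 200; dur <- 2
  counts <- vapply(1:200, function(s) length(poissonTrain(rate, dur, s)), 0L)
  lambda <- rate * dur
  expect_equal(mean(counts), lambda, tolerance = 0.05)
  # index of dispersion ~ chi-squared with n-1 df
  disp <- (length(counts) - 1) * var(counts) / lambda
  expect_gt(disp, qchisq(0.005, length(counts) - 1))
  expect_lt(disp, qchisq(0.995, length(counts) - 1))
})

test_that("simulation is deterministic given config, input and seed", {
  net <- buildNetwork(defaultNetworkConfig())
  st <- hfoSpikeTrain()
  a <- simulateNetwork(net, st, 0.06, seed = 5)
  b <- simulateNetwork(net, st, 0.06, seed = 5)
  expect_identical(a$slSpikes, b$slSpikes)
  expect_identical(a$giSpikes, b$giSpikes)
  expect_identical(a$diSpikes, b$diSpikes)
})

test_that("a coarse integration step triggers the aliasing warning", {
  cfg <- defaultNetworkConfig(dt = 1e-3)
  expect_warning(simulateNetwork(buildNetwork(cfg), hfoSpikeTrain(), 0.06),
                 "aliasing")
})

test_that("dis-inhibition responds only after at least one full UP-DN cycle", {
  net <- buildNetwork(defaultNetworkConfig())
  st <- hfoSpikeTrain(start = 0.01)
  act <- simulateNetwork(net, st, 0.06, seed = 3)
  expect_gt(length(act$diSpikes), 0)
  firstCycleEnd <- 0.01 + 2.6e-3
  expect_gte(act$diSpikes[1], firstCycleEnd)
})

test_that("more cycles never recruit fewer second-layer neurons", {
  net <- buildNetwork(defaultNetworkConfig())
  responding <- vapply(c(3, 6, 12), function(nc) {
    st <- hfoSpikeTrain(nCycles = nc, duration = 0.09)
    act <- simulateNetwork(net, st, 0.09, seed = 4)
    sum(lengths(act$slSpikes) > 0)
  }, 0L)
  expect_true(all(diff(responding) >= 0))
})

test_that("GI calibration reaches the target rate", {
  cfg <- calibrateGI(defaultNetworkConfig(), targetHz = 135, duration = 3,
                     seed = 2)
  expect_equal(attr(cfg, "achievedRateHz"), 135, tolerance = 0.05)
})
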