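test_that("residual classification uses the inclusive 1/min threshold", {
  expect_equal(classifyResidual(14), "residual")
  expect_equal(classifyResidual(0.99), "no_residual")
  expect_equal(classifyResidual(1.0), "residual")
  expect_error(classifyResidual(-1), "non-negative")
})

test_that("the shipped patient table reproduces the published confusion counts", {
  tab <- readPatientTable(system.file("extdata", "patient_outcomes.tsv",
                                      package = "snnHFO"))
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$post_censored[tab$patient_id != "6"]))
  pred <- predictOutcomes(tab)
  expect_equal(unname(pred$counts), c(1L, 7L, 0L, 0L))
  m <- confusionMetrics(1, 7, 0, 0)
  expect_equal(m$acc, 1)
  expect_equal(m$sens, 1)
  expect_equal(m$spec, 1)
  expect_equal(m$ppv, 1)
  expect_equal(m$npv, 1)
})

test_that("outcome labelling equals the brute-force cross-tabulation", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:30, 1)
    rec <- data.frame(patient_id = as.character(seq_len(n)),
                      post_max_rate = round(rexp(n, 0.5), 2),
                      ilae = sample(1:6, n, replace = TRUE))
    pred <- predictOutcomes(rec)
    resid <- rec$post_max_rate >= 1
    freedom <- rec$ilae == 1
    expect_equal(unname(pred$counts),
                 c(sum(resid & !freedom), sum(!resid & freedom),
                   sum(resid & freedom), sum(!resid & !freedom)))
    # ordering invariance
    shuf <- predictOutcomes(rec[sample(n), ])
    expect_equal(shuf$counts, pred$counts)
  }
})

test_that("prediction metrics match their defining formulas", {
  expect_equal(confusionMetrics(0, 0, 1, 1)$acc, 0)
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(0:8, 4, replace = TRUE)
    if (sum(k) == 0) k[1] <- 1
    m <- suppressWarnings(confusionMetrics(k[1], k[2], k[3], k[4]))
    reference <- function(num, den) if (den == 0) NA_real_ else num / den
    expect_equal(m$ppv, reference(k[1], k[1] + k[3]))
    expect_equal(m$npv, reference(k[2], k[2] + k[4]))
    expect_equal(m$sens, reference(k[1], k[1] + k[4]))
    expect_equal(m$spec, reference(k[2], k[2] + k[3]))
    expect_equal(m$acc, (k[1] + k[2]) / sum(k))
  }
  w <- capture_warnings(confusionMetrics(0, 5, 0, 0))
  expect_match(w, "PPV", all = FALSE)
  expect_match(w, "sensitivity", all = FALSE)
  expect_error(confusionMetrics(0, 0, 0, 0), "zero")
})

test_that("the exact binomial interval reproduces the printed 8/8 bounds", {
  expect_equal(round(binomialCI(8, 8), 2), c(0.63, 1.00))
  expect_equal(binomialCI(0, 5)[1], 0)
  expect_equal(binomialCI(5, 5)[2], 1)
  expect_error(binomialCI(3, 0), "n must")
  expect_error(binomialCI(9, 8), "k must")
})

test_that("the interval matches direct inversion of the binomial tails", {
  invertLow <- function(k, n, a = 0.025) {
    uniroot(function(p) 1 - pbinom(k - 1, n, p) - a, c(1e-12, 1 - 1e-12),
            tol = 1e-12)$root
  }
  invertHigh <- function(k, n, a = 0.025) {
    uniroot(function(p) pbinom(k, n, p) - a, c(1e-12, 1 - 1e-12),
            tol = 1e-12)$root
  }
  for (case in list(c(7, 8), c(3, 10), c(1, 4), c(12, 20))) {
    ci <- binomialCI(case[1], case[2])
    expect_equal(ci[1], invertLow(case[1], case[2]), tolerance = 1e-8)
    expect_equal(ci[2], invertHigh(case[1], case[2]), tolerance = 1e-8)
    # agrees with the stock exact test as an independent cross-check
    bt <- binom.test(case[1], case[2])$conf.int
    expect_equal(ci, as.numeric(bt), tolerance = 1e-8)
  }
})

test_that("the interval contains k/n and widens as n shrinks", {
  for (n in c(40, 20, 10, 5)) {
    k <- round(0.8 * n)
    ci <- binomialCI(k, n)
    expect_gte(k / n, ci[1])
    expect_lte(k / n, ci[2])
  }
  widths <- vapply(c(40, 20, 10, 5),
                   function(n) diff(binomialCI(round(0.8 * n), n)), 0)
  expect_true(all(diff(widths) > 0))
})

test_that("threshold sweeps change true positives monotonically", {
  tab <- readPatientTable(system.file("extdata", "patient_outcomes.tsv",
                                      package = "snnHFO"))
  tps <- vapply(c(0.25, 1, 5, 20, 50),
                function(th) predictOutcomes(tab, threshold = th)$counts[["tp"]],
                0L)
  expect_true(all(diff(tps) <= 0))
})
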