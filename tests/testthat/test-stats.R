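# Inferential layer: BCa bootstrap, resampling tests, circular CIs, phase
# coherence, FDR, cluster permutation, paired effect size.

test_that("the BCa bootstrap engine matches its reference implementation", {
  skip_if_not_installed("boot")
  set.seed(5)
  x <- rnorm(16, 1, 2)
  bt <- bootstrapEngine(x, mean, nResamples = 20000L, seed = 9)
  expect_equal(bt$estimate, mean(x))
  # independent cross-check: boot::boot.ci BCa interval
  b <- boot::boot(x, function(d, i) mean(d[i]), R = 20000)
  ref <- boot::boot.ci(b, type = "bca")$bca[4:5]
  expect_equal(unname(bt$ci), ref, tolerance = 0.02)
  # degenerate single-participant case
  expect_warning(d1 <- bootstrapEngine(3, mean, nResamples = 100L), "degenerate")
  expect_true(d1$degenerate)
  expect_equal(diff(d1$ci), 0)
})

test_that("BCa intervals achieve their nominal coverage", {
  # coverage oracle: 95% intervals for a normal mean, n = 16, 1000 replicates
  mu <- 2
  cover <- 0
  for (r in seq_len(1000)) {
    x <- withr::with_seed(r + 500, rnorm(16, mu, 1))
    bt <- bootstrapEngine(x, mean, nResamples = 1000L, seed = r)
    cover <- cover + (bt$ci[1] <= mu && mu <= bt$ci[2])
  }
  # BCa at n = 16 undercovers slightly (the method's known small-sample
  # behaviour, matched exactly by the reference implementation above); the
  # band detects implementation faults, not the asymptotic ideal
  expect_gt(cover / 1000, 0.90)
  expect_lt(cover / 1000, 0.98)
})

test_that("the spectral peak test follows the (N + 1)/(B + 1) convention", {
  # all-positive statistics: every resample supports the alternative
  res <- spectralPeakTest(rep(1, 16) + (1:16) / 100, nResamples = 10000L,
                          seed = 1)
  expect_equal(pValue(res), 1 / 10001)
  expect_equal(round(pValue(res), 4), 1e-04)   # the printed floor p = 0.0001
  # all-negative statistics: ceiling
  resNeg <- spectralPeakTest(-(1:16) / 10, nResamples = 1000L, seed = 1)
  expect_equal(pValue(resNeg), 1)
  expect_identical(res@sidedness, "one-sided")
  expect_equal(res@nResamples, 10000L)
})

test_that("the paired power-difference test is two-sided and symmetric", {
  set.seed(8)
  a <- rnorm(16, 1)
  res <- powerDifferenceTest(a, a, nResamples = 1000L, seed = 2)
  expect_equal(pValue(res), 1)                    # identical conditions
  big <- powerDifferenceTest(a + 10, a, nResamples = 1000L, seed = 2)
  expect_equal(pValue(big), 1 / 1001)
  swapped <- powerDifferenceTest(a, a + 10, nResamples = 1000L, seed = 2)
  expect_equal(pValue(big), pValue(swapped))      # two-sided symmetry
  expect_error(powerDifferenceTest(a, a[-1]), "equal length")
})

test_that("the cross-experiment test separates shifted groups only", {
  set.seed(9)
  a <- rnorm(16)
  res <- crossExperimentTest(a, a + rnorm(16, 0, 1e-6),
                             nResamples = 1000L, seed = 3)
  expect_gt(pValue(res), 0.5)
  far <- crossExperimentTest(a, a + 50, nResamples = 1000L, seed = 3)
  expect_lte(pValue(far), 3 / 1001)
})

test_that("resampling tests hold their nominal type-I error", {
  # null calibration at alpha = 0.05; 600 replicates keep the Monte-Carlo
  # error on the rejection rate below one percentage point
  nRep <- 600
  rejPower <- rejCross <- 0
  for (r in seq_len(nRep)) {
    vals <- withr::with_seed(2000 + r, matrix(rnorm(32), 16))
    p1 <- pValue(powerDifferenceTest(vals[, 1], vals[, 2],
                                     nResamples = 1000L, seed = r))
    p2 <- pValue(crossExperimentTest(vals[, 1], vals[, 2],
                                     nResamples = 1000L, seed = r))
    rejPower <- rejPower + (p1 < 0.05)
    rejCross <- rejCross + (p2 < 0.05)
  }
  expect_gte(rejPower / nRep, 0.02); expect_lte(rejPower / nRep, 0.09)
  expect_gte(rejCross / nRep, 0.02); expect_lte(rejCross / nRep, 0.09)
})

test_that("phase CIs are shortest covering arcs", {
  # all resamples equal: zero width
  ci0 <- phaseDifferenceCI(rep(33, 500))
  expect_equal(attr(ci0, "width"), 0)
  expect_equal(ci0[1], 33)
  # V = 100 with uniform resamples: (essentially) the full circle
  set.seed(3)
  ciFull <- phaseDifferenceCI(runif(2000, -180, 180), coverage = 100)
  expect_gt(attr(ciFull, "width"), 350)
  # shortest-arc property against a brute-force oracle on a small sample
  x <- c(-170, -160, 10, 20, 30, 40, 170)
  ci <- phaseDifferenceCI(x, coverage = 60)       # 5 of 7 angles
  bruteWidth <- min(vapply(seq_along(x), function(k) {
    xs <- sort(x %% 360)
    m <- ceiling(0.6 * length(x))
    ext <- c(xs, xs + 360)
    min(ext[seq_along(xs) + m - 1] - xs)
  }, numeric(1)))
  expect_equal(attr(ci, "width"), bruteWidth)
  expect_error(phaseDifferenceCI(x, coverage = 0), "coverage")
  # an interval straddling the +-180 seam still covers its angles
  seam <- c(175, 178, -179, -176)
  ciS <- phaseDifferenceCI(seam, coverage = 100)
  expect_lt(attr(ciS, "width"), 15)
})

test_that("bootstrap circular-mean CIs cover the true phase", {
  # wrapped-Gaussian phases, n = 16; 95% arcs from 500 resampled circular
  # means should cover the true mean direction in roughly 95% of replicates
  nRep <- 300
  cover <- 0
  for (r in seq_len(nRep)) {
    phases <- withr::with_seed(900 + r, wrapDegrees(rnorm(16, 40, 30)))
    res <- bootstrapCircularMean(phases, nResamples = 500L, seed = r)
    ci <- phaseDifferenceCI(res, coverage = 95)
    inArc <- (40 - ci[1]) %% 360 <= attr(ci, "width")
    cover <- cover + inArc
  }
  expect_gt(cover / nRep, 0.88)
  expect_lt(cover / nRep, 0.995)
})

test_that("phase coherence is tested against a uniform null", {
  res <- phaseCoherenceTest(rep(25, 16), nNull = 10000L, seed = 4)
  expect_equal(statistic(res), 1)
  expect_equal(pValue(res), 1 / 10001)
  anti <- phaseCoherenceTest(c(0, 180), nNull = 1000L, seed = 4)
  expect_lt(statistic(anti), 1e-12)
  expect_gt(pValue(anti), 0.9)
  # null calibration: uniform phases give approximately uniform p-values
  ps <- vapply(seq_len(200), function(r)
    pValue(phaseCoherenceTest(withr::with_seed(r, runif(16, -180, 180)),
                              nNull = 1000L, seed = r)), numeric(1))
  rej <- mean(ps < 0.05)
  expect_gte(rej, 0.02); expect_lte(rej, 0.09)
  expect_error(phaseCoherenceTest(10), "at least two")
})

test_that("FDR adjustment equals the brute-force step-up computation", {
  stepUp <- function(p) {
    # independent oracle: Benjamini-Hochberg step-up from first principles
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(fdrAdjust(0.03), 0.03)                  # single p unchanged
  expect_equal(fdrAdjust(rep(0.2, 5)), rep(0.2, 5))    # equal ps unchanged
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)),
               stepUp(c(0.01, 0.02, 0.03, 0.04)))
  set.seed(6)
  for (r in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(fdrAdjust(p), stepUp(p), tolerance = 1e-12)
    # ordering preserved and adjusted >= raw
    expect_true(all(fdrAdjust(p) >= p - 1e-15))
    expect_identical(order(fdrAdjust(p)), order(stepUp(p)))
  }
  expect_error(fdrAdjust(c(0.5, 0)), "0, 1")
  expect_error(fdrAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("the cluster permutation test localises injected differences", {
  n <- 16; nT <- 109; fs <- 128; t0 <- -0.1
  tt <- t0 + (seq_len(nT) - 1) / fs
  inject <- ifelse(tt >= 0.30 & tt <= 0.50, 1.5, 0)
  set.seed(31)
  erpA <- matrix(rnorm(n * nT), n) + matrix(inject, n, nT, byrow = TRUE)
  erpB <- matrix(rnorm(n * nT), n)
  res <- clusterPermutationTest(erpA, erpB, nPermutations = 1000L,
                                samplingRate = fs, timeOffset = t0, seed = 7)
  cl <- clusters(res)
  hit <- cl[cl$p < 0.05, , drop = FALSE]
  expect_gt(nrow(hit), 0)
  expect_true(any(hit$start <= 0.50 & hit$end >= 0.30))
  expect_equal(res@nPermutations, 1000L)
  # identical conditions: no suprathreshold points at all
  same <- clusterPermutationTest(erpA, erpA, nPermutations = 100L, seed = 7)
  expect_equal(nrow(clusters(same)), 0)
  expect_error(clusterPermutationTest(erpA[1, , drop = FALSE],
                                      erpB[1, , drop = FALSE]), "two")
})

test_that("the cluster test controls family-wise error under the null", {
  nRep <- 200
  fwe <- 0
  for (r in seq_len(nRep)) {
    d <- withr::with_seed(4000 + r, list(a = matrix(rnorm(12 * 40), 12),
                                         b = matrix(rnorm(12 * 40), 12)))
    res <- clusterPermutationTest(d$a, d$b, nPermutations = 500L, seed = r)
    fwe <- fwe + any(clusters(res)$p < 0.05)
  }
  expect_gte(fwe / nRep, 0.02)
  expect_lte(fwe / nRep, 0.09)
})

test_that("paired effect sizes and achieved power behave like Cohen's d", {
  # Monte-Carlo oracle: population d = 1.0, n = 16
  ds <- vapply(seq_len(200), function(r) {
    x <- withr::with_seed(6000 + r, rnorm(16, 1, 1))
    y <- rep(0, 16)
    pairedEffectSize(x, y)$d
  }, numeric(1))
  expect_lt(abs(mean(ds) - 1), 0.15)
  # power approaches alpha as the true effect vanishes
  es <- pairedEffectSize(c(1, 2, 3, 2, 1, 2.2, 2.8, 1.4),
                         c(1.1, 2, 2.9, 2.1, 1, 2.2, 2.75, 1.45))
  expect_lt(es$power, 0.2)
  # degenerate zero-variance differences are an error
  expect_error(pairedEffectSize(c(2, 3, 4), c(1, 2, 3)), "zero variance")
})

test_that("resampling results are deterministic given their seed", {
  x <- rnorm(16)
  expect_identical(pValue(spectralPeakTest(x, 500L, seed = 11)),
                   pValue(spectralPeakTest(x, 500L, seed = 11)))
  a <- matrix(rnorm(8 * 30), 8); b <- matrix(rnorm(8 * 30), 8)
  expect_identical(clusters(clusterPermutationTest(a, b, 200L, seed = 5)),
                   clusters(clusterPermutationTest(a, b, 200L, seed = 5)))
  expect_identical(bootstrapCircularMean(x * 30, 200L, seed = 3),
                   bootstrapCircularMean(x * 30, 200L, seed = 3))
})
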