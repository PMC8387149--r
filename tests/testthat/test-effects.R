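test_that("bootstrap mean difference handles identity and degenerate cases", {
  es <- bootstrapMeanDifference(c(1, 2, 3), c(1, 2, 3), nBoot = 1000,
                                seed = 4)
  expect_equal(meanDifference(es), 0)
  ci <- confint95(es)
  expect_lte(ci[1], 0); expect_gte(ci[2], 0)

  # zero-variance groups: exact difference, degenerate CI, logged downgrade
  expect_message(
    es2 <- bootstrapMeanDifference(c(0, 0, 0, 0), c(1, 1, 1, 1),
                                   nBoot = 1000, seed = 4),
    "falling back to percentile")
  expect_equal(meanDifference(es2), 1)
  expect_equal(confint95(es2), c(1, 1))
  expect_equal(es2@ciMethod, "percentile")
  expect_true(is.na(effectD(es2)))

  expect_error(bootstrapMeanDifference(1, c(1, 2), seed = 1), "n >= 2")
  expect_error(bootstrapMeanDifference(c(1, NA), c(1, 2), seed = 1),
               "non-finite")
  expect_error(bootstrapMeanDifference(c(1, 2), c(1, 2), nBoot = 10,
                                       seed = 1), "1000")
})

test_that("identical seed and inputs give a bit-identical effect size", {
  set.seed(1); a <- rnorm(15); b <- rnorm(17, 0.8)
  e1 <- bootstrapMeanDifference(a, b, nBoot = 2000, seed = 99)
  e2 <- bootstrapMeanDifference(a, b, nBoot = 2000, seed = 99)
  expect_identical(e1, e2)
  e3 <- bootstrapMeanDifference(a, b, nBoot = 2000, seed = 100)
  expect_false(identical(confint95(e1), confint95(e3)))
})

test_that("swapping groups negates the estimate and mirrors the CI", {
  set.seed(2); a <- rnorm(12); b <- rnorm(12, 1)
  eab <- bootstrapMeanDifference(a, b, nBoot = 2000, seed = 7,
                                 ciMethod = "percentile")
  eba <- bootstrapMeanDifference(b, a, nBoot = 2000, seed = 7,
                                 ciMethod = "percentile")
  expect_equal(meanDifference(eba), -meanDifference(eab))
  expect_equal(effectD(eba), -effectD(eab))
  # mirrored CI up to bootstrap resampling noise
  expect_equal(confint95(eba), -rev(confint95(eab)), tolerance = 0.15)
})

test_that("BCa interval agrees with the boot package on a shared problem", {
  set.seed(99)
  a <- rnorm(15, 0, 1); b <- rnorm(18, 1, 1.4)
  es <- bootstrapMeanDifference(a, b, nBoot = 20000, seed = 5)
  dat <- data.frame(v = c(a, b), g = rep(1:2, c(15, 18)))
  bt <- boot::boot(dat, function(d, i)
    mean(d$v[i][d$g == 2]) - mean(d$v[i][d$g == 1]),
    R = 20000, strata = dat$g)
  ref <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  expect_equal(confint95(es), ref, tolerance = 0.08)
})

test_that("Cohen's d matches hand arithmetic and its invariances", {
  expect_equal(cohensD(c(0, 2), c(1, 3)), 1 / sqrt(2))
  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cohensD(c(1, 1), c(1, 1)), "zero variance")

  set.seed(3); a <- rnorm(30, 0, 2); b <- rnorm(25, 1, 2)
  d <- cohensD(a, b)
  expect_equal(cohensD(a + 5, b + 5), d)          # shift invariance
  expect_equal(cohensD(a * 3, b * 3), d)          # scale invariance
  es <- bootstrapMeanDifference(a * 3, b * 3, nBoot = 1000, seed = 1)
  expect_equal(meanDifference(es), 3 * (mean(b) - mean(a)))
})

test_that("percent change follows the ratio-to-control definition", {
  expect_equal(percentChange(c(5, 5), c(5, 5)), 0)
  expect_equal(percentChange(rep(344.11, 4), rep(100, 4)), 244.11)
  expect_lt(percentChange(c(1, 2), c(10, 20)), 0)
  expect_error(percentChange(c(1, 2), c(0, 0)), "control mean")
})

test_that("effect-size regression handles exact, decoupled and degenerate designs", {
  x <- c(-1, 0, 1, 2.5, 4)
  reg <- fitEffectSizeRegression(x, 2 * x + 1)
  expect_equal(reg@rSquared, 1)
  expect_equal(reg@slope, 2)
  expect_equal(reg@intercept, 1)

  # two points are always collinear
  expect_equal(fitEffectSizeRegression(c(0, 1), c(3, 5))@rSquared, 1)

  # y decoupled from x
  set.seed(5)
  xs <- rnorm(500); ys <- rnorm(500)
  expect_lt(fitEffectSizeRegression(xs, ys)@rSquared, 0.1)

  expect_error(fitEffectSizeRegression(c(1, 1, 1), c(1, 2, 3)),
               "degenerate design")

  # R^2 invariant under affine transforms of either axis
  yy <- 0.7 * xs + rnorm(500)
  r2 <- fitEffectSizeRegression(xs, yy)@rSquared
  r2b <- fitEffectSizeRegression(3 * xs - 2, -5 * yy + 4)@rSquared
  expect_equal(r2, r2b, tolerance = 1e-12)

  # bootstrap CI over points brackets the estimate
  reg2 <- fitEffectSizeRegression(xs[1:30], 0.7 * xs[1:30] + rnorm(30),
                                  nBoot = 500, seed = 8)
  expect_lte(reg2@r2CiLow, reg2@rSquared + 1e-9)
  expect_gte(reg2@r2CiHigh, reg2@rSquared - 0.2)
})

test_that("cumulative seizing curve counts onsets at or before each checkpoint", {
  cur <- cumulativeSeizingFraction(c(10, 30, 50, NA),
                                   checkpoints = seq(10, 120, 10))
  expect_equal(cur$fraction_seizing[1:5], c(0.25, 0.25, 0.5, 0.5, 0.75))
  expect_equal(cur$fraction_seizing[12], 0.75)   # censored animal never counts
  expect_true(all(diff(cur$fraction_seizing) >= 0))

  expect_equal(unique(cumulativeSeizingFraction(
    rep(0, 5))$fraction_seizing), 1)
  expect_equal(unique(cumulativeSeizingFraction(
    rep(NA_real_, 5))$fraction_seizing), 0)
  expect_error(cumulativeSeizingFraction(numeric(0)), "empty cohort")
  expect_error(cumulativeSeizingFraction(c(1, 2), checkpoints = c(2, 1)),
               "increasing")
})

test_that("derived child seeds are deterministic, label-sensitive and in range", {
  s1 <- deriveSeed(123, "a", "b", "vortex")
  expect_identical(s1, deriveSeed(123, "a", "b", "vortex"))
  expect_false(s1 == deriveSeed(123, "a", "b", "heat"))
  expect_false(s1 == deriveSeed(124, "a", "b", "vortex"))
  for (s in c(0, 1, 2^30, 2147483646))
    expect_true(deriveSeed(s, "x") >= 0 && deriveSeed(s, "x") < 2^31)
})
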