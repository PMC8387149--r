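mkSummary <- function(means, genotype = "CS", nBursts = 5L) {
  data.frame(trace_id = sprintf("%s_%02d", genotype, seq_along(means)),
             genotype = genotype, n_bursts = nBursts,
             mean_burst_duration_s = means, stringsAsFactors = FALSE)
}

test_that("reference band is mean +/- k sample SD of per-trace means", {
  band <- buildReferenceBand(mkSummary(c(0.1, 0.2, 0.3)), "CS", k = 1.5)
  expect_equal(bandMean(band), 0.2)
  expect_equal(bandSD(band), 0.1)
  expect_equal(bandLower(band), 0.05)
  expect_equal(bandUpper(band), 0.35)
  expect_equal(band@nTraces, 3L)

  # k = 0 degenerates to a point band
  b0 <- buildReferenceBand(mkSummary(c(0.1, 0.2, 0.3)), "CS", k = 0)
  expect_equal(bandLower(b0), bandUpper(b0))

  # identical reference traces: SD 0, band = point
  bp <- buildReferenceBand(mkSummary(c(0.2, 0.2, 0.2)), "CS")
  expect_equal(bandSD(bp), 0)
  expect_equal(bandLower(bp), bandUpper(bp))
})

test_that("band construction rejects insufficient references", {
  expect_error(buildReferenceBand(mkSummary(0.2), "CS"),
               "insufficient reference")
  expect_error(buildReferenceBand(mkSummary(c(0.1, 0.2)), "OR"),
               "no traces for reference genotype")
  # zero-burst reference traces are excluded with a message
  s <- mkSummary(c(0.1, 0.2, NA))
  s$n_bursts[3] <- 0L
  expect_message(band <- buildReferenceBand(s, "CS"), "zero-burst")
  expect_equal(band@nTraces, 2L)
})

test_that("labels follow the band with inclusive bounds", {
  band <- buildReferenceBand(mkSummary(c(0.1, 0.2, 0.3)), "CS", k = 1.5)
  test <- mkSummary(c(0.2, 0.35, 0.35 + 1e-9, 0.05, 0.05 - 1e-9, 0.15),
                    genotype = "mut")
  test$n_bursts[6] <- 0L
  test$mean_burst_duration_s[6] <- NA
  lab <- classifyTraces(test, band)
  expect_equal(lab$label, c("normal", "normal", "elongated",
                            "normal", "short", "unclassifiable"))
})

test_that("elongated fraction counts only classifiable traces", {
  lab <- data.frame(trace_id = sprintf("t%02d", 1:14), genotype = "jus",
                    label = c(rep("elongated", 5), rep("normal", 7),
                              rep("unclassifiable", 2)))
  fr <- fractionElongated(lab)
  expect_equal(fr$n_classifiable, 12L)
  expect_equal(fr$n_elongated, 5L)
  expect_equal(fr$fraction_elongated, 5 / 12, tolerance = 1e-12)
  expect_equal(fr$n_unclassifiable, 2L)

  # permutation invariance
  fr2 <- fractionElongated(lab[sample(nrow(lab)), ])
  expect_equal(fr2$fraction_elongated, fr$fraction_elongated)

  # all normal -> 0; no classifiable -> NA
  expect_equal(fractionElongated(
    data.frame(genotype = "a", label = rep("normal", 3)))$fraction_elongated, 0)
  expect_true(is.na(fractionElongated(
    data.frame(genotype = "a",
               label = rep("unclassifiable", 2)))$fraction_elongated))
})

test_that("elongated fraction is monotone non-increasing in k", {
  set.seed(42)
  ref <- mkSummary(rnorm(30, 0.2, 0.03))
  test <- mkSummary(rnorm(50, 0.25, 0.08), genotype = "mut")
  fr <- vapply(c(0.5, 1, 1.5, 2, 3), function(k)
    fractionElongated(classifyTraces(
      test, buildReferenceBand(ref, "CS", k)))$fraction_elongated,
    numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("classification is scale-equivariant", {
  set.seed(43)
  ref <- mkSummary(rnorm(20, 0.2, 0.05))
  test <- mkSummary(rnorm(40, 0.3, 0.1), genotype = "mut")
  lab1 <- classifyTraces(test, buildReferenceBand(ref, "CS"))
  refS <- ref; refS$mean_burst_duration_s <- ref$mean_burst_duration_s * 7
  testS <- test; testS$mean_burst_duration_s <- test$mean_burst_duration_s * 7
  lab2 <- classifyTraces(testS, buildReferenceBand(refS, "CS"))
  expect_equal(lab1$label, lab2$label)
})
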