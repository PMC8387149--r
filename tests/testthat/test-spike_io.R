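writeTempTSV <- function(df, name = "tmp.tsv") {
  p <- file.path(tempdir(), name)
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

test_that("spike files parse into validated SpikeTrain objects", {
  sp <- writeTempTSV(data.frame(trace_id = "t1",
                                spike_time_s = c(0.1, 0.2, 0.5)), "sp1.tsv")
  me <- writeTempTSV(data.frame(trace_id = "t1", genotype = "CS",
                                cell_type = "aCC",
                                group_role = "wildtype_reference",
                                duration_s = 180), "me1.tsv")
  trains <- readSpikeTrains(sp, me)
  expect_length(trains, 1L)
  expect_equal(spikeTimes(trains$t1), c(0.1, 0.2, 0.5))
  expect_equal(genotype(trains$t1), "CS")
  expect_equal(traceDuration(trains$t1), 180)
})

test_that("reader is tolerant of row order and duplicates, strict on invariants", {
  # unsorted rows come back sorted
  sp <- writeTempTSV(data.frame(trace_id = "t1",
                                spike_time_s = c(0.5, 0.1)), "sp2.tsv")
  expect_equal(spikeTimes(readSpikeTrains(sp)$t1), c(0.1, 0.5))

  # duplicates collapse with a warning
  sp <- writeTempTSV(data.frame(trace_id = "t1",
                                spike_time_s = c(0.1, 0.1, 0.4)), "sp3.tsv")
  expect_warning(trains <- readSpikeTrains(sp), "duplicate")
  expect_equal(nSpikes(trains$t1), 2L)

  # header-only file -> empty list
  sp <- writeTempTSV(data.frame(trace_id = character(0),
                                spike_time_s = numeric(0)), "sp4.tsv")
  expect_length(readSpikeTrains(sp), 0L)

  # millisecond time column converts
  sp <- writeTempTSV(data.frame(trace_id = "t1",
                                spike_time_ms = c(100, 250)), "sp5.tsv")
  expect_equal(spikeTimes(readSpikeTrains(sp)$t1), c(0.1, 0.25))
})

test_that("reader errors name the problem", {
  sp <- writeTempTSV(data.frame(trace_id = "t1", wrong = 1), "bad1.tsv")
  expect_error(readSpikeTrains(sp), "spike_time_s")

  sp <- writeTempTSV(data.frame(trace_id = "t1",
                                spike_time_s = c("0.1", "oops")), "bad2.tsv")
  expect_error(readSpikeTrains(sp), "line 3")

  sp <- writeTempTSV(data.frame(trace_id = "t1", spike_time_s = -0.5),
                     "bad3.tsv")
  expect_error(readSpikeTrains(sp), "negative")

  # spike beyond the declared duration
  sp <- writeTempTSV(data.frame(trace_id = "t1", spike_time_s = 200),
                     "bad4.tsv")
  me <- writeTempTSV(data.frame(trace_id = "t1", genotype = "CS",
                                cell_type = "aCC", group_role = "control",
                                duration_s = 180), "bad4m.tsv")
  expect_error(readSpikeTrains(sp, me), "beyond its declared duration")

  expect_error(readSpikeTrains(file.path(tempdir(), "nope.tsv")),
               "not found")
})

test_that("behavior tables validate and case-fold assay labels", {
  be <- writeTempTSV(data.frame(animal_id = sprintf("a%d", 1:10),
                                genotype = "bss", assay = "Vortex",
                                value = 1:10), "be1.tsv")
  rec <- readBehavior(be)
  expect_equal(nrow(rec), 10L)
  expect_true(all(rec$assay == "vortex"))
  expect_true(all(is.na(rec$onset_time_s)))

  be <- writeTempTSV(data.frame(animal_id = "a", genotype = "x",
                                assay = "shake", value = 1), "be2.tsv")
  expect_error(readBehavior(be), "vortex, heat, eshock")

  be <- writeTempTSV(data.frame(animal_id = "a", genotype = "x",
                                assay = "vortex", value = -1), "be3.tsv")
  expect_error(readBehavior(be), "negative value")
})

test_that("result tables round-trip to at least 12 significant digits", {
  df <- data.frame(id = c("a", "b"),
                   x = c(pi * 1e-4, 123456.789012345),
                   n = c(3L, 0L),
                   flag = c(NA_real_, 0.1 + 0.2))
  p <- file.path(tempdir(), "round.tsv")
  writeResultTable(df, p)
  back <- readResultTable(p)
  expect_equal(back$id, df$id)
  expect_equal(back$x, df$x, tolerance = 1e-13)
  expect_equal(back$n, df$n)
  expect_equal(back$flag, df$flag, tolerance = 1e-13)

  # zero-row table -> header-only file that reads back empty
  writeResultTable(df[0, ], p)
  expect_equal(nrow(readResultTable(p)), 0L)

  expect_error(
    suppressWarnings(
      writeResultTable(df, file.path(tempdir(), "no/such/dir/x.tsv"))),
    "I/O error")
})
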