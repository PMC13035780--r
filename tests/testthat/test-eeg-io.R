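test_that("EDF round-trip preserves signals to within one quantization step", {
  rec <- noiseRec(fs = 100, durationS = 3, sdUv = 35, seed = 4)
  p <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, p)
  back <- readEDF(p)
  rng <- apply(eegData(rec), 1L, function(v) diff(range(v)))
  step <- rng / (2^16 - 1)
  err <- abs(eegData(back) - eegData(rec))
  expect_true(all(err <= matrix(step, nrow = 6, ncol = nSamples(rec)) + 1e-9))
  expect_identical(channelNames(back), channelNames(rec))  # order kept
  expect_equal(samplingRate(back), 100)
  expect_equal(subjectId(back), "s01")
  expect_equal(session(back), "T0")
})

test_that("EDF handles non-integer record splits and flat channels", {
  x <- rbind(sin(seq_len(150)), rep(2, 150))  # 1.5 s at 100 Hz; one flat
  rec <- makeRec(x, fs = 100, channels = c("C3", "C4"))
  p <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, p)
  back <- readEDF(p, requireChannels = NULL)
  expect_equal(nSamples(back), 150L)
  expect_lt(max(abs(eegData(back)[1, ] - x[1, ])), 1e-3)
  expect_lt(max(abs(eegData(back)[2, ] - 2)), 1e-3)
})

test_that("reading an EDF missing required channels names the absent labels", {
  rec <- makeRec(matrix(rnorm(200), 2), fs = 100, channels = c("C3", "C4"))
  p <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, p)
  err <- tryCatch(readEDF(p), error = conditionMessage)
  for (ch in c("P3", "P4", "O1", "O2")) expect_match(err, ch)
  expect_s4_class(readEDF(p, requireChannels = NULL), "EEGRecording")
})

test_that("malformed EDF headers and empty recordings are rejected", {
  p <- withr::local_tempfile(fileext = ".edf")
  writeLines("this is not an EDF file, just text long enough to read", p)
  expect_error(readEDF(p), "malformed")
  expect_error(readEDF(file.path(tempdir(), "nope.edf")), "not found")
  expect_error(makeRec(matrix(numeric(0), 0, 0), fs = 10,
                       channels = character(0)), "channel")
})

test_that("array sidecar round-trip is lossless", {
  rec <- noiseRec(fs = 120, durationS = 2, seed = 9, session = "T1")
  base <- file.path(withr::local_tempdir(), "rec1")
  writeEEGArray(rec, base)
  back <- readEEGArray(base)
  expect_equal(eegData(back), eegData(rec), ignore_attr = TRUE)
  expect_identical(channelNames(back), channelNames(rec))
  expect_equal(session(back), "T1")
})

test_that("cohort CSV round-trips and validates labels and NIHSS ranges", {
  df <- tinyCohortDf()
  p <- withr::local_tempfile(fileext = ".csv")
  writeCohortCSV(df, p)
  back <- readCohortCSV(p)
  expect_equal(back$delta_nihss, c(7L, 4L, 3L, 4L))
  expect_equal(nrow(back), 4L)
  expect_equal(as.integer(table(back$group)[c("experimental", "control")]),
               c(2L, 2L))

  bad <- df; bad$group[2] <- "treated"
  expect_error(validateCohort(bad), "experimental")
  bad2 <- df; bad2$nihss_t0[1] <- 23L
  expect_warning(validateCohort(bad2), "5-20")
  expect_error(validateCohort(bad2, strict = "error"), "5-20")
  expect_silent(validateCohort(bad2, strict = "none"))
  bad3 <- df; bad3$nihss_t1[1] <- -1L
  expect_error(validateCohort(bad3), "non-negative")
})

test_that("deltaNihss follows the baseline-minus-followup convention", {
  expect_identical(deltaNihss(13, 6), 7L)
  expect_identical(deltaNihss(12, 12), 0L)
  expect_identical(deltaNihss(5, 8), -3L)   # worsening allowed
  expect_error(deltaNihss(NA, 5), "missing")
  expect_identical(deltaNihss(tinyCohortDf())[1], 7L)
})
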