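test_that("synthSignal validates inputs and hits single-band limits", {
  expect_error(synthSignal(c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(synthSignal(c(2, -1, 0, 0)), "non-negative")
  expect_error(synthSignal(c(1, 0, 0, 0), durationS = 2), "durationS")
  expect_error(synthSignal(c(1, 0, 0, 0), fs = 40), "fs")

  ## pure alpha tone: all analyzed power in alpha
  x <- synthSignal(c(0, 0, 1, 0), complexityLevel = 0, durationS = 20,
                   fs = 1000, seed = 1)
  r <- signalRpsd(x, 1000)
  expect_gt(r$rpsd["alpha"], 0.99)
})

test_that("synthSignal places band variance exactly (Parseval, uncompensated)", {
  f <- c(0.25, 0.25, 0.25, 0.25)
  bands <- eegBands()
  fr <- vapply(1:5, function(s) {
    x <- synthSignal(f, complexityLevel = 1, durationS = 20, fs = 500,
                     seed = s, amplitudeUv = 10, compensate = FALSE)
    sp <- Mod(fft(x))^2
    fgrid <- (seq_along(x) - 1) / 20
    bp <- vapply(seq_len(4), function(b) {
      hi <- if (b < 4) bands$hi[b] else 30.0001
      sum(sp[fgrid >= bands$lo[b] & fgrid < hi])
    }, 0)
    c(bp / sum(bp), var(x))
  }, numeric(5))
  ## total variance ~ amplitude^2; FFT-grid fractions recover the quarters
  expect_equal(mean(fr[5, ]), 100, tolerance = 0.1)
  expect_lt(max(abs(rowMeans(fr[1:4, , drop = FALSE]) - f)), 0.03)
})

test_that("the complexity knob is monotone in LZC and ApEn", {
  f <- c(0.4, 0.25, 0.2, 0.15)
  levs <- c(0.1, 0.5, 1)
  mlzc <- mapen <- numeric(3)
  for (k in seq_along(levs)) {
    vals <- vapply(1:6, function(s) {
      x <- synthSignal(f, levs[k], durationS = 4, fs = 500, seed = 100 + s,
                       compensate = FALSE)
      c(lzc(x)$value, apen(x))
    }, numeric(2))
    mlzc[k] <- mean(vals[1, ]); mapen[k] <- mean(vals[2, ])
  }
  expect_true(all(diff(mlzc) >= 0))
  expect_true(all(diff(mapen) >= 0))
})

test_that("generated complexity orders periodic < narrowband < broadband", {
  per <- synthSignal(c(0, 0, 1, 0), 0, durationS = 4, fs = 500, seed = 5,
                     compensate = FALSE)               # pure tone
  nar <- synthSignal(c(0, 0, 1, 0), 1, durationS = 4, fs = 500, seed = 5,
                     compensate = FALSE)               # alpha-band noise
  bro <- synthSignal(rep(0.25, 4), 1, durationS = 4, fs = 500, seed = 5,
                     compensate = FALSE)               # broadband noise
  expect_lt(lzc(per)$value, lzc(nar)$value)
  expect_lt(lzc(nar)$value, lzc(bro)$value)
  expect_lt(apen(per), apen(nar))
  expect_lt(apen(nar), apen(bro))
})

test_that("synthCohort produces the right counts, labels and determinism", {
  spec <- cohortSpec(nPerGroup = 3, seed = 21, fs = 250, durationS = 20)
  cs <- synthCohort(spec)
  expect_equal(nrow(cs$cohort), 6L)
  expect_equal(length(cs$recordings), 12L)
  expect_equal(as.integer(table(cs$cohort$group)[c("experimental", "control")]),
               c(3L, 3L))
  expect_true(all(cs$cohort$nihss_t0 >= 5 & cs$cohort$nihss_t0 <= 20))
  expect_true(all(cs$cohort$nihss_t1 >= 0))
  rec <- cs$recordings[["s001_T0"]]
  expect_equal(channelNames(rec), requiredChannels())
  expect_equal(nSamples(rec), 250L * 20L)

  cs2 <- synthCohort(spec)
  expect_identical(cs$cohort, cs2$cohort)
  expect_identical(eegData(cs$recordings[["s002_T1"]]),
                   eegData(cs2$recordings[["s002_T1"]]))
  ## different seed changes the data
  cs3 <- synthCohort(cohortSpec(nPerGroup = 3, seed = 22, fs = 250))
  expect_false(identical(cs$cohort, cs3$cohort))
})

test_that("generating a session subset leaves metadata and signals unchanged", {
  spec <- cohortSpec(nPerGroup = 2, seed = 31, fs = 250)
  full <- synthCohort(spec)
  t1 <- synthCohort(spec, sessions = "T1")
  expect_identical(full$cohort, t1$cohort)
  expect_identical(eegData(full$recordings[["s001_T1"]]),
                   eegData(t1$recordings[["s001_T1"]]))
  expect_false("s001_T0" %in% names(t1$recordings))
})

test_that("cohort spec validity catches malformed fractions", {
  bf <- qeeg:::defaultBandFractions()
  bf["experimental", "T0", "affected", ] <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(cohortSpec(bandFractions = bf), "sum to 1")
  expect_error(cohortSpec(nPerGroup = 1), "nPerGroup")
  cl <- qeeg:::defaultComplexityLevel(); cl[1, 1] <- 1.4
  expect_error(cohortSpec(complexityLevel = cl), "complexity")
})

test_that("NIHSS improvement tracks the alpha/beta ratio by construction", {
  spec <- cohortSpec(nPerGroup = 30, seed = 41, fs = 250, durationS = 4)
  cs <- synthCohort(spec, sessions = character(0))   # metadata only
  exp <- cs$cohort[cs$cohort$group == "experimental", ]
  expect_equal(mean(exp$delta_nihss), 7.2, tolerance = 1.5)
  ctrl <- cs$cohort[cs$cohort$group == "control", ]
  expect_equal(mean(ctrl$delta_nihss), 4.5, tolerance = 1.5)
  expect_gt(mean(exp$delta_nihss), mean(ctrl$delta_nihss))
})

test_that("writeSynthCohort writes EDFs and a readable cohort.csv", {
  dir <- withr::local_tempdir()
  writeSynthCohort(cohortSpec(nPerGroup = 2, seed = 51, fs = 100,
                              durationS = 20), dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_length(list.files(dir, pattern = "\\.edf$"), 8L)
  back <- readEDF(file.path(dir, "s001_T0.edf"))
  expect_equal(nSamples(back), 2000L)
})
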