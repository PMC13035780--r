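test_that("binarize thresholds at the median (or mean) and flags constants", {
  expect_identical(binarize(c(1, 3, 2, 5)), c(0L, 1L, 0L, 1L))
  expect_identical(binarize(c(1, 3, 2, 5), "mean"), c(0L, 1L, 0L, 1L))
  expect_warning(b <- binarize(c(7, 7, 7, 7)), "constant")
  expect_identical(b, c(0L, 0L, 0L, 0L))
  set.seed(1)
  x <- rnorm(500)
  expect_length(binarize(x), 500L)
  expect_error(binarize(3), "at least 2")
})

test_that("lz76 matches frozen oracle values", {
  expect_equal(lz76("0"), 1L)
  expect_equal(lz76("0000"), 2L)
  expect_equal(lz76(rep(0L, 50)), 2L)
  ## value fixed by the brute-force production-rule parser
  expect_equal(lz76("0001101001000101"), 6L)
  expect_equal(lz76Oracle("0001101001000101"), 6L)
  expect_error(lz76(c(0L, 2L)), "binary")
})

test_that("lz76 equals the production-rule oracle on random strings", {
  set.seed(42)
  for (i in 1:300) {
    b <- sample(0:1, sample(1:16, 1L), replace = TRUE)
    expect_identical(lz76(b), lz76Oracle(b))
  }
})

test_that("normalized LZC separates periodic from random sequences", {
  set.seed(3)
  coin <- sample(0:1, 20000, replace = TRUE)
  v <- lzc(coin, "none")
  expect_gt(v$value, 0.85)
  expect_lt(v$value, 1.15)
  per <- lzc(rep(c(0L, 1L), 10000), "none")
  expect_lt(per$value, 0.05)
  expect_equal(v$value, v$count * log2(v$n) / v$n)
  suppressWarnings(const <- lzc(rep(5, 100)))
  expect_equal(const$count, 2L)    # all-zeros sequence after binarization
})

test_that("LZC with median binarization is invariant under monotone transforms", {
  set.seed(4)
  x <- rnorm(2000)
  v0 <- lzc(x)$value
  expect_equal(lzc(exp(x))$value, v0)
  expect_equal(lzc(3 * x - 7)$value, v0)
  expect_equal(lzc(x^3)$value, v0)
})

test_that("apen matches the naive O(N^2) oracle", {
  set.seed(5)
  for (i in 1:12) {
    x <- rnorm(100)
    expect_equal(apen(x), apenOracle(x), tolerance = 1e-10)
  }
  x <- arima.sim(list(ar = 0.9), 150)
  expect_equal(apen(as.numeric(x), m = 3),
               apenOracle(as.numeric(x), m = 3), tolerance = 1e-10)
})

test_that("apen behaves as a regularity statistic", {
  expect_warning(v <- apen(rep(1, 100)), "constant")
  expect_equal(v, 0)
  alt <- rep(c(1, 5), 500)
  expect_lt(apen(alt), 0.01)
  set.seed(6)
  wn <- rnorm(1000)
  expect_gt(apen(wn), apen(alt))
  ## scale invariance: r tracks the SD
  expect_equal(apen(10 * wn + 2), apen(wn), tolerance = 1e-12)
  expect_error(apen(rnorm(3), m = 2), "too short")
})

test_that("epoch complexity averages over epochs", {
  set.seed(7)
  e1 <- matrix(rnorm(2 * 300), 2, dimnames = list(c("C3", "C4"), NULL))
  e2 <- matrix(rnorm(2 * 300), 2, dimnames = list(c("C3", "C4"), NULL))
  es <- EpochSet(list(e1, e2), fs = 100)
  cc <- epochComplexity(es, "C3")
  expect_equal(cc$lzc, mean(c(lzc(e1[1, ])$value, lzc(e2[1, ])$value)))
  expect_equal(cc$apen, mean(c(apen(e1[1, ]), apen(e2[1, ]))))
  expect_error(epochComplexity(es, "O1"), "not present")
})

test_that("hemisphere features pick the infarct side and average regions", {
  feats <- expand.grid(subject_id = c("s01", "s02"), session = c("T0"),
                       channel = requiredChannels(),
                       stringsAsFactors = FALSE)
  feats$delta <- 0.4; feats$theta <- 0.25
  feats$alpha <- ifelse(feats$channel == "C3", 0.3,
                        ifelse(feats$channel == "P3", 0.5, 0.7))
  feats$beta <- 0.1; feats$lzc <- 0.5; feats$apen <- 0.8
  feats$total_power <- 100
  cohort <- data.frame(subject_id = c("s01", "s02"),
                       infarct_side = c("left", "right"))
  hf <- hemisphereFeatures(feats, cohort)
  s1 <- hf$perElectrode[hf$perElectrode$subject_id == "s01", ]
  expect_setequal(s1$channel, c("C3", "P3", "O1"))
  s2 <- hf$perElectrode[hf$perElectrode$subject_id == "s02", ]
  expect_setequal(s2$channel, c("C4", "P4", "O2"))
  sm1 <- hf$summary[hf$summary$subject_id == "s01", ]
  expect_equal(sm1$alpha, 0.5)                       # mean(0.3, 0.5, 0.7)
  expect_equal(sm1$lzc, 0.5)
  expect_equal(sm1$ab_ratio, 0.5 / 0.1)
  ## missing electrode is named
  err <- tryCatch(hemisphereFeatures(feats[feats$channel != "P3", ], cohort),
                  error = conditionMessage)
  expect_match(err, "P3")
})
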