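test_that("welchPsd concentrates a sinusoid's power at its frequency", {
  fs <- 1000
  x <- sin(2 * pi * 10 * seq_len(4 * fs) / fs)
  p <- welchPsd(x, fs)
  expect_equal(p$freq[which.max(p$psd)], 10)
  expect_equal(sum(p$psd) * diff(p$freq[1:2]), 0.5, tolerance = 0.02)
  near10 <- abs(p$freq - 10) <= 2
  expect_gt(sum(p$psd[near10]) / sum(p$psd), 0.999)
})

test_that("welchPsd satisfies Parseval for white noise", {
  set.seed(7)
  fs <- 200
  tot <- replicate(10, {
    x <- rnorm(20 * fs)
    p <- welchPsd(x, fs)
    (sum(p$psd) * diff(p$freq[1:2])) / var(x)
  })
  expect_lt(abs(mean(tot) - 1), 0.05)
})

test_that("welchPsd handles degenerate and short inputs", {
  p <- welchPsd(rep(3, 400), 100)     # DC only; detrended away
  expect_lt(max(p$psd), 1e-20)
  expect_error(welchPsd(rnorm(50), 100), "shorter than the Welch window")
})

test_that("with one 1-s window Welch equals the tapered periodogram", {
  set.seed(8)
  fs <- 100
  x <- rnorm(fs)
  p <- welchPsd(x, fs)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(fs) / fs)
  X <- fft((x - mean(x)) * w)
  nf <- fs / 2 + 1
  direct <- Mod(X[1:nf])^2 / (fs * sum(w^2))
  direct[2:(nf - 1)] <- 2 * direct[2:(nf - 1)]
  expect_equal(p$psd, direct, tolerance = 1e-12)
})

test_that("band fractions are scale invariant and tile the total band", {
  set.seed(9)
  x <- rnorm(4000)
  p1 <- signalRpsd(x, 1000, bandpass = FALSE)
  p2 <- signalRpsd(137.5 * x, 1000, bandpass = FALSE)
  expect_equal(p1$rpsd, p2$rpsd, tolerance = 1e-12)
  expect_equal(sum(p1$rpsd), 1, tolerance = 1e-9)

  ## shared band edges are apportioned, never double counted: the band
  ## powers reassemble the total-band integral exactly
  p <- welchPsd(x, 1000)
  br <- bandRpsd(p$freq, p$psd)
  bandSum <- sum(br$rpsd) * br$totalPower
  expect_equal(bandSum, br$totalPower, tolerance = 1e-9)
  ## a tone on the alpha/beta edge is split between the two bands only
  tone <- sin(2 * pi * 13 * seq_len(4000) / 1000)
  bt <- bandRpsd(welchPsd(tone, 1000)$freq, welchPsd(tone, 1000)$psd)
  expect_equal(unname(bt$rpsd["alpha"] + bt$rpsd["beta"]), 1,
               tolerance = 1e-3)
  expect_lt(bt$rpsd["delta"] + bt$rpsd["theta"], 1e-3)
})

test_that("a pure 10 Hz tone is attributed to alpha", {
  tone <- sin(2 * pi * 10 * seq_len(20000) / 1000)
  r <- signalRpsd(tone, 1000)
  expect_gt(r$rpsd["alpha"], 0.99)
  expect_true(all(r$rpsd[c("delta", "theta", "beta")] <= 0.01))
})

test_that("epoch averaging equals the single-epoch result for identical epochs", {
  set.seed(10)
  e <- matrix(rnorm(6 * 400), 6, dimnames = list(requiredChannels(), NULL))
  es1 <- EpochSet(list(e), fs = 100, subjectId = "a")
  es5 <- EpochSet(rep(list(e), 5), fs = 100, subjectId = "a")
  r1 <- epochAverageRpsd(es1, "C3")
  r5 <- epochAverageRpsd(es5, "C3")
  expect_equal(r1$rpsd, r5$rpsd, tolerance = 1e-12)
  expect_equal(r1$totalPower, r5$totalPower, tolerance = 1e-12)
})

test_that("mixing alpha and beta epochs power-weights the fractions", {
  fs <- 1000
  tt <- seq_len(4 * fs) / fs
  alphaE <- matrix(rep(sin(2 * pi * 10 * tt), each = 1), 1,
                   dimnames = list("C3", NULL))
  betaE <- matrix(sin(2 * pi * 20 * tt), 1, dimnames = list("C3", NULL))
  es <- EpochSet(c(rep(list(alphaE), 4), list(betaE)), fs = fs)
  r <- epochAverageRpsd(es, "C3")
  expect_equal(unname(r$rpsd["alpha"]), 0.8, tolerance = 0.01)
  expect_equal(unname(r$rpsd["beta"]), 0.2, tolerance = 0.01)
})

test_that("bandRpsd refuses a grid that cannot cover the total band", {
  p <- welchPsd(rnorm(300), 50)   # Nyquist 25 Hz < 30
  expect_error(bandRpsd(p$freq, p$psd), "cover")
})
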