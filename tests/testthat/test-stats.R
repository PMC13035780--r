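test_that("pairedT matches the closed-form t on the differences", {
  x0 <- c(10, 11, 12, 13)
  x1 <- x0 - c(1, 2, 3, 4)          # differences 1,2,3,4
  h <- pairedT(x0, x1)
  expect_equal(h$statistic, 2.5 / (sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-8)
  expect_equal(h$statistic, 3.872983, tolerance = 1e-6)
  expect_equal(h$df, 3)
  expect_equal(h$p, 2 * pt(-abs(h$statistic), 3), tolerance = 1e-10)
  expect_error(pairedT(x0, x0), "degenerate")
  expect_error(pairedT(x0, x0 + 1), "degenerate")
  expect_error(pairedT(1:3, 1:4), "equal length")
})

test_that("independentT matches the pooled closed form and is antisymmetric", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  h <- independentT(a, b)
  expect_equal(h$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(h$df, 4)
  h2 <- independentT(b, a)
  expect_equal(h2$statistic, -h$statistic)
  expect_equal(h2$p, h$p)
  same <- independentT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(independentT(c(2, 2), c(2, 2)), "degenerate")
  ## Welch variant has non-integer df
  hw <- independentT(c(1, 2, 3, 9), b, pooled = FALSE)
  expect_false(hw$df == round(hw$df))
})

test_that("chiSquareTest reproduces the hand-computed statistic", {
  even <- matrix(20, 2, 2)
  h <- chiSquareTest(even)
  expect_equal(h$statistic, 0)
  expect_equal(h$p, 1)
  tab <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  h2 <- chiSquareTest(tab)
  expect_equal(h2$statistic, 20, tolerance = 1e-10)   # sum (O-E)^2/E
  expect_equal(h2$df, 1)
  expect_equal(chiSquareTest(t(tab))$statistic, h2$statistic)
  expect_error(chiSquareTest(matrix(c(1, 0, 2, 0), 2)), "zero marginal")
  expect_error(chiSquareTest(matrix(c(1.5, 1, 2, 1), 2)), "integer")
  ## Yates correction is selectable
  expect_lt(chiSquareTest(tab, correct = TRUE)$statistic, 20)
})

test_that("pearsonCorr reproduces hand-computed r and exact limits", {
  x <- c(1, 2, 3, 4)
  h <- pearsonCorr(x, c(2, 1, 4, 3))
  expect_equal(h$r, 0.6, tolerance = 1e-10)
  expect_equal(h$df, 2)
  expect_equal(pearsonCorr(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCorr(x, -x)$r, -1)
  expect_error(pearsonCorr(x, rep(2, 4)), "zero variance")
  expect_error(pearsonCorr(1:2, 2:1), "n >= 3")
})

test_that("bhFdr equals the brute-force step-up definition", {
  expect_equal(bhFdr(0.03), 0.03)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(11)
  for (i in 1:200) {
    p <- runif(sample(1:10, 1))
    expect_equal(bhFdr(p), bhOracle(p), tolerance = 1e-12)
  }
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
})

test_that("bhFdr corrects within families independently", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.01, 0.02)
  fam <- c("a", "a", "a", "a", "b", "b")
  q <- bhFdr(p, fam)
  expect_equal(q[1:4], bhOracle(p[1:4]))
  expect_equal(q[5:6], bhOracle(p[5:6]))
  expect_error(bhFdr(p, fam[1:3]), "match")
})

test_that("analyzeCohort assembles contrasts, families and correlations", {
  set.seed(12)
  n <- 10
  subj <- sprintf("s%02d", 1:(2 * n))
  cohort <- data.frame(subject_id = subj,
                       group = rep(c("experimental", "control"), each = n),
                       infarct_side = rep(c("left", "right"), n),
                       age = sample(40:80, 2 * n, TRUE),
                       sex = sample(c("male", "female"), 2 * n, TRUE),
                       nihss_t0 = sample(5:20, 2 * n, TRUE))
  mkSummary <- function(ses, shift) {
    data.frame(subject_id = subj, session = ses,
               delta = rnorm(2 * n, 0.45 - shift, 0.02),
               theta = rnorm(2 * n, 0.25, 0.02),
               alpha = rnorm(2 * n, 0.18 + shift / 2, 0.02),
               beta = rnorm(2 * n, 0.12 + shift / 2, 0.02),
               lzc = rnorm(2 * n, 0.4 + shift, 0.02),
               apen = rnorm(2 * n, 0.8 + shift, 0.02))
  }
  s0 <- mkSummary("T0", 0)
  s1 <- mkSummary("T1", 0.1)
  smry <- rbind(s0, s1)
  smry$ab_ratio <- smry$alpha / smry$beta
  cohort$nihss_t1 <- pmax(0L, cohort$nihss_t0 -
                            round(5 + 4 * (smry$ab_ratio[smry$session == "T1"] -
                                             mean(smry$ab_ratio))))
  an <- analyzeCohort(smry, cohort)
  st <- an$stats
  expect_setequal(unique(st$contrast),
                  c("within_group_T0_vs_T1", "between_group_at_T1"))
  ## every EEG feature appears in each family, q defined
  eeg <- st[!is.na(st$family), ]
  expect_equal(sort(unique(eeg$family)),
               c("between_T1", "within_control", "within_experimental"))
  expect_true(all(eeg$q_fdr >= eeg$p_raw - 1e-12))
  expect_true(all(eeg$q_fdr <= 1))
  ## q equals the family-wise BH of the raw p-values
  for (f in unique(eeg$family)) {
    i <- eeg$family == f
    expect_equal(eeg$q_fdr[i], bhOracle(eeg$p_raw[i]))
  }
  ## clinical rows present, uncorrected
  expect_true("nihss" %in% st$feature)
  expect_true("delta_nihss" %in% st$feature)
  expect_true(all(is.na(st$q_fdr[st$feature %in% c("nihss", "delta_nihss")])))
  ## correlations cover the three reported features
  expect_setequal(an$correlations$feature, c("ab_ratio", "lzc", "apen"))
  expect_true(all(abs(an$correlations$r) <= 1, na.rm = TRUE))
  expect_setequal(an$baseline$feature,
                  c("age", "nihss_t0", "sex", "infarct_side"))
})
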