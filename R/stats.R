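## The statistical battery: paired/independent t, chi-square, Pearson
## correlation, and Benjamini-Hochberg FDR within families. Computation is
## delegated to the classical base-R tests; these wrappers fix the
## conventions (two-sided, pooled variance by default, no continuity
## correction) and the degenerate-input behaviour.

degenerateStop <- function(what)
  stop("degenerate input: ", what, call. = FALSE)

#' Paired t-test (two-sided)
#'
#' Classical paired t on the differences `x - y`, df = n - 1.
#'
#' @param x,y equal-length paired samples (e.g. a feature at T0 and T1,
#'   matched by subject).
#' @return List with `statistic`, `df`, `p`, `meanDiff`, `n`.
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2L) stop("need n >= 2 pairs")
  d <- x - y
  if (sd(d) == 0) degenerateStop("zero-variance paired differences")
  h <- t.test(x, y, paired = TRUE)
  list(statistic = unname(h$statistic), df = unname(h$parameter),
       p = h$p.value, meanDiff = mean(d), n = length(x))
}

#' Independent-samples t-test (two-sided)
#'
#' Student's pooled-variance t by default; set `pooled = FALSE` for the
#' Welch variant.
#'
#' @param a,b the two samples (each n >= 2).
#' @param pooled assume equal variances (default `TRUE`).
#' @return List with `statistic`, `df`, `p`, `meanA`, `meanB`, `sdA`, `sdB`.
#' @export
independentT <- function(a, b, pooled = TRUE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (sd(a) == 0 && sd(b) == 0 && a[1L] == b[1L])
    degenerateStop("both groups constant and equal")
  h <- t.test(a, b, var.equal = pooled)
  list(statistic = unname(h$statistic), df = unname(h$parameter),
       p = h$p.value, meanA = mean(a), meanB = mean(b),
       sdA = sd(a), sdB = sd(b))
}

#' Pearson chi-square test on a 2 x k contingency table
#'
#' No continuity correction by default (set `correct = TRUE` for Yates).
#'
#' @param tab 2 x k matrix of non-negative integer counts.
#' @param correct apply Yates continuity correction (2 x 2 only).
#' @return List with `statistic`, `df`, `p`.
#' @export
chiSquareTest <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in contingency table")
  h <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(h$statistic), df = unname(h$parameter),
       p = h$p.value)
}

#' Pearson correlation with t-based two-sided p-value
#'
#' @param x,y numeric vectors, n >= 3, non-zero variance.
#' @return List with `r`, `p`, `n`, `df`.
#' @export
pearsonCorr <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) degenerateStop("zero variance")
  h <- cor.test(x, y, method = "pearson")
  list(r = unname(h$estimate), p = h$p.value, n = length(x),
       df = unname(h$parameter))
}

#' Benjamini-Hochberg q-values within families
#'
#' Step-up FDR correction applied separately within each family:
#' `q(i) = min over j >= i of m * p(j) / j` on the sorted p-values.
#'
#' @param p p-values in `[0, 1]`.
#' @param family optional family labels (same length as `p`); `NULL` treats
#'   all p-values as one family.
#' @return q-values, order-preserving within each family.
#' @export
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bhFdr <- function(p, family = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  if (is.null(family)) return(p.adjust(p, method = "BH"))
  if (length(family) != length(p)) stop("family labels must match p")
  ave(p, family, FUN = function(v) p.adjust(v, method = "BH"))
}

## ---- cohort-level battery ---------------------------------------------------

corrFeatures <- function() c("ab_ratio", "lzc", "apen")

#' Run the full statistical battery on a cohort's hemisphere summary
#'
#' Within-group T0-vs-T1 paired t-tests and between-group-at-T1 independent
#' t-tests for every available EEG feature, Benjamini-Hochberg correction
#' within each contrast family (one family per group for the within-group
#' tests, one for the between-group tests), baseline comparability tests
#' (age and baseline NIHSS by t; sex and infarct side by chi-square),
#' clinical NIHSS tests, and Pearson correlations of the
#' experimental-group T1 features with the NIHSS improvement.
#'
#' Clinical and baseline rows are not FDR-corrected (`q_fdr = NA`); the
#' corrected families span EEG features only.
#'
#' @param summary hemisphere summary from [hemisphereFeatures()].
#' @param cohort cohort metadata (with `delta_nihss`, as from
#'   [validateCohort()]).
#' @param pooled pooled-variance independent t (default `TRUE`).
#' @return List with `stats` (contrast table), `correlations`, and
#'   `baseline`.
#' @export
analyzeCohort <- function(summary, cohort, pooled = TRUE) {
  if (!"delta_nihss" %in% names(cohort))
    cohort <- validateCohort(cohort, strict = "none")
  feats <- intersect(c(featureNames(), "ab_ratio"), names(summary))
  feats <- feats[vapply(feats, function(f) !anyNA(summary[[f]]), TRUE)]
  wide <- merge(summary[summary$session == "T0", c("subject_id", feats)],
                summary[summary$session == "T1", c("subject_id", feats)],
                by = "subject_id", suffixes = c("_T0", "_T1"))
  wide <- merge(wide, cohort[, c("subject_id", "group", "delta_nihss")],
                by = "subject_id")
  ## degenerate inputs (e.g. zero-variance differences in tiny cohorts)
  ## yield NA rows rather than aborting the whole battery
  safely <- function(call) tryCatch(call, error = function(e)
    list(statistic = NA_real_, df = NA_real_, p = NA_real_))
  srow <- function(contrast, feature, group, h, family) {
    data.frame(contrast = contrast, feature = feature, group = group,
               stat = h$statistic, df = h$df, p_raw = h$p,
               q_fdr = NA_real_,
               mean_a = if (!is.null(h$meanA)) h$meanA else NA_real_,
               sd_a = if (!is.null(h$sdA)) h$sdA else NA_real_,
               mean_b = if (!is.null(h$meanB)) h$meanB else NA_real_,
               sd_b = if (!is.null(h$sdB)) h$sdB else NA_real_,
               family = family)
  }
  rows <- list()
  for (g in c("experimental", "control")) {
    d <- wide[wide$group == g, ]
    for (f in feats) {
      x0 <- d[[paste0(f, "_T0")]]; x1 <- d[[paste0(f, "_T1")]]
      h <- safely(pairedT(x0, x1))
      r <- srow("within_group_T0_vs_T1", f, g, h, paste0("within_", g))
      r$mean_a <- mean(x0); r$sd_a <- sd(x0)
      r$mean_b <- mean(x1); r$sd_b <- sd(x1)
      rows[[length(rows) + 1L]] <- r
    }
    ## clinical NIHSS change within group
    cg <- cohort[cohort$group == g, ]
    h <- safely(pairedT(cg$nihss_t0, cg$nihss_t1))
    r <- srow("within_group_T0_vs_T1", "nihss", g, h, NA_character_)
    r$mean_a <- mean(cg$nihss_t0); r$sd_a <- sd(cg$nihss_t0)
    r$mean_b <- mean(cg$nihss_t1); r$sd_b <- sd(cg$nihss_t1)
    rows[[length(rows) + 1L]] <- r
  }
  for (f in feats) {
    e <- wide[wide$group == "experimental", paste0(f, "_T1")]
    c0 <- wide[wide$group == "control", paste0(f, "_T1")]
    h <- safely(independentT(e, c0, pooled))
    rows[[length(rows) + 1L]] <-
      srow("between_group_at_T1", f, "both", h, "between_T1")
  }
  h <- safely(independentT(cohort$delta_nihss[cohort$group == "experimental"],
                           cohort$delta_nihss[cohort$group == "control"],
                           pooled))
  rows[[length(rows) + 1L]] <-
    srow("between_group_at_T1", "delta_nihss", "both", h, NA_character_)
  stats <- do.call(rbind, rows)
  inFam <- !is.na(stats$family)
  stats$q_fdr[inFam] <- bhFdr(stats$p_raw[inFam], stats$family[inFam])

  ## baseline comparability
  bl <- list()
  for (f in c("age", "nihss_t0")) {
    h <- safely(independentT(cohort[[f]][cohort$group == "experimental"],
                             cohort[[f]][cohort$group == "control"], pooled))
    bl[[length(bl) + 1L]] <- data.frame(feature = f, test = "t",
                                        stat = h$statistic, df = h$df,
                                        p = h$p)
  }
  for (f in c("sex", "infarct_side")) {
    tab <- table(cohort$group, cohort[[f]])
    h <- tryCatch(chiSquareTest(tab),
                  error = function(e) list(statistic = NA_real_,
                                           df = NA_real_, p = NA_real_))
    bl[[length(bl) + 1L]] <- data.frame(feature = f, test = "chi-square",
                                        stat = h$statistic, df = h$df,
                                        p = h$p)
  }
  baseline <- do.call(rbind, bl)

  ## correlations: experimental group, T1 features vs NIHSS improvement
  de <- wide[wide$group == "experimental", ]
  cf <- intersect(corrFeatures(), feats)
  correlations <- do.call(rbind, lapply(cf, function(f) {
    h <- tryCatch(pearsonCorr(de[[paste0(f, "_T1")]], de$delta_nihss),
                  error = function(e) list(r = NA_real_, p = NA_real_,
                                           n = nrow(de)))
    data.frame(feature = f, r = h$r, p = h$p, n = h$n)
  }))
  list(stats = stats, correlations = correlations, baseline = baseline)
}

#' Type-I-error calibration under a null simulation
#'
#' Both groups are generated from the same specification (the control-group
#' targets at both timepoints), the band-power pipeline is run, and the
#' fraction of FDR-corrected EEG comparisons with `q < alpha` is reported.
#' Under the null that fraction should not exceed `alpha` (up to binomial
#' sampling error).
#'
#' @param nReps number of simulated cohorts.
#' @param nPerGroup subjects per group in each replicate.
#' @param seed master seed; replicate r uses `seed + r`.
#' @param alpha significance level (default 0.05).
#' @param durationS,fs signal parameters for the replicates.
#' @return List with `fraction` (of q-values below `alpha`), `nTests`,
#'   `perFamily` fractions, and the binomial bound
#'   `alpha + 2 * sqrt(alpha * (1 - alpha) / nTests)`.
#' @export
nullCalibration <- function(nReps, nPerGroup = 15, seed = 1, alpha = 0.05,
                            durationS = 20, fs = 1000) {
  bf <- defaultBandFractions()
  ctrl <- bf["control", "T0", "affected", ]
  bf[, , "affected", ] <- rep(ctrl, each = 4L)
  bf[, , "healthy", ] <- rep(ctrl, each = 4L)
  cl <- defaultComplexityLevel()
  cl[, ] <- 0.6
  qs <- list()
  for (r in seq_len(nReps)) {
    spec <- cohortSpec(nPerGroup = nPerGroup, seed = seed + r, fs = fs,
                       durationS = durationS, bandFractions = bf,
                       complexityLevel = cl)
    cs <- synthCohort(spec)
    fx <- cohortFeatures(cs$recordings, features = "rpsd")
    hs <- hemisphereFeatures(fx, cs$cohort)
    an <- analyzeCohort(hs$summary, cs$cohort)
    ok <- !is.na(an$stats$family)
    qs[[r]] <- data.frame(family = an$stats$family[ok],
                          q = an$stats$q_fdr[ok])
  }
  qs <- do.call(rbind, qs)
  nTests <- nrow(qs)
  list(fraction = mean(qs$q < alpha),
       nTests = nTests,
       perFamily = tapply(qs$q < alpha, qs$family, mean),
       bound = alpha + 2 * sqrt(alpha * (1 - alpha) / nTests))
}
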