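## Synthetic EEG cohort generator.
##
## Signals are sums of band-limited Gaussian noise (constructed in the
## frequency domain, so Parseval makes the placed band variances exact) and
## per-band sinusoids whose share of each band's variance is controlled by a
## single complexity knob. Group-level calibration targets reproduce the
## study conditions: two groups x two sessions, affected- vs
## healthy-hemisphere electrode sets, NIHSS scores linearly linked to the
## post-treatment alpha/beta power ratio.

normRow <- function(x) x / sum(x)

defaultBandFractions <- function() {
  ## group x session x hemisphere x band; affected-hemisphere values follow
  ## the study's printed group means (rows normalized to the simplex);
  ## control values are reused at T1 and for the healthy hemisphere, which
  ## the study reports as unchanged.
  expT0 <- normRow(c(46.3, 25.1, 18.2, 11.3))
  expT1 <- normRow(c(36.3, 21.8, 24.5, 18.6))
  ctrl <- normRow(c(42.8, 23.7, 17.9, 11.6))
  a <- array(NA_real_, c(2L, 2L, 2L, 4L),
             dimnames = list(group = c("experimental", "control"),
                             session = c("T0", "T1"),
                             hemisphere = c("affected", "healthy"),
                             band = eegBands()$name))
  a["experimental", "T0", "affected", ] <- expT0
  a["experimental", "T1", "affected", ] <- expT1
  a["control", "T0", "affected", ] <- ctrl
  a["control", "T1", "affected", ] <- ctrl
  a[, , "healthy", ] <- rep(ctrl, each = 4L)
  a
}

defaultComplexityLevel <- function() {
  matrix(c(0.6, 0.9, 0.6, 0.6), 2L, 2L, byrow = TRUE,
         dimnames = list(c("experimental", "control"), c("T0", "T1")))
}

defaultNihssModel <- function() {
  list(experimental = list(intercept = 7.2, slope = 2.55, noiseSd = 1.63),
       control = list(intercept = 4.5, slope = 1.37, noiseSd = 1.5))
}

#' CohortSpec: parameters of the synthetic cohort
#'
#' Use [cohortSpec()] to construct; defaults encode the study conditions
#' the package emulates.
#'
#' @slot nPerGroup subjects per group.
#' @slot seed master RNG seed; per-subject streams are derived
#'   arithmetically so cohorts are extensible without reshuffling.
#' @slot fs sampling rate (Hz).
#' @slot durationS recording duration (s).
#' @slot amplitudeUv RMS amplitude per channel (microvolts).
#' @slot bandFractions 4-d array group x session x hemisphere x band of
#'   target analyzed band fractions (each 4-vector sums to 1).
#' @slot complexityLevel group x session matrix in `[0, 1]`; the broadband
#'   share of each band's variance (1 = pure noise, 0 = pure tones).
#' @slot complexitySd per-subject SD of the complexity level.
#' @slot concentration Dirichlet concentration of per-subject band-fraction
#'   heterogeneity around the group targets.
#' @slot nihssModel per-group list (`intercept`, `slope`, `noiseSd`) linking
#'   NIHSS improvement to the subject's realized T1 affected-hemisphere
#'   alpha/beta ratio.
#' @slot targetCorr the Pearson correlation the experimental-group model is
#'   calibrated for (documentation; the slope/noise encode it).
#' @slot toneFreqs per-band tone frequencies (Hz).
#' @slot compensate pre-distort band variances through the analysis chain's
#'   attribution response so analyzed fractions land on target.
#' @export
setClass("CohortSpec",
  representation(nPerGroup = "numeric", seed = "numeric", fs = "numeric",
                 durationS = "numeric", amplitudeUv = "numeric",
                 bandFractions = "array", complexityLevel = "matrix",
                 complexitySd = "numeric", concentration = "numeric",
                 nihssModel = "list", targetCorr = "numeric",
                 toneFreqs = "numeric", compensate = "logical"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPerGroup < 2) msg <- c(msg, "nPerGroup must be >= 2")
  if (object@fs < 60) msg <- c(msg, "fs must be >= 60 Hz (Nyquist above 30)")
  if (object@durationS < 4) msg <- c(msg, "durationS must be >= 4 s")
  s <- apply(object@bandFractions, c(1L, 2L, 3L), sum)
  if (any(abs(s - 1) > 1e-9))
    msg <- c(msg, "each band-fraction 4-vector must sum to 1")
  if (any(object@bandFractions < 0))
    msg <- c(msg, "band fractions must be non-negative")
  if (any(object@complexityLevel < 0 | object@complexityLevel > 1))
    msg <- c(msg, "complexity levels must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic-cohort specification
#'
#' @param nPerGroup subjects per group (default 40).
#' @param seed master seed (default 1).
#' @param fs,durationS,amplitudeUv signal parameters; defaults 1000 Hz,
#'   20 s, 20 uV RMS.
#' @param bandFractions,complexityLevel,complexitySd,concentration,nihssModel,targetCorr,toneFreqs,compensate
#'   see [CohortSpec-class]; defaults encode the emulated study conditions.
#' @return A validated [CohortSpec-class].
#' @export
#' @examples
#' spec <- cohortSpec(nPerGroup = 3, seed = 7)
#' spec
cohortSpec <- function(nPerGroup = 40, seed = 1, fs = 1000, durationS = 20,
                       amplitudeUv = 20,
                       bandFractions = defaultBandFractions(),
                       complexityLevel = defaultComplexityLevel(),
                       complexitySd = 0.05, concentration = 60,
                       nihssModel = defaultNihssModel(),
                       targetCorr = 0.632,
                       toneFreqs = c(2.5, 6, 10, 21.5),
                       compensate = TRUE) {
  new("CohortSpec", nPerGroup = nPerGroup, seed = seed, fs = fs,
      durationS = durationS, amplitudeUv = amplitudeUv,
      bandFractions = bandFractions, complexityLevel = complexityLevel,
      complexitySd = complexitySd, concentration = concentration,
      nihssModel = nihssModel, targetCorr = targetCorr,
      toneFreqs = toneFreqs, compensate = compensate)
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d subjects/group, %g s @ %g Hz, seed %g\n",
              object@nPerGroup, object@durationS, object@fs, object@seed))
  cat(sprintf("  concentration %g, complexity levels [%s], compensate=%s\n",
              object@concentration,
              paste(format(object@complexityLevel), collapse = ", "),
              object@compensate))
})

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- alpha            # pathological underflow guard
  g / sum(g)
}

## Frequency-domain synthesis of one multichannel recording.
## fracs: nCh x 4 matrix of generated band variance fractions;
## levels: per-channel broadband share; tonePhase: per-channel constant
## phase of the band tones (zero-sum within hemisphere triples in cohort
## use, so the average reference cancels the coherent part exactly).
## Unit total variance per channel, scaled to amplitudeUv RMS.
synthChannels <- function(fracs, levels, fs, durationS, amplitudeUv,
                          toneFreqs, tonePhase = rep(0, nrow(fracs))) {
  n <- round(durationS * fs)
  nCh <- nrow(fracs)
  bands <- eegBands()
  fgrid <- (seq_len(n %/% 2L - 1L)) / durationS   # bins 1 .. n/2-1
  H <- matrix(0 + 0i, n, nCh)
  tt <- seq_len(n) / fs
  x <- matrix(0, nCh, n)
  maskIdx <- lapply(seq_len(4L), function(b) {
    if (b < 4L) which(fgrid >= bands$lo[b] & fgrid < bands$hi[b])
    else which(fgrid >= bands$lo[b] & fgrid <= bands$hi[b])
  })
  for (ch in seq_len(nCh)) {
    lev <- levels[ch]
    for (b in seq_len(4L)) {
      idx <- maskIdx[[b]]
      vNoise <- fracs[ch, b] * lev
      if (vNoise > 0 && length(idx)) {
        sj <- sqrt(vNoise * n^2 / (4 * length(idx)))
        H[idx + 1L, ch] <- H[idx + 1L, ch] +
          complex(real = rnorm(length(idx), 0, sj),
                  imaginary = rnorm(length(idx), 0, sj))
      }
      vTone <- fracs[ch, b] * (1 - lev)
      if (vTone > 0)
        x[ch, ] <- x[ch, ] + sqrt(2 * vTone) *
          cos(2 * pi * toneFreqs[b] * tt + tonePhase[ch])
    }
  }
  ## hermitian completion and one inverse FFT for all channels
  H[n:(n %/% 2L + 2L), ] <- Conj(H[2:(n %/% 2L), ])
  x <- x + t(Re(mvfft(H, inverse = TRUE)) / n)
  x * amplitudeUv
}

#' Synthesize a single EEG channel with prescribed band composition
#'
#' The signal is a sum of band-limited Gaussian noise (FFT-domain
#' construction) and fixed per-band sinusoids; `complexityLevel` sets the
#' broadband share of each band's variance (1 = pure noise, 0 = pure
#' tones), so increasing it increases signal complexity without changing
#' band power. With `compensate = TRUE` (default) the placed variances are
#' pre-distorted through [bandTransfer()] so the band fractions recovered
#' by the default analysis chain match `bandFractions` in expectation.
#'
#' @param bandFractions 4-vector of target band fractions (delta, theta,
#'   alpha, beta), summing to 1.
#' @param complexityLevel scalar in `[0, 1]`.
#' @param durationS duration (s), at least 4.
#' @param fs sampling rate (Hz), at least 60.
#' @param seed optional seed for reproducibility.
#' @param amplitudeUv RMS amplitude (microvolts).
#' @param toneFreqs per-band tone frequencies (Hz).
#' @param compensate pre-distort through the analysis-chain response.
#' @return Numeric vector of length `durationS * fs` (microvolts).
#' @export
#' @examples
#' x <- synthSignal(c(0, 0, 1, 0), complexityLevel = 0, durationS = 4,
#'                  fs = 200, seed = 1, compensate = FALSE)  # 10 Hz tone
synthSignal <- function(bandFractions, complexityLevel = 1, durationS = 20,
                        fs = 1000, seed = NULL, amplitudeUv = 20,
                        toneFreqs = c(2.5, 6, 10, 21.5), compensate = TRUE) {
  if (abs(sum(bandFractions) - 1) > 1e-9)
    stop("band fractions must sum to 1")
  if (any(bandFractions < 0)) stop("band fractions must be non-negative")
  if (durationS < 4) stop("durationS must be >= 4 s")
  if (fs < 60) stop("fs must be >= 60 Hz")
  if (!is.null(seed)) set.seed(seed)
  g <- if (compensate)
    compensateFractions(bandFractions, complexityLevel,
                        bandTransfer(fs, durationS, toneFreqs = toneFreqs))
  else bandFractions
  drop(synthChannels(matrix(g, 1L), complexityLevel, fs, durationS,
                     amplitudeUv, toneFreqs))
}

subjectSeed <- function(masterSeed, i) {
  (((masterSeed %% 1000003) * 1009 + i * 7919) %% 2147483629) + 1
}

affectedChannels <- function(side) {
  if (side == "left") c("C3", "P3", "O1") else c("C4", "P4", "O2")
}

#' Generate a synthetic two-group, two-timepoint EEG cohort
#'
#' For each subject, per-session band-fraction targets are drawn from a
#' Dirichlet distribution around the group targets (affected- and
#' healthy-hemisphere electrode sets separately), six-channel recordings
#' are synthesized for T0 and T1, and NIHSS scores are generated with the
#' improvement linearly linked to the subject's realized T1
#' affected-hemisphere alpha/beta ratio. Fully reproducible from the spec's
#' seed; per-subject streams are derived arithmetically, so enlarging the
#' cohort does not reshuffle existing subjects.
#'
#' @param spec a [cohortSpec()].
#' @param sessions sessions to synthesize recordings for (metadata always
#'   covers both).
#' @return List with `recordings` (named list of [EEGRecording-class],
#'   names `<subject>_<session>`) and `cohort` (metadata data frame as from
#'   [readCohortCSV()]).
#' @export
#' @examples
#' cs <- synthCohort(cohortSpec(nPerGroup = 2, durationS = 4, fs = 250))
#' cs$cohort
synthCohort <- function(spec, sessions = c("T0", "T1")) {
  validObject(spec)
  n2 <- 2L * spec@nPerGroup
  bands <- eegBands()$name
  transfer <- if (spec@compensate)
    bandTransfer(spec@fs, spec@durationS, toneFreqs = spec@toneFreqs)
  else NULL
  recs <- list()
  rows <- vector("list", n2)
  for (i in seq_len(n2)) {
    grp <- if (i <= spec@nPerGroup) "experimental" else "control"
    ## metadata stream: covariates and per-session targets; signal synthesis
    ## uses its own derived streams so that generating a subset of sessions
    ## leaves the metadata unchanged
    set.seed(subjectSeed(spec@seed, i))
    side <- if (runif(1) < 0.5) "left" else "right"
    sex <- if (runif(1) < 0.5) "male" else "female"
    age <- sample(40:80, 1L)
    nihssT0 <- sample(5:20, 1L)
    sid <- sprintf("s%03d", i)
    affCh <- affectedChannels(side)
    chans <- requiredChannels()
    isAff <- chans %in% affCh
    fA <- fH <- list()
    lv <- c(T0 = NA_real_, T1 = NA_real_)
    for (ses in c("T0", "T1")) {
      fA[[ses]] <- rdirichlet1(spec@concentration *
                                 spec@bandFractions[grp, ses, "affected", ])
      fH[[ses]] <- rdirichlet1(spec@concentration *
                                 spec@bandFractions[grp, ses, "healthy", ])
      lv[ses] <- min(1, max(0.02, spec@complexityLevel[grp, ses] +
                              rnorm(1L, 0, spec@complexitySd)))
    }
    nihssNoise <- rnorm(1L)
    for (ses in intersect(c("T0", "T1"), sessions)) {
      lev <- lv[[ses]]
      if (spec@compensate) {
        um <- jointCompensate(fA[[ses]], fH[[ses]], lev, transfer)
        gA <- um$aff; gH <- um$heal
      } else {
        gA <- fA[[ses]]; gH <- fH[[ses]]
      }
      fr <- matrix(0, 6L, 4L)
      fr[isAff, ] <- matrix(gA, 3L, 4L, byrow = TRUE)
      fr[!isAff, ] <- matrix(gH, 3L, 4L, byrow = TRUE)
      ## zero-sum tone phases within each hemisphere triple
      ph <- numeric(6L)
      ph[isAff] <- 2 * pi * (0:2) / 3
      ph[!isAff] <- 2 * pi * (0:2) / 3
      set.seed((subjectSeed(spec@seed, i) +
                  match(ses, c("T0", "T1")) * 1000003) %% 2147483629 + 1)
      x <- synthChannels(fr, rep(lev, 6L), spec@fs, spec@durationS,
                         spec@amplitudeUv, spec@toneFreqs, tonePhase = ph)
      rownames(x) <- chans
      recs[[paste0(sid, "_", ses)]] <-
        EEGRecording(x, fs = spec@fs, subjectId = sid, session = ses)
    }
    ratioT1 <- fA[["T1"]][3L] / fA[["T1"]][4L]
    mdl <- spec@nihssModel[[grp]]
    refRatio <- spec@bandFractions[grp, "T1", "affected", "alpha"] /
      spec@bandFractions[grp, "T1", "affected", "beta"]
    dn <- round(mdl$intercept + mdl$slope * (ratioT1 - refRatio) +
                  nihssNoise * mdl$noiseSd)
    dn <- min(dn, nihssT0)                 # nihss_t1 >= 0
    dn <- max(dn, nihssT0 - 42L)           # nihss_t1 <= scale maximum
    rows[[i]] <- data.frame(subject_id = sid, group = grp,
                            infarct_side = side, age = age, sex = sex,
                            nihss_t0 = nihssT0, nihss_t1 = nihssT0 - dn)
  }
  cohort <- validateCohort(do.call(rbind, rows), strict = "none")
  list(recordings = recs, cohort = cohort)
}

#' Write a synthetic cohort to disk as EDF files plus cohort.csv
#'
#' @param spec a [cohortSpec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeSynthCohort <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cs <- synthCohort(spec)
  for (nm in names(cs$recordings))
    writeEDF(cs$recordings[[nm]], file.path(dir, paste0(nm, ".edf")))
  writeCohortCSV(cs$cohort, file.path(dir, "cohort.csv"))
  invisible(dir)
}
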