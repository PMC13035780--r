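## Band-attribution transfer of the analysis chain.
##
## A 1-s Welch window smears spectral energy by about +/-1 Hz and the 1-45 Hz
## Butterworth bandpass attenuates the lower delta range, so the band power
## the pipeline ATTRIBUTES to a band differs systematically from the power a
## generator PLACES in it (for delta the misattribution reaches several
## percentage points). The functions here measure that linear response
## exactly, by probing the package's own analysis path with sinusoidal
## lines, and invert it so the synthetic generator can place power such that
## the analyzed band fractions land on target.

transferCache <- new.env(parent = emptyenv())

## Absolute band powers attributed to a unit-variance sinusoid at f Hz.
## Averaging the two probe phases {0, pi/2} gives the uniform-phase
## expectation exactly, because the whole chain is linear in the signal and
## quadratic in the spectrum.
lineAttribution <- function(f, fs, durationS, welch, pre, bandpass) {
  tt <- seq_len(round(durationS * fs)) / fs
  a <- vapply(c(0, pi / 2), function(phi) {
    r <- signalRpsd(sqrt(2) * cos(2 * pi * f * tt + phi), fs,
                    welch = welch, pre = pre, bandpass = bandpass)
    r$rpsd * r$totalPower
  }, numeric(4L))
  rowMeans(a)
}

#' Band-attribution transfer matrices of the analysis chain
#'
#' Column `b` of `noise` gives the absolute band powers the default analysis
#' chain attributes to unit power spread uniformly over band `b`; column `b`
#' of `tone` does the same for a unit-power sinusoid at that band's tone
#' frequency. Results are cached per configuration.
#'
#' @param fs sampling rate (Hz).
#' @param durationS probe duration in seconds (matching the recording
#'   length analyzed).
#' @param welch a [welchConfig()].
#' @param pre a [preprocessConfig()].
#' @param toneFreqs per-band tone frequencies (Hz).
#' @param bandpass include the bandpass stage in the probed chain?
#' @param gridStep probe line spacing (Hz).
#' @return List with 4x4 matrices `noise` and `tone` (rows: attributed
#'   band; columns: source band).
#' @export
bandTransfer <- function(fs = 1000, durationS = 20, welch = welchConfig(),
                         pre = preprocessConfig(),
                         toneFreqs = c(2.5, 6, 10, 21.5),
                         bandpass = TRUE, gridStep = 0.1) {
  key <- paste(fs, durationS, welch$windowLength, welch$overlap, welch$taper,
               paste(welch$totalBand, collapse = ","),
               pre$bpLo, pre$bpHi, pre$epochLength, pre$order,
               paste(toneFreqs, collapse = ","), bandpass, gridStep,
               sep = "|")
  hit <- transferCache[[key]]
  if (!is.null(hit)) return(hit)
  bands <- eegBands()
  noise <- matrix(0, 4L, 4L, dimnames = list(bands$name, bands$name))
  for (b in seq_len(4L)) {
    fgrid <- seq(bands$lo[b] + gridStep / 2, bands$hi[b] - gridStep / 2,
                 by = gridStep)
    att <- vapply(fgrid, lineAttribution, numeric(4L), fs = fs,
                  durationS = durationS, welch = welch, pre = pre,
                  bandpass = bandpass)
    noise[, b] <- rowMeans(att)
  }
  tone <- vapply(toneFreqs, lineAttribution, numeric(4L), fs = fs,
                 durationS = durationS, welch = welch, pre = pre,
                 bandpass = bandpass)
  dimnames(tone) <- dimnames(noise)
  out <- list(noise = noise, tone = tone)
  transferCache[[key]] <- out
  out
}

#' Pre-distort band fractions so the analyzed fractions hit their targets
#'
#' Solves the linear attribution system for the per-band generated variances
#' `g` such that the expected analyzed relative band power equals `target`.
#' Negative solutions (possible for extreme targets) are clipped to zero and
#' the result renormalized.
#'
#' @param target desired analyzed band fractions (4-vector summing to 1).
#' @param complexityLevel broadband mixing weight in `[0, 1]`; `1 - level`
#'   of each band's variance is carried by its tone.
#' @param transfer a [bandTransfer()] result.
#' @return Generated band variance fractions (4-vector summing to 1).
#' @export
compensateFractions <- function(target, complexityLevel, transfer) {
  Tm <- complexityLevel * transfer$noise +
    (1 - complexityLevel) * transfer$tone
  g <- tryCatch(solve(Tm, target), error = function(e) target)
  g[g < 0] <- 0
  s <- sum(g)
  if (s <= 0) return(target)
  g / s
}

## Joint pre-distortion for a montage of nAff affected + nHeal healthy
## channels behind an average reference. Independent noise mixes across
## channels in power (weights from the reference algebra); the per-band
## tones are generated with zero-sum phases within each hemisphere triple,
## so the reference leaves them exactly unchanged (identity mixing). The
## 8x8 linear system below makes the expected analyzed band fractions of
## both hemispheres hit their targets simultaneously.
jointCompensate <- function(fAff, fHeal, complexityLevel, transfer,
                            nAff = 3L, nHeal = 3L) {
  k <- nAff + nHeal
  wSA <- ((k - 1)^2 + (nAff - 1)) / k^2
  wOA <- nHeal / k^2
  wSH <- ((k - 1)^2 + (nHeal - 1)) / k^2
  wOH <- nAff / k^2
  lev <- complexityLevel
  Tn <- transfer$noise
  Tt <- transfer$tone
  AA <- lev * wSA * Tn + (1 - lev) * Tt
  BA <- lev * wOA * Tn
  AH <- lev * wSH * Tn + (1 - lev) * Tt
  BH <- lev * wOH * Tn
  M <- rbind(cbind(AA, BA), cbind(BH, AH))
  g <- tryCatch(solve(M, c(fAff, fHeal)),
                error = function(e) c(fAff, fHeal))
  g[g < 0] <- 0
  s <- (sum(g[1:4]) + sum(g[5:8])) / 2
  if (s <= 0) return(list(aff = fAff, heal = fHeal))
  list(aff = g[1:4] / s, heal = g[5:8] / s)
}
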