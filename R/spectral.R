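## Welch power spectral density and relative band power.

#' Canonical EEG frequency bands
#'
#' Delta 1-4, theta 4-8, alpha 8-13, beta 13-30 Hz. Bands share edges; band
#' power integration apportions shared PSD bins so no energy is counted
#' twice (see [bandRpsd()]).
#'
#' @return Data frame with columns `name`, `lo`, `hi`.
#' @export
eegBands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             lo = c(1, 4, 8, 13), hi = c(4, 8, 13, 30))
}

#' Welch spectral estimation configuration
#'
#' @param windowLength segment length in seconds (default 1 s).
#' @param overlap fractional overlap between segments in `[0, 1)`
#'   (default 0.5).
#' @param taper `"hann"` (default), `"hamming"` or `"boxcar"`.
#' @param totalBand frequency range (Hz) whose power normalizes the relative
#'   band power (default `c(1, 30)`).
#' @return A list of class `WelchConfig`.
#' @export
welchConfig <- function(windowLength = 1, overlap = 0.5, taper = "hann",
                        totalBand = c(1, 30)) {
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  taper <- match.arg(taper, c("hann", "hamming", "boxcar"))
  structure(list(windowLength = windowLength, overlap = overlap,
                 taper = taper, totalBand = totalBand),
            class = "WelchConfig")
}

taperWindow <- function(n, type) {
  switch(type,
    hann = 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n),   # periodic Hann
    hamming = 0.54 - 0.46 * cos(2 * pi * seq_len(n) / n),
    boxcar = rep(1, n),
    stop("unknown taper: ", type))
}

## Core estimator on a matrix whose columns are equal-length segments.
## Each segment is mean-detrended, tapered, and its one-sided periodogram
## computed; segments are averaged. Scaling is such that
## sum(psd) * df == mean segment variance (discrete Parseval).
welchPsdSegments <- function(segs, fs, taper = "hann") {
  nfft <- nrow(segs)
  w <- taperWindow(nfft, taper)
  segs <- sweep(segs, 2L, colMeans(segs))
  X <- mvfft(segs * w)
  nf <- nfft %/% 2L + 1L
  p <- rowMeans(Mod(X[seq_len(nf), , drop = FALSE])^2)
  scale <- 1 / (fs * sum(w^2))
  p <- p * scale
  ## one-sided: double everything except DC (and Nyquist when nfft is even)
  dbl <- rep(2, nf)
  dbl[1L] <- 1
  if (nfft %% 2L == 0L) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * fs / nfft, psd = p * dbl)
}

segmentStarts <- function(n, nfft, overlap) {
  step <- max(1L, round(nfft * (1 - overlap)))
  seq.int(1L, n - nfft + 1L, by = step)
}

#' Welch power spectral density
#'
#' Averaged mean-detrended, tapered periodograms over overlapping segments.
#' The estimate is one-sided and satisfies the discrete Parseval identity:
#' `sum(psd) * df` equals the average detrended segment variance.
#'
#' @param x numeric signal (microvolts).
#' @param fs sampling rate in Hz.
#' @param config a [welchConfig()].
#' @return List with `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
#' @examples
#' s <- sin(2 * pi * 10 * seq(0, 4, by = 1 / 250))
#' p <- welchPsd(s, 250)
#' p$freq[which.max(p$psd)]  # 10
welchPsd <- function(x, fs, config = welchConfig()) {
  x <- as.numeric(x)
  nfft <- round(config$windowLength * fs)
  if (length(x) < nfft)
    stop("signal (", length(x), " samples) is shorter than the Welch window (",
         nfft, " samples)")
  starts <- segmentStarts(length(x), nfft, config$overlap)
  segs <- vapply(starts, function(s) x[s:(s + nfft - 1L)], numeric(nfft))
  welchPsdSegments(matrix(segs, nrow = nfft), fs, config$taper)
}

#' Relative band power from a PSD
#'
#' Band power is a rectangle-rule integral in which each PSD bin represents
#' the `df`-wide frequency interval centred on it; a bin lying on a shared
#' band edge is apportioned pro rata to the two bands, so the four bands
#' tile the total band exactly and no energy is double counted. Fractions
#' are normalized by the power in `totalBand`.
#'
#' @param freq frequency grid (Hz), equally spaced.
#' @param psd PSD values on `freq`.
#' @param bands band definition table, default [eegBands()].
#' @param totalBand normalization range, default `c(1, 30)` Hz.
#' @return List with `rpsd` (named fractions summing to 1) and `totalPower`
#'   (uV^2 in `totalBand`).
#' @export
bandRpsd <- function(freq, psd, bands = eegBands(), totalBand = c(1, 30)) {
  df <- diff(freq[1:2])
  if (min(freq) - df / 2 > totalBand[1] || max(freq) + df / 2 < totalBand[2])
    stop("frequency grid does not cover the total band [",
         totalBand[1], ", ", totalBand[2], "] Hz")
  binW <- function(lo, hi) {
    ## overlap of each bin interval [f - df/2, f + df/2) with [lo, hi)
    pmax(0, pmin(freq + df / 2, hi) - pmax(freq - df / 2, lo)) / df
  }
  totalPower <- sum(psd * binW(totalBand[1], totalBand[2])) * df
  bp <- vapply(seq_len(nrow(bands)), function(i)
    sum(psd * binW(bands$lo[i], bands$hi[i])) * df, 0)
  names(bp) <- bands$name
  if (totalPower <= 0) stop("total band power is zero")
  list(rpsd = bp / totalPower, totalPower = totalPower)
}

#' Epoch-averaged relative band power for one channel
#'
#' Welch segments are pooled across the epochs (no window spans an epoch
#' boundary), their periodograms averaged, and band power integrated once
#' from the averaged PSD.
#'
#' @param epochSet an [EpochSet-class].
#' @param channel channel label.
#' @param config a [welchConfig()].
#' @return List with `subjectId`, `session`, `channel`, `rpsd` (named
#'   fractions) and `totalPower`.
#' @export
epochAverageRpsd <- function(epochSet, channel, config = welchConfig()) {
  stopifnot(is(epochSet, "EpochSet"))
  ch <- match(normalizeChannelLabel(channel),
              normalizeChannelLabel(channelNames(epochSet)))
  if (is.na(ch)) stop("channel not present: ", channel)
  sp <- channelPsds(epochSet, channelNames(epochSet)[ch], config)
  br <- bandRpsd(sp$freq, sp$psd[, 1L], totalBand = config$totalBand)
  list(subjectId = subjectId(epochSet), session = session(epochSet),
       channel = channelNames(epochSet)[ch], rpsd = br$rpsd,
       totalPower = br$totalPower)
}

## Pool Welch segments from a list of single-channel epochs into one matrix.
epochSegments <- function(epochList, fs, config) {
  nfft <- round(config$windowLength * fs)
  n <- length(epochList[[1L]])
  if (n < nfft) stop("epoch shorter than the Welch window")
  starts <- segmentStarts(n, nfft, config$overlap)
  idx <- outer(seq_len(nfft) - 1L, starts, `+`)
  do.call(cbind, lapply(epochList, function(x)
    matrix(x[idx], nrow = nfft)))
}

## Epoch-pooled Welch PSD for several channels at once (one FFT batch).
## Returns freq and an nf x nChannels PSD matrix.
channelPsds <- function(epochSet, channels, config = welchConfig()) {
  fs <- samplingRate(epochSet)
  eps <- epochs(epochSet)
  chIdx <- match(normalizeChannelLabel(channels),
                 normalizeChannelLabel(channelNames(epochSet)))
  if (anyNA(chIdx))
    stop("channel not present: ",
         paste(channels[is.na(chIdx)], collapse = ", "))
  nfft <- round(config$windowLength * fs)
  n <- ncol(eps[[1L]])
  if (n < nfft) stop("epoch shorter than the Welch window")
  starts <- segmentStarts(n, nfft, config$overlap)
  idx <- outer(seq_len(nfft) - 1L, starts, `+`)
  nSeg <- length(starts) * length(eps)
  segs <- matrix(0, nfft, nSeg * length(chIdx))
  for (k in seq_along(chIdx)) {
    off <- (k - 1L) * nSeg
    for (e in seq_along(eps)) {
      x <- eps[[e]][chIdx[k], ]
      cols <- off + (e - 1L) * length(starts) + seq_along(starts)
      segs[, cols] <- x[idx]
    }
  }
  sp <- welchPsdSegmentsGrouped(segs, fs, config$taper, nSeg)
  list(freq = sp$freq, psd = sp$psd)
}

## Like welchPsdSegments but averaging within consecutive groups of
## `groupSize` columns (one group per channel).
welchPsdSegmentsGrouped <- function(segs, fs, taper, groupSize) {
  nfft <- nrow(segs)
  w <- taperWindow(nfft, taper)
  segs <- sweep(segs, 2L, colMeans(segs))
  X <- mvfft(segs * w)
  nf <- nfft %/% 2L + 1L
  P <- Mod(X[seq_len(nf), , drop = FALSE])^2
  nCh <- ncol(segs) / groupSize
  p <- vapply(seq_len(nCh), function(k)
    rowMeans(P[, (k - 1L) * groupSize + seq_len(groupSize),
               drop = FALSE]), numeric(nf))
  dbl <- rep(2, nf)
  dbl[1L] <- 1
  if (nfft %% 2L == 0L) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * fs / nfft,
       psd = matrix(p * dbl / (fs * sum(w^2)), nrow = nf))
}

#' Band fractions of a single raw signal through the standard chain
#'
#' Applies the default analysis chain to one channel: zero-phase bandpass
#' (unless disabled), segmentation into epochs, pooled Welch PSD, and
#' relative band power. This is the per-channel path the cohort pipeline
#' uses, exposed for calibration and testing.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param welch a [welchConfig()].
#' @param pre a [preprocessConfig()]; only the bandpass corners, filter
#'   order and epoch length are used (no amplitude rejection).
#' @param bandpass apply the bandpass stage?
#' @return As [bandRpsd()].
#' @export
signalRpsd <- function(x, fs, welch = welchConfig(), pre = preprocessConfig(),
                       bandpass = TRUE) {
  x <- as.numeric(x)
  if (bandpass && !is.null(pre$bpLo) && !is.null(pre$bpHi))
    x <- bandpassFilter(x, pre$bpLo, pre$bpHi, fs = fs, order = pre$order)
  wlen <- round(pre$epochLength * fs)
  nEp <- max(1L, floor(length(x) / wlen))
  eps <- lapply(seq_len(nEp), function(w) x[((w - 1L) * wlen + 1L):(w * wlen)])
  segs <- epochSegments(eps, fs, welch)
  sp <- welchPsdSegments(segs, fs, welch$taper)
  bandRpsd(sp$freq, sp$psd, totalBand = welch$totalBand)
}
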