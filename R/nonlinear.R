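## Lempel-Ziv complexity and approximate entropy.

#' Binarize a signal around its median or mean
#'
#' Samples strictly above the threshold map to 1, the rest to 0. A constant
#' signal yields the all-zeros sequence (the threshold equals every sample)
#' with a degenerate-input warning.
#'
#' @param x numeric signal, length at least 2.
#' @param method `"median"` (default; invariant under strictly monotone
#'   amplitude transforms) or `"mean"`.
#' @return Integer vector of 0/1, same length as `x`.
#' @export
#' @examples
#' binarize(c(1, 3, 2, 5))  # 0 1 0 1
binarize <- function(x, method = c("median", "mean")) {
  method <- match.arg(method)
  if (length(x) < 2L) stop("need at least 2 samples")
  thr <- if (method == "median") median(x) else mean(x)
  if (max(x) == min(x))
    warning("constant signal: binarization yields the all-zeros sequence",
            call. = FALSE)
  as.integer(x > thr)
}

#' LZ76 exhaustive-history phrase count
#'
#' Parses a binary sequence by the scan-and-copy rule: each new phrase is
#' the shortest extension of the unparsed suffix that cannot be copied from
#' the extended history, with a one-symbol innovation allowed; an
#' unfinished reproducible tail counts as one phrase.
#'
#' @param s integer/numeric vector of 0s and 1s (or a character string of
#'   `"0"`/`"1"`).
#' @return The phrase count `c(n)`.
#' @export
#' @examples
#' lz76(c(0, 0, 0, 0))   # 2  ("0" | "000")
lz76 <- function(s) {
  if (is.character(s)) {
    stopifnot(length(s) == 1L)
    s <- as.integer(strsplit(s, "")[[1L]])
  }
  .lz76Count(as.integer(s))
}

#' Normalized Lempel-Ziv complexity of a signal
#'
#' The signal is binarized and parsed by the LZ76 rule; the phrase count is
#' normalized as `c(n) * log2(n) / n`, which tends to 1 for i.i.d. fair-coin
#' sequences as n grows. Higher values indicate a more complex, less
#' predictable signal.
#'
#' @param x numeric signal (length >= 2), or an already binary 0/1 vector
#'   when `binarization = "none"`.
#' @param binarization `"median"` (default), `"mean"`, or `"none"`.
#' @return List with `value` (normalized LZC), `count` (raw phrase count)
#'   and `n`.
#' @export
lzc <- function(x, binarization = c("median", "mean", "none")) {
  binarization <- match.arg(binarization)
  b <- if (binarization == "none") as.integer(x) else binarize(x, binarization)
  n <- length(b)
  if (n < 2L) stop("need at least 2 samples")
  cn <- .lz76Count(b)
  list(value = cn * log2(n) / n, count = cn, n = n)
}

#' Approximate entropy (Pincus)
#'
#' `ApEn(m, r) = Phi^m(r) - Phi^(m+1)(r)` with
#' `Phi^m(r) = (N-m+1)^-1 * sum_i log(C_i^m(r))`, where `C_i^m(r)` is the
#' fraction of templates within Chebyshev distance `r` of template `i`,
#' self-matches included. The tolerance is `rFrac` times the sample
#' standard deviation, so the measure is scale invariant. A constant series
#' returns 0 with a degenerate-input warning.
#'
#' @param x numeric series, length > m + 1.
#' @param m embedding dimension (default 2).
#' @param rFrac tolerance as a fraction of `sd(x)` (default 0.2).
#' @return The ApEn value (non-negative up to numerical jitter).
#' @export
apen <- function(x, m = 2L, rFrac = 0.2) {
  x <- as.numeric(x)
  if (m < 1L) stop("m must be >= 1")
  if (rFrac <= 0) stop("rFrac must be positive")
  if (length(x) <= m + 1L) stop("series too short for m = ", m)
  s <- sd(x)
  if (s == 0) {
    warning("constant series: ApEn is 0 by convention", call. = FALSE)
    return(0)
  }
  .apenCpp(x, as.integer(m), rFrac * s)
}

#' Epoch-averaged complexity features for one channel
#'
#' LZC and ApEn are computed per epoch and averaged, avoiding the
#' artificial discontinuities that concatenating epochs would introduce.
#'
#' @param epochSet an [EpochSet-class].
#' @param channel channel label.
#' @param lzcBinarization binarization method for [lzc()].
#' @param m,rFrac ApEn parameters, see [apen()].
#' @param what which measures to compute.
#' @return Named list with elements `lzc` and/or `apen`.
#' @export
epochComplexity <- function(epochSet, channel, lzcBinarization = "median",
                            m = 2L, rFrac = 0.2,
                            what = c("lzc", "apen")) {
  ch <- match(normalizeChannelLabel(channel),
              normalizeChannelLabel(channelNames(epochSet)))
  if (is.na(ch)) stop("channel not present: ", channel)
  out <- list()
  eps <- epochs(epochSet)
  if ("lzc" %in% what)
    out$lzc <- mean(vapply(eps, function(e)
      lzc(e[ch, ], lzcBinarization)$value, 0))
  if ("apen" %in% what)
    out$apen <- mean(vapply(eps, function(e)
      apen(e[ch, ], m = m, rFrac = rFrac), 0))
  out
}
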