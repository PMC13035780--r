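# Independent reference implementations used as oracles. They follow the
# textbook definitions directly and share no code with the package.

# LZ76 phrase count by the production definition: grow the candidate phrase
# until it no longer occurs in the extended history, one-symbol innovation
# included; a reproducible tail counts as one phrase.
lz76Oracle <- function(bits) {
  if (is.character(bits) && length(bits) == 1L) bits <- strsplit(bits, "")[[1L]]
  s <- paste(bits, collapse = "")
  n <- nchar(s); cc <- 0L; l <- 1L
  while (l <= n) {
    k <- 1L; done <- FALSE
    while (l + k - 1L <= n) {
      phrase <- substr(s, l, l + k - 1L)
      hist <- substr(s, 1L, l + k - 2L)
      if (!grepl(phrase, hist, fixed = TRUE)) {
        cc <- cc + 1L; l <- l + k; done <- TRUE; break
      }
      k <- k + 1L
    }
    if (!done) { cc <- cc + 1L; break }
  }
  cc
}

# Naive O(N^2) approximate entropy straight from the Pincus formulas
# (Chebyshev distance, self-matches included, natural log).
apenOracle <- function(x, m = 2L, r = 0.2 * sd(x)) {
  phi <- function(mm) {
    N <- length(x); nm <- N - mm + 1L
    tpl <- vapply(0:(mm - 1L), function(k) x[seq_len(nm) + k], numeric(nm))
    Ci <- vapply(seq_len(nm), function(i) {
      d <- apply(abs(tpl - matrix(tpl[i, ], nm, mm, byrow = TRUE)), 1L, max)
      mean(d <= r)
    }, 0)
    mean(log(Ci))
  }
  phi(m) - phi(m + 1L)
}

# Brute-force Benjamini-Hochberg: q(i) = min over j >= i of m * p(j) / j on
# sorted p-values, capped at 1.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), 0)
  out <- numeric(m)
  out[o] <- q
  out
}
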