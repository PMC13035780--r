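# Small in-code fixtures.

makeRec <- function(data, fs = 100, channels = NULL, subjectId = "s01",
                    session = "T0") {
  if (is.null(channels)) channels <- requiredChannels()[seq_len(nrow(data))]
  EEGRecording(data, fs = fs, channels = channels, subjectId = subjectId,
               session = session)
}

# A six-channel recording of independent white noise.
noiseRec <- function(fs = 250, durationS = 20, sdUv = 10, seed = 1,
                     subjectId = "s01", session = "T0") {
  set.seed(seed)
  n <- fs * durationS
  makeRec(matrix(rnorm(6 * n, sd = sdUv), nrow = 6), fs = fs,
          subjectId = subjectId, session = session)
}

tinyCohortDf <- function() {
  data.frame(subject_id = c("s01", "s02", "s03", "s04"),
             group = c("experimental", "experimental", "control", "control"),
             infarct_side = c("left", "right", "left", "right"),
             age = c(55L, 62L, 70L, 48L),
             sex = c("male", "female", "female", "male"),
             nihss_t0 = c(13L, 9L, 12L, 16L),
             nihss_t1 = c(6L, 5L, 9L, 12L))
}
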