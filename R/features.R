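## Per-channel feature extraction and affected-hemisphere summaries.

#' Compute per-channel features for one epoch set
#'
#' Relative band power (Welch, epoch-averaged PSD), normalized LZC and ApEn
#' (epoch-averaged) per channel.
#'
#' @param epochSet an [EpochSet-class].
#' @param welch a [welchConfig()].
#' @param features subset of `c("rpsd", "lzc", "apen")`.
#' @param channels channels to compute (default: all in the set).
#' @param lzcBinarization,m,rFrac complexity parameters, see
#'   [epochComplexity()].
#' @return Data frame with one row per channel and columns
#'   `subject_id, session, channel, delta, theta, alpha, beta,
#'   total_power, lzc, apen` (complexity columns are `NA` when not
#'   requested).
#' @export
computeFeatures <- function(epochSet, welch = welchConfig(),
                            features = c("rpsd", "lzc", "apen"),
                            channels = NULL, lzcBinarization = "median",
                            m = 2L, rFrac = 0.2) {
  stopifnot(is(epochSet, "EpochSet"))
  if (is.null(channels)) channels <- channelNames(epochSet)
  channels <- normalizeChannelLabel(channels)
  out <- data.frame(subject_id = subjectId(epochSet),
                    session = session(epochSet), channel = channels,
                    delta = NA_real_, theta = NA_real_, alpha = NA_real_,
                    beta = NA_real_, total_power = NA_real_,
                    lzc = NA_real_, apen = NA_real_)
  if ("rpsd" %in% features) {
    sp <- channelPsds(epochSet, channels, welch)
    for (k in seq_along(channels)) {
      br <- bandRpsd(sp$freq, sp$psd[, k], totalBand = welch$totalBand)
      out[k, c("delta", "theta", "alpha", "beta")] <- as.list(br$rpsd)
      out$total_power[k] <- br$totalPower
    }
  }
  cx <- intersect(features, c("lzc", "apen"))
  if (length(cx)) for (k in seq_along(channels)) {
    cc <- epochComplexity(epochSet, channels[k], lzcBinarization, m, rFrac,
                          what = cx)
    for (nm in names(cc)) out[[nm]][k] <- cc[[nm]]
  }
  out
}

#' Features for every recording of a cohort
#'
#' Runs the preprocessing chain and [computeFeatures()] on each recording.
#'
#' @param recordings named list of [EEGRecording-class] (as from
#'   [synthCohort()]).
#' @param pre a [preprocessConfig()].
#' @inheritParams computeFeatures
#' @return Combined feature data frame.
#' @export
cohortFeatures <- function(recordings, pre = preprocessConfig(),
                           welch = welchConfig(),
                           features = c("rpsd", "lzc", "apen"),
                           channels = NULL, lzcBinarization = "median",
                           m = 2L, rFrac = 0.2) {
  do.call(rbind, lapply(recordings, function(rec) {
    es <- preprocessRecording(rec, pre)
    computeFeatures(es, welch, features, channels, lzcBinarization, m, rFrac)
  })) |> (\(d) { rownames(d) <- NULL; d })()
}

featureNames <- function() c("delta", "theta", "alpha", "beta", "lzc", "apen")

#' Affected- (or healthy-) hemisphere feature summary
#'
#' Selects each subject's affected-side electrodes (`C3, P3, O1` for a
#' left-sided infarct, `C4, P4, O2` for right; 10-20 convention, odd =
#' left) and reports per-electrode values plus the across-region mean as
#' the hemisphere summary, with the alpha/beta power ratio of the summary
#' added as `ab_ratio`.
#'
#' @param features feature table from [cohortFeatures()].
#' @param cohort cohort metadata (needs `subject_id`, `infarct_side`).
#' @param hemisphere `"affected"` (default) or `"healthy"`.
#' @return List with `perElectrode` (one row per subject x session x
#'   electrode) and `summary` (one row per subject x session; feature
#'   columns are across-electrode means).
#' @export
hemisphereFeatures <- function(features, cohort,
                               hemisphere = c("affected", "healthy")) {
  hemisphere <- match.arg(hemisphere)
  side <- setNames(cohort$infarct_side, cohort$subject_id)
  if (anyNA(side[unique(features$subject_id)]))
    stop("cohort metadata missing for subject(s): ",
         paste(setdiff(unique(features$subject_id), cohort$subject_id),
               collapse = ", "))
  perE <- do.call(rbind, lapply(split(features,
                                      features[c("subject_id", "session")],
                                      drop = TRUE), function(d) {
    s <- side[[d$subject_id[1L]]]
    want <- affectedChannels(if (hemisphere == "affected") s
                             else if (s == "left") "right" else "left")
    miss <- setdiff(want, d$channel)
    if (length(miss))
      stop("subject ", d$subject_id[1L], " session ", d$session[1L],
           " is missing electrode(s): ", paste(miss, collapse = ", "))
    d[match(want, d$channel), ]
  }))
  rownames(perE) <- NULL
  num <- c(featureNames(), "total_power")
  smry <- do.call(rbind, lapply(split(perE,
                                      perE[c("subject_id", "session")],
                                      drop = TRUE), function(d) {
    out <- data.frame(subject_id = d$subject_id[1L],
                      session = d$session[1L])
    for (nm in num) out[[nm]] <- mean(d[[nm]])
    out$ab_ratio <- out$alpha / out$beta
    out
  }))
  rownames(smry) <- NULL
  list(perElectrode = perE, summary = smry)
}
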