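## Array+JSON sidecar interchange format and cohort metadata CSV.

#' Write a recording as a raw array with a JSON header sidecar
#'
#' A dependency-light interchange format: `<base>.dat` holds the signal as
#' little-endian float64 (channel-major, i.e. all samples of channel 1, then
#' channel 2, ...) and `<base>.json` the metadata. Unlike EDF it is lossless.
#'
#' @param rec an [EEGRecording-class].
#' @param base output path without extension.
#' @return Invisibly, the path of the JSON header.
#' @export
writeEEGArray <- function(rec, base) {
  stopifnot(is(rec, "EEGRecording"))
  hdr <- list(subject_id = subjectId(rec), session = session(rec),
              fs = samplingRate(rec), channels = channelNames(rec),
              n_samples = nSamples(rec), unit = "uV",
              dtype = "float64le")
  jsonlite::write_json(hdr, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(eegData(rec))), con, size = 8L, endian = "little")
  invisible(paste0(base, ".json"))
}

#' Read a recording written by [writeEEGArray()]
#'
#' @param base path without extension (as passed to [writeEEGArray()]), or
#'   the path of the `.json` header.
#' @param requireChannels as in [readEDF()].
#' @return An [EEGRecording-class].
#' @export
readEEGArray <- function(base, requireChannels = requiredChannels()) {
  base <- sub("\\.json$", "", base)
  hdr <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  con <- file(paste0(base, ".dat"), "rb")
  on.exit(close(con))
  n <- hdr$n_samples * length(hdr$channels)
  x <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
  if (length(x) != n) stop("truncated data file for ", base)
  m <- t(matrix(x, nrow = hdr$n_samples))
  rec <- EEGRecording(m, fs = hdr$fs, channels = hdr$channels,
                      subjectId = hdr$subject_id, session = hdr$session)
  if (!is.null(requireChannels)) checkRequiredChannels(rec, requireChannels)
  rec
}

#' NIHSS improvement score
#'
#' The clinical improvement is the baseline score minus the post-treatment
#' score, `nihss_t0 - nihss_t1`; positive values mean improvement, negative
#' values worsening.
#'
#' @param nihssT0,nihssT1 integer NIHSS scores at baseline and after
#'   treatment. `nihssT0` may also be a cohort data frame with columns
#'   `nihss_t0` and `nihss_t1`.
#' @return Integer vector of score differences.
#' @export
#' @examples
#' deltaNihss(13, 6)   # 7
deltaNihss <- function(nihssT0, nihssT1) {
  if (is.data.frame(nihssT0)) {
    df <- nihssT0
    if (!all(c("nihss_t0", "nihss_t1") %in% names(df)))
      stop("cohort table must have nihss_t0 and nihss_t1 columns")
    nihssT0 <- df$nihss_t0
    nihssT1 <- df$nihss_t1
  }
  if (anyNA(nihssT0) || anyNA(nihssT1))
    stop("missing NIHSS score; both timepoints are required")
  as.integer(nihssT0) - as.integer(nihssT1)
}

cohortColumns <- function() c("subject_id", "group", "infarct_side",
                              "age", "sex", "nihss_t0", "nihss_t1")

#' Validate a cohort metadata table
#'
#' @param df data frame with columns
#'   `subject_id,group,infarct_side,age,sex,nihss_t0,nihss_t1`.
#' @param strict how to treat NIHSS baseline scores outside the 5-20
#'   inclusion window: `"warn"` (default), `"error"`, or `"none"`.
#' @return The validated data frame with an added integer `delta_nihss`
#'   column.
#' @export
validateCohort <- function(df, strict = c("warn", "error", "none")) {
  strict <- match.arg(strict)
  miss <- setdiff(cohortColumns(), names(df))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id in cohort table")
  badGroup <- setdiff(unique(df$group), c("experimental", "control"))
  if (length(badGroup))
    stop("unknown group label(s) ", paste(sQuote(badGroup), collapse = ", "),
         "; allowed: 'experimental', 'control'")
  badSide <- setdiff(unique(df$infarct_side), c("left", "right"))
  if (length(badSide))
    stop("unknown infarct_side label(s) ",
         paste(sQuote(badSide), collapse = ", "),
         "; allowed: 'left', 'right'")
  if (anyNA(df$nihss_t0) || anyNA(df$nihss_t1))
    stop("missing NIHSS scores are not allowed")
  if (any(df$nihss_t1 < 0))
    stop("nihss_t1 must be non-negative")
  out <- df$nihss_t0 < 5 | df$nihss_t0 > 20
  if (any(out)) {
    msg <- paste0("nihss_t0 outside the 5-20 inclusion window for subject(s): ",
                  paste(df$subject_id[out], collapse = ", "))
    if (strict == "error") stop(msg)
    if (strict == "warn") warning(msg, call. = FALSE)
  }
  df$delta_nihss <- deltaNihss(df$nihss_t0, df$nihss_t1)
  df
}

#' Read cohort metadata from CSV
#'
#' The file must have the header
#' `subject_id,group,infarct_side,age,sex,nihss_t0,nihss_t1`.
#'
#' @param path CSV file path.
#' @inheritParams validateCohort
#' @return A data frame, one row per subject, with `delta_nihss` added.
#' @export
readCohortCSV <- function(path, strict = c("warn", "error", "none")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validateCohort(df, strict = match.arg(strict))
}

#' Write cohort metadata to CSV
#'
#' @param cohort cohort data frame (the `delta_nihss` column, if present, is
#'   dropped since it is derived).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeCohortCSV <- function(cohort, path) {
  write.csv(cohort[, cohortColumns()], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
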