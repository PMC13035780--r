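## End-to-end pipeline: simulate (or read) -> preprocess -> features ->
## statistics -> report bundle, driven by a single YAML config, seeded and
## deterministic.

cfgChecksum <- function(s) {
  ## tiny polynomial checksum for the run manifest (not cryptographic)
  h <- 2166136261
  for (b in as.integer(charToRaw(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default pipeline configuration
#'
#' @return Nested list mirroring the YAML schema of [runPipeline()].
#' @export
pipelineConfig <- function() {
  list(simulate = list(n_per_group = 40),
       preprocess = list(bp_lo = 1, bp_hi = 45, epoch_length_s = 4,
                         n_epochs = 5, amp_reject_uv = 200),
       welch = list(window_length_s = 1, overlap_frac = 0.5, taper = "hann"),
       features = c("rpsd", "lzc", "apen"),
       lzc = list(binarization = "median"),
       apen = list(m = 2, r_frac = 0.2),
       stats = list(pooled = TRUE),
       seed = 1,
       output_dir = "qeeg-out")
}

cfgMerge <- function(user) {
  cfg <- pipelineConfig()
  if (!is.null(user$input_dir)) cfg$simulate <- NULL
  cfg <- modifyList(cfg, user)
  if (!is.null(cfg$input_dir) && !is.null(cfg$simulate))
    stop("config must have exactly one of input_dir / simulate")
  if (is.null(cfg$input_dir) && is.null(cfg$simulate))
    stop("config must have one of input_dir / simulate")
  cfg
}

specFromConfig <- function(sim, seed) {
  args <- list(seed = seed)
  map <- c(n_per_group = "nPerGroup", fs = "fs", duration_s = "durationS",
           amplitude_uv = "amplitudeUv", concentration = "concentration",
           complexity_sd = "complexitySd", target_corr = "targetCorr",
           compensate = "compensate")
  for (nm in names(map))
    if (!is.null(sim[[nm]])) args[[map[[nm]]]] <- sim[[nm]]
  do.call(cohortSpec, args)
}

loadRecordingDir <- function(dir) {
  cohortPath <- file.path(dir, "cohort.csv")
  if (!file.exists(cohortPath)) stop("no cohort.csv in ", dir)
  cohort <- readCohortCSV(cohortPath)
  recs <- list()
  for (sid in cohort$subject_id) {
    for (ses in c("T0", "T1")) {
      p <- file.path(dir, paste0(sid, "_", ses, ".edf"))
      if (!file.exists(p))
        stop("stage input: missing recording for subject ", sid,
             " session ", ses, " (expected ", p, ")")
      recs[[paste0(sid, "_", ses)]] <- readEDF(p)
    }
  }
  list(recordings = recs, cohort = cohort)
}

stageLog <- function(name, t0) {
  message(sprintf("[qeeg] %-10s %6.1f s", name,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort (or loads EDF recordings and `cohort.csv` from
#' `input_dir`), preprocesses every recording, extracts the per-channel
#' features, runs the statistical battery on the affected-hemisphere
#' summaries, and writes the report bundle: `features.csv`, `stats.csv`,
#' `correlations.csv`, `tables.md`, `summary.json` and `manifest.json`.
#' Identical config + seed give byte-identical CSV output.
#'
#' @param config a config list, or the path of a YAML file with the same
#'   structure (see [pipelineConfig()]); must contain exactly one of
#'   `simulate` / `input_dir`.
#' @param outDir output directory (overrides `config$output_dir`).
#' @param seed seed (overrides `config$seed`).
#' @return Invisibly, a list with `features`, `summary` (hemisphere
#'   summary), `analysis` (from [analyzeCohort()]), `tables` (markdown
#'   lines), `cohort` and `paths`.
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- cfgMerge(config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(outDir)) cfg$output_dir <- outDir
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())

  if (!is.null(cfg$simulate)) {
    cs <- synthCohort(specFromConfig(cfg$simulate, cfg$seed))
    stageLog("simulate", t0)
  } else {
    cs <- loadRecordingDir(cfg$input_dir)
    stageLog("load", t0)
  }

  pre <- preprocessConfig(bpLo = cfg$preprocess$bp_lo,
                          bpHi = cfg$preprocess$bp_hi,
                          epochLength = cfg$preprocess$epoch_length_s,
                          nEpochs = cfg$preprocess$n_epochs,
                          ampRejectUv = cfg$preprocess$amp_reject_uv)
  welch <- welchConfig(windowLength = cfg$welch$window_length_s,
                       overlap = cfg$welch$overlap_frac,
                       taper = cfg$welch$taper)
  feats <- lapply(names(cs$recordings), function(nm) {
    rec <- cs$recordings[[nm]]
    tryCatch({
      es <- preprocessRecording(rec, pre)
      computeFeatures(es, welch, features = cfg$features,
                      lzcBinarization = cfg$lzc$binarization,
                      m = cfg$apen$m, rFrac = cfg$apen$r_frac)
    }, error = function(e)
      stop("stage features failed for subject ", subjectId(rec),
           " (", session(rec), "): ", conditionMessage(e), call. = FALSE))
  })
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  stageLog("features", t0)

  hf <- hemisphereFeatures(features, cs$cohort)
  an <- analyzeCohort(hf$summary, cs$cohort, pooled = cfg$stats$pooled)
  stageLog("stats", t0)

  tables <- makeReportTables(hf$summary, cs$cohort, an)
  paths <- list(features = file.path(cfg$output_dir, "features.csv"),
                stats = file.path(cfg$output_dir, "stats.csv"),
                correlations = file.path(cfg$output_dir, "correlations.csv"),
                tables = file.path(cfg$output_dir, "tables.md"),
                summary = file.path(cfg$output_dir, "summary.json"),
                manifest = file.path(cfg$output_dir, "manifest.json"))
  numfmt <- function(d) { d[] <- lapply(d, function(v)
    if (is.numeric(v)) signif(v, 10) else v); d }
  write.csv(numfmt(features), paths$features, row.names = FALSE)
  stats <- an$stats[, setdiff(names(an$stats), "family")]
  write.csv(numfmt(stats), paths$stats, row.names = FALSE)
  write.csv(numfmt(an$correlations), paths$correlations, row.names = FALSE)
  writeLines(tables, paths$tables)

  groupMeans <- reportCellStats(hf$summary, cs$cohort)
  jsonlite::write_json(
    list(group_feature_means = groupMeans, correlations = an$correlations,
         baseline = an$baseline),
    paths$summary, auto_unbox = TRUE, digits = 10, dataframe = "rows")
  cfgEcho <- cfg
  jsonlite::write_json(
    list(config = cfgEcho, seed = cfg$seed,
         config_hash = cfgChecksum(jsonlite::toJSON(cfgEcho, auto_unbox = TRUE)),
         package_version = as.character(utils::packageVersion("qeeg"))),
    paths$manifest, auto_unbox = TRUE)
  stageLog("report", t0)
  invisible(list(features = features, summary = hf$summary, analysis = an,
                 tables = tables, cohort = cs$cohort, paths = paths))
}

## group x session mean/sd of every feature in the hemisphere summary
reportCellStats <- function(summary, cohort) {
  d <- merge(summary, cohort[, c("subject_id", "group")], by = "subject_id")
  num <- intersect(c(featureNames(), "ab_ratio"), names(d))
  out <- list()
  for (g in unique(d$group)) for (s in c("T0", "T1")) {
    sub <- d[d$group == g & d$session == s, num, drop = FALSE]
    out[[length(out) + 1L]] <- c(list(group = g, session = s),
                                 lapply(sub, mean), setNames(
                                   lapply(sub, sd), paste0(num, "_sd")))
  }
  out
}

markerFor <- function(q, sym1, sym2) {
  if (is.na(q)) "" else if (q < 0.01) paste0(sym2, sym2)
  else if (q < 0.05) sym1 else ""
}

#' Formatted summary tables of the analysis
#'
#' Three markdown tables in the layout of a clinical qEEG report: relative
#' band power by group and timepoint (mean +/- SD, percent), complexity
#' measures (LZC/ApEn), and NIHSS scores with the improvement column.
#' Significance markers: `*`/`**` for the within-group T0-vs-T1 comparison
#' (q < 0.05 / q < 0.01), `#`/`##` for the between-group comparison at T1.
#'
#' @param summary hemisphere summary from [hemisphereFeatures()].
#' @param cohort cohort metadata.
#' @param analysis result of [analyzeCohort()] (may have empty `stats`, in
#'   which case no markers are drawn).
#' @return Character vector of markdown lines.
#' @export
makeReportTables <- function(summary, cohort, analysis) {
  d <- merge(summary, cohort[, c("subject_id", "group")], by = "subject_id")
  st <- analysis$stats
  qOf <- function(contrast, feature, group) {
    if (is.null(st) || !nrow(st)) return(NA_real_)
    i <- st$contrast == contrast & st$feature == feature &
      st$group == group
    if (!any(i)) NA_real_ else st$q_fdr[which(i)[1L]]
  }
  cell <- function(g, s, f, scale = 100, digits = 1) {
    v <- d[d$group == g & d$session == s, f]
    mk <- ""
    if (s == "T1") {
      mk <- paste0(mk, markerFor(qOf("within_group_T0_vs_T1", f, g),
                                 "*", "*"))
      if (g == "experimental")
        mk <- paste0(mk, markerFor(qOf("between_group_at_T1", f, "both"),
                                   "#", "#"))
    }
    sprintf(paste0("%.", digits, "f ± %.", digits, "f%s"),
            mean(v) * scale, sd(v) * scale, mk)
  }
  lines <- c("## Relative band power, affected hemisphere (%)", "",
             "| Group | Time | Delta | Theta | Alpha | Beta |",
             "|---|---|---|---|---|---|")
  for (g in c("experimental", "control")) for (s in c("T0", "T1"))
    lines <- c(lines, paste0("| ", g, " | ", s, " | ",
                             paste(vapply(c("delta", "theta", "alpha",
                                            "beta"),
                                          function(f) cell(g, s, f), ""),
                                   collapse = " | "), " |"))
  lines <- c(lines, "",
             "## Complexity of the affected hemisphere", "",
             "| Group | Time | LZC | ApEn |", "|---|---|---|---|")
  haveCx <- all(c("lzc", "apen") %in% names(d)) &&
    !anyNA(d$lzc) && !anyNA(d$apen)
  if (haveCx) {
    for (g in c("experimental", "control")) for (s in c("T0", "T1"))
      lines <- c(lines, paste0("| ", g, " | ", s, " | ",
                               cell(g, s, "lzc", 1, 3), " | ",
                               cell(g, s, "apen", 1, 3), " |"))
  } else {
    lines <- c(lines, "| (complexity features not computed) | | | |")
  }
  lines <- c(lines, "", "## NIHSS scores", "",
             "| Group | NIHSS (T0) | NIHSS (T1) | Delta NIHSS |",
             "|---|---|---|---|")
  dnq <- qOf("between_group_at_T1", "delta_nihss", "both")
  dnp <- if (is.null(st) || !nrow(st)) NA_real_ else
    st$p_raw[st$feature == "delta_nihss"][1L]
  for (g in c("experimental", "control")) {
    cg <- cohort[cohort$group == g, ]
    mk <- if (g == "experimental" && !is.na(dnp) && dnp < 0.01) "**"
    else if (g == "experimental" && !is.na(dnp) && dnp < 0.05) "*" else ""
    lines <- c(lines, sprintf(
      "| %s | %.1f ± %.1f | %.1f ± %.1f | %.1f ± %.1f%s |",
      g, mean(cg$nihss_t0), sd(cg$nihss_t0), mean(cg$nihss_t1),
      sd(cg$nihss_t1), mean(cg$delta_nihss), sd(cg$delta_nihss), mk))
  }
  c(lines, "",
    paste0("Markers: `*` q < 0.05, `**` q < 0.01 vs T0 (within group); ",
           "`#` q < 0.05, `##` q < 0.01 experimental vs control at T1; ",
           "NIHSS markers use the raw between-group p."))
}
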