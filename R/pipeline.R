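# End-to-end pipeline: synthesize (or read) a cohort, extract features,
# run the group statistics and the stacked estimator, and write all
# tabular outputs plus a run manifest. All randomness derives from one
# global seed via named child streams, so stages are independently
# reproducible.

#' Pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Global seed; every stage derives a named child seed from it.
#' @param synth Generate a synthetic cohort (`TRUE`) or read real
#'   recordings from `audio_dir`/`textgrid_dir`.
#' @param n_control,n_osa,coupling Cohort parameters (see [cohort_params()]).
#' @param mode Fold mode for the estimator.
#' @param n_folds Number of folds.
#' @param rf_ntree,mlp_epochs,cnn_epochs Estimator settings.
#' @param audio_dir,textgrid_dir Input directories when `synth = FALSE`.
#' @param log_level `"info"` or `"quiet"`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "vowelpap_out", seed = 1L,
                            synth = TRUE, n_control = 18L, n_osa = 13L,
                            coupling = 0.7, mode = "by_observation",
                            n_folds = 6L, rf_ntree = 500L,
                            mlp_epochs = 500L, cnn_epochs = 500L,
                            audio_dir = NA_character_,
                            textgrid_dir = NA_character_,
                            log_level = "info") {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synth = isTRUE(synth), n_control = as.integer(n_control),
                 n_osa = as.integer(n_osa), coupling = as.numeric(coupling),
                 mode = mode, n_folds = as.integer(n_folds),
                 rf_ntree = as.integer(rf_ntree),
                 mlp_epochs = as.integer(mlp_epochs),
                 cnn_epochs = as.integer(cnn_epochs),
                 audio_dir = audio_dir, textgrid_dir = textgrid_dir,
                 log_level = log_level),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as plain-text key = value
#'
#' The on-disk form round-trips losslessly; unknown keys are rejected.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `path` / the configuration, invisibly / visibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) as.character(v), "")), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec(
    "^[[:space:]]*([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.*)$", lines))
  bad_lines <- lines[lengths(kv) == 0]
  if (length(bad_lines))
    stop("read_pipeline_config: unparseable line(s): ",
         paste(bad_lines, collapse = "; "))
  keys <- vapply(kv, `[`, "", 2)
  vals <- trimws(vapply(kv, `[`, "", 3))
  defaults <- pipeline_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown))
    stop("read_pipeline_config: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg <- as.list(defaults)
  for (i in seq_along(keys)) {
    tmpl <- defaults[[keys[i]]]
    cfg[[keys[i]]] <- if (is.logical(tmpl)) as.logical(vals[i])
      else if (is.integer(tmpl)) as.integer(vals[i])
      else if (is.numeric(tmpl)) as.numeric(vals[i])
      else if (identical(vals[i], "NA")) NA_character_
      else vals[i]
  }
  structure(cfg, class = "pipeline_config")
}

.log <- function(config, ...) {
  if (!identical(config$log_level, "quiet"))
    message("[vowelpap] ", ...)
}

#' Run the full analysis pipeline
#'
#' Stages: synthesize or load the cohort; preprocess and extract the
#' 106-feature vectors; score NoSAS; run the vowel-wise and group-wise
#' comparisons, the See-Sah delta analysis and the feature-PAP correlation
#' map; run the six-fold stacked estimation. Writes `features.csv`,
#' `nosas.csv`, `comparisons.csv`, `deltas.csv`, `correlation_matrix.csv`,
#' `estimation.csv`, `metrics.csv` and `manifest.txt` into
#' `config$out_dir`. A rerun with an identical configuration produces
#' identical CSVs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ow <- function(df, name) {
    utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
  }

  if (config$synth) {
    .log(config, "synthesizing cohort (", config$n_control, " control / ",
         config$n_osa, " OSA)")
    params <- cohort_params(n_control = config$n_control,
                            n_osa = config$n_osa,
                            coupling = config$coupling,
                            seed = child_seed(config$seed, "synth"))
    cohort <- generate_cohort(params)
    audio_dir <- file.path(config$out_dir, "audio")
    write_cohort(cohort, audio_dir)
    textgrid_dir <- audio_dir
    demographics <- cohort$profiles
    pap <- cohort$pap
  } else {
    audio_dir <- config$audio_dir
    textgrid_dir <- config$textgrid_dir
    demographics <- utils::read.csv(file.path(audio_dir, "demographics.csv"))
    pap <- utils::read.csv(file.path(audio_dir, "pap.csv"))
  }

  .log(config, "extracting features")
  wavs <- sort(list.files(audio_dir, pattern = "\\.wav$", full.names = TRUE))
  segs <- list()
  for (w in wavs) {
    tg <- file.path(textgrid_dir,
                    paste0(tools::file_path_sans_ext(basename(w)), ".TextGrid"))
    if (!file.exists(tg)) stop("run_pipeline [extract]: missing TextGrid for ", w)
    pid <- sub("_[iuaeo]$", "", tools::file_path_sans_ext(basename(w)))
    raw <- read_segments(w, tg, participant_id = pid)
    segs <- c(segs, lapply(raw, preprocess_segment))
  }
  features <- extract_features(segs)
  features <- merge(demographics[, c("participant_id", "group")], features,
                    by = "participant_id")
  features <- features[order(features$participant_id, features$vowel), ]
  ow(features, "features.csv")

  .log(config, "scoring NoSAS")
  nosas <- nosas_table(demographics)
  ow(nosas, "nosas.csv")

  .log(config, "running statistics")
  comparisons <- .pipeline_comparisons(features, pap)
  ow(comparisons, "comparisons.csv")
  deltas <- .pipeline_deltas(features, pap)
  ow(deltas, "deltas.csv")
  cells <- correlate_features(features, pap)
  ow(cells, "correlations.csv")
  ow(correlation_matrix(cells), "correlation_matrix.csv")

  .log(config, "estimating PAP from features (", config$n_folds, "-fold )")
  est <- estimate_pap(features, pap, mode = config$mode,
                      seed = child_seed(config$seed, "estimate"),
                      n_folds = config$n_folds,
                      config = list(rf_ntree = config$rf_ntree,
                                    mlp_epochs = config$mlp_epochs,
                                    cnn_epochs = config$cnn_epochs))
  ow(est$predictions, "estimation.csv")
  metrics <- merge(
    stats::aggregate(cbind(rmse, r) ~ model, est$per_fold,
                     function(v) c(mean = mean(v), sd = stats::sd(v))),
    est$overall, by = "model", suffixes = c("_fold", "_overall"))
  metrics <- do.call(data.frame, metrics)
  ow(metrics, "metrics.csv")

  cfg_path <- file.path(config$out_dir, "config.txt")
  write_pipeline_config(config, cfg_path)
  manifest <- c(
    sprintf("package_version = %s",
            as.character(utils::packageVersion("vowelpap"))),
    sprintf("seed = %d", config$seed),
    sprintf("config_md5 = %s", unname(tools::md5sum(cfg_path))),
    sprintf("n_segments = %d", nrow(features)),
    sprintf("outputs = %s", paste(
      c("features.csv", "nosas.csv", "comparisons.csv", "deltas.csv",
        "correlations.csv", "correlation_matrix.csv", "estimation.csv",
        "metrics.csv"), collapse = ", ")))
  writeLines(manifest, file.path(config$out_dir, "manifest.txt"))
  .log(config, "done: ", config$out_dir)
  invisible(list(features = features, nosas = nosas,
                 comparisons = comparisons, deltas = deltas,
                 correlations = cells, estimation = est))
}

# group comparisons (see/sah), within-group paired see-vs-sah, one-way
# ANOVA of PAP across vowels, and the mixed RM-ANOVA on see/sah PAP
.pipeline_comparisons <- function(features, pap) {
  rows <- NULL
  add <- function(measure, vowel, contrast, res) {
    rbind(rows, data.frame(measure = measure, vowel = vowel,
                           contrast = contrast, test = res$test_used,
                           statistic = res$statistic, p = res$p))
  }
  for (v in c("i", "a")) {
    pc <- pap$pap_mm[pap$vowel == v & pap$group == "control"]
    po <- pap$pap_mm[pap$vowel == v & pap$group == "osa"]
    rows <- add("PAP", v, "control_vs_osa", select_test(pc, po))
  }
  for (g in c("control", "osa")) {
    d <- delta_table(pap[pap$group == g, ])
    rows <- add("PAP", "i_vs_a", paste0("paired_", g),
                select_test(d$value_see, d$value_sah, paired = TRUE))
  }
  aov1 <- anova_one_way(pap$pap_mm, pap$vowel)
  rows <- rbind(rows, data.frame(measure = "PAP", vowel = "all",
                                 contrast = "between_vowels",
                                 test = aov1$test_used,
                                 statistic = aov1$statistic, p = aov1$p))
  rm_in <- pap[pap$vowel %in% c("i", "a"),
               c("participant_id", "group", "vowel", "pap_mm")]
  names(rm_in)[4] <- "value"
  rm2 <- anova_two_way_rm(rm_in)
  rows <- rbind(rows, data.frame(measure = "PAP", vowel = "i_vs_a",
                                 contrast = paste0("rm_", rm2$table$term),
                                 test = "two_way_rm_anova",
                                 statistic = rm2$table$F, p = rm2$table$p))
  for (feat in c("pitch_mean", "F2")) {
    for (v in c("i", "a")) {
      fc <- features[features$vowel == v & features$group == "control", feat]
      fo <- features[features$vowel == v & features$group == "osa", feat]
      fc <- fc[is.finite(fc)]; fo <- fo[is.finite(fo)]
      if (length(fc) >= 3 && length(fo) >= 3)
        rows <- add(feat, v, "control_vs_osa", select_test(fc, fo))
    }
  }
  rows
}

# long-format See-minus-Sah deltas for PAP and every feature
.pipeline_deltas <- function(features, pap) {
  out <- delta_table(pap)
  out <- cbind(measure = "PAP", out)
  for (feat in intersect(feature_names(), names(features))) {
    d <- delta_table(features, value = feat)
    if (nrow(d)) out <- rbind(out, cbind(measure = feat, d))
  }
  out
}
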