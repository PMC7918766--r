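# End-to-end orchestration: simulate or load a cohort, preprocess, extract
# features, label, run the requested experiments, and write a report
# bundle.

#' Pipeline configuration
#'
#' @param source `"simulate"` or a path to a directory of recording
#'   subdirectories (the layout written by [simulate_cohort()]).
#' @param sim A [sim_config()] used when `source = "simulate"`.
#' @param framing A [framing_spec()].
#' @param labeling A [labeling_config()].
#' @param feature_mode `"scattering"` or `"stft"`.
#' @param classifier A [classifier_spec()].
#' @param tasks Character vector of tasks for [run_cv()].
#' @param schemes Character vector of validation schemes.
#' @param runs Repetitions per experiment (default 10).
#' @param seed Master seed; every stage derives its own child seed from
#'   it, so a fixed configuration reproduces byte-identical outputs.
#' @param out_dir Output directory (`NULL` = no files written).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(source = "simulate",
                            sim = sim_config(),
                            framing = framing_spec(),
                            labeling = labeling_config(),
                            feature_mode = c("scattering", "stft"),
                            classifier = classifier_spec(),
                            tasks = "multiclass",
                            schemes = "kfold10",
                            runs = 10,
                            seed = 1,
                            out_dir = NULL) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(inherits(sim, "sim_config"), inherits(framing, "framing_spec"),
            inherits(labeling, "labeling_config"),
            inherits(classifier, "classifier_spec"), is_count(runs))
  for (tk in tasks) cv_task_classes(tk)
  for (sc in schemes) match.arg(sc, c("kfold10", "one_patient_out"))
  structure(
    list(source = source, sim = sim, framing = framing, labeling = labeling,
         feature_mode = feature_mode, classifier = classifier,
         tasks = tasks, schemes = schemes, runs = runs,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Build the pooled dataset of a cohort
#'
#' Preprocesses every recording, extracts features in the requested mode,
#' z-scores per subject, and labels the frames.
#'
#' @param recordings List of [multimodal_recording()]s.
#' @param feature_mode `"scattering"` or `"stft"`.
#' @param framing A [framing_spec()].
#' @param labeling A [labeling_config()].
#' @param progress Log each subject to stderr.
#' @return A list with `features` (pooled matrix), `labels` (factor),
#'   `subjects` (character), `frame_start_s`, and the per-subject
#'   `feature_matrices` and `frame_labels`.
#' @export
build_dataset <- function(recordings, feature_mode = "scattering",
                          framing = framing_spec(),
                          labeling = labeling_config(),
                          progress = FALSE) {
  fms <- list(); fls <- list()
  for (rec in recordings) {
    if (progress)
      message("processing subject ", rec$subject_id)
    pre <- preprocess_recording(rec)
    fm <- zscore_by_subject(
      extract_features(pre, mode = feature_mode, framing = framing))
    fl <- label_frames(rec$reports, recording_duration(pre),
                       framing = framing, config = labeling)
    stopifnot(length(fl$class) == nrow(fm$values))
    fms[[rec$subject_id]] <- fm
    fls[[rec$subject_id]] <- fl
  }
  list(
    features = do.call(rbind, lapply(fms, `[[`, "values")),
    labels = factor(unlist(lapply(fls, function(l) as.character(l$class))),
                    levels = PAIN_CLASSES),
    subjects = unlist(lapply(fms, function(m)
      rep(m$subject_id, nrow(m$values)))),
    frame_start_s = unlist(lapply(fms, `[[`, "frame_start_s")),
    feature_matrices = fms,
    frame_labels = fls
  )
}

#' Run the full assessment pipeline
#'
#' Simulates (or loads) a cohort, builds the pooled feature/label dataset,
#' runs every requested task x scheme experiment, and optionally writes
#' per-subject feature and label CSVs, a results JSON, and a run log.
#'
#' @param config A [pipeline_config()].
#' @return A list with the `dataset`, a named list of `cv_result`s
#'   (`<task>_<scheme>`), and the `config`; invisibly writes the report
#'   bundle when `config$out_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  logit <- function(...) {
    line <- sprintf("[%s] %s", "painreact", sprintf(...))
    message(line)
    log_lines <<- c(log_lines, line)
  }

  if (identical(config$source, "simulate")) {
    logit("simulating cohort: %d subjects, seed %d",
          config$sim$n_subjects, config$sim$seed)
    cohort <- simulate_cohort(config$sim)
    recordings <- lapply(cohort, `[[`, "recording")
  } else {
    dirs <- list.dirs(config$source, recursive = FALSE)
    if (!length(dirs)) stop("no recording directories under ", config$source)
    logit("loading %d recordings from %s", length(dirs), config$source)
    recordings <- lapply(dirs, load_recording)
  }

  logit("extracting %s features (%d s window, %d s hop)",
        config$feature_mode, config$framing$window_s, config$framing$hop_s)
  dataset <- build_dataset(recordings, config$feature_mode,
                           config$framing, config$labeling)
  logit("dataset: %d frames x %d features, %d subjects",
        nrow(dataset$features), ncol(dataset$features),
        length(unique(dataset$subjects)))

  results <- list()
  for (tk in config$tasks) {
    for (sc in config$schemes) {
      key <- paste(tk, sc, sep = "_")
      logit("experiment %s: %s, %d runs", key, config$classifier$kind,
            config$runs)
      results[[key]] <- run_cv(
        dataset$features, dataset$labels, dataset$subjects,
        task = tk, scheme = sc, classifier = config$classifier,
        runs = config$runs, seed = child_seed(config$seed, length(results) + 1)
      )
    }
  }

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    dir.create(file.path(out, "features"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out, "labels"), showWarnings = FALSE)
    dir.create(file.path(out, "results"), showWarnings = FALSE)
    for (sid in names(dataset$feature_matrices)) {
      write.csv(as.data.frame(dataset$feature_matrices[[sid]]),
                file.path(out, "features", paste0(sid, ".csv")),
                row.names = FALSE)
      write.csv(as.data.frame(dataset$frame_labels[[sid]]),
                file.path(out, "labels", paste0(sid, ".csv")),
                row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(results, cv_result_json),
      file.path(out, "results", "cv_results.json"),
      auto_unbox = TRUE, digits = 10, pretty = TRUE
    )
    writeLines(log_lines, file.path(out, "run.log"))
  }
  list(dataset = dataset, results = results, config = config)
}

# Tables-style serialization: experiment descriptor plus per-class
# mean/sd per metric.
cv_result_json <- function(res) {
  list(
    task = res$task[1], scheme = res$scheme[1], classifier = res$classifier[1],
    metrics = lapply(split(res, res$class), function(chunk) {
      out <- lapply(seq_len(nrow(chunk)), function(i)
        list(mean = chunk$mean[i], sd = chunk$sd[i],
             sd_between_runs = chunk$sd_between_runs[i]))
      names(out) <- chunk$metric
      out
    })
  )
}
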