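#' Simulate a cohort of recordings to disk
#'
#' Writes one gaze CSV plus episode sidecar per simulated participant
#' session (default cohort: 22 recordings, matching a typical small
#' human-factors study).
#'
#' @param out_dir Output directory (created if needed).
#' @param n_recordings Number of recordings.
#' @param duration Per-recording duration, seconds.
#' @param scan A [scanpath_params()] object.
#' @param episodes An [episode_params()] object.
#' @param seed Integer seed.
#' @return Character vector of the written gaze-table paths, invisibly.
#' @export
pipeline_simulate <- function(out_dir, n_recordings = 22, duration = 5400,
                              scan = scanpath_params(),
                              episodes = episode_params(), seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(n_recordings)
  for (r in seq_len(n_recordings)) {
    rec <- simulate_recording(scan, episodes, duration = duration,
                              seed = seed + 131 * r)
    paths[r] <- file.path(out_dir, sprintf("recording_%02d.csv", r))
    write_gaze_table(rec, paths[r])
  }
  invisible(paths)
}

#' Extract per-window features from a directory of gaze tables
#'
#' Reads every `*.csv` gaze table (with its episode sidecar when present),
#' preprocesses, windows, labels, and computes the 44 features; one output
#' row per window.
#'
#' @param gaze_dir Directory of gaze CSVs written by [pipeline_simulate()]
#'   or exported from a tracker.
#' @param out_file Output CSV path (columns: `recording`, `window`,
#'   `label`, then the 44 manifest features).
#' @param sample_rate Sampling frequency, Hz.
#' @param events_cfg An [event_config()].
#' @param min_overlap Episode-overlap fraction for labelling.
#' @return The feature tibble, invisibly.
#' @export
pipeline_extract <- function(gaze_dir, out_file, sample_rate = 100,
                             events_cfg = event_config(),
                             min_overlap = 0.5) {
  files <- sort(list.files(gaze_dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[!grepl("\\.episodes$", files)]
  if (length(files) == 0)
    stop(sprintf("no gaze tables found in %s", gaze_dir), call. = FALSE)
  rows <- list()
  for (f in files) {
    rec <- read_gaze_table(f, sample_rate = sample_rate)
    rec <- preprocess_recording(rec)
    w <- assign_labels(slide_windows(rec), rec$episodes,
                       min_overlap = min_overlap)
    fm <- recording_features(rec, w, events_cfg = events_cfg)
    if (nrow(fm$features) == 0) next
    rows[[f]] <- tibble::as_tibble(cbind(
      data.frame(recording = basename(f), window = seq_len(nrow(fm$features)),
                 label = fm$labels),
      as.data.frame(fm$features)))
  }
  out <- do.call(rbind, rows)
  readr::write_csv(out, out_file)
  invisible(out)
}

#' Train and compare all methods on an extracted feature file
#'
#' Assembles 6-event sequences per recording from a feature CSV written by
#' [pipeline_extract()], optionally balances the classes, runs the chosen
#' methods under shuffled k-fold cross-validation, and writes a comparison
#' table.
#'
#' @param feature_file Feature CSV from [pipeline_extract()].
#' @param report_file Output CSV path for the comparison table.
#' @param methods Methods to run (see [five_fold_cv()]).
#' @param cfg A [train_config()].
#' @param model_config A [hybrid_config()].
#' @param balance Logical; balance classes by downsampling negatives.
#' @param seq_len Sequence length.
#' @return The comparison tibble, invisibly.
#' @export
pipeline_train_eval <- function(feature_file, report_file,
                                methods = c("hybrid", "conv_only",
                                            "recurrent_only", "logistic"),
                                cfg = train_config(),
                                model_config = hybrid_config(),
                                balance = TRUE, seq_len = 6) {
  if (!file.exists(feature_file))
    stop(sprintf("feature file not found: %s", feature_file), call. = FALSE)
  tab <- readr::read_csv(feature_file, show_col_types = FALSE)
  need <- c("recording", "window", "label", feature_manifest()$name)
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("feature file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sets <- list()
  for (rid in unique(tab$recording)) {
    sub <- tab[tab$recording == rid, ]
    sub <- sub[order(sub$window), ]
    X <- as.matrix(sub[, feature_manifest()$name])
    sets[[rid]] <- assemble_sequences(X, sub$label, length = seq_len)
  }
  seqs <- bind_sequences(sets)
  if (balance) seqs <- balance_sequences(seqs, seed = cfg$seed + 7)
  entries <- lapply(methods, function(m)
    five_fold_cv(seqs, cfg, method = m, model_config = model_config))
  rep_tab <- comparison_report(entries)
  out <- rep_tab[, c("method", "mean_accuracy", "sd_accuracy", "seed")]
  per_fold <- vapply(rep_tab$fold_accuracy, function(a)
    paste(sprintf("%.4f", a), collapse = ";"), "")
  out$fold_accuracy <- per_fold
  readr::write_csv(out, report_file)
  invisible(rep_tab)
}
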