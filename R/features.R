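#' Feature computation configuration
#'
#' Fixes the free constants in the feature definitions: the screen geometry
#' (for centre-referenced and grid-based metrics) and the amplitude cut
#' separating "global" from "local" saccades.
#'
#' @param screen_extent Screen size `c(width, height)`, px.
#' @param grid Number of grid cells `c(cols, rows)` for the visited-cell
#'   metrics.
#' @param global_amplitude Amplitude threshold (px) above which a saccade
#'   counts as global.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(screen_extent = c(1680, 1050),
                           grid = c(4, 4),
                           global_amplitude = 100) {
  structure(list(screen_extent = screen_extent, grid = grid,
                 global_amplitude = global_amplitude),
            class = "feature_config")
}

# Population moments with zero-fallbacks for degenerate inputs.
pop_sd <- function(v) {
  if (length(v) < 2) return(0)
  sqrt(mean((v - mean(v))^2))
}
pop_skewness <- function(v) {
  if (length(v) < 3) return(0)
  m2 <- mean((v - mean(v))^2)
  if (m2 == 0) return(0)
  mean((v - mean(v))^3) / m2^1.5
}
pop_kurtosis <- function(v) {
  if (length(v) < 3) return(0)
  m2 <- mean((v - mean(v))^2)
  if (m2 == 0) return(0)
  mean((v - mean(v))^4) / m2^2 - 3
}
zero_if_empty <- function(v, f) if (length(v) == 0) 0 else f(v)

max_pairwise_distance <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  max(stats::dist(cbind(x, y)))
}

#' The 44-feature manifest
#'
#' Frozen mapping from feature index to name and group; columns of every
#' feature matrix produced by the package follow this order (23 time-related
#' metrics, then 21 time-independent metrics).
#'
#' @return Tibble with columns `index`, `name`, `group` (`"tc"` or `"tic"`),
#'   `category`.
#' @export
feature_manifest <- function() {
  tc <- tibble::tibble(
    name = c("n_fixations", "fixations_per_second", "mean_fixation_duration",
             "gaze_width", "nearest_neighbor_distance", "total_fixation_time",
             "max_fixation_time", "gaze_density",
             "n_blinks", "blink_rate", "longest_blink_duration",
             "current_blink_duration", "closed_eye_time",
             "n_saccades", "total_saccade_length", "max_saccade_distance",
             "mean_saccade_length", "total_saccade_time",
             "mean_saccade_time", "max_saccade_time", "mean_saccade_speed",
             "overall_saccade_speed", "mean_pupil_diameter"),
    category = c(rep("fixation", 8), rep("blink", 5), rep("saccade", 9),
                 "other"),
    group = "tc"
  )
  tic <- tibble::tibble(
    name = c("median_fixation_duration", "fixation_time_ratio",
             "fixation_dispersion_sd", "horizontal_range",
             "fixation_duration_sd", "fixation_duration_skewness",
             "fixation_duration_kurtosis", "first_fixation_offcenter",
             "blink_count_sd", "noting", "returning",
             "arithmetic_mean_center", "weighted_mean_center",
             "vertical_range", "median_saccade_distance",
             "saccade_distance_sd", "saccade_distance_skewness",
             "saccade_distance_kurtosis", "scanpath_length",
             "global_local_ratio", "saccade_dispersion"),
    category = c(rep("fixation", 8), rep("blink", 3), rep("saccade", 10)),
    group = "tic"
  )
  out <- rbind(tc, tic)
  tibble::tibble(index = seq_len(nrow(out)), name = out$name,
                 group = out$group, category = out$category)
}

#' Time-related features of one window
#'
#' Computes the 23 time-related metrics (counts, totals, rates and the mean
#' pupil diameter) from the detected events of a preprocessed window.
#' Degenerate windows (no fixations, saccades or blinks) yield 0 for the
#' affected metrics; the result is always finite.
#'
#' @param samples Window sample tibble.
#' @param fixations,saccades,blinks Event tibbles from [detect_events()].
#' @param sample_rate Sampling frequency, Hz.
#' @param config A [feature_config()].
#' @return Named numeric vector of length 23, in manifest order.
#' @export
compute_time_related <- function(samples, fixations, saccades, blinks,
                                 sample_rate = 100,
                                 config = feature_config()) {
  wdur <- length(samples$timestamp) / sample_rate
  nf <- length(fixations$onset)
  ns <- length(saccades$onset)
  nb <- length(blinks$onset)

  nn_dist <- 0
  if (nf >= 2) {
    d <- as.matrix(stats::dist(cbind(fixations$x, fixations$y)))
    diag(d) <- Inf
    nn_dist <- mean(apply(d, 1, min))
  }
  bbox_area <- if (nf == 0) 1 else
    max(diff(range(fixations$x)), 0) * max(diff(range(fixations$y)), 0)
  bbox_area <- max(bbox_area, 1)          # floored at 1 px^2

  amp <- saccades$amplitude
  sdur <- saccades$duration
  speed_ok <- sdur > 0
  total_sacc_time <- sum(sdur)

  out <- c(
    n_fixations = nf,
    fixations_per_second = nf / wdur,
    mean_fixation_duration = zero_if_empty(fixations$duration, mean),
    gaze_width = max_pairwise_distance(fixations$x, fixations$y),
    nearest_neighbor_distance = nn_dist,
    total_fixation_time = sum(fixations$duration),
    max_fixation_time = zero_if_empty(fixations$duration, max),
    gaze_density = nf / bbox_area,
    n_blinks = nb,
    blink_rate = nb / wdur * 60,
    longest_blink_duration = zero_if_empty(blinks$duration, max),
    current_blink_duration = if (nb == 0) 0 else blinks$duration[nb],
    closed_eye_time = sum(blinks$duration),
    n_saccades = ns,
    total_saccade_length = sum(amp),
    max_saccade_distance = zero_if_empty(amp, max),
    mean_saccade_length = zero_if_empty(amp, mean),
    total_saccade_time = total_sacc_time,
    mean_saccade_time = zero_if_empty(sdur, mean),
    max_saccade_time = zero_if_empty(sdur, max),
    mean_saccade_speed = if (!any(speed_ok)) 0 else
      mean(amp[speed_ok] / sdur[speed_ok]),
    overall_saccade_speed = if (total_sacc_time == 0) 0 else
      sum(amp) / total_sacc_time,
    mean_pupil_diameter = mean(samples$pupil, na.rm = TRUE)
  )
  out[!is.finite(out)] <- 0
  out
}

#' Time-independent features of one window
#'
#' Computes the 21 distributional and spatial metrics (medians, ranges,
#' moments, centre distances and grid-visit counts).  Skewness and kurtosis
#' fall back to 0 when fewer than three values exist; all outputs are
#' finite.
#'
#' @inheritParams compute_time_related
#' @return Named numeric vector of length 21, in manifest order.
#' @export
compute_time_independent <- function(samples, fixations, saccades, blinks,
                                     sample_rate = 100,
                                     config = feature_config()) {
  wdur <- length(samples$timestamp) / sample_rate
  nf <- length(fixations$onset)
  ns <- length(saccades$onset)
  nb <- length(blinks$onset)
  centre <- config$screen_extent / 2

  disp_sd <- 0
  if (nf > 0) {
    mx <- mean(fixations$x); my <- mean(fixations$y)
    disp_sd <- sqrt(mean((fixations$x - mx)^2 + (fixations$y - my)^2))
  }
  first_off <- if (nf == 0) 0 else
    sqrt((fixations$x[1] - centre[1])^2 + (fixations$y[1] - centre[2])^2)

  # per-second blink counts over the window's 1-s bins (onset bin)
  n_bins <- max(1, floor(wdur))
  bink <- rep(0, n_bins)
  if (nb > 0) {
    b <- pmin(floor(blinks$onset) + 1, n_bins)
    for (i in b) bink[i] <- bink[i] + 1
  }

  # grid-visit metrics over a cols x rows partition of the screen
  noting <- 0; returning <- 0
  if (nf > 0) {
    cx <- pmin(pmax(ceiling(fixations$x / config$screen_extent[1] *
                              config$grid[1]), 1), config$grid[1])
    cy <- pmin(pmax(ceiling(fixations$y / config$screen_extent[2] *
                              config$grid[2]), 1), config$grid[2])
    cell <- (cy - 1) * config$grid[1] + cx
    noting <- length(unique(cell))
    if (nf >= 2) {
      seen <- cell[1]
      for (i in 2:nf) {
        if (cell[i] != cell[i - 1] && cell[i] %in% seen)
          returning <- returning + 1
        seen <- c(seen, cell[i])
      }
    }
  }

  amc <- wmc <- 0
  if (nf > 0) {
    amc <- sqrt((mean(fixations$x) - centre[1])^2 +
                  (mean(fixations$y) - centre[2])^2)
    w <- fixations$duration / sum(fixations$duration)
    wmc <- sqrt((sum(w * fixations$x) - centre[1])^2 +
                  (sum(w * fixations$y) - centre[2])^2)
  }

  sx <- samples$x; sy <- samples$y
  ok <- !is.na(sx) & !is.na(sy)
  scanpath <- 0
  if (sum(ok) >= 2) {
    xs <- sx[ok]; ys <- sy[ok]
    scanpath <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
  }

  amp <- saccades$amplitude
  sacc_disp <- 0
  if (ns > 0) {
    ex <- saccades$x1; ey <- saccades$y1
    sacc_disp <- sqrt(mean((ex - mean(ex))^2 + (ey - mean(ey))^2))
  }

  out <- c(
    median_fixation_duration = zero_if_empty(fixations$duration,
                                             stats::median),
    fixation_time_ratio = sum(fixations$duration) / wdur,
    fixation_dispersion_sd = disp_sd,
    horizontal_range = if (nf == 0) 0 else max(diff(range(fixations$x)), 0),
    fixation_duration_sd = pop_sd(fixations$duration),
    fixation_duration_skewness = pop_skewness(fixations$duration),
    fixation_duration_kurtosis = pop_kurtosis(fixations$duration),
    first_fixation_offcenter = first_off,
    blink_count_sd = pop_sd(bink),
    noting = noting,
    returning = returning,
    arithmetic_mean_center = amc,
    weighted_mean_center = wmc,
    vertical_range = if (nf == 0) 0 else max(diff(range(fixations$y)), 0),
    median_saccade_distance = zero_if_empty(amp, stats::median),
    saccade_distance_sd = pop_sd(amp),
    saccade_distance_skewness = pop_skewness(amp),
    saccade_distance_kurtosis = pop_kurtosis(amp),
    scanpath_length = scanpath,
    global_local_ratio = sum(amp > config$global_amplitude) /
      max(1, sum(amp <= config$global_amplitude)),
    saccade_dispersion = sacc_disp
  )
  out[!is.finite(out)] <- 0
  out
}

#' All 44 features of one window
#'
#' Runs event detection and both feature groups on one preprocessed window.
#'
#' @param samples Window sample tibble.
#' @param events_cfg An [event_config()].
#' @param sample_rate Sampling frequency, Hz.
#' @param config A [feature_config()].
#' @return Named numeric vector of length 44 in manifest order.
#' @export
window_features <- function(samples, events_cfg = event_config(),
                            sample_rate = 100, config = feature_config()) {
  ev <- detect_events(samples, events_cfg, sample_rate)
  c(compute_time_related(samples, ev$fixations, ev$saccades, ev$blinks,
                         sample_rate, config),
    compute_time_independent(samples, ev$fixations, ev$saccades, ev$blinks,
                             sample_rate, config))
}

#' Feature matrix of a whole recording
#'
#' Computes the 44 features for every window of a preprocessed recording.
#'
#' @param recording A preprocessed `gaze_recording`.
#' @param windows Window tibble from [slide_windows()] (labels optional).
#' @param window_length Window length in samples.
#' @param events_cfg An [event_config()].
#' @param config A [feature_config()].
#' @return List with `features` (windows x 44 matrix, manifest column
#'   names) and `labels` (integer vector, `NA` where unassigned).
#' @export
recording_features <- function(recording, windows, window_length = 500,
                               events_cfg = event_config(),
                               config = feature_config()) {
  n <- nrow(windows)
  X <- matrix(0, nrow = n, ncol = 44)
  colnames(X) <- feature_manifest()$name
  # plain-vector fast path: column extraction once, per-window slicing only
  ts <- recording$samples$timestamp
  sx <- recording$samples$x
  sy <- recording$samples$y
  pu <- recording$samples$pupil
  bl <- recording$samples[["blink"]]
  if (is.null(bl)) bl <- rep(FALSE, length(ts))
  fs <- recording$sample_rate
  for (i in seq_len(n)) {
    a <- windows$start_index[i]
    idx <- a:(a + window_length - 1)
    s <- list(timestamp = ts[idx], x = sx[idx], y = sy[idx],
              pupil = pu[idx])
    blinks <- blinks_core(s$timestamp, bl[idx], events_cfg, fs)
    fix <- fixations_core(s$timestamp, s$x, s$y, bl[idx], events_cfg, fs)
    sac <- saccades_core(fix, blinks)
    X[i, ] <- c(compute_time_related(s, fix, sac, blinks, fs, config),
                compute_time_independent(s, fix, sac, blinks, fs, config))
  }
  list(features = X, labels = windows$label)
}

#' Fit min-max normalisation parameters
#'
#' Learns per-feature minima and maxima from a training feature matrix
#' (training folds only, to avoid leakage into validation data).
#'
#' @param X Numeric training matrix (rows = windows, columns = features).
#' @return List of class `minmax_params` with `min`, `max` and a
#'   `degenerate` flag per feature (max == min).
#' @export
fit_minmax <- function(X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  if (nrow(X) == 0) stop("fit_minmax: empty training set", call. = FALSE)
  mn <- apply(X, 2, min)
  mx <- apply(X, 2, max)
  structure(list(min = mn, max = mx, degenerate = mx == mn),
            class = "minmax_params")
}

#' Apply min-max normalisation
#'
#' Maps each feature by `(x - min) / (max - min)`.  Degenerate features
#' (max == min in training) map to 0; values outside the training range are
#' clipped into `[0, 1]`.
#'
#' @param X Numeric matrix (or vector) to normalise.
#' @param params A `minmax_params` object from [fit_minmax()].
#' @return Matrix of the same shape with all entries in `[0, 1]`.
#' @export
apply_minmax <- function(X, params) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, ncol = length(params$min), byrow = TRUE)
  rng <- params$max - params$min
  rng[params$degenerate] <- 1
  out <- sweep(sweep(X, 2, params$min), 2, rng, "/")
  out[, params$degenerate] <- 0
  out <- pmin(pmax(out, 0), 1)
  if (vec) out <- drop(out)
  out
}

#' Assemble event sequences from consecutive windows
#'
#' Groups `length` consecutive windows ("events") of one
#' recording into overlapping sequences at the given stride; the sequence
#' label is the label of its final window.  Recordings with fewer than
#' `length` windows yield no sequences.
#'
#' @param features Windows x 44 feature matrix of one recording, in
#'   temporal order (manifest column order).
#' @param labels Integer labels (0 normal / 1 forgetting) per window.
#' @param length Sequence length (number of consecutive windows; default 6).
#' @param stride Step between consecutive sequence starts (default 1).
#' @return An `event_sequences` object: list with `tc`
#'   (n x length x 23 array), `tic` (n x length x 21 array), `labels`.
#' @export
assemble_sequences <- function(features, labels, length = 6, stride = 1) {
  if (is.null(dim(features)) || ncol(features) != 44)
    stop("assemble_sequences: features must be a windows x 44 matrix",
         call. = FALSE)
  n_win <- nrow(features)
  starts <- if (n_win < length) integer(0) else
    seq.int(1, n_win - length + 1, by = stride)
  n_seq <- base::length(starts)
  tc <- array(0, dim = c(n_seq, length, 23))
  tic <- array(0, dim = c(n_seq, length, 21))
  lab <- integer(n_seq)
  for (s in seq_len(n_seq)) {
    idx <- starts[s]:(starts[s] + length - 1)
    tc[s, , ] <- features[idx, 1:23, drop = FALSE]
    tic[s, , ] <- features[idx, 24:44, drop = FALSE]
    lab[s] <- labels[idx[base::length(idx)]]
  }
  new_event_sequences(tc, tic, lab, recording = rep(1L, n_seq),
                      start = as.integer(starts))
}

# recording/start metadata records which windows each sequence came from,
# so evaluation splits can respect temporal adjacency.
new_event_sequences <- function(tc, tic, labels, recording = NULL,
                                start = NULL) {
  n <- dim(tc)[1]
  if (is.null(recording)) recording <- rep(1L, n)
  if (is.null(start)) start <- seq_len(n)
  structure(list(tc = tc, tic = tic, labels = as.integer(labels),
                 recording = as.integer(recording),
                 start = as.integer(start)),
            class = "event_sequences")
}

#' @export
print.event_sequences <- function(x, ...) {
  cat(sprintf(
    "<event_sequences> %d sequences of length %d (%d positive, %d negative)\n",
    dim(x$tc)[1], dim(x$tc)[2], sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' Number of sequences
#' @param x An `event_sequences` object.
#' @return Integer count.
#' @export
n_sequences <- function(x) dim(x$tc)[1]

#' Subset an event-sequence set
#' @param x An `event_sequences` object.
#' @param idx Integer index vector of sequences to keep.
#' @return The subset as `event_sequences`.
#' @export
subset_sequences <- function(x, idx) {
  new_event_sequences(x$tc[idx, , , drop = FALSE],
                      x$tic[idx, , , drop = FALSE],
                      x$labels[idx],
                      recording = x$recording[idx],
                      start = x$start[idx])
}

#' Concatenate event-sequence sets
#' @param sets List of `event_sequences` objects.
#' @return One combined `event_sequences` object.
#' @export
bind_sequences <- function(sets) {
  sets <- sets[vapply(sets, n_sequences, 1L) > 0]
  if (length(sets) == 0)
    stop("bind_sequences: no non-empty sequence sets", call. = FALSE)
  tc <- do.call(abind3, lapply(sets, `[[`, "tc"))
  tic <- do.call(abind3, lapply(sets, `[[`, "tic"))
  rec <- unlist(lapply(seq_along(sets), function(i)
    rep(i, n_sequences(sets[[i]]))))
  new_event_sequences(tc, tic, unlist(lapply(sets, `[[`, "labels")),
                      recording = rec,
                      start = unlist(lapply(sets, `[[`, "start")))
}

# Bind 3-d arrays along the first dimension.
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], 1L))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 1
  for (a in arrs) {
    k <- dim(a)[1]
    if (k > 0) out[at:(at + k - 1), , ] <- a
    at <- at + k
  }
  out
}

#' Normalise the features of a sequence set
#'
#' Fits min-max parameters on the 44 per-window features of a training
#' sequence set (pooling all windows of all its sequences) and applies them
#' to any sequence set.  Keeping the fit to training folds only prevents
#' information leaking into validation data.
#'
#' @param train An `event_sequences` object to fit on.
#' @return A list of two `minmax_params` (`tc`, `tic`).
#' @export
fit_sequence_minmax <- function(train) {
  flat <- function(a) matrix(a, nrow = dim(a)[1] * dim(a)[2])
  list(tc = fit_minmax(flat(train$tc)), tic = fit_minmax(flat(train$tic)))
}

#' @rdname fit_sequence_minmax
#' @param x An `event_sequences` object to normalise.
#' @param params Parameters from [fit_sequence_minmax()].
#' @return `x` with all feature entries mapped into `[0, 1]`.
#' @export
apply_sequence_minmax <- function(x, params) {
  norm_arr <- function(a, p) {
    d <- dim(a)
    m <- apply_minmax(matrix(a, nrow = d[1] * d[2]), p)
    array(m, dim = d)
  }
  new_event_sequences(norm_arr(x$tc, params$tc),
                      norm_arr(x$tic, params$tic),
                      x$labels)
}

#' Balance a sequence set by downsampling the majority class
#'
#' Forgetting episodes are rare, so negative sequences dominate; for
#' benchmarking, accuracy is only interpretable on a balanced set.
#'
#' @param x An `event_sequences` object.
#' @param seed Integer seed for the downsampling draw.
#' @return A balanced `event_sequences` object (shuffled).
#' @export
balance_sequences <- function(x, seed) {
  set.seed(as.integer(seed))
  pos <- which(x$labels == 1)
  neg <- which(x$labels == 0)
  k <- min(length(pos), length(neg))
  if (k == 0)
    stop("balance_sequences: need both classes present", call. = FALSE)
  keep <- c(sample(pos, k), sample(neg, k))
  subset_sequences(x, sample(keep))
}
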