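#' Scanpath generator parameters
#'
#' Bundles the oculomotor parameters of the synthetic scanpath generator.
#' The generator emulates a radar-monitoring task: gaze alternates between
#' fixations on a fixed set of on-screen targets and saccadic jumps between
#' them, with spontaneous blinks and slow pupil drift overlaid, sampled at
#' `sample_rate` Hz like a head-mounted research eye tracker.
#'
#' @param n_targets Number of simulated radar targets on screen.
#' @param fixation_duration_log_mean,fixation_duration_log_sd Parameters of
#'   the lognormal fixation-duration distribution (log seconds). Defaults
#'   give a median fixation of 0.30 s, typical of visual search.
#' @param saccade_peak_velocity Peak saccade velocity in px/s; saccade
#'   duration is `1.875 * amplitude / saccade_peak_velocity` (the
#'   minimum-jerk peak-to-mean velocity ratio), floored at two samples.
#' @param blink_rate Spontaneous blink rate, blinks per minute.
#' @param blink_duration_range Blink duration bounds in seconds.
#' @param pupil_baseline Baseline pupil diameter, mm.
#' @param pupil_noise_sd Standard deviation of the slow AR(1) pupil noise, mm.
#' @param screen_extent Screen size `c(width, height)` in px.
#' @param sample_rate Sampling frequency, Hz.
#' @param fixation_jitter_sd Within-fixation positional tremor, px.
#' @param target_min_separation Minimum pairwise distance between targets,
#'   px; keeps consecutive fixations spatially resolvable.
#' @param dropout_rate Rate of short non-blink signal dropouts ("improper
#'   collection" losses), events per minute.
#' @param dropout_length_range Duration bounds of a dropout, seconds.
#' @return A list of class `scanpath_params`.
#' @export
scanpath_params <- function(n_targets = 20,
                            fixation_duration_log_mean = log(0.30),
                            fixation_duration_log_sd = 0.40,
                            saccade_peak_velocity = 15000,
                            blink_rate = 15,
                            blink_duration_range = c(0.10, 0.40),
                            pupil_baseline = 4.0,
                            pupil_noise_sd = 0.08,
                            screen_extent = c(1680, 1050),
                            sample_rate = 100,
                            fixation_jitter_sd = 2,
                            target_min_separation = 120,
                            dropout_rate = 2,
                            dropout_length_range = c(0.01, 0.03)) {
  p <- list(
    n_targets = n_targets,
    fixation_duration_log_mean = fixation_duration_log_mean,
    fixation_duration_log_sd = fixation_duration_log_sd,
    saccade_peak_velocity = saccade_peak_velocity,
    blink_rate = blink_rate,
    blink_duration_range = blink_duration_range,
    pupil_baseline = pupil_baseline,
    pupil_noise_sd = pupil_noise_sd,
    screen_extent = screen_extent,
    sample_rate = sample_rate,
    fixation_jitter_sd = fixation_jitter_sd,
    target_min_separation = target_min_separation,
    dropout_rate = dropout_rate,
    dropout_length_range = dropout_length_range
  )
  class(p) <- "scanpath_params"
  validate_scanpath_params(p)
  p
}

validate_scanpath_params <- function(p) {
  if (!is.numeric(p$sample_rate) || p$sample_rate <= 0)
    stop("scanpath_params: sample_rate must be > 0", call. = FALSE)
  if (p$n_targets < 2)
    stop("scanpath_params: need at least 2 targets", call. = FALSE)
  if (p$fixation_duration_log_sd <= 0)
    stop("scanpath_params: fixation_duration_log_sd must be > 0", call. = FALSE)
  if (p$saccade_peak_velocity <= 0)
    stop("scanpath_params: saccade_peak_velocity must be > 0", call. = FALSE)
  if (p$blink_rate < 0)
    stop("scanpath_params: blink_rate must be >= 0", call. = FALSE)
  if (length(p$blink_duration_range) != 2 ||
      p$blink_duration_range[1] <= 0 ||
      p$blink_duration_range[1] >= p$blink_duration_range[2])
    stop("scanpath_params: blink_duration_range must be 0 < min < max",
         call. = FALSE)
  if (p$pupil_baseline <= 0)
    stop("scanpath_params: pupil_baseline must be > 0", call. = FALSE)
  if (length(p$screen_extent) != 2 || any(p$screen_extent <= 0))
    stop("scanpath_params: screen_extent must be two positive numbers",
         call. = FALSE)
  invisible(p)
}

#' Forgetting-episode parameters
#'
#' Controls the simulated control-forgetting (attention-lapse) episodes and
#' how oculomotor behaviour shifts while one is in progress.  With all
#' multipliers at 1 and `pupil_shift_mm = 0` the generator is a null model:
#' episodes are annotated but carry no oculomotor signal.
#'
#' @param episode_rate Episodes per hour.
#' @param episode_duration_range Episode duration bounds, seconds.
#' @param fixation_duration_multiplier Multiplies fixation durations during
#'   an episode (attentional tunnelling lengthens fixations).
#' @param saccade_amplitude_multiplier Scales saccadic jump amplitude during
#'   an episode (neglect shrinks the scanned area).
#' @param blink_rate_multiplier Multiplies the blink rate during an episode.
#' @param pupil_shift_mm Additive pupil-diameter shift during an episode, mm.
#' @return A list of class `episode_params`.
#' @export
episode_params <- function(episode_rate = 6,
                           episode_duration_range = c(30, 90),
                           fixation_duration_multiplier = 1.5,
                           saccade_amplitude_multiplier = 0.7,
                           blink_rate_multiplier = 1.5,
                           pupil_shift_mm = 0.3) {
  p <- list(
    episode_rate = episode_rate,
    episode_duration_range = episode_duration_range,
    fixation_duration_multiplier = fixation_duration_multiplier,
    saccade_amplitude_multiplier = saccade_amplitude_multiplier,
    blink_rate_multiplier = blink_rate_multiplier,
    pupil_shift_mm = pupil_shift_mm
  )
  class(p) <- "episode_params"
  validate_episode_params(p)
  p
}

#' Null (no-signal) episode parameters
#'
#' Episodes are still annotated at the given rate but all effect sizes are
#' neutral, so labelled and unlabelled windows are statistically identical.
#'
#' @param episode_rate Episodes per hour.
#' @param episode_duration_range Episode duration bounds, seconds.
#' @return A list of class `episode_params` with unit multipliers.
#' @export
null_episode_params <- function(episode_rate = 6,
                                episode_duration_range = c(30, 90)) {
  episode_params(episode_rate = episode_rate,
                 episode_duration_range = episode_duration_range,
                 fixation_duration_multiplier = 1,
                 saccade_amplitude_multiplier = 1,
                 blink_rate_multiplier = 1,
                 pupil_shift_mm = 0)
}

validate_episode_params <- function(p) {
  if (p$episode_rate < 0)
    stop("episode_params: episode_rate must be >= 0", call. = FALSE)
  if (length(p$episode_duration_range) != 2 ||
      p$episode_duration_range[1] <= 0 ||
      p$episode_duration_range[1] > p$episode_duration_range[2])
    stop("episode_params: episode_duration_range must be 0 < min <= max",
         call. = FALSE)
  for (nm in c("fixation_duration_multiplier", "saccade_amplitude_multiplier",
               "blink_rate_multiplier")) {
    if (p[[nm]] <= 0)
      stop(sprintf("episode_params: %s must be > 0", nm), call. = FALSE)
  }
  invisible(p)
}

# Minimum-jerk position profile on [0, 1].
minimum_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

in_intervals <- function(t, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(intervals))) {
    out <- out | (t >= intervals$start[i] & t < intervals$end[i])
  }
  out
}

# Rejection-sample target layout with minimum pairwise separation.
sample_targets <- function(n, extent, min_sep) {
  margin <- 0.05 * extent
  xs <- numeric(n); ys <- numeric(n)
  k <- 0; tries <- 0
  while (k < n && tries < 20000) {
    tries <- tries + 1
    x <- stats::runif(1, margin[1], extent[1] - margin[1])
    y <- stats::runif(1, margin[2], extent[2] - margin[2])
    if (k == 0 || all((xs[seq_len(k)] - x)^2 + (ys[seq_len(k)] - y)^2 >= min_sep^2)) {
      k <- k + 1
      xs[k] <- x; ys[k] <- y
    }
  }
  if (k < n)
    stop("could not place targets with the requested separation", call. = FALSE)
  cbind(x = xs, y = ys)
}

# Non-overlapping episode intervals by rejection placement.
sample_episodes <- function(ep, duration) {
  n_ep <- stats::rpois(1, ep$episode_rate * duration / 3600)
  if (n_ep == 0)
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  starts <- numeric(0); ends <- numeric(0)
  for (i in seq_len(n_ep)) {
    dur <- stats::runif(1, min(ep$episode_duration_range[1], duration),
                        min(ep$episode_duration_range[2], duration))
    placed <- FALSE
    for (try in 1:200) {
      s <- stats::runif(1, 0, max(duration - dur, 0))
      e <- s + dur
      if (!any(s < ends + 1 & e > starts - 1)) { # 1 s guard gap
        starts <- c(starts, s); ends <- c(ends, e)
        placed <- TRUE
        break
      }
    }
    # an episode that cannot be placed without overlap is dropped
  }
  o <- order(starts)
  tibble::tibble(start = starts[o], end = ends[o])
}

#' Simulate an annotated gaze recording
#'
#' Generates a seeded synthetic eye-tracker recording: a fixation–saccade
#' scanpath over randomly placed targets, spontaneous blinks (pupil samples
#' missing with confidence 0), short collection dropouts, AR(1) pupil noise,
#' and annotated forgetting episodes during which the episode effect sizes
#' apply to the generating distributions.
#'
#' @param params A [scanpath_params()] object.
#' @param episodes An [episode_params()] object.
#' @param duration Recording length in seconds (default 5400, a 90-minute
#'   session at 100 Hz, i.e. 540,000 samples).
#' @param seed Integer seed; the seed fully determines the output.
#' @return An object of class `gaze_recording`: a list with elements
#'   `samples` (tibble with columns `timestamp`, `x`, `y`, `pupil`,
#'   `confidence`), `sample_rate`, `episodes` (tibble `start`/`end` in
#'   seconds), `truth` (generated fixation/saccade/blink schedules, for
#'   detector validation), `seed` and `params`.
#' @examples
#' rec <- simulate_recording(duration = 30, seed = 1)
#' nrow(rec$samples)  # 3000 samples at 100 Hz
#' @export
simulate_recording <- function(params = scanpath_params(),
                               episodes = episode_params(),
                               duration = 5400,
                               seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("simulate_recording: an integer seed is required", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0)
    stop("simulate_recording: duration must be > 0", call. = FALSE)
  validate_scanpath_params(params)
  validate_episode_params(episodes)

  set.seed(as.integer(seed))
  fs <- params$sample_rate
  n <- round(duration * fs)
  ts <- (seq_len(n) - 1) / fs

  targets <- sample_targets(params$n_targets, params$screen_extent,
                            params$target_min_separation)
  ep_tab <- sample_episodes(episodes, duration)

  # --- event schedule: alternate fixations and saccades ------------------
  cap <- ceiling(duration / 0.20) + 10
  ev_type <- integer(cap)                       # 1 fixation, 2 saccade
  ev_t0 <- ev_t1 <- ev_x0 <- ev_y0 <- ev_x1 <- ev_y1 <- numeric(cap)
  k <- 0
  cur <- sample.int(params$n_targets, 1)
  pos <- targets[cur, ] + stats::rnorm(2, 0, 5)
  t <- 0
  while (t < duration) {
    in_ep <- any(t >= ep_tab$start & t < ep_tab$end)
    fdur <- stats::rlnorm(1, params$fixation_duration_log_mean,
                          params$fixation_duration_log_sd)
    if (in_ep) fdur <- fdur * episodes$fixation_duration_multiplier
    k <- k + 1
    ev_type[k] <- 1L
    ev_t0[k] <- t; ev_t1[k] <- t + fdur
    ev_x0[k] <- pos[1]; ev_y0[k] <- pos[2]
    t <- t + fdur
    if (t >= duration) break

    nxt <- sample.int(params$n_targets - 1, 1)
    if (nxt >= cur) nxt <- nxt + 1
    aim <- targets[nxt, ] + stats::rnorm(2, 0, 5)
    in_ep <- any(t >= ep_tab$start & t < ep_tab$end)
    m <- if (in_ep) episodes$saccade_amplitude_multiplier else 1
    dest <- pos + m * (aim - pos)
    dest[1] <- min(max(dest[1], 0), params$screen_extent[1])
    dest[2] <- min(max(dest[2], 0), params$screen_extent[2])
    amp <- sqrt(sum((dest - pos)^2))
    sdur <- max(2 / fs, 1.875 * amp / params$saccade_peak_velocity)
    k <- k + 1
    ev_type[k] <- 2L
    ev_t0[k] <- t; ev_t1[k] <- t + sdur
    ev_x0[k] <- pos[1]; ev_y0[k] <- pos[2]
    ev_x1[k] <- dest[1]; ev_y1[k] <- dest[2]
    t <- t + sdur
    pos <- dest
    cur <- nxt
  }
  ev_type <- ev_type[seq_len(k)]
  ev_t0 <- ev_t0[seq_len(k)]; ev_t1 <- ev_t1[seq_len(k)]
  ev_x0 <- ev_x0[seq_len(k)]; ev_y0 <- ev_y0[seq_len(k)]
  ev_x1 <- ev_x1[seq_len(k)]; ev_y1 <- ev_y1[seq_len(k)]
  ev_t1[k] <- max(ev_t1[k], duration)           # last event covers the tail

  # --- render gaze positions (vectorised over samples) -------------------
  idx <- findInterval(ts, ev_t0)
  idx[idx < 1] <- 1L
  is_fix <- ev_type[idx] == 1L
  x <- y <- numeric(n)
  x[is_fix] <- ev_x0[idx[is_fix]]
  y[is_fix] <- ev_y0[idx[is_fix]]
  if (any(!is_fix)) {
    j <- idx[!is_fix]
    tau <- (ts[!is_fix] - ev_t0[j]) / (ev_t1[j] - ev_t0[j])
    s <- minimum_jerk(tau)
    x[!is_fix] <- ev_x0[j] + s * (ev_x1[j] - ev_x0[j])
    y[!is_fix] <- ev_y0[j] + s * (ev_y1[j] - ev_y0[j])
  }
  x <- x + stats::rnorm(n, 0, params$fixation_jitter_sd)
  y <- y + stats::rnorm(n, 0, params$fixation_jitter_sd)

  # --- pupil: baseline + episode shift + slow AR(1) noise ----------------
  phi <- 0.95
  innov <- stats::rnorm(n, 0, params$pupil_noise_sd * sqrt(1 - phi^2))
  ar <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  shift <- episodes$pupil_shift_mm * as.numeric(in_intervals(ts, ep_tab))
  pupil <- params$pupil_baseline + shift + ar
  confidence <- stats::runif(n, 0.95, 1)

  # --- blinks: inhomogeneous Poisson via thinning ------------------------
  max_rate <- params$blink_rate *
    max(1, episodes$blink_rate_multiplier) / 60     # per second
  blink_on <- blink_off <- numeric(0)
  if (params$blink_rate > 0) {
    n_cand <- stats::rpois(1, max_rate * duration)
    cand <- sort(stats::runif(n_cand, 0, duration))
    rate_mult <- ifelse(in_intervals(cand, ep_tab),
                        episodes$blink_rate_multiplier, 1)
    keep <- stats::runif(n_cand) <
      (params$blink_rate * rate_mult / 60) / max_rate
    cand <- cand[keep]
    durs <- stats::runif(length(cand), params$blink_duration_range[1],
                         params$blink_duration_range[2])
    last_end <- -Inf
    for (i in seq_along(cand)) {
      if (cand[i] > last_end + 0.2 && cand[i] + durs[i] < duration) {
        blink_on <- c(blink_on, cand[i])
        blink_off <- c(blink_off, cand[i] + durs[i])
        last_end <- cand[i] + durs[i]
      }
    }
  }
  blink_tab <- tibble::tibble(onset = blink_on, offset = blink_off)
  bl <- in_intervals(ts, tibble::tibble(start = blink_on, end = blink_off))
  pupil[bl] <- NA_real_
  confidence[bl] <- 0

  # --- collection dropouts: all channels lost, confidence low ------------
  n_drop <- stats::rpois(1, params$dropout_rate * duration / 60)
  if (n_drop > 0) {
    d_on <- stats::runif(n_drop, 0, duration)
    d_len <- stats::runif(n_drop, params$dropout_length_range[1],
                          params$dropout_length_range[2])
    dr <- in_intervals(ts, tibble::tibble(start = d_on, end = d_on + d_len))
    dr <- dr & !bl                               # blinks take precedence
    x[dr] <- NA_real_; y[dr] <- NA_real_; pupil[dr] <- NA_real_
    confidence[dr] <- 0.2
  }

  fx <- ev_type == 1L
  truth <- list(
    fixations = tibble::tibble(onset = ev_t0[fx], offset = ev_t1[fx],
                               x = ev_x0[fx], y = ev_y0[fx]),
    saccades = tibble::tibble(onset = ev_t0[!fx], offset = ev_t1[!fx],
                              x0 = ev_x0[!fx], y0 = ev_y0[!fx],
                              x1 = ev_x1[!fx], y1 = ev_y1[!fx]),
    blinks = blink_tab
  )

  new_gaze_recording(
    samples = tibble::tibble(timestamp = ts, x = x, y = y,
                             pupil = pupil, confidence = confidence),
    sample_rate = fs,
    episodes = ep_tab,
    truth = truth,
    seed = as.integer(seed),
    params = list(scanpath = params, episodes = episodes)
  )
}

new_gaze_recording <- function(samples, sample_rate, episodes = NULL,
                               truth = NULL, seed = NULL, params = NULL) {
  structure(
    list(samples = samples, sample_rate = sample_rate, episodes = episodes,
         truth = truth, seed = seed, params = params),
    class = "gaze_recording"
  )
}

#' @export
print.gaze_recording <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<gaze_recording> %d samples @ %g Hz (%.1f s)\n",
              n, x$sample_rate, n / x$sample_rate))
  if (!is.null(x$episodes))
    cat(sprintf("  %d annotated episode(s)\n", nrow(x$episodes)))
  n_miss <- sum(is.na(x$samples$pupil))
  cat(sprintf("  %d missing pupil sample(s)\n", n_miss))
  invisible(x)
}

#' Write a gaze recording as delimited text
#'
#' Writes the sample table as CSV (missing values as empty fields) plus, if
#' episodes are annotated, a sidecar CSV with one `start_s,end_s` row per
#' episode at `<path>.episodes`.
#'
#' @param recording A `gaze_recording`.
#' @param path Output file path for the sample table.
#' @param episodes_path Sidecar path (default `<path>.episodes`).
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(recording, path,
                             episodes_path = paste0(path, ".episodes")) {
  readr::write_csv(recording$samples, path, na = "")
  if (!is.null(recording$episodes)) {
    ep <- recording$episodes
    readr::write_csv(
      tibble::tibble(start_s = ep$start, end_s = ep$end),
      episodes_path, na = ""
    )
  }
  invisible(path)
}

#' Read an episode sidecar file
#'
#' @param path Two-column delimited file of episode start/end seconds, with
#'   or without a header line.
#' @return Tibble with columns `start`, `end`.
#' @export
read_episode_file <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  tab <- utils::read.csv(path, header = has_header,
                         sep = if (grepl("\t", first)) "\t" else ",")
  if (ncol(tab) < 2)
    stop("episode file must have two columns (start, end)", call. = FALSE)
  tibble::tibble(start = as.numeric(tab[[1]]), end = as.numeric(tab[[2]]))
}

#' Null-signal sanity check for the generator
#'
#' Generates recordings, runs the full preprocessing + feature pipeline, and
#' tests every one of the 44 per-window features for a distributional
#' difference between episode-overlapping and non-overlapping windows
#' (two-sample Kolmogorov–Smirnov, Holm-adjusted).  With unit effect
#' multipliers no feature should reject; with a real effect size the
#' corresponding features should.
#'
#' @param n_recordings Number of recordings to simulate.
#' @param seed Integer seed.
#' @param params A [scanpath_params()] object.
#' @param episodes An [episode_params()] object (use [null_episode_params()]
#'   for the null check).
#' @param duration Per-recording duration, seconds.
#' @param alpha Significance level applied to Holm-adjusted p-values.
#' @return Tibble with one row per feature: `feature`, `statistic`, `p`,
#'   `p_adj`, `reject`, plus attributes `n_pos` / `n_neg` window counts.
#' @export
null_signal_check <- function(n_recordings = 20, seed,
                              params = scanpath_params(),
                              episodes = null_episode_params(),
                              duration = 600, alpha = 0.01) {
  if (missing(seed)) stop("null_signal_check: seed is required", call. = FALSE)
  feats <- list()
  labels <- integer(0)
  for (r in seq_len(n_recordings)) {
    rec <- simulate_recording(params, episodes, duration = duration,
                              seed = seed + r)
    rec <- preprocess_recording(rec)
    w <- slide_windows(rec)
    w <- assign_labels(w, rec$episodes)
    fm <- recording_features(rec, w)
    feats[[r]] <- fm$features
    labels <- c(labels, fm$labels)
  }
  X <- do.call(rbind, feats)
  pos <- labels == 1L
  if (!any(pos) || all(pos))
    stop("null_signal_check: need both labelled and unlabelled windows",
         call. = FALSE)
  pvals <- stats <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    kt <- suppressWarnings(stats::ks.test(X[pos, j], X[!pos, j]))
    pvals[j] <- kt$p.value
    stats[j] <- unname(kt$statistic)
  }
  p_adj <- stats::p.adjust(pvals, method = "holm")
  out <- tibble::tibble(
    feature = colnames(X),
    statistic = stats,
    p = pvals,
    p_adj = p_adj,
    reject = p_adj < alpha
  )
  attr(out, "n_pos") <- sum(pos)
  attr(out, "n_neg") <- sum(!pos)
  out
}

#' Ground-truth fixation count within a time span
#'
#' Counts the fixation segments the generator actually rendered inside
#' `[start, end)`: each scheduled fixation is first cut by any overlapping
#' blinks (eyes closed means no observable fixation), and every remaining
#' eye-open sub-segment at least `min_duration` long inside the span counts
#' as one fixation.  This is the reference an event detector should be
#' compared against.
#'
#' @param recording A simulated `gaze_recording` (with `truth`).
#' @param start,end Span bounds in seconds.
#' @param min_duration Minimum segment duration, s (match the detector's
#'   minimum fixation duration).
#' @return Integer count.
#' @export
planted_fixation_count <- function(recording, start, end,
                                   min_duration = 0.1) {
  if (is.null(recording$truth))
    stop("planted_fixation_count: recording has no generator truth",
         call. = FALSE)
  fx <- recording$truth$fixations
  bl <- recording$truth$blinks
  count <- 0L
  for (i in seq_len(nrow(fx))) {
    a <- fx$onset[i]; b <- fx$offset[i]
    if (b <= start || a >= end) next
    # cut the fixation into eye-open segments
    segs <- matrix(c(a, b), ncol = 2)
    if (nrow(bl) > 0) {
      for (j in seq_len(nrow(bl))) {
        keep <- list()
        for (k in seq_len(nrow(segs))) {
          sa <- segs[k, 1]; sb <- segs[k, 2]
          if (bl$offset[j] <= sa || bl$onset[j] >= sb) {
            keep[[length(keep) + 1]] <- c(sa, sb)
          } else {
            if (bl$onset[j] > sa)
              keep[[length(keep) + 1]] <- c(sa, bl$onset[j])
            if (bl$offset[j] < sb)
              keep[[length(keep) + 1]] <- c(bl$offset[j], sb)
          }
        }
        segs <- do.call(rbind, keep)
        if (is.null(segs)) break
      }
    }
    if (is.null(segs)) next
    vis <- pmin(segs[, 2], end) - pmax(segs[, 1], start)
    count <- count + sum(vis >= min_duration)
  }
  count
}
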