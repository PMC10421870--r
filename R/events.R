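#' Event-detection configuration
#'
#' Thresholds for segmenting a gaze window into blinks, fixations (I-DT
#' dispersion-threshold identification) and saccades.  At 100 Hz,
#' sample-to-sample velocity estimates are noisy, so a dispersion rule is
#' used rather than a velocity threshold.
#'
#' @param dispersion_threshold Maximum spatial spread
#'   `(max x - min x) + (max y - min y)` of a fixation, px.
#' @param min_fixation_duration Minimum fixation duration, s.
#' @param min_blink_duration,max_blink_duration Plausible blink duration
#'   bounds, s; flagged runs outside the bounds are ignored.
#' @param merge_max_gap Maximum gap (s) between consecutive fixations that
#'   are merged when their centroids lie within the dispersion threshold.
#'   Greedy dispersion grouping occasionally splits one fixation in two
#'   (saccade-tail samples inflate the entry dispersion); the merge pass is
#'   the standard repair.  Set to 0 to disable.
#' @return A list of class `event_config`.
#' @export
event_config <- function(dispersion_threshold = 30,
                         min_fixation_duration = 0.1,
                         min_blink_duration = 0.05,
                         max_blink_duration = 0.5,
                         merge_max_gap = 0.075) {
  if (dispersion_threshold <= 0 || min_fixation_duration <= 0 ||
      min_blink_duration <= 0 || max_blink_duration <= min_blink_duration ||
      merge_max_gap < 0)
    stop("event_config: thresholds must be positive with min_blink < max_blink",
         call. = FALSE)
  structure(
    list(dispersion_threshold = dispersion_threshold,
         min_fixation_duration = min_fixation_duration,
         min_blink_duration = min_blink_duration,
         max_blink_duration = max_blink_duration,
         merge_max_gap = merge_max_gap),
    class = "event_config"
  )
}

# ---- internal cores on plain vectors (hot path: thousands of windows) ----

blinks_core <- function(ts, blink_flag, cfg, fs) {
  empty <- list(onset = numeric(0), offset = numeric(0),
                duration = numeric(0))
  if (is.null(blink_flag) || !any(blink_flag)) return(empty)
  runs <- true_runs(blink_flag)
  dur <- unname((runs[, 2] - runs[, 1] + 1) / fs)
  keep <- dur >= cfg$min_blink_duration & dur <= cfg$max_blink_duration
  onset <- unname(ts[runs[keep, 1]] - ts[1])
  list(onset = onset, offset = onset + dur[keep], duration = dur[keep])
}

fixations_core <- function(ts, x, y, blink_flag, cfg, fs) {
  empty <- list(x = numeric(0), y = numeric(0), onset = numeric(0),
                offset = numeric(0), duration = numeric(0),
                start_index = integer(0), end_index = integer(0))
  if (is.null(blink_flag)) blink_flag <- rep(FALSE, length(ts))
  usable <- !blink_flag & !is.na(x) & !is.na(y)
  if (!any(usable)) return(empty)
  min_len <- max(2L, ceiling(cfg$min_fixation_duration * fs))
  runs <- true_runs(usable)
  cx <- cy <- on <- du <- numeric(0)
  si <- ei <- integer(0)
  for (r in seq_len(nrow(runs))) {
    a <- runs[r, 1]; b <- runs[r, 2]
    if (b - a + 1 < min_len) next
    spans <- idt_spans(x[a:b], y[a:b], min_len, cfg$dispersion_threshold)
    for (s in seq_len(nrow(spans))) {
      i <- unname(a + spans[s, 1] - 1L)
      j <- unname(a + spans[s, 2] - 1L)
      cx <- c(cx, mean(x[i:j])); cy <- c(cy, mean(y[i:j]))
      on <- c(on, ts[i] - ts[1])
      du <- c(du, (j - i + 1) / fs)
      si <- c(si, i); ei <- c(ei, j)
    }
  }
  fix <- list(x = cx, y = cy, onset = on, offset = on + du, duration = du,
              start_index = si, end_index = ei)
  merge_split_fixations(fix, cfg)
}

# Merge consecutive fixations separated by at most merge_max_gap whose
# centroids are within the dispersion threshold: these are one fixation the
# greedy grouping split, not two gaze targets.
merge_split_fixations <- function(fix, cfg) {
  n <- length(fix$onset)
  if (n < 2 || cfg$merge_max_gap <= 0) return(fix)
  i <- 1
  while (i < length(fix$onset)) {
    gap <- fix$onset[i + 1] - fix$offset[i]
    cd <- sqrt((fix$x[i + 1] - fix$x[i])^2 + (fix$y[i + 1] - fix$y[i])^2)
    if (gap <= cfg$merge_max_gap && cd <= cfg$dispersion_threshold) {
      w1 <- fix$duration[i]; w2 <- fix$duration[i + 1]
      fix$x[i] <- (w1 * fix$x[i] + w2 * fix$x[i + 1]) / (w1 + w2)
      fix$y[i] <- (w1 * fix$y[i] + w2 * fix$y[i + 1]) / (w1 + w2)
      fix$offset[i] <- fix$offset[i + 1]
      fix$end_index[i] <- fix$end_index[i + 1]
      fix$duration[i] <- fix$offset[i] - fix$onset[i]
      for (f in names(fix)) fix[[f]] <- fix[[f]][-(i + 1)]
    } else {
      i <- i + 1
    }
  }
  fix
}

saccades_core <- function(fix, blinks) {
  empty <- list(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                y1 = numeric(0), amplitude = numeric(0), onset = numeric(0),
                offset = numeric(0), duration = numeric(0))
  nf <- length(fix$onset)
  if (nf < 2) return(empty)
  i <- seq_len(nf - 1)
  on <- fix$offset[i]
  off <- fix$onset[i + 1]
  keep <- rep(TRUE, nf - 1)
  nb <- length(blinks$onset)
  if (nb > 0) {
    for (b in seq_len(nb)) {
      keep <- keep & !(blinks$onset[b] < off & blinks$offset[b] > on)
    }
  }
  i <- i[keep]
  if (length(i) == 0) return(empty)
  dx <- fix$x[i + 1] - fix$x[i]
  dy <- fix$y[i + 1] - fix$y[i]
  list(x0 = fix$x[i], y0 = fix$y[i], x1 = fix$x[i + 1], y1 = fix$y[i + 1],
       amplitude = sqrt(dx^2 + dy^2),
       onset = fix$offset[i], offset = fix$onset[i + 1],
       duration = pmax(fix$onset[i + 1] - fix$offset[i], 0))
}

# I-DT core on plain coordinate vectors; returns start/end index pairs.
idt_spans <- function(x, y, min_len, threshold) {
  n <- length(x)
  starts <- ends <- integer(0)
  i <- 1
  while (i + min_len - 1 <= n) {
    j <- i + min_len - 1
    xmin <- min(x[i:j]); xmax <- max(x[i:j])
    ymin <- min(y[i:j]); ymax <- max(y[i:j])
    if ((xmax - xmin) + (ymax - ymin) <= threshold) {
      while (j < n) {
        nx <- x[j + 1]; ny <- y[j + 1]
        nxmin <- min(xmin, nx); nxmax <- max(xmax, nx)
        nymin <- min(ymin, ny); nymax <- max(ymax, ny)
        if ((nxmax - nxmin) + (nymax - nymin) > threshold) break
        j <- j + 1
        xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
      }
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  cbind(start = starts, end = ends)
}

# ---- public tibble-returning surface -------------------------------------

#' Detect blinks in a window
#'
#' Each maximal blink-flagged run whose duration lies within the configured
#' bounds becomes one blink; runs outside the bounds are ignored.  Onsets
#' and offsets are relative to the window's own time axis.
#'
#' @param samples Window sample tibble (with the `blink` flag column kept by
#'   preprocessing).
#' @param cfg An [event_config()].
#' @param sample_rate Sampling frequency, Hz.
#' @return Tibble with columns `onset`, `offset`, `duration` (seconds).
#' @export
detect_blinks <- function(samples, cfg = event_config(), sample_rate = 100) {
  tibble::as_tibble(blinks_core(samples$timestamp, samples[["blink"]], cfg,
                                sample_rate))
}

#' Detect fixations in a window (I-DT)
#'
#' Greedy dispersion-threshold identification: within each run of non-blink
#' samples, a candidate span of at least `min_fixation_duration` grows while
#' its dispersion `(max x - min x) + (max y - min y)` stays within the
#' threshold; accepted spans become fixations with the centroid at the mean
#' member coordinate.  Fixations are non-overlapping and temporally ordered.
#'
#' @inheritParams detect_blinks
#' @return Tibble with columns `x`, `y` (centroid), `onset`, `offset`,
#'   `duration` (window-relative seconds), `start_index`, `end_index`.
#' @export
detect_fixations <- function(samples, cfg = event_config(),
                             sample_rate = 100) {
  tibble::as_tibble(fixations_core(samples$timestamp, samples$x, samples$y,
                                   samples[["blink"]], cfg, sample_rate))
}

#' Derive saccades from consecutive fixation pairs
#'
#' Each pair of consecutive fixations not separated by a blink yields one
#' saccade: start and end points are the two centroids, onset/offset are the
#' first fixation's offset and the second's onset, and the amplitude is the
#' centroid distance.  A blink between the two fixations suppresses the
#' saccade (a jump across an eyes-closed interval is not a saccade).
#'
#' @param fixations Fixation tibble from [detect_fixations()].
#' @param blinks Blink tibble from [detect_blinks()]; `NULL` disables blink
#'   suppression.
#' @return Tibble with columns `x0`, `y0`, `x1`, `y1`, `amplitude`, `onset`,
#'   `offset`, `duration`.
#' @export
derive_saccades <- function(fixations, blinks = NULL) {
  if (is.null(blinks)) blinks <- list(onset = numeric(0),
                                      offset = numeric(0))
  tibble::as_tibble(saccades_core(fixations, blinks))
}

#' Segment a window into all three event classes
#'
#' @inheritParams detect_blinks
#' @return List with elements `fixations`, `saccades`, `blinks` (tibbles).
#' @export
detect_events <- function(samples, cfg = event_config(), sample_rate = 100) {
  blinks <- detect_blinks(samples, cfg, sample_rate)
  fixations <- detect_fixations(samples, cfg, sample_rate)
  saccades <- derive_saccades(fixations, blinks)
  list(fixations = fixations, saccades = saccades, blinks = blinks)
}
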