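#' Read a raw gaze table
#'
#' Reads a delimited (comma or tab, auto-detected) eye-tracker export with
#' header columns `timestamp`, `x`, `y`, `pupil`, `confidence` in any order.
#' Empty fields become missing values.  Rows are sorted by timestamp if
#' needed (with a message); unparsable rows and absent columns raise errors
#' naming the offending line or column.
#'
#' @param path Path to the delimited text file.
#' @param sample_rate Sampling frequency in Hz (not stored in the export).
#' @param episodes_path Optional episode sidecar (see [read_episode_file()]);
#'   defaults to `<path>.episodes` when that file exists.
#' @return A `gaze_recording`.
#' @export
read_gaze_table <- function(path, sample_rate = 100, episodes_path = NULL) {
  if (!file.exists(path))
    stop(sprintf("gaze table not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  tab <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_double()),
    na = c("", "NA", "nan", "NaN")
  )
  probs <- readr::problems(tab)
  if (nrow(probs) > 0)
    stop(sprintf("unparsable value in %s at line %d: expected %s, got '%s'",
                 path, probs$row[1] + 1, probs$expected[1], probs$actual[1]),
         call. = FALSE)
  required <- c("timestamp", "x", "y", "pupil", "confidence")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    stop(sprintf("gaze table %s is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  tab <- tab[, required]
  if (any(!is.finite(tab$timestamp)))
    stop(sprintf("non-finite timestamp at line %d of %s",
                 which(!is.finite(tab$timestamp))[1] + 1, path),
         call. = FALSE)
  if (is.unsorted(tab$timestamp)) {
    message("read_gaze_table: timestamps out of order; sorting")
    tab <- tab[order(tab$timestamp), ]
  }
  cf <- tab$confidence
  if (any(cf < 0 | cf > 1, na.rm = TRUE))
    stop("confidence values outside [0, 1]", call. = FALSE)

  episodes <- NULL
  if (is.null(episodes_path)) {
    cand <- paste0(path, ".episodes")
    if (file.exists(cand)) episodes_path <- cand
  }
  if (!is.null(episodes_path)) episodes <- read_episode_file(episodes_path)

  new_gaze_recording(samples = tab, sample_rate = sample_rate,
                     episodes = episodes)
}

# Runs of consecutive TRUE values -> matrix of (start, end) indices.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Classify missing runs as blink loss or collection loss
#'
#' A maximal run of missing pupil samples counts as blink loss when
#' confidence is 0 for at least 80% of the run (a short tracker dropout can
#' interrupt an otherwise clean blink) and its duration lies within
#' `[min_blink, max_blink]`; all other missingness (any channel) is
#' collection loss.  Adds a logical `blink` column to the sample table.
#'
#' @param recording A `gaze_recording`.
#' @param min_blink,max_blink Plausible blink duration bounds, seconds.
#' @return The recording with a `blink` flag column.
#' @export
flag_missing_runs <- function(recording, min_blink = 0.05, max_blink = 0.5) {
  s <- recording$samples
  fs <- recording$sample_rate
  blink <- rep(FALSE, nrow(s))
  miss <- is.na(s$pupil)
  if (any(miss)) {
    runs <- true_runs(miss)
    for (i in seq_len(nrow(runs))) {
      a <- runs[i, 1]; b <- runs[i, 2]
      dur <- (b - a + 1) / fs
      if (dur >= min_blink && dur <= max_blink &&
          mean(s$confidence[a:b] == 0, na.rm = TRUE) >= 0.8) {
        blink[a:b] <- TRUE
      }
    }
  }
  recording$samples$blink <- blink
  recording
}

#' Fill blink-lost pupil samples by linear interpolation
#'
#' Replaces every blink-flagged missing pupil value with the straight line
#' between the flanking valid values; gaze coordinates are untouched.  A gap
#' touching a recording boundary is filled with the nearest valid value
#' (with a message), since interpolation is undefined there.
#'
#' @param recording A `gaze_recording`; [flag_missing_runs()] is applied
#'   first if the `blink` flag column is absent.
#' @return The recording with blink gaps in `pupil` filled; the `blink`
#'   flag column is retained for event detection.
#' @export
fill_blink_gaps <- function(recording) {
  if (!"blink" %in% names(recording$samples))
    recording <- flag_missing_runs(recording)
  s <- recording$samples
  fill_idx <- which(s$blink & is.na(s$pupil))
  if (length(fill_idx) == 0) return(recording)
  valid <- which(!is.na(s$pupil))
  if (length(valid) == 0)
    stop("fill_blink_gaps: no valid pupil samples to interpolate from",
         call. = FALSE)
  if (fill_idx[1] < valid[1] || fill_idx[length(fill_idx)] > valid[length(valid)])
    message("fill_blink_gaps: gap at recording boundary filled with ",
            "nearest valid value")
  interp <- stats::approx(x = valid, y = s$pupil[valid], xout = fill_idx,
                          method = "linear", rule = 2)$y
  recording$samples$pupil[fill_idx] <- interp
  recording
}

#' Fill collection-loss gaps with the local average
#'
#' Each non-blink missing value in `x`, `y` or `pupil` is replaced by the
#' mean of the valid samples within `radius` samples on either side.
#'
#' @param recording A `gaze_recording`; missing runs are classified first if
#'   needed.
#' @param radius Neighbourhood half-width in samples.
#' @return The repaired recording.
#' @export
fill_collection_gaps <- function(recording, radius = 10) {
  if (!"blink" %in% names(recording$samples))
    recording <- flag_missing_runs(recording)
  s <- recording$samples
  n <- nrow(s)
  for (ch in c("x", "y", "pupil")) {
    v <- s[[ch]]
    v0 <- v                         # fill from the original values only
    idx <- if (ch == "pupil") which(is.na(v) & !s$blink) else which(is.na(v))
    for (i in idx) {
      lo <- max(1, i - radius); hi <- min(n, i + radius)
      nb <- v0[lo:hi]
      nb <- nb[!is.na(nb)]
      if (length(nb) == 0)
        stop(sprintf(
          "fill_collection_gaps: no valid %s sample within %d samples of index %d (t = %.3f s)",
          ch, radius, i, s$timestamp[i]), call. = FALSE)
      v[i] <- mean(nb)
    }
    s[[ch]] <- v
  }
  recording$samples <- s
  recording
}

#' Full preprocessing: classify, then repair, missing data
#'
#' Applies [flag_missing_runs()], [fill_blink_gaps()] and
#' [fill_collection_gaps()] in order, mirroring the repair rules the
#' feature pipeline assumes: blink losses interpolated linearly, collection
#' losses filled with the surrounding average.
#'
#' @param recording A `gaze_recording`.
#' @param radius Neighbourhood half-width for collection-loss repair.
#' @return The repaired recording (blink flags retained).
#' @export
preprocess_recording <- function(recording, radius = 10) {
  recording <- flag_missing_runs(recording)
  recording <- fill_blink_gaps(recording)
  fill_collection_gaps(recording, radius = radius)
}

#' Cut a recording into overlapping fixed-length windows
#'
#' Windows are `window_length` samples long and adjacent windows share
#' `overlap` samples, so starts fall at multiples of
#' `stride = window_length - overlap`; a trailing remainder shorter than one
#' window is discarded.
#'
#' @param recording A `gaze_recording`.
#' @param window_length Window length in samples (default 500, i.e. 5 s at
#'   100 Hz).
#' @param overlap Overlap between adjacent windows in samples (default 100).
#' @return Tibble with one row per window: `start_index` (1-based),
#'   `start_time`, `end_time`, `label` (`NA` until assigned).
#' @export
slide_windows <- function(recording, window_length = 500, overlap = 100) {
  if (window_length <= overlap || overlap < 0)
    stop("slide_windows: need window_length > overlap >= 0", call. = FALSE)
  n <- nrow(recording$samples)
  stride <- window_length - overlap
  if (n < window_length)
    return(tibble::tibble(start_index = integer(0), start_time = numeric(0),
                          end_time = numeric(0), label = integer(0)))
  n_windows <- (n - window_length) %/% stride + 1
  start_index <- (seq_len(n_windows) - 1L) * stride + 1L
  ts <- recording$samples$timestamp
  fs <- recording$sample_rate
  tibble::tibble(
    start_index = start_index,
    start_time = ts[start_index],
    end_time = ts[start_index] + window_length / fs,
    label = rep(NA_integer_, n_windows)
  )
}

#' Label windows by episode overlap
#'
#' A window is labelled as forgetting (1) when its time span overlaps any
#' annotated episode by at least `min_overlap` of the window duration,
#' otherwise normal (0).
#'
#' @param windows Window tibble from [slide_windows()].
#' @param episodes Tibble with `start` / `end` columns (seconds), or `NULL`.
#' @param min_overlap Minimum overlap fraction (default 0.5).
#' @return The window tibble with the `label` column filled in.
#' @export
assign_labels <- function(windows, episodes, min_overlap = 0.5) {
  n <- nrow(windows)
  if (n == 0) return(windows)
  lab <- rep(0L, n)
  if (!is.null(episodes) && nrow(episodes) > 0) {
    for (i in seq_len(n)) {
      a <- windows$start_time[i]; b <- windows$end_time[i]
      ov <- pmax(0, pmin(b, episodes$end) - pmax(a, episodes$start))
      if (sum(ov) >= min_overlap * (b - a)) lab[i] <- 1L
    }
  }
  windows$label <- lab
  windows
}

#' Extract the samples of one window
#'
#' @param recording A `gaze_recording`.
#' @param start_index 1-based start sample of the window.
#' @param window_length Window length in samples.
#' @return The sample tibble slice of length `window_length`.
#' @export
window_samples <- function(recording, start_index, window_length = 500) {
  n <- nrow(recording$samples)
  if (start_index < 1 || start_index + window_length - 1 > n)
    stop("window_samples: window exceeds the recording", call. = FALSE)
  recording$samples[start_index:(start_index + window_length - 1), ]
}
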