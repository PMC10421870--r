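# Shared fixture builders: everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A recording built directly from vectors (no simulator), for I/O and
# repair tests.
manual_recording <- function(pupil, x = NULL, y = NULL, confidence = NULL,
                             sample_rate = 100, blink = NULL) {
  n <- length(pupil)
  if (is.null(x)) x <- rep(100, n)
  if (is.null(y)) y <- rep(100, n)
  if (is.null(confidence)) confidence <- rep(1, n)
  samples <- tibble::tibble(
    timestamp = (seq_len(n) - 1) / sample_rate,
    x = x, y = y, pupil = pupil, confidence = confidence
  )
  if (!is.null(blink)) samples$blink <- blink
  gazelapse:::new_gaze_recording(samples, sample_rate)
}

# Window samples with point clusters at given centres, for event tests.
cluster_window <- function(centres, n_per = 15, sample_rate = 100,
                           jitter = 0) {
  xs <- ys <- numeric(0)
  for (i in seq_len(nrow(centres))) {
    xs <- c(xs, centres[i, 1] + jitter * stats::rnorm(n_per))
    ys <- c(ys, centres[i, 2] + jitter * stats::rnorm(n_per))
  }
  n <- length(xs)
  tibble::tibble(
    timestamp = (seq_len(n) - 1) / sample_rate,
    x = xs, y = ys, pupil = rep(4, n), confidence = rep(1, n),
    blink = rep(FALSE, n)
  )
}

# Synthetic event lists for direct feature-formula tests.
make_fixations <- function(durations, x, y, gap = 0.05) {
  if (length(durations) == 0)
    return(tibble::tibble(x = numeric(0), y = numeric(0),
                          onset = numeric(0), offset = numeric(0),
                          duration = numeric(0)))
  onset <- cumsum(c(0, utils::head(durations, -1) + gap))
  tibble::tibble(x = x, y = y, onset = onset, offset = onset + durations,
                 duration = durations)
}

make_saccades <- function(amplitudes, durations = rep(0.05,
                                                      length(amplitudes))) {
  if (length(amplitudes) == 0)
    return(tibble::tibble(x0 = numeric(0), y0 = numeric(0),
                          x1 = numeric(0), y1 = numeric(0),
                          amplitude = numeric(0), onset = numeric(0),
                          offset = numeric(0), duration = numeric(0)))
  onset <- cumsum(c(0, utils::head(durations, -1) + 0.3))
  tibble::tibble(x0 = 0, y0 = 0, x1 = amplitudes, y1 = 0,
                 amplitude = amplitudes, onset = onset,
                 offset = onset + durations, duration = durations)
}

empty_blinks <- function() {
  tibble::tibble(onset = numeric(0), offset = numeric(0),
                 duration = numeric(0))
}

plain_samples <- function(n = 500, sample_rate = 100) {
  list(timestamp = (seq_len(n) - 1) / sample_rate,
       x = rep(100, n), y = rep(100, n), pupil = rep(4, n))
}

# Linearly separable toy sequences: one time-related feature carries the
# label, everything else is noise.
toy_sequences <- function(n = 60, seq_len = 6, seed = 1, signal = 2,
                          tc_width = 23, tic_width = 21) {
  set.seed(seed)
  lab <- rep(c(0L, 1L), length.out = n)
  tc <- array(stats::rnorm(n * seq_len * tc_width, 0, 0.3),
              c(n, seq_len, tc_width))
  tic <- array(stats::rnorm(n * seq_len * tic_width, 0, 0.3),
               c(n, seq_len, tic_width))
  tc[, , 1] <- tc[, , 1] + signal * lab
  tic[, , 1] <- tic[, , 1] + signal * lab
  gazelapse:::new_event_sequences(tc, tic, lab)
}

# Small architecture for fast training tests.
small_config <- function(arch = "hybrid") {
  hybrid_config(arch = arch, channels = 8, hidden = 8, lstm_layers = 2,
                conv_layers = 2)
}
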