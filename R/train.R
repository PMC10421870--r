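#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-4).
#' @param epochs Training epochs (default 100).
#' @param batch_size Sequences per batch (default 64).
#' @param beta1,beta2 Adam exponential decay rates for the first and second
#'   gradient moments.
#' @param adam_eps Adam denominator stabiliser.
#' @param folds Cross-validation folds (default 5).
#' @param seed Integer seed governing shuffling, fold assignment and
#'   initialisation.
#' @param class_weights Logical; weight the loss by inverse class frequency
#'   (useful when forgetting sequences are rare).
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 100, batch_size = 64,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         folds = 5, seed = 1, class_weights = FALSE) {
  if (learning_rate <= 0 || epochs <= 0 || batch_size <= 0 || folds < 2)
    stop("train_config: rates/counts must be positive, folds >= 2",
         call. = FALSE)
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, folds = folds, seed = as.integer(seed),
                 class_weights = class_weights),
            class = "train_config")
}

#' Initialise Adam optimiser state
#'
#' @param params Named list of parameter arrays.
#' @return List with zeroed first/second moment accumulators and step 0.
#' @export
adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim = if (is.null(dim(p)))
    length(p) else dim(p)))
  list(m = zeros, v = zeros, t = 0L)
}

#' One Adam update step
#'
#' Exponential moving averages of the gradient and squared gradient with
#' bias correction: `m <- b1 m + (1-b1) g`, `v <- b2 v + (1-b2) g^2`,
#' `p <- p - lr * mhat / (sqrt(vhat) + eps)`.
#'
#' @param params,grads Named lists of parameter / gradient arrays.
#' @param state Optimiser state from [adam_init()].
#' @param cfg A [train_config()] (provides `learning_rate`, `beta1`,
#'   `beta2`, `adam_eps`).
#' @return List with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      cfg$learning_rate * mhat / (sqrt(vhat) + cfg$adam_eps)
  }
  list(params = params, state = state)
}

#' Train a hybrid model with Adam
#'
#' Mini-batch training of the (optionally class-weighted) cross-entropy
#' with per-epoch reshuffling under the configuration seed.  Batches of a
#' single sequence are skipped (training-mode batch normalisation is
#' undefined there).
#'
#' @param model An initialised `hybrid_model`.
#' @param sequences A normalised `event_sequences` training set.
#' @param cfg A [train_config()].
#' @return List with the trained `model` and `loss_trace` (mean training
#'   loss per epoch).
#' @export
adam_train <- function(model, sequences, cfg = train_config()) {
  n <- n_sequences(sequences)
  if (n == 0) stop("adam_train: empty training set", call. = FALSE)
  w_class <- c(1, 1)
  if (isTRUE(cfg$class_weights)) {
    n1 <- max(sum(sequences$labels == 1L), 1)
    n0 <- max(sum(sequences$labels == 0L), 1)
    w_class <- c(n / (2 * n0), n / (2 * n1))   # index 1: label 0, 2: label 1
  }
  state <- adam_init(model$params)
  loss_trace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    set.seed(cfg$seed + ep)
    ord <- sample.int(n)
    ep_loss <- 0; ep_n <- 0
    at <- 1
    while (at <= n) {
      idx <- ord[at:min(at + cfg$batch_size - 1, n)]
      at <- at + cfg$batch_size
      if (length(idx) < 2) next
      lab <- sequences$labels[idx]
      w <- w_class[lab + 1L]
      lg <- hybrid_loss_grads(model,
                              sequences$tc[idx, , , drop = FALSE],
                              sequences$tic[idx, , , drop = FALSE],
                              lab, weights = w)
      model$running <- lg$running
      upd <- adam_step(model$params, lg$grads, state, cfg)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + lg$loss * length(idx)
      ep_n <- ep_n + length(idx)
    }
    loss_trace[ep] <- ep_loss / max(ep_n, 1)
  }
  list(model = model, loss_trace = loss_trace)
}

#' Classification accuracy on a sequence set
#'
#' Fraction of sequences whose predicted class matches the label.  A
#' sequence is called forgetting only when `p_forgetting > 0.5`, so an
#' exact tie goes to the normal class.
#'
#' @param model A trained model with a [predict_proba()] method.
#' @param sequences An `event_sequences` object (normalised as in
#'   training).
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_accuracy <- function(model, sequences) {
  n <- n_sequences(sequences)
  if (n == 0) stop("evaluate_accuracy: empty sequence set", call. = FALSE)
  p <- predict_proba(model, sequences)
  pred <- as.integer(p[, 1] > 0.5)
  mean(pred == sequences$labels)
}

#' Logistic-regression baseline
#'
#' Binary logistic regression on the per-sequence mean of the 44 base
#' features (each sequence's six event vectors averaged), fitted by
#' iteratively reweighted least squares.  All methods therefore see the
#' same sequences and labels; only the representation differs.
#'
#' @param sequences A normalised `event_sequences` training set.
#' @return An object of class `logistic_lapse` with the coefficient vector.
#' @export
train_logistic_baseline <- function(sequences) {
  X <- sequence_mean_features(sequences)
  y <- sequences$labels
  fit <- suppressWarnings(stats::glm.fit(
    x = cbind(1, X), y = y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  if (!fit$converged)
    warning("logistic baseline did not converge", call. = FALSE)
  structure(list(coef = fit$coefficients, converged = fit$converged),
            class = "logistic_lapse")
}

sequence_mean_features <- function(sequences) {
  flat <- function(a) apply(a, c(1, 3), mean)
  cbind(flat(sequences$tc), flat(sequences$tic))
}

#' @export
predict_proba.logistic_lapse <- function(model, sequences,
                                         batch_size = NULL) {
  X <- sequence_mean_features(sequences)
  eta <- drop(cbind(1, X) %*% ifelse(is.na(model$coef), 0, model$coef))
  p1 <- stats::plogis(eta)
  cbind(p_forgetting = p1, p_normal = 1 - p1)
}

#' Shuffled consecutive fold assignment
#'
#' One shuffle under the seed, then a partition into `k` consecutive folds
#' of near-equal size.
#'
#' @param n Number of items.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold memberships (1..k) per item.
#' @export
make_folds <- function(n, k, seed) {
  if (n < k) stop("make_folds: fewer items than folds", call. = FALSE)
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  fold
}

fit_one_method <- function(method, train, valid, cfg, model_config) {
  norm <- fit_sequence_minmax(train)
  train_n <- apply_sequence_minmax(train, norm)
  valid_n <- apply_sequence_minmax(valid, norm)
  if (method == "logistic") {
    fit <- train_logistic_baseline(train_n)
    list(model = fit, accuracy = evaluate_accuracy(fit, valid_n),
         loss_trace = NULL)
  } else {
    arch <- switch(method, hybrid = "hybrid", conv_only = "conv_only",
                   recurrent_only = "recurrent_only",
                   stop("unknown method: ", method, call. = FALSE))
    mc <- model_config
    mc$arch <- arch
    model <- init_params(do.call(hybrid_config, mc[names(mc) != "splice_width"]),
                         seed = cfg$seed + 77)
    tr <- adam_train(model, train_n, cfg)
    list(model = tr$model,
         accuracy = evaluate_accuracy(tr$model, valid_n),
         loss_trace = tr$loss_trace)
  }
}

#' Five-fold cross-validation of one method
#'
#' The standard protocol: one shuffle of the sequence set under the seed, a
#' partition into `cfg$folds` consecutive folds, and for each fold a fresh
#' initialisation, normalisation parameters fitted on the training folds
#' only, training, and validation accuracy on the held-out fold.  The
#' summary accuracy is the arithmetic mean over folds.
#'
#' @param sequences An `event_sequences` object (raw, unnormalised
#'   features; normalisation happens per fold).
#' @param cfg A [train_config()].
#' @param method One of `"hybrid"`, `"conv_only"`, `"recurrent_only"`,
#'   `"logistic"`.
#' @param model_config A [hybrid_config()] for the network methods (its
#'   `arch` is overridden by `method`).
#' @return List of class `cv_result`: `method`, `fold_accuracy`,
#'   `mean_accuracy`, `loss_traces`, `folds` (assignment vector), `seed`.
#' @export
five_fold_cv <- function(sequences, cfg = train_config(), method = "hybrid",
                         model_config = hybrid_config()) {
  n <- n_sequences(sequences)
  if (n < cfg$folds)
    stop("five_fold_cv: fewer sequences than folds", call. = FALSE)
  fold <- make_folds(n, cfg$folds, cfg$seed)
  accs <- numeric(cfg$folds)
  traces <- vector("list", cfg$folds)
  for (k in seq_len(cfg$folds)) {
    train <- subset_sequences(sequences, which(fold != k))
    valid <- subset_sequences(sequences, which(fold == k))
    fk <- cfg
    fk$seed <- cfg$seed + 1000 * k
    r <- fit_one_method(method, train, valid, fk, model_config)
    accs[k] <- r$accuracy
    traces[[k]] <- r$loss_trace
  }
  structure(list(method = method, fold_accuracy = accs,
                 mean_accuracy = mean(accs), loss_traces = traces,
                 folds = fold, seed = cfg$seed),
            class = "cv_result")
}

#' Compare methods evaluated on identical folds
#'
#' @param entries List of `cv_result` objects (or holdout results) sharing
#'   one fold assignment.
#' @return Tibble sorted by descending mean accuracy with per-fold detail
#'   and the across-fold standard deviation.
#' @export
comparison_report <- function(entries) {
  if (length(entries) < 2)
    stop("comparison_report: need at least two entries", call. = FALSE)
  f0 <- entries[[1]]$folds
  for (e in entries) {
    if (!identical(e$folds, f0))
      stop("comparison_report: entries were evaluated on different folds",
           call. = FALSE)
  }
  tab <- tibble::tibble(
    method = vapply(entries, `[[`, "", "method"),
    mean_accuracy = vapply(entries, `[[`, 0, "mean_accuracy"),
    sd_accuracy = vapply(entries, function(e) stats::sd(e$fold_accuracy), 0),
    fold_accuracy = lapply(entries, `[[`, "fold_accuracy"),
    seed = vapply(entries, `[[`, 0L, "seed")
  )
  tab[order(-tab$mean_accuracy), ]
}

#' Blocked train/validation split of overlapping sequences
#'
#' Consecutive stride-1 sequences share all but one of their windows, so a
#' random sequence-level split would place near-duplicates of validation
#' items in the training set and inflate every method's validation accuracy
#' (most visibly on null data, where chance is the truth).  This split
#' keeps time contiguous: each recording's sequences are cut into
#' `n_blocks` blocks, whole blocks go to validation, and training
#' sequences that share any window with a validation sequence are purged.
#'
#' @param sequences An `event_sequences` object with recording/start
#'   metadata.
#' @param fraction Target fraction of blocks per recording held out.
#' @param seed Integer seed for the block draw.
#' @param n_blocks Blocks per recording.
#' @return List with integer index vectors `train` and `valid`.
#' @export
blocked_holdout_split <- function(sequences, fraction, seed, n_blocks = 8) {
  L <- dim(sequences$tc)[2]
  n <- n_sequences(sequences)
  for (try in 0:49) {
    set.seed(as.integer(seed) + 1000L * try)
    valid <- logical(n)
    purged <- logical(n)
    for (r in unique(sequences$recording)) {
      idx <- which(sequences$recording == r)
      idx <- idx[order(sequences$start[idx])]
      nb <- min(n_blocks, length(idx))
      block <- cut(seq_along(idx), nb, labels = FALSE)
      pick <- sample.int(nb, max(1, round(fraction * nb)))
      v <- idx[block %in% pick]
      valid[v] <- TRUE
      if (length(v) > 0) {
        st <- sequences$start[idx]
        vs <- sequences$start[v]
        for (b in pick) {
          rng <- range(sequences$start[idx[block == b]])
          purged[idx[st >= rng[1] - (L - 1) & st <= rng[2] + (L - 1)]] <- TRUE
        }
      }
    }
    train <- which(!valid & !purged)
    valid_i <- which(valid)
    both <- function(ii) length(unique(sequences$labels[ii])) == 2
    if (length(train) > 0 && length(valid_i) > 0 &&
        both(train) && both(valid_i))
      return(list(train = train, valid = valid_i))
  }
  stop("blocked_holdout_split: could not draw a split with both classes ",
       "on both sides", call. = FALSE)
}

#' Blocked holdout benchmark of several methods
#'
#' One leakage-free blocked train/validation split under the seed (see
#' [blocked_holdout_split()]), shared by all methods; both sides are then
#' class-balanced by downsampling negatives, and normalisation is fitted on
#' the training split only.
#'
#' @param sequences An `event_sequences` object (raw features,
#'   unbalanced).
#' @param methods Character vector of methods (see [five_fold_cv()]).
#' @param cfg A [train_config()].
#' @param model_config A [hybrid_config()].
#' @param holdout_fraction Fraction of blocks held out for validation.
#' @param balance Logical; balance classes on each side of the split.
#' @param n_blocks Contiguous blocks per recording for the split.
#' @return Tibble with one row per method: `method`, `accuracy`, `n_train`,
#'   `n_valid`, sorted by descending accuracy.
#' @export
holdout_benchmark <- function(sequences,
                              methods = c("hybrid", "conv_only",
                                          "recurrent_only", "logistic"),
                              cfg = train_config(),
                              model_config = hybrid_config(),
                              holdout_fraction = 0.25, balance = TRUE,
                              n_blocks = 8) {
  sp <- blocked_holdout_split(sequences, holdout_fraction, cfg$seed,
                              n_blocks = n_blocks)
  train <- subset_sequences(sequences, sp$train)
  valid <- subset_sequences(sequences, sp$valid)
  if (balance) {
    train <- balance_sequences(train, seed = cfg$seed + 11)
    valid <- balance_sequences(valid, seed = cfg$seed + 12)
  }
  acc <- numeric(length(methods))
  for (m in seq_along(methods)) {
    r <- fit_one_method(methods[m], train, valid, cfg, model_config)
    acc[m] <- r$accuracy
  }
  out <- tibble::tibble(method = methods, accuracy = acc,
                        n_train = n_sequences(train),
                        n_valid = n_sequences(valid))
  out[order(-out$accuracy), ]
}

#' Simulate a labelled benchmark sequence set
#'
#' Simulates `n_recordings` annotated recordings, runs the preprocessing,
#' windowing, labelling and feature pipeline, assembles 6-event sequences
#' per recording, pools them, and (optionally) balances the classes by
#' downsampling negatives.
#'
#' @param n_recordings Number of recordings.
#' @param duration Per-recording duration, seconds.
#' @param scan A [scanpath_params()] object.
#' @param episodes An [episode_params()] object.
#' @param seed Integer seed.
#' @param balance Logical; balance classes by downsampling negatives
#'   (leave `FALSE` when a blocked split will balance each side itself).
#' @param seq_len Sequence length.
#' @return An `event_sequences` object with raw (unnormalised) features.
#' @export
make_benchmark_dataset <- function(n_recordings = 4, duration = 5400,
                                   scan = scanpath_params(),
                                   episodes = episode_params(),
                                   seed = 1, balance = FALSE, seq_len = 6) {
  sets <- list()
  for (r in seq_len(n_recordings)) {
    rec <- simulate_recording(scan, episodes, duration = duration,
                              seed = seed + 131 * r)
    rec <- preprocess_recording(rec)
    w <- assign_labels(slide_windows(rec), rec$episodes)
    fm <- recording_features(rec, w)
    sets[[r]] <- assemble_sequences(fm$features, fm$labels, length = seq_len)
  }
  seqs <- bind_sequences(sets)
  if (balance) seqs <- balance_sequences(seqs, seed = seed + 7)
  seqs
}

#' One-call benchmark under signal or null study conditions
#'
#' Simulates a benchmark dataset under the default scanpath parameters with
#' either the default (signal-bearing) or the null (unit-multiplier)
#' episode effects, then runs the blocked, class-balanced holdout
#' comparison of the requested methods.
#'
#' @param seed Integer seed controlling simulation, split and training.
#' @param condition `"signal"` (default episode effect sizes) or `"null"`
#'   (annotated episodes with no oculomotor signal).
#' @param n_recordings,duration Dataset size (recordings x seconds).
#' @param epochs Training epochs.
#' @param holdout_fraction Validation fraction of the blocked split.
#' @param methods Methods to compare (see [five_fold_cv()]).
#' @param n_blocks Contiguous blocks per recording for the split.
#' @return Tibble from [holdout_benchmark()] plus a `n_sequences` column.
#' @export
lapse_benchmark <- function(seed, condition = c("signal", "null"),
                            n_recordings = 4, duration = 5400, epochs = 30,
                            holdout_fraction = 0.25,
                            methods = c("hybrid", "conv_only",
                                        "recurrent_only", "logistic"),
                            n_blocks = 8) {
  condition <- match.arg(condition)
  episodes <- if (condition == "signal") episode_params() else
    null_episode_params()
  seqs <- make_benchmark_dataset(n_recordings = n_recordings,
                                 duration = duration,
                                 episodes = episodes, seed = seed,
                                 balance = FALSE)
  cfg <- train_config(epochs = epochs, seed = seed + 503)
  out <- holdout_benchmark(seqs, methods = methods, cfg = cfg,
                           holdout_fraction = holdout_fraction,
                           n_blocks = n_blocks)
  out$n_sequences <- out$n_train + out$n_valid   # balanced modelling set
  out
}
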