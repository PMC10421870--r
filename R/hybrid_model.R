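#' Hybrid model configuration
#'
#' Architecture hyperparameters of the dual-branch lapse classifier.  The
#' default dimension ladder for the time-related branch is
#' 6x23 -> conv -> 6x64 -> splice -> 6x87 -> batch norm -> LSTM -> 6x128 ->
#' head -> 2, and for the time-independent branch 6x21 -> conv -> 6x64 ->
#' flatten -> 2; the two length-2 outputs are fused (width 4) and mapped to
#' the final two-class softmax.
#'
#' @param arch One of `"hybrid"` (both branches as above), `"conv_only"`
#'   (recurrent encoder removed: conv -> splice -> batch norm -> flatten ->
#'   head) or `"recurrent_only"` (conv extractor removed: the LSTM consumes
#'   the 23 raw time-related features directly).
#' @param tc_width,tic_width Widths of the time-related / time-independent
#'   feature vectors.
#' @param seq_len Events per sequence.
#' @param channels Convolution channels per layer (all layers).
#' @param conv_layers Number of convolution layers per branch.
#' @param hidden LSTM hidden width.
#' @param lstm_layers Number of stacked LSTM layers.
#' @param bn_eps Batch-normalisation stabiliser added to the variance.
#' @param bn_momentum Running-statistics update rate.
#' @return A list of class `hybrid_config`.
#' @export
hybrid_config <- function(arch = c("hybrid", "conv_only", "recurrent_only"),
                          tc_width = 23, tic_width = 21, seq_len = 6,
                          channels = 64, conv_layers = 3,
                          hidden = 128, lstm_layers = 3,
                          bn_eps = 1e-5, bn_momentum = 0.1) {
  arch <- match.arg(arch)
  structure(
    list(arch = arch, tc_width = tc_width, tic_width = tic_width,
         seq_len = seq_len, channels = channels, conv_layers = conv_layers,
         hidden = hidden, lstm_layers = lstm_layers, bn_eps = bn_eps,
         bn_momentum = bn_momentum,
         splice_width = channels + tc_width),
    class = "hybrid_config"
  )
}

init_conv_stack <- function(params, running, prefix, in_width, cfg) {
  w <- in_width
  for (l in seq_len(cfg$conv_layers)) {
    nm <- paste0(prefix, "_conv", l)
    fan_in <- 2 * w                              # kernel spans 2 time steps
    params[[paste0(nm, "_W1")]] <- kaiming_matrix(w, cfg$channels, fan_in) # t-1 tap
    params[[paste0(nm, "_W2")]] <- kaiming_matrix(w, cfg$channels, fan_in) # t tap
    params[[paste0(nm, "_gamma")]] <- rep(1, cfg$channels)
    params[[paste0(nm, "_beta")]] <- numeric(cfg$channels)
    running[[paste0(nm, "_mean")]] <- numeric(cfg$channels)
    running[[paste0(nm, "_var")]] <- rep(1, cfg$channels)
    w <- cfg$channels
  }
  list(params = params, running = running)
}

#' Initialise a hybrid model (Kaiming scheme)
#'
#' Draws every convolution, recurrent and affine weight from the
#' fan-in-scaled normal scheme `N(0, 2 / fan_in)`; all biases start at 0,
#' batch-norm scales at 1.  The seed fully determines the parameters.
#'
#' @param config A [hybrid_config()].
#' @param seed Integer seed.
#' @return An object of class `hybrid_model`: list with `config`, `params`
#'   (flat named list of weight arrays) and `running` (batch-norm running
#'   statistics).
#' @export
init_params <- function(config = hybrid_config(), seed) {
  if (missing(seed)) stop("init_params: seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  cfg <- config
  params <- list()
  running <- list()

  if (cfg$arch %in% c("hybrid", "conv_only")) {
    st <- init_conv_stack(params, running, "tc", cfg$tc_width, cfg)
    params <- st$params; running <- st$running
    params$sp_gamma <- rep(1, cfg$splice_width)
    params$sp_beta <- numeric(cfg$splice_width)
    running$sp_mean <- numeric(cfg$splice_width)
    running$sp_var <- rep(1, cfg$splice_width)
  }
  if (cfg$arch %in% c("hybrid", "recurrent_only")) {
    in_w <- if (cfg$arch == "hybrid") cfg$splice_width else cfg$tc_width
    for (l in seq_len(cfg$lstm_layers)) {
      params[[paste0("lstm", l, "_Wx")]] <- kaiming_matrix(in_w, 4 * cfg$hidden)
      params[[paste0("lstm", l, "_Wh")]] <-
        kaiming_matrix(cfg$hidden, 4 * cfg$hidden)
      params[[paste0("lstm", l, "_b")]] <- numeric(4 * cfg$hidden)
      in_w <- cfg$hidden
    }
  }
  tc_head_in <- switch(cfg$arch,
    hybrid = cfg$hidden,
    recurrent_only = cfg$hidden,
    conv_only = cfg$seq_len * cfg$splice_width)
  params$tc_head_W <- kaiming_matrix(tc_head_in, 2)
  params$tc_head_b <- numeric(2)

  st <- init_conv_stack(params, running, "tic", cfg$tic_width, cfg)
  params <- st$params; running <- st$running
  params$tic_head_W <- kaiming_matrix(cfg$seq_len * cfg$channels, 2)
  params$tic_head_b <- numeric(2)

  params$fc_W <- kaiming_matrix(4, 2)
  params$fc_b <- numeric(2)

  structure(list(config = cfg, params = params, running = running),
            class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<hybrid_model> arch = %s, %d parameters in %d arrays\n",
              x$config$arch, n_par, length(x$params)))
  invisible(x)
}

run_conv_stack <- function(model, X, prefix, training) {
  cfg <- model$config
  p <- model$params
  running <- model$running
  caches <- vector("list", cfg$conv_layers)
  for (l in seq_len(cfg$conv_layers)) {
    nm <- paste0(prefix, "_conv", l)
    fw <- conv_layer_forward(
      X, p[[paste0(nm, "_W1")]], p[[paste0(nm, "_W2")]],
      p[[paste0(nm, "_gamma")]],
      p[[paste0(nm, "_beta")]], cfg$bn_eps, training,
      running[[paste0(nm, "_mean")]], running[[paste0(nm, "_var")]],
      cfg$bn_momentum)
    X <- fw$out
    caches[[l]] <- fw$cache
    running[[paste0(nm, "_mean")]] <- fw$run_mean
    running[[paste0(nm, "_var")]] <- fw$run_var
  }
  list(out = X, caches = caches, running = running)
}

back_conv_stack <- function(model, dX, caches, prefix) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  for (l in rev(seq_len(cfg$conv_layers))) {
    nm <- paste0(prefix, "_conv", l)
    bw <- conv_layer_backward(dX, caches[[l]], p[[paste0(nm, "_W1")]],
                              p[[paste0(nm, "_W2")]],
                              p[[paste0(nm, "_gamma")]])
    grads[[paste0(nm, "_W1")]] <- bw$dW1
    grads[[paste0(nm, "_W2")]] <- bw$dW2
    grads[[paste0(nm, "_gamma")]] <- bw$dgamma
    grads[[paste0(nm, "_beta")]] <- bw$dbeta
    dX <- bw$dX
  }
  list(dX = dX, grads = grads)
}

flatten_bt <- function(X) {
  d <- dim(X)
  dim(X) <- c(d[1], d[2] * d[3])
  X
}
unflatten_bt <- function(M, T) {
  B <- nrow(M)
  dim(M) <- c(B, T, ncol(M) / T)
  M
}

#' Forward pass of the hybrid model
#'
#' Runs the full dual-branch forward pass and returns logits, class
#' probabilities and (optionally) the caches needed for backpropagation.
#' Batch-norm layers use batch statistics in training mode (and update the
#' returned running estimates) and running statistics in inference mode.
#'
#' @param model A `hybrid_model`.
#' @param tc Batch x seq_len x 23 array of normalised time-related features.
#' @param tic Batch x seq_len x 21 array of normalised time-independent
#'   features.
#' @param training Logical; batch-statistics mode.
#' @return List with `logits` (batch x 2), `prob` (batch x 2, columns
#'   `(p_forgetting, p_normal)`), `cache`, and updated `running` statistics.
#' @export
hybrid_forward <- function(model, tc, tic, training = FALSE) {
  cfg <- model$config
  p <- model$params
  if (dim(tc)[3] != cfg$tc_width || dim(tic)[3] != cfg$tic_width ||
      dim(tc)[2] != cfg$seq_len || dim(tic)[2] != cfg$seq_len)
    stop(sprintf(
      "hybrid_forward: expected tc %d x %d and tic %d x %d per sample",
      cfg$seq_len, cfg$tc_width, cfg$seq_len, cfg$tic_width), call. = FALSE)
  if (dim(tc)[1] != dim(tic)[1])
    stop("hybrid_forward: tc and tic batch sizes differ", call. = FALSE)
  B <- dim(tc)[1]
  if (training && B < 2)
    stop("hybrid_forward: training mode needs a batch of at least 2",
         call. = FALSE)
  cache <- list(B = B)
  running <- model$running

  # ---- time-related branch ----
  if (cfg$arch %in% c("hybrid", "conv_only")) {
    cs <- run_conv_stack(
      structure(list(config = cfg, params = p, running = running),
                class = "hybrid_model"), tc, "tc", training)
    running <- cs$running
    spliced <- abind_feat(cs$out, tc)                       # deep block first
    bn <- bn_forward(arr2mat(spliced), p$sp_gamma, p$sp_beta, cfg$bn_eps,
                     training, running$sp_mean, running$sp_var,
                     cfg$bn_momentum)
    running$sp_mean <- bn$run_mean
    running$sp_var <- bn$run_var
    normed <- mat2arr(bn$out, B, cfg$seq_len)
    cache$tc_conv <- cs$caches
    cache$sp_bn <- bn
  }

  if (cfg$arch == "hybrid") {
    lstm_in <- normed
  } else if (cfg$arch == "recurrent_only") {
    lstm_in <- tc
  }

  if (cfg$arch %in% c("hybrid", "recurrent_only")) {
    lstm_caches <- vector("list", cfg$lstm_layers)
    X <- lstm_in
    for (l in seq_len(cfg$lstm_layers)) {
      fw <- lstm_layer_forward(X, p[[paste0("lstm", l, "_Wx")]],
                               p[[paste0("lstm", l, "_Wh")]],
                               p[[paste0("lstm", l, "_b")]])
      lstm_caches[[l]] <- list(steps = fw$caches, X = X)
      X <- fw$out
    }
    cache$lstm <- lstm_caches
    h_last <- matrix(X[, cfg$seq_len, ], nrow = B)
    cache$h_last <- h_last
    cache$lstm_out <- X
    tc_out <- affine_forward(h_last, p$tc_head_W, p$tc_head_b)
  } else {                                     # conv_only: flatten the splice
    flat <- flatten_bt(normed)
    cache$tc_flat <- flat
    tc_out <- affine_forward(flat, p$tc_head_W, p$tc_head_b)
  }
  cache$tc_out_in <- if (cfg$arch == "conv_only") cache$tc_flat else
    cache$h_last

  # ---- time-independent branch ----
  cs2 <- run_conv_stack(
    structure(list(config = cfg, params = p, running = running),
              class = "hybrid_model"), tic, "tic", training)
  running <- cs2$running
  tic_flat <- flatten_bt(cs2$out)
  tic_out <- affine_forward(tic_flat, p$tic_head_W, p$tic_head_b)
  cache$tic_conv <- cs2$caches
  cache$tic_flat <- tic_flat

  # ---- fusion head ----
  x_final <- cbind(tc_out, tic_out)
  logits <- affine_forward(x_final, p$fc_W, p$fc_b)
  cache$x_final <- x_final
  cache$tc_out <- tc_out
  cache$tic_out <- tic_out

  list(logits = logits, prob = softmax_rows(logits), cache = cache,
       running = running)
}

# Concatenate two (B, T, F) arrays along the feature axis, first then second.
abind_feat <- function(A, B_) {
  d1 <- dim(A); d2 <- dim(B_)
  out <- array(0, c(d1[1], d1[2], d1[3] + d2[3]))
  out[, , seq_len(d1[3])] <- A
  out[, , d1[3] + seq_len(d2[3])] <- B_
  out
}

#' Loss and analytic gradients for one batch
#'
#' Forward pass in training mode followed by full backpropagation of the
#' (optionally class-weighted) mean cross-entropy.
#'
#' @param model A `hybrid_model`.
#' @param tc,tic Feature arrays as in [hybrid_forward()].
#' @param labels Integer vector (1 forgetting, 0 normal).
#' @param weights Optional per-sample loss weights.
#' @return List with `loss`, `grads` (named like `model$params`), `prob`,
#'   and updated `running` statistics.
#' @export
hybrid_loss_grads <- function(model, tc, tic, labels, weights = NULL) {
  cfg <- model$config
  p <- model$params
  fw <- hybrid_forward(model, tc, tic, training = TRUE)
  ce <- softmax_ce(fw$logits, labels, weights)
  cache <- fw$cache
  B <- cache$B
  grads <- list()

  # fusion head
  dlogits <- ce$dlogits
  grads$fc_W <- crossprod(cache$x_final, dlogits)
  grads$fc_b <- colSums(dlogits)
  dxf <- tcrossprod(dlogits, p$fc_W)
  dtc_out <- dxf[, 1:2, drop = FALSE]
  dtic_out <- dxf[, 3:4, drop = FALSE]

  # tic branch
  grads$tic_head_W <- crossprod(cache$tic_flat, dtic_out)
  grads$tic_head_b <- colSums(dtic_out)
  dtic_flat <- tcrossprod(dtic_out, p$tic_head_W)
  dtic_deep <- unflatten_bt(dtic_flat, cfg$seq_len)
  bs <- back_conv_stack(model, dtic_deep, cache$tic_conv, "tic")
  grads <- c(grads, bs$grads)

  # tc branch
  grads$tc_head_W <- crossprod(cache$tc_out_in, dtc_out)
  grads$tc_head_b <- colSums(dtc_out)
  dhead_in <- tcrossprod(dtc_out, p$tc_head_W)

  if (cfg$arch %in% c("hybrid", "recurrent_only")) {
    H <- cfg$hidden
    dH_top <- array(0, c(B, cfg$seq_len, H))
    dH_top[, cfg$seq_len, ] <- dhead_in
    dX <- dH_top
    for (l in rev(seq_len(cfg$lstm_layers))) {
      bw <- lstm_layer_backward(dX, cache$lstm[[l]]$steps,
                                cache$lstm[[l]]$X,
                                p[[paste0("lstm", l, "_Wx")]],
                                p[[paste0("lstm", l, "_Wh")]])
      grads[[paste0("lstm", l, "_Wx")]] <- bw$dWx
      grads[[paste0("lstm", l, "_Wh")]] <- bw$dWh
      grads[[paste0("lstm", l, "_b")]] <- bw$db
      dX <- bw$dX
    }
    dlstm_in <- dX
  }

  if (cfg$arch %in% c("hybrid", "conv_only")) {
    dnormed <- if (cfg$arch == "hybrid") dlstm_in else
      unflatten_bt(dhead_in, cfg$seq_len)
    bnb <- bn_backward(arr2mat(dnormed), cache$sp_bn, p$sp_gamma)
    grads$sp_gamma <- bnb$dgamma
    grads$sp_beta <- bnb$dbeta
    dspliced <- mat2arr(bnb$dZ, B, cfg$seq_len)
    ddeep <- dspliced[, , seq_len(cfg$channels), drop = FALSE]
    bs2 <- back_conv_stack(model, ddeep, cache$tc_conv, "tc")
    grads <- c(grads, bs2$grads)
  }

  list(loss = ce$loss, grads = grads, prob = ce$prob, running = fw$running)
}

#' Class probabilities for a sequence set
#'
#' Inference-mode forward pass (running batch-norm statistics) in batches.
#'
#' @param model A trained `hybrid_model`.
#' @param sequences An `event_sequences` object (normalised).
#' @param batch_size Forward batch size.
#' @return Matrix n x 2 of `(p_forgetting, p_normal)` rows.
#' @export
predict_proba <- function(model, sequences, batch_size = 256) {
  UseMethod("predict_proba")
}

#' @export
predict_proba.hybrid_model <- function(model, sequences, batch_size = 256) {
  n <- n_sequences(sequences)
  out <- matrix(0, n, 2)
  colnames(out) <- c("p_forgetting", "p_normal")
  at <- 1
  while (at <= n) {
    idx <- at:min(at + batch_size - 1, n)
    fw <- hybrid_forward(model,
                         sequences$tc[idx, , , drop = FALSE],
                         sequences$tic[idx, , , drop = FALSE],
                         training = FALSE)
    out[idx, ] <- fw$prob
    at <- at + batch_size
  }
  out
}

# ---- exported branch operations (module surface) -------------------------

#' Convolutional feature extractor of the time-related branch
#'
#' Applies the three causal temporal convolution layers
#' (ReLU(BN(Conv(x, W)))) to a batch of time-related sequences; same-length
#' padding keeps the sequence length, so a batch x 6 x 23 input yields a
#' batch x 6 x 64 output with the default configuration.
#'
#' @param model A `hybrid_model` with a convolutional time-related branch.
#' @param tc Batch x seq_len x tc_width array.
#' @param training Logical; batch-statistics mode (needs batch >= 2).
#' @return Batch x seq_len x channels array of deep features.
#' @export
conv_branch_forward <- function(model, tc, training = FALSE) {
  if (!model$config$arch %in% c("hybrid", "conv_only"))
    stop("this architecture has no time-related conv branch", call. = FALSE)
  if (dim(tc)[3] != model$config$tc_width)
    stop(sprintf("conv_branch_forward: expected feature width %d, got %d",
                 model$config$tc_width, dim(tc)[3]), call. = FALSE)
  run_conv_stack(model, tc, "tc", training)$out
}

#' Splice deep and original time-related features
#'
#' Per-event concatenation with the deep block first, so the last
#' `tc_width` entries of each spliced vector are the original features,
#' bit-unchanged.
#'
#' @param deep Batch x seq_len x channels array of conv features.
#' @param original_tc Batch x seq_len x tc_width array of raw features.
#' @return Batch x seq_len x (channels + tc_width) array.
#' @export
splice_features <- function(deep, original_tc) {
  if (!all(dim(deep)[1:2] == dim(original_tc)[1:2]))
    stop("splice_features: batch/sequence dimensions differ", call. = FALSE)
  abind_feat(deep, original_tc)
}

#' Batch-normalise the spliced sequence
#'
#' Normalises each of the spliced features over all batch x sequence
#' positions: `z = gamma * (x - mu) / sqrt(sigma^2 + eps) + beta`.  Training
#' mode uses batch statistics and updates the model's running estimates;
#' inference mode uses the running estimates.
#'
#' @param model A `hybrid_model` (provides gamma, beta, eps and running
#'   statistics).
#' @param spliced Batch x seq_len x splice_width array.
#' @param training Logical.
#' @return List with `out` (same shape) and the updated `model`.
#' @export
splice_batch_norm <- function(model, spliced, training = TRUE) {
  cfg <- model$config
  B <- dim(spliced)[1]
  if (training && B < 2)
    stop("splice_batch_norm: training mode needs at least 2 sequences ",
         "per batch (batch statistics are undefined for one)", call. = FALSE)
  bn <- bn_forward(arr2mat(spliced), model$params$sp_gamma,
                   model$params$sp_beta, cfg$bn_eps, training,
                   model$running$sp_mean, model$running$sp_var,
                   cfg$bn_momentum)
  model$running$sp_mean <- bn$run_mean
  model$running$sp_var <- bn$run_var
  list(out = mat2arr(bn$out, B, dim(spliced)[2]), model = model)
}

#' Stacked LSTM encoder
#'
#' Unrolls the stacked gated recurrence over the sequence: at each step
#' `i_t = sigma(w_i x_t + U_i h_{t-1} + b_i)`,
#' `f_t = sigma(w_f x_t + U_f h_{t-1} + b_f)`,
#' `o_t = sigma(w_o x_t + U_o h_{t-1} + b_o)`,
#' `c~_t = tanh(w_c x_t + U_c h_{t-1} + b_c)`,
#' `c_t = f_t * c_{t-1} + i_t * c~_t`, `h_t = o_t * tanh(c_t)`, with states
#' initialised to zero.  Returns all hidden states of the top layer.
#'
#' @param model A `hybrid_model` with a recurrent branch.
#' @param spliced Batch x seq_len x input-width array (87 for the hybrid
#'   architecture, 23 for `recurrent_only`).
#' @return Batch x seq_len x hidden array.
#' @export
lstm_forward <- function(model, spliced) {
  if (!model$config$arch %in% c("hybrid", "recurrent_only"))
    stop("this architecture has no recurrent branch", call. = FALSE)
  X <- spliced
  for (l in seq_len(model$config$lstm_layers)) {
    X <- lstm_layer_forward(X, model$params[[paste0("lstm", l, "_Wx")]],
                            model$params[[paste0("lstm", l, "_Wh")]],
                            model$params[[paste0("lstm", l, "_b")]])$out
  }
  X
}

#' Time-related head
#'
#' Affine map from the final event's top-layer hidden state to a length-2
#' output vector.
#'
#' @param model A `hybrid_model`.
#' @param features Batch x seq_len x hidden array from [lstm_forward()].
#' @return Batch x 2 matrix.
#' @export
tc_head <- function(model, features) {
  B <- dim(features)[1]
  h_last <- matrix(features[, dim(features)[2], ], nrow = B)
  affine_forward(h_last, model$params$tc_head_W, model$params$tc_head_b)
}

#' Time-independent branch
#'
#' The same three-layer convolution stack applied to the time-independent
#' features, flattened over (sequence x channels) and affinely mapped to a
#' length-2 output.
#'
#' @param model A `hybrid_model`.
#' @param tic Batch x seq_len x tic_width array.
#' @param training Logical; batch-statistics mode.
#' @return Batch x 2 matrix.
#' @export
tic_branch_forward <- function(model, tic, training = FALSE) {
  if (dim(tic)[3] != model$config$tic_width)
    stop(sprintf("tic_branch_forward: expected feature width %d, got %d",
                 model$config$tic_width, dim(tic)[3]), call. = FALSE)
  deep <- run_conv_stack(model, tic, "tic", training)$out
  affine_forward(flatten_bt(deep), model$params$tic_head_W,
                 model$params$tic_head_b)
}

#' Fuse the two branch outputs and classify
#'
#' Concatenates the two length-2 branch outputs (width 4), applies the
#' final fully connected layer, and maps to class probabilities with
#' softmax.
#'
#' @param model A `hybrid_model`.
#' @param tc_out,tic_out Batch x 2 branch outputs.
#' @return Batch x 2 probability matrix `(p_forgetting, p_normal)`; rows
#'   sum to 1.
#' @export
fuse_and_classify <- function(model, tc_out, tic_out) {
  x_final <- cbind(tc_out, tic_out)
  softmax_rows(affine_forward(x_final, model$params$fc_W, model$params$fc_b))
}

#' Cross-entropy loss
#'
#' Mean over the batch of `-log(exp(y[class]) / sum_i exp(y[i]))`.
#'
#' @param logits Batch x 2 matrix of unnormalised scores, columns ordered
#'   `(forgetting, normal)`.
#' @param labels Integer vector with entries in \{0, 1\} (1 = forgetting).
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(logits, labels) {
  if (!all(labels %in% c(0L, 1L)))
    stop("cross_entropy_loss: labels must be 0 or 1", call. = FALSE)
  softmax_ce(logits, labels)$loss
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single RDS file containing the architecture
#' configuration, all parameters and the batch-norm running statistics, so
#' a reloaded model reproduces predictions exactly.
#'
#' @param model A `hybrid_model`.
#' @param path Checkpoint file path.
#' @return `path` (saving) or the restored `hybrid_model` (loading),
#'   invisibly for the writer.
#' @export
save_hybrid_model <- function(model, path) {
  stopifnot(inherits(model, "hybrid_model"))
  saveRDS(list(config = model$config, params = model$params,
               running = model$running), path)
  invisible(path)
}

#' @rdname save_hybrid_model
#' @export
load_hybrid_model <- function(path) {
  obj <- readRDS(path)
  if (!all(c("config", "params", "running") %in% names(obj)))
    stop("not a gazelapse model checkpoint: ", path, call. = FALSE)
  structure(list(config = obj$config, params = obj$params,
                 running = obj$running), class = "hybrid_model")
}
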