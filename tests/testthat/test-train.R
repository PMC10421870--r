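test_that("Adam iterates match a hand-rolled single-parameter oracle", {
  cfg <- train_config(learning_rate = 0.1, epochs = 1)
  # quadratic loss L(p) = 0.5 p^2, gradient p
  params <- list(w = 2)
  state <- adam_init(params)
  # independent oracle: the update equations written out longhand
  m <- 0; v <- 0; w_ref <- 2
  for (t in 1:25) {
    g <- w_ref
    m <- 0.9 * m + 0.1 * g
    v <- 0.999 * v + 0.001 * g^2
    mhat <- m / (1 - 0.9^t)
    vhat <- v / (1 - 0.999^t)
    w_ref <- w_ref - 0.1 * mhat / (sqrt(vhat) + 1e-8)

    upd <- adam_step(params, list(w = params$w), state, cfg)
    params <- upd$params
    state <- upd$state
    expect_equal(unname(as.numeric(params$w)), w_ref, tolerance = 1e-8)
  }

  # zero gradient is a fixed point
  p0 <- list(w = matrix(1:4, 2))
  s0 <- adam_init(p0)
  upd0 <- adam_step(p0, list(w = matrix(0, 2, 2)), s0, cfg)
  expect_equal(upd0$params$w, p0$w)
})

test_that("training reduces the loss on separable toy sequences", {
  sq <- toy_sequences(n = 64, seed = 3, signal = 3)
  norm <- fit_sequence_minmax(sq)
  sqn <- apply_sequence_minmax(sq, norm)
  m <- init_params(small_config(), seed = 1)
  cfg <- train_config(learning_rate = 3e-3, epochs = 40, batch_size = 32,
                      seed = 2)
  tr <- adam_train(m, sqn, cfg)
  expect_length(tr$loss_trace, 40)
  smooth <- stats::filter(tr$loss_trace, rep(1 / 5, 5), sides = 1)
  expect_lt(smooth[40], smooth[10])
  expect_gt(evaluate_accuracy(tr$model, sqn), 0.9)
  expect_error(adam_train(m, subset_sequences(sq, integer(0)), cfg),
               "empty")
})

test_that("accuracy counts argmax matches with ties going to normal", {
  sq <- toy_sequences(n = 20, seed = 5)

  # perfect predictor: probability 1 on the true class
  perfect <- structure(list(truth = sq$labels), class = "mock_perfect")
  # registered locally for the test
  assign("predict_proba.mock_perfect",
         function(model, sequences, batch_size = NULL) {
           cbind(model$truth, 1 - model$truth)
         }, envir = globalenv())
  withr::defer(rm("predict_proba.mock_perfect", envir = globalenv()))
  expect_equal(evaluate_accuracy(perfect, sq), 1.0)

  # constant (0.5, 0.5): tie broken toward normal -> accuracy = share of 0s
  constant <- structure(list(), class = "mock_constant")
  assign("predict_proba.mock_constant",
         function(model, sequences, batch_size = NULL) {
           matrix(0.5, n_sequences(sequences), 2)
         }, envir = globalenv())
  withr::defer(rm("predict_proba.mock_constant", envir = globalenv()))
  expect_equal(evaluate_accuracy(constant, sq), mean(sq$labels == 0))

  # brute-force confusion count on random probabilities
  set.seed(11)
  probs <- matrix(runif(20), 20, 1)
  probs <- cbind(probs, 1 - probs)
  random <- structure(list(p = probs), class = "mock_random")
  assign("predict_proba.mock_random",
         function(model, sequences, batch_size = NULL) model$p,
         envir = globalenv())
  withr::defer(rm("predict_proba.mock_random", envir = globalenv()))
  manual <- sum((probs[, 1] > 0.5) == (sq$labels == 1)) / 20
  expect_equal(evaluate_accuracy(random, sq), manual)

  expect_error(evaluate_accuracy(perfect, subset_sequences(sq, integer(0))),
               "empty")
})

test_that("logistic baseline matches a hand-rolled Newton-Raphson fit", {
  # small 2-d dataset fitted by an independent Newton iteration
  set.seed(13)
  n <- 40
  X <- cbind(rnorm(n), rnorm(n))
  eta_true <- -0.3 + 1.2 * X[, 1] - 0.8 * X[, 2]
  y <- rbinom(n, 1, plogis(eta_true))

  # package route: wrap into sequences whose event mean equals X
  tc <- array(0, c(n, 6, 23)); tic <- array(0, c(n, 6, 21))
  for (k in 1:6) { tc[, k, 1] <- X[, 1]; tc[, k, 2] <- X[, 2] }
  sq <- gazelapse:::new_event_sequences(tc, tic, y)
  fit <- train_logistic_baseline(sq)
  got <- fit$coef[1:3]                        # intercept + the two live cols

  # oracle: Newton-Raphson on the 3-parameter likelihood
  Z <- cbind(1, X)
  beta <- numeric(3)
  for (it in 1:50) {
    p <- plogis(drop(Z %*% beta))
    W <- p * (1 - p)
    beta <- beta + solve(t(Z) %*% (Z * W), t(Z) %*% (y - p))
  }
  expect_equal(unname(got), unname(drop(beta)), tolerance = 1e-4)

  # separable single feature -> perfect accuracy
  sq2 <- toy_sequences(n = 40, seed = 14, signal = 6)
  fit2 <- train_logistic_baseline(sq2)
  expect_equal(evaluate_accuracy(fit2, sq2), 1.0)
})

test_that("logistic accuracy sits at chance under permuted labels", {
  accs <- numeric(10)
  for (s in 1:10) {
    sq <- toy_sequences(n = 80, seed = 200 + s, signal = 2)
    set.seed(300 + s)
    sq$labels <- sample(sq$labels)            # break the association
    train <- subset_sequences(sq, 1:60)
    valid <- subset_sequences(sq, 61:80)
    fit <- train_logistic_baseline(train)
    accs[s] <- evaluate_accuracy(fit, valid)
  }
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("fold assignment partitions the data deterministically", {
  f <- make_folds(100, 5, seed = 21)
  expect_equal(length(f), 100)
  expect_equal(as.integer(table(f)), rep(20L, 5))
  expect_identical(f, make_folds(100, 5, seed = 21))
  expect_false(identical(f, make_folds(100, 5, seed = 22)))
  expect_error(make_folds(3, 5, seed = 1), "fewer items")
})

test_that("cross-validation keeps folds disjoint and averages accuracies", {
  sq <- toy_sequences(n = 50, seed = 23, signal = 4)
  cfg <- train_config(epochs = 3, batch_size = 16, seed = 31, folds = 5)
  r <- five_fold_cv(sq, cfg, method = "logistic")
  expect_s3_class(r, "cv_result")
  expect_length(r$fold_accuracy, 5)
  expect_equal(r$mean_accuracy, mean(r$fold_accuracy))
  for (k in 1:5) {
    expect_equal(sum(r$folds == k), 10)      # balanced partition
  }
  expect_error(five_fold_cv(subset_sequences(sq, 1:3), cfg, "logistic"),
               "fewer sequences")
})

test_that("ablation architectures expose the documented head shapes and learn", {
  co <- init_params(small_config("conv_only"), seed = 1)
  cfg_s <- small_config("conv_only")
  expect_equal(nrow(co$params$tc_head_W),
               cfg_s$seq_len * (cfg_s$channels + cfg_s$tc_width))
  expect_null(co$params$lstm1_Wx)

  ro <- init_params(small_config("recurrent_only"), seed = 1)
  expect_equal(nrow(ro$params$lstm1_Wx), 23)   # raw features straight in
  expect_equal(ncol(ro$params$lstm1_Wx), 4 * small_config()$hidden)
  expect_null(ro$params$tc_conv1_W1)

  # both ablations learn a separable toy above chance
  sq <- toy_sequences(n = 64, seed = 33, signal = 3)
  sqn <- apply_sequence_minmax(sq, fit_sequence_minmax(sq))
  cfg <- train_config(learning_rate = 3e-3, epochs = 25, batch_size = 32,
                      seed = 5)
  for (arch in c("conv_only", "recurrent_only")) {
    tr <- adam_train(init_params(small_config(arch), seed = 2), sqn, cfg)
    expect_gt(evaluate_accuracy(tr$model, sqn), 0.75)
  }
})

test_that("comparison report sorts by mean accuracy and rejects fold mismatch", {
  e1 <- structure(list(method = "a", fold_accuracy = c(0.7, 0.72),
                       mean_accuracy = 0.71, folds = c(1, 1, 2, 2),
                       seed = 1L), class = "cv_result")
  e2 <- structure(list(method = "b", fold_accuracy = c(0.8, 0.78),
                       mean_accuracy = 0.79, folds = c(1, 1, 2, 2),
                       seed = 1L), class = "cv_result")
  rep_tab <- comparison_report(list(e1, e2))
  expect_equal(rep_tab$method, c("b", "a"))
  expect_equal(rep_tab$sd_accuracy[1], sd(c(0.8, 0.78)))

  e3 <- e2
  e3$folds <- c(2, 2, 1, 1)
  expect_error(comparison_report(list(e1, e3)), "different folds")

  # identical entries -> zero difference between rows
  rep2 <- comparison_report(list(e1, e1))
  expect_equal(diff(rep2$mean_accuracy), 0)
})

test_that("class weighting rebalances the loss contributions", {
  sq <- toy_sequences(n = 60, seed = 41, signal = 3)
  sq$labels <- c(rep(1L, 10), rep(0L, 50))
  sqn <- apply_sequence_minmax(sq, fit_sequence_minmax(sq))
  cfg <- train_config(learning_rate = 3e-3, epochs = 5, batch_size = 30,
                      seed = 6, class_weights = TRUE)
  tr <- adam_train(init_params(small_config(), seed = 3), sqn, cfg)
  expect_true(all(is.finite(tr$loss_trace)))
})
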