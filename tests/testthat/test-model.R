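test_that("the dimension ladder holds through both branches", {
  m <- init_params(hybrid_config(), seed = 1)
  B <- 64
  set.seed(1)
  tc <- array(runif(B * 6 * 23), c(B, 6, 23))
  tic <- array(runif(B * 6 * 21), c(B, 6, 21))

  deep <- conv_branch_forward(m, tc, training = TRUE)
  expect_equal(dim(deep), c(64, 6, 64))
  sp <- splice_features(deep, tc)
  expect_equal(dim(sp), c(64, 6, 87))
  lo <- lstm_forward(m, splice_batch_norm(m, sp, training = TRUE)$out)
  expect_equal(dim(lo), c(64, 6, 128))
  expect_equal(dim(tc_head(m, lo)), c(64, 2))
  expect_equal(dim(tic_branch_forward(m, tic, training = TRUE)), c(64, 2))

  fw <- hybrid_forward(m, tc, tic, training = TRUE)
  expect_equal(dim(fw$logits), c(64, 2))

  # batch 1 works in inference mode
  fw1 <- hybrid_forward(m, tc[1, , , drop = FALSE], tic[1, , , drop = FALSE])
  expect_equal(dim(fw1$prob), c(1, 2))

  # width mismatch is a shape error
  expect_error(hybrid_forward(m, tic, tc), "expected tc")
})

test_that("splicing passes the original features through unchanged", {
  B <- 5
  set.seed(2)
  tc <- array(runif(B * 6 * 23), c(B, 6, 23))
  deep <- array(0, c(B, 6, 64))
  sp <- splice_features(deep, tc)
  expect_equal(sp[, , 65:87], tc)               # deep block first
  expect_true(all(sp[, , 1:64] == 0))

  deep2 <- array(rnorm(B * 6 * 64), c(B, 6, 64))
  sp2 <- splice_features(deep2, tc)
  expect_identical(sp2[, , 65:87], tc)          # bit-unchanged pass-through
  expect_error(splice_features(deep2[, 1:3, , drop = FALSE], tc),
               "dimensions differ")
})

test_that("splice batch norm standardises, respects the affine law, guards batch 1", {
  m <- init_params(hybrid_config(), seed = 3)
  B <- 32
  set.seed(3)
  sp <- array(rnorm(B * 6 * 87, mean = 2, sd = 3), c(B, 6, 87))
  out <- splice_batch_norm(m, sp, training = TRUE)$out
  flat <- matrix(out, nrow = B * 6)
  expect_equal(unname(colMeans(flat)), rep(0, 87), tolerance = 1e-8)
  expect_equal(unname(apply(flat, 2, function(v) mean(v^2))), rep(1, 87),
               tolerance = 1e-3)                # up to eps

  # gamma = 2, beta = 3 on standardised input -> mean 3, variance 4
  m2 <- m
  m2$params$sp_gamma <- rep(2, 87)
  m2$params$sp_beta <- rep(3, 87)
  out2 <- matrix(splice_batch_norm(m2, sp, training = TRUE)$out, nrow = B * 6)
  expect_equal(unname(colMeans(out2)), rep(3, 87), tolerance = 1e-8)
  expect_equal(unname(apply(out2, 2, function(v) mean((v - 3)^2))),
               rep(4, 87), tolerance = 5e-3)

  # constant feature column maps to beta everywhere
  spc <- sp
  spc[, , 1] <- 7
  outc <- splice_batch_norm(m2, spc, training = TRUE)$out
  expect_equal(unname(as.vector(outc[, , 1])), rep(3, B * 6),
               tolerance = 1e-2)

  expect_error(splice_batch_norm(m, sp[1, , , drop = FALSE],
                                 training = TRUE), "at least 2")
})

test_that("the recurrence matches a literal step-by-step evaluation", {
  # scalar toy: width-1 gates, hand-picked weights, stepped by hand
  cfg <- hybrid_config(arch = "recurrent_only", tc_width = 1, hidden = 1,
                       lstm_layers = 1, seq_len = 3)
  m <- init_params(cfg, seed = 1)
  wx <- c(0.5, -0.3, 0.8, 1.0)            # i, f, o, candidate
  wh <- c(0.2, 0.1, -0.4, 0.6)
  b <- c(0.05, -0.1, 0.2, 0.0)
  m$params$lstm1_Wx <- matrix(wx, 1, 4)
  m$params$lstm1_Wh <- matrix(wh, 1, 4)
  m$params$lstm1_b <- b
  xs <- c(0.7, -0.2, 0.4)
  X <- array(xs, c(1, 3, 1))
  out <- lstm_forward(m, X)

  sig <- function(z) 1 / (1 + exp(-z))
  h <- 0; cst <- 0; ref <- numeric(3)
  for (t in 1:3) {
    i_t <- sig(wx[1] * xs[t] + wh[1] * h + b[1])
    f_t <- sig(wx[2] * xs[t] + wh[2] * h + b[2])
    o_t <- sig(wx[3] * xs[t] + wh[3] * h + b[3])
    g_t <- tanh(wx[4] * xs[t] + wh[4] * h + b[4])
    cst <- f_t * cst + i_t * g_t
    h <- o_t * tanh(cst)
    ref[t] <- h
  }
  expect_equal(as.vector(out[1, , 1]), ref, tolerance = 1e-6)

  # random multi-unit case against an independent per-timestep loop
  cfg2 <- hybrid_config(arch = "recurrent_only", tc_width = 4, hidden = 3,
                        lstm_layers = 1, seq_len = 5)
  m2 <- init_params(cfg2, seed = 5)
  set.seed(6)
  X2 <- array(rnorm(2 * 5 * 4), c(2, 5, 4))
  out2 <- lstm_forward(m2, X2)
  Wx <- m2$params$lstm1_Wx; Wh <- m2$params$lstm1_Wh; bb <- m2$params$lstm1_b
  H <- 3
  for (batch in 1:2) {
    h <- numeric(H); cs <- numeric(H)
    for (t in 1:5) {
      z <- drop(X2[batch, t, ] %*% Wx + h %*% Wh) + bb
      i_t <- sig(z[1:H]); f_t <- sig(z[H + 1:H])
      o_t <- sig(z[2 * H + 1:H]); g_t <- tanh(z[3 * H + 1:H])
      cs <- f_t * cs + i_t * g_t
      h <- o_t * tanh(cs)
      expect_equal(unname(out2[batch, t, ]), unname(h), tolerance = 1e-6)
    }
  }
})

test_that("zero-weight recurrence stays at the zero fixed point", {
  cfg <- hybrid_config(arch = "recurrent_only", tc_width = 23)
  m <- init_params(cfg, seed = 2)
  for (l in 1:3) {
    m$params[[paste0("lstm", l, "_Wx")]][] <- 0
    m$params[[paste0("lstm", l, "_Wh")]][] <- 0
    m$params[[paste0("lstm", l, "_b")]][] <- 0
  }
  X <- array(runif(4 * 6 * 23), c(4, 6, 23))
  expect_true(all(lstm_forward(m, X) == 0))
})

test_that("cross-entropy matches direct evaluation of the formula", {
  expect_equal(cross_entropy_loss(matrix(0, 1, 2), 1L), log(2),
               tolerance = 1e-12)
  # large margin toward the true class drives the loss to zero
  expect_lt(cross_entropy_loss(matrix(c(30, 0), 1), 1L), 1e-8)
  expect_error(cross_entropy_loss(matrix(0, 1, 2), 2L), "labels")

  set.seed(7)
  L <- matrix(rnorm(20), 10, 2)
  lab <- sample(0:1, 10, replace = TRUE)
  direct <- mean(vapply(seq_len(10), function(i) {
    ci <- if (lab[i] == 1) 1 else 2
    -log(exp(L[i, ci]) / sum(exp(L[i, ])))
  }, 0))
  expect_equal(cross_entropy_loss(L, lab), direct, tolerance = 1e-8)
})

test_that("the fused classifier outputs shift-invariant probability pairs", {
  m <- init_params(hybrid_config(), seed = 4)
  set.seed(8)
  tc_out <- matrix(rnorm(12), 6, 2)
  tic_out <- matrix(rnorm(12), 6, 2)
  p <- fuse_and_classify(m, tc_out, tic_out)
  expect_equal(unname(rowSums(p)), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p > 0))

  # zeroed final layer -> equal logits -> (0.5, 0.5)
  m0 <- m
  m0$params$fc_W[] <- 0
  m0$params$fc_b[] <- 0
  p0 <- fuse_and_classify(m0, tc_out, tic_out)
  expect_equal(unname(as.vector(p0)), rep(0.5, 12))

  # adding a constant to both logits leaves probabilities unchanged
  mb <- m
  mb$params$fc_b <- m$params$fc_b + 5
  expect_equal(fuse_and_classify(mb, tc_out, tic_out), p, tolerance = 1e-9)
})

test_that("initialisation is seed-deterministic with fan-scaled variance", {
  a <- init_params(hybrid_config(), seed = 11)
  b <- init_params(hybrid_config(), seed = 11)
  c <- init_params(hybrid_config(), seed = 12)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params$fc_W, c$params$fc_W))

  # lstm1_Wx: 87 x 512 = 44544 draws with fan-in 87 -> variance ~ 2/87
  v <- var(as.vector(a$params$lstm1_Wx))
  expect_lt(abs(v - 2 / 87) / (2 / 87), 0.2)
  # conv taps share a fan-in of 2 * input width
  v2 <- var(c(as.vector(a$params$tc_conv1_W1),
              as.vector(a$params$tc_conv1_W2)))
  expect_lt(abs(v2 - 2 / 46) / (2 / 46), 0.2)
  # gate biases start at zero, batch-norm scales at one
  expect_true(all(a$params$lstm1_b == 0))
  expect_true(all(a$params$sp_gamma == 1))
})

test_that("analytic gradients agree with finite differences on a reduced model", {
  for (arch in c("hybrid", "conv_only", "recurrent_only")) {
    cfg <- hybrid_config(arch = arch, channels = 3, hidden = 4,
                         tc_width = 5, tic_width = 4, seq_len = 3)
    m <- init_params(cfg, seed = 2)
    set.seed(9)
    B <- 4
    tc <- array(runif(B * 3 * 5), c(B, 3, 5))
    tic <- array(runif(B * 3 * 4), c(B, 3, 4))
    lab <- c(1L, 0L, 1L, 0L)
    lg <- hybrid_loss_grads(m, tc, tic, lab)
    eps <- 1e-5
    for (nm in names(m$params)) {
      p <- m$params[[nm]]
      for (k in sample(length(p), min(3, length(p)))) {
        m2 <- m
        m2$params[[nm]][k] <- p[k] + eps
        l1 <- hybrid_loss_grads(m2, tc, tic, lab)$loss
        m2$params[[nm]][k] <- p[k] - eps
        l0 <- hybrid_loss_grads(m2, tc, tic, lab)$loss
        num <- (l1 - l0) / (2 * eps)
        ana <- lg$grads[[nm]][k]
        expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 1e-4)
      }
    }
  }
})

test_that("batch permutation permutes predictions identically", {
  m <- init_params(hybrid_config(), seed = 6)
  set.seed(10)
  B <- 10
  tc <- array(runif(B * 6 * 23), c(B, 6, 23))
  tic <- array(runif(B * 6 * 21), c(B, 6, 21))
  p <- hybrid_forward(m, tc, tic)$prob
  perm <- sample(B)
  p2 <- hybrid_forward(m, tc[perm, , , drop = FALSE],
                       tic[perm, , , drop = FALSE])$prob
  expect_equal(p2, p[perm, ], tolerance = 1e-10)

  t2 <- tic_branch_forward(m, tic[perm, , , drop = FALSE])
  expect_equal(t2, tic_branch_forward(m, tic)[perm, ], tolerance = 1e-10)
})

test_that("zero input with zeroed affine heads yields zero logits", {
  m <- init_params(hybrid_config(arch = "conv_only"), seed = 3)
  B <- 4
  tic0 <- array(0, c(B, 6, 21))
  m$params$tic_head_W[] <- m$params$tic_head_W * 0
  # all-zero input stays zero through conv (BN in inference state maps 0->0)
  out <- tic_branch_forward(m, tic0, training = FALSE)
  expect_true(all(out == 0))
})

test_that("a checkpoint round-trips predictions exactly", {
  m <- init_params(small_config(), seed = 9)
  sq <- toy_sequences(n = 8, seed = 10)
  p1 <- predict_proba(m, sq)
  path <- withr::local_tempfile(fileext = ".rds")
  save_hybrid_model(m, path)
  m2 <- load_hybrid_model(path)
  expect_identical(predict_proba(m2, sq), p1)
  expect_error(load_hybrid_model({
    bad <- withr::local_tempfile(fileext = ".rds")
    saveRDS(list(a = 1), bad); bad
  }), "checkpoint")
})
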