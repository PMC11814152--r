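test_that("positional encoding is deterministic, bounded and starts at sin(0)", {
  p <- positional_encoding(12, 8)
  expect_equal(dim(p), c(12, 8))
  expect_equal(p[1, 1], 0)                         # sin(0)
  expect_true(all(p >= -1 & p <= 1))
  expect_identical(p, positional_encoding(12, 8))
})

test_that("attention with zero projections is uniform; hand example matches softmax", {
  z <- matrix(rnorm(20), 5, 4)
  zero <- matrix(0, 4, 4)
  out <- dynamic_attention_layer(z, zero, zero, diag(4), use_positional = FALSE)
  expect_equal(out$A, matrix(1 / 5, 5, 5), tolerance = 1e-12)
  # hand-computed: T'=2, D=1, all weights 1, Z = (1, 0)
  z2 <- matrix(c(1, 0), 2, 1)
  one <- matrix(1, 1, 1)
  out2 <- dynamic_attention_layer(z2, one, one, one, use_positional = FALSE)
  expect_equal(out2$A[1, ], c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-4)
  expect_equal(out2$A[1, ], c(0.7311, 0.2689), tolerance = 1e-4)
  # rows always sum to one
  expect_equal(rowSums(out2$A), c(1, 1), tolerance = 1e-12)
})

test_that("attention matches a brute-force two-loop implementation to 1e-10", {
  set.seed(31)
  for (trial in 1:5) {
    z <- matrix(rnorm(32), 8, 4)
    Wq <- matrix(rnorm(16), 4, 4); Wk <- matrix(rnorm(16), 4, 4)
    Wv <- matrix(rnorm(16), 4, 4)
    fast <- dynamic_attention_layer(z, Wq, Wk, Wv, use_positional = FALSE)
    # brute force: per time step, per key, explicit dot products
    d <- 4; tp <- 8
    A <- matrix(0, tp, tp); out <- matrix(0, tp, d)
    for (t in 1:tp) {
      q_t <- Wq %*% z[t, ]
      scores <- numeric(tp)
      for (s in 1:tp) scores[s] <- sum(q_t * (Wk %*% z[s, ])) / sqrt(d)
      e <- exp(scores - max(scores))
      A[t, ] <- e / sum(e)
      for (s in 1:tp) out[t, ] <- out[t, ] + A[t, s] * as.vector(Wv %*% z[s, ])
    }
    expect_lt(max(abs(fast$A - A)), 1e-10)
    expect_lt(max(abs(fast$output - out)), 1e-10)
  }
})

test_that("attention without positions is permutation-equivariant", {
  set.seed(32)
  z <- matrix(rnorm(20), 5, 4)
  Wq <- matrix(rnorm(16), 4, 4); Wk <- matrix(rnorm(16), 4, 4)
  Wv <- matrix(rnorm(16), 4, 4)
  base <- dynamic_attention_layer(z, Wq, Wk, Wv, use_positional = FALSE)
  for (trial in 1:5) {
    perm <- sample(5)
    permed <- dynamic_attention_layer(z[perm, ], Wq, Wk, Wv,
                                      use_positional = FALSE)
    expect_equal(permed$output, base$output[perm, ], tolerance = 1e-12)
  }
})

test_that("temporal convolution matches identity, moving-sum and a triple-loop oracle", {
  # k = 1 identity kernel reproduces the input
  z <- matrix(rnorm(24), 6, 4)
  ident <- array(0, c(1, 4, 4)); ident[1, , ] <- diag(4)
  expect_equal(temporal_conv_layer(z, ident, activation = "identity"), z,
               tolerance = 1e-12)
  # k = 3, D = 1, all-ones kernel on an impulse gives a moving sum
  imp <- matrix(0, 7, 1); imp[4, 1] <- 1
  ker <- array(1, c(3, 1, 1))
  out <- temporal_conv_layer(imp, ker, activation = "identity")
  expect_equal(out[, 1], c(0, 0, 1, 1, 1, 0, 0))
  # triple-loop oracle on random input
  set.seed(33)
  z2 <- matrix(rnorm(8 * 4), 8, 4)
  k <- 3; kern <- array(rnorm(k * 4 * 4), c(k, 4, 4))
  fast <- temporal_conv_layer(z2, kern, activation = "identity")
  pad <- (k - 1) / 2
  zp <- rbind(matrix(0, pad, 4), z2, matrix(0, pad, 4))
  slow <- matrix(0, 8, 4)
  for (t in 1:8) for (o in 1:4) for (i in 1:k) {
    slow[t, o] <- slow[t, o] + sum(kern[i, o, ] * zp[t + i - 1, ])
  }
  expect_lt(max(abs(fast - slow)), 1e-10)
  # ReLU clamps to nonnegative
  expect_true(all(temporal_conv_layer(z2, kern) >= 0))
  expect_error(temporal_conv_layer(z2, array(0, c(2, 4, 4))), "odd")
})

test_that("layer norm standardizes rows and is shift-invariant pre-affine", {
  set.seed(34)
  h <- matrix(rnorm(40, sd = 5), 8, 5)
  out <- residual_ln_block(h, function(x) 0 * x)
  expect_lt(max(abs(rowMeans(out))), 1e-4)
  expect_lt(max(abs(apply(out, 1, function(r) sqrt(mean(r^2))) - 1)), 1e-3)
  # adding a per-row constant leaves the normalized rows unchanged
  shifted <- layer_norm(h + 100)
  expect_equal(shifted, layer_norm(h), tolerance = 1e-6)
  # stability at large magnitudes
  big <- layer_norm(matrix(runif(40, -1e6, 1e6), 8, 5))
  expect_true(all(is.finite(big)))
})

test_that("multi-scale integration pools branches and concatenates M x D features", {
  set.seed(35)
  h <- matrix(rnorm(24), 6, 4)
  ident <- array(0, c(1, 4, 4)); ident[1, , ] <- diag(4)
  # degenerate single branch, identity fc: F_int equals F_1
  res <- multi_scale_integrate(h, list(list(W = ident, b = rep(0, 4))),
                               fc_W = diag(4), fc_b = rep(0, 4))
  expect_equal(res$f_int, res$scale_features[[1]], tolerance = 1e-12)
  # concat length is M x D
  brs <- lapply(c(3, 5, 7), function(k)
    list(W = array(rnorm(k * 16), c(k, 4, 4)), b = rep(0, 4)))
  res3 <- multi_scale_integrate(h, brs)
  expect_equal(length(res3$concat), 3 * 4)
  # constant rows + identity-preserving branch: pooled feature equals any row
  hc <- matrix(rep(c(1, -2, 3, 0.5), each = 6), 6, 4)
  resc <- multi_scale_integrate(hc, list(list(W = ident, b = rep(0, 4))))
  expect_equal(resc$scale_features[[1]], pmax(hc[1, ], 0), tolerance = 1e-12)
})

test_that("hierarchical pooling gives uniform weights for zero query and saturates on dominant scores", {
  set.seed(36)
  h <- matrix(rnorm(20), 5, 4)
  res <- hierarchical_attention_pool(h, rep(0, 4), diag(4))
  expect_equal(res$weights, rep(1 / 5, 5), tolerance = 1e-12)
  expect_equal(res$v, colMeans(h), tolerance = 1e-12)
  expect_equal(sum(res$weights), 1, tolerance = 1e-6)
  expect_true(all(res$weights >= 0))
  # score gap >= 50 makes the pooled vector the dominant row
  h2 <- matrix(rnorm(20), 5, 4)
  Wk <- diag(4)
  q <- rep(0, 4)
  h2[3, ] <- c(200, 0, 0, 0)            # score huge for row 3 with q = e1
  q <- c(1, 0, 0, 0)
  res2 <- hierarchical_attention_pool(h2, q, Wk)
  expect_equal(res2$v, h2[3, ], tolerance = 1e-6)
})

test_that("prediction head is a stable shift-invariant softmax", {
  k5 <- prediction_head(rep(0, 4), matrix(0, 5, 4), rep(0, 5))
  expect_equal(k5$probs, rep(0.2, 5), tolerance = 1e-12)
  p1 <- prediction_head(c(1, 2), diag(2), c(0, 0))
  p2 <- prediction_head(c(1, 2), diag(2), c(100, 100))
  expect_equal(p1$probs, p2$probs, tolerance = 1e-12)
  expect_equal(prediction_head(c(1, 0), diag(2), c(0, 0))$probs,
               c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(sum(p1$probs), 1, tolerance = 1e-8)
  # extreme logits stay finite
  pb <- prediction_head(c(1e4, -1e4), diag(2), c(0, 0))
  expect_true(all(is.finite(pb$probs)))
})

test_that("eval-mode forward is deterministic and normalization invariants hold", {
  cfg <- tiny_cfg()
  params <- aten_init(cfg, seed = 2)
  z <- matrix(rnorm(15), 5, 3)
  t1 <- aten_forward(z, params, cfg, mode = "eval")
  t2 <- aten_forward(z, params, cfg, mode = "eval")
  expect_identical(t1$probs, t2$probs)
  expect_identical(t1$logits, t2$logits)
  set.seed(37)
  for (trial in 1:25) {
    zt <- matrix(rnorm(5 * 3, sd = runif(1, 0.1, 10)), 5, 3)
    tr <- aten_forward(zt, params, cfg, mode = "eval")
    expect_lt(abs(sum(tr$probs) - 1), 1e-6)
    expect_true(all(tr$probs >= 0))
    expect_lt(max(abs(rowSums(tr$attention[[1]]) - 1)), 1e-6)
    expect_lt(abs(sum(tr$hier_weights) - 1), 1e-6)
  }
})

test_that("output dimension is K for any window length", {
  cfg <- tiny_cfg()
  params <- aten_init(cfg, seed = 3)
  for (tp in c(10, 50, 1000)) {
    tr <- aten_forward(matrix(rnorm(tp * 3), tp, 3), params, cfg)
    expect_length(tr$probs, 5)
  }
  expect_error(aten_forward(matrix(0, 5, 7), params, cfg), "shape error")
})

test_that("train-mode dropout is seeded and eval ignores the seed", {
  cfg <- tiny_cfg()
  cfg$dropout_p <- 0.5
  params <- aten_init(cfg, seed = 4)
  z <- matrix(rnorm(15), 5, 3)
  a <- aten_forward(z, params, cfg, mode = "train", seed = 9)
  b <- aten_forward(z, params, cfg, mode = "train", seed = 9)
  c_ <- aten_forward(z, params, cfg, mode = "train", seed = 10)
  expect_identical(a$probs, b$probs)
  expect_false(identical(a$probs, c_$probs))
  e1 <- aten_forward(z, params, cfg, mode = "eval")
  e2 <- aten_forward(z, params, cfg, mode = "eval")
  expect_identical(e1$probs, e2$probs)
})

test_that("analytic gradients match central finite differences", {
  set.seed(40)
  cfg <- aten_config(d_input = 3, d_model = 4, n_layers = 1,
                     kernel_sizes = c(3, 5), d_int = 6, n_classes = 5,
                     dropout_p = 0, d_hier = 4)
  params <- aten_init(cfg, seed = 41)
  z <- matrix(rnorm(15), 5, 3)
  y <- 2L
  prior <- constraint_prior()
  lam <- 0.1
  lossfun <- function(p) {
    tr <- aten_forward(z, p, cfg, mode = "eval")
    -log(max(tr$probs[y + 1], 1e-12)) +
      lam * sum(abs(tr$probs - prior[y + 1, ]))
  }
  tr <- aten_forward(z, params, cfg, mode = "eval", keep_cache = TRUE)
  s <- sign(tr$probs - prior[y + 1, ])
  yv <- rep(0, 5); yv[y + 1] <- 1
  dlog <- (tr$probs - yv) +
    lam * (tr$probs * s - tr$probs * sum(tr$probs * s))
  g <- aten_backward(tr, dlog, params, cfg)
  check <- function(get, set, gval, n = 5) {
    vals <- get(params)
    for (i in sample(length(vals), min(n, length(vals)))) {
      eps <- 1e-6
      fd <- (lossfun(set(params, replace(vals, i, vals[i] + eps))) -
               lossfun(set(params, replace(vals, i, vals[i] - eps)))) / (2 * eps)
      expect_lt(abs(fd - gval[i]) / max(1e-6, abs(fd) + abs(gval[i])), 1e-4)
    }
  }
  check(function(p) p$W_in, function(p, v) { p$W_in[] <- v; p }, g$W_in)
  check(function(p) p$layers[[1]]$Wq,
        function(p, v) { p$layers[[1]]$Wq[] <- v; p }, g$layers[[1]]$Wq)
  check(function(p) p$layers[[1]]$Wv,
        function(p, v) { p$layers[[1]]$Wv[] <- v; p }, g$layers[[1]]$Wv)
  check(function(p) p$layers[[1]]$conv,
        function(p, v) { p$layers[[1]]$conv[] <- v; p }, g$layers[[1]]$conv)
  check(function(p) p$layers[[1]]$ln2_g,
        function(p, v) { p$layers[[1]]$ln2_g[] <- v; p }, g$layers[[1]]$ln2_g)
  check(function(p) p$branches[[2]]$W,
        function(p, v) { p$branches[[2]]$W[] <- v; p }, g$branches[[2]]$W)
  check(function(p) p$fc_W, function(p, v) { p$fc_W[] <- v; p }, g$fc_W)
  check(function(p) p$hier_q, function(p, v) { p$hier_q[] <- v; p }, g$hier_q)
  check(function(p) p$hier_Wk, function(p, v) { p$hier_Wk[] <- v; p },
        g$hier_Wk)
  check(function(p) p$Wo, function(p, v) { p$Wo[] <- v; p }, g$Wo)
})

test_that("checkpoints round-trip parameters and configuration", {
  cfg <- tiny_cfg()
  params <- aten_init(cfg, seed = 8)
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(params, cfg, f, extra = list(feat_mode = "bands"))
  ck <- load_checkpoint(f)
  expect_equal(ck$cfg$d_model, cfg$d_model)
  expect_equal(ck$cfg$kernel_sizes, cfg$kernel_sizes)
  expect_equal(ck$params$W_in, params$W_in, tolerance = 1e-12)
  expect_equal(ck$params$layers[[1]]$conv, params$layers[[1]]$conv,
               tolerance = 1e-12)
  expect_equal(ck$params$hier_q, params$hier_q, tolerance = 1e-12)
  expect_equal(ck$extra$feat_mode, "bands")
  # identical forward output from reloaded parameters
  z <- matrix(rnorm(15), 5, 3)
  expect_equal(aten_forward(z, ck$params, ck$cfg)$probs,
               aten_forward(z, params, cfg)$probs, tolerance = 1e-12)
})
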