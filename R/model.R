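#' Adaptive temporal encoder network configuration
#'
#' Architecture hyperparameters of the encoder: model width, depth, the
#' kernel sizes of the multi-scale convolution branches, the integrated
#' feature dimension, number of classes and dropout rate. Ablation
#' switches (`use_attention`, `use_conv`, `use_multiscale`) disable whole
#' sub-blocks for component-contribution studies.
#'
#' @param d_input Input feature dimension `D_in` (columns of `Z`).
#' @param d_model Hidden width `D` (default 64).
#' @param n_layers Number of encoder layers `L` (default 2).
#' @param kernel_sizes Odd kernel sizes of the `M` multi-scale branches
#'   (default `c(3, 5, 7)`); the first one is also the in-layer
#'   convolution kernel size.
#' @param d_int Integrated feature dimension `D'` (default 64).
#' @param n_classes Number of output classes `K` (default 5).
#' @param dropout_p Dropout probability in train mode (default 0.5).
#' @param use_positional Add sinusoidal positional encodings to queries
#'   and keys (default `TRUE`).
#' @param d_hier Hierarchical attention dimension (default `d_model`).
#' @param attn_scale `"sqrt"` (scaled dot-product, `1/sqrt(D)`) or
#'   `"linear"` (`1/D`, the literal printed form).
#' @param use_attention,use_conv,use_multiscale Ablation switches.
#' @return An `aten_config` list.
#' @export
aten_config <- function(d_input, d_model = 64, n_layers = 2,
                        kernel_sizes = c(3, 5, 7), d_int = 64,
                        n_classes = 5, dropout_p = 0.5,
                        use_positional = TRUE, d_hier = d_model,
                        attn_scale = c("sqrt", "linear"),
                        use_attention = TRUE, use_conv = TRUE,
                        use_multiscale = TRUE) {
  attn_scale <- match.arg(attn_scale)
  stopifnot(d_input >= 1, d_model >= 1, n_layers >= 1, d_int >= 1,
            n_classes >= 2, dropout_p >= 0, dropout_p < 1)
  if (any(kernel_sizes %% 2 == 0))
    stop("parameter error: kernel sizes must be odd for symmetric padding")
  structure(list(d_input = as.integer(d_input), d_model = as.integer(d_model),
                 n_layers = as.integer(n_layers),
                 kernel_sizes = as.integer(kernel_sizes),
                 d_int = as.integer(d_int), n_classes = as.integer(n_classes),
                 dropout_p = dropout_p, use_positional = use_positional,
                 d_hier = as.integer(d_hier), attn_scale = attn_scale,
                 use_attention = use_attention, use_conv = use_conv,
                 use_multiscale = use_multiscale),
            class = "aten_config")
}

xavier <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

#' Initialize encoder parameters
#'
#' Xavier-uniform weight matrices, unit layer-norm gains, zero offsets and
#' biases. Fully deterministic given `seed`.
#'
#' @param cfg An `aten_config`.
#' @param seed Integer seed.
#' @return An `aten_params` list whose shapes match `cfg`.
#' @export
aten_init <- function(cfg, seed = 0L) {
  set.seed(seed)
  d <- cfg$d_model
  layers <- lapply(seq_len(cfg$n_layers), function(l) {
    k <- cfg$kernel_sizes[1]
    conv <- array(stats::rnorm(k * d * d, 0, sqrt(2 / (k * d))), c(k, d, d))
    list(Wq = xavier(d, d), Wk = xavier(d, d), Wv = xavier(d, d),
         ln1_g = rep(1, d), ln1_b = rep(0, d),
         conv = conv, conv_b = rep(0, d),
         ln2_g = rep(1, d), ln2_b = rep(0, d))
  })
  m <- length(cfg$kernel_sizes)
  branches <- lapply(cfg$kernel_sizes, function(k) {
    list(W = array(stats::rnorm(k * d * d, 0, sqrt(2 / (k * d))), c(k, d, d)),
         b = rep(0, d))
  })
  d_concat <- (if (cfg$use_multiscale) m * d else d) + d  # + hier vector
  structure(list(
    W_in = xavier(d, cfg$d_input), b_in = rep(0, d),
    layers = layers, branches = branches,
    fc_W = xavier(cfg$d_int, d_concat), fc_b = rep(0, cfg$d_int),
    hier_q = stats::rnorm(cfg$d_hier, 0, 1 / sqrt(cfg$d_hier)),
    hier_Wk = xavier(cfg$d_hier, d),
    Wo = xavier(cfg$n_classes, cfg$d_int), bo = rep(0, cfg$n_classes)
  ), class = "aten_params")
}

#' Sinusoidal positional encoding table
#'
#' Deterministic table `P` (`t_prime x d`) of interleaved sines and
#' cosines at geometrically spaced wavelengths; all entries lie in
#' `[-1, 1]`. Added to queries and keys only, never to values.
#'
#' @param t_prime Number of time steps.
#' @param d Feature dimension.
#' @return A `t_prime x d` matrix.
#' @export
positional_encoding <- function(t_prime, d) {
  pos <- 0:(t_prime - 1)
  p <- matrix(0, t_prime, d)
  for (j in 0:(d - 1)) {
    rate <- 1 / 10000^((2 * (j %/% 2)) / d)
    p[, j + 1] <- if (j %% 2 == 0) sin(pos * rate) else cos(pos * rate)
  }
  p
}

#' Row-wise numerically stable softmax
#' @param x Numeric matrix (or vector).
#' @return Matrix (or vector) of the same shape; rows are nonnegative and
#'   sum to 1.
#' @export
softmax_rows <- function(x) {
  if (is.null(dim(x))) {
    z <- exp(x - max(x)); return(z / sum(z))
  }
  z <- exp(x - apply(x, 1, max))
  z / rowSums(z)
}

#' Dynamic per-step attention layer
#'
#' Scaled dot-product self-attention recomputed from the current features
#' at every time step: queries `q_t = W_Q (z_t + p_t)`, keys
#' `K = W_K (Z + P)` (positional terms omitted when `use_positional` is
#' `FALSE`), attention row `a_t = softmax(q_t K^T / sqrt(D))`, output row
#' `t` equal to `a_t (Z W_V^T)`. Every attention row sums to 1.
#'
#' @param z Input matrix `T' x D`.
#' @param Wq,Wk,Wv `D x D` projection matrices.
#' @param use_positional Add the sinusoidal table to queries/keys.
#' @param attn_scale `"sqrt"` for `1/sqrt(D)` scaling or `"linear"` for
#'   `1/D`.
#' @return List with `output` (`T' x D`) and `A` (`T' x T'` attention).
#' @export
dynamic_attention_layer <- function(z, Wq, Wk, Wv, use_positional = TRUE,
                                    attn_scale = "sqrt") {
  if (!all(is.finite(z))) stop("numeric error: non-finite attention input")
  d <- ncol(z)
  zp <- if (use_positional) z + positional_encoding(nrow(z), d) else z
  q <- zp %*% t(Wq)
  k <- zp %*% t(Wk)
  scl <- if (attn_scale == "sqrt") sqrt(d) else d
  a <- softmax_rows(q %*% t(k) / scl)
  list(output = a %*% (z %*% t(Wv)), A = a)
}

#' Temporal convolution over the time axis
#'
#' Same-length 1-D convolution with symmetric zero padding of
#' `(k - 1)/2` on each side:
#' `out_t = act(b + sum_i W[i,,] z_{t + i - 1 - (k-1)/2})`.
#'
#' @param z Input matrix `T' x D_in`.
#' @param kernel Array `k x D_out x D_in` (k odd).
#' @param bias Optional `D_out` bias vector.
#' @param activation `"relu"` or `"identity"`.
#' @return Output matrix `T' x D_out`.
#' @export
temporal_conv_layer <- function(z, kernel, bias = NULL,
                                activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  k <- dim(kernel)[1]
  if (k %% 2 == 0) stop("parameter error: kernel size must be odd")
  t_ <- nrow(z); d_out <- dim(kernel)[2]
  pad <- (k - 1) / 2
  zp <- rbind(matrix(0, pad, ncol(z)), z, matrix(0, pad, ncol(z)))
  u <- matrix(if (is.null(bias)) 0 else rep(bias, each = t_), t_, d_out)
  for (i in seq_len(k)) {
    u <- u + zp[i:(i + t_ - 1), , drop = FALSE] %*% t(kernel[i, , , drop = TRUE])
  }
  if (activation == "relu") u <- pmax(u, 0)
  u
}

#' Row-wise layer normalization with learned affine transform
#'
#' Per time step (row), subtract the feature mean and divide by the
#' feature standard deviation (epsilon 1e-5), then apply gain and offset.
#'
#' @param h Matrix `T' x D`.
#' @param gain,offset Length-`D` learned parameters.
#' @param eps Variance floor.
#' @return Normalized matrix of the same shape.
#' @export
layer_norm <- function(h, gain = rep(1, ncol(h)), offset = rep(0, ncol(h)),
                       eps = 1e-5) {
  mu <- rowMeans(h)
  va <- rowMeans((h - mu)^2)
  xhat <- (h - mu) / sqrt(va + eps)
  sweep(xhat * rep(gain, each = nrow(h)), 2, offset, `+`)
}

#' Residual block with layer normalization
#'
#' Computes `LayerNorm(H + sublayer(H))`, the standard pre-activation
#' residual wrapper applied to both the attention and convolution
#' sub-blocks.
#'
#' @param h Matrix `T' x D`.
#' @param sublayer Shape-preserving function of `h`.
#' @param gain,offset Layer-norm parameters.
#' @return Matrix `T' x D`.
#' @export
residual_ln_block <- function(h, sublayer, gain = rep(1, ncol(h)),
                              offset = rep(0, ncol(h))) {
  layer_norm(h + sublayer(h), gain, offset)
}

#' Multi-scale feature integration
#'
#' Each branch applies its temporal convolution stack (one kernel size per
#' branch) to `H` and mean-pools over time to a `D`-vector `F_m`; the
#' concatenation of all `F_m` is projected by the fully connected map to
#' the integrated feature vector `F_int`.
#'
#' @param h Matrix `T' x D`.
#' @param branches List of branch parameter lists (`W`: `k x D x D`
#'   kernel, `b`: bias).
#' @param fc_W,fc_b Fully connected projection (`D' x (M D)` and `D'`).
#'   Pass `NULL` to return the raw concatenation.
#' @return List with `f_int` (`D'` vector), `scale_features` (list of
#'   `F_m`) and `concat`.
#' @export
multi_scale_integrate <- function(h, branches, fc_W = NULL, fc_b = NULL) {
  fs <- lapply(branches, function(br)
    colMeans(temporal_conv_layer(h, br$W, br$b, activation = "relu")))
  u <- unlist(fs, use.names = FALSE)
  f_int <- if (is.null(fc_W)) u else as.vector(fc_W %*% u + fc_b)
  list(f_int = f_int, scale_features = fs, concat = u)
}

#' Hierarchical attention pooling over time
#'
#' Aggregates the encoder output into a single vector: scores
#' `s_t = q . (W_k h_t) / sqrt(D_hier)`, weights `softmax(s)`, pooled
#' vector `v = sum_t w_t h_t`. With a zero query the weights are uniform
#' and `v` is the time-mean.
#'
#' @param h Matrix `T' x D`.
#' @param q Query vector (`D_hier`).
#' @param Wk Key projection (`D_hier x D`).
#' @param attn_scale `"sqrt"` or `"linear"`.
#' @return List with `v` (`D` vector) and `weights` (`T'` vector summing
#'   to 1).
#' @export
hierarchical_attention_pool <- function(h, q, Wk, attn_scale = "sqrt") {
  d_h <- length(q)
  scl <- if (attn_scale == "sqrt") sqrt(d_h) else d_h
  kh <- h %*% t(Wk)
  s <- as.vector(kh %*% q) / scl
  w <- softmax_rows(s)
  list(v = as.vector(t(h) %*% w), weights = w)
}

#' Softmax prediction head
#'
#' Maps the integrated feature vector to class probabilities:
#' `softmax(Wo f + bo)`, computed with max subtraction for stability.
#'
#' @param f_int Feature vector (`D'`).
#' @param Wo Weight matrix `K x D'`.
#' @param bo Bias vector `K`.
#' @return List with `probs` (sums to 1) and `logits`.
#' @export
prediction_head <- function(f_int, Wo, bo) {
  logits <- as.vector(Wo %*% f_int + bo)
  list(probs = softmax_rows(logits), logits = logits)
}

# inverted dropout mask (train mode); returns list(x, mask)
.dropout <- function(x, p) {
  if (p <= 0) return(list(x = x, mask = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x), ncol(x)) >= p) / (1 - p)
  list(x = x * mask, mask = mask)
}
.dropout_vec <- function(x, p) {
  if (p <= 0) return(list(x = x, mask = NULL))
  mask <- (stats::runif(length(x)) >= p) / (1 - p)
  list(x = x * mask, mask = mask)
}

#' Full encoder forward pass
#'
#' Composes the pipeline: input projection, `L` encoder layers (each a
#' residual layer-normalized attention sub-block followed by a residual
#' layer-normalized temporal-convolution sub-block), multi-scale
#' integration over the branch kernel sizes, hierarchical attention
#' pooling (the pooled vector is appended to the multi-scale
#' concatenation before the fully connected integration), and the softmax
#' prediction head. Dropout is applied to each sub-block output and to
#' the integrated features in train mode only; eval mode is fully
#' deterministic.
#'
#' @param z Feature matrix (`T' x D_in` numeric matrix or a
#'   `feature_matrix`).
#' @param params An `aten_params`.
#' @param cfg The matching `aten_config`.
#' @param mode `"eval"` (deterministic) or `"train"` (dropout active).
#' @param seed Optional seed for the train-mode dropout draws.
#' @param keep_cache Retain intermediate activations (needed by
#'   [aten_backward()]).
#' @return A `forward_trace`: `probs`, `logits`, `f_int`, `attention`
#'   (per-layer `T' x T'` matrices), `scale_features`, `hier_weights`,
#'   and (optionally) `cache`.
#' @export
aten_forward <- function(z, params, cfg, mode = c("eval", "train"),
                         seed = NULL, keep_cache = FALSE) {
  mode <- match.arg(mode)
  if (inherits(z, "feature_matrix")) z <- z$data
  if (ncol(z) != cfg$d_input)
    stop("shape error at input projection: expected ", cfg$d_input,
         " feature columns, found ", ncol(z))
  if (!all(is.finite(z))) stop("numeric error: non-finite encoder input")
  if (!is.null(seed) && mode == "train") set.seed(seed)
  p_drop <- if (mode == "train") cfg$dropout_p else 0
  t_ <- nrow(z); d <- cfg$d_model
  scl <- if (cfg$attn_scale == "sqrt") sqrt(d) else d
  pos <- if (cfg$use_positional) positional_encoding(t_, d) else matrix(0, t_, d)

  cache <- list(z = z, pos = pos, layers = vector("list", cfg$n_layers))
  h <- z %*% t(params$W_in) + rep(params$b_in, each = t_)
  cache$h0 <- h
  attn_list <- vector("list", cfg$n_layers)

  for (l in seq_len(cfg$n_layers)) {
    lp <- params$layers[[l]]
    lc <- list(h_in = h)
    if (cfg$use_attention) {
      zp <- h + pos
      qm <- zp %*% t(lp$Wq)
      km <- zp %*% t(lp$Wk)
      a <- softmax_rows(qm %*% t(km) / scl)
      hv <- h %*% t(lp$Wv)
      o <- a %*% hv
      dr <- .dropout(o, p_drop)
      r1 <- h + dr$x
      lc <- c(lc, list(zp = zp, q = qm, k = km, a = a, hv = hv, o = o,
                       mask1 = dr$mask, r1 = r1))
      h1 <- .ln_fwd(r1, lp$ln1_g, lp$ln1_b, lc, "ln1")
      lc <- attr(h1, "lc"); attributes(h1) <- attributes(h1)["dim"]
      attn_list[[l]] <- a
    } else {
      h1 <- h
      lc$skip_attn <- TRUE
    }
    lc$h1 <- h1
    if (cfg$use_conv) {
      cv <- .conv_fwd(h1, lp$conv, lp$conv_b)
      dr2 <- .dropout(cv$post, p_drop)
      r2 <- h1 + dr2$x
      lc <- c(lc, list(conv_pre = cv$pre, conv_post = cv$post,
                       mask2 = dr2$mask, r2 = r2))
      h2 <- .ln_fwd(r2, lp$ln2_g, lp$ln2_b, lc, "ln2")
      lc <- attr(h2, "lc"); attributes(h2) <- attributes(h2)["dim"]
    } else {
      h2 <- h1
      lc$skip_conv <- TRUE
    }
    lc$h_out <- h2
    cache$layers[[l]] <- lc
    h <- h2
  }
  cache$h_enc <- h

  # multi-scale branches
  if (cfg$use_multiscale) {
    br_cache <- lapply(params$branches, function(br) .conv_fwd(h, br$W, br$b))
    fs <- lapply(br_cache, function(bc) colMeans(bc$post))
    cache$branches <- br_cache
  } else {
    fs <- list(colMeans(h))
    cache$branches <- NULL
  }
  # hierarchical pooling
  kh <- h %*% t(params$hier_Wk)
  scl_h <- if (cfg$attn_scale == "sqrt") sqrt(cfg$d_hier) else cfg$d_hier
  s <- as.vector(kh %*% params$hier_q) / scl_h
  wgt <- softmax_rows(s)
  v <- as.vector(t(h) %*% wgt)
  cache <- c(cache, list(kh = kh, hier_s = s, hier_w = wgt, hier_v = v,
                         scl_h = scl_h, scl = scl))

  u <- c(unlist(fs, use.names = FALSE), v)
  f_int <- as.vector(params$fc_W %*% u + params$fc_b)
  drf <- .dropout_vec(f_int, p_drop)
  cache <- c(cache, list(u = u, f_int_pre = f_int, mask_f = drf$mask))
  f_use <- drf$x
  logits <- as.vector(params$Wo %*% f_use + params$bo)
  probs <- softmax_rows(logits)
  cache$f_use <- f_use

  structure(list(probs = probs, logits = logits, f_int = f_int,
                 attention = attn_list, scale_features = fs,
                 hier_weights = wgt,
                 cache = if (keep_cache) cache else NULL,
                 mode = mode),
            class = "forward_trace")
}

# layer norm forward that stashes per-row stats into the layer cache `lc`
# under names `<tag>_*`; returns the normalized matrix with lc attached.
.ln_fwd <- function(x, g, b, lc, tag) {
  mu <- rowMeans(x)
  va <- rowMeans((x - mu)^2)
  isd <- 1 / sqrt(va + 1e-5)
  xhat <- (x - mu) * isd
  y <- xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x))
  lc[[paste0(tag, "_xhat")]] <- xhat
  lc[[paste0(tag, "_isd")]] <- isd
  attr(y, "lc") <- lc
  y
}

# convolution forward keeping pre-activation; kernel k x D_out x D_in
.conv_fwd <- function(h, kernel, bias) {
  k <- dim(kernel)[1]; t_ <- nrow(h); pad <- (k - 1) / 2
  hp <- rbind(matrix(0, pad, ncol(h)), h, matrix(0, pad, ncol(h)))
  u <- matrix(rep(bias, each = t_), t_, dim(kernel)[2])
  for (i in seq_len(k)) {
    u <- u + hp[i:(i + t_ - 1), , drop = FALSE] %*% t(kernel[i, , , drop = TRUE])
  }
  list(pre = u, post = pmax(u, 0), hp = hp, k = k, pad = pad)
}

# layer-norm backward for one block; dy, cached xhat and inverse sd
.ln_bwd <- function(dy, xhat, isd, g) {
  t_ <- nrow(dy)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(g, each = t_)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * isd
  list(dx = dx, dg = dg, db = db)
}

# convolution backward; returns gradients and dH
.conv_bwd <- function(d_post, bc, kernel) {
  du <- d_post * (bc$pre > 0)
  k <- bc$k; t_ <- nrow(du); pad <- bc$pad
  db <- colSums(du)
  dW <- array(0, dim(kernel))
  dhp <- matrix(0, nrow(bc$hp), ncol(bc$hp))
  for (i in seq_len(k)) {
    rows <- i:(i + t_ - 1)
    dW[i, , ] <- t(du) %*% bc$hp[rows, , drop = FALSE]
    dhp[rows, ] <- dhp[rows, ] + du %*% kernel[i, , , drop = TRUE]
  }
  list(dW = dW, db = db,
       dh = dhp[(pad + 1):(pad + t_), , drop = FALSE])
}

#' Backward pass of the encoder
#'
#' Hand-written reverse-mode differentiation of [aten_forward()] with
#' respect to every learnable parameter, given the gradient of the loss at
#' the logits. Verified against central finite differences in the test
#' suite.
#'
#' @param trace A `forward_trace` produced with `keep_cache = TRUE`.
#' @param dlogits Gradient of the scalar loss w.r.t. the logits (`K`).
#' @param params,cfg The parameters and configuration used in the forward
#'   pass.
#' @return An `aten_params`-shaped list of gradients.
#' @export
aten_backward <- function(trace, dlogits, params, cfg) {
  cache <- trace$cache
  if (is.null(cache)) stop("forward trace was built without keep_cache = TRUE")
  t_ <- nrow(cache$z)
  g <- list(W_in = 0 * params$W_in, b_in = 0 * params$b_in,
            layers = vector("list", cfg$n_layers),
            branches = vector("list", length(params$branches)),
            fc_W = 0 * params$fc_W, fc_b = 0 * params$fc_b,
            hier_q = 0 * params$hier_q, hier_Wk = 0 * params$hier_Wk,
            Wo = 0 * params$Wo, bo = 0 * params$bo)

  g$Wo <- outer(dlogits, cache$f_use)
  g$bo <- dlogits
  df_use <- as.vector(t(params$Wo) %*% dlogits)
  if (!is.null(cache$mask_f)) df_use <- df_use * cache$mask_f
  g$fc_W <- outer(df_use, cache$u)
  g$fc_b <- df_use
  du <- as.vector(t(params$fc_W) %*% df_use)

  d <- cfg$d_model
  n_br <- if (cfg$use_multiscale) length(params$branches) else 1
  dv <- du[(n_br * d + 1):(n_br * d + d)]
  dh_enc <- matrix(0, t_, d)

  # hierarchical pool backward
  h <- cache$h_enc
  w <- cache$hier_w
  dw <- as.vector(h %*% dv)
  dh_enc <- dh_enc + outer(w, dv)
  ds <- w * (dw - sum(dw * w))
  g$hier_q <- as.vector(t(cache$kh) %*% ds) / cache$scl_h
  dkh <- outer(ds, params$hier_q) / cache$scl_h
  g$hier_Wk <- t(dkh) %*% h
  dh_enc <- dh_enc + dkh %*% params$hier_Wk

  # branch backward
  if (cfg$use_multiscale) {
    for (m in seq_along(params$branches)) {
      dfm <- du[((m - 1) * d + 1):(m * d)]
      d_post <- matrix(rep(dfm / t_, each = t_), t_, d)
      bb <- .conv_bwd(d_post, cache$branches[[m]], params$branches[[m]]$W)
      g$branches[[m]] <- list(W = bb$dW, b = bb$db)
      dh_enc <- dh_enc + bb$dh
    }
  } else {
    dfm <- du[1:d]
    dh_enc <- dh_enc + matrix(rep(dfm / t_, each = t_), t_, d)
  }

  dh <- dh_enc
  for (l in rev(seq_len(cfg$n_layers))) {
    lp <- params$layers[[l]]
    lc <- cache$layers[[l]]
    gl <- list(Wq = 0 * lp$Wq, Wk = 0 * lp$Wk, Wv = 0 * lp$Wv,
               ln1_g = 0 * lp$ln1_g, ln1_b = 0 * lp$ln1_b,
               conv = 0 * lp$conv, conv_b = 0 * lp$conv_b,
               ln2_g = 0 * lp$ln2_g, ln2_b = 0 * lp$ln2_b)
    # conv sub-block
    if (is.null(lc$skip_conv)) {
      ln2 <- .ln_bwd(dh, lc$ln2_xhat, lc$ln2_isd, lp$ln2_g)
      gl$ln2_g <- ln2$dg; gl$ln2_b <- ln2$db
      dr2 <- ln2$dx
      d_post <- dr2
      if (!is.null(lc$mask2)) d_post <- d_post * lc$mask2
      cb <- .conv_bwd(d_post, list(pre = lc$conv_pre, hp = rbind(
        matrix(0, (dim(lp$conv)[1] - 1) / 2, d), lc$h1,
        matrix(0, (dim(lp$conv)[1] - 1) / 2, d)),
        k = dim(lp$conv)[1], pad = (dim(lp$conv)[1] - 1) / 2), lp$conv)
      gl$conv <- cb$dW; gl$conv_b <- cb$db
      dh1 <- dr2 + cb$dh
    } else {
      dh1 <- dh
    }
    # attention sub-block
    if (is.null(lc$skip_attn)) {
      ln1 <- .ln_bwd(dh1, lc$ln1_xhat, lc$ln1_isd, lp$ln1_g)
      gl$ln1_g <- ln1$dg; gl$ln1_b <- ln1$db
      dr1 <- ln1$dx
      do_ <- dr1
      if (!is.null(lc$mask1)) do_ <- do_ * lc$mask1
      da <- do_ %*% t(lc$hv)
      dhv <- t(lc$a) %*% do_
      ds_ <- lc$a * (da - rowSums(da * lc$a))
      dq <- (ds_ %*% lc$k) / cache$scl
      dk <- (t(ds_) %*% lc$q) / cache$scl
      gl$Wq <- t(dq) %*% lc$zp
      gl$Wk <- t(dk) %*% lc$zp
      gl$Wv <- t(dhv) %*% lc$h_in
      dzp <- dq %*% lp$Wq + dk %*% lp$Wk
      dh_in <- dr1 + dzp + dhv %*% lp$Wv
    } else {
      dh_in <- dh1
    }
    g$layers[[l]] <- gl
    dh <- dh_in
  }

  g$W_in <- t(dh) %*% cache$z
  g$b_in <- colSums(dh)
  g
}
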