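#' Training configuration
#'
#' Optimization settings: Adam with either the cosine cyclic learning-rate
#' schedule (default) or step decay (factor 0.1 every 10 epochs), batch
#' size 64, at most 50 epochs, early stopping with patience 5 on the
#' validation loss, dropout 0.5 (carried by the model config), constraint
#' regularization strength `lambda_reg`, and a 70/15/15 subject-wise
#' train/validation/test split.
#'
#' @param eta_min,eta_max Learning-rate bounds (defaults 1e-5, 1e-3; the
#'   maximum is the initial rate).
#' @param t_cycle Steps per learning-rate cycle; `NULL` means 10 epochs'
#'   worth of steps, computed once the data size is known.
#' @param schedule `"cyclic"` or `"step_decay"`.
#' @param step_decay_factor,step_decay_period Step-decay parameters
#'   (0.1 every 10 epochs).
#' @param batch_size Minibatch size (default 64).
#' @param max_epochs Maximum epochs (default 50).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param min_delta Minimum validation-loss improvement that counts as
#'   progress for early stopping (default 0: any improvement counts).
#' @param lambda_reg Constraint-regularizer weight (default 0.1).
#' @param fractions Train/validation/test subject fractions (sum to 1).
#' @param seed Master seed controlling initialization, shuffling,
#'   augmentation and dropout.
#' @param augment `NULL` to disable training-set augmentation, or an
#'   [augment_config()].
#' @return A `train_config` list.
#' @export
train_config <- function(eta_min = 1e-5, eta_max = 1e-3, t_cycle = NULL,
                         schedule = c("cyclic", "step_decay"),
                         step_decay_factor = 0.1, step_decay_period = 10,
                         batch_size = 64, max_epochs = 50, patience = 5,
                         min_delta = 0, lambda_reg = 0.1,
                         fractions = c(train = 0.70, val = 0.15, test = 0.15),
                         seed = 0L, augment = augment_config()) {
  schedule <- match.arg(schedule)
  stopifnot(eta_min > 0, eta_min <= eta_max, abs(sum(fractions) - 1) < 1e-9)
  structure(list(eta_min = eta_min, eta_max = eta_max, t_cycle = t_cycle,
                 schedule = schedule, step_decay_factor = step_decay_factor,
                 step_decay_period = step_decay_period,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 lambda_reg = lambda_reg,
                 fractions = fractions, seed = as.integer(seed),
                 augment = augment),
            class = "train_config")
}

#' Mean cross-entropy loss
#'
#' Mean over samples of the negative log-probability assigned to the true
#' class, with a probability floor of 1e-12. Uniform 5-class predictions
#' give `log(5)`.
#'
#' @param probs `N x K` matrix of predicted probabilities (rows sum to 1).
#' @param labels Integer class codes 0..K-1, length `N`.
#' @return Nonnegative scalar.
#' @export
cross_entropy_loss <- function(probs, labels) {
  probs <- rbind(probs)
  if (nrow(probs) != length(labels)) stop("shape error: probs rows != labels")
  p_true <- probs[cbind(seq_len(nrow(probs)), as.integer(labels) + 1L)]
  mean(-log(pmax(p_true, 1e-12)))
}

#' Expected-distribution constraint prior
#'
#' Row-stochastic `K x K` matrix whose row `k` is the expected probability
#' profile for true class `k`. The default is a label-smoothed one-hot
#' profile (0.9 on the true class, the remainder spread evenly), encoding
#' the physiological expectation that the predicted distribution
#' concentrates on the labeled cognitive state without claiming certainty.
#'
#' @param n_classes Number of classes `K`.
#' @param confidence Probability mass on the true class (default 0.9).
#' @return `K x K` matrix, each row summing to 1.
#' @export
constraint_prior <- function(n_classes = 5, confidence = 0.9) {
  off <- (1 - confidence) / (n_classes - 1)
  m <- matrix(off, n_classes, n_classes)
  diag(m) <- confidence
  m
}

#' Cognitive-state constraint regularizer
#'
#' L1 deviation of the predicted distribution from the expected profile of
#' the true class, averaged over the batch and scaled by `lambda_reg`:
#' `lambda * mean_i sum_j |p_i(j) - prior[y_i, j]|`. Averaging (rather
#' than summing) over samples keeps the meaning of `lambda` independent of
#' batch size.
#'
#' @param probs `N x K` probability matrix.
#' @param labels Integer codes 0..K-1.
#' @param prior `K x K` row-stochastic matrix ([constraint_prior()]).
#' @param lambda_reg Regularization weight.
#' @return Nonnegative scalar.
#' @export
constraint_regularizer <- function(probs, labels, prior = constraint_prior(),
                                   lambda_reg = 0.1) {
  if (lambda_reg == 0) return(0)
  probs <- rbind(probs)
  resid <- abs(probs - prior[as.integer(labels) + 1L, , drop = FALSE])
  lambda_reg * mean(rowSums(resid))
}

#' Cosine cyclic learning rate
#'
#' `eta(t) = eta_min + (eta_max - eta_min)/2 * (1 + cos(pi * t / t_cycle))`
#' with `t` taken modulo `t_cycle` (warm restarts): `eta(0) = eta_max`,
#' `eta(t_cycle/2)` is the midpoint and `eta(t_cycle) = eta_min` just
#' before the restart.
#'
#' @param t Step index (>= 0).
#' @param eta_min,eta_max Learning-rate bounds.
#' @param t_cycle Cycle length in steps (> 0).
#' @return Learning rate.
#' @export
cyclic_lr <- function(t, eta_min = 1e-5, eta_max = 1e-3, t_cycle = 100) {
  if (t_cycle <= 0) stop("parameter error: t_cycle must be positive")
  tm <- t %% t_cycle
  # the cycle endpoint itself evaluates the closed form at t = t_cycle
  if (t > 0 && tm == 0) tm <- t_cycle
  eta_min + 0.5 * (eta_max - eta_min) * (1 + cos(tm * pi / t_cycle))
}

#' Step-decay learning rate
#'
#' `base_lr * factor^floor(epoch / period)`: a tenth of the rate every 10
#' epochs at the defaults.
#'
#' @param epoch Epoch index (>= 0).
#' @param base_lr Initial rate.
#' @param factor Decay factor (default 0.1).
#' @param period Epochs between decays (default 10).
#' @return Learning rate.
#' @export
step_decay_lr <- function(epoch, base_lr = 1e-3, factor = 0.1, period = 10) {
  base_lr * factor^(epoch %/% period)
}

#' Subject-wise stratified train/validation/test split
#'
#' Partitions subjects (never windows) so no individual contributes data
#' to more than one partition. Stratification is approximate and greedy:
#' subjects are grouped by dominant class, shuffled within groups, ordered
#' group-by-group and dealt to the partition with the largest remaining
#' quota, which balances class composition across partitions.
#'
#' @param subjects Character vector of subject ids, or a data frame with
#'   columns `subject_id` and `dominant_class`.
#' @param fractions Named train/val/test fractions summing to 1.
#' @param seed Integer seed.
#' @return A `split_plan`: data frame with `subject_id` and `partition`
#'   (factor train/val/test).
#' @export
subject_split <- function(subjects,
                          fractions = c(train = 0.70, val = 0.15, test = 0.15),
                          seed = 0L) {
  if (is.data.frame(subjects)) {
    ids <- as.character(subjects$subject_id)
    dom <- as.character(subjects$dominant_class)
  } else {
    ids <- as.character(subjects)
    dom <- rep("all", length(ids))
  }
  n <- length(ids)
  if (n < 3) stop("need at least 3 subjects to fill three partitions")
  set.seed(seed)
  ord <- order(dom, stats::runif(n))
  quota <- c(train = round(fractions[["train"]] * n),
             val = round(fractions[["val"]] * n),
             test = round(fractions[["test"]] * n))
  quota[["train"]] <- n - quota[["val"]] - quota[["test"]]  # train absorbs rounding
  remaining <- quota
  part <- character(n)
  for (i in ord) {
    # deal to the partition with the largest remaining share of its quota:
    # proportional round-robin, so consecutive (same-dominant-class)
    # subjects spread over partitions
    score <- remaining / pmax(quota, 1)
    pick <- names(which.max(score))
    if (remaining[[pick]] <= 0) pick <- names(which.max(remaining))
    part[i] <- pick
    remaining[[pick]] <- remaining[[pick]] - 1
  }
  structure(data.frame(subject_id = ids,
                       partition = factor(part, levels = c("train", "val", "test")),
                       stringsAsFactors = FALSE),
            class = c("split_plan", "data.frame"))
}

#' Subject-wise k-fold cross-validation plans
#'
#' Assigns every subject to exactly one test fold; within each fold the
#' remaining subjects are split train/validation at the configured ratio.
#'
#' @param subjects Character vector of subject ids.
#' @param k Number of folds (default 10).
#' @param val_frac Fraction of the non-test subjects used for validation
#'   (default `0.15 / 0.85`, matching the 70/15/15 split).
#' @param seed Integer seed.
#' @return List of `k` `split_plan` data frames.
#' @export
kfold_subject_cv <- function(subjects, k = 10, val_frac = 0.15 / 0.85,
                             seed = 0L) {
  ids <- as.character(subjects)
  n <- length(ids)
  if (k > n) stop("parameter error: more folds than subjects")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  lapply(seq_len(k), function(f) {
    part <- character(n)
    part[fold == f] <- "test"
    rest <- which(fold != f)
    n_val <- round(length(rest) * val_frac)
    val_idx <- rest[sample.int(length(rest), n_val)]
    part[val_idx] <- "val"
    part[part == ""] <- "train"
    structure(data.frame(subject_id = ids,
                         partition = factor(part, levels = c("train", "val", "test")),
                         stringsAsFactors = FALSE),
              class = c("split_plan", "data.frame"))
  })
}

# Adam update in-place over the nested parameter list
.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in seq_along(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      upd(p, g, m, v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = structure(r$p, class = "aten_params"), state = state)
}

.zero_like <- function(p) {
  if (is.list(p)) lapply(p, .zero_like) else p * 0
}

# gradient of (CE + lambda * L1-to-prior) at the logits, for one sample
.loss_grad_logits <- function(probs, label, prior, lambda) {
  y <- rep(0, length(probs)); y[label + 1] <- 1
  d <- probs - y
  if (lambda > 0) {
    s <- sign(probs - prior[label + 1, ])
    d <- d + lambda * (probs * s - probs * sum(probs * s))
  }
  d
}

# accumulate grads: a + b elementwise over nested lists
.acc_grads <- function(a, b) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- .acc_grads(a[[nm]], b[[nm]])
    a
  } else a + b
}
.scale_grads <- function(a, s) {
  if (is.list(a)) lapply(a, .scale_grads, s = s) else a * s
}

#' Train the encoder on a windowed dataset
#'
#' Full optimization loop: featurizes the windows, splits them by the
#' subject-wise plan (asserting that no validation/test subject ever
#' contributes a gradient), augments the training partition only,
#' minimizes cross-entropy plus the constraint regularizer with Adam under
#' the configured learning-rate schedule, and early-stops on validation
#' loss with the configured patience, returning the best-validation
#' parameters. Fully reproducible given `train_cfg$seed`.
#'
#' @param ds A labeled `windowed_dataset`.
#' @param plan A `split_plan` over the dataset's subjects.
#' @param model_cfg An `aten_config`, or `NULL` to build the default small
#'   model for the featurized input dimension.
#' @param train_cfg A `train_config`.
#' @param feat_cfg A `feature_config` (default band-power mode).
#' @param prior Constraint prior matrix (default [constraint_prior()]).
#' @param verbose Print per-epoch progress.
#' @return An `aten_fit`: `params`, `model_cfg`, `feat_cfg`, `history`
#'   (per-epoch data frame), `best_epoch`, `plan`, `train_cfg`.
#' @export
train_model <- function(ds, plan, model_cfg = NULL,
                        train_cfg = train_config(),
                        feat_cfg = feature_config(),
                        prior = constraint_prior(), verbose = FALSE) {
  subj <- dataset_subjects(ds)
  part <- plan$partition[match(subj, plan$subject_id)]
  if (anyNA(part)) stop("split plan does not cover all subjects")
  idx_train <- which(part == "train")
  idx_val <- which(part == "val")
  if (length(idx_train) == 0) stop("empty training partition")

  train_ds <- dataset_subset(ds, idx_train)
  if (!is.null(train_cfg$augment) && train_cfg$augment$ratio_aug_per_orig > 0) {
    aug <- train_cfg$augment
    aug$seed <- train_cfg$seed
    train_ds <- augment_dataset(train_ds, aug)
  }
  # leakage assertion: every window that can contribute a gradient comes
  # from a training subject
  stopifnot(all(dataset_subjects(train_ds) %in%
                  plan$subject_id[plan$partition == "train"]))

  zs_train <- build_features(train_ds, feat_cfg)
  y_train <- dataset_labels(train_ds)
  zs_val <- build_features(dataset_subset(ds, idx_val), feat_cfg)
  y_val <- dataset_labels(ds)[idx_val]

  d_input <- ncol(zs_train[[1]]$data)
  if (is.null(model_cfg)) model_cfg <- aten_config(d_input = d_input)
  if (model_cfg$d_input != d_input)
    stop("shape error: model expects ", model_cfg$d_input,
         " input features, data has ", d_input)

  n <- length(zs_train)
  steps_per_epoch <- ceiling(n / train_cfg$batch_size)
  t_cycle <- if (is.null(train_cfg$t_cycle)) 10 * steps_per_epoch else train_cfg$t_cycle

  params <- aten_init(model_cfg, seed = train_cfg$seed)
  state <- list(t = 0, m = .zero_like(params), v = .zero_like(params))

  eval_loss <- function(zs, y, params) {
    if (length(zs) == 0) return(NA_real_)
    probs <- t(vapply(zs, function(z)
      aten_forward(z, params, model_cfg, mode = "eval")$probs,
      numeric(model_cfg$n_classes)))
    cross_entropy_loss(probs, y) +
      constraint_regularizer(probs, y, prior, train_cfg$lambda_reg)
  }

  history <- data.frame()
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  wait <- 0L; step <- 0L
  for (epoch in seq_len(train_cfg$max_epochs)) {
    set.seed(train_cfg$seed * 7919L + epoch)
    ord <- sample.int(n)
    ep_loss <- 0; ep_n <- 0
    for (b in seq_len(steps_per_epoch)) {
      ids <- ord[((b - 1) * train_cfg$batch_size + 1):min(b * train_cfg$batch_size, n)]
      lr <- if (train_cfg$schedule == "cyclic") {
        cyclic_lr(step, train_cfg$eta_min, train_cfg$eta_max, t_cycle)
      } else {
        step_decay_lr(epoch - 1, train_cfg$eta_max,
                      train_cfg$step_decay_factor, train_cfg$step_decay_period)
      }
      grads <- NULL
      batch_loss <- 0
      for (i in ids) {
        tr <- aten_forward(zs_train[[i]]$data, params, model_cfg,
                           mode = "train",
                           seed = (train_cfg$seed * 104729L + step * 613L + i) %%
                             .Machine$integer.max,
                           keep_cache = TRUE)
        yi <- y_train[i]
        batch_loss <- batch_loss - log(max(tr$probs[yi + 1], 1e-12)) +
          train_cfg$lambda_reg * sum(abs(tr$probs - prior[yi + 1, ]))
        dlog <- .loss_grad_logits(tr$probs, yi, prior, train_cfg$lambda_reg)
        gi <- aten_backward(tr, dlog, params, model_cfg)
        grads <- if (is.null(grads)) gi else .acc_grads(grads, gi)
      }
      grads <- .scale_grads(grads, 1 / length(ids))
      batch_loss <- batch_loss / length(ids)
      if (!is.finite(batch_loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             ", step ", step)
      r <- .adam_step(params, grads, state, lr)
      params <- r$params; state <- r$state
      ep_loss <- ep_loss + batch_loss * length(ids); ep_n <- ep_n + length(ids)
      step <- step + 1L
    }
    val_loss <- eval_loss(zs_val, y_val, params)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / ep_n, val_loss = val_loss,
      lr = if (train_cfg$schedule == "cyclic")
        cyclic_lr(step - 1, train_cfg$eta_min, train_cfg$eta_max, t_cycle)
      else step_decay_lr(epoch - 1, train_cfg$eta_max,
                         train_cfg$step_decay_factor,
                         train_cfg$step_decay_period)))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                      ep_loss / ep_n, val_loss))
    monitor <- if (is.na(val_loss)) ep_loss / ep_n else val_loss
    if (monitor < best_val - train_cfg$min_delta) {
      best_val <- monitor; best_params <- params; best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= train_cfg$patience) break
    }
  }
  structure(list(params = best_params, model_cfg = model_cfg,
                 feat_cfg = feat_cfg, history = history,
                 best_epoch = best_epoch, plan = plan,
                 train_cfg = train_cfg, prior = prior),
            class = "aten_fit")
}

#' @export
print.aten_fit <- function(x, ...) {
  cat(sprintf("<aten_fit> %d epochs run, best validation at epoch %d (loss %.4f)\n",
              nrow(x$history), x$best_epoch,
              min(x$history$val_loss, na.rm = TRUE)))
  invisible(x)
}

#' Predict class probabilities for a windowed dataset
#'
#' Deterministic eval-mode forward pass per window.
#'
#' @param fit An `aten_fit` (or a list with `params`, `model_cfg`,
#'   `feat_cfg`).
#' @param ds A `windowed_dataset`.
#' @return `N x K` probability matrix.
#' @export
predict_proba <- function(fit, ds) {
  zs <- build_features(ds, fit$feat_cfg)
  t(vapply(zs, function(z)
    aten_forward(z, fit$params, fit$model_cfg, mode = "eval")$probs,
    numeric(fit$model_cfg$n_classes)))
}

# rank-statistic (Mann-Whitney) AUC for one positive class, ties averaged
.rank_auc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics report
#'
#' Accuracy (argmax with lowest-index tie-break), macro-averaged recall
#' and F1 over the classes present in the labels, macro one-vs-rest AUC
#' (rank statistic), and the `K x K` confusion matrix (rows = true class,
#' columns = predicted).
#'
#' @param probs `N x K` probability matrix.
#' @param labels Integer class codes 0..K-1.
#' @return A `metrics_report` list: `accuracy`, `recall_macro`,
#'   `f1_macro`, `auc_macro` (`NA` with `auc_defined = FALSE` when labels
#'   hold a single class), `confusion`, `n_classes_present`.
#' @export
evaluate_metrics <- function(probs, labels) {
  probs <- rbind(probs)
  k <- ncol(probs)
  labels <- as.integer(labels)
  pred <- max.col(probs, ties.method = "first") - 1L
  conf <- matrix(0L, k, k,
                 dimnames = list(true = 0:(k - 1), pred = 0:(k - 1)))
  for (i in seq_along(labels)) {
    conf[labels[i] + 1, pred[i] + 1] <- conf[labels[i] + 1, pred[i] + 1] + 1L
  }
  present <- sort(unique(labels))
  rec <- f1 <- auc <- numeric(0)
  for (c_ in present) {
    tp <- sum(pred == c_ & labels == c_)
    fn <- sum(pred != c_ & labels == c_)
    fp <- sum(pred == c_ & labels != c_)
    r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- c(rec, r)
    f1 <- c(f1, if (is.na(r) || p + r == 0) 0 else 2 * p * r / (p + r))
    auc <- c(auc, .rank_auc(probs[, c_ + 1], labels == c_))
  }
  auc_def <- length(present) > 1
  structure(list(accuracy = mean(pred == labels),
                 recall_macro = mean(rec, na.rm = TRUE),
                 f1_macro = mean(f1),
                 auc_macro = if (auc_def) mean(auc, na.rm = TRUE) else NA_real_,
                 auc_defined = auc_def,
                 confusion = conf,
                 n_classes_present = length(present)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro recall %.4f | macro F1 %.4f | macro AUC %s\n",
              x$accuracy, x$recall_macro, x$f1_macro,
              if (x$auc_defined) sprintf("%.4f", x$auc_macro) else "undefined"))
  invisible(x)
}

#' Evaluate a fitted model on one partition of a dataset
#'
#' @param fit An `aten_fit`.
#' @param ds The full `windowed_dataset`.
#' @param partition Which partition of `fit$plan` to evaluate
#'   (default `"test"`).
#' @return A `metrics_report`.
#' @export
evaluate_model <- function(fit, ds, partition = "test") {
  subj <- dataset_subjects(ds)
  keep_subj <- fit$plan$subject_id[fit$plan$partition == partition]
  idx <- which(subj %in% keep_subj)
  if (length(idx) == 0) stop("no windows in partition '", partition, "'")
  sub <- dataset_subset(ds, idx)
  evaluate_metrics(predict_proba(fit, sub), dataset_labels(sub))
}
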