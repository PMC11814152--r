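test_that("cross-entropy matches closed forms", {
  uni <- matrix(0.2, 4, 5)
  expect_equal(cross_entropy_loss(uni, c(0L, 1L, 2L, 3L)), log(5),
               tolerance = 1e-12)
  onehot <- diag(5)
  expect_equal(cross_entropy_loss(onehot, 0:4), 0, tolerance = 1e-9)
  # batch loss is the mean of per-sample losses
  set.seed(50)
  p <- softmax_rows(matrix(rnorm(15), 3, 5))
  y <- c(1L, 4L, 0L)
  per <- vapply(1:3, function(i) cross_entropy_loss(p[i, , drop = FALSE], y[i]),
                numeric(1))
  expect_equal(cross_entropy_loss(p, y), mean(per), tolerance = 1e-12)
})

test_that("constraint regularizer matches the hand-computed L1 deviation", {
  prior2 <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2, byrow = TRUE)
  p <- matrix(c(0.8, 0.2), 1, 2)
  expect_equal(constraint_regularizer(p, 0L, prior2, lambda_reg = 1), 0.4,
               tolerance = 1e-12)
  expect_equal(constraint_regularizer(p, 0L, prior2, lambda_reg = 0), 0)
  # exact match with the prior gives zero
  expect_equal(constraint_regularizer(matrix(c(0.6, 0.4), 1, 2), 0L, prior2,
                                      lambda_reg = 1), 0, tolerance = 1e-12)
  # prior rows are stochastic
  pr <- constraint_prior()
  expect_equal(rowSums(pr), rep(1, 5), tolerance = 1e-8)
  expect_equal(diag(pr), rep(0.9, 5))
})

test_that("cyclic learning rate hits its endpoints, midpoint and period", {
  expect_equal(cyclic_lr(0, 1e-5, 1e-3, 100), 1e-3)
  expect_equal(cyclic_lr(100, 1e-5, 1e-3, 100), 1e-5)
  expect_equal(cyclic_lr(50, 1e-5, 1e-3, 100), (1e-5 + 1e-3) / 2,
               tolerance = 1e-12)
  for (t in c(3, 47, 90)) {
    expect_equal(cyclic_lr(t, 1e-5, 1e-3, 100),
                 cyclic_lr(t + 100, 1e-5, 1e-3, 100), tolerance = 1e-15)
  }
  expect_error(cyclic_lr(5, t_cycle = 0), "parameter error")
})

test_that("step decay divides the rate by 10 every 10 epochs", {
  expect_equal(step_decay_lr(0, 0.001), 0.001)
  expect_equal(step_decay_lr(10, 0.001), 1e-4)
  expect_equal(step_decay_lr(25, 0.001), 1e-5)
})

test_that("subject split respects fractions and never spans partitions", {
  ids <- sprintf("s%03d", 1:100)
  plan <- subject_split(ids, seed = 1)
  expect_equal(sum(plan$partition == "train"), 70)
  expect_equal(sum(plan$partition == "val"), 15)
  expect_equal(sum(plan$partition == "test"), 15)
  expect_equal(anyDuplicated(plan$subject_id), 0)
  # determinism
  expect_identical(subject_split(ids, seed = 1), plan)
  expect_false(identical(subject_split(ids, seed = 2)$partition,
                         plan$partition))
  expect_error(subject_split(c("a", "b")), "at least 3")
})

test_that("no subject appears in two partitions across 1000 random cohorts", {
  set.seed(60)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    ids <- paste0("s", seq_len(n))
    dom <- sample(state_levels(), n, replace = TRUE)
    plan <- subject_split(data.frame(subject_id = ids, dominant_class = dom),
                          seed = i)
    expect_equal(sort(plan$subject_id), sort(ids))
    expect_equal(anyDuplicated(plan$subject_id), 0)
    expect_equal(nrow(plan), n)
  }
})

test_that("k-fold subject CV partitions subjects exactly once into test folds", {
  ids <- paste0("s", 1:20)
  folds <- kfold_subject_cv(ids, k = 10, seed = 3)
  expect_length(folds, 10)
  test_sets <- lapply(folds, function(p) p$subject_id[p$partition == "test"])
  expect_true(all(lengths(test_sets) == 2))
  all_test <- sort(unlist(test_sets))
  expect_equal(all_test, sort(ids))               # union = all, disjoint
  # each fold has train and val subjects too
  for (p in folds) expect_true(all(c("train", "val") %in% p$partition))
  # determinism
  expect_identical(kfold_subject_cv(ids, k = 10, seed = 3), folds)
  expect_error(kfold_subject_cv(ids[1:5], k = 10), "more folds")
})

test_that("metrics match hand-computed values and Monte-Carlo AUC", {
  # perfect predictions
  p <- diag(5)[c(1, 2, 3, 4, 5), ]
  m <- evaluate_metrics(p, 0:4)
  expect_equal(m$accuracy, 1)
  expect_equal(m$recall_macro, 1)
  expect_equal(m$f1_macro, 1)
  expect_equal(m$auc_macro, 1)
  expect_equal(sum(m$confusion), 5)
  # binary confusion TP=40 FN=10 FP=20 TN=30 for the positive class (0)
  y <- c(rep(0L, 50), rep(1L, 50))
  pred <- c(rep(0L, 40), rep(1L, 10), rep(0L, 20), rep(1L, 30))
  probs <- cbind(1 - pred, pred)           # argmax reproduces pred
  m2 <- evaluate_metrics(probs, y)
  expect_equal(m2$confusion[1, 1], 40L)
  expect_equal(m2$confusion[1, 2], 10L)
  expect_equal(m2$confusion[2, 1], 20L)
  rec_pos <- 40 / 50
  f1_pos <- 2 * (2 / 3) * rec_pos / (2 / 3 + rec_pos)
  expect_equal(f1_pos, 8 / 11, tolerance = 1e-12)
  # macro values include both classes; class-0 row matches hand values
  expect_equal(m2$accuracy, 0.7)
  # random scores on balanced binary labels give AUC ~ 0.5
  set.seed(61)
  n <- 10000
  yb <- rep(c(0L, 1L), each = n / 2)
  sc <- runif(n)
  m3 <- evaluate_metrics(cbind(1 - sc, sc), yb)
  expect_gt(m3$auc_macro, 0.48)
  expect_lt(m3$auc_macro, 0.52)
  # single-class labels: AUC undefined and flagged
  m4 <- evaluate_metrics(matrix(0.2, 3, 5), c(1L, 1L, 1L))
  expect_false(m4$auc_defined)
  expect_true(is.na(m4$auc_macro))
})

test_that("rank AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(62)
  y <- rbinom(200, 1, 0.4)
  sc <- runif(200) + 0.3 * y
  ours <- evaluate_metrics(cbind(1 - sc, sc), y)$auc_macro
  ref_pos <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE)))
  ref_neg <- as.numeric(pROC::auc(pROC::roc(1 - y, 1 - sc, quiet = TRUE)))
  expect_equal(ours, (ref_pos + ref_neg) / 2, tolerance = 1e-10)
})

test_that("argmax ties break toward the lowest class index", {
  m <- evaluate_metrics(matrix(0.2, 2, 5), c(0L, 3L))
  expect_equal(m$confusion[1, 1], 1L)    # predicted HCL
  expect_equal(m$confusion[4, 1], 1L)    # true A predicted HCL
})

test_that("training reduces the loss, early-stops, and is seed-reproducible", {
  suppressMessages({
    coh <- small_cohort(n_subjects = 6, n_channels = 4)
    ds <- preprocess_cohort(coh)
    plan <- subject_split(subject_table(ds), seed = 2)
    tc <- train_config(seed = 5, max_epochs = 12, batch_size = 16)
    fit1 <- train_model(ds, plan, train_cfg = tc)
    expect_lt(fit1$history$train_loss[5], fit1$history$train_loss[1])
    expect_lte(nrow(fit1$history), 12)
    # identical seed reproduces the run bit-for-bit
    fit2 <- train_model(ds, plan, train_cfg = tc)
    expect_equal(fit1$history$val_loss, fit2$history$val_loss,
                 tolerance = 1e-6)
    expect_identical(fit1$params$W_in, fit2$params$W_in)
    # early stopping on a plateau: with a tiny learning rate the validation
    # loss cannot improve by min_delta, so patience 2 halts immediately
    tc2 <- train_config(seed = 5, max_epochs = 50, batch_size = 16,
                        patience = 2, eta_max = 1e-8, eta_min = 1e-8,
                        min_delta = 0.01)
    fit3 <- train_model(ds, plan, train_cfg = tc2)
    expect_lte(nrow(fit3$history), 4)
  })
})

test_that("lambda = 0 recovers pure cross-entropy training bit-for-bit", {
  suppressMessages({
    coh <- small_cohort(n_subjects = 4, n_channels = 3)
    ds <- preprocess_cohort(coh)
    plan <- subject_split(subject_table(ds), seed = 3)
    tc0 <- train_config(seed = 9, max_epochs = 3, batch_size = 8,
                        lambda_reg = 0)
    fit_a <- train_model(ds, plan, train_cfg = tc0)
    fit_b <- train_model(ds, plan, train_cfg = tc0,
                         prior = constraint_prior(confidence = 0.5))
    # with lambda 0 the prior is inert: identical parameters
    expect_identical(fit_a$params$Wo, fit_b$params$Wo)
    tc1 <- train_config(seed = 9, max_epochs = 3, batch_size = 8,
                        lambda_reg = 0.5)
    fit_c <- train_model(ds, plan, train_cfg = tc1)
    expect_false(identical(fit_a$params$Wo, fit_c$params$Wo))
  })
})

test_that("no validation/test subject contributes training windows", {
  suppressMessages({
    coh <- small_cohort(n_subjects = 5, n_channels = 3)
    ds <- preprocess_cohort(coh)
    plan <- subject_split(subject_table(ds), seed = 4)
    # corrupt the plan so a training window belongs to a test subject:
    # the leakage assertion must fire
    bad_plan <- plan
    bad_plan$subject_id[bad_plan$partition == "train"][1] <- "ghost"
    expect_error(train_model(ds, bad_plan,
                             train_cfg = train_config(seed = 1,
                                                      max_epochs = 1)),
                 "cover")
  })
})
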