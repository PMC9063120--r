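# Staged MLP specifications, teacher/student training, pseudo-labeling and
# balancing. Heavy end-to-end runs live in the acceptance suite; here the
# networks are kept tiny (short feature vectors) so each fit takes seconds.

make_toy_problem <- function(n = 200L, d = 16L, seed = 3L) {
  # two linearly separable combination classes (0 and 16 = first target on)
  set.seed(seed)
  X <- matrix(rbinom(n * d, 1, 0.3), n)
  active <- X[, 1L] == 1L
  labels <- cbind(as.integer(active), matrix(0L, n, 4))
  list(X = X, labels = labels,
       Y = class_onehot(encode_label_matrix(labels), 32))
}

toy_config <- function(...) {
  defaults <- list(epochs = 40L, batch_size = 32L, patience = 40L,
                   val_fraction = 0.1)
  do.call(plans_config, utils::modifyList(defaults, list(...)))
}

test_that("MLP width plans follow the printed tier definitions", {
  small <- build_mlp_spec("small", 2048, 32)
  expect_identical(small$hidden_widths,
                   c(4096L, 8192L, 8192L, 4096L, 2048L, 1024L, 512L))
  medium <- build_mlp_spec("medium", 2048, 32)
  expect_length(medium$hidden_widths, 9L)
  expect_identical(sum(medium$hidden_widths == 6144L), 2L)
  expect_identical(medium$hidden_widths[c(2L, 5L)], c(6144L, 6144L))
  large <- build_mlp_spec("large", 300, 32)
  expect_length(large$hidden_widths, 11L)
  expect_identical(sum(large$hidden_widths == 1800L), 2L)
  expect_identical(large$hidden_widths[4:5], c(1800L, 1800L))
  expect_equal(small$dropout_rate, 0.3)
  expect_error(build_mlp_spec("huge", 2048, 32), "unknown tier")
  expect_error(build_mlp_spec("small", 2, 32), "input_len")
})

test_that("parameter counts strictly increase Small < Medium < Large", {
  for (L in c(4L, 16L, 300L, 512L, 2048L)) {
    n_small <- mlp_spec_n_params(build_mlp_spec("small", L, 32))
    n_medium <- mlp_spec_n_params(build_mlp_spec("medium", L, 32))
    n_large <- mlp_spec_n_params(build_mlp_spec("large", L, 32))
    expect_lt(n_small, n_medium)
    expect_lt(n_medium, n_large)
  }
})

test_that("a Small teacher fits a linearly separable toy problem", {
  toy <- make_toy_problem()
  spec <- build_mlp_spec("small", ncol(toy$X), 32)
  cfg <- toy_config()
  teacher <- expect_silent(train_teacher(toy$X, toy$Y, spec, cfg))
  expect_identical(attr(teacher, "role"), "teacher")
  expect_equal(teacher$dropout_rate, 0)  # teachers are noise-free
  pred <- predict_plans(teacher, toy$X, 5, "onehot")
  expect_gte(mean(pred$class == encode_label_matrix(toy$labels)), 0.95)

  # cross-entropy of a perfect prediction is zero
  expect_equal(nn_loss(toy$Y, toy$Y, "softmax"), 0, tolerance = 1e-9)

  # fixed seed reproduces the fit
  t2 <- train_teacher(toy$X, toy$Y, spec, cfg)
  expect_equal(teacher$best_val_loss, t2$best_val_loss, tolerance = 1e-10)

  # single-class degeneracy warns but trains
  expect_warning(
    train_teacher(toy$X[1:20, ], toy$Y[rep(1L, 20), ], spec,
                  toy_config(epochs = 2)),
    "degenerate"
  )
})

test_that("students carry dropout and mixup noise; inference is deterministic", {
  toy <- make_toy_problem()
  spec <- build_mlp_spec("small", ncol(toy$X), 32)
  cfg <- toy_config(mixup = mixup_config(alpha = 0.4, enabled = TRUE))
  student <- train_student(toy$X, toy$Y, spec, cfg, seed = 2)
  expect_identical(attr(student, "role"), "student")
  expect_equal(student$dropout_rate, 0.3)
  p1 <- nn_predict_probs(student, toy$X[1:5, , drop = FALSE])
  p2 <- nn_predict_probs(student, toy$X[1:5, , drop = FALSE])
  expect_identical(p1, p2)
})

test_that("pseudo-labels complete partials and normalize unlabeled rows", {
  toy <- make_toy_problem()
  spec <- build_mlp_spec("small", ncol(toy$X), 32)
  teacher <- train_teacher(toy$X, toy$Y, spec, toy_config(epochs = 10))

  partials <- rbind(
    c(0, 1, NA, 0, 0),
    c(0, 1, 1, 0, 1),   # no missing entries
    c(NA, NA, NA, NA, NA)
  )
  bundle <- plans_bundle(
    features_full = toy$X, labels_full = toy$labels,
    features_partial = toy$X[1:3, ], labels_partial = partials,
    features_unlabeled = toy$X[4:6, ]
  )
  pl <- pseudo_label(teacher, bundle, "onehot")
  expect_identical(dim(pl$partial), c(3L, 32L))
  # support restricted to the candidate classes
  expect_true(all((which(pl$partial[1, ] > 0) - 1L) %in% c(8L, 12L)))
  # fully observed partial -> hard one-hot at class 13, teacher ignored
  expect_equal(pl$partial[2, 13 + 1L], 1)
  expect_equal(rowSums(pl$partial), rep(1, 3))
  expect_equal(rowSums(pl$unlabeled), rep(1, 3), tolerance = 1e-9)
})

test_that("balancing caps every class at the all-negative count", {
  d <- 4L
  mk <- function(classes) {
    list(X = matrix(runif(length(classes) * d), ncol = d),
         Y = class_onehot(classes, 32))
  }
  base <- mk(c(rep(0L, 100), rep(5L, 10)))
  pool <- mk(rep(5L, 500))
  out <- balance_training_set(base$X, base$Y, pool$X, pool$Y)
  counts <- tabulate(max.col(out$Y), nbins = 32)
  expect_identical(counts[6L], 100L)   # class 5 filled to the cap
  expect_identical(out$added[6L], 90L)

  # all-negative pool rows are never added
  pool0 <- mk(rep(0L, 50))
  out0 <- balance_training_set(base$X, base$Y, pool0$X, pool0$Y)
  expect_identical(nrow(out0$X), nrow(base$X))

  # class already at cap stays unchanged
  full <- mk(c(rep(0L, 20), rep(3L, 20)))
  pool3 <- mk(rep(3L, 500))
  out2 <- balance_training_set(full$X, full$Y, pool3$X, pool3$Y)
  expect_identical(sum(out2$added), 0L)
  expect_identical(nrow(balance_training_set(base$X, base$Y,
                                             NULL, NULL)$X),
                   nrow(base$X))
})

test_that("balancing invariants hold over random pseudo-labeled pools", {
  d <- 4L
  for (s in 1:20) {
    set.seed(s)
    base_cls <- sample(0:7, 60, replace = TRUE,
                       prob = c(0.5, rep(0.5 / 7, 7)))
    base <- list(X = matrix(runif(60 * d), ncol = d),
                 Y = class_onehot(base_cls, 32))
    pool_soft <- matrix(rexp(80 * 32), 80)
    pool_soft <- pool_soft / rowSums(pool_soft)
    pool_X <- matrix(runif(80 * d), ncol = d)
    out <- balance_training_set(base$X, base$Y, pool_X, pool_soft)

    counts <- tabulate(max.col(out$Y, ties.method = "first"), nbins = 32)
    cap <- sum(base_cls == 0L)
    # no class is raised above the all-negative count
    added_cls <- max.col(out$Y[-seq_len(60), , drop = FALSE],
                         ties.method = "first")
    expect_true(all(added_cls != 1L))
    base_counts <- tabulate(max.col(base$Y, ties.method = "first"),
                            nbins = 32)
    grown <- which(counts > base_counts)
    expect_true(all(counts[grown] <= cap))
    # original rows are an intact prefix of the balanced set
    expect_identical(out$X[seq_len(60), ], base$X)
    expect_identical(out$Y[seq_len(60), ], base$Y)
  }
})

test_that("run_plans degenerates to staged supervised training without pools", {
  toy <- make_toy_problem(n = 150)
  bundle <- plans_bundle(toy$X, toy$labels)
  cfg <- toy_config(epochs = 10, mixup = mixup_config(enabled = FALSE),
                    seed = 7)
  res <- run_plans(bundle, cfg)
  expect_s3_class(res, "gp_plans_result")
  expect_named(res$history, c("small", "medium", "large"))
  expect_identical(attr(res$model, "spec")$tier, "large")
  # test split untouched: train/test partition the fully labeled pool
  expect_identical(sort(c(res$train_idx, res$test_idx)), 1:150)
  expect_length(res$test_idx, 45L)
  r <- res$history$large
  expect_s3_class(r, "gp_metrics")
  expect_true(r$accuracy >= 0 && r$accuracy <= 1)
  expect_error(run_plans(plans_bundle(toy$X[0, , drop = FALSE],
                                      toy$labels[0, , drop = FALSE]),
                         cfg),
               "empty fully labeled")
})

test_that("predictions decode argmax classes to label vectors", {
  toy <- make_toy_problem(n = 80)
  spec <- build_mlp_spec("small", ncol(toy$X), 32)
  teacher <- train_teacher(toy$X, toy$Y, spec, toy_config(epochs = 5))
  pred <- predict_plans(teacher, toy$X[1:10, ], 5, "onehot")
  expect_equal(rowSums(pred$probs), rep(1, 10), tolerance = 1e-9)
  for (i in 1:10) {
    expect_identical(pred$labels[i, ], decode_class(pred$class[i], 5))
  }
  # class 13 decodes to the printed example
  fake <- class_onehot(13L, 32)
  expect_identical(decode_class_matrix(max.col(fake) - 1L, 5)[1, ],
                   c(0L, 1L, 1L, 0L, 1L))
  expect_error(predict_plans(teacher, toy$X[, 1:4], 5, "onehot"),
               "does not match")
})

test_that("per-target scores aggregate the class probabilities consistently", {
  probs <- matrix(0, 2, 32)
  probs[1, 13 + 1L] <- 1            # [0,1,1,0,1]
  probs[2, 8 + 1L] <- 0.5           # [0,1,0,0,0]
  probs[2, 12 + 1L] <- 0.5          # [0,1,1,0,0]
  s <- target_scores_from_class_probs(probs, 5)
  expect_equal(s[1, ], c(0, 1, 1, 0, 1))
  expect_equal(s[2, ], c(0, 1, 0.5, 0, 0))
})

test_that("the Small teacher recovers the planted rule on clean complete labels", {
  # noise-free, fully labeled synthetic panel: the substructure rule is
  # learnable, so held-out micro-F1 must clear 0.9
  ds <- simulate_dataset(synthetic_config(1600, label_noise = 0,
                                          missing_rate = 0,
                                          unlabeled_fraction = 0, seed = 2))
  X <- ecfp_matrix(ds$fully_labeled$smiles, radius = 2, n_bits = 512,
                   quiet = TRUE)
  labels <- ds$fully_labeled$labels
  cfg <- plans_config(epochs = 60, batch_size = 64, patience = 10,
                      seed = 5, mixup = mixup_config(enabled = FALSE))
  set_seed_scrambled(12)
  n <- nrow(X)
  tr <- sample.int(n, round(0.7 * n))
  te <- setdiff(seq_len(n), tr)
  Y <- class_onehot(encode_label_matrix(labels[tr, ]), 32)
  teacher <- train_teacher(X[tr, ], Y, build_mlp_spec("small", 512, 32),
                           cfg)
  pred <- predict_plans(teacher, X[te, ], 5, "onehot")
  r <- score(pred$labels, labels[te, ], pred$target_scores)
  expect_gte(r$micro_f1, 0.9)
})

test_that("multi-label mode trains sigmoid heads end to end", {
  toy <- make_toy_problem(n = 120)
  bundle <- plans_bundle(toy$X, toy$labels)
  cfg <- toy_config(epochs = 8, mode = "multilabel",
                    mixup = mixup_config(enabled = FALSE), seed = 2)
  res <- run_plans(bundle, cfg)
  pred <- predict_plans(res, toy$X[1:5, ])
  expect_identical(dim(pred$labels), c(5L, 5L))
  expect_true(all(pred$probs >= 0 & pred$probs <= 1))
  expect_error(plans_config(mode = "multilabel", balancing = TRUE),
               "one-hot")
})
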