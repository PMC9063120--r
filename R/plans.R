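# The PLANS loop: staged multilayer perceptrons (Small/Medium/Large), an
# initial teacher trained on fully labeled data only, pseudo-labeling of
# partially labeled and unlabeled pools, optional class balancing against
# the all-negative class, and noisy (dropout + mixup) student training.

#' Staged MLP architecture specification
#'
#' Hidden-layer width plans, as multiples of the input length L:
#' * Small: seven hidden layers of 2L, 4L, 4L, 2L, L, L/2, L/4 units;
#' * Medium: Small with a 3L layer inserted after hidden layer 1 and after
#'   hidden layer 3;
#' * Large: Medium with two 6L layers inserted after hidden layer 2 of the
#'   Small plan.
#' All tiers place one dropout stage before the final output layer;
#' trainable-parameter counts strictly increase Small < Medium < Large.
#'
#' @param tier `"small"`, `"medium"` or `"large"` (case-insensitive).
#' @param input_len Feature vector length L (>= 4).
#' @param output_dim Number of output units (e.g. `2^n_targets` combination
#'   classes, or `n_targets` in multi-label mode).
#' @param dropout_rate Drop probability of the dropout stage (default 0.3).
#' @return A `gp_mlp_spec` list with the resolved `hidden_widths`.
#' @examples
#' build_mlp_spec("small", 2048, 32)$hidden_widths
#' # 4096 8192 8192 4096 2048 1024 512
#' @export
build_mlp_spec <- function(tier, input_len, output_dim,
                           dropout_rate = 0.3) {
  tier <- tolower(as.character(tier))
  if (!tier %in% c("small", "medium", "large")) {
    stop("unknown tier: ", tier, " (expected small, medium or large)")
  }
  stopifnot(input_len >= 4L, output_dim >= 1L,
            dropout_rate >= 0, dropout_rate < 1)
  mults <- switch(tier,
    small  = c(2, 4, 4, 2, 1, 0.5, 0.25),
    medium = c(2, 3, 4, 4, 3, 2, 1, 0.5, 0.25),
    large  = c(2, 3, 4, 6, 6, 4, 3, 2, 1, 0.5, 0.25)
  )
  structure(
    list(tier = tier,
         input_len = as.integer(input_len),
         hidden_widths = as.integer(floor(mults * input_len)),
         dropout_rate = dropout_rate,
         output_dim = as.integer(output_dim)),
    class = "gp_mlp_spec"
  )
}

#' Trainable-parameter count of an MLP specification
#'
#' @param spec A `gp_mlp_spec`.
#' @return Total number of weights and biases.
#' @export
mlp_spec_n_params <- function(spec) {
  stopifnot(inherits(spec, "gp_mlp_spec"))
  nn_n_params(c(spec$input_len, spec$hidden_widths, spec$output_dim))
}

#' PLANS training configuration
#'
#' @param split_ratio Fraction of the fully labeled pool used for training
#'   (the rest is the held-out test split); default 0.7.
#' @param mixup A [mixup_config()]; mixup noise is applied to student
#'   training only. Use `mixup_config(enabled = FALSE)` to switch it off.
#' @param balancing Balance each student's training set against the
#'   all-negative class using pseudo-labeled unlabeled data (one-hot mode
#'   only).
#' @param use_unlabeled Include pseudo-labeled unlabeled rows in student
#'   training when balancing is off. With balancing on, unlabeled rows
#'   enter only through the balancing rule.
#' @param dropout_rate Student dropout probability (default 0.3; a keep
#'   probability of 0.7).
#' @param epochs,batch_size,learning_rate,weight_decay,patience,val_fraction
#'   Optimizer settings shared by all stages (Adam with decoupled weight
#'   decay; early stopping on a held-out validation fraction of the
#'   training rows).
#' @param extra_rounds Additional Large-tier student rounds after the
#'   Small-Medium-Large schedule; each repeats pseudo-labeling with the
#'   latest teacher and stops early once the validation loss stops
#'   improving (patience 1).
#' @param mode `"onehot"` for softmax over the `2^n` combination classes or
#'   `"multilabel"` for independent per-target sigmoids.
#' @param seed Seed governing the split, initialization and noise.
#' @return A `gp_plans_config` list.
#' @export
plans_config <- function(split_ratio = 0.7, mixup = mixup_config(),
                         balancing = FALSE, use_unlabeled = TRUE,
                         dropout_rate = 0.3, epochs = 60L, batch_size = 32L,
                         learning_rate = 1e-3, weight_decay = 1e-4,
                         patience = 5L,
                         val_fraction = 0.1, extra_rounds = 0L,
                         mode = c("onehot", "multilabel"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(split_ratio > 0, split_ratio < 1,
            inherits(mixup, "gp_mixup_config"))
  if (balancing && mode == "multilabel") {
    stop("class balancing is defined for one-hot combination mode only")
  }
  structure(
    list(split_ratio = split_ratio, mixup = mixup, balancing = balancing,
         use_unlabeled = use_unlabeled, dropout_rate = dropout_rate,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, weight_decay = weight_decay,
         patience = as.integer(patience),
         val_fraction = val_fraction, extra_rounds = as.integer(extra_rounds),
         mode = mode, seed = as.integer(seed)),
    class = "gp_plans_config"
  )
}

#' Assemble a dataset bundle for PLANS
#'
#' @param features_full Feature matrix of the fully labeled pool.
#' @param labels_full Binary label matrix (no missing entries), one row per
#'   fully labeled molecule.
#' @param features_partial Feature matrix of the partially labeled pool
#'   (may have 0 rows).
#' @param labels_partial Label matrix over {0, 1, NA}, same row count.
#' @param features_unlabeled Feature matrix of the unlabeled pool (may have
#'   0 rows).
#' @param feature_kind Label for reporting, e.g. `"ECFP"` or `"GINFP"`.
#' @return A `gp_bundle` list.
#' @export
plans_bundle <- function(features_full, labels_full,
                         features_partial = NULL, labels_partial = NULL,
                         features_unlabeled = NULL,
                         feature_kind = "ECFP") {
  d <- ncol(features_full)
  features_partial <- features_partial %||% matrix(numeric(0), ncol = d)
  features_unlabeled <- features_unlabeled %||% matrix(numeric(0), ncol = d)
  labels_partial <- labels_partial %||%
    matrix(numeric(0), ncol = ncol(labels_full))
  stopifnot(nrow(features_full) == nrow(labels_full),
            nrow(features_partial) == nrow(labels_partial),
            ncol(features_partial) == d, ncol(features_unlabeled) == d)
  if (anyNA(labels_full)) stop("fully labeled pool has missing entries")
  structure(
    list(features_full = as.matrix(features_full),
         labels_full = as.matrix(labels_full),
         features_partial = as.matrix(features_partial),
         labels_partial = as.matrix(labels_partial),
         features_unlabeled = as.matrix(features_unlabeled),
         n_targets = ncol(labels_full),
         feature_kind = feature_kind),
    class = "gp_bundle"
  )
}

# Resolve per-mode training targets for the fully labeled rows.
full_label_targets <- function(labels, mode) {
  if (mode == "onehot") {
    class_onehot(encode_label_matrix(labels), 2^ncol(labels))
  } else {
    as.matrix(labels)
  }
}

#' Train a teacher model
#'
#' Fits an MLP of the given specification to fully labeled training rows by
#' cross-entropy, with early stopping once the validation loss is stable.
#' Teachers are trained without noise: no dropout and no mixup (noise is
#' reserved for student training).
#'
#' @param X Feature matrix.
#' @param Y Target matrix: one-hot/soft class rows (softmax mode) or binary
#'   target rows (multi-label mode).
#' @param spec A [build_mlp_spec()] result.
#' @param config A [plans_config()].
#' @param seed Optional override of `config$seed`.
#' @return A `gp_mlp` with attribute `role = "teacher"`.
#' @export
train_teacher <- function(X, Y, spec, config = plans_config(), seed = NULL) {
  stopifnot(inherits(spec, "gp_mlp_spec"))
  if (nrow(X) == 0L) stop("cannot train a teacher on an empty training set")
  if (nrow(unique(Y)) == 1L) {
    warning("degenerate training set: every row has the same class")
  }
  model <- nn_fit(
    X, Y, hidden = spec$hidden_widths,
    output_type = if (config$mode == "onehot") "softmax" else "sigmoid",
    dropout_rate = 0, epochs = config$epochs,
    batch_size = config$batch_size, lr = config$learning_rate,
    weight_decay = config$weight_decay,
    val_fraction = config$val_fraction, patience = config$patience,
    mixup = NULL, seed = seed %||% config$seed
  )
  attr(model, "role") <- "teacher"
  attr(model, "spec") <- spec
  model
}

train_student <- function(X, Y, spec, config, seed) {
  model <- nn_fit(
    X, Y, hidden = spec$hidden_widths,
    output_type = if (config$mode == "onehot") "softmax" else "sigmoid",
    dropout_rate = config$dropout_rate, epochs = config$epochs,
    batch_size = config$batch_size, lr = config$learning_rate,
    weight_decay = config$weight_decay,
    val_fraction = config$val_fraction, patience = config$patience,
    mixup = if (isTRUE(config$mixup$enabled)) config$mixup else NULL,
    seed = seed
  )
  attr(model, "role") <- "student"
  attr(model, "spec") <- spec
  model
}

#' Generate pseudo-labels with a teacher model
#'
#' Runs the teacher (noise-free inference) over the partially labeled and
#' unlabeled pools. Partial rows are completed by restricting the teacher's
#' class distribution to the candidate classes of the partial label
#' ([complete_partial_label()]); unlabeled rows receive the teacher's full
#' soft distribution. In multi-label mode missing targets are filled with
#' the teacher's per-target probabilities.
#'
#' @param teacher A trained `gp_mlp`.
#' @param bundle A [plans_bundle()].
#' @param mode `"onehot"` or `"multilabel"`.
#' @return List with matrices `partial` (soft labels for the partial pool)
#'   and `unlabeled` (soft labels for the unlabeled pool); either may have
#'   0 rows.
#' @export
pseudo_label <- function(teacher, bundle, mode = c("onehot", "multilabel")) {
  mode <- match.arg(mode)
  stopifnot(inherits(bundle, "gp_bundle"))
  n_out <- if (mode == "onehot") 2^bundle$n_targets else bundle$n_targets

  part <- if (nrow(bundle$features_partial)) {
    probs <- nn_predict_probs(teacher, bundle$features_partial)
    t(vapply(seq_len(nrow(probs)), function(i) {
      if (mode == "onehot") {
        complete_partial_label(bundle$labels_partial[i, ], probs[i, ])
      } else {
        complete_partial_multilabel(bundle$labels_partial[i, ], probs[i, ])
      }
    }, numeric(n_out)))
  } else {
    matrix(numeric(0), ncol = n_out)
  }

  unlab <- if (nrow(bundle$features_unlabeled)) {
    nn_predict_probs(teacher, bundle$features_unlabeled)
  } else {
    matrix(numeric(0), ncol = n_out)
  }
  list(partial = part, unlabeled = unlab)
}

#' Balance a training set against the all-negative class
#'
#' Implements the pseudo-label balancing rule: a pooled (pseudo-labeled)
#' row is added to the training set only if its predicted class (argmax of
#' its soft label) is not the all-negative class 0 and that class currently
#' has fewer rows than the all-negative class. Original training rows are
#' never removed; per-class counts never exceed the all-negative count.
#'
#' @param X,Y Current training rows (features and soft/one-hot labels over
#'   the `2^n` classes).
#' @param X_pool,Y_pool Candidate pseudo-labeled rows.
#' @return List with the augmented `X`, `Y`, and `added` (per-class counts
#'   of pool rows taken).
#' @export
balance_training_set <- function(X, Y, X_pool, Y_pool) {
  n_classes <- ncol(Y)
  added <- integer(n_classes)
  if (is.null(X_pool) || nrow(X_pool) == 0L) {
    return(list(X = X, Y = Y, added = added))
  }
  stopifnot(ncol(Y_pool) == n_classes, ncol(X_pool) == ncol(X))
  cls <- max.col(Y, ties.method = "first")           # 1-based class + 1
  counts <- tabulate(cls, nbins = n_classes)
  cap <- counts[1L]                                   # all-negative count
  pool_cls <- max.col(Y_pool, ties.method = "first")
  take <- logical(nrow(X_pool))
  for (r in seq_len(nrow(X_pool))) {
    k <- pool_cls[r]
    if (k == 1L) next                                 # never add all-negative
    if (counts[k] < cap) {
      take[r] <- TRUE
      counts[k] <- counts[k] + 1L
      added[k] <- added[k] + 1L
    }
  }
  list(X = rbind(X, X_pool[take, , drop = FALSE]),
       Y = rbind(Y, Y_pool[take, , drop = FALSE]),
       added = added)
}

#' Run the PLANS self-training loop
#'
#' Workflow: split the fully labeled pool into training and test sets
#' (`split_ratio`); train the Small model on the fully labeled training
#' rows as the initial teacher; then for each student tier (Medium, then
#' Large, then any extra Large rounds) regenerate pseudo-labels for the
#' partially labeled and unlabeled pools with the current teacher, rebuild
#' the balanced training set from scratch if balancing is enabled, train
#' the student with dropout and mixup noise, and promote it to teacher.
#' The test split is never touched during training; the final (Large)
#' student is evaluated on it once at the end of every stage so the metric
#' history can be inspected.
#'
#' @param bundle A [plans_bundle()].
#' @param config A [plans_config()].
#' @return A `gp_plans_result` with the final model, per-stage `history`
#'   (a list of [score()] reports), the test-split indices and the config.
#' @export
run_plans <- function(bundle, config = plans_config()) {
  stopifnot(inherits(bundle, "gp_bundle"),
            inherits(config, "gp_plans_config"))
  if (nrow(bundle$features_full) == 0L) {
    stop("bundle has an empty fully labeled pool")
  }
  set_seed_scrambled(config$seed)
  n <- nrow(bundle$features_full)
  n_train <- max(1L, round(config$split_ratio * n))
  train_idx <- sample.int(n, n_train)
  test_idx <- setdiff(seq_len(n), train_idx)

  X_tr <- bundle$features_full[train_idx, , drop = FALSE]
  Y_tr <- full_label_targets(
    bundle$labels_full[train_idx, , drop = FALSE], config$mode)
  X_te <- bundle$features_full[test_idx, , drop = FALSE]
  truth_te <- bundle$labels_full[test_idx, , drop = FALSE]

  out_dim <- ncol(Y_tr)
  evaluate <- function(model) {
    if (nrow(X_te) == 0L) return(NULL)
    pred <- predict_plans(model, X_te, n_targets = bundle$n_targets,
                          mode = config$mode)
    score(pred$labels, truth_te, scores = pred$target_scores)
  }

  spec_small <- build_mlp_spec("small", ncol(X_tr), out_dim,
                               config$dropout_rate)
  teacher <- train_teacher(X_tr, Y_tr, spec_small, config,
                           seed = config$seed)
  history <- list(small = evaluate(teacher))

  stages <- c("medium", "large", rep("large", config$extra_rounds))
  prev_val <- teacher$best_val_loss
  for (si in seq_along(stages)) {
    tier <- stages[si]
    spec <- build_mlp_spec(tier, ncol(X_tr), out_dim, config$dropout_rate)
    pl <- pseudo_label(teacher, bundle, config$mode)

    X_stage <- rbind(X_tr, bundle$features_partial)
    Y_stage <- rbind(Y_tr, pl$partial)
    if (config$balancing) {
      bal <- balance_training_set(X_stage, Y_stage,
                                  bundle$features_unlabeled, pl$unlabeled)
      X_stage <- bal$X
      Y_stage <- bal$Y
    } else if (config$use_unlabeled) {
      X_stage <- rbind(X_stage, bundle$features_unlabeled)
      Y_stage <- rbind(Y_stage, pl$unlabeled)
    }

    student <- train_student(X_stage, Y_stage, spec, config,
                             seed = config$seed + si)
    nm <- if (si <= 2L) tier else paste0("large_round", si - 1L)
    history[[nm]] <- evaluate(student)

    if (si > 2L && student$best_val_loss >= prev_val - 1e-6) {
      # extra Large rounds stop as soon as they no longer improve
      teacher <- student
      break
    }
    prev_val <- student$best_val_loss
    teacher <- student
  }

  structure(
    list(model = teacher, history = history, train_idx = train_idx,
         test_idx = test_idx, config = config, n_targets = bundle$n_targets,
         feature_kind = bundle$feature_kind),
    class = "gp_plans_result"
  )
}

#' Predict with a trained PLANS model
#'
#' Noise-free inference: soft class distribution per row, hard class by
#' argmax (lowest index wins ties), and the decoded per-target binary
#' matrix. Per-target soft scores are obtained by summing the class
#' probabilities of all classes in which the target is active (one-hot
#' mode) or taken directly from the sigmoid outputs (multi-label mode).
#'
#' @param model A `gp_mlp` (teacher/student) from the PLANS loop, or a
#'   `gp_plans_result`.
#' @param X Feature matrix with the model's input length.
#' @param n_targets Number of binary targets.
#' @param mode `"onehot"` or `"multilabel"`.
#' @return List with `probs`, `class` (0-based, one-hot mode only),
#'   `labels` (binary matrix) and `target_scores`.
#' @export
predict_plans <- function(model, X, n_targets,
                          mode = c("onehot", "multilabel")) {
  mode <- match.arg(mode)
  if (inherits(model, "gp_plans_result")) {
    n_targets <- model$n_targets
    mode <- model$config$mode
    model <- model$model
  }
  probs <- nn_predict_probs(model, X)
  if (mode == "onehot") {
    cls <- max.col(probs, ties.method = "first") - 1L
    labels <- decode_class_matrix(cls, n_targets)
    target_scores <- target_scores_from_class_probs(probs, n_targets)
    list(probs = probs, class = cls, labels = labels,
         target_scores = target_scores)
  } else {
    list(probs = probs, class = NULL,
         labels = (probs >= 0.5) * 1L, target_scores = probs)
  }
}

# P(target t active) = sum of probabilities of classes whose decoded label
# has bit t set.
target_scores_from_class_probs <- function(probs, n_targets) {
  bit_matrix <- decode_class_matrix(0:(2^n_targets - 1L), n_targets)
  probs %*% bit_matrix
}

#' @export
print.gp_plans_result <- function(x, ...) {
  cat("<gp_plans_result> final tier ", attr(x$model, "spec")$tier,
      ", ", length(x$history), " stages, features ", x$feature_kind,
      ", ", length(x$test_idx), " test rows\n", sep = "")
  invisible(x)
}
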