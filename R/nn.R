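# Minimal dense neural-network engine: forward/backward passes, Adam, and a
# training loop with validation-based early stopping. Written in base R
# matrix algebra (BLAS does the heavy lifting); this is the substrate for
# the GIN reconstruction head and the staged PLANS perceptrons.
#
# Conventions: X is n x d (rows = samples); hidden activations are ReLU;
# the output layer is linear, with the loss head (softmax cross-entropy or
# sigmoid binary cross-entropy) applied on top. Dropout, when active, is
# applied to the last hidden activation only (one dropout stage before the
# output layer), using inverted scaling so inference needs no correction.

nn_init_params <- function(layer_dims) {
  lapply(seq_len(length(layer_dims) - 1L), function(l) {
    fan_in <- layer_dims[l]
    list(
      W = matrix(stats::rnorm(fan_in * layer_dims[l + 1L],
                              sd = sqrt(2 / fan_in)),
                 nrow = fan_in),
      b = numeric(layer_dims[l + 1L])
    )
  })
}

nn_n_params <- function(layer_dims) {
  sum(vapply(seq_len(length(layer_dims) - 1L), function(l) {
    layer_dims[l] * layer_dims[l + 1L] + layer_dims[l + 1L]
  }, numeric(1L)))
}

# Forward pass. Returns output logits plus caches needed for backprop.
nn_forward <- function(params, X, dropout_rate = 0, training = FALSE) {
  L <- length(params)
  acts <- vector("list", L + 1L)
  zs <- vector("list", L)
  acts[[1L]] <- X
  mask <- NULL
  for (l in seq_len(L)) {
    z <- add_bias(acts[[l]] %*% params[[l]]$W, params[[l]]$b)
    if (l < L) {
      a <- relu(z)
      if (l == L - 1L && training && dropout_rate > 0) {
        mask <- matrix(stats::rbinom(length(a), 1L, 1 - dropout_rate),
                       nrow = nrow(a)) / (1 - dropout_rate)
        a <- a * mask
      }
      acts[[l + 1L]] <- a
    } else {
      acts[[l + 1L]] <- z
    }
    zs[[l]] <- z
  }
  list(logits = acts[[L + 1L]], acts = acts, zs = zs, mask = mask)
}

nn_output_probs <- function(logits, output_type) {
  switch(output_type,
         softmax = softmax_rows(logits),
         sigmoid = sigmoid(logits),
         stop("unknown output type: ", output_type))
}

# Mean loss: categorical cross-entropy -sum(y log p) averaged over rows, or
# per-entry binary cross-entropy averaged over all entries.
nn_loss <- function(probs, Y, output_type) {
  if (output_type == "softmax") {
    -mean(rowSums(Y * safe_log(probs)))
  } else {
    -mean(Y * safe_log(probs) + (1 - Y) * safe_log(1 - probs))
  }
}

# Backward pass; returns gradient list parallel to params.
nn_backward <- function(params, cache, probs, Y, output_type) {
  L <- length(params)
  n <- nrow(Y)
  dZ <- if (output_type == "softmax") {
    (probs - Y) / n
  } else {
    (probs - Y) / (n * ncol(Y))
  }
  grads <- vector("list", L)
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(cache$acts[[l]], dZ),
                       b = colSums(dZ))
    if (l > 1L) {
      dA <- tcrossprod(dZ, params[[l]]$W)
      if (l - 1L == L - 1L && !is.null(cache$mask)) dA <- dA * cache$mask
      dZ <- dA * (cache$zs[[l - 1L]] > 0)
    }
  }
  grads
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
    v = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  # bias corrections folded into one scale and one epsilon so the update
  # is a single fused expression per tensor (memory traffic dominates the
  # optimizer cost at these sizes)
  bc2_sqrt <- sqrt(1 - beta2^state$t)
  scale <- lr * bc2_sqrt / (1 - beta1^state$t)
  eps2 <- eps * bc2_sqrt
  for (l in seq_along(params)) {
    for (nm in c("W", "b")) {
      g <- grads[[l]][[nm]]
      m <- state$m[[l]][[nm]] <- beta1 * state$m[[l]][[nm]] + (1 - beta1) * g
      v <- state$v[[l]][[nm]] <- beta2 * state$v[[l]][[nm]] + (1 - beta2) * g * g
      p <- params[[l]][[nm]] - scale * m / (sqrt(v) + eps2)
      if (weight_decay > 0 && nm == "W") {
        # decoupled (AdamW-style) decay on weights, never on biases
        p <- p - lr * weight_decay * params[[l]][[nm]]
      }
      params[[l]][[nm]] <- p
    }
  }
  list(params = params, state = state)
}

# In-place variant used by the dense training loop: parameters and moment
# estimates are mutated through the compiled fused kernel, so the caller
# must deep-copy any snapshot it wants to keep (see best_params below).
adam_step_inplace <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                              beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc2_sqrt <- sqrt(1 - beta2^state$t)
  scale <- lr * bc2_sqrt / (1 - beta1^state$t)
  eps2 <- eps * bc2_sqrt
  for (l in seq_along(params)) {
    adam_update_inplace(params[[l]]$W, state$m[[l]]$W, state$v[[l]]$W,
                        grads[[l]]$W, beta1, beta2, scale, eps2,
                        lr * weight_decay)
    adam_update_inplace(params[[l]]$b, state$m[[l]]$b, state$v[[l]]$b,
                        grads[[l]]$b, beta1, beta2, scale, eps2, 0)
  }
  state
}

deep_copy_params <- function(params) {
  lapply(params, function(p) list(W = p$W + 0, b = p$b + 0))
}

# Training loop with optional mixup noise and early stopping on a held-out
# validation fraction. Returns a gp_mlp model object.
nn_fit <- function(X, Y, hidden, output_type = c("softmax", "sigmoid"),
                   dropout_rate = 0, epochs = 100L, batch_size = 64L,
                   lr = 1e-3, weight_decay = 0, val_fraction = 0.1,
                   patience = 5L, mixup = NULL, seed = NULL,
                   verbose = FALSE) {
  output_type <- match.arg(output_type)
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y))
  if (nrow(X) == 0L) stop("cannot train on an empty dataset")
  if (!is.null(seed)) set_seed_scrambled(seed)

  n <- nrow(X)
  dims <- c(ncol(X), hidden, ncol(Y))
  params <- nn_init_params(dims)
  state <- adam_init(params)

  n_val <- if (val_fraction > 0 && n >= 10L) max(1L, round(val_fraction * n)) else 0L
  idx <- sample.int(n)
  val_idx <- if (n_val > 0L) idx[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(idx, val_idx)

  use_mixup <- !is.null(mixup) && isTRUE(mixup$enabled)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_loss <- Inf
  best_params <- deep_copy_params(params)
  wait <- 0L

  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    batch_losses <- numeric(length(batches))
    for (k in seq_along(batches)) {
      bi <- batches[[k]]
      Xb <- X[bi, , drop = FALSE]
      Yb <- Y[bi, , drop = FALSE]
      if (use_mixup && length(bi) > 1L) {
        lam <- sample_lambda(mixup)
        perm <- sample.int(nrow(Xb))
        Xb <- lam * Xb + (1 - lam) * Xb[perm, , drop = FALSE]
        Yb <- lam * Yb + (1 - lam) * Yb[perm, , drop = FALSE]
      }
      fw <- nn_forward(params, Xb, dropout_rate, training = TRUE)
      probs <- nn_output_probs(fw$logits, output_type)
      batch_losses[k] <- nn_loss(probs, Yb, output_type)
      grads <- nn_backward(params, fw, probs, Yb, output_type)
      state <- adam_step_inplace(params, grads, state, lr,
                                 weight_decay = weight_decay)
    }

    # epoch train loss = mean of the minibatch losses already computed
    tr_loss <- mean(batch_losses)
    if (n_val > 0L) {
      va_probs <- nn_output_probs(
        nn_forward(params, X[val_idx, , drop = FALSE])$logits, output_type)
      va_loss <- nn_loss(va_probs, Y[val_idx, , drop = FALSE], output_type)
    } else {
      va_loss <- tr_loss
    }
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = tr_loss,
                                val_loss = va_loss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep, tr_loss, va_loss))
    }
    if (va_loss < best_loss - 1e-6) {
      best_loss <- va_loss
      best_params <- deep_copy_params(params)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }

  structure(
    list(params = best_params, dims = dims, output_type = output_type,
         dropout_rate = dropout_rate, history = history,
         best_val_loss = best_loss),
    class = "gp_mlp"
  )
}

# Deterministic inference (noise always off).
nn_predict_probs <- function(model, X) {
  stopifnot(inherits(model, "gp_mlp"))
  if (ncol(X) != model$dims[1L]) {
    stop("feature length ", ncol(X), " does not match model input length ",
         model$dims[1L])
  }
  nn_output_probs(nn_forward(model$params, X)$logits, model$output_type)
}

#' @export
print.gp_mlp <- function(x, ...) {
  cat("<gp_mlp> layers ", paste(x$dims, collapse = "-"),
      " (", x$output_type, " head), ",
      nrow(x$history), " epochs, best val loss ",
      signif(x$best_val_loss, 4), "\n", sep = "")
  invisible(x)
}
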