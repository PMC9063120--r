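# Graph Isomorphism Network (GIN) with self-supervised ECFP-reconstruction
# pretraining. The pooled hidden state of the pretrained network is the
# continuous molecular fingerprint (GINFP).
#
# Layer update: for node v at layer k the neighborhood aggregate is
#   a_v = (1 - eps_k) h_v^(k-1) + sum_{u in N(v)} h_u^(k-1)
# (neighbors are SUMMED, never averaged - this is what lets the network
# separate nodes by neighbor multiset), followed by the layer's node MLP.
# The sign in front of eps is configurable via `epsilon_sign`: -1 gives the
# (1 - eps) form, +1 the (1 + eps) form of the original GIN formulation.
# Node embeddings from all layers are summed per node, then mean-pooled
# over nodes to give the graph-level embedding.

#' GIN configuration
#'
#' @param n_layers Number of GIN message-passing layers (default 5).
#' @param node_mlp_hidden Hidden widths of each layer's node MLP
#'   (default `c(1024, 512)`).
#' @param embed_dim Dimension of node/graph embeddings - the GINFP length
#'   (default 300).
#' @param head_hidden Hidden width(s) of the two-layer reconstruction head.
#' @param out_dim Output dimension of the reconstruction head; must equal
#'   the ECFP bit length used for pretraining (default 2048).
#' @param epsilon_sign Either `-1` (update uses `(1 - eps)`, the default) or
#'   `+1` (`(1 + eps)`, the original GIN convention).
#' @param seed Seed used for parameter initialization.
#' @return A `gp_gin_config` list.
#' @export
gin_config <- function(n_layers = 5L, node_mlp_hidden = c(1024L, 512L),
                       embed_dim = 300L, head_hidden = 512L,
                       out_dim = 2048L, epsilon_sign = -1L, seed = 1L) {
  stopifnot(n_layers >= 1L, embed_dim >= 1L, out_dim >= 1L,
            epsilon_sign %in% c(-1L, 1L), length(node_mlp_hidden) >= 1L)
  structure(
    list(n_layers = as.integer(n_layers),
         node_mlp_hidden = as.integer(node_mlp_hidden),
         embed_dim = as.integer(embed_dim),
         head_hidden = as.integer(head_hidden),
         out_dim = as.integer(out_dim),
         epsilon_sign = as.integer(epsilon_sign),
         seed = as.integer(seed)),
    class = "gp_gin_config"
  )
}

#' Initialize GIN parameters
#'
#' Allocates the input projection (raw node features to `embed_dim`), the
#' per-layer node MLPs with one trainable epsilon scalar per layer
#' (initialized at 0), and the reconstruction head.
#'
#' @param config A [gin_config()].
#' @param feat_dim Length of the raw node-feature vectors.
#' @return A `gp_gin_params` list.
#' @export
gin_init_params <- function(config, feat_dim = node_feature_length()) {
  stopifnot(inherits(config, "gp_gin_config"))
  set_seed_scrambled(config$seed)
  D <- config$embed_dim
  layer_dims <- c(D, config$node_mlp_hidden, D)
  structure(
    list(
      proj = nn_init_params(c(feat_dim, D))[[1L]],
      layers = lapply(seq_len(config$n_layers), function(k) {
        list(mlp = nn_init_params(layer_dims), eps = 0)
      }),
      head = nn_init_params(c(D, config$head_hidden, config$out_dim)),
      feat_dim = feat_dim
    ),
    class = "gp_gin_params"
  )
}

gin_n_params <- function(params, config) {
  D <- config$embed_dim
  layer_dims <- c(D, config$node_mlp_hidden, D)
  params$feat_dim * D + D +
    config$n_layers * (nn_n_params(layer_dims) + 1L) +
    nn_n_params(c(D, config$head_hidden, config$out_dim))
}

# Stack a list of gp_graph into one batched block structure: node features
# X, symmetric sparse adjacency, and a graphs x nodes mean-pooling matrix.
batch_graphs <- function(graphs) {
  n_nodes <- vapply(graphs, function(g) g$n_nodes, integer(1L))
  if (any(n_nodes == 0L)) stop("cannot embed an empty graph (0 nodes)")
  offset <- cumsum(c(0L, n_nodes[-length(n_nodes)]))
  N <- sum(n_nodes)
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))

  ii <- integer(0); jj <- integer(0)
  for (g in seq_along(graphs)) {
    e <- graphs[[g]]$edges
    if (nrow(e)) {
      a <- e[, "i"] + 1L + offset[g]
      b <- e[, "j"] + 1L + offset[g]
      ii <- c(ii, a, b)
      jj <- c(jj, b, a)
    }
  }
  adj <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(N, N))
  pool <- Matrix::sparseMatrix(
    i = rep(seq_along(graphs), n_nodes),
    j = seq_len(N),
    x = rep(1 / n_nodes, n_nodes),
    dims = c(length(graphs), N)
  )
  list(X = X, adj = adj, pool = pool, n_nodes = n_nodes)
}

# Node MLP forward within one layer; returns output and caches.
node_mlp_forward <- function(mlp, A) {
  L <- length(mlp)
  acts <- vector("list", L + 1L)
  zs <- vector("list", L)
  acts[[1L]] <- A
  for (l in seq_len(L)) {
    z <- add_bias(acts[[l]] %*% mlp[[l]]$W, mlp[[l]]$b)
    acts[[l + 1L]] <- if (l < L) relu(z) else z
    zs[[l]] <- z
  }
  list(out = acts[[L + 1L]], acts = acts, zs = zs)
}

node_mlp_backward <- function(mlp, cache, dOut) {
  L <- length(mlp)
  grads <- vector("list", L)
  dZ <- dOut
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(cache$acts[[l]], dZ), b = colSums(dZ))
    if (l > 1L) {
      dZ <- tcrossprod(dZ, mlp[[l]]$W) * (cache$zs[[l - 1L]] > 0)
    }
  }
  dIn <- tcrossprod(dZ, mlp[[1L]]$W)
  list(grads = grads, dIn = dIn)
}

# Full batched forward pass; with keep_cache the intermediates needed for
# backprop are retained.
gin_forward <- function(params, batch, config, keep_cache = FALSE) {
  coef <- function(eps) 1 + config$epsilon_sign * eps
  H <- add_bias(batch$X %*% params$proj$W, params$proj$b)
  H_list <- vector("list", config$n_layers)
  A_list <- vector("list", config$n_layers)
  mlp_caches <- vector("list", config$n_layers)
  H_prev_list <- vector("list", config$n_layers)
  S <- 0
  for (k in seq_len(config$n_layers)) {
    lay <- params$layers[[k]]
    A <- as.matrix(batch$adj %*% H) + coef(lay$eps) * H
    mf <- node_mlp_forward(lay$mlp, A)
    if (keep_cache) {
      H_prev_list[[k]] <- H
      A_list[[k]] <- A
      mlp_caches[[k]] <- mf
    }
    H_list[[k]] <- mf$out
    S <- S + mf$out
    H <- mf$out
  }
  G <- as.matrix(batch$pool %*% S)
  hf <- node_mlp_forward(params$head, G)
  out <- list(embed = G, logits = hf$out)
  if (keep_cache) {
    out$cache <- list(H_prev = H_prev_list, A = A_list, mlp = mlp_caches,
                      head = hf, S = S, G = G)
  }
  out
}

# Backward pass for BCE reconstruction loss; probs = sigmoid(logits).
gin_backward <- function(params, batch, config, fw, probs, Y) {
  nG <- nrow(Y)
  dLogits <- (probs - Y) / (nG * ncol(Y))
  hb <- node_mlp_backward(params$head, fw$cache$head, dLogits)
  dG <- hb$dIn
  dS <- as.matrix(Matrix::crossprod(batch$pool, dG))

  K <- config$n_layers
  grads <- list(head = hb$grads, layers = vector("list", K))
  dH_next <- NULL  # gradient flowing into H_k from layer k+1's aggregate
  for (k in K:1) {
    lay <- params$layers[[k]]
    dHk <- dS
    if (!is.null(dH_next)) dHk <- dHk + dH_next
    mb <- node_mlp_backward(lay$mlp, fw$cache$mlp[[k]], dHk)
    dA <- mb$dIn
    H_prev <- fw$cache$H_prev[[k]]
    g_eps <- config$epsilon_sign * sum(dA * H_prev)
    grads$layers[[k]] <- list(mlp = mb$grads, eps = g_eps)
    dH_next <- as.matrix(batch$adj %*% dA) +
      (1 + config$epsilon_sign * lay$eps) * dA
  }
  # dH_next now holds the gradient w.r.t. H0 (the projected input).
  grads$proj <- list(W = crossprod(batch$X, dH_next), b = colSums(dH_next))
  grads
}

# Flatten GIN params/grads into the nn engine's Adam-friendly layout.
gin_flatten <- function(p, config) {
  out <- list(p$proj)
  for (k in seq_len(config$n_layers)) {
    out <- c(out, p$layers[[k]]$mlp,
             list(list(W = matrix(p$layers[[k]]$eps), b = numeric(0))))
  }
  c(out, p$head)
}

gin_unflatten <- function(flat, template, config) {
  n_mlp <- length(template$layers[[1L]]$mlp)
  pos <- 1L
  template$proj <- flat[[pos]]; pos <- pos + 1L
  for (k in seq_len(config$n_layers)) {
    template$layers[[k]]$mlp <- flat[pos:(pos + n_mlp - 1L)]
    pos <- pos + n_mlp
    template$layers[[k]]$eps <- flat[[pos]]$W[1L, 1L]
    pos <- pos + 1L
  }
  template$head <- flat[pos:length(flat)]
  template
}

gin_flatten_grads <- function(g, config) {
  out <- list(g$proj)
  for (k in seq_len(config$n_layers)) {
    out <- c(out, g$layers[[k]]$mlp,
             list(list(W = matrix(g$layers[[k]]$eps), b = numeric(0))))
  }
  c(out, g$head)
}

#' Neighborhood aggregate of the GIN update rule
#'
#' Computes, for every node v, `(1 +/- eps) * h_v + sum of neighbor
#' embeddings` - the aggregation step of the layer update, before the node
#' MLP is applied. Exposed separately so the arithmetic of the update rule
#' can be inspected and tested directly.
#'
#' @param graph A `gp_graph`.
#' @param h_prev Numeric matrix, one row per node.
#' @param eps The layer's epsilon scalar.
#' @param epsilon_sign -1 for the `(1 - eps)` form (default), +1 for
#'   `(1 + eps)`.
#' @return Matrix of aggregates, same shape as `h_prev`.
#' @export
gin_aggregate <- function(graph, h_prev, eps = 0, epsilon_sign = -1L) {
  stopifnot(inherits(graph, "gp_graph"))
  if (!is.matrix(h_prev)) h_prev <- matrix(h_prev, nrow = graph$n_nodes)
  if (nrow(h_prev) != graph$n_nodes) {
    stop("h_prev must have one row per node (", graph$n_nodes, "), got ",
         nrow(h_prev))
  }
  agg <- (1 + epsilon_sign * eps) * h_prev
  e <- graph$edges
  if (nrow(e)) {
    for (r in seq_len(nrow(e))) {
      i <- e[r, "i"] + 1L
      j <- e[r, "j"] + 1L
      agg[i, ] <- agg[i, ] + h_prev[j, ]
      agg[j, ] <- agg[j, ] + h_prev[i, ]
    }
  }
  agg
}

#' One GIN layer update
#'
#' Applies the layer-k aggregation ([gin_aggregate()], with layer k's
#' trainable epsilon) followed by layer k's node MLP.
#'
#' @param k Layer index (1-based).
#' @param graph A `gp_graph`.
#' @param h_prev Node embedding matrix from the previous layer.
#' @param params A `gp_gin_params`.
#' @param config The matching [gin_config()].
#' @return Updated node embedding matrix (`n_nodes` x `embed_dim`).
#' @export
gin_node_update <- function(k, graph, h_prev, params, config) {
  stopifnot(inherits(params, "gp_gin_params"),
            inherits(config, "gp_gin_config"),
            k >= 1L, k <= config$n_layers)
  agg <- gin_aggregate(graph, h_prev, params$layers[[k]]$eps,
                       config$epsilon_sign)
  node_mlp_forward(params$layers[[k]]$mlp, agg)$out
}

#' Graph-level embedding (GINFP)
#'
#' Runs the full GIN forward pass on one molecular graph: per-node
#' embeddings from all layers are summed per node, then averaged over nodes
#' (graph-level mean pooling). With pretrained parameters this vector is
#' the molecule's GINFP.
#'
#' @param graph A `gp_graph`.
#' @param params A `gp_gin_params`.
#' @param config The matching [gin_config()].
#' @return Numeric vector of length `config$embed_dim`.
#' @export
graph_embed <- function(graph, params, config) {
  stopifnot(inherits(graph, "gp_graph"))
  if (graph$n_nodes == 0L) stop("cannot embed an empty graph (0 nodes)")
  batch <- batch_graphs(list(graph))
  as.numeric(gin_forward(params, batch, config)$embed)
}

#' Pretrain a GIN by ECFP reconstruction
#'
#' Self-supervised pretraining: the graph embedding is passed through a
#' two-layer head whose sigmoid outputs are trained to reconstruct the
#' molecule's binary ECFP under mean per-bit binary cross-entropy. Training
#' stops early when the validation loss has not improved for `patience`
#' epochs; the parameters from the best validation epoch are returned.
#'
#' @param graphs List of `gp_graph` objects.
#' @param fingerprints Matrix of 0/1 ECFP rows (one per graph) with
#'   `config$out_dim` columns.
#' @param config A [gin_config()].
#' @param epochs Maximum number of epochs.
#' @param batch_size Graphs per minibatch.
#' @param lr Adam learning rate.
#' @param val_fraction Fraction of graphs held out for early stopping.
#' @param patience Early-stopping patience (epochs).
#' @param seed Seed for initialization, shuffling and the validation split.
#' @param verbose Print per-epoch losses.
#' @return A `gp_gin` model: `params`, `config` and a per-epoch
#'   `history` data frame with train/validation BCE.
#' @export
gin_pretrain <- function(graphs, fingerprints, config = gin_config(),
                         epochs = 50L, batch_size = 32L, lr = 1e-3,
                         val_fraction = 0.1, patience = 5L, seed = 1L,
                         verbose = FALSE) {
  stopifnot(inherits(config, "gp_gin_config"))
  n <- length(graphs)
  if (n == 0L) stop("cannot pretrain on an empty dataset")
  if (!is.matrix(fingerprints) || nrow(fingerprints) != n) {
    stop("fingerprints must be a matrix with one row per graph")
  }
  if (ncol(fingerprints) != config$out_dim) {
    stop("fingerprint length ", ncol(fingerprints),
         " does not match config out_dim ", config$out_dim)
  }

  params <- gin_init_params(config, ncol(graphs[[1L]]$node_features))
  set_seed_scrambled(seed)
  flat <- gin_flatten(params, config)
  state <- adam_init(flat)

  n_val <- if (val_fraction > 0 && n >= 10L) max(1L, round(val_fraction * n)) else 0L
  idx <- sample.int(n)
  val_idx <- if (n_val > 0L) idx[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(idx, val_idx)
  val_batch <- if (n_val > 0L) batch_graphs(graphs[val_idx]) else NULL
  tr_eval_batch <- batch_graphs(graphs[tr_idx])

  eval_loss <- function(p, batch, Y) {
    probs <- sigmoid(gin_forward(p, batch, config)$logits)
    -mean(Y * safe_log(probs) + (1 - Y) * safe_log(1 - probs))
  }

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_loss <- Inf
  best_params <- params
  wait <- 0L

  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    bs <- split(ord, ceiling(seq_along(ord) / batch_size))
    for (bi in bs) {
      batch <- batch_graphs(graphs[bi])
      Yb <- fingerprints[bi, , drop = FALSE]
      fw <- gin_forward(params, batch, config, keep_cache = TRUE)
      probs <- sigmoid(fw$logits)
      grads <- gin_backward(params, batch, config, fw, probs, Yb)
      upd <- adam_step(gin_flatten(params, config),
                       gin_flatten_grads(grads, config), state, lr)
      params <- gin_unflatten(upd$params, params, config)
      state <- upd$state
    }

    tr_loss <- eval_loss(params, tr_eval_batch,
                         fingerprints[tr_idx, , drop = FALSE])
    va_loss <- if (n_val > 0L) {
      eval_loss(params, val_batch, fingerprints[val_idx, , drop = FALSE])
    } else {
      tr_loss
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = tr_loss,
                                         val_loss = va_loss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep, tr_loss, va_loss))
    }
    if (va_loss < best_loss - 1e-6) {
      best_loss <- va_loss
      best_params <- params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }

  structure(
    list(params = best_params, config = config, history = history,
         best_val_loss = best_loss),
    class = "gp_gin"
  )
}

#' @export
print.gp_gin <- function(x, ...) {
  cat("<gp_gin> ", x$config$n_layers, " layers, embed dim ",
      x$config$embed_dim, ", ", nrow(x$history), " epochs, best val BCE ",
      signif(x$best_val_loss, 4), "\n", sep = "")
  invisible(x)
}

#' Embed a set of SMILES with a (pre)trained GIN
#'
#' Parses each SMILES, builds its graph and computes the GINFP. Unloadable
#' molecules are dropped and their input indices reported.
#'
#' @param smiles Character vector of SMILES.
#' @param model A `gp_gin` from [gin_pretrain()] (or a list with `params`
#'   and `config`).
#' @param batch_size Graphs per forward batch.
#' @param quiet Suppress the dropped-record message.
#' @return Numeric matrix, one row per loadable molecule in input order,
#'   `embed_dim` columns (named `ginfp_0..`), with attribute `dropped`.
#' @export
embed_dataset <- function(smiles, model, batch_size = 128L, quiet = FALSE) {
  parsed <- parse_smiles_batch(smiles, quiet = quiet)
  graphs <- lapply(parsed$mols, build_graph)
  D <- model$config$embed_dim
  if (length(graphs) == 0L) {
    out <- matrix(numeric(0), ncol = D)
  } else {
    chunks <- split(seq_along(graphs),
                    ceiling(seq_along(graphs) / batch_size))
    out <- do.call(rbind, lapply(chunks, function(ci) {
      gin_forward(model$params, batch_graphs(graphs[ci]), model$config)$embed
    }))
  }
  colnames(out) <- paste0("ginfp_", seq_len(D) - 1L)
  rownames(out) <- smiles[parsed$kept]
  attr(out, "dropped") <- parsed$dropped
  out
}

#' Save / load a GIN checkpoint
#'
#' The checkpoint is a single RDS file with the configuration embedded.
#'
#' @param model A `gp_gin`.
#' @param path File path.
#' @return `load_gin_checkpoint` returns the `gp_gin` model.
#' @export
save_gin_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "gp_gin"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_gin_checkpoint
#' @export
load_gin_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "gp_gin"))
  model
}
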