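# GIN layer arithmetic, pooling, permutation invariance and
# ECFP-reconstruction pretraining.

test_that("the aggregation step follows the printed update rule", {
  # isolated node, eps = 0: empty neighbor sum leaves the embedding alone
  g1 <- build_graph(fixture_mol("C"))
  h <- matrix(c(2.5), 1)
  expect_equal(gin_aggregate(g1, h, eps = 0), matrix(2.5, 1))

  # a node with two neighbors, all embeddings 1, eps = 0 -> 3
  path <- structure(
    list(n_nodes = 3L, node_features = matrix(0, 3, 2),
         edges = cbind(i = c(0L, 1L), j = c(1L, 2L))),
    class = "gp_graph"
  )
  h3 <- matrix(1, 3, 1)
  agg <- gin_aggregate(path, h3, eps = 0)
  expect_equal(agg[2, 1], 3)      # center: own 1 + two neighbors
  expect_equal(agg[1, 1], 2)      # leaf: own 1 + one neighbor

  # (1 - eps) form: eps = 0.25 scales the self term only
  agg2 <- gin_aggregate(path, h3, eps = 0.25, epsilon_sign = -1L)
  expect_equal(agg2[2, 1], 0.75 + 2)
  # (1 + eps) form under the configurable sign
  agg3 <- gin_aggregate(path, h3, eps = 0.25, epsilon_sign = 1L)
  expect_equal(agg3[2, 1], 1.25 + 2)
})

test_that("sum aggregation separates centers by neighbor count", {
  star <- function(k) {
    structure(
      list(n_nodes = k + 1L, node_features = matrix(0, k + 1L, 2),
           edges = cbind(i = rep(0L, k), j = seq_len(k))),
      class = "gp_graph"
    )
  }
  h2 <- matrix(1, 3, 1)
  h3 <- matrix(1, 4, 1)
  a2 <- gin_aggregate(star(2), h2, eps = 0)[1, 1]
  a3 <- gin_aggregate(star(3), h3, eps = 0)[1, 1]
  expect_false(isTRUE(all.equal(a2, a3)))
  expect_equal(a3 - a2, 1)  # exactly one extra summed neighbor
})

test_that("gin_node_update applies the layer MLP after aggregation", {
  cfg <- tiny_gin_config()
  g <- build_graph(fixture_mol("CCO"))
  params <- gin_init_params(cfg, ncol(g$node_features))
  h <- matrix(rnorm(3 * cfg$embed_dim), 3)
  out <- gin_node_update(1L, g, h, params, cfg)
  expect_identical(dim(out), c(3L, cfg$embed_dim))
  # with all-zero neighbors and eps = 0 the update is the node MLP of h_v
  iso <- build_graph(fixture_mol("C"))
  h1 <- matrix(rnorm(cfg$embed_dim), 1)
  direct <- node_mlp_forward(params$layers[[1L]]$mlp, h1)$out
  expect_equal(gin_node_update(1L, iso, h1, params, cfg), direct)
  expect_error(gin_node_update(1L, g, h1, params, cfg), "row per node")
})

test_that("graph embeddings have the configured dimension (300 by default)", {
  cfg <- gin_config()
  expect_identical(cfg$embed_dim, 300L)
  g <- build_graph(fixture_mol("CCO"))
  params <- gin_init_params(cfg, ncol(g$node_features))
  emb <- graph_embed(g, params, cfg)
  expect_length(emb, 300L)
  expect_true(all(is.finite(emb)))
  # deterministic forward pass
  expect_identical(emb, graph_embed(g, params, cfg))
})

test_that("graph embeddings are invariant to node permutations", {
  cfg <- tiny_gin_config()
  graphs <- fixture_graphs(20)
  params <- gin_init_params(cfg, ncol(graphs[[1]]$node_features))
  set.seed(17)
  for (g in graphs) {
    base <- graph_embed(g, params, cfg)
    for (rep in 1:10) {
      perm <- sample(g$n_nodes)
      expect_equal(graph_embed(permute_graph(g, perm), params, cfg), base,
                   tolerance = 1e-5)
    }
  }
})

test_that("embedding an empty graph is an error", {
  cfg <- tiny_gin_config()
  g <- build_graph(fixture_mol("C"))
  params <- gin_init_params(cfg, ncol(g$node_features))
  empty <- structure(
    list(n_nodes = 0L, node_features = matrix(0, 0, ncol(g$node_features)),
         edges = matrix(integer(0), ncol = 2,
                        dimnames = list(NULL, c("i", "j")))),
    class = "gp_graph"
  )
  expect_error(graph_embed(empty, params, cfg), "0 nodes")
})

test_that("pretraining decreases the loss and can overfit one molecule", {
  cfg <- tiny_gin_config(out_dim = 64L)
  smi <- generate_molecules(60, seed = 21)
  graphs <- lapply(parse_smiles_batch(smi, quiet = TRUE)$mols, build_graph)
  fps <- ecfp_matrix(smi, radius = 2, n_bits = 64, quiet = TRUE)
  gin <- gin_pretrain(graphs, fps, cfg, epochs = 25, batch_size = 16,
                      patience = 25, seed = 3)
  expect_lt(gin$history$val_loss[nrow(gin$history)],
            gin$history$val_loss[1L])

  # perfect-prediction limit of the loss head
  probs <- matrix(c(1, 0, 1), 1)
  y <- matrix(c(1, 0, 1), 1)
  expect_equal(-mean(y * safe_log(probs) + (1 - y) * safe_log(1 - probs)), 0,
               tolerance = 1e-10)

  # a single molecule is memorized to 100% per-bit accuracy
  one <- gin_pretrain(graphs[1], fps[1, , drop = FALSE], cfg,
                      epochs = 300, batch_size = 1, patience = 300,
                      val_fraction = 0, seed = 3)
  rec <- sigmoid(gin_forward(one$params, batch_graphs(graphs[1]),
                             cfg)$logits) >= 0.5
  expect_identical(as.integer(rec), as.integer(fps[1, ] == 1))
  expect_error(gin_pretrain(list(), fps[0, , drop = FALSE], cfg), "empty")
})

test_that("embed_dataset keeps input order, drops bad SMILES and is reproducible", {
  cfg <- tiny_gin_config(out_dim = 64L)
  smi <- c("CCO", "CCN", "%%bad%%", "CCO", "c1ccccc1")
  g <- build_graph(fixture_mol("CCO"))
  params <- gin_init_params(cfg, ncol(g$node_features))
  model <- structure(list(params = params, config = cfg,
                          history = NULL, best_val_loss = NA),
                     class = "gp_gin")
  m <- suppressMessages(embed_dataset(smi, model))
  expect_identical(dim(m), c(4L, cfg$embed_dim))
  expect_identical(attr(m, "dropped"), 3L)
  expect_equal(m[1, ], m[3, ])  # identical SMILES -> identical rows
  expect_identical(colnames(m)[1], "ginfp_0")

  ck <- file.path(withr::local_tempdir(), "gin.rds")
  save_gin_checkpoint(model, ck)
  m2 <- suppressMessages(embed_dataset(smi, load_gin_checkpoint(ck)))
  expect_equal(m, m2)
})
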