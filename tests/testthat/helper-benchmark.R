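# The shared synthetic benchmark: 1,000 molecules under the default study
# conditions (5 substructure targets, label noise 0.05, ~40% partially
# labeled, 30% unlabeled, all-negative class dominant). Built once per test
# run and reused by every test that needs it. Fingerprints for GIN
# pretraining are 256-bit radius-2 ECFPs; GINFP features come from a
# reduced-width GIN with the standard 300-dimension embedding.

benchmark_raw <- function() {
  memo("bench_raw", function() {
    ds <- simulate_dataset(synthetic_config(1000, seed = 42))
    smiles <- c(ds$fully_labeled$smiles, ds$partially_labeled$smiles,
                ds$unlabeled)
    parsed <- parse_smiles_batch(smiles, quiet = TRUE)
    stopifnot(length(parsed$dropped) == 0L)
    graphs <- lapply(parsed$mols, build_graph)
    fps <- t(vapply(parsed$mols, function(m) {
      as.integer(compute_ecfp(m, radius = 2, n_bits = 256))
    }, integer(256)))
    list(ds = ds, graphs = graphs, fps = fps,
         n_full = length(ds$fully_labeled$smiles),
         n_partial = length(ds$partially_labeled$smiles))
  })
}

benchmark_gin <- function() {
  memo("bench_gin", function() {
    raw <- benchmark_raw()
    cfg <- gin_config(n_layers = 3L, node_mlp_hidden = c(64L, 64L),
                      embed_dim = 300L, head_hidden = 256L,
                      out_dim = 256L, seed = 4L)
    gin_pretrain(raw$graphs, raw$fps, cfg, epochs = 15, batch_size = 64,
                 patience = 4, seed = 4)
  })
}

benchmark_bundle <- function() {
  memo("bench_bundle", function() {
    raw <- benchmark_raw()
    gin <- benchmark_gin()
    chunks <- split(seq_along(raw$graphs),
                    ceiling(seq_along(raw$graphs) / 128))
    G <- do.call(rbind, lapply(chunks, function(ci) {
      gin_forward(gin$params, batch_graphs(raw$graphs[ci]),
                  gin$config)$embed
    }))
    G <- standardize_features(G)
    i1 <- seq_len(raw$n_full)
    i2 <- raw$n_full + seq_len(raw$n_partial)
    i3 <- (raw$n_full + raw$n_partial + 1L):nrow(G)
    plans_bundle(G[i1, ], raw$ds$fully_labeled$labels,
                 G[i2, ], raw$ds$partially_labeled$labels,
                 G[i3, ], feature_kind = "GINFP")
  })
}

# PLANS settings used for the benchmark comparisons: the headline PLANS
# configuration (no mixup), desk-scale optimizer budget.
benchmark_plans_config <- function(seed) {
  plans_config(epochs = 12, batch_size = 128, patience = 4, seed = seed,
               mixup = mixup_config(enabled = FALSE))
}
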