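# Shared fixtures, built in code. Heavier objects are memoised so multiple
# test files can reuse one instance.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, builder(), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# Small clean synthetic dataset (no noise, no masking, no unlabeled pool).
clean_dataset <- function() {
  memo("clean_ds", function() {
    simulate_dataset(synthetic_config(
      200, label_noise = 0, missing_rate = 0, unlabeled_fraction = 0,
      seed = 101
    ))
  })
}

# Default-condition dataset: noise, masking and an unlabeled pool.
noisy_dataset <- function() {
  memo("noisy_ds", function() {
    simulate_dataset(synthetic_config(400, seed = 202))
  })
}

# A couple of parsed molecules used across graph/fingerprint tests.
fixture_mol <- function(smiles) {
  key <- paste0("mol_", smiles)
  memo(key, function() parse_smiles(smiles))
}

# Tiny GIN configuration used wherever training speed matters more than
# capacity.
tiny_gin_config <- function(out_dim = 128L, seed = 11L) {
  gin_config(n_layers = 2L, node_mlp_hidden = c(16L, 16L), embed_dim = 8L,
             head_hidden = 32L, out_dim = out_dim, seed = seed)
}

# Random small graphs for property tests: parse from generated molecules.
fixture_graphs <- function(n = 20L, seed = 33L) {
  key <- paste0("graphs_", n, "_", seed)
  memo(key, function() {
    smi <- generate_molecules(n, seed = seed)
    lapply(parse_smiles_batch(smi, quiet = TRUE)$mols, build_graph)
  })
}

# Apply a node permutation to a gp_graph (edges remapped accordingly).
permute_graph <- function(graph, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  e <- graph$edges
  a <- inv[e[, "i"] + 1L] - 1L
  b <- inv[e[, "j"] + 1L] - 1L
  structure(
    list(n_nodes = graph$n_nodes,
         node_features = graph$node_features[perm, , drop = FALSE],
         edges = cbind(i = pmin(a, b), j = pmax(a, b))),
    class = "gp_graph"
  )
}
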