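# ginplans

Semi-supervised QSAR modeling from SMILES, combining a self-supervised
graph-neural-network fingerprint with partially-labeled noisy-student
self-training.

Activity panels — a compound screened against n binary targets, such as
the five major cytochrome P450 isoforms — are typically *partially*
labeled (some assays never run), accompanied by large unlabeled compound
pools, and dominated by the all-negative profile. `ginplans` is a toolkit
for exactly this setting, aimed at computational chemists and ML
practitioners who want to exploit partial labels and unlabeled molecules
instead of discarding them.

## What is inside

* **Chemistry layer** — SMILES parsing (OpenBabel via ChemmineR),
  featurized heavy-atom molecular graphs, and binary
  extended-connectivity fingerprints (ECFP; radius 4, 2048 bits by
  default) computed by iterative neighborhood hashing.
* **GINFP** — a Graph Isomorphism Network with per-layer update

      a_v = (1 − ε⁽ᵏ⁾) h_v⁽ᵏ⁻¹⁾ + Σ_{u∈𝒩(v)} h_u⁽ᵏ⁻¹⁾,   h_v⁽ᵏ⁾ = MLP_k(a_v)

  (neighbors summed, ε trainable per layer), node embeddings summed
  across layers and mean-pooled into a 300-dimension graph embedding,
  pretrained to reconstruct ECFPs under per-bit binary cross-entropy.
  The pooled embedding of the pretrained network is the molecule's GINFP.
* **Label algebra** — n binary targets encoded as 2ⁿ combination classes
  (first target = most significant bit; `[0,1,1,0,1] → 13`), candidate
  enumeration for partial labels (`[0,1,_,0,0] → {8, 12}`), completion by
  restricting and renormalizing a teacher's class distribution, and mixup
  augmentation with Beta(α, α)-drawn coefficients (α = 0.4).
* **PLANS trainer** — staged MLPs (Small/Medium/Large width plans of
  2L,4L,4L,2L,L,L/2,L/4 hidden units and their 3L/6L insertions), an
  initial Small teacher trained on fully labeled data, pseudo-labeling of
  partial and unlabeled pools, optional class balancing capped by the
  all-negative class, and dropout+mixup noise applied to students only;
  cross-entropy loss −Σᵢ yᵢ log pᵢ over combination classes.
* **Evaluation** — exact combination accuracy, micro
  precision/recall/F1 over decoded per-target labels, average precision
  from soft scores, and mean ± sd aggregation over repeated runs.
* **Synthetic benchmark** — a fragment-grammar molecule generator with
  substructure-planted labels, label noise, missing-at-random masking and
  an unlabeled pool, so the full pipeline is testable without external
  assay data.

## Worked example

```r
library(ginplans)

# a synthetic partially labeled panel: 400 molecules, 5 targets
ds <- simulate_dataset(synthetic_config(400, seed = 202))
ds
#> <gp_synth_dataset> 400 molecules: 133 fully labeled, 147 partially labeled, 120 unlabeled

# label algebra on the five-target panel
encode_full_label(c(0, 1, 1, 0, 1))
#> [1] 13
enumerate_candidates(c(0, 1, NA, 0, 0))
#> [1]  8 12
p <- rep(0, 32); p[c(9, 13)] <- c(0.3, 0.1)     # teacher mass on classes 8, 12
complete_partial_label(c(0, 1, NA, 0, 0), p)[c(9, 13)]
#> [1] 0.75 0.25

# ECFP features and the PLANS loop (small settings for illustration)
bundle <- bundle_from_synthetic(ds, "ecfp", radius = 2, n_bits = 256)
res <- run_plans(bundle, plans_config(epochs = 15, seed = 5, balancing = TRUE))
res$history$large
#> accuracy 30.00%  micro P 0.632  R 0.261  F1 0.369  AP(macro) 0.554
```

Held-out metrics for every stage (Small teacher, Medium and Large
students) are in `res$history`; `predict_plans(res, X)` returns soft
class distributions, argmax classes and decoded per-target labels for new
feature rows. For GINFP features, pretrain a GIN with `gin_pretrain()`
(or the `pretrain-gin` CLI command) and pass it via
`bundle_from_synthetic(ds, "ginfp", gin_model = ...)`.

A command-line interface covering simulation, featurization, GIN
pretraining, embedding, training and evaluation ships at
`inst/cli/ginplans.R` (run `Rscript <path> <command> --help`).

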