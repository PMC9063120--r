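---
title: "Semi-supervised QSAR with graph-embedding fingerprints and noisy-student self-training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised QSAR with graph-embedding fingerprints and noisy-student self-training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Quantitative structure–activity relationship (QSAR) panels rarely come
fully labeled. A compound screened against a panel of n binary targets —
for example the five major drug-metabolizing cytochrome P450 isoforms
(1A2, 2C9, 2C19, 2D6, 3A4) — often has assay results for only a subset of
the targets, and the vast majority of known chemical matter has no labels
at all. On top of that, activity panels are strongly imbalanced: most
compounds bind none of the targets, so the "all-negative" profile
dominates.

`ginplans` implements two complementary answers:

* **GINFP** — a continuous, fixed-length (300-dimension by default)
  molecular fingerprint produced by a Graph Isomorphism Network (GIN)
  that is pretrained, without any activity labels, to reconstruct the
  molecule's extended-connectivity fingerprint (ECFP) from its molecular
  graph. The embedding therefore encodes circular-substructure content in
  a dense vector that downstream models digest more easily than sparse
  2048-bit ECFPs.
* **PLANS** (partially-labeled noisy student) — a self-training loop in
  which a Small teacher network trained on the fully labeled subset
  completes the labels of partially labeled and unlabeled molecules, and
  progressively larger "noisy" student networks (dropout + mixup) are
  trained on the union, each student becoming the next teacher.

# Label algebra

With n binary targets, a full activity profile is encoded as one of `2^n`
*combination classes*, reading the label vector left-to-right with the
first target as the most significant bit: `[0,0,0,0,0] -> 0` (the
all-negative class), `[0,1,1,0,1] -> 13`. Classification is then a single
softmax over the `2^n` classes, and predictions are decoded back to
per-target labels for evaluation. The package refuses this encoding above
n = 16 targets, where `2^n` stops being a sensible output dimension.

A *partial* label — some entries missing — is consistent with exactly
`2^m` classes, m the number of missing entries, obtained by filling the
missing positions with every 0/1 combination: `[0,1,_,0,0]` is consistent
with classes 8 and 12 only. PLANS completes such labels by restricting
the teacher's predicted class distribution to that candidate set and
renormalizing to sum 1; all other classes get probability zero. A fully
observed vector therefore completes to a hard one-hot regardless of the
teacher, and an entirely missing vector to the teacher's full (softmax)
distribution. If the teacher assigns zero mass to every candidate — only
possible with degenerate teachers — the completion falls back to the
uniform distribution over the candidates and reports that it did so.

For Tox21-style problems the package also offers a *multi-label* mode: n
independent sigmoid outputs, partial labels completed per target with the
teacher's per-target probability. The one-hot combination mode is the
primary, fully exercised formulation; multi-label mode is provided
because panels with 12+ targets make the `2^n` encoding unattractive, and
its completion rule is the per-target specialization of the candidate
restriction.

# Molecules, graphs and fingerprints

SMILES parsing is delegated to OpenBabel (via ChemmineR/ChemmineOB).
Unparseable strings are *dropped and reported*, never silently imputed;
all matrix-producing operations record the dropped indices. Because
OpenBabel kekulizes aromatic rings on output, the package re-perceives
aromatic rings and flags their atoms and bonds, so `c1ccccc1` and
`C1=CC=CC=C1` produce identical graphs and fingerprints.

Molecular graphs are heavy-atom graphs: nodes are atoms with a
fixed-length feature vector (one-hot atom type, degree, formal charge and
hybridization, each with an overflow bucket, plus an aromaticity flag and
a stereo-parity tag), edges are chemical bonds, one undirected edge per
bond, 0-based indices. Hydrogens are implicit, following the standard
ECFP/GNN convention; implicit hydrogen counts are derived from default
valences and enter the fingerprint's atom invariants. Hybridization is
derived from bond orders (triple or cumulated double -> sp, double or
aromatic -> sp2, otherwise sp3) — a deterministic approximation that
serves as a node feature, not a chemistry engine.

The ECFP is computed in-package by the canonical iterative
neighborhood-hashing (Morgan) scheme: per-atom invariants (atomic number,
heavy degree, implicit H count, formal charge, aromaticity; stereo parity
optional and off by default) are re-hashed `radius` times with the sorted
(bond order, neighbor identifier) pairs, and all identifiers are folded
into `n_bits` bits. Defaults are radius 4 and 2048 bits; bit collisions
under folding are accepted, as is standard at this length. The
fingerprint is deterministic and invariant to how the SMILES was written,
but it is not bit-compatible with any other toolkit's hash — nothing in
the pipeline requires cross-toolkit bit identity, since fingerprints act
as reconstruction targets and features, not as exchange formats.

# The GIN and its pretraining

Each GIN layer updates node v's embedding by

    a_v = (1 - eps_k) * h_v + sum over neighbors u of h_u
    h_v' = MLP_k(a_v)

with one trainable scalar `eps_k` per layer and a per-layer node MLP
(default hidden widths 1024 and 512, output back to the embedding
dimension). Neighbors are **summed, never averaged** — sum aggregation is
what lets the network distinguish nodes by their neighbor multiset, which
matters in molecules full of locally identical atoms. The `(1 - eps)`
form is implemented exactly as specified for this model family; because
the original GIN formulation uses `(1 + eps)`, the sign is exposed as
`epsilon_sign` (default -1, i.e. `(1 - eps)`). At `eps = 0`, where every
layer starts, the two conventions coincide, so the choice only matters as
training moves `eps` away from zero.

Node embeddings from **all** layers are summed per node, then averaged
over nodes (graph-level mean pooling) to give the graph embedding; the
initial projection of raw node features is not included in the sum. For
pretraining, a two-layer head maps the graph embedding to `n_bits`
sigmoid outputs trained with mean per-bit binary cross-entropy against
the molecule's ECFP. Early stopping monitors a held-out validation
fraction (default 10%) with a patience of 5 epochs, and the parameters
from the best validation epoch are kept. Optimization is Adam (learning
rate 1e-3 by default) on minibatches of graphs; graphs in a batch are
stacked into one block-diagonal sparse adjacency, so the whole batch is a
single set of matrix products.

Unstated architectural details were resolved minimally and are all
configurable: 5 GIN layers; the initial node embedding is a linear
projection of the raw feature vector; per-layer (not shared) node MLPs;
no bond features in message passing (bonds define edges only).

# The PLANS loop

The staged perceptrons are defined relative to the input length L:

* **Small** — seven hidden layers of 2L, 4L, 4L, 2L, L, L/2, L/4 units;
* **Medium** — Small with a 3L layer inserted after hidden layers 1 and 3;
* **Large** — Medium with two 6L layers inserted after hidden layer 2 of
  the Small plan.

Parameter counts strictly increase Small < Medium < Large for any L >= 4.
All tiers have a single dropout stage immediately before the output
layer. The dropout *drop* probability defaults to 0.3 (equivalently, a
keep probability of 0.7 — the two conventions describe the same layer).

The loop: split the fully labeled pool 7:3 into training and test sets;
train the Small model on the fully labeled training rows as the initial
teacher; then for each student (Medium, then Large, then optional extra
Large rounds) regenerate pseudo-labels for the partial and unlabeled
pools with the current teacher, optionally rebuild the balanced training
set from scratch, train the student, and promote it to teacher. The test
split is never used for any training decision. Noise placement follows
the noisy-student recipe: dropout and mixup act **only while training
students**; teachers — including the initial Small model — are trained
and queried noise-free, and all inference is deterministic. (The teacher
itself could alternatively be trained with dropout; the package keeps
teachers noise-free so that the noise asymmetry between teacher and
student is exact.)

Pseudo-labels are kept *soft* — students train on the teacher's
probability vectors, not on argmax-hardened classes — following the
knowledge-distillation rationale: probabilities near 0/1 mark easy
examples, probabilities near 0.5 mark hard ones, and that information
would be destroyed by hardening.

Mixup draws a coefficient λ from Beta(α, α) (α = 0.4 by default; 0.2
behaves similarly) once per minibatch and replaces the batch by convex
combinations `λ x_i + (1-λ) x_j` of its rows under a random
within-batch pairing, with labels mixed by the same λ. Mixing label
vectors keeps them valid distributions because the combination is convex.

**Balancing.** When enabled, pseudo-labeled unlabeled rows are not simply
appended: a pool row joins the training set only if its predicted class
(argmax of the soft label) is *not* the all-negative class and that class
currently has fewer rows than the all-negative class. Original rows are
never removed, and the pool is re-drawn from scratch — previous unlabeled
additions discarded — every time a new teacher is promoted. Balancing is
defined for the one-hot combination mode, where "class" is well defined;
in multi-label mode the flag is rejected rather than silently
reinterpreted. Whether unlabeled rows should be used at all when
balancing is off is genuinely ambiguous in this model family, so it is an
explicit flag (`use_unlabeled`, default TRUE) rather than a guess.

Remaining optimizer choices (Adam, learning rate 1e-3, decoupled weight
decay 1e-4, batch size 32, early-stopping patience 5 on a 10% validation
split, extra-round patience 1) are recorded in `plans_config()` and all
configurable; none of them is stated by the model description this
package implements, and the defaults were chosen once as ordinary
practice for networks of this size.

Ties at argmax are broken toward the lowest class index, making
predictions deterministic.

# Evaluation

`score()` reports: exact combination accuracy (every target right);
micro precision/recall/F1 pooling true/false positives across all targets
of all samples; and average precision (AP) computed per target from soft
scores and macro-averaged (the micro-pooled AP over all cells is reported
alongside, since for 12-target panels either convention is defensible).
In one-hot mode the per-target soft score is the summed probability of
all classes in which the target is active. `aggregate_metrics()`
summarizes repeated runs as mean ± sample standard deviation, with
accuracy formatted as a percentage with two decimals.

# The synthetic benchmark

Real activity panels are external and large; the package instead ships a
generator whose datasets exercise every pipeline stage. Molecules are
assembled by concatenating 2–6 fragments from a curated chainable
vocabulary (alkyl chains, ethers, amines, benzene/toluene rings), which
guarantees chemical validity by construction. Five target-defining motifs
— carboxyl/ester, pyridine, amide, thioether sulfur, chlorine — are each
inserted with probability 0.18 per molecule; ground-truth label j is
"molecule contains motif j", recovered independently by SMARTS matching.
None of the base fragments contains a motif, so planted labels have no
incidental matches.

The default conditions emulate a partially labeled, imbalanced panel:
label noise 0.05 (each cell flipped independently), per-cell masking
probability 0.16, and 30% of molecules stripped of all labels. With five
targets, masking at 0.16 leaves roughly 40% of all molecules partially
labeled and 30% fully labeled, and the motif frequency makes the
all-negative class the largest by a wide margin (about 37% of molecules,
versus under 10% for any single-motif class) — the imbalance profile the
balancing rule is designed for. Masking is missing-at-random by
construction; the clean ground-truth matrix is retained separately from
the masked labels so recovery tests cannot leak through the training
path.

What the generator does *not* emulate: realistic medicinal-chemistry
property distributions, activity cliffs, correlated label structure from
related targets, or property-matched decoys. Tests passing on this
benchmark demonstrate that the machinery — encoding, completion,
balancing, staged self-training — behaves as specified on data with the
right *structure*; they do not certify predictive performance on real
assay panels.

# Problem sizes and numerical choices in the test suite

The shipped tests scale the models to desk size while keeping every
mechanism intact. The end-to-end semi-supervised comparison uses 1,000
synthetic molecules under the default conditions above, GINFP-300
features from a reduced-width GIN (3 layers, 64/64 node MLPs, 256-bit
radius-2 ECFP reconstruction targets), and 5 paired seeds: the PLANS
Large student is compared against a Large model trained on the fully
labeled rows alone with identical noise, optimizer settings and splits,
so the only difference is the pseudo-labeled data. GIN pretraining sanity
uses 500 molecules at similarly reduced widths. Radius-2 fingerprints are
used for the synthetic benchmark because its fragment molecules are
small; the radius-4/2048-bit defaults remain the package defaults.
Training runs in these tests use larger minibatches (128) than the
default 32 purely to reduce optimizer-step overhead.

Numerical details worth knowing: softmax is computed with row-max
shifting; cross-entropy clamps probabilities at 1e-12; fingerprint
hashing uses an exact-in-doubles polynomial hash modulo 2^31-1;
permutation invariance of graph embeddings holds to 1e-5 (float
accumulation order differs across node orderings); early stopping
restores the best-validation parameters rather than the last ones; and
all training entry points take explicit seeds, giving bit-reproducible
runs on a fixed BLAS. Two implementation notes: the Adam update for the
dense networks runs through a small compiled kernel that updates
parameters and moment estimates in place (at multi-million-parameter
sizes the optimizer is memory-bound, and R-level temporaries dominate its
cost); and user-visible seeds are passed through a fixed integer
scrambling before reaching `set.seed()`, because R's Mersenne–Twister
seeding gives consecutive integer seeds heavily overlapping `sample()`
streams — without scrambling, "independent" repeats with seeds k and k+1
can share most of their random draws.

# Known limitations

* The dense-layer engine is plain R matrix algebra: adequate at
  desk scale, not a GPU substitute; full-scale pretraining on millions of
  molecules is out of scope.
* Chirality: stereo parity is carried as a node feature and an optional
  ECFP invariant, but no 3D or conformer information exists anywhere in
  the pipeline.
* The implicit-hydrogen and hybridization rules are deterministic
  approximations sufficient for featurization; they are not a valence
  model.
* Balancing can only *raise* minority-class counts to the all-negative
  cap using available pool rows; classes rare in the pool stay rare.
* In multi-label mode, balancing and the combination-class machinery are
  intentionally unavailable.
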