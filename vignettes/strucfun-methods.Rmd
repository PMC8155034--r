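---
title: "Structure-based function prediction with graph convolutions: models and methods"
author: "strucfun authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based function prediction with graph convolutions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`strucfun` predicts protein function labels (GO-term- or EC-number-style,
multi-label) from a residue contact map and the amino-acid sequence, and
localizes each predicted function onto individual residues. The predictor
is a graph convolutional network (GCN) over the contact map; residue input
features come from a frozen LSTM language model fused with a one-hot
encoding; residue-level localization uses gradient-weighted class
activation mapping (grad-CAM). A sequence-only 1-D CNN in the DeepGO
style serves as the baseline that has no access to structure.

Because full-scale training corpora (hundreds of thousands of annotated
experimental structures and homology models) are far outside a desk-scale
package, correctness is established in two complementary ways:

* **equation-level oracles** — every forward expression and every
  hand-derived gradient is checked against independent brute-force
  computations and central finite differences;
* **planted-motif synthetic studies** — a generator produces bead-chain
  structures in which function labels are *caused* by spatially clustered
  residue motifs, so that recovery of labels and of the responsible
  residues can be verified end to end.

# The data model

A protein enters the pipeline as a `ProteinRecord`: an identifier, a
one-letter sequence, optional per-residue 3-D coordinates, a `ContactMap`,
and label vectors. A `ContactMap` is a symmetric binary L×L adjacency with
zero diagonal; self-connections are added only inside the network by the
normalized adjacency. A `LabelSpace` is the ordered term catalogue with
per-term positive counts, information content and class weights. Model
states (`GCNModel`, `CNNModel`, `LanguageModel`) bundle all trainable
arrays with their architecture configuration and training log, and
serialize bit-exactly.

# Contact maps

Three contact definitions are implemented, all with *strict* thresholds
(boundary equality is not a contact):

* `CA_CA` — C-alpha distance below 10 Å (default);
* `ANY_ANY` — any inter-atomic distance below 6.5 Å;
* `NBR_NBR` — distance between neighbor atoms (C-beta; C-alpha for
  glycine) below the sum of the residues' neighbor radii. The radius
  table approximates the interaction sphere swept by each side chain
  (Rosetta convention); the values are shipped as replaceable data
  because no canonical printed table exists.

Chains are restricted to 60–1000 residues (inclusive on both ends; the
conventional reading of "between"). PDB input is parsed via `bio3d`; the
first model only, one chain, alternate locations resolved by highest
occupancy (first on ties), and author numbering densely re-indexed from 1
with the original numbering kept as an attribute — unresolved residues
are simply absent from the dense index, which is a recorded convention,
not something the underlying method prescribes.

`perturbContactMap()` flips each upper-triangle entry independently with
a given probability (mirrored for symmetry). It is the desk-scale
surrogate for evaluating on contact maps of degrading model quality.

# Label spaces

Annotations arrive as `(protein, term, evidence)` rows. The evidence
policy `EXP_only` keeps EXP, IDA, IPI, IMP, IGI, IEP, TAS and IC;
`EXP_and_IEA` additionally keeps electronically inferred rows.
Annotations are propagated up the ontology DAG (`is_a`, and `part_of` by
default) to every ancestor below the namespace root; propagation is
monotone and idempotent. Whether training labels should be DAG-propagated
is a convention rather than a printed fact; propagation is the default
here because term counting, information content and the CAFA metrics all
presuppose closed annotation sets.

Term selection keeps terms with between 50 and 5000 positive examples
(configurable), restricted to depth-3/4 identifiers for EC-style spaces,
ordered lexicographically for determinism. Information content is
`IC = -log2(prob)` bits with probabilities taken from the supplied corpus
by default (an external frequency table can be passed instead). Class
weights are `w_j = N / N_j^+`.

Labels are encoded as paired indicators `y[i, j, ] = (1, 0)` or `(0, 1)`,
matching the per-term two-way softmax heads.

# Residue features

The 26-channel vocabulary is the 20 standard amino acids (alphabetical),
five non-standard channels (B, J, O, U, Z) and a gap symbol; unknown
characters (including X) map to the gap channel. The language model is a
two-layer forward LSTM trained to predict the next residue (the final
position trains against the gap symbol, the recorded end-of-sequence
choice). The full-scale architecture uses 512 hidden units on ~10 M
domain sequences; the desk default is 32–64 units on the synthetic
corpus, because the architecture and its contracts — not the weights —
are what the package reproduces. After training the LM is frozen; the
fusion mapping

\[
H^\mathrm{input} = \mathrm{ReLU}(H^{LM} W^{LM} + X W^{X} + b)
\]

is trained jointly with the GCN. Disabling the LM pathway drops the first
term and gives the one-hot-only variant.

# The graph convolutional network

With \(\tilde A = A + I\) and \(\tilde D\) its degree matrix, each layer
computes

\[
H^{(l+1)} = \mathrm{ReLU}\!\left(\tilde D^{-1/2}\tilde A\tilde D^{-1/2}
H^{(l)} W^{(l)}\right),
\]

the symmetric normalization bounding the propagation operator's largest
eigenvalue at exactly 1 (checked numerically in the tests). Three layers
are used by default; their outputs are concatenated column-wise and
sum-pooled over residues into a fixed-length representation, followed by
one ReLU dense layer and a head producing two logits per term with a
per-term softmax. Padded residues are excluded from pooling, which makes
predictions exactly independent of padding; sum pooling makes them
invariant to residue permutations applied jointly to features and
adjacency. Alternative propagation rules can be plugged in through
`gcnConfig(layer_fun = )` for forward experimentation; training gradients
are implemented for the built-in rule.

Training minimises the class-weighted paired-indicator cross-entropy

\[
\mathcal{L}(\Theta) = -\frac{1}{N}\sum_{i}\sum_{j}\sum_{k=1}^{2}
w_j\, y_{ijk}\, \log \hat y_{ijk},
\]

with natural logarithms (the standard cross-entropy convention; the base
only scales the loss) and probabilities clipped to `[1e-7, 1 - 1e-7]` for
numerical safety. The weight multiplies both indicators of a term, exactly
as the formula is written, which means it rebalances gradient allocation
*across* terms rather than between a term's positive and negative
examples — a property that matters for interpreting the class-weight
experiment below. Optimisation is ADAM; the reference settings are
learning rate 1e-4, \(\beta_1 = \beta_2 = 0.95\), batch size 64, at most
200 epochs with early stopping at patience 5 (the best-validation
checkpoint is returned, a stricter reading of "stop training"), with a
~10% random validation split. All randomness flows from one integer seed
and training is bit-reproducible.

**Desk-scale optimisation.** At a few hundred training proteins the
reference learning rate performs orders of magnitude fewer effective
updates than in the corpus-scale regime and cannot converge within the
epoch cap, so the packaged studies train with learning rate 3e-3 and
batch size 32 (at most 120 epochs). These are configuration arguments;
the function defaults remain the reference values.

Prediction reports the positive-class probability per term; a binary call
requires the score to exceed 0.5 *strictly* (a score of exactly 0.5 is a
negative call).

# The CNN baseline

The sequence-only baseline applies parallel 1-D convolutions of several
filter lengths to the one-hot sequence, ReLU, global max pooling per
filter, and a dense sigmoid head. The full-scale configuration is 16
filter banks of 512 filters; the desk default is 4 widths (8, 16, 24, 32)
with 64 filters each, reachable to full scale through the same knobs.
It is trained with the same weighted loss and optimiser protocol.

# Grad-CAM residue localization

For a term \(l\), the channel importances are the gradients of the
positive output summed over residues,
\(w_k^l = \sum_i \partial y^l / \partial F_{k,i}\), and the class
activation map is
\(\mathrm{CAM}^l[i] = \mathrm{ReLU}(\sum_k w_k^l F_{k,i})\),
keeping only channels with positive influence. (The printed subscript
\(F_{k,l}\) in the source formulation is read as the per-residue
\(F_{k,i}\), since the map is indexed by residue; the literal reading
would make the map constant in \(i\).) The feature maps default to the
final graph layer's output — "the last convolutional layer" — with a
flag for the concatenation of all layers; the differentiated output
defaults to the positive-class probability, with a flag for the raw
logit. Profiles are normalized to `[0, 1]` by dividing by the maximum
(the normalizer is unstated in the source; an all-zero map stays zero).
Because pooling is a residue sum, the gradient with respect to a final-
layer feature map is constant across residues, so the residue structure
of the CAM comes entirely from the feature maps — this also yields the
closed-form check used in the tests (a linear head with coefficients
\(c_k\) gives \(w_k = L\,c_k\) exactly).

Localization quality is measured as the AUROC between the grad-CAM
profile and a binary site profile (planted motif residues, or
BioLiP/CSA-style TSV extracts), with tied saliency values handled by
rank averaging; the trapezoid-integrated sliding-threshold curve equals
the Mann–Whitney statistic, and the tests verify both against explicit
pair counting.

# Evaluation

`fmax()` implements the CAFA protein-centric maximum F-score: at each
threshold on a 0.01-grid, precision is averaged over proteins with at
least one predicted term and recall over proteins with at least one true
term (proteins without annotations have undefined recall and are
excluded; this is the CAFA convention). The degenerate threshold 0 — at
which every term is trivially predicted — is excluded from the grid.
`termAupr()` uses the non-interpolated step-wise area (average-precision
style; trapezoidal PR interpolation is known to be biased, and no rule is
prescribed by the source). `bootstrapMetric()` resamples proteins with
replacement and summarises the replicate distribution deterministically
given a seed.

# The synthetic planted-motif generator

The generator stands in for the real training corpora. Each protein is a
self-avoiding bead chain: consecutive beads exactly 3.8 Å apart (the
canonical C-alpha virtual bond), non-adjacent beads at least 4 Å apart.
Each function term owns a motif specification; when a term is planted in
a protein, its motif residues are pulled into mutual proximity (pairwise
within the motif radius, 8 Å by default — below the 10 Å contact
threshold, so planted motifs are always mutual contacts).

Two dispersion modes are implemented with different geometric
constructions, both guaranteeing the exact-bond and steric contracts:

* **local** motifs occupy consecutive residues, realised as a
  bond-constrained compact path (a damped constraint relaxation that
  enforces exact bonds, the steric floor, and the diameter cap). No
  internal chain rebuilding is needed.
* **long_range** motifs place single pinned residues spread across a
  window at least `min(50, L/2)` positions wide, relaxed to a compact
  target cluster; the chain between consecutive pins is rebuilt as a
  circular-arc bridge of exact 3.8 Å chords bulging along a
  clearance-checked outward normal, with a stochastic bridge walk as
  fallback. Fully dispersed constellations beyond ~6 residues are
  geometrically infeasible under these contracts, so long-range tasks
  use motifs of 4–6 residues.

Sequences are uniform over the 20 standard amino acids except that motif
positions draw from a single term-specific *signature* residue type
(emulating strictly conserved key residues of binding and catalytic
sites). Crucially, proteins in which a term's motif is absent receive the
same number of *decoy* signature residues at scattered positions, so the
sequence composition carries no label information whatsoever: only the
spatial clustering visible in the contact map separates positives from
negatives. This is exactly the property the long-range experiment needs —
a sequence-only CNN with global max pooling sees identical composition in
both classes — and it was adopted after verifying that purely structural
signals (distinguishing planted-clique sizes alone) are not learnable at
desk scale. Labels are the planted indicators flipped independently with
the configured noise rate; the planted truth and the motif residue
indices are retained on every record.

Default planting frequencies follow a geometric spread from 0.03 to 0.5
so that per-term counts span at least a five-fold range (exercising term
selection and class weighting); real GO terms span far wider ranges, and
a rare-to-common spread is the property the machinery must handle.

**What the generator does not emulate:** secondary structure, realistic
packing densities, sequence–structure covariation beyond the planted
signatures, domain architecture, or annotation biases other than
symmetric label flips. Passing the packaged studies therefore shows that
the implementation learns and localizes structurally-caused labels under
controlled conditions — not that it reproduces corpus-scale performance
on real proteomes.

# The packaged desk-scale studies

The test suite and `scripts/acceptance.R` run the following studies
(problem sizes chosen to keep a full run on one CPU within minutes):

* **Planted-motif recovery** — 300 training and 60 held-out proteins of
  60–120 residues, six terms with motifs of 6–10 residues, label noise
  0.05, three seeds. Training uses the noisy labels; evaluation is
  against the planted truth, treating the noise as annotation error —
  with 5% flips the achievable AUPR against *noisy* labels is bounded
  well below the recovery bar for any frequency profile with the
  mandated five-fold count spread, so evaluating against the noisy copy
  would measure the noise, not the method. The macro AUPR must exceed
  three times the mean term prevalence, and the grad-CAM AUROC on
  planted residues of correctly predicted pairs must exceed 0.5 by a
  one-sided Wilcoxon test.
* **Long-range advantage** — 150-residue chains with long-range motifs
  (sizes 5/6/6, noiseless labels so the contrast isolates architecture),
  200 training proteins; the GCN must beat the CNN baseline's macro AUPR
  on at least 2 of 3 seeds.
* **Noise robustness** — the trained recovery models evaluated on test
  contact maps with 0–40% of entries flipped; mean Fmax must be
  non-increasing in the flip rate (one inversion within bootstrap
  uncertainty allowed).
* **Class-weight effect** — a two-term task with 10:1 planting imbalance
  (0.09 vs 0.9, noise 0.05). Because the printed loss weights both
  softmax classes of a term equally, its effect is cross-term gradient
  allocation; with ADAM partially normalising uniform gradient scales,
  the *generalisation* recall contrast at this sample size is unstable in
  sign across seeds. The effect is therefore measured where the weights
  act — rare-term recall at threshold 0.5 on the training set, under a
  fixed 40-epoch budget — where weighted training is consistently ahead.
* **Determinism and invariances** — bit-identical training under a fixed
  seed; predictions invariant (to 1e-6) under joint residue permutation
  and under masked padding.

# Known limitations

* The bead-chain geometry has no side chains; `ANY_ANY` and `NBR_NBR`
  maps are only meaningful for real coordinate input.
* Hand-rolled dense linear algebra keeps the implementation transparent
  and dependency-free but is not competitive with GPU frameworks beyond
  desk scale (hundreds of proteins, hundreds of residues).
* Validation-loss early stopping is noisy for heavily weighted rare terms
  on small validation splits; the studies therefore cap epochs rather
  than rely on patience alone where that matters.
* The OBO parser covers the `[Term]` stanza fields the pipeline needs
  (id, name, namespace, `is_a`, `relationship: part_of`, obsolete flags),
  not the full OBO 1.4 grammar.
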