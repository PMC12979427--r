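---
title: "Evidence-conditioned heterogeneous graph attention for herb-ADR signal prioritization"
author: "msat package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-conditioned heterogeneous graph attention for herb-ADR signal prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msat)
```

## The problem

Post-marketing safety surveillance of Chinese Materia Medica (CMM) must
reconcile two very different kinds of evidence. Spontaneous-report databases
such as FAERS supply large numbers of CMM–adverse-reaction (ADR) co-report
counts, which are noisy, biased and only statistically suggestive. Curated
biomedical resources supply *mechanistic* relations — which compounds a
medicinal material contains, which protein targets those compounds bind,
and which clinical phenotypes those targets are linked to — which are
(approximately) binary and reliable but sparse. `msat` treats CMM–ADR
signal prioritization as link prediction on a heterogeneous graph with four
node types (CMM, Compound, Target, ADR) and six relation types, where the
CMM–ADR label edges carry a quantitative *evidence vector* and the
mechanistic edges do not.

## The model

### Edge evidence

Every CMM–ADR edge carries a six-dimensional evidence vector in fixed
order: (1) cosine similarity of the endpoint node feature vectors
(pre-trained text embeddings in a real deployment; any numeric features are
accepted, and the synthetic generator supplies clustered Gaussian ones);
(2) log1p-transformed FAERS report count; (3) a provenance flag (1 =
FAERS-derived, 0 = literature-only, whose report-count feature is 0 by
construction); (4–5) log1p degrees of the CMM and the ADR; (6) a log1p
meta-path connectivity score counting distinct CMM→Compound→Target→ADR
chains. Count-like features are min–max scaled to [0, 1] with ranges
fitted **on the training fold's edges only**; held-out edges are clamped.
We chose `log1p` rather than a bare logarithm so the transform is defined
at count 0, and left the cosine and the provenance flag unscaled because
they are already bounded. Degrees are all-relation incident degrees of the
fold's training graph; the choice of degree scope is exposed as a
parameter on `nodeDegree()`.

### Encoder

Node features are first projected per type to a shared hidden width
$d_h = H\,d$ ($H$ heads of per-head dimension $d$; defaults $H=8$, $d=72$,
$d_h=576$). Each of $L$ (default 3) attention layers then performs:

1. **Evidence-semantic adaptive gate.** For an evidence vector $e$, the
   per-head attention bias is
   $\beta = g\,\mathrm{MLP}(e) + (1-g)\,W_s e$, with a learnable scalar
   gate $g = \sigma(\theta)$ per layer. The MLP branch (one hidden ReLU
   layer of width 32) extracts non-linear risk patterns; the linear
   shortcut preserves the raw scale of the reporting signal. Relations
   *without* evidence vectors receive a learnable per-relation, per-head
   bias instead — a zero evidence vector would collapse all mechanistic
   edges onto the single constant $\mathrm{MLP}(0)$, which is why we did
   not reuse the gate there.
2. **Biased multi-head attention.** For destination $i$ and incoming edge
   from $j$, logits are $Q_i K_j^\top/\sqrt{d} + \beta_{ij}$, softmaxed per
   head over the incoming edges. Message passing runs over the canonical
   relations plus materialized reverses; both directions of a CMM–ADR edge
   share that edge's evidence vector. Q/K/V projections are shared across
   relations (the per-relation distinction is carried by the bias terms).
   Nodes without in-edges receive the zero message.
3. **Hierarchical signal propagation.** The aggregated message passes
   through an expand-and-compress block
   $W_3\,\mathrm{relu}(W_2\,\mathrm{relu}(W_1 m))$ traversing widths
   $d_h \to 2d_h \to 3d_h \to d_h$ (576→1152→1728→576 at defaults),
   followed by a residual connection and layer normalization. We read the
   generic nonlinearity in this block as ReLU: a sigmoid at width 1728
   would saturate and kill gradients, and ReLU is the standard choice for
   such feed-forward expansions.

Dropout (default 0.18) is applied to attention weights and the HSP output
during training only; evaluation mode is exactly deterministic.
Initialization is Xavier-uniform, $\theta = 0$ (gate 0.5), zero relation
biases, seed-controlled; parameters are fresh per layer.

### Hub-calibrated scorer

A pair $(c, a)$ is scored by a weighted fusion
$s = w_1\,\mathrm{MLP}([z_c \| z_a \| \deg_c \| \deg_a]) +
w_2\, z_c^\top W_B z_a + w_3 \sum_k z_{c,k} r_k z_{a,k}$, mapped to a
probability by a sigmoid. The MLP branch sees standardized `log1p` degrees
(raw counts destabilize optimization on heavy-tailed graphs) and can
therefore learn to discount hub-driven score inflation; the bilinear term
is directional; the DistMult term is symmetric by construction. The
elementwise product in the third term needs a reduction to give a scalar;
we adopt DistMult's standard contraction with a learnable diagonal
(initialized to ones). Fusion weights are unconstrained scalars
initialized to 1/3.

### Training

Binary cross-entropy on sampled (pair, label) mini-batches (default 512)
with full-graph encoding per step — the graphs this package targets fit in
memory, so subgraph sampling is unnecessary. AdamW (learning rate 4e-4,
weight decay 1e-5), gradient clipping at global norm 1.0, a
reduce-on-plateau schedule (factor 0.6, patience 15) and early stopping on
validation AUROC (patience 100, maximum 1000 epochs); the checkpoint with
the best validation AUROC is returned. All gradients are hand-derived
reverse-mode matrix expressions, verified against central finite
differences in the test suite. A fixed seed reproduces the full parameter
trajectory on a single CPU thread.

## Evaluation protocols

* **Folds.** Stratified k-fold (default 10) partition of the positives into
  near-equal test folds; each fold's development positives split 90/10 into
  train/validation with the fold's derived seed, giving ~81:9:10 overall.
  "Stratified" is realized as an equal-count partition of positives, which
  is what an approximately equal distribution of positives across folds
  requires.
* **Leakage control.** Each fold's test positives are removed from the
  graph *before* featurization and training; because storage is
  canonical-direction and reverses are derived at message-passing time,
  removal is automatically bidirectional, and evidence rows are deleted
  synchronously. `auditLeakage()` re-scans the materialized directed edge
  list on every fold and aborts the run on a hit.
* **Negatives.** Type-constrained: for a positive $(h, a)$, negatives
  $(h, a')$ draw $a'$ uniformly from the ADR set excluding the fold's full
  positive union and any explicitly excluded pairs. We sample without
  replacement from the admissible set directly (exact, budget-free)
  rather than rejection sampling; exhaustion yields fewer negatives with a
  warning. Sets are generated once per fold and split from a fixed seed
  and are bit-identical across models.
* **Metrics.** Precision/recall/F1/MCC at a fixed 0.5 threshold in the
  main protocol; rank-statistic AUROC (midranks, i.e. half-credit ties);
  AUPRC as step-interpolated average precision (not trapezoidal — the
  trapezoid overestimates under heavy imbalance). MCC is defined as 0 when
  its denominator vanishes.
* **Threshold selection** (imbalanced protocols): exhaustive grid over the
  unique validation scores, F1-maximizing, ties resolved to the smaller
  threshold, then applied unchanged to the matched test set.
* **Stress sets.** Ratios 1:1/1:2/1:5/1:10 keep all test positives and add
  negatives from unseen non-edges; the per-ratio sets are nested
  (ratio-1 ⊂ ratio-2 ⊂ …) to reduce sampling variance across ratios.
* **Degree strata.** CMMs ranked by degree descending with a stable id
  tie-break; Head = top `ceil(0.2 n)`, Tail = bottom `ceil(0.2 n)`,
  Medium = rest.
* **Cold start.** Train on FAERS-provenance positives only, hold out
  literature positives, report the unseen-CMM fraction of the test split.
* **Model comparison.** Two-sided paired t-tests on fold-wise metrics;
  zero-variance differences are flagged degenerate instead of producing an
  undefined statistic.

## MedDRA → TCM functional systems

The mapping layer is pure data: a YAML rule file with a 16-system
vocabulary and two rule classes. An exact Preferred-Term rule always beats
the System-Organ-Class default (first match wins) — this dual-input
precedence is what lets "Jaundice" map to the Liver system while "Nausea",
in the same gastrointestinal SOC, maps to Spleen and Stomach. Unmatched
terms are flagged, never dropped. On the vocabulary: enumerating five Zang
organs, six Fu organs and the four cross-cutting systems gives fifteen
names, yet the schema is a sixteen-category one; we ship the Pericardium
as the sixth Zang-side organ — the standard way Zang–Fu enumerations reach
twelve organs — and document this as an interpretation rather than
silently renumbering. The shipped rules cover the worked Preferred Terms
plus SOC defaults; the full expert rule list behind a production system is
institution-specific and the file is meant to be edited and versioned.

## The synthetic study

The generator plants exactly the signals the architecture presumes, so
that end-to-end learning is testable without any external download:

* mechanistic edges are independent Bernoulli draws at configurable
  densities (defaults: 60 CMMs, 150 compounds, 300 targets, 120 ADRs,
  a few compounds per CMM, a few targets per compound);
* node features sit around *orthonormal* cluster centroids shared across
  node types (Gaussian noise, sd 0.15), so feature cosine is ~1 within a
  cluster and ~0 across clusters;
* labels follow
  $P(\text{positive}) = \mathrm{logistic}(a + b\cdot\text{metapaths} + c\cdot\text{cosine})$
  with $a = \mathrm{logit}(\texttt{positiveRate})$ (baseline 0.002),
  $b = 1.5$, $c = 10$ — a strong planted signal whose Bayes-optimal AUROC
  (scoring by the true probability) is ≈0.98 at the default seed;
* FAERS-provenance positives get negative-binomial report counts
  (size 1.5) with mean increasing in meta-path support, literature-only
  positives (5%) get count 0.

What the generator does **not** emulate: reporting biases (stimulated
reporting, channeling), co-medication confounding, duplicate-report
structure beyond simple case versioning, and the heavy-tailed degree
distributions of real curated resources. Passing the learning-sanity
bands therefore shows that the implementation can recover a planted
mechanistic+semantic signal under the stated protocols — not that it
would attain any particular performance on real pharmacovigilance data.

## Problem sizes and numerical choices

The package's own checks run at desk scale: equation oracles on 1–2-head
toy configurations, protocol properties on graphs of tens of nodes, and
learning sanity as 3-fold cross-validation on the default 60/150/300/120
synthetic study with a scaled-down encoder (4 heads × dimension 8, 2
layers, gate hidden width 16, scorer hidden width 64, learning rate 2e-3,
at most 100 epochs with early-stopping patience 25). These sizes were
chosen so a full run completes in about a minute on one CPU while leaving
the planted-signal bands (held-out AUROC ≥ 0.9; permuted-label AUROC in
[0.4, 0.6]) comfortably attainable; the full-size defaults (8 × 72, 3
layers) remain the package defaults for real studies.

Further numerical conventions: softmax logits are stabilized by the
per-destination-group maximum; cosine similarity of a zero vector is 0;
min–max scaling of a constant feature returns 0; probabilities are clamped
away from 0/1 only inside the cross-entropy; `which.max` tie-breaking
makes threshold selection deterministic. Ties at the maximum case version
in curation cannot occur under the record-uniqueness contract and are
rejected as validation errors.

## Known limitations

* The encoder trains full-graph per step; graphs far beyond ~10⁵ edges
  would need the (provided but off-by-default) subgraph hooks and a
  compiled backend.
* Negatives are unobserved pairs, not verified non-associations; scores
  are relative signal strengths for triage, not risks.
* The TCM rule file is a starting vocabulary, not a clinical consensus
  instrument.
* Pooled out-of-fold score comparisons are exposed only via the fold-wise
  paired test; a pooled bootstrap is left to the analyst.
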