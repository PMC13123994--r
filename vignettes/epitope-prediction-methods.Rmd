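---
title: "Methods: graph-based conformational epitope prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-based conformational epitope prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Conformational B-cell epitopes are surface patches of an antigen that an
antibody binds; their residues are often distant in sequence and brought
together by folding, which is why sequence-window predictors
underperform structure-aware ones.  `epigcn` scores every residue of an
antigen chain with the probability of belonging to such a patch.

The model is a dual-branch network over per-residue features.

**Feature fusion.**  Three modalities are ingested per residue: a
sequence-language-model embedding, an inverse-folding embedding, and a
structural block derived from DSSP output plus backbone geometry.  Since
the raw widths are wildly unequal (thousands vs. tens of dimensions),
each modality is first projected into a common 256-dimensional space,
`ReLU(LayerNorm(W x + b))`, with its own parameters, and the three
projections are concatenated.  This prevents the widest embedding from
drowning the structural signal.

The structural block deserves one note.  Its components are a
nine-state secondary-structure one-hot (the eight DSSP states H, B, E,
G, I, T, S, `-`, plus an explicit *unknown* state), relative solvent
accessibility, and the four torsion terms
$[\sin\phi, \cos\phi, \sin\psi, \cos\psi]$.  That is 9 + 1 + 4 = **14**
columns, and the package consistently uses 14 even though this kind of
feature set is often loosely described as "13-dimensional" in the
literature; the arithmetic of the stated components is authoritative
here.  Undefined torsions (chain termini, missing backbone atoms) are
encoded as the off-circle pair (0, 0), which no real angle can produce,
so the network can distinguish "undefined" from any actual torsion.
rASA is absolute ASA divided by the residue type's theoretical maximum
(Tien et al. 2013 table; nonstandard residues use the table mean) and is
capped at 1 — exposed conformers can exceed the theoretical maximum, and
the cap keeps the feature in [0, 1].

**Attention branch.**  Additive attention computes scores
$e_i = V^\top \tanh(W x_i)$, weights $a = \mathrm{softmax}(e)$, and a
pooled context $Z = \sum_i a_i x_i$.  Pooling yields one vector per
protein, but prediction is per residue, so the branch output is the
broadcast concatenation $[x_i \,|\, Z]$: every residue sees itself plus
the globally attended context.  This is the minimal per-residue reading
of a pooled attention module and is a deliberate design choice.

**Graph branch.**  The residue graph uses three edge types over
positional indices: sequential ($0 < |i-j| < d_\text{seq}$), radius
(Cα distance $< d_r$ and $|i-j| \ge d_\text{long}$), and k-nearest
neighbours (among candidates with $|i-j| \ge d_\text{long}$, ties broken
towards the lower index, then symmetrized).  Defaults:
$d_\text{seq} = 3$, $d_r = 10$ Å, $k = 10$, $d_\text{long} = 5$, with
$d_\text{long} > d_\text{seq}$ enforced so mid-range separations
($3 \le |i-j| < 5$) carry no edge at all — short-range proximity is
already modelled by sequential edges and local propagation.  Strictness
follows the inequality symbols exactly: `<` for $d_r$ and
$d_\text{seq}$, `≥` for $d_\text{long}$.

The multi-scale GCN reads the *union* graph through its k-hop adjacency
stack: $A_k[i,j] = 1$ iff the shortest-path distance is $\le k$, plus
self-loops, so $A_1 \subseteq A_2 \subseteq A_3$ give nested receptive
fields.  "k-hop neighbourhood" is read as the BFS ball (within ≤ k
hops), computed on the union graph, because the GCN's symmetric
normalization $D^{-1/2} A D^{-1/2}$ presupposes self-inclusive
propagation.  Edge *types* are retained in the data model and the
export format, but propagation is untyped: the layer update has no
edge-type term, and a typed-weight variant is left as an explicit
non-goal rather than guessed.  Each layer runs three parallel kernels
(one per $A_k$, degrees computed per scale), concatenates them, and
fuses with a linear map + ReLU; two such layers are stacked.  A
residual mix $H = \lambda H_0 + (1-\lambda) H_\text{deep}$ combats
over-smoothing; $\lambda$ is kept strictly inside (0, 1) by the
logistic reparameterization $\lambda = \sigma(\theta)$, initialized at
0.5 ($\theta = 0$).  $H_0$ is the fused input passed through a
dimension-matching linear map when widths differ.

**Head and loss.**  The two branch outputs are concatenated per residue
and fed to an MLP (two hidden layers, 256 and 64 by default, ReLU,
dropout 0.3 during training) ending in one logit; training minimizes
mean binary cross-entropy (probabilities clipped at $10^{-7}$) with
Adam (lr $10^{-3}$, $\beta = (0.9, 0.999)$), one whole-protein graph
per step, early stopping on validation AUPR with patience 10.  The MLP
widths, dropout, Adam settings and early-stopping rule are the
package's own recorded defaults.  All weights are Glorot-uniform from a
recorded seed; LayerNorm uses $\varepsilon = 10^{-5}$.  The whole
network and its analytic backward pass are implemented in plain dense
linear algebra, and the test suite checks every gradient against
central finite differences.

## Labels, surface filter, class imbalance

Ground truth follows the heavy-atom contact rule: a residue is an
epitope iff any of its heavy atoms lies within 4 Å (inclusive — the
natural reading of "within") of any antibody heavy atom.  Hydrogens are
parsed but excluded from every distance computation.  Surface residues
are those with rASA ≥ 0.15 (boundary inclusive).

Epitope residues are rare (a few percent of surface residues in real
data), so two rebalancing mechanisms exist:

* `resample_hybrid()` — the standalone hybrid scheme: SMOTE-style
  synthetic positives (uniform interpolation towards one of the 5
  nearest positive neighbours) grow the minority class (doubling it by
  default), then negatives are randomly under-sampled to an exact 1:2
  positive:negative mix (33.33% positives).  A set already at or below
  1:2 passes through unchanged.
* Inside `epigcn_fit()` — per-epoch random under-sampling of negative
  residues in the *loss* to the same 1:2 mix.  Synthetic SMOTE residues
  have no coordinates and therefore no graph edges, so injecting them
  into message passing would be ill-defined; rebalancing the loss keeps
  the graph intact while matching the intended class mix.  This is the
  package's resolution of a genuinely open interaction between SMOTE
  and graph convolution.

## Threshold, metrics, statistics

The decision threshold maximizes F1 over all midpoints between
consecutive distinct validation scores (± infinity included); ties take
the lowest threshold, and if no threshold achieves positive F1 (e.g. no
positive labels) the threshold is $+\infty$, i.e. predict all-negative.
Zero-division conventions: precision 0 when nothing is called positive,
F1 0 when precision + recall is 0, MCC 0 when any denominator factor
vanishes.

ROC-AUC uses the rank (Mann–Whitney) formulation with half-credit ties;
AUPR is step-wise average precision (no linear interpolation, tied
scores processed as one block).  Model comparison uses the paired
DeLong test (placement-value covariance, two-sided normal reference)
for AUC and stratified bootstrap (positives and negatives resampled
separately, percentile 95% intervals) for threshold metrics.
Cross-validation is protein-level, 10 folds by default, fold sizes
within one protein of each other.  Two model-selection protocols are
implemented: the default picks the fold model with the best
fold-validation AUC (leak-free); an alternative "external" protocol
picks the fold model with the highest AUC on a supplied external test
set, which reproduces a selection style used in this literature but is
optimistic, since the test set then participates in selection.

## The synthetic study

`make_dataset()` generates everything the pipeline ingests:

* **Backbones** by internal-coordinate (NeRF) placement with idealized
  bond geometry and a trans peptide bond, from per-residue φ/ψ draws
  (alternating helical/extended stretches with 10° jitter), so torsion
  recovery has an exact ground truth.
* **Epitope patches**: all residues within a radius of a random centre,
  the radius set to the distance quantile matching the target positive
  fraction (default 0.15 per protein, a typical single-epitope fraction
  for small antigens) — labels are spatially contiguous, as real
  epitopes are.
* **Embeddings**: standard-normal rows with the positive-class mean
  shifted by δ (in pooled-SD units) along one fixed random unit
  direction per modality, shared across all proteins of a dataset.
  δ = 0 plants no signal.  The signal lives in the embedding branch, not
  the DSSP block, so modality-ablation experiments have a predictable
  direction.
* **Toy complexes** for the labeling rule: single-atom antigen residues
  spaced 12 Å apart with antibody pseudo-atoms at an exact gap from the
  chosen contact residues, giving a bit-exact expected label vector.

Default study conditions used by the tests and the acceptance script:
30 proteins of 30–60 residues, reduced embedding widths 64/32 (every
operation is width-agnostic; the real-data widths 2,560/512 are the
package defaults), δ = 2, projection width 32, GCN width 32, MLP
(32, 16), ≤ 40 epochs.  Under these conditions the trained model
reaches validation AUC ≥ 0.95, a label-permuted control stays near 0.5,
and validation AUC is monotone in δ over {0, 0.5, 1, 2}.

What the fixtures do *not* emulate: real embedding statistics beyond
dimensionality and class-conditional shift, side chains (backbones are
N/CA/C alanines), chain breaks, or multi-chain antigens (the package
operates per declared antigen chain).  Passing the synthetic suite
demonstrates that the machinery — featurization, graph construction,
optimization, evaluation — is correct, not that real-data benchmark
performance is reproduced; the latter would require the curated antigen
sets and frozen multi-billion-parameter embedders, which are outside
this package's scope.

## Numerical and I/O choices

* PDB parsing via bio3d; alternate locations resolve to the highest
  occupancy, ties to altloc "A", for deterministic parsing.  mmCIF is
  read by a minimal in-package `atom_site` tokenizer.  Only the first
  model of multi-model files is used; waters and ligands are dropped;
  nonstandard residues map to "X" but remain graph nodes.
* Internal residue indexing is 0-based and contiguous per chain; all
  graph math (|i−j|) uses positional indices, and author numbering is
  carried only for reporting.
* DSSP is consumed as a file (classic and mmCIF dialects); residues
  missing from DSSP get the unknown state and ASA 0; lowercase SS
  letters (the disulfide-cysteine convention) map to unknown.
* Prediction PDBs store score × 100 in the B-factor column (two
  decimals, hence round-trip accuracy 0.01).
* Checkpoints are single-file JSON (named tensors + config), so models
  are portable text.
* Determinism: every source of randomness (fixtures, initialization,
  shuffling, dropout, under-sampling, bootstrap) is derived from
  explicit seeds; identical seeds give bit-identical results.

## Known limitations

No internal secondary-structure/ASA algorithm (DSSP files are
required for those features; torsions are computed internally); no
edge-feature message passing; no biological-assembly expansion or
symmetry mates; per-chain operation only; the "external" model-selection
protocol is provided for comparability but intentionally not the
default.
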