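# epigcn

Residue-level prediction of **conformational B-cell epitopes** from protein
3D structures, for structural immunologists and vaccine-design pipelines
that need per-residue antigenicity scores on antigens without a solved
antibody complex.

## What it computes

An antigen chain is turned into a residue graph and each residue into a
fused feature vector; a dual-branch neural network then scores every
residue with the probability that it belongs to an epitope (a surface
patch contacted by an antibody).

**Inputs per antigen.** A structure (PDB or mmCIF, experimental or
predicted), a DSSP output file (optional), and two precomputed
per-residue embedding matrices: a sequence-language-model embedding
(nominally 2,560-d) and an inverse-folding embedding (nominally 512-d).
The embedding producers are treated as frozen upstream tools; the package
only ingests their matrices.

**Residue graph** G = (N, E, R) over positional indices i:

* sequential edges: 0 < |i − j| < d_seq,
* radius edges: ‖c_i − c_j‖₂ < d_r and |i − j| ≥ d_long (Cα coordinates),
* k-nearest-neighbour edges: j among the k nearest Cα neighbours of i
  with |i − j| ≥ d_long (symmetrized),

with defaults d_seq = 3, d_r = 10 Å, k = 10, d_long = 5.  The GCN
consumes the union graph through the k-hop adjacency stack
A₁ ⊆ A₂ ⊆ A₃ (within ≤ k hops, self-loops included).

**Node features.** Each modality m ∈ {sequence embedding, inverse-folding
embedding, DSSP block} is projected as
x ↦ ReLU(LayerNorm(W₀ᵐ x + b₀ᵐ)) into 256 dimensions and concatenated to
X₀ ∈ R^{N×768}.  The DSSP block is the concatenation of a 9-state
secondary-structure one-hot (8 DSSP states + unknown), relative solvent
accessibility rASA ∈ [0,1], and [sin φ, cos φ, sin ψ, cos ψ].

**Dual branch.**

* Additive attention: e_i = Vᵀ tanh(W x_i), a = softmax(e),
  Z = Σ a_i x_i; per-residue output [x_i | Z].
* Multi-scale GCN (two layers): per hop radius k ∈ {1,2,3},
  H^(k) = ReLU(D_k^{-1/2} A_k D_k^{-1/2} H W_k), fused by
  ReLU([H^(1)|H^(2)|H^(3)] W₁ + b₁); then the residual mix
  H = λ H₀ + (1 − λ) H_deep with learnable λ = logistic(θ) ∈ (0,1).

The branch outputs are concatenated per residue and an MLP head with a
sigmoid yields p_i ∈ (0,1).  Training: binary cross-entropy + Adam, with
per-epoch 1:2 positive:negative rebalancing of the loss, early stopping
on validation AUPR, and an F1-maximizing decision threshold.

**Evaluation stack.** Precision/recall/F1/MCC/balanced accuracy from
confusion counts, rank-based ROC-AUC, step-wise AUPR, protein-level
10-fold cross-validation, paired DeLong tests for correlated AUCs, and
stratified bootstrap confidence intervals.

**Labels and surface filter.** Ground truth follows the contact rule: a
residue is an epitope iff any of its heavy atoms lies within 4 Å of any
antibody heavy atom (`label_epitopes()`); surface residues are those
with rASA ≥ 0.15.  Standalone hybrid resampling (SMOTE-style minority
oversampling + random under-sampling to 1:2) is provided as
`resample_hybrid()`.

A synthetic-fixture generator (`make_dataset()`) builds
torsion-parameterised backbones, spatially clustered epitope patches,
class-conditional Gaussian embeddings with a plantable signal of effect
size δ, and toy antigen–antibody geometries, so the entire pipeline runs
and is tested end-to-end without any downloads.

## Worked example

```r
library(epigcn)

# a small synthetic study: 30 antigens, planted class signal delta = 2
spec <- fixture_spec(n_proteins = 30, d_seq_emb = 64, d_if_emb = 32,
                     delta = 2, seed = 42)
ds <- make_dataset(spec)

dims <- model_dims(d_seq_emb = 64, d_if_emb = 32, proj_dim = 32,
                   gcn_dim = 32, mlp_hidden = c(32, 16))
fit <- epigcn_fit(ds, dims = dims, epochs = 40, seed = 7)
fit
#> Dual-branch epitope model (additive attention + multi-scale GCN)
#>   fused width 96 (proj 32 x 3), GCN width 32, lambda 0.478
#>   trained 36 epochs on 30 proteins; threshold 0.1318
#>   validation: AUC 0.9801 AUPR 0.9321 F1 0.8810
```

The validation line is computed on held-out proteins: the model ranks
epitope residues above non-epitope residues with AUC 0.98 on this
synthetic study, and the stored threshold (0.13) maximizes F1 on the
validation split.  Scoring a new antigen:

```r
p <- predict(fit, ds[[1]])                       # per-residue P(epitope)
calls <- predict(fit, ds[[1]], type = "class")   # 0/1 at the threshold
write_prediction_pdb(ds[[1]]$structure, "A", p, "scored.pdb")  # B-factors
```

Evaluating any score vector against labels:

```r
evaluate_predictions(unlist(predict(fit, ds)),
                     unlist(lapply(ds, `[[`, "labels")))
```

A thin command-line wrapper with the same functionality
(`simulate`, `featurize`, `build-graph`, `train`, `predict`,
`evaluate`, `compare`) is installed at
`system.file("scripts", "epigcn", package = "epigcn")`.

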