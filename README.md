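# loopmodes

Many enzymes carry a catalytic loop (typically 10–21 residues) that swings
shut over the active site when substrate binds. A long-standing question in
structural enzymology is whether these seemingly local loop reconfigurations
are induced by the ligand, or whether they ride on the collective, low-energy
("soft") modes of motion that the overall fold encodes even in the apo state.
`loopmodes` implements the full analysis pipeline for answering that question
quantitatively from crystal structures alone, for structural biologists and
computational biophysicists with an ensemble of open/closed structures of an
enzyme and a loop definition in hand.

## What it computes

For each enzyme the pipeline compares two descriptions of the loop motion:

* **Experimental.** The ensemble of crystal structures is superposed with an
  iterative Kabsch algorithm; the 3N-dimensional positional covariance matrix
  `C = 1/(m−1) Σ_s ΔR^s (ΔR^s)ᵀ` is diagonalized into principal components
  `p⁽ⁱ⁾` with variance fractions `f_i = σ_i / Σ_j σ_j`. For a two-structure
  (apo/holo) pair, PC1 reduces to the normalized open→closed deformation
  vector.
* **Computational.** The anisotropic network model (ANM) on the Cα trace of a
  representative open structure: uniform springs `γ` between residues within
  `r_cut` (default 15 Å), Hessian superblocks
  `H⁽ⁱʲ⁾ = −γ Γ_ij R_ij R_ijᵀ / |R_ij|²`, eigendecomposed into 3N−6 internal
  modes `u⁽ʲ⁾` with stiffness eigenvalues `λ_j` (mode 1 = softest).

They are compared through

* the **overlap** `O_1j = |p⁽¹⁾ · u⁽ʲ⁾|` and **cumulative overlap**
  `CO₁ᴶ = (Σ_{j≤J} O_1j²)^{1/2}` (equal to 1 over the complete basis);
* the **loop (segment) overlap**: the same cosine on the renormalized
  3s-component loop subvectors — orientation only;
* the **weighted-average overlap** `<O|s>_p = Σ_j w_j O_sj / Σ_j w_j` over a
  window of p modes with weights `w_j = ‖u_s⁽ʲ⁾‖²/λ_j`, which folds the
  *magnitude* of the predicted loop motion back in;
* a **random-mode null**: orthonormal Gaussian mode sets (rigid-body space
  projected out) carrying the same eigenvalues, giving per-sequence-window
  difference profiles `Δ<O|s>_p` and the **enhancement factor**
  `<O|loop>_p^ANM / <O|loop>_p^random`;
* per-residue square fluctuations from selected modes vs. experimental
  B-factors (Pearson r), and the entropy-based mode **collectivity** κ.

A synthetic-data module generates compact toy folds with a protruding loop
and plants conformer ensembles along a chosen ANM mode, so every statistic is
testable against a known ground truth with no downloads.

## Worked example

```r
library(loopmodes)

fold  <- make_toy_fold(n_residues = 60, loop_length = 11, seed = 1)
truth <- planted_truth(loop = fold$loop, amplitude = 2, noise_sigma = 0.3,
                       m = 20, seed = 7)
ens   <- plant_ensemble(fold$model, truth)           # 20 conformers along ANM mode 1

aligned <- iterative_superpose_ensemble(ens)
pca     <- ensemble_pca(aligned)
modes   <- anm_modes(build_hessian(fold$model, r_cut = 15))
cs      <- attr(ens, "coefficients")
dv      <- deformation_vector(ens[[which.min(cs)]], ens[[which.max(cs)]])

cat(sprintf("PC1 variance fraction: %.2f\n", pca$fractions[1]))
cat(sprintf("PC1 / ANM1 overlap:    %.3f\n",
            overlap(pca$vectors[, 1], modes$vectors[, 1])))
cat(sprintf("loop overlap (ANM1):   %.3f\n",
            segment_overlap(dv, modes, fold$loop, keys = modes$keys, j = 1)))
print(enhancement_analysis(dv, modes, fold$loop, p = 10, n_random = 100,
                           seed = 42))
```

prints

```
PC1 variance fraction: 0.90
PC1 / ANM1 overlap:    0.996
loop overlap (ANM1):   0.996
enhancement_analysis: s = 11, p = 10, 100 random sets
  loop <O|s>_p: ANM 0.740, random 0.145 (se 0.00776) -> enhancement 5.10
```

Read: the dominant experimental variation (90% of ensemble variance) is
essentially the softest ANM mode (overlap 0.996); at the loop the soft-mode
weighted-average overlap is 5.1× what random modes of the same spectrum
achieve — the planted loop–mode coupling is recovered.

The same analysis runs from a config file (examples for ten real enzyme
open/closed pairs ship under `inst/extdata/configs/`):

```sh
Rscript inst/cli/loopmodes.R synth --n-residues 60 --loop-length 11 --m 20 --seed 7 --out synth/
Rscript inst/cli/loopmodes.R analyze --config synth/config.yaml --out results/
```

which writes `table1.csv` (RMSD/tip-motion deviation metrics), `table2.csv`
(loop overlaps, enhancement factor), overlap and window profiles, mode sets
and a run log.

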