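---
title: "Quantifying the coupling between catalytic-loop motions and intrinsic collective dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the coupling between catalytic-loop motions and intrinsic collective dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopmodes)
```

## The question and the two sides of the comparison

Catalytic loops close over enzyme active sites when substrate binds. If that
reconfiguration were purely ligand-induced, nothing about it should be
predictable from the apo structure alone. The alternative hypothesis is that
the fold itself encodes soft, collective modes of motion whose local
component at the loop already points along the open→closed direction.
`loopmodes` quantifies this by comparing, for one enzyme at a time:

* **the experimentally observed deformation** — either PC1 of a superposed
  crystal-structure ensemble, or, for an apo/holo pair, the normalized
  3N-dimensional open→closed difference vector (`deformation_vector()`); and
* **the predicted intrinsic motions** — the normal modes of an anisotropic
  network model (ANM) built on the Cα trace of a representative unliganded
  structure (`build_hessian()`, `anm_modes()`).

Both live in the same 3N-dimensional space once structures are reduced to
one Cα per residue and a shared residue correspondence, so they can be
compared with cosines.

## Models and statistics

**Ensemble PCA.** Structures are superposed by an iterative Kabsch procedure:
each model is fitted onto the running mean over the residues resolved in
*every* member (listwise deletion; overlap statistics require one fixed common
dimension), the mean is recomputed, and iteration stops when the mean moves
less than `tolerance` (default 1e-5 Å RMS, `max_iter` 100; the first model's
frame seeds the mean). The covariance `C = 1/(m−1) Σ ΔR^s ΔR^sᵀ` is
diagonalized; eigenvalues below 1e-10 of the largest are truncated and
variance fractions are reported over the retained modes. The 1/(m−1)
normalization is a convention only — fractions and every overlap statistic are
invariant to it.

**ANM.** Residues within `r_cut` of each other are joined by springs of
uniform constant `γ`. The off-diagonal 3×3 Hessian superblock for a connected
pair is `−γ R_ij R_ijᵀ/|R_ij|²`; diagonal superblocks enforce translation
invariance. A connected, non-collinear network has exactly six zero
eigenvalues (rigid-body motions), discarded at a relative threshold of 1e-8;
any surplus of near-zero eigenvalues is reported as a degeneracy rather than
silently dropped. `γ` cancels from every statistic the package reports
(overlaps, correlations, collectivity, enhancement), so it defaults to 1.
`r_cut` does matter; the default is 15 Å, the convention of the Cα-ANM
lineage, and per-enzyme checks against published loop overlaps treat
{13, 15, 18} Å as a sensitivity sweep.

**Overlap statistics.** With `p` the experimental unit vector and `u⁽ʲ⁾` the
modes:

* overlap `O_1j = |p · u⁽ʲ⁾|`;
* cumulative overlap `CO₁ᴶ = (Σ_{j≤J} O_1j²)^{1/2}`, which reaches 1 over the
  complete 3N−6 basis for any reference orthogonal to the rigid-body space
  (the package's data-free acceptance quantity). Because published
  "explained variance" readings of this curve are ambiguous between CO and
  CO², profiles carry both columns;
* loop overlap: the same cosine on the renormalized 3s-component loop
  subvectors — purely orientational, independent of how much amplitude either
  vector puts on the loop;
* weighted-average overlap over a window of `p` modes,
  `<O|s>_p = Σ w_j O_sj / Σ w_j`. The weighting is a genuine design choice:
  the defining requirement is that magnitudes of predicted loop motion enter,
  and that random surrogate modes can inherit the real eigenvalues. The
  default `w_j = ‖u_s⁽ʲ⁾‖²/λ_j` multiplies the share of mode amplitude on the
  segment by the mode's thermal amplitude `1/λ_j`; `"amplitude"`
  (`‖u_s⁽ʲ⁾‖²` only) and `"uniform"` schemes are selectable, and results that
  depend on the choice should be read as ranges across schemes.

**Random-mode null.** `random_modeset()` draws i.i.d. Gaussian 3N vectors,
projects out the six rigid-body generators, Gram–Schmidt-orthonormalizes in
order, and pairs the r-th vector with the r-th real eigenvalue. The null
answers: how much weighted-average loop overlap would modes with the same
spectrum but no structural information achieve? `enhancement_analysis()`
slides an s-residue window along each chain (step 1, never across chain
boundaries), reports `Δ<O|s>_p` = ANM − random-baseline per window, and the
enhancement factor at the loop window. One set of `n_random` draws (default
100, with the mean's standard error reported) is reused across windows, so
profiles are smooth in the window index.

**Per-residue fluctuations and collectivity.** Square fluctuations
`Σ_j |u_i⁽ʲ⁾|²/λ_j` over a mode subset (default: mode 1 alone, matching how
theoretical temperature factors are usually displayed; any subset, including
all modes — where the result equals the diagonal of the Hessian pseudoinverse
— is available) are compared to experimental B-factors by Pearson
correlation, which absorbs the unknown kT/γ and 8π²/3 scales. Collectivity
`κ = exp(−Σ q_i ln q_i)/N` on normalized squared residue amplitudes
summarizes how delocalized a mode is (1 = uniform, 1/N = single residue).

## Structure handling choices

PDB files are read through `bio3d`; the package keeps one Cα per residue
keyed by (chain, residue number, insertion code). Alternate locations resolve
to the highest occupancy, ties alphabetically; residues lacking a Cα are
skipped with a warning, never imputed; HETATM Cα records are accepted only
for common modified amino acids (MSE and kin), so ligands, ions and waters
never enter the network — which also means an ANM of a holo structure is
automatically computed "with the cofactor removed". Only model 1 of
multi-model files is used unless asked otherwise. All correspondence is by
residue key, never by array position, and no sequence-alignment mapping is
attempted: mixed-species ensembles require the user to renumber.

## The synthetic generator: what it does and does not emulate

`make_toy_fold()` builds a self-avoiding Cα chain (bond length 3.8 Å)
compacted into a globule of radius ∝ n^(1/3) with one protruding hairpin —
the designated "loop" — which, having fewer contacts, naturally attracts
soft-mode amplitude. `plant_ensemble()` then displaces the fold along one ANM
mode with per-conformer coefficients `c_s = ±Uniform(0.5, 1)` (half negative
"open", half positive "closed", so representative-pair extraction is well
posed), adds isotropic Gaussian noise, and sets B-factors proportional to the
planted per-residue variance. Defaults — 60 residues, 11-residue loop, m = 20
conformers, 2 Å RMS per-residue amplitude at |c| = 1, 0.3 Å noise — give a
dominant PC1 (≈0.9 of the variance) over a realistic noise floor; the
amplitude-to-noise ratio is comparable to a loop moving several Å against
sub-Å lattice variation.

The generator emulates the *statistical* structure the method assumes: one
dominant collective deformation with loop participation plus isotropic noise.
It does not emulate real protein geometry (no side chains, no secondary
structure, bonds stretch when the planted amplitude is large — flagged by a
warning), anisotropic or correlated crystallographic noise, missing residues,
or ensembles that mix distinct ligation states with different mechanisms.
Passing recovery tests therefore show the statistics are implemented and
powered as designed, not that any particular real enzyme will show coupling.

## Numerical and design choices

* Dense `eigen()` is used for all decompositions; at the package's intended
  problem sizes (3N ≲ 1500) a full decomposition takes seconds and gives the
  complete basis that cumulative-overlap checks need.
* Kabsch fits exclude reflections (determinant forced to +1) and reject
  point sets of rank < 2.
* Degenerate loop subvectors (near-zero norm on a window) raise classed
  errors; profile code logs and skips such windows instead of fabricating
  values.
* Ties in altloc occupancy break alphabetically; ties in "highest loop
  overlap" resolve to the softer mode via `which.max`.
* **ANM input structure.** The real-data protocol computes the ANM on the
  representative open (apo) structure, restricted to the ensemble
  correspondence so every comparison shares one basis. For *synthetic*
  ensembles the config option `anm: structure: ensemble_mean` exists because
  a planted ensemble is generated symmetrically about its reference fold: an
  extreme conformer of a 60-residue toy displaced 2 Å RMS along a localized
  mode has a measurably rewired contact network, while the ensemble mean
  estimates the generative topology. Real crystal structures, being larger
  and topology-preserving across ligation states, use the open structure —
  as the per-enzyme example configs do.
* Loop metrics for multimers are reported for the configured chain
  (conventionally A) and per chain in the window profiles; the "loop tip" is
  defined operationally as the loop residue with maximal Cα displacement
  between the representative pair after whole-protein superposition.
* Table-style summaries restrict the "overlap ≥ 0.5" scan to the softest 10
  modes (`n_soft_modes`, configurable).
* Loop overlaps are computed against the open→closed deformation vector by
  default, with PC1-based variants emitted alongside, since published usage
  varies between the two for multi-structure ensembles.

## Test problem sizes and the optional full-ensemble check

The test suite exercises everything on 30–60-residue toys (full analysis in
seconds) with 20-conformer planted ensembles, 50-seed replicate checks for
the enhancement null, and 100–2000-draw Monte-Carlo checks of the random-mode
model; these sizes were chosen so the whole suite characterizes the
statistics well while remaining quick to run routinely. Checks against
published per-enzyme numbers (deviation metrics, loop overlaps, collectivity,
B-factor correlation, enhancement factors) load the named PDB entries via the
fetch cache and fail with an explicit message when the entries are
unavailable. Reproducing published PC variance fractions (e.g. 53%/90%/71%/52%
for the four case-study enzymes) additionally requires the full curated
multi-structure ensembles rather than representative pairs; that check is
documented here as an optional validation for users who assemble those
ensembles, not a gating test — the gating test verifies the fraction
machinery itself (well-formed, descending, summing to 1).

## Known limitations

* Exact residue-key matching only; no alignment-based correspondence.
* No internal-coordinate or weighted PCA variants; no distance-dependent
  force constants or GNM; no MD trajectory readers (the PCA accepts any
  conformer list, but trajectory formats are out of scope).
* The weighted-average overlap weighting is a documented convention, not a
  uniquely determined formula; compare schemes before interpreting small
  differences in enhancement factors.
* Enhancement factors on short chains (toys) have appreciable Monte-Carlo
  spread; the reported standard error of the random baseline should be
  propagated when comparing enzymes.
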