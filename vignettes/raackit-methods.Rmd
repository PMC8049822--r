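---
title: "Classifying proteins over reduced amino acid alphabets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying proteins over reduced amino acid alphabets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`raackit` builds binary protein classifiers from sequence composition
alone. The pipeline has four stages:

1. **Alphabet reduction.** A reduction scheme is an ordered partition of
   the 20 standard amino acids into *k* groups (2 ≤ k ≤ 19 in the bundled
   family); every residue is rewritten as its group's label (the group's
   first letter, a fixed convention so that feature names are
   deterministic). Reduction suppresses mutation-level noise while keeping
   the physicochemical signal that determines fold and function. The
   bundled 18-scheme ladder was derived by maximizing the mutual
   information of paired residue contacts; its coarse end groups aromatics
   (FWY), aliphatics plus sulfur (CILMV), acids (DE), bases (HR), small
   residues (AT) and polar residues (NQS), and its size-19 scheme keeps
   only Q and S merged.
2. **N-peptide composition.** A reduced sequence of length *L* becomes the
   vector of overlapping *N*-mer frequencies, `count(w) / (L - N + 1)` for
   every length-*N* word *w* over the *k* labels, *N* ∈ {1, 2, 3}; the
   vector has *k*^*N* entries in a fixed lexicographic order (label order
   of the scheme, first position most significant) and sums to 1. The
   denominator is the number of windows, which the source material leaves
   implicit; sequences shorter than *N* are excluded per run rather than
   zero-padded, so no row ever carries an undefined frequency.
3. **ANOVA ranking and incremental feature selection (IFS).** Each feature
   is scored with the standard two-group one-way ANOVA F (between-group
   mean square over within-group mean square, df 1 and n−2). The printed
   formula in the source describes a ratio of two within-group variances,
   which is not the quantity its own text describes ("ratio of features
   between and within groups"); this package implements the standard F.
   Features with zero within-group variance but distinct means get
   F = +∞ and rank first; all-constant features get 0; ties keep column
   order. IFS then evaluates cross-validated accuracy on growing prefixes
   of the ranking (step 1) and keeps the smallest prefix attaining the
   maximum.
4. **RBF-SVM.** A C-SVC with kernel `exp(-gamma * ||x - z||^2)`, trained by
   an in-package SMO solver (see "Numerical choices"). C and gamma are grid
   searched inside the open box 2⁻⁵ < C < 2¹⁵, 2⁻¹⁵ < gamma < 2³; the
   default lattice steps exponents by 2 (10 × 9 = 90 candidates).
   Performance is reported as Sn = TP/(TP+FN), Sp = TN/(TN+FP),
   Acc = (TP+TN)/n, plus the ROC over pooled out-of-fold decision scores
   and its trapezoidal AUC (equal to the Mann–Whitney statistic).

A full run scans every (scheme, N) combination by cross-validated
accuracy, tunes C and gamma on the winning encoding, runs IFS, and trains
a final model whose serialization carries its provenance (scheme notation,
N, selected features), so predictions on a differently encoded matrix fail
loudly.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| folds | 5 | convention for this problem family; stratified because the motivating benchmark is ~1:6 imbalanced |
| decision threshold | 0 | the SVM's native boundary; no threshold tuning anywhere |
| grid (full) | C = 2^{-4..14}, gamma = 2^{-14..2}, step 2 | strictly inside the stated open box; 90 fits is desk-scale |
| scan config | C = 2⁵, gamma = "scale" | a single moderate configuration for the 54-row scan; `"scale"` resolves to 1/(p · mean column variance) per encoding so that alphabets of very different dimensionality are compared at comparable kernel bandwidth (a fixed numeric gamma systematically favors arbitrary dimensionalities) |
| scan cv_repeats | 3 | model selection over 50+ highly correlated encodings is sensitive to single-shuffle fold noise (~1 pooled sample); averaging over three seeded shuffles removes most of it at 3x scan cost |
| IFS grid | winner's tuned (C, gamma) | the source is silent on per-prefix re-tuning; a fixed configuration keeps IFS at one CV per prefix, and a grid can be passed when wanted |
| class weights | none | not used by the source; stratification handles the imbalance at fold level |

Tie-breaking is deterministic everywhere: grid search prefers smaller C
then smaller gamma; the scan prefers smaller alphabet then smaller N
(simpler encodings); IFS prefers fewer features.

## The synthetic generator

Real antioxidant-protein benchmarks are external downloads, so every
stage is exercised on generated FASTA data with a *planted, reduced-space*
signal. Sequences are drawn from a first-order Markov chain over the
reduced symbols of a chosen scheme and lifted to amino acids uniformly
within each group; the negative class uses uniform transition rows, while
the positive class tilts `n_biased` randomly chosen reduced dipeptides by
`effect` (compensated evenly across the rest of the row; infeasible tilts
are rejected with the offending magnitude). Because the lift is uniform,
no information distinguishes the classes below the planted granularity —
the reduction step is what exposes the signal. With `effect = 0` the
classes are exchangeable by construction.

Defaults: lengths uniform on 50–300 residues (typical single-domain
range), `n_biased = 20` of the 100 size-10 dipeptide cells,
`effect = 0.12` (roughly doubling a tilted transition probability). The
strong-signal setting was calibrated once against its two stated
requirements — near-ceiling (≥ 0.95) cross-validated accuracy under the
planted encoding *and* sub-saturation, so that coarser alphabets do not
tie at accuracy 1.0 — and then frozen. The benchmark-shaped spec (40
positives vs 240 negatives) mirrors the motivating dataset's ~1:6
imbalance at desk scale.

What a green test does establish: the encoder, ranking, selection and
evaluation machinery recover a known compositional signal end to end, at
the correct granularity most of the time, with calibrated null behavior
(effect 0 stays in the 0.35–0.65 balanced-accuracy band). What it does
not: anything about real antioxidant biology — motifs, domains, homology
structure, length/composition confounds — which the generator
deliberately does not emulate.

## Numerical choices

* **SMO solver.** No SVM implementation ships with the target
  environment, so the dual C-SVC problem is solved in compiled code:
  sequential minimal optimization with second-order working-set selection
  (maximal violating pair *i*, then the *j* maximizing the quadratic gain),
  stopping tolerance 1e-3 on the KKT violation, bias from the free support
  vectors (midpoint of the KKT bounds when none are free). On precomputed
  kernels of a few hundred samples this agrees with a reference SVC
  implementation to ~1e-3 in decision values (the shared optimizer
  tolerance). Kernel matrices are built from a squared-distance matrix
  computed once per feature set via the Gram matrix (BLAS), reused across
  folds, configurations and gamma values; IFS updates the distance matrix
  incrementally with one rank-one term per added feature.
* **F-score edge cases.** 0/0 (all-constant feature) is defined as 0, not
  NaN; positive/0 is +∞, not an arbitrary cap, so perfect separators rank
  first deterministically.
* **ROC ties.** Thresholds sweep distinct score values; tied scores move
  as a block, so the curve's trapezoids reproduce the ½-tie convention of
  the rank-statistic AUC exactly.
* **Determinism.** All randomness (fold shuffles, generator draws) flows
  through seeds derived from a single root seed; the global RNG state is
  saved and restored around every seeded region. Artifact files are
  written with fixed newline conventions, so identical configurations
  reproduce byte-identical scan tables, reports and models. Model JSON
  stores numerics at 17 significant digits, enough to round-trip IEEE
  doubles exactly.

## Known limitations

* **Planted-scheme identifiability.** Selecting the planted (scheme, N)
  as the arg-max of cross-validated accuracy over 54 correlated encodings
  is intrinsically noisy. Two structural facts cap the recovery rate of
  this generator class: (i) additive count bias survives coarsening —
  merging two alphabet groups sums their feature counts, which preserves
  the class difference — so the schemes one merge below the planted one
  retain most of the signal and occasionally win (or, at saturation, tie
  at accuracy 1.0 and win the smaller-alphabet tie-break); (ii) finer
  schemes express the planted signal exactly (the ladder above size 10
  refines it), losing only a dimensionality penalty of similar size to CV
  noise. Measured under the shipped defaults, recovery is ~6/10 replicates
  rather than the 9/10 the acceptance criterion asks for; the criterion is
  asserted as stated and left red rather than weakened, and the
  surrounding clauses (winner accuracy, null calibration) hold.
* **N = 3 planted bias** would need a second-order chain; the generator
  supports orders 1 and 2 (encoding and evaluation of N = 3 features are
  unaffected).
* The SMO solver assumes the full kernel matrix fits in memory —
  appropriate for desk-scale datasets (thousands of sequences), not for
  proteome-scale corpora.
* Only the 18-scheme family ships with the package; the full external
  scheme catalog can be supplied as a plain-text file
  (`type size clusters` per line) via `load_catalog()`.
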