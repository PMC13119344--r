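---
title: "Methods: HCDR3 blueprint classification and disulphide geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HCDR3 blueprint classification and disulphide geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbblueprint)
```

This vignette is the package's account of the science it implements: the
models, the parameters that matter, the numerical choices made where the
design was genuinely open, and what the synthetic fixtures do and do not
demonstrate.

## The blueprint dichotomy and its descriptors

A VHH's HCDR3 loop either folds back over the framework-2 surface that in
conventional antibodies would face the light chain ("kinked") or projects
into solvent ("extended"). Everything in this package runs on the AHo
numbering, a fixed 149-slot structural alignment; the regions are FR1 1–26,
HCDR1 27–42, FR2 43–56, HCDR2 57–69, FR3 70–107, HCDR3 108–138, FR4
139–149, all ranges closed.

Six descriptors characterize the blueprint:

* **Stem pseudo-angles** (`alpha_n`, `tau_n`, `alpha_c`, `tau_c`, degrees).
  At each HCDR3 stem — AHo 105–108 (N) and 135–138 (C) — `alpha` is the
  signed four-Cα pseudo-torsion over the window and `tau` the three-Cα
  pseudo-bond angle over the window's first three positions.
  *Semantics decision.* The published parameter table reports `alpha` means
  of −62.09° and −13.31°, impossible for an arccos output, while the `tau`
  means (126.22°, 109.68°) are textbook bond-angle values. We therefore
  assign the signed torsion to `alpha` and the arccos bond angle to `tau`,
  the established α/τ stem-angle convention; the bond-angle anchor within
  each window (`tau_anchor`) is configurable because only the windows
  themselves are pinned down.
* **Contact density** (dimensionless). Heavy-atom pairs within 4.5 Å
  between non-stem HCDR3 residues and FR2 residues at AHo 44–55, divided by
  the full HCDR3 length (residues present at 108–138). Stem residues 108,
  109, 136–138 are excluded from counting but kept in the length.
  Hydrogens are never counted: most experimental models lack them.
* **FR2 key-position RSA** (`fr2_rsa_key`, fraction). Mean relative solvent
  accessibility of AHo 44 and 54, i.e. residue SASA divided by the
  theoretical Gly-X-Gly maximum for that residue type (Tien et al. 2013
  theoretical values, shipped as `max_asa_gxg()`). RSA is deliberately not
  clipped at 1: mildly super-exposed residues are real and informative.

### The Shrake–Rupley SASA

SASA is computed from scratch: each atom's accessible sphere (van der Waals
radius + 1.4 Å probe) is sampled at 960 quasi-uniform Fibonacci-spiral
points, and a point is accessible when outside every neighbour's accessible
sphere (neighbour search capped at `r_i + r_j + 2·probe`). The radii table
is a single per-element set (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å),
editable as packaged TSV; per-element radii can differ from chemotype-aware
sets by a few percent, which is within the tolerance of the RSA feature's
role in the classifier.

One numerical choice deserves emphasis: the quadrature grid is laid out in
a *molecule-intrinsic frame* built from the structure's own atoms (first
atom, last atom, and the atom farthest from their axis). A lab-fixed grid
makes SASA rotation-dependent at the quadrature-error level (~0.1 Ų per
atom); the intrinsic frame makes it exactly covariant, so every descriptor
is invariant under rigid motions to machine precision — a property the test
suite asserts at 1e-6.

## The structure classifier

`P(kinked) = σ( Σᵢ wᵢ (xᵢ − μᵢ)/σᵢ + b )` over the six descriptors, with
the published means, SDs, weights and intercept (b = −0.352) shipped in
`nbframe_structure_params()`. Two closed forms pin the implementation down:
features exactly at the training means give σ(−0.352) ≈ 0.4129, and +1 SD
of contact density (w = +1.86) gives σ(1.508) ≈ 0.8187. Probabilities are
discretized by `call_blueprint()` under two published schemes: deployment
(extended < 0.3, kinked > 0.7) and evaluation (extended < 0.25,
kinked > 0.55). Saturated probabilities (exactly 0 or 1 in floating point)
are accepted and binned to their pole.

## Hallmarks and the sequence classifier

For every framework (position, amino-acid) pair, enrichment between kinked
and extended training sequences is `Log2FC = log₂((f_K+ε)/(f_E+ε))` with
ε = 0.5/N. Candidates must pass a two-sided Fisher exact test at p < 0.05
and carry ≥ 30 observations summed over both classes; survivors are ranked
by |point-biserial correlation with the class label| × |Pearson correlation
with the structure-classifier probability| and the top 20 kept. CDR
positions are excluded by construction: engineered libraries make CDR
composition biased and uninformative about the framework-encoded blueprint.

Choices worth recording:

* **Fisher convention.** Two-sided p-values use the tie-inclusive
  minimum-likelihood convention (the behaviour of standard statistical
  packages; `stats::fisher.test()` behind the package surface). The test
  suite cross-checks it against a full hypergeometric enumeration for all
  tables with n ≤ 40. Borderline hallmarks can move under other two-sided
  conventions; the threshold is a plain argument (`p_max`).
* **Packaged table self-consistency.** The shipped 20-row hallmark table
  carries class percentages printed to one decimal; recomputing Log2FC from
  them reproduces the printed values within 0.03 (the propagation bound of
  that rounding), exactly at two decimals for the rows whose percentages
  round cleanly.
* **Standardization order.** The sequence model standardizes the *encoded*
  (zero-masked) features, as its defining equation is written; gaps and
  unknown residues never match a hallmark.
* **Sequence weights.** The original fitted sequence-classifier weights
  were never published. The packaged `nbframe_sequence_params_synthetic()`
  is fitted (by `scripts/make_sequence_params.R`) on a synthetic training
  set whose hallmark positions follow the packaged per-class carrier
  percentages, with class sizes 478/351 — it demonstrates the format and
  pipeline and must not be mistaken for the original parameterization.

### Soft-label training

The trainer minimizes cross-entropy against *continuous* targets in [0, 1]
(structure-classifier probabilities), optionally with an L2 penalty, by a
damped Newton iteration: deterministic, starting from zero weights, halving
the step until the objective does not increase, declaring convergence when
the gradient max-norm falls below `tol` (default 1e-8). On hard 0/1 labels
this reduces to ordinary logistic regression, which is how it is validated:
coefficients agree with an independent IRLS fit (`glm`) to better than 1e-4
relative. Two analytic fixed points are also asserted: uniform 0.5 targets
yield the zero solution in zero iterations, and the loss trace is
monotonically non-increasing.

## Disulphide geometry

Cysteine pairing is decided on ground-truth SG–SG distances: pairs within
[1.42, 3.00] Å are candidates; a non-overlapping bonded set is selected
greedily in ascending distance. The greedy *order* is a design choice (the
source convention is unstated): shortest contacts are the physical bonds,
and ties — which cannot occur between real sulphur positions — break toward
the lower residue-index pair. The test suite checks agreement with an
exhaustive maximum-cardinality, minimum-distance matching on 200 seeded
instances built the way cysteines actually occur (well-separated bonded
pairs, lone cysteines, occasional sub-3 Å triangles). Uniform point clouds
are deliberately not used: chains of three or more mutually-bonded-range
sulphurs are sterically impossible in structures, and only in such
arrangements can greedy selection and global matching disagree.

The loss terms, all on the prediction with the pairing fixed by the ground
truth:

| term | form | constants |
|---|---|---|
| SG–SG | hinge into band; non-bonded hinge repulsion | [1.84, 2.26] Å; ≥ 4.1 Å |
| Cβ–Cβ | flat-bottom hinge | [2.85, 4.50] Å |
| S–S–Cβ angle | Huber on both angles per bond | target 2.0 rad, δ = 0.04 |
| χ₃ dihedral | −log of a two-mode wrapped Gaussian mixture | modes +1.66012, −1.79512 rad; σ = 0.5 |
| distogram | symmetric cross-entropy, both pair orders | one-hot target at the 2.05 Å bin |

The composite is `0.5·L_SG + 0.25·L_CB + 10⁻⁴·(L_ang + L_χ3) + 1·L_disto`,
scaled by an annealing factor `min(step/100000, 1)`. The 10⁻⁴ coefficient
is applied to *both* angular terms — the source expression is typographically
ambiguous, and reading the coefficient as covering the parenthesized pair
keeps both angular terms on the same, deliberately weak scale; all five
weights are exposed in `disulphide_config()` regardless. The distogram
binning follows the convention of the architecture family this objective
was designed for: 64 equal-width bins spanning [2.3125, 21.6875] Å with
open outer bins, so 2.05 Å falls in the first bin; the target is one-hot
(the defining text says "a target bin"). Degenerate dihedral geometry
(collinear triples) raises an error rather than silently scoring zero.

Analytic anchors asserted by the tests: χ₃ loss ≈ 0 at either mode and
5.180 at φ = 0; uniform logits give 2·ln 64 ≈ 8.3178 per bond; ideal
geometry (d = 2.05, r = 3.8, θ = 2.0, φ = 1.66012) puts every term below
1e-6; step 0 gives total exactly 0; and hinge slopes are ±1 outside their
bands.

## Evaluation

Predictions are compared to references after a single Kabsch superposition
on the shared framework backbone atoms (N, CA, C, O — "CO" in tabulated
backbone definitions is read as the carbonyl oxygen); per-region RMSDs are
then computed under that one transform, never refitted per region, so loop
RMSDs reflect placement relative to the framework. Blueprint recovery bins
both sides with the evaluation thresholds and reports the fraction of
matching bins; pairs whose *reference* bin is unclear are excluded from the
headline percentage by default (reported separately), since scoring a
prediction against an ambiguous reference is a policy question — the flag
`include_unclear_ref` flips it. NCDB recovery uses the 2.46 Å SG–SG
threshold (the 99th percentile of experimental disulphide distances);
expected pairs come from reference SG distances below 3 Å; a structure with
several non-canonical pairs counts as recovered only if *all* are, with the
per-pair rate also reported. Confidence intervals are percentile bootstrap
(10,000 resamples by default) — the plain nonparametric choice, not BCa.
Distillation-style filters are pure functions: mean HCDR3 confidence ≥ 0.7,
and C(i)–N(i+1) peptide bonds within 1.33 ± 0.3 Å with AHo gaps treated as
chain breaks.

## What the synthetic fixtures are, and are not

The generators exist so that every code path runs, with known answers, on
no external data:

* `make_stem_trace()` embeds four Cα atoms realizing any requested
  (torsion, bond-angle) pair to 1e-6°, with seeded random embeddings.
* `make_ideal_disulphide()` realizes requested SG–SG distance, both
  S–S–Cβ angles, χ₃ and Cβ–Cβ distance simultaneously by solving for the
  shared Cβ–SG bond length; an inconsistent request errors.
* `make_toy_vhh()` builds a serpentine framework whose fourth 14-residue
  row is exactly FR2, stem windows carrying the classifier's training-mean
  angles (so angles contribute nothing and the blueprint call is driven by
  contacts and burial, as in real domains), an HCDR3 that either caps FR2
  at contact range or projects away, and cysteine pairs with exact 2.05 Å
  SG separations. The kinked/extended pair is separated by the structure
  classifier by construction (ΔP > 0.3).
* `sample_hallmark_dataset()` draws aligned sequences independently per
  position with planted class-conditional carrier frequencies and emits
  label-correlated probabilities (0.9/0.1 ± 0.05 noise).

These are geometric and statistical idealizations. The toy domain has
single-pseudo-atom sidechains, free-floating disulphide sulphurs, turn
geometry that is not peptide-exact, and no rotamers, packing or real
sequence statistics; the sequence sampler has no per-position conservation
profile or phylogenetic correlation. Passing tests therefore demonstrate
the correctness of the *computations* — angle measurement, counting,
quadrature, losses, fits, RMSDs — not calibration of the classifiers on
real structures, which requires curated experimental data outside this
package's scope.

Two statistical choices in the hallmark-recovery study were fixed from
power analysis before any runs. First, the planted-hallmark accuracy claim
(Log2FC within ±0.15 of log₂(0.8/0.2) = 2) is made on the across-seed mean:
at 500 sequences per class a single seed's Log2FC has sampling SD ≈ 0.13,
so a per-seed ±0.15 bound would fail ~25% of the time by sampling noise
alone, while the mean over 20 seeds has SE ≈ 0.03. Rank-first recovery is
asserted per seed (≥ 19/20). Second, the null-control simulation runs at
100 + 100 sequences over the uniform 20-letter background: there the
expected carrier count per (position, amino-acid) cell is ~10, below the
≥ 30-observation floor, making that filter the operative type-I control —
the regime the filter is for. At large n every cell clears the floor and a
raw p < 0.05 screen over ~2,000 correlated tests will always emit nominal
positives; controlling that regime would require multiplicity correction,
which the published procedure does not use.

## Problem sizes and runtime

Defaults were chosen so the full suite runs comfortably on a laptop: toy
domains of ~110 residues (~560 atoms; one six-feature evaluation ≈ 0.9 s,
dominated by SASA), hallmark datasets of 1,000 sequences (discovery ≈ 1 s),
20-seed recovery studies, 200 pairing instances, bootstrap with 500–1,000
resamples in tests (10,000 as the user-facing default). The acceptance
script completes in under a minute.

## Known limitations

* AHo numbering of raw, unaligned sequences is out of scope; inputs must
  arrive pre-aligned (149-char strings) or pre-renumbered structures with
  an optional author→AHo map. Insertion codes are rejected unless the map
  resolves them — guessing a slot silently would corrupt every downstream
  position.
* The disulphide losses are validation scores here; no gradients are
  provided for training loops.
* The packaged sequence-classifier weights are a synthetic reference fit
  (see above), and the radii/max-ASA tables are single published sets:
  replacing any of them is a one-file edit, and results should be reported
  with the tables used.
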