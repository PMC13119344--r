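# nbblueprint

Nanobodies (VHHs, single-domain camelid antibodies) place their long HCDR3
loop in one of two global regimes, or *blueprints*: **kinked**, with the loop
folded back onto the framework, shielding the hydrophobic former VH–VL
interface (FR2, AHo positions 43–56), or **extended**, with the loop
projecting into solvent. The blueprint is a major determinant of antigen
engagement and a useful invariant to check in predicted structures.
`nbblueprint` is an R toolkit for structural bioinformaticians and antibody
engineers that implements, end to end:

- **The six structural blueprint descriptors** of a VHH domain on the fixed
  149-position AHo alignment: the stem pseudo-torsion and pseudo-bond angles
  at the HCDR3 N-stem (AHo 105–108) and C-stem (AHo 135–138); the HCDR3→FR2
  heavy-atom contact density (4.5 Å cutoff, stem residues excluded,
  normalized by HCDR3 length); and the mean relative solvent accessibility
  of FR2 key positions 44 and 54, computed with a built-in Shrake–Rupley
  SASA (probe 1.4 Å, 960 quadrature points, Gly-X-Gly max-ASA
  normalization).
- **The structure classifier**: a standardized logistic model
  `P(kinked) = σ( Σᵢ wᵢ·(xᵢ−μᵢ)/σᵢ + b )` over the six descriptors, shipped
  with its published parameterization (intercept b = −0.352).
- **The sequence classifier pipeline**: log₂ fold-change hallmark
  enrichment `Log2FC(p,a) = log₂((f_K+ε)/(f_E+ε))` with pseudo-count
  ε = 0.5/N, Fisher-exact + minimum-observation filtering, correlation-based
  ranking of framework (position, amino-acid) hallmarks, and a soft-label
  logistic trainer (damped Newton on cross-entropy with continuous targets).
  The 20-hallmark table is packaged; the fitted sequence weights shipped
  here are a clearly labelled synthetic-data reference fit, since the
  original fitted weights were not published.
- **Disulphide-geometry scoring**: greedy non-overlapping cysteine pairing
  from ground-truth SG–SG distances (candidate band 1.42–3.00 Å), hinge
  losses on SG–SG (band 1.84–2.26 Å, non-bonded repulsion 4.1 Å) and Cβ–Cβ
  (2.85–4.50 Å) distances, a Huber penalty on the S–S–Cβ angle (target
  2.0 rad, δ = 0.04), a bimodal wrapped-Gaussian χ₃ dihedral prior (modes
  +1.66012 / −1.79512 rad, σ = 0.5), a symmetric distogram cross-entropy
  against the 2.05 Å bin, and the annealed composite
  `0.5·L_SG + 0.25·L_CB + 10⁻⁴(L_ang + L_χ3) + 1·L_disto`.
- **Evaluation utilities**: Kabsch framework superposition,
  region-stratified backbone RMSD (N, CA, C, O), blueprint-bin recovery
  (evaluation thresholds 0.25/0.55), non-canonical disulphide (NCDB)
  recovery at the 2.46 Å SG–SG threshold, percentile bootstrap CIs for
  medians, mean-HCDR3-confidence and peptide-bond filters, and the
  cysteine-pattern rules (4–5 cysteines, anchor at AHo 40/57, HCDR3
  cysteine) that define NCDB candidate sequences.
- **Seeded synthetic fixtures** for every input above, so the full surface
  runs and is tested without any external data.

Everything is tidyverse-shaped: atom tables and sequence tables are tibbles
keyed by `id`, every classifier adds columns, results pipe into `dplyr` and
`ggplot2` (`plot_hallmarks()`, `plot_blueprint_calls()`,
`plot_region_rmsd()`), and the soft-label fit has broom-style `tidy()` /
`glance()` methods.

## Worked example

```r
library(nbblueprint)

# a synthetic kinked VHH with a non-canonical disulphide tethering
# HCDR3 position 115 to the anchor cysteine at AHo 57
toy <- make_toy_vhh("kinked", ncdb = c(57, 115), seed = 4)

vhh_features(toy$atoms) |> classify_structure()
#> # A tibble: 1 × 8
#>   id         alpha_n tau_n alpha_c tau_c contact_density fr2_rsa_key p_kinked
#>   <chr>        <dbl> <dbl>   <dbl> <dbl>           <dbl>       <dbl>    <dbl>
#> 1 toy_kinked   -62.1  126.   -13.3  110.            17.5       0.168        1
```

The stem angles sit at the classifier's training means (so they contribute
nothing), while the dense HCDR3–FR2 contacts (17.5 contacts per loop
residue vs. a training mean of 0.29) and the buried FR2 key positions
(RSA 0.17) drive `P(kinked)` to 1. The extended variant of the same domain
gives `contact_density = 0` and `p_kinked = 0.040` — bin "extended" under
both threshold schemes.

```r
# NCDB recovery against a perturbed "prediction"
pred <- perturb_structure(toy$atoms, "HCDR3", 0.5, "per_atom_noise", seed = 9)
ncdb_recovered(pred, extract_expected_pairs(toy$atoms))
#> # A tibble: 2 × 7
#>   pos_i pos_j  dist canonical pred_dist violation recovered
#>   <int> <int> <dbl> <lgl>         <dbl> <lgl>     <lgl>
#> 1    23   106  2.05 TRUE           2.05 FALSE     TRUE
#> 2    57   115  2.05 FALSE          2.09 FALSE     TRUE
```

Both the canonical 23–106 bridge and the planted 57–115 NCDB stay under the
2.46 Å recovery threshold after 0.5 Å of coordinate noise.

```r
# hallmark discovery on a seeded dataset with one planted hallmark
d <- sample_hallmark_dataset(500, 500,
  planted = data.frame(position = 44, aa = "F", f_k = 0.8, f_e = 0.2),
  seed = 7)
discover_hallmarks(d) |> head(1)
#> # A tibble: 1 × 8
#>   region position aa    log2fc  p_value freq_kinked freq_extended score
#>   <chr>     <int> <chr>  <dbl>    <dbl>       <dbl>         <dbl> <dbl>
#> 1 FR2          44 F       2.00 3.81e-81        0.78         0.194 0.341
```

The planted FR2/44/F hallmark is ranked first with its generative
enrichment (log₂(0.8/0.2) = 2) recovered.

A thin CLI wraps the same functions, e.g.
`exec/nbblueprint features in.pdb -o features.tsv` and
`exec/nbblueprint ncdb-check --ref ref.pdb --pred pred.pdb`.

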