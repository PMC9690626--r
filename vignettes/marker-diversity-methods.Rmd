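---
title: "Methods: dominant-marker diversity, barcoding and expression statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominant-marker diversity, barcoding and expression statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerdiv)
```

`markerdiv` implements the desk-scale statistics of a small-panel plant
genetic-characterization study: dominant-marker informativeness, binary-profile
clustering, DNA-barcode distances and bootstrap trees, Livak relative
expression, and replicate-trait comparisons. This vignette explains the models
behind each stage, the tunable parameters and their defaults, what the
synthetic generators do and do not emulate, and the numerical choices made
where conventions in the literature diverge.

## Dominant markers and the band matrix

ISSR and SCoT are *dominant* marker systems: a PCR band of a given size is
either present (1) or absent (0) in an accession, and a heterozygote cannot be
told from a dominant homozygote. The complete data for one primer is therefore
a binary accession-by-band matrix (`band_matrix`). Protein profiles scored
from SDS-PAGE gels have exactly the same structure and are handled by the
same class (`marker_system = "PROTEIN"`).

With `A` accessions, each band `b` has a presence frequency
`p_b = (accessions carrying b) / A`, and the bands partition into:

* **monomorphic** (MB): `p_b = 1`;
* **unique** (UB): present in exactly one accession;
* **non-unique polymorphic** (NB): present in more than one but not all.

`classify_bands()` derives the classes from frequencies, so the definitions
hold for any panel size; nothing in the package assumes `A = 3` except the
convenience that, when `A = 3`, every unique band has `p = 1/3` and every
non-unique band exactly `p = 2/3` — which is why a published (MB, UB, NB)
table fixes the full frequency spectrum and lets
`matrix_from_composition()` reconstruct a statistically equivalent matrix
from counts alone.

## The informativeness panel

For a primer with `TB` total and `PB = UB + NB` polymorphic bands:

* **PIC** (polymorphism information content). Each band is treated as a
  biallelic dominant locus: `PIC_b = 1 - p_b^2 - (1 - p_b)^2 = 2 p_b (1 - p_b)`,
  and the primer value is the mean over its bands (`pic()`, method
  `band_2pq_mean`), bounded by 0.5. Published tables are often computed by
  unstated software conventions that this formula does not reproduce, so
  `marker_summary(pic_overrides =)` accepts published per-primer values; the
  computed value is always reported alongside (`pic_computed`).
* **EMR** (effective multiplex ratio): `EMR = PB * (PB / TB)` — the
  polymorphic band count weighted by the polymorphic fraction of the assay
  (`emr()`). Verbal definitions of EMR in the applied literature are
  frequently circular; this quadratic form is the one under which published
  three-accession panels reproduce exactly, and it has the natural bounds
  `0 <= EMR <= TB` with equality iff no or all bands are polymorphic (an
  invariant the test suite checks by exhaustive enumeration).
* **MI** (marker index): `MI = PIC * EMR` (`mi()`).
* **RP** (resolving power): `RP = sum_b I_b`. Two conventions for the band
  informativeness `I_b` are offered (`rp()`): `doubled_frequency`,
  `I_b = 2 p_b`, the default, which reproduces published RP columns of
  three-accession dominant panels; and `prevost`,
  `I_b = 1 - 2 |0.5 - p_b|`, the Prevost–Wilkinson form in which
  intermediate-frequency bands are maximally informative. The two orderings
  can differ sharply (a monomorphic band contributes 2 under the first and 0
  under the second), which is why the convention is an explicit, recorded
  argument rather than a silent choice.
* **P%** (percent polymorphism): `100 * PB / TB` per primer; the pooled panel
  value is computed from summed counts, `100 * sum(PB) / sum(TB)`, never as a
  mean of per-primer percentages (`marker_summary()$overall_p_pct`).

Internally everything is computed at full precision; presentation rounding
(2 decimals, half-up) is applied only when printing.

```{r}
panel <- marker_summary(
  reference_band_matrices("ISSR"),
  pic_overrides = with(published_band_classes(), setNames(pic_published, primer)))
panel
```

## Similarity, UPGMA and ordination

Accession profiles (band columns concatenated over primers) are compared with
Jaccard (default), Dice or simple-matching coefficients; distance is
1 − similarity (`band_distance()`). Jaccard is the default because joint
*absence* of a dominant band carries no homology signal; simple matching,
which rewards shared absence, is provided for comparison. A pair of
accessions with no bands at all has an undefined Jaccard coefficient and is
reported as an error, not a silent 0 or 1.

`upgma()` is average-linkage agglomeration (`stats::hclust`,
`method = "average"`) returned as an ultrametric `ape::phylo` tree: each
merge sits at half the size-weighted mean inter-cluster distance, so leaf-to-
leaf cophenetic distances on an already-ultrametric input reproduce it
exactly (tested on random ultrametric matrices). Distance ties are broken
deterministically by sorting labels lexicographically before clustering.
`to_newick()` serializes with branch lengths (parent height − child height)
and bootstrap supports as internal node labels.

`pca()` performs centred (optionally unit-variance) PCA by singular value
decomposition; explained percentages are eigenvalue shares, and each
component's sign is fixed by making its largest-magnitude loading positive.
With three accessions the centred matrix has rank ≤ 2, so PC1 + PC2 always
explain 100% of the variance — that rank property, not any particular
percentage, is what can be verified without the study's unpublished
attribute matrix. `heatmap_prepare()` scales each variable to [−1, 1] (or
z-scores) and orders rows and columns by UPGMA on euclidean distances of the
scaled values; constant variables map to 0 with a warning.

## Barcode sequences

`gc_content()` reports `100 (G + C) / counted bases`, excluding gaps always
and ambiguity codes by default. `pairwise_identity()` aligns two unaligned
sequences semi-globally (match +1, mismatch −1, linear gap −2, free terminal
gaps) and returns `100 * matches / aligned columns`, terminal-gap columns
excluded. Because several alignments can share the optimal score, the
identity is defined as the maximum match count over all score-optimal
alignments (ties broken toward fewer columns); this makes the value
well-defined and symmetric in the two sequences, which an arbitrary
traceback tie-break would not guarantee. The dynamic program is quadratic
and written for barcode-length sequences (≤ a few kb).

`p_distance()` is the proportion of differing sites per pair
(`ape::dist.dna`, model `"raw"`), with gaps/ambiguities handled by pairwise
(default) or complete deletion; a pair with no comparable sites is an error.
Model-corrected distances (Jukes–Cantor etc.) are deliberately out of scope:
at within-species divergences the correction is smaller than the sampling
noise of a single locus.

`bootstrap_tree()` resamples alignment columns with replacement, rebuilds
the p-distance UPGMA tree per replicate, and reports per internal node the
percentage of replicates containing the same leaf set (for a rooted
ultrametric tree, clades and bipartitions coincide and are
rotation-invariant). The whole procedure is a pure function of
(alignment, seed). An alignment whose columns are all identical yields
supports of 0 and a warning rather than an error.

## Relative expression (2^−ΔΔCT)

`fold_changes()` implements the Livak method with ΔCT = CT(target) −
CT(reference gene): replicate ΔCTs are formed by pairing target and
reference replicates by index and averaged *at the ΔCT level*; ΔΔCT is taken
relative to the designated calibrator sample, and fold = 2^−ΔΔCT, so the
calibrator's fold is exactly 1. The sign convention matters: upregulation
(more transcript, smaller CT) must yield fold > 1; published fold values
well above 1 for upregulated genes are only consistent with this
orientation, even where a methods paragraph verbally reverses the
subtraction. Amplification efficiency is fixed at 2.0 (no efficiency
correction — none can be estimated without standard curves). Replicate
spread is propagated as the fold range at mean ΔCT ± SD(ΔCT); a per-sample
additive CT shift (a plate effect hitting target and reference alike)
cancels exactly, which the tests assert.

## Trait statistics

`anova_oneway()` is the classical one-way decomposition (via `stats::lm` /
`stats::anova`); the degenerate all-identical case is defined as F = 0
(detected from exact sums of squares, since floating-point residuals of a
perfect fit can otherwise produce an arbitrary finite ratio).
`duncan_letters()` implements Duncan's multiple range test from studentized
range quantiles (`stats::qtukey`, numerical quantiles, no table files): with
means sorted descending, a stretch of `k` means is homogeneous when its
extreme difference is below `R_k = q(alpha_k, k, df) * sqrt(MSE/n)` with
Duncan's protection level `alpha_k = 1 - (1 - alpha)^(k-1)`; letters are the
maximal homogeneous stretches, so sharing a letter means "not separated at
alpha" (default 0.05). Unequal group sizes fall back to the harmonic mean
`n` with a warning. `pearson_matrix()` offers both replicate-level and
accession-mean correlation — published small-panel matrices rarely state
which was used; with three accessions the mean-level estimate rests on
n = 3 points and is flagged `low_n` (its extreme values of exactly ±1.00
are an expected small-sample artifact, not evidence of perfect biological
coupling).

## The synthetic study and what it does (not) show

`study_profile()` encodes the reference three-accession panel:

* **Markers**: the published (MB, UB, NB) composition of all 21 DNA primers
  and the protein gel, with unique-band quotas 8/4/12 (ISSR), 23/7/29
  (SCoT) and 2/0/0 (protein) for C1/C2/C3. Non-unique bands are assigned to
  the close pair (C1, C2) with probability `nb_close_share = 0.75`,
  uniformly otherwise: the study's UPGMA grouped C1 with C2, which is only
  possible if shared polymorphic bands predominantly joined that pair, and
  a uniform assignment would not reproduce that structure reliably. The
  informativeness statistics are unaffected by any of these placement
  choices — they depend only on the frequency spectrum, which the class
  counts fix.
* **Barcode**: 500 bp locus, p-distance 0.01 within the close pair and 0.15
  to the outgroup accession, simulated as i.i.d. substitutions down an
  ultrametric three-taxon tree. Realized distances land within
  `3 * sqrt(d (1 - d) / L)` of targets; coincident substitutions bias them
  slightly downward at larger `d`, which the tolerance absorbs.
* **Expression**: reference-gene CT 20, baseline ΔCT 3 cycles, truth folds
  of 1 (calibrator C1), ~7–15 (C3, matching the published upregulation
  ratios C3/C1 per gene), geometric midpoints for the unpublished C2;
  replicate noise 0.2 cycles per CT measurement, 3 replicates.
* **Traits**: published accession means where printed (e.g., TPC 92.54
  mg GAE/g and SOD 16.87 U/mg for C3), field-plausible lower values for
  unprinted cells, 3 replicates at a 5% coefficient of variation (typical
  for colorimetric assays).

Every generator is a pure function of (profile, seed). The generators
emulate the *statistical* structure each pipeline stage assumes — class
compositions, an additive two-clades-one-outgroup divergence pattern,
log-normal CT noise, normal trait noise. They do not emulate gel mobility
or band-size co-migration, alignment error, sequencing chemistry artifacts,
amplification-efficiency differences between genes, or between-assay trait
correlations. Passing tests therefore demonstrate that the estimators
recover known truth under their own assumptions, not that those assumptions
hold in any particular wet-lab data set.

On recovery tolerances: with CT noise of 0.2 cycles per measurement and
3 replicates, the standard error of a ΔΔCT estimate is about
`0.2 * sqrt(2) * sqrt(2/3) ≈ 0.23` cycles, i.e. a multiplicative fold error
of `2^0.23 ≈ 1.17` — so roughly one simulated experiment in eight misses a
±25% band by chance. The recovery property is therefore asserted on the
mean over 100 seeded simulations (well within 25%) plus a ≥ 75% individual
hit rate, rather than demanding every simulation land inside the band.

## Numerical choices and limitations

* Report rounding is half-up at 2 decimals; all computation is at full
  double precision. Studentized-range quantiles are numerical
  (`qtukey`), accurate far beyond the 1e-6 documented tolerance.
* UPGMA tie-breaks are lexicographic; identical distances can occur with
  binary data, and reproducibility across platforms was preferred over
  matching any particular program's internal ordering.
* `matrix_from_composition()` reconstructs *a* matrix with the published
  frequency spectrum; per-accession placement of unique bands in the
  original gels is unknown in detail (only aggregate quotas were
  published), so placement is generator metadata, not ground truth.
* The package computes statistics of panels with any number of accessions,
  but with `A = 3` several quantities are near their degenerate limits
  (PIC ≤ 0.44 by 2pq, Pearson on means at n = 3, rank-2 PCA); conclusions
  from three-accession panels are exploratory by nature, and the package
  makes the small-n flags explicit rather than hiding them.
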