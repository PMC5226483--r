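---
title: "Weighted white-matter connectome analysis with wmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted white-matter connectome analysis with wmnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

wmnet analyzes weighted structural brain networks built from diffusion-MRI
tractography. Its unit of analysis is a per-subject 90 × 90 connectivity
matrix over the AAL-90 anatomical parcellation, and its purpose is the
comparison of network topology across three diagnostic groups — normal
controls (NC), subjective cognitive decline (SCD), and amnestic mild
cognitive impairment (aMCI) — together with covariate-adjusted correlations
between nodal network properties and neuropsychological scores.

## The network model

Tractography yields, for every pair of regions *i, j*, a streamline count
FN~ij~ and the mean fractional anisotropy FA~ij~ along those streamlines,
plus each region's volume in mm³. Two regions are connected when at least
`fn_threshold` streamlines join them (default 3, inclusive: an edge with
exactly 3 streamlines is kept). The connection weight is

$$ w_{ij} = \frac{\mathrm{FN}_{ij}\,\mathrm{FA}_{ij}}{(v_i + v_j)/2}, $$

where the denominator — the arithmetic mean of the two region volumes —
offsets the tendency of large regions to accrue spurious streamlines. The
result is a symmetric, non-negative matrix with zero diagonal. The
threshold is a judgment call; `validate_threshold_stability()` recomputes
the network and its global metrics over a range of thresholds (1–5 by
default) so its influence can be inspected. Raising the threshold can only
delete edges, never add them.

Matrices read from disk are symmetrized by averaging the two triangles when
the asymmetry is within 1e-8 (relative); larger asymmetry is treated as a
data error, since tractography matrices are nominally symmetric. Node order
is fixed by the atlas; indices are 1-based in all reports.

## Graph metrics

Weights encode coupling strength, so the *length* of an edge for path-based
metrics is the reciprocal of its weight: stronger connections are shorter.
All-pairs shortest paths use Dijkstra's algorithm on these lengths.
Disconnected pairs have infinite length.

* **Global efficiency** `Eg` is the mean of 1/L~ij~ over ordered pairs;
  disconnected pairs contribute zero. No largest-component restriction is
  applied.
* **Characteristic path length** `Lp` is the harmonic mean of the path
  lengths — the reciprocal of `Eg`, so `Lp * Eg = 1` holds identically and
  is asserted in the tests to 1e-10. A network with no finite pair has
  `Lp = Inf` (with a warning).
* **Clustering coefficient** `Cp` follows the edge-count definition: for
  node *i* with degree D~i~ ≥ 2, the number of edges among its neighbors
  divided by D~i~(D~i~−1)/2, computed on the binarized topology of the
  thresholded graph; nodes of degree < 2 contribute 0, and `Cp` is the mean
  over all N nodes. A weighted variant (geometric mean of normalized
  triangle weights) is available via `weighted = TRUE` but is not the
  default, keeping the headline number interpretable as a fraction of
  realized neighbor links.
* **Local efficiency** `Eloc` is the mean over nodes of the global
  efficiency of the weighted subgraph induced on each node's neighbors
  (the node itself excluded); subgraphs with fewer than two nodes
  contribute 0.
* **Betweenness centrality** is Freeman's fraction-of-shortest-paths count
  over unordered pairs, on the weighted graph, reported unnormalized (a
  `normalized` option divides by (N−1)(N−2)/2). Whether betweenness should
  use the weighted or binarized graph is genuinely open in this literature;
  wmnet follows the weighted reading since the network is declared
  weighted throughout. Path-count ties are resolved by the shortest-path
  library's exact comparison; with continuous weights, exact ties between
  distinct paths have probability zero, and the brute-force oracle used in
  the tests tolerates floating-point tie noise at a relative 1e-9.

## Small-world normalization

`Cp` and `Lp` are meaningful only relative to a null model. wmnet uses
degree-preserving randomization: repeated double-edge swaps
(a,b),(c,d) → (a,d),(c,b), rejected whenever a self-loop or multi-edge
would result. Weights travel with their edges, so every null network has
exactly the source network's degree sequence *and* weight multiset — both
are asserted, exactly, on every draw in the test suite. Defaults are 10
attempted swaps per edge and an ensemble of `n_nulls = 100` networks.

The normalized parameters are γ = Cp/⟨Cp~rand~⟩, λ = Lp/⟨Lp~rand~⟩, and
σ = γ/λ. Small-world organization means random-like path lengths with
excess clustering: λ ≈ 1, γ > 1, σ > 1. On a dense random graph — its own
null class — σ ≈ 1; on a ring lattice γ and σ exceed 1. Both behaviors are
acceptance-tested. σ is computed per subject (then compared across groups),
not on group-mean networks; the alternative is not exposed because averaging
weight matrices across subjects changes edge density and would make the null
ensembles incomparable.

Per-null seeds derive from one master seed by a fixed counter scheme
(`seed_i = (master + 747796405·i) mod (2^31 − 1)`), so ensembles are
reproducible draw-by-draw; keep master seeds below 2^31. Strength-sequence-
preserving nulls and lattice references for the ω small-world index are out
of scope.

## Hubs and group statistics

Hubs are the top `ceiling(0.10 × N)` regions — exactly 9 of 90 — ranked by
group-mean nodal betweenness (per-subject betweenness averaged within group,
then ranked; the group-mean-network alternative is not used because the
whole metric pipeline is per-subject). A tie exactly at the cutoff keeps the
lower region index and warns; ties do not occur with continuous weights.

Group comparisons come in two forms:

* `anova_oneway()` — the classical between/within decomposition, with
  pooled-variance pairwise t tests Bonferroni-adjusted over the three pairs,
  attached only when the omnibus test is significant (p < 0.05);
* `ancova_group_effect()` — the default for network metrics: a linear model
  `metric ~ age + sex + education + group`, with the group factor tested by
  the partial F of the full against the covariates-only model, and
  Bonferroni-adjusted pairwise contrasts of adjusted group means. Sex is
  coded 0/1. The covariate list is configurable.

`anova_from_summary()` reconstructs the one-way F from published group
means, SDs and sizes — useful for checking reported statistics when raw
data are unavailable; with exact summaries it equals `anova_oneway()` on
the raw data (an identity kept under test).

Nodal betweenness is compared across groups at all 90 regions. The default
applies no correction across regions (a `nodal_correction` switch offers
FDR or Bonferroni; the output always records the mode chosen), because the
downstream correlation stage treats the significant set as a screen, not as
confirmatory inference. Score–betweenness correlations are then computed
within each patient group, for the screened regions only (a flag widens
this to all regions), as partial correlations controlling age, sex and
education: Pearson correlation of the two residual vectors, with the t
transform on n − 2 − k degrees of freedom.

## The synthetic cohort generator

No clinical data ship with the package; the generator exists so every stage
can be exercised end-to-end with known ground truth. It emulates:

* the three-group design with the reference sizes 36/21/33;
* tractography-like inputs: negative-binomial streamline counts (mean 20,
  dispersion 5), Beta-distributed FA scaled to [0.2, 0.7], log-normal
  region volumes (median 8000 mm³, sdlog 0.3);
* a shared small-world anatomy: one ring lattice (k = 8) with a fixed
  count of randomly placed rewired shortcuts (10% of edges) is drawn per
  cohort and shared by all its subjects, because subjects share gross
  anatomy. The fixed shortcut count keeps the planted effect size constant
  across cohorts;
* graded disease effects: on the long-range (rewired) edges, FN and FA are
  each attenuated by 15% in SCD and 30% in aMCI; edges incident to the
  targeted hub (right precuneus, PCUN.R) are attenuated by 40% in aMCI
  only. Long-range edges carry the effect because disconnection of distant
  regions is the phenomenon of interest; the hub attenuation is confined to
  aMCI because hub loss is modeled as a later-stage event, with the SCD hub
  set control-like. Attenuating FN and FA jointly makes the edge weight
  inherit the effect monotonically, and FN attenuation can push edges below
  the streamline threshold — edge loss, not just edge weakening;
* between-subject heterogeneity: a per-subject log-normal global scale on
  streamline counts with SD 0.18. This value was set, once, by simulation
  so that the default cohort reproduces the reference study's pattern of
  significance — the NC–aMCI efficiency contrast is powered (significant in
  ≳90% of cohorts) while NC–SCD is not (nonsignificant in ≳70%) — which is
  the generator's design target, not an empirical discovery;
* demographics near the reference cohort (age ~ N(62, 9²) truncated to
  50–80, education ~ N(10.5, 4²) truncated at 0, group-specific sex
  ratios) and cognitive scores (MMSE, MoCA, AVLT immediate/delayed/
  recognition) drawn around group means with a planted positive link from
  hub betweenness to MoCA and delayed recall (coefficient 0.4 score-SD per
  betweenness-SD, i.e. a true partial correlation near 0.4).

What it does **not** emulate: anatomically realistic edge geometry or
distance-dependent connection probabilities, crossing-fiber and
long-distance tracking biases, scanner/site effects, missing data, or any
dependence of FA on age and sex. Passing tests on synthetic cohorts
therefore demonstrate that the pipeline recovers planted effects of
realistic magnitude at the reference sample sizes — not that it would
detect, or correctly size, effects in real tractography data.

Everything is a pure function of the cohort spec (which includes the master
seed): the same spec yields bit-identical cohorts.

## Numerical choices and degenerate inputs

* Edge length 1/w; disconnected pairs contribute 0 to efficiency sums and
  to the harmonic Lp.
* Matrices asymmetric beyond 1e-8 (relative) are errors; smaller wobble is
  averaged away.
* Zero within-group variance, empty groups, rank-deficient ANCOVA designs
  (the collinear column is named), constant residuals in partial
  correlations, and null ensembles with degenerate mean Cp or Lp all raise
  classed errors rather than returning NaN.
* Networks where no legal double-edge swap exists (e.g. stars) are returned
  unchanged from the rewiring step with a warning.
* Hub-cutoff ties break toward the lower region index, with a warning.

## Problem sizes in the test suite

The tests run the full 90-region, 36/21/33 cohort for the planted-effect
recovery checks (50 independent cohorts) and the type-I calibration (200
null cohorts), brute-force oracle comparisons on 200 random graphs of 5–8
nodes, and null ensembles of 100 networks for the small-world checks;
smaller toy cohorts (20–40 regions) cover the pipeline plumbing. These
sizes keep the default suite in the tens of minutes on one CPU while
leaving every scientific claim tested at the reference scale.

## Limitations

The package starts from FN/FA/volume matrices: tractography, registration
and parcellation are upstream and out of scope, as are rich-club,
modularity and assortativity analyses, permutation-based group tests, and
effect-size measures. The bundled AAL-90 coordinates are approximate
centroids intended only for the BrainNet-style `.node`/`.edge`
visualization files.
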