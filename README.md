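# wmnet — weighted white-matter connectome analysis

wmnet is an R package for graph-theoretical analysis of weighted structural
brain networks built from diffusion-MRI tractography. It is aimed at
neuroimaging researchers comparing connectome topology across diagnostic
groups — here normal controls (NC), subjective cognitive decline (SCD), and
amnestic mild cognitive impairment (aMCI) — starting from per-subject
fiber-number (FN) matrices, mean fractional-anisotropy (FA) matrices, and
region volumes over the 90-region AAL parcellation.

## What it computes

**Network construction.** Regions *i, j* are connected when FN_ij ≥ 3
(configurable, inclusive), with weight

    w_ij = FN_ij * FA_ij / ((v_i + v_j) / 2)

— streamline count times tract integrity, normalized by the mean volume of
the two regions. Each subject yields a symmetric 90 × 90 weight matrix.

**Graph metrics.** With edge length 1/w (stronger = shorter) and Dijkstra
shortest paths L_ij:

- global efficiency `Eg = (1/(N(N-1))) Σ_{i≠j} 1/L_ij`
- characteristic path length `Lp = 1/Eg` (harmonic mean, robust to
  disconnected pairs)
- clustering coefficient `Cp`: mean over nodes of E_i / (D_i(D_i−1)/2),
  the realized fraction of neighbor-neighbor edges
- local efficiency `Eloc`: mean over nodes of Eg of the neighbor-induced
  weighted subgraph
- nodal betweenness `B(i) = Σ_{j≠i≠k} δ_jk(i)/δ_jk` on the weighted graph

**Small-world normalization.** γ = Cp/⟨Cp_rand⟩, λ = Lp/⟨Lp_rand⟩,
σ = γ/λ against 100 degree-preserving random networks (double-edge swaps;
weights travel with edges, so degree sequence and weight multiset are
preserved exactly).

**Hubs and statistics.** Hubs are the top 10% of regions (9 of 90) by
group-mean betweenness. Group effects are tested by one-way ANOVA or, by
default, ANCOVA adjusting for age, sex and education, with Bonferroni
post hoc contrasts; `anova_from_summary()` reconstructs F statistics from
published means/SDs/ns; score–metric associations use partial correlations
with the same covariates. Results export as tidy CSVs plus BrainNet-style
`.node`/`.edge` files.

**Synthetic cohorts.** `cohort_spec()`/`generate_cohort()` simulate
three-group cohorts (36/21/33 by default) with planted, graded disruption of
long-range connections and a targeted hub, so the whole pipeline is testable
with known ground truth. See the vignette
(`vignettes/white-matter-networks.Rmd`) for the generator's design and its
limits.

## Worked example

```r
library(wmnet)

# a synthetic cohort at the reference group sizes, then the full pipeline
coh <- generate_cohort(cohort_spec(master_seed = 1))
res <- run_pipeline(coh, fn_threshold = 3, n_nulls = 100, seed = 2,
                    out_dir = "results/run1")

dplyr::select(res$global_comparisons, metric, statistic, p.value, p_NC_aMCI)
#> # A tibble: 7 × 4
#>   metric statistic  p.value p_NC_aMCI
#>   <chr>      <dbl>    <dbl>     <dbl>
#> 1 Cp         0.386 6.81e- 1 NA
#> 2 Lp        10.0   1.22e- 4  7.82e- 5
#> 3 Eg        10.5   8.28e- 5  4.77e- 5
#> 4 Eloc       1.42  2.47e- 1 NA
#> 5 gamma      0.328 7.21e- 1 NA
#> 6 lambda   148.    3.03e-28  9.58e-29
#> 7 sigma    106.    9.33e-24  3.04e-24
```

The first column is the ANCOVA partial F for group; `p_NC_aMCI` is the
Bonferroni-adjusted NC-vs-aMCI contrast, attached only when the omnibus test
is significant. On this cohort the planted long-range disruption is
recovered where it should be: characteristic path length and global
efficiency show strong group effects (Eg falls from NC 5.2e-4 through SCD
4.6e-4 to aMCI 4.1e-4), clustering — which the planted effect barely
touches — does not, and every group is small-world (mean σ ≈ 5.4 against
degree-preserving nulls). The very large λ and σ effects are a real feature
of the generator: attenuated streamline counts push long-range edges below
the threshold in aMCI, making those networks more lattice-like relative to
their own null ensembles.

```r
hubs_nc <- identify_hubs(dplyr::filter(res$nodal_metrics, group == "NC"))
nrow(hubs_nc)
#> [1] 9
```

A command-line wrapper with `simulate`, `run`, `metrics` and `nulls`
subcommands lives at `inst/cli/wmnet.R`.

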