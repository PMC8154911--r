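# geothermflora

Analysis of vascular-plant communities along geothermal soil gradients: which
taxa are filtered by soil heating, whether thermotolerant species are
phylogenetically clustered, how thermal-zone floras overlap, and which
edaphic factors limit which species. The package is written for ecologists
and soil scientists working on heated soils (hot-spring margins, fumarole
fields, geothermal catenas), and for anyone who needs its components —
hypergeometric taxon enrichment, a pair-subsampling NRI, composition-overlap
permutation tests, a Spearman + Hoeffding dependence screen, soil temperature
and weathering indices — as tested building blocks.

## The statistics at its core

**Taxon enrichment.** For a pool of *N* species with *K* in a taxon and a
group of *n* species with *k* of them,

    p(k) = C(K,k) · C(N−K, n−k) / C(N,n)

with inclusive tails P_over = Σ p(i), i ∈ [k, min(K,n)] and
P_under = Σ p(i), i ∈ [0, k]; calls at raw P ≤ 0.05, with Benjamini–Hochberg
q-values (FDR 15 %) reported alongside.

**Net relatedness index.** For a species group on an ultrametric phylogeny,
MPD_obs is the mean patristic distance over (at most) 100 subsampled pairs;
the null re-draws the same number of pairs from the whole pool 10,000 times;

    NRI = −(MPD_obs − mean(MPD_null)) / SD(MPD_null)

(positive = clustered), p by left-tail rank with the add-one rule, medians
over 10 replicates, averaged over three tree variants built by grafting
missing species as basal polytomies, at random within their families, or
constrained by family→order taxonomy. A calibrated group-resampling null is
available as `null_model = "groups"` (see the methods vignette for why the
pair null is anti-conservative for random groups).

**Zone overlap.** Shared-species counts between zones against a null of
independent uniform subsets of the same sizes from the pool (1,000 draws;
right/left tail p-values).

**Edaphic screen.** Per (species, property): Spearman rank correlation and
Hoeffding's D with a permutation p; *important* if either p ≤ 0.01; a
one-sided Fisher exact aggregation asks which properties matter for more
thermophytes than chance expects.

**Soil indices.** Temperature–depth gradient T(d) = k·d + T15 and its angle
α = arctan(k); STI = 100·SiO₂/(SiO₂/TiO₂ + Al₂O₃/TiO₂ + SiO₂/Al₂O₃);
Silica/R₂O₃ = SiO₂/(Al₂O₃+Fe₂O₃+TiO₂); one-sided Mann–Whitney zone
comparisons with Bonferroni correction; zone-I-normalised composition
profiles.

A seeded synthetic-data generator (`synthetic_config()`, `gen_dataset()`)
produces a 292-species / 60-family flora on a pure-birth phylogeny, planted
thermophyte clusters, four thermal zones with monotone soil gradients, and
cover values tied to soil properties through a Gaussian copula — so the whole
pipeline runs and is tested without any field data.

## Worked example

```r
library(geothermflora)

bundle <- run_demo(seed = 1)   # synthetic survey with planted signals, full pipeline
print(bundle)
#> <geo_bundle>
#>   enrichment: 328 taxon tests, 31 over-represented calls
#>   NRI (obligate): 7.003, p = 9.999e-05
#>   NRI (facultative): 0.632, p = 0.2732
#>   zone overlap: 4 zones, pool 44
#>   edaphic: 484 cells, 218 important
#>   soil: 36 samples, 84 pairwise comparisons
```

The demo plants its signals, and the bundle recovers them. The obligate
thermophytes were generated fully clustered (`clustering_strength = 1`), so
their NRI is strongly positive (7.0) at the smallest attainable p
(1/10001 per replicate); the facultative group spreads over more families and
shows only weak clustering (NRI 0.63, p 0.27). Family-level enrichment finds
the planted all-thermal families:

```r
dplyr::filter(bundle$enrichment, group == "obligate", rank == "family")[1:2, c(2,5:8,12:13)]
#>   taxon      K     n     k   p_over call  call_fdr
#> 1 Fam029     8    18     8 3.68e-11 over  over        # all 8 species obligate
#> 2 Fam052     6    18     6 2.27e- 8 over  over
```

Zone compositions: the two hottest zones share more species than random
subsets of the observed flora would (p_right(III, IV) = 0.035), while zone I
is not similar to zone II beyond chance (p_right = 0.998) — the non-thermal
flora is lost on heated ground:

```r
round(bundle$zone_overlap$p_right, 3)
#>        I    II   III    IV
#> I  0.001 0.998 0.924 0.751
#> II 0.998 0.001 0.608 0.465
#> III 0.924 0.608 0.001 0.035
#> IV  0.751 0.465 0.035 0.001
```

The planted cover–conductivity association is flagged by the edaphic screen
(Spearman rho = 0.93, p = 1.2e-05 at 12 plots), and the soil stage reproduces
the expected gradient geometry — median gradient angle 4.9° in the non-heated
zone vs 31.8° in the strongly heated zone, with the worked index values
STI(60, 1, 15) = 75.95 and Silica/R₂O₃(60, 15, 8, 1) = 2.5.

`tidy()`, `glance()` and `autoplot()` methods expose the NRI, overlap and
importance results as tibbles and ggplots; `write_bundle()` writes the whole
run as deterministic TSV/newick/YAML files.

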