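---
title: "Methods: community phylogenetics and soil gradients of geothermal plant habitats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community phylogenetics and soil gradients of geothermal plant habitats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geothermflora)
```

# The problem

Soils heated by endogenous geothermal fluids form short, steep environmental
gradients: within tens of metres, temperature at rooting depth can climb from
ambient to near-boiling, while acidity, salinity, redox state, texture and
mineralogy shift in concert. The vascular plants that persist along such a
catena are a filtered subset of the regional flora, and three questions recur
in their analysis:

1. **Which taxa are filtered in or out?** Are some families or orders over-
   or under-represented among the thermotolerant species relative to the
   regional species pool?
2. **Is thermotolerance phylogenetically clustered?** Do obligate and
   facultative thermophytes sit closer together on the regional phylogeny
   than random species sets would?
3. **Which soil properties limit which species**, and are some properties
   disproportionately important for the thermophytes?

`geothermflora` implements the complete computational chain for these
questions — taxon enrichment, the net relatedness index with a
pair-subsampling null, zone-composition overlap tests, an edaphic screen, and
soil temperature/weathering indices — together with a seeded synthetic-data
generator so that every stage is testable end to end without field data.

# Taxon enrichment

For a pool of $N$ species containing $K$ members of a taxon, and a focal
group of $n$ species containing $k$ of them, the probability of observing
exactly $k$ by chance is hypergeometric:

$$p(k) = \frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}}.$$

Over-representation is judged by the inclusive upper tail
$P_{over} = \sum_{i=k}^{\min(K,n)} p(i)$ and under-representation by the
inclusive lower tail $P_{under} = \sum_{i=0}^{k} p(i)$; both tails contain
$i = k$, so $P_{over} + P_{under} = 1 + p(k)$ — a useful internal identity
that the tests assert to $10^{-12}$. The primary decision rule is the raw
$P \le 0.05$ per taxon; Benjamini–Hochberg q-values are attached across the
taxa of each rank and called at an FDR of 0.15, and both calls are reported
side by side. Single-species taxa are flagged `low_power` rather than
suppressed. All combinatorics are evaluated in log space (`lchoose`), which
is exact to working precision at pool sizes in the hundreds; the test suite
checks the implementation against an exact binomial-coefficient oracle on
every small-pool case.

Two design points were genuinely open:

* **Within-rank vs global FDR.** Families, orders and classes answer
  different questions, so q-values are computed within a rank.
* **Status merging.** When two survey sources disagree, a species thermal in
  at least one source is kept thermal; contradictory obligate-vs-facultative
  labels resolve to facultative, because an obligate label is falsified by a
  single observation outside heated ground while a facultative label is not.
  A non-thermal classification in one source does **not** downgrade a
  thermal label from the other, since "not classified thermal" is weaker
  evidence than "observed outside heat".

# Net relatedness index

For a species group $G$ on an ultrametric phylogeny, the observed mean
pairwise (patristic) distance is

$$\mathrm{MPD}_{obs} = \overline{d(a, b)},\quad \{a,b\} \in \text{pairs}(G),$$

with pair subsampling for tractability: if $G$ forms more than `max_pairs`
(default 100) pairs, a uniform sample of 100 distinct pairs is averaged,
otherwise all pairs. The null distribution subsamples the **same number of
pairs from the whole pool**, 10,000 times, and

$$\mathrm{NRI} = -\,\frac{\mathrm{MPD}_{obs} -
\overline{\mathrm{MPD}}_{null}}{\mathrm{SD}(\mathrm{MPD}_{null})},$$

positive when the group is phylogenetically clustered. The procedure is
repeated 10 times per tree (fresh pair subsamples and nulls) and the median
NRI and median rank p-value are taken; across trees (the three grafting
variants below) the per-tree medians are averaged.

Numerical conventions, stated once:

* **Mean, not minimum, as the null reference.** The index is sometimes
  written with $\min(\mathrm{MPD}_{null})$ in place of the null mean. A
  min-standardised index is one-signed — it cannot be negative for
  over-dispersed groups — which contradicts the stated interpretation of the
  index (positive = clustered, negative = evenly spread). We therefore treat
  the min-form as a typographical slip, default to the null mean, and retain
  `convention = "min"` for verbatim fidelity.
* **SD** is the sample standard deviation ($n-1$) of the null draws.
* **p-value**: left tail (clustering makes MPD small), with the add-one
  permutation formula $p = (\#\{null \le obs\} + 1)/(draws + 1)$ so that
  $p = 0$ is never reported.
* Pair subsampling is without replacement within a draw; the null sampler is
  a partial Fisher–Yates in compiled code driven by R's RNG, so every result
  is reproducible from one integer seed.

## Calibration of the pair-subsampling null

This null draws *pairs*, not *groups*. The observed statistic averages 100
pairs confined to one group of, say, 20 species; those pairs share species
and are positively correlated, so the sampling variance of
$\mathrm{MPD}_{obs}$ across random groups **exceeds** the variance of a mean
of 100 independent pool pairs. Consequently the rank p-value of a uniformly
random group is not uniform: empirically (292-tip pure-birth tree, groups of
20, 10 replicates, 10,000 draws, 200 seeds) about 12–17 % of random groups
reach $p \le 0.05$ and a Kolmogorov–Smirnov test rejects uniformity. The
pair null is kept as the default because it is the procedure this package
sets out to implement, but its anti-conservatism for random groups is a real
property that users should know; the package therefore also provides
`null_model = "groups"`, which resamples whole random groups of the same
size and processes them exactly like the observed group. That null is
exactly calibrated by symmetry, and the test suite verifies both the
calibration of the group null and the planted-signal behaviour of the
default (single-clade groups are detected with $p < 0.05$ in over 90 % of
seeds; the two nulls agree closely for strongly clustered groups because the
signal dwarfs the variance discrepancy).

## Grafting species onto the backbone

Species present in the pool but absent from the backbone tree are grafted by
three methods: as basal polytomies at their family's MRCA; at a uniformly
chosen internal node within the family clade; or taxonomy-constrained
(family MRCA when the family is present, otherwise the order's MRCA — an
in-package stand-in for placement against a taxonomic megatree service). The
pendant branch always spans from the attachment point to the tree height, so
ultrametricity is preserved exactly, and grafting never changes distances
among pre-existing tips. When a family is represented by a single tip, a new
node is created halfway down that tip's pendant branch so the family stays
monophyletic. Polytomies created by grafting are kept as polytomies: nothing
in the downstream distance computations requires resolving them, and any
resolution rule would add arbitrary structure.

# Zone-composition overlap

For two zones with $N_A$ and $N_B$ species drawn from a pool of $P$, the
number of shared species is compared with a null built by drawing
independent uniform subsets of the same sizes 1,000 times (null mean
$N_A N_B / P$, the hypergeometric expectation — asserted in the tests within
Monte-Carlo error). Right- and left-tail p-values ("more similar" / "less
similar than random") are both reported with the add-one correction; both
tails include ties, so $p_{right} + p_{left} \ge 1$. The pool for this test
should be the survey-specific species list, not the whole regional flora —
the pipeline uses the union of the observed zone compositions by default and
the pool is an explicit argument everywhere.

# Edaphic screen

Every (species, property) cell gets two tests on the plot-level data:
Spearman rank correlation (mid-ranks; exact permutation p for $n \le 9$
without ties, t-approximation otherwise) for monotone response, and
Hoeffding's D for dependence of any shape — the intended catch-all for
unimodal optima, e.g. cover peaking at intermediate pH. D is computed from
joint and marginal rank counts with mid-rank tie handling, scaled by 30 to
lie in roughly $[-0.5, 1]$; its p-value is obtained by permuting one margin
(9,999 permutations by default for single screens, fewer inside the grid
screen) rather than by the classical asymptotic approximation — permutation
is exact in distribution at any $n$ and needs no tie corrections. A property
is *important* for a species when either test reaches $p \le 0.01$. No
correction is applied across the grid — the per-cell rule is the decision
procedure being implemented, and under fully independent data the expected
flag rate is at most $2\alpha$ (asserted in the tests) — but BH q-values
over the grid are attached for users who want them.

Properties important for more thermophytes than chance expects are found by
a one-sided Fisher exact test per property on the 2×2 table (thermophyte vs
not) × (important vs not); this is algebraically the hypergeometric tail
`p_over(N, K, n, k)` and is computed by it, cross-checked against
`fisher.test` in the suite.

# Soil indices and comparisons

* **Temperature gradient**: the linear model $T(d) = k\,d + T_{15}$ anchored
  at the 15 cm reference depth; with the standard two measurement depths (15
  and 50 cm) $k = (T_{50}-T_{15})/35$, with more depths the least-squares
  slope. The gradient angle is $\alpha = \arctan k$ in degrees: about
  4.6–5.2° for non-heated profiles ($\Delta T \approx 2.8\!-\!3.2$ °C over
  35 cm) and 23–37° for strongly heated ones.
* **Weathering**: the silica–titanium index
  $STI = 100\,\mathrm{SiO_2} / (\mathrm{SiO_2/TiO_2} +
  \mathrm{Al_2O_3/TiO_2} + \mathrm{SiO_2/Al_2O_3})$ and the sesquioxide
  ratio $\mathrm{SiO_2}/(\mathrm{Al_2O_3+Fe_2O_3+TiO_2})$ on oxide mass
  percentages. The ratio is scale-invariant; STI is homogeneous of degree 1
  in the oxides — both behaviours are asserted in tests.
* **Group comparisons**: one- or two-sided Mann–Whitney tests for every pair
  of groups (zones, temperature classes `<30`, `[30,50)`, `[50,80)`,
  `>=80` °C — boundaries left-closed, so a 30 °C sample is "slightly
  heated" — or depth layers), exact when sample sizes permit and tie-free,
  Bonferroni-corrected over the pairwise tests performed. The one-sided
  direction must be declared by the caller; the pipeline derives it from
  each property's configured gradient direction.
* **Composition profiles** are normalised per variable to the reference
  (coolest) zone as ratios of medians — the median is used for robustness at
  $n \approx 9$ samples per zone and the statistic is an argument.

# The synthetic-data generator

The generator defines the study conditions under which everything is tested.
Defaults emulate a geothermal-valley flora and catena at realistic scale:

* **Pool**: 292 species in 60 families (1–9 species per family), grouped
  into orders of ~3 families and two classes; ultrametric depth-1 pure-birth
  (Yule) phylogeny in which every family is monophyletic — the simplest
  process giving realistic clade structure.
* **Thermophytes**: 18 obligate + 33 facultative. The facultative count is
  the published survey scale; the obligate count is a free parameter (no
  published total exists) fixed once at 18, consistent with a flora where 9
  of 60 families contain obligate species and the largest obligate family
  holds 4. `clustering_strength` is the probability that each successive
  thermal species is drawn from an already-thermal family: 0 gives uniform
  (hypergeometric per-family counts, asserted by Monte Carlo), 1 packs
  thermophytes into the fewest families — the planted signal used by the
  clustering tests.
* **Zones**: four, with weakly decreasing richness 24 > 18 > 12 > 6 species
  (survey plots ranged from ~24 species on non-heated ground to ≤6 on hot
  ground). Hotter zones sample from the previous zone's species plus all
  thermophytes, with non-thermal candidates down-weighted by
  $e^{-1.2(z-1)}$ — non-thermal species are lost first, and hot-zone
  compositions are approximately nested.
* **Soils**: per-zone property means with truncated Gaussian noise (pH
  6.3→4.2, EC 0.15→3.5 dS/m, SOC 12→1.5 %, SiO₂ down, Al/Fe/Ti oxides up,
  clay up, sand down along the catena); per-pit gradient angles drawn from
  the zone windows (4.6–5.2°, 10–19°, 23–37°, 0–11°) and temperatures
  propagated through the linear depth model. Percentages are truncated to
  valid ranges and particle-size fractions repaired to sum to 100.
* **Cover**: species' percent covers at 12 plots; nominated (species,
  property) pairs are tied through a Gaussian copula at a configured latent
  correlation (defaults plant a +0.95 conductivity effect on the first
  obligate, −0.85 pH and +0.85 SOC effects on a facultative and a
  non-thermal species), and those species are guaranteed to occur along the
  whole catena. A latent correlation of 0.95 corresponds to a population
  Spearman of ≈ 0.94, comfortably detectable at $n = 12$.

What the generator does **not** emulate: spatial autocorrelation among
plots, mineral co-occurrence structure beyond monotone zone trends,
abundance distributions with realistic zero-inflation, detection error, or
correlated property blocks like real geochemistry (each property gets
independent noise). Passing tests therefore demonstrate that the statistics
recover signals of the planted form at survey scale — not that real
geothermal data meet these assumptions. One consequence is visible in the
demonstration bundle: because zone membership drives both cover and soils,
many (species, property) cells are genuinely associated, so a high
importance rate in the synthetic screen is a property of the planted world,
not a false-positive rate.

# Reproducibility and problem sizes

Every stochastic function takes an integer `seed` and uses it through an
isolated RNG scope; nested stages consume sub-seeds derived from their
parent, so a config plus one seed reproduces a dataset and a full result
bundle byte for byte (asserted in the tests). The pipeline writes outputs
only after all requested stages succeed, so a failure never leaves a partial
bundle.

The test suite runs the procedures at the scales stated in the methods
(10,000 null draws, 10 replicates, 100-pair subsampling, 200-seed
calibration sweeps for the NRI null; 5,000-simulation calibration of the
Hoeffding permutation p) and scales down only auxiliary Monte-Carlo checks
(e.g. 2,000 repetitions for generator uniformity); each test states its own
sizes. Known limitations: the pair-subsampling NRI null's anti-conservatism
discussed above; Hoeffding's D is $O(n^2)$ per evaluation, fine for plot
counts in the tens; and the taxonomy-constrained grafting method is an
approximation to megatree-service placement, not a reimplementation of it.
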