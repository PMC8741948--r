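---
title: "Methods: root-mycobiome diversity, guilds and co-occurrence networks"
author: "milletmyco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: root-mycobiome diversity, guilds and co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`milletmyco` implements the downstream statistical analysis of a fungal ITS
metabarcoding survey of plant roots, organized around the comparison of
cultivated and wild pearl millet across three agro-ecological sites. The
pipeline takes an OTU count table (OTUs × samples), a taxonomy table, a
FUNGuild-style guild lookup and per-sample metadata (site, plant type, plot,
soil chemistry), and produces:

1. rarefaction-normalized counts and per-sample α-diversity;
2. Bray–Curtis β-diversity with NMDS ordination, PERMANOVA, a multivariate
   dispersion test and environmental vector fitting;
3. trophic-mode and guild relative abundances with per-site soil
   correlations;
4. a prevalence-based core mycobiome;
5. per-plant-type Spearman co-occurrence networks with topology metrics,
   hub calling and a cross-network comparison.

Upstream read processing (assembly, OTU clustering, taxonomic
classification) is out of scope: taxonomy is an input. So are mixed-effects
model fits and differential-abundance testing; the pipeline exports the
tidy per-sample tables those models would consume.

A synthetic-data module generates complete datasets with planted ground
truth, so every stage is validated by parameter recovery rather than by
eyeballing.

# Models and procedures

## Rarefaction and α-diversity

Libraries are subsampled **without replacement** (multivariate
hypergeometric) to a common depth, 25,556 reads by default — the smallest
library of the emulated design, whose sizes span 25,556–154,517. A single
draw is taken under a recorded seed, matching the single normalized dataset
a typical workflow analyses; the test suite instead averages over 1,000
draws and checks the closed-form hypergeometric expectation of rarefied
richness. Samples below the target depth are dropped with a logged warning.

Per sample we report observed richness, Shannon entropy in nats
($H = -\sum_i p_i \ln p_i$) and the Gini–Simpson index
($1 - \sum_i p_i^2$); the raw Simpson concentration is exported alongside.
Natural-log Shannon and Gini–Simpson are the R-ecosystem defaults and make
the indices comparable with the bulk of the amplicon literature.

## β-diversity

Bray–Curtis dissimilarity,
$d(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$, is computed on the
rarefied counts.

**NMDS** minimizes Kruskal stress-1 by alternating monotone (isotonic)
regression of configuration distances on the dissimilarity order with
Guttman-transform updates. Ties in the dissimilarities are handled by the
primary approach (tied pairs are pre-sorted by current configuration
distance, so they never constrain each other). Twenty restarts are used by
default — the first from classical scaling, the rest random — and the
lowest-stress solution is returned, centred and rotated to principal axes.
Iteration stops when the stress improvement falls below $10^{-7}$ or after
300 iterations; an uphill safeguard reverts any step that would increase
stress, so the reported stress sequence is non-increasing. On random
Bray–Curtis matrices the stress agrees with `vegan::metaMDS` to well within
0.02 (cross-implementation test).

**PERMANOVA** partitions the Gower-centred inner-product matrix
$G = -\tfrac12 C D^{(2)} C$ sequentially (Type-I) over the terms site,
plant type and their interaction — the classic `adonis` behaviour and the
order in which such tables are reported. Pseudo-F statistics use the
residual of the full model; p values come from permuting whole samples,
with the add-one convention $p = (\#\{F^* \ge F\} + 1)/(n_{perm} + 1)$ so p
never reaches zero. `permutations = "exact"` enumerates all $n!$
relabelings for small n, and equals a brute-force enumeration oracle in the
tests. Permutations are unrestricted: nothing in the emulated design
dictates plot-level restriction, and the permutation scheme is configurable
if a user's design does.

**Dispersion homogeneity** embeds the distance matrix by principal
coordinates, keeping negative eigenvalues as an imaginary correction, and
measures each sample's distance to its group centroid as
$\sqrt{\max(0, d_{real}^2 - d_{imag}^2)}$; this reproduces
`vegan::betadisper(type = "centroid")` distances to machine precision. The
group F statistic on those distances is tested by permuting the distances
across groups. Singleton groups are excluded from the test with a warning.

**Environmental fitting** regresses each (centred) soil variable on the 2-D
NMDS scores — the configuration actually displayed in ordination figures —
reporting the squared multiple correlation $r^2$, unit direction cosines,
and a permutation p from shuffling the variable across samples. Missing
soil values are dropped pairwise with a logged count; constant variables
return $r^2 = 0$, $p = 1$ with a warning.

## Guilds and trophic modes

OTUs are looked up in a FUNGuild-style table at the most specific
taxonomic rank present (species > genus > family > …), case-insensitively;
when several rows match a name, a row whose declared `taxonomicLevel`
equals the matched rank is preferred. Only assignments ranked *Highly
Probable* or *Probable* are accepted; others are retained in the output but
marked `Unassigned`, as are unmatched OTUs. Trophic-mode strings are
canonicalized order-insensitively into the seven groups Pathotroph,
Saprotroph, Symbiotroph, Pat_Sap, Pat_Sym, Sap_Sym and Pat_Sap_Sym.

Group relative abundances are read-weighted proportions over **assigned
OTUs only** (the denominator excludes `Unassigned`), so rows sum to 1 over
assigned groups; an OTU-incidence mode is available behind a flag. Where a
choice existed between per-sample means and pooled-count proportions for
group summaries, per-sample means are used (both are exportable): they
weight samples equally, which matches how replicate-level models treat the
data.

Soil correlations are Pearson r per (soil variable, trophic group) within
each site, with two-sided p from the t distribution on $n-2$ df. Stars
(0.05 / 0.01 / 0.001) code the **unadjusted** p — the convention of
per-cell heatmap annotation — and a BH-adjusted column over all cells is
exported alongside for readers who want multiplicity control.

## Core mycobiome and co-occurrence networks

The core is the set of OTUs present in at least 75% of all pooled samples
(boundary inclusive). Its summary reports the share of observed richness
and of reads, as percentages rounded to one decimal.

Networks are built per plant-type stratum on the rarefied core counts
(after equal-depth rarefaction this is equivalent to using relative
abundances for a rank statistic). Spearman's ρ with average-rank ties is
computed for every unordered OTU pair, two-sided p values are BH-adjusted
**within each network** (the two networks are built and interpreted
separately), and edges require $|\rho| > 0.6$ and $q < 0.01$. Constant
OTUs are excluded with a warning; nodes without a surviving edge are
dropped.

Topology is computed on the unweighted, sign-blind graph (correlation
magnitudes stay available as edge attributes): degree; unnormalized
shortest-path betweenness; classic closeness normalized within each
connected component; eigenvector centrality on the largest component (0
elsewhere); average path length and diameter over the largest component;
density $2E/N(N-1)$; mean local clustering (degree-<2 nodes count 0); and
Louvain modularity at resolution 1, reported as the best of 10 seeded runs
(the spread across runs is also reported and is < 0.02 on the test
graphs).

**Hubs** are OTUs in the top $k = \lceil 0.02 N \rceil$ of *both* degree
and betweenness (ties at rank k included), i.e. the intersection of the
two candidate sets; a union rule is available behind a flag. Intersection
is the stricter reading of a "top 2% of degree and betweenness" rule and
reproduces few-hub behaviour from ~5 candidates per metric at the
published network size (N = 214 → k = 5). On small graphs this rule
degenerates: with N ≈ 17 nodes, k = 1 and the intersection of two top-1
sets is usually empty. The parameter-recovery tests therefore scale the
fraction so the candidate sets have a few members (top 20% of ~17 nodes =
4 candidates, the same regime as 2% of 214); the method default remains
0.02.

Node-metric distributions of two networks are compared per metric with a
two-sided Wilcoxon rank-sum test: exact enumeration when both networks
have ≤ 10 nodes and no ties, otherwise the normal approximation with tie
correction.

# The synthetic-data generator

The generator emulates the study design: 3 sites partitioned into 6 plots
(2/3/1 by default), 2 plant types, 5 replicates per plot and plant type —
60 samples — with library sizes drawn log-uniformly in 25,556–154,517 and
~long-tail (log-normal, sdlog 2) OTU abundances.

Counts follow a **Gaussian copula with negative-binomial marginals**
(dispersion 0.5): a multivariate-normal draw per sample is
probability-transformed through per-OTU NB quantile functions, then
multinomially subsampled to the sample's library size, so column sums
equal the drawn depths exactly. The copula was chosen because it
approximately preserves rank correlation — precisely the statistic the
network stage consumes. Non-PSD correlation inputs are projected to the
nearest PSD correlation (eigenvalue clipping) with a warning.

Planted structure, all recorded as ground truth:

* **Correlation blocks** (`block_spec`): uniform within-block ρ; a
  negative sign alternates loadings so roughly half the block's pairs are
  negative. Defaults (12 @ 0.85, 10 @ 0.8, 8 @ 0.75 positive; 10 @ 0.85
  signed) yield scaled-down networks with a strong predominance of
  positive edges, as observed in real root mycobiomes.
* **Hub systems** (`hub_spec`): one hub correlated at ρ with each of its
  partners via a single factor (partner–partner correlation ρ², the
  minimum a valid correlation matrix essentially allows).
* **Site and plant effects**: log-scale per-OTU effects. Planted OTUs
  share a per-block site response scaled by their copula loading — the
  habitat-filtering signal that keeps co-occurring taxa correlated across
  heterogeneous sites — while independent OTUs respond idiosyncratically.
  `site_effect_sd = 1.0` and `plant_effect_sd = 0.3` were set so the
  PERMANOVA partition of simulated data lands near the regime the design
  emulates (site R² ≈ 0.2, plant ≈ 0.03, interaction ≈ 0.03-0.04, NMDS
  stress ≈ 0.2); they are fixed defaults, not fitting knobs.
* **Abundance placement**: block/hub OTUs receive evenly spaced abundance
  ranks in the upper tier so they are prevalent enough to enter the 75%
  core, where the real study's co-occurrence analysis lives.
* **Diversity tilt** (`diversity_effect = 0.2`): wild-sample base means
  are raised to the power 1.2 and renormalized, increasing dominance and
  hence lowering wild richness/evenness — reproducing the
  higher-diversity-in-cultivated pattern.
* **Guild mixture** (`guild_mix`): per-plant-type trophic-group
  proportions (defaults anchored at ~38% pathotroph / ~28% saprotroph
  overall, pathotroph-enriched in cultivated, saprotroph-enriched in
  wild); 27% of OTUs are left guild-unresolvable. Genus names are drawn
  from a packaged miniature synthetic guild lookup (~44 genera with
  plausible but curated trophic modes) so assignment resolves end-to-end.
* **Soil chemistry** (`soil_corr_spec`): within each site, a targeted
  variable is built as $r\,z(\text{group abundance}) +
  \sqrt{1-r^2}\,\varepsilon$ on the variable's natural scale (pH ~6.2,
  total C ~0.5%, total P ~70 mg/kg, matching sandy ferruginous topsoils),
  with site-level baseline shifts; realized per-site correlations are
  recorded in the ground truth.

One master seed expands into per-stage child seeds through a label hash
(`child_seed`), so any stage can be regenerated independently and
identical configurations reproduce every artifact byte-for-byte.

**What the generator does not emulate**: read-level errors, chimeras and
taxonomy mis-assignment; compositional closure beyond multinomial
subsampling; spatial autocorrelation between plots; block-diagonal
correlation only (no overlapping modules); and the real study's taxonomic
richness (defaults use 600 OTUs, not 5,524 — the generator scales, but
tests run scaled-down). Passing recovery tests therefore demonstrates
that the statistical machinery detects the structure it claims to detect,
not that real root mycobiomes satisfy these models.

# Numerical choices and degenerate inputs

* p values from permutation tests are never 0 (add-one convention).
* Spearman p values use the t approximation on $n-2$ df with average-rank
  ties; perfect monotone pairs are assigned p = 0 explicitly.
* The NMDS safeguard accepts only downhill steps; degenerate collapses
  (all distances zero) stop the run.
* All-zero count vectors, all-zero samples, constant variables, singleton
  groups and empty networks produce errors or flagged NA/empty outputs
  rather than silent results; the pipeline logs every dropped sample/OTU
  with a reason code in the manifest.
* Rarefying an already-rarefied table resamples again (documented); the
  pipeline rarefies exactly once.

# Problem sizes used by the test suite

Module tests run on toys (≤ 60 OTUs, ≤ 30 samples) with closed-form or
brute-force oracles. The end-to-end checks use: 1,000 null PERMANOVA
datasets (12 samples × 15 OTUs, 99 permutations) for type-I calibration;
50 replicates of 30-sample networks for spurious-edge, block-recovery and
hub-recovery rates; 1,000 rarefaction draws for the hypergeometric
oracle; and the default 60-sample, 600-OTU design for the full pipeline.
These sizes were chosen to make the Monte-Carlo assertions stable at the
tolerances tested.

# Known limitations

* Plain Spearman co-occurrence ignores compositionality;
  compositionality-aware methods (SparCC, SPIEC-EASI) are deliberately
  out of scope, and spurious negative correlation from closure is partly
  absorbed by the rarefied-counts design but not eliminated.
* The packaged guild lookup is a synthetic miniature, suitable for tests
  and simulation, not for annotating real data — point `read_guild_db()`
  at a real FUNGuild export for that.
* Mixed-effects refits (plot as random factor) are out of scope; the
  α-diversity and guild tables are exported in exactly the tidy layout
  such a refit consumes.
* The dispersion test permutes centroid distances (not model residuals);
  for balanced designs of this kind the two approaches agree closely.
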