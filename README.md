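# milletmyco

Downstream analysis of root-associated fungal communities (mycobiomes)
profiled by ITS metabarcoding, built around the comparison of **cultivated
vs wild pearl millet** across contrasting agro-ecological sites. The
package is for microbial ecologists who have an OTU count table, a
taxonomy table, a FUNGuild-style guild lookup and sample metadata (site,
plant type, plot, soil chemistry), and want the full battery of
community-level statistics behind a typical root-mycobiome paper — as
tested, reusable functions rather than a one-off script.

## What it computes

* **Normalization & α-diversity** — multivariate-hypergeometric
  rarefaction to equal depth (default 25,556 reads); observed richness,
  Shannon *H* = −Σ *p*ᵢ ln *p*ᵢ, Gini–Simpson 1 − Σ *p*ᵢ².
* **β-diversity** — Bray–Curtis *d*(x,y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ); NMDS
  minimizing Kruskal stress-1 (isotonic regression + Guttman updates,
  multi-restart); PERMANOVA with sequential (Type-I) partitioning of the
  Gower-centred distance matrix over site, plant type and their
  interaction, permutation p values; homogeneity of multivariate
  dispersions; environmental vector fitting of soil variables onto the
  ordination; Benjamini–Hochberg FDR utilities.
* **Trophic guilds** — FUNGuild-style assignment at the most specific
  matching rank with a Highly Probable/Probable confidence filter;
  aggregation into the 7 trophic-mode groups (Pathotroph, Saprotroph,
  Symbiotroph and their combinations); per-site Pearson correlations
  between soil properties and group abundances with significance stars.
* **Core mycobiome** — OTUs present in ≥ 75% of samples, with richness
  and read shares.
* **Co-occurrence networks** — per plant type, Spearman ρ over all core
  OTU pairs, edges kept at |ρ| > 0.6 and BH-FDR q < 0.01; node topology
  (degree, betweenness, closeness, eigenvector), network topology
  (average degree, path length, diameter, density, Louvain modularity,
  clustering); **hub OTUs** as the intersection of the top-2% sets of
  degree and betweenness; Wilcoxon comparison of node metrics between
  networks.
* **Synthetic data with ground truth** — a Gaussian-copula /
  negative-binomial simulator reproducing the 60-sample design (3 sites ×
  2 plant types × 6 plots × 5 replicates, library sizes 25,556–154,517),
  with planted correlation blocks, hub systems, site/plant effects and
  soil–guild correlations, so every stage is validated by parameter
  recovery.

See `vignettes/millet-mycobiome-methods.Rmd` for the models, parameter
choices and limitations.

## Worked example

```r
library(milletmyco)

ds   <- generate_dataset(sim_config(seed = 42))       # 600 OTUs x 60 samples
rare <- rarefy_counts(ds$counts, 25556, seed = 1)

alpha <- alpha_table(rare, ds$metadata)
aggregate(cbind(richness, shannon) ~ plant_type, alpha, mean)
#>   plant_type richness shannon
#> 1 cultivated    354.2   3.946
#> 2       wild    304.8   3.603

d <- bray_curtis(rare)
nmds(d, k = 2, seed = 2)
#> NMDS ordination: 60 samples, 2 dimensions, stress = 0.2160 (converged)

permanova(d, ds$metadata, permutations = 999, seed = 3)
#> PERMANOVA (999 permutations)
#>             term df      SS     MS     F      R2     p
#>             site  2  3.2475 1.6237 8.217 0.22015 0.001
#>       plant_type  1  0.3797 0.3797 1.921 0.02574 0.010
#>  site:plant_type  2  0.4533 0.2266 1.147 0.03073 0.228
#>        Residuals 54 10.6707 0.1976    NA 0.72338    NA
#>            Total 59 14.7511     NA    NA 1.00000    NA

core <- core_mycobiome(rare, 0.75)
core
#> Core mycobiome at 75% prevalence: 173 of 600 OTUs
#>   28.8% of observed richness, 92.1% of reads; 2 OTU(s) in every sample

cult <- ds$metadata$sample_id[ds$metadata$plant_type == "cultivated"]
net  <- build_network(rare[core$otu_ids, cult],
                      annotations = ds$annotations, label = "cultivated")
net
#> Co-occurrence network [cultivated]: 66 nodes, 203 edges (91.13% positive), 30 samples

identify_hubs(node_metrics(net), 0.02)
#> Hub OTUs (intersection of top-2 sets; degree >= 11, betweenness >= 23.379): OTU_0004
```

Reading the output: the simulated communities are structured mainly by
site (R² = 0.22, p = 0.001) with a smaller plant-type effect, cultivated
samples are more diverse than wild, about a quarter of OTUs form the
prevalence core, and the cultivated-stratum network is dominated by
positive co-occurrences with one OTU in the top tier of both degree and
betweenness centrality (a hub/keystone candidate). All of these are
planted properties of the simulation — `ds$truth` holds the ground truth.

The whole analysis can also be run as one orchestrated, manifest-logged
pipeline:

```r
cfg <- pipeline_config(sim = sim_config(seed = 7), out_dir = "out")
run_pipeline(cfg)   # writes TSV/GraphML/JSON outputs + manifest.json
```

or from a shell via the thin wrapper `inst/scripts/milletmyco`
(subcommands `validate`, `alpha`, `beta`, `guilds`, `network`, `run`).

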