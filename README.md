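# fecology

Downstream analysis of fungal endophyte communities (FECs) profiled by
amplicon sequencing across several host species and sampling sites.

Surveys of plant endophytes typically produce a taxa-by-sample count table
(denoised amplicon variants, possibly agglomerated to species), sample
metadata (host species, site), and a taxonomy table. From there, the
questions are always the same: how should the table be filtered; how diverse
is each population of plants; how different are the plants within a
population and the populations of one host across sites; do host and site
structure the communities; and which taxa co-occur consistently enough
across sites to look like hubs of community assembly. `fecology` implements
that whole downstream path as tested, reusable R functions, plus a synthetic
multi-host community generator with known ground truth so every stage has a
parameter-recovery test without any external data.

## What it computes

* **Dataset bookkeeping** — species-level agglomeration, removal of sparse
  samples (< 1000 reads), whole-dataset singleton/doubleton removal, the
  incidence < 5 core-prevalence filter, shared/unique taxon partitions
  across hosts, class-level composition, and top-taxa ranking with per-taxon
  host ANOVA.
* **Alpha diversity** — incidence-based Hill numbers ^q^D for q = 0, 1, 2
  (richness, exponential Shannon entropy, inverse Simpson concentration)
  with sample-size-based rarefaction and extrapolation. For q = 0 the
  interpolated value is the exact expected richness of a random subset of
  *t* sampling units,
  S(t) = S_obs − Σ_i C(T−Y_i, t) / C(T, t),
  and extrapolation uses the Chao2 unseen-taxa term
  Q̂₀ = ((T−1)/T) · Q₁² / (2Q₂). Bootstrap intervals resample sampling
  units (plants) with replacement.
* **Kosman statistics** — the assignment-based dispersion KW of a
  population (minimal average dissimilarity over a fixed-point-free optimal
  matching of its plants), the Kosman distance KB between populations
  (optimal one-to-one cross-population matching), the differentiation
  statistic D from the additive partition of dispersion
  (total = within + among) with a permutation test, and the effective
  number of populations ¹D(TM) = 1 + (N−1)·M with its normalisation
  ¹nD(TM) = M. The assignment problems are solved exactly by a compiled
  shortest-augmenting-path solver.
* **Beta diversity** — Bray–Curtis dissimilarity on Hellinger-transformed
  abundances, Dice dissimilarity on incidence, principal coordinate
  analysis, and one-factor PERMANOVA / ANOSIM permutation tests (through
  vegan).
* **Co-occurrence networks** — per-population Spearman edges at genus level
  (p < 0.001, t approximation, midranks), discard of single-site
  associations, combination into per-host networks with per-sign
  accumulated rho, vertex centralities, hub-candidate ranking (high degree
  and closeness, low betweenness), and network summary statistics.

## Worked example

```r
library(fecology)

# simulate a two-host, two-site survey with known ground truth
cfg <- synthetic_config(hosts = c("wheat", "wild"),
                        sites = list(wheat = c("north", "south"),
                                     wild  = c("north", "south")),
                        plants_per_population = 20,
                        n_core_taxa = 80, n_sporadic_taxa = 120,
                        host_effect_sd = 0.6, seed = 42)
g <- generate_community(cfg)

# incidence-based Hill diversity of one population
inc <- to_incidence(g$counts)
pop <- population_labels(g$metadata)
f <- incidence_frequencies(inc, names(pop)[pop == "wild@north"])
c(S_obs = f$S_obs, chao2 = hill_asymptote(f, 0),
  D1 = hill_estimate(f, 1, f$T), D2 = hill_estimate(f, 2, f$T))
#>     S_obs     chao2        D1        D2
#> 158.00000 237.82639 100.56656  90.32939

# Kosman dispersion within each population, on Dice distances
dmx <- dice(inc)
within_population_variation(dmx, pop[colnames(inc)], pooled = FALSE)
#>    population  n         KW mean_dispersion effective normalized
#> 1 wheat@north 20 0.06121559      0.07381127  2.163096 0.06121559
#> 2 wheat@south 20 0.06446689      0.08209391  2.224871 0.06446689
#> 3  wild@north 20 0.07389938      0.08864448  2.404088 0.07389938
#> 4  wild@south 20 0.07203577      0.09030109  2.368680 0.07203577

# differentiation among the wild host's two site populations
host <- g$metadata$host[match(colnames(inc), g$metadata$sample_id)]
differentiation(dmx[host == "wild", host == "wild"],
                pop[colnames(inc)][host == "wild"], n_perm = 999, seed = 1)
#> Differentiation among 2 populations (partition variant)
#>   D = -0.000356, p = 0.864 (999 permutations)
#>   mean Kosman distance M = 0.07242, 1D(TM) = 1.072, 1nD(TM) = 0.07242

# host effect on community structure
permanova(bray_curtis(hellinger_transform(g$counts)), host,
          n_perm = 999, seed = 1)
#> PERMANOVA: statistic = 21.273, R2 = 0.2143, p = 0.001 (999 permutations)
```

Reading the output: the observed richness of the `wild@north` population is
158 taxa, with a Chao2 asymptote of ~238 — many taxa remain undetected at 20
plants. The per-population KW values are small because this generic
configuration plants only a weak site effect, and accordingly the
differentiation D between the wild host's two sites is indistinguishable
from its permutation null (p = 0.86). The planted host effect, in contrast,
is detected clearly (PERMANOVA p = 0.001, R² = 0.21).

`run_pipeline(pipeline_config(synthetic = preset_paper_shape(seed = 1)),
"out/")` runs every stage on a full survey-scale synthetic dataset
(3 hosts, 14 populations, ~530 samples, ~1760 taxa) and writes all stage
tables, per-host GraphML networks and a JSON manifest; `pipeline_report()`
renders a markdown summary.

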