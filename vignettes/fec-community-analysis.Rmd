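---
title: "Methods: diversity, differentiation and co-occurrence analysis of endophyte communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, differentiation and co-occurrence analysis of endophyte communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fecology)
```

This vignette is the package's account of its statistical methods: the
models and estimators, the parameters that matter, the numerical
conventions adopted where the field's usage is ambiguous, and what the
synthetic generator does and does not emulate.

## The data model

All stages consume a taxa-by-sample matrix of non-negative integer read
counts, sample metadata assigning each sample (one plant) to a *population*
(host species x site), and a seven-rank taxonomy in which a rank that could
not be assigned carries the `UNASSIGNED` sentinel, with everything below an
unassigned rank unassigned too. Two derived value scales are used
downstream: the Hellinger transform (per sample, square root of relative
abundance; the squared values of a sample sum to one), which damps the
dominance of abundant taxa before Bray-Curtis and ordination, and the 0/1
incidence matrix, on which all within-population diversity statistics
operate.

## Filtering conventions

The preparation chain is agglomeration, then a sample read floor, then
rarity filters:

* **Species agglomeration** sums all taxa sharing an identical full
  species-level assignment; taxa unassigned at species rank keep their own
  identity, since nothing certifies that two unassigned variants are the
  same species. Read totals are conserved.
* **Sample floor**: samples with total reads strictly below 1000 are
  dropped. The boundary sample (exactly 1000 reads) is kept.
* **Singletons and doubletons** are read here as taxa with *total read
  count* of 1 or 2 across the whole dataset (preset `singleton_doubleton`,
  `min_total_reads = 3`). An incidence-based reading exists in the
  literature; both are expressible because `filter_rare_taxa()` takes the
  two thresholds independently.
* **Core prevalence**: "incidence below 5" is implemented as *keep if
  incidence >= 5*, so a taxon present in exactly 5 samples survives. The
  boundary is genuinely ambiguous in common usage ("incidence < 5 removed"
  vs "prevalence threshold of > 5"); we chose the inclusive keep and made
  the threshold a plain argument so the other reading is one character away.
* The `beta` preset (>= 3 reads and incidence >= 5) feeds the
  dissimilarity-based stages. Alpha diversity deliberately runs on the
  *unfiltered* (post-sample-floor) table: uniques and duplicates carry the
  information that richness estimators need, so removing rare taxa before
  estimating richness biases the asymptote downwards.

Shared/unique taxon partitions (`venn_partition()`) report read shares
against a caller-supplied reference table, because the natural statement is
"the taxa unique to host X account for such-and-such a share of the *full*
dataset", not of the filtered core.

## Incidence-based Hill numbers

For a population of `T` plants, the incidence frequency `Y_i` of taxon *i*
is the number of plants containing it; `U = sum(Y_i)`; `Q1` and `Q2` count
uniques and duplicates. Diversity of order q weighs taxa by their relative
incidence `Y_i / U`: q = 0 is richness, q = 1 the exponential of Shannon
entropy, q = 2 the inverse of Simpson concentration, and the ordering
`D0 >= D1 >= D2` holds at every sample size.

Rarefaction and extrapolation follow the incidence formulas of the
sample-size-based framework used throughout community ecology:

* **q = 0, interpolation**: `S(t) = S_obs - sum_i C(T-Y_i, t) / C(T, t)`,
  the exact expectation of richness over all subsets of `t` plants (the
  test suite verifies this against exhaustive subset enumeration for all
  `T <= 10`).
* **q = 0, extrapolation**: Chao2 unseen-taxa term
  `Q0 = ((T-1)/T) Q1^2 / (2 Q2)` when `Q2 > 0`, else
  `((T-1)/T) Q1 (Q1-1) / 2`, approached exponentially in the number of
  added plants.
* **q = 1**: interpolation goes through the expected incidence frequency
  counts `Q_k(t)`; at `t = T` this reduces analytically to the observed
  exponential entropy. For extrapolation the log-diversity blends the
  observed and asymptotic entropies in proportion `T/t` and `(t-T)/t`, so
  the curve is continuous at `T` and approaches the asymptotic estimator;
  the asymptotic incidence entropy uses the standard
  digamma-plus-unseen-mass estimator. q = 1 is always computed by its own
  estimator, never as a numerical limit in q.
* **q = 2**: a single closed-form estimator
  `D2(t) = U_t^2 / sum_i [ (t/T) Y_i + (t(t-1))/(T(T-1)) Y_i (Y_i - 1) ]`
  is unbiased on both sides of `T`.

Asymptotes are floored at the observed diversity. Extrapolation is capped
at `2T` by default; the cap is an argument (`extrap_factor`) because no
universal endpoint exists.

**Bootstrap intervals** resample the `T` plants with replacement and
recompute the whole curve, taking percentile intervals. This is simpler
than the estimated-assemblage bootstrap some packages use: it conditions on
the observed assemblage and therefore gives zero-width intervals for
degenerate populations (all plants identical), which we consider honest
behaviour. The replicate count (default 200; the pipeline default is 50)
trades interval smoothness against runtime.

## Kosman dispersion and differentiation

Within a population with pairwise distance matrix `d` (Dice on incidence by
convention), the assignment-based dispersion is

> `KW = (1/n) * min over fixed-point-free permutations s of sum_i d(i, s(i))`

— each plant is matched to its most similar *other* plant, globally
optimally; mutual pairings (2-cycles) are allowed, self-pairing is not.
This is solved as a linear assignment problem with the diagonal set to a
cost larger than any derangement can accumulate, using a compiled exact
shortest-augmenting-path solver; the fixed-point-free property of the
optimum is asserted post hoc, and the solver is property-tested against
brute-force enumeration over all derangements (n <= 7).

Between two populations, the Kosman distance `KB` is the minimal average
cost of matching every member of the smaller population to a distinct
member of the larger (rectangular assignment, averaged over `min(n_a,
n_b)` matched pairs). The references' balancing scheme for unequal sizes is
not printed anywhere we could verify, and real populations do differ in
size, so the rectangular matching is the least-assumption choice.

For `N` populations of one host, `M` is the mean of the `N(N-1)/2` pairwise
`KB` values; the effective number of populations is
`1D(TM) = 1 + (N-1) M` and its normalisation `1nD(TM) = M`. The identity is
exercised in the tests against the reported survey tables
(`fec_survey_differentiation()`) at their printed precision. For
within-population variation the same normalisation is applied with `M = KW`
and `N` = the number of plants, so the normalised effective number of
distinct plants equals KW itself — which is why published tables of
"normalised variation" are tables of KW.

**The differentiation statistic D** is stated in the source literature only
as "the additive partition of the average-based dispersion". Two readings
survive that phrase, and the printed numbers cannot disambiguate them
(published tables print only normalised quantities, so the raw dispersions
are unrecoverable). Both are implemented behind `variant=`:

* `"partition"` (default): `D = M_pooled - W`, where `M_pooled` is the mean
  pairwise distance over the pooled set of all the host's plants and `W`
  the size-weighted mean of within-population mean dispersions — the
  among-population component of total = within + among.
* `"assignment"`: `D = mean pairwise KB - size-weighted mean KW`.

The permutation test reshuffles plants among the host's populations
preserving population sizes and recomputes D; `p = (1 + hits)/(1 + B)`, so
p is never zero and has resolution `1/(B+1)`. The default `B = 1000`
matches common practice for this statistic. Under the partition variant
the pooled term is permutation-invariant, which keeps the test cheap.

## Ordination and group tests

Bray-Curtis runs on Hellinger-transformed abundances; Dice on incidence.
Both are obtained through `vegan::vegdist` (Dice is binary Bray-Curtis) and
validated into labelled symmetric matrices with zero diagonal in [0, 1].
Two all-zero samples have undefined dissimilarity and are rejected by name.
PCoA is classical metric scaling (double-centred `-d^2/2`); axes with
non-positive eigenvalues are dropped, negative eigenvalues are reported,
and proportions explained are taken over the positive spectrum. PERMANOVA
(`vegan::adonis2`) and ANOSIM (`vegan::anosim`) are deliberately
single-factor: host and site are reported as separate one-factor results,
so no sequential multi-factor partitioning is attempted. The one-factor
pseudo-F is independently verified in the tests against a direct
sums-of-squared-distances oracle, and the permutation p against exhaustive
relabelling on six items.

## Co-occurrence networks

Correlations run at genus level (taxa unassigned at genus rank are
removed, since a nameless vertex is uninterpretable) on within-sample
relative abundances by default. The value scale matters — Spearman is
invariant to per-taxon monotone transforms but not to per-sample
renormalisation — so it is an explicit argument (`raw`, `relative`,
`hellinger`). Per population, every genus pair present in at least 5 plants
(`min_prevalence`, a floor that avoids degenerate rank vectors; the source
protocols are silent here) gets a Spearman rho with midrank ties and a
two-sided p from the t approximation; pairs with `p < 0.001` are kept, with
no multiple-testing correction, matching the raw-threshold convention of
this literature (a Benjamini-Hochberg option would be a one-line wrapper
around the returned p-values). Constant genera are skipped with a message.

Edges are then combined across a host's populations: a pair seen in only
one population is discarded as likely random, surviving pairs record the
number of populations and their accumulated rho, summed separately for
positive and negative values (a pair may flip sign between sites; both
accumulators are kept). Centralities on the combined graph: degree;
harmonic closeness (well-defined on disconnected graphs); normalised
betweenness; eigenvector centrality per connected component with component
scores scaled by the component's share of vertices (a global eigenvector
would assign zero to all but the dominant component). Hub candidates are
ranked by the composite rule high degree + high closeness + low
betweenness, as the sum of three ranks with "min" tie handling and genus id
as the final tie-break; on a star graph this rule correctly rejects the
centre, whose betweenness is maximal. Diameter and mean distance are
reported for the largest connected component; edge density uses the full
vertex set.

## The synthetic generator

`generate_community()` emulates the post-denoising state of a multi-host,
multi-site endophyte survey: per-taxon log-normal latent abundances, host
and site effects as per-taxon log-scale shifts (`host_effect_sd`,
`site_effect_sd`; site effects are shared between hosts sampled at the same
site, mimicking paired sampling), plant-level log-normal noise, sporadic
taxa occurring independently with a small probability, optional
host-specific taxa, and multinomial read counts given a log-normal library
size. Correlated taxon pairs are planted through a Gaussian copula on the
plant-level noise: the latent Pearson correlation is set to
`2 sin(pi rho / 6)` so the *rank* correlation targets `rho`, and the
monotone chain from latent abundance to counts keeps the target
interpretable. Correlated taxa are given above-average base abundance
(mean + 1.5 sd) because count sampling attenuates rank correlations of
rare taxa; with that choice, a planted `rho = 0.9` realises sample Spearman
values of roughly 0.65-0.9 at 40 plants.

`preset_paper_shape()` freezes the survey-scale conditions: 3 hosts with
7/4/3 sites (the wild hosts paired to a subset of the crop's sites), 38
plants per population (532 samples), 400 core plus 1300 sporadic taxa plus
20 host-unique taxa per host, `core_log_abundance_sd = 4`,
`plant_noise_sd = 3`, median library ~8000 reads, sporadic occurrence
probability 0.05. These values were chosen once so that the emitted
communities match the qualitative structure such surveys report — a few
tens of taxa per plant, a few hundred per site out of ~1700 total,
within-population Dice dispersion around 0.5, and a dominant shared core —
and are not revisited.

Reproducibility uses a single `set.seed(cfg$seed)` with a fixed draw order
(populations, then plants) rather than hashed per-population sub-streams:
the guarantee — identical output for identical config — is the same, with
less machinery. The trade-off is that inserting a new draw anywhere changes
all downstream draws; acceptable for a generator whose contract is
whole-dataset determinism.

**What the generator does not emulate**: PCR/sequencing error and chimeras
(it starts after denoising), taxonomic misassignment, overdispersion beyond
the log-normal-multinomial hierarchy (no Dirichlet-multinomial layer),
phylogenetic correlation among taxa, spatial structure within a site, and
compositional interactions other than the planted copula pairs. Passing
parameter-recovery tests on generated data therefore demonstrates that the
estimators recover what was planted under this model — not that real
communities satisfy the model.

## Numerical conventions and degenerate inputs

* Binomial coefficients in the Hill estimators are computed on the
  log scale (`lchoose`) to avoid overflow at large T.
* Estimates at `t = T` reproduce observed diversity to 1e-9 (tested), and
  the q-ordering is enforced only up to the same tolerance.
* Distance matrices are symmetrised on read and validated to 1e-12
  asymmetry; the TSV writer prints 12 significant digits.
* Empty populations, all-zero samples, zero-variance taxa, populations of
  size one, and graphs with no surviving edge all have defined behaviour
  (error with names, skip with warning/message, or empty result) rather
  than NA propagation.
* Permutation p-values are `(1 + hits)/(1 + B)` everywhere.
* ANOVA p-values on zero-variance taxa are defined as 1.

## Problem sizes used by the test suite

The statistical suites run at deliberately modest scale, chosen as the
smallest sizes at which each property is expected to hold with margin:
null calibration uses 200 replicate communities of 3 populations x 10
plants x 120 taxa with 199 permutations each; monotone recovery uses 3
host-effect levels x 20 replicates; network recovery uses 2 replicates of
3 sites x 40 plants with 6 planted pairs; the end-to-end determinism check
runs the full 532-sample survey-scale preset twice. Enumeration oracles
(derangements, injections, subsets) run exactly, at n <= 7 and T <= 10.
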