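# dispkin

Multi-temporal gene-dispersal analysis for georeferenced multilocus genotype
surveys of plant populations — nuclear microsatellites plus a maternally
inherited plastid haplotype — with a spatially explicit forward mating
simulator that provides a ground-truth pedigree for every estimator.

The package targets the classic two-window design for trees: *historical*
dispersal read off the fine-scale spatial genetic structure (SGS) accumulated
over many generations, and *contemporary* dispersal read off parentage
assignment of the current seedling cohort, in the same plots and with the
same markers.

## What it computes

**Diversity and inbreeding** (per site and DBH size class): allelic richness
by hypergeometric rarefaction to a fixed number of gene copies, observed and
unbiased expected heterozygosity, multilocus F<sub>IS</sub> = 1 −
H<sub>O</sub>/H<sub>E</sub> with a gene-copy permutation test, Weir–Cockerham
pairwise F<sub>ST</sub>, selfing rate both from the equilibrium transform
s = 2F<sub>IS</sub>/(1+F<sub>IS</sub>) and from the multilocus identity
disequilibrium g<sub>2</sub> (jackknife over loci), and plastid haplotype
diversity.

**SGS and historical dispersal**: pairwise Loiselle kinship F<sub>ij</sub>
(diploid nuclear or haploid plastid mode), distance-class correlograms with
location-permutation envelopes, and the summary statistics

  Sp = −b<sub>log</sub> / (1 − F<sub>1</sub>),  NS = 1/Sp,

where F<sub>1</sub> is the mean kinship in the first distance class and
b<sub>log</sub> the regression slope of pairwise kinship on ln(distance).
Under drift–dispersal equilibrium Sp ≈ 1/(4πD<sub>e</sub>σ<sub>g</sub>²) for
nuclear markers and 1/(2πD<sub>e</sub>σ<sub>s</sub>²) for plastid markers
(σ² = half the mean squared axial dispersal distance; D<sub>e</sub> =
effective density, by default 25% of the census adult density); the
estimator inverts these with an iterative restricted-range re-fit of the
kinship–ln(d) regression, and the pollen component follows from

  σ<sub>g</sub>² = σ<sub>s</sub>² + ½σ<sub>p</sub>².

**Parentage and contemporary dispersal**: CERVUS-style pair LOD scores with
a per-allele mis-scoring error model and Monte-Carlo-calibrated Δ
(LOD-gap) confidence thresholds; an independent Mendelian-exclusion
assignment; a concordance merge keeping only pairs found by both methods;
sibship clustering by shared parents; mother/father role resolution by
plastid haplotype sharing; seed (mother→offspring) and pollen
(father→mother) distances with percentile-bootstrap confidence intervals.

**Reproductive skew**: per-adult offspring tallies, DBH–fecundity
regression, paired Wilcoxon mother-vs-father role test, the Gini index of
per-adult reproductive output, and pairwise between-site permutation tests
of Gini differences.

**Simulator**: Thomas-process adult placement, Dirichlet-founded allele
frequencies, exponential-power seed and pollen kernels, selfing,
immigration, Gamma fecundity skew, strictly maternal plastid inheritance,
burn-in generations of replacement reproduction, and a truth pedigree with
realised dispersal distances (`simulate_site()`, `simulate_study_sites()`).

## Worked example

```r
library(dispkin)

p <- sim_params(plot_width = 500, plot_height = 400, adult_density = 6,
                n_offspring = 150, seed_kernel = list(scale = 20, shape = 1),
                pollen_kernel = list(scale = 100, shape = 1),
                immigration_rate = 0.1, site = "demo")
s <- simulate_site(p, seed = 42)
parts <- split_size_classes(s$table, threshold = 30)
#> size classes at 30.0 cm: SSS 150, ADL 135 (0 missing DBH)

adl <- parts$adl
autocorrelogram(loiselle_kinship(adl, mode = "diploid"),
                pairwise_distances(adl), n_perm = 999, seed = 42)
#> SGS (diploid): F1 = 0.0215, b_log = -0.0119, Sp = 0.0122**, NS = 81.9 (999 perms)

hist <- dispersal_history(s$table, area_ha = 20)
#> sigma_g = 196.5 m, sigma_s = 104.4 m, sigma_p = 235.5 m
```

The correlogram output says: mean kinship among adults less than 30 m apart
is 0.0215, kinship decays by 0.0119 per unit ln(metres), and the resulting
Sp = 0.0122 is significant at the 1% level against the location-permutation
null, corresponding to a Wright neighbourhood of ~82 effectively
interbreeding adults. The historical decomposition then converts nuclear and
plastid Sp into axial gene, seed and pollen dispersal distances.

```r
freqs <- allele_frequencies(s$table)
thr <- calibrate_thresholds(freqs, n_sim_offspring = 500, n_candidates = 100,
                            prop_sampled = 0.25, error = error_model(0.01),
                            seed = 42)
#> relaxed (80%): delta >= 18.273   strict (95%): delta >= 31.001

conc <- concordant(
  assign_likelihood(parts$sss, adl, thr, freqs = freqs,
                    error = error_model(0.01)),
  assign_exclusion(parts$sss, adl))
trios <- resolve_roles(conc, s$table)
ev <- dispersal_distances(trios, s$table)
dispersal_summary(ev, n_boot = 2000, seed = 42)
#>   site n_events seed_mean_m seed_ci_half seed_median_m pollen_mean_m ...
#> 1 demo       32        36.0          7.6          28.2         132.3

gini(tally_success(conc, adl, trios)$total)
#> [1] 0.59
```

Thirty-two seedlings get a concordant parent pair whose mother is pinned
down by the plastid haplotype; their median realised seed distance (28 m)
sits close to the simulated kernel median (34 m), pollen moves about four
times further than seed, and reproductive output among adults is strongly
skewed (Gini 0.59).

A small example input file in the native CSV dialect ships in
`inst/extdata/synthetic_demo_site.csv` (synthetic data); `read_individuals()`
loads it. `run_pipeline()` chains every stage over multiple sites from one
config and writes report tables, correlogram/histogram data and a
reproducibility manifest.

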