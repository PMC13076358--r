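---
title: "Models and methods behind dispkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dispkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dispkin estimates gene, seed and pollen dispersal in plant populations over
two time windows: a historical one, read from the fine-scale spatial genetic
structure (SGS) that restricted dispersal builds up over generations, and a
contemporary one, read from parentage assignment of the current recruit
cohort. This vignette explains the models, the conventions and defaults
that matter, the design choices that were genuinely open, and what the
simulation-based tests do and do not demonstrate.

## Data model

The unit of analysis is a georeferenced individual with a diploid genotype
at a shared panel of microsatellite loci, a maternally inherited plastid
haplotype, a site label, and a diameter at breast height (DBH, cm). A DBH
threshold (default 30 cm) splits each site into seedlings–saplings–subadults
(SSS, DBH < threshold) and adults (ADL, DBH ≥ threshold); the boundary
value goes to the adults, matching the convention that trees at or above
the threshold are potentially reproductive. Coordinates are either planar
metres or lon/lat degrees; geodesic distances use the haversine on a sphere
of radius 6,371,008.8 m, and a local equirectangular projection about the
site centroid converts lon/lat to planar metres when a planar analysis is
requested. At plot scale (tens of hectares) the projection error is
millimetres, which the test suite checks directly. Whether distances were
computed planar or geodesic is recorded in the run manifest, since field
datasets mix GPS capture with metric tape distances.

Missing data use one sentinel: a locus with either allele missing is
untyped for that individual, and every statistic is computed over the
typed subset (pairwise deletion). Allele pairs are stored order-normalised
so genotype identity is well defined.

## Diversity statistics

Allelic richness is rarefied to a standard number of gene copies k
(default 50) with the exact hypergeometric form
`A_R = sum_a [1 - C(n_l - n_a, k)/C(n_l, k)]`; loci with fewer than k typed
copies are dropped from A_R only. Expected heterozygosity uses the
small-sample correction `n_l/(n_l - 1)(1 - sum p^2)` (gene copies n_l);
observed heterozygosity is the simple proportion. The multilocus
F_IS = 1 − H_O/H_E weights loci by their expected heterozygosity (ratio of
sums). Its permutation null shuffles gene copies among individuals within
each locus, which leaves allele frequencies — and hence H_E — fixed, so only
H_O varies; the two-sided p doubles the smaller tail probability with the
add-one convention. Across 200 simulated Hardy–Weinberg populations this
test rejects at close to the nominal 5% (checked in the acceptance suite).

Pairwise F_ST is the Weir–Cockerham variance-component estimator, summed
over loci and alleles, with significance from permuting individuals between
the two sites.

Two selfing estimates are reported side by side. The equilibrium transform
s = 2F_IS/(1 + F_IS) is cheap but confounds selfing with any other source
of heterozygote deficit. The identity-disequilibrium route computes the
multilocus g2 statistic — the standardised excess of within-individual
co-heterozygosity across locus pairs, computed with pairwise-complete sums
over missing data — and converts it to a selfing rate through the
mixed-mating equilibrium relation

  g2 = s / ((4 − s)(1 − s)),

which we derived from the geometric distribution of consecutive selfed
generations (heterozygosity halves per selfed generation) and verified by
direct Monte-Carlo simulation of the equilibrium mixture before freezing
it. Because published software does not print its internal conversion, the
package documents its own formula and validates it purely by parameter
recovery: populations simulated at s = 0.3 with 66 loci return a mean
estimate within ±0.05. Significance comes from a delete-one-locus jackknife
(t statistic on g2 > 0).

## Kinship and SGS

Pairwise kinship is the Loiselle estimator: per locus and allele, with
individual allele frequencies p_i ∈ {0, ½, 1} (diploid) or {0, 1}
(haploid) and reference frequency p computed from the analysed group
itself,

  F_ij = Σ_l Σ_a [(p_ila − p_la)(p_jla − p_la) + p_la(1 − p_la)/(n_l − 1)]
         / Σ_l Σ_a p_la(1 − p_la),

with sums restricted to loci jointly typed in the pair, so loci contribute
in proportion to their polymorphism. The second numerator term is the
finite-sample correction with n_l the typed gene copies. The plastid
haplotype is treated as one haploid multiallelic locus. A literal
double-loop implementation lives in the test helpers and the vectorised
estimator must agree with it to 1e−12, missing data included. Pairs typed
at fewer than 20 nuclear loci (1 plastid) are dropped.

The correlogram averages F_ij in half-open distance classes with upper
bounds (default) 30, 60, 90, 130, 170, 220, 300, 600 m. F_1 is the
first-class mean; b_log is the least-squares slope of *pairwise* F_ij on
ln(d) over all positive-distance pairs — pairwise rather than class-mean
regression, since the Sp literature defines the slope on pairs; co-located
pairs (d = 0) are excluded and counted. Then

  Sp = −b_log/(1 − F_1),  NS = 1/Sp.

The null distribution permutes individual *locations* (coordinates shuffled
among individuals, kinship fixed), recomputing class means and slope each
permutation; class envelopes are the 2.5/97.5 permutation percentiles and
the slope test is two-sided. The distance-class list is the eight-bound
grid above even though parts of the source literature describe "six"
classes while listing eight values; the implementation follows the listed
values.

## Historical dispersal

Under drift–dispersal equilibrium in two dimensions, Sp approximates
1/(4πD_e σ_g²) for biparentally inherited nuclear markers and
1/(2πD_e σ_s²) for maternally inherited plastid markers, where σ² is the
*axial* variance — half the mean squared dispersal distance — and D_e the
effective population density. D_e defaults to 25% of the census adult
density, reflecting strong interannual variation in which adults actually
reproduce; the same D_e is used for both marker modes (a maternal-only
D_e/2 variant is available for sensitivity analysis via the `fraction`
argument). Estimation inverts the relevant formula starting from the
full-range slope, then iteratively re-fits b_log over (σ, 20σ] — the range
where the ln(d) approximation is informative — until σ changes by less
than 1% (multiplier and tolerance configurable). Non-convergence is an
explicit flagged outcome, never a silent drop: the iteration stops with a
censored σ when Sp turns non-positive, the restricted range leaves the
sampled area, too few pairs remain, or the iteration cap is hit. The exact
stopping rule of legacy implementations is not published; these defaults
follow the cited iterative-range methodology and are exposed as arguments.

The pollen component follows from σ_g² = σ_s² + ½σ_p² (two gene copies
move with seed, one with pollen), so σ_p = sqrt(2(σ_g² − σ_s²)), undefined
with an explanatory flag when σ_s > σ_g — a real outcome under estimation
noise, reported rather than clamped.

## Parentage

The likelihood route scores every candidate parent pair (selfed pairs
included — the species model is monoecious with a small selfing rate) by

  LOD = Σ_l ln P(offspring genotype | pair, Mendel, ε)
            − ln P(offspring genotype | random draw from frequencies),

with a per-allele mis-scoring model: each recorded offspring allele is,
with probability ε (default 0.01), a random draw from the locus frequency
distribution, folded into the transmission probability as
u_c(x) = (1 − ε)T_c(x) + ε p(x). Candidates untyped at a locus transmit
like the background. Confidence uses the CERVUS-style Δ (LOD gap between
best and second-best pair), thresholded at values calibrated by Monte-Carlo:
simulated offspring from Hardy–Weinberg parents, true parents present with
probability `prop_sampled` (default 0.25, defaults 10,000 simulated
offspring and 500 candidates), thresholds chosen so that accepted
assignments are correct at the stated rate (relaxed 80%, strict 95%). With
a fully informative panel at ε = 0, wrong pairs are Mendelian-excluded and
Δ is infinite; thresholds then sit at infinity and the ≥ comparison still
accepts true pairs — a deliberate convention. Exact ties give tier `none`,
never an arbitrary choice.

The second, independent route is deliberately *not* a re-implementation of
COLONY's full-likelihood sibship machinery: it is Mendelian-exclusion pair
assignment (a pair is accepted only when it is the unique pair with at most
`max_mismatch` incompatible loci, default 1, and each dyad also within the
budget), followed by connected-component sibship clustering over shared
inferred parents. This preserves the two-method concordance logic — only
pairs identical under both methods survive the merge — and the
family-structure outputs, while keeping the algorithmic scope honest.

Maternity within an accepted pair is resolved by the plastid rule: the
parent sharing the offspring haplotype is the mother, provided the other
parent carries a different haplotype; both-share cases are excluded as
ambiguous, neither-share cases are flagged as conflicts and excluded from
distance summaries (the conservative reading of an inconsistent trio).
Seed distance is mother→offspring; pollen distance is father→mother (the
mating event), with father→offspring also emitted since report conventions
differ. Means carry 95% percentile-bootstrap intervals (default 10,000
resamples); the percentile method is the plain reading of "non-parametric
bootstrap", and the method name is recorded in output metadata.

## Reproductive skew

Each concordant offspring contributes one count per parental slot, so the
single parent of a selfed offspring gains two totals — the convention is
documented because the source conventions are silent. Zero-offspring
adults stay in the Gini computation (skew among *potential* breeders is
the biologically meaningful quantity; an option excludes them). The Gini
uses the plain pairwise form G = Σ_ij |x_i − x_j| / (2n²x̄) with no
small-sample correction; between-site differences are tested by pooling
two sites' per-adult counts and reassigning them at the original sizes
(add-one p-values, pairwise across sites, no multiplicity correction by
default with Holm available). The conventional 0.45 skew threshold is an
annotation, not a decision rule. The paired Wilcoxon mother-vs-father test
drops zero-difference pairs per the standard procedure and returns p = 1
with a flag when every pair ties.

## The simulator

The generator is a forward mating model on a closed, fully censused
rectangular plot, with known truth for every estimator: adults from a
Thomas cluster process (aggregates under a hectare in extent mirror the
field system; CSR available), founding allele frequencies from a symmetric
Dirichlet whose concentration is tuned to a target gene diversity, plastid
haplotypes from a separately tuned founding pool, reproduction by
fecundity-weighted mother sampling (Gamma multipliers, shape 1/dispersion),
father sampling weighted by fecundity × pollen-kernel density at the
father→mother distance, offspring placed by a seed-kernel displacement
with rejection at the plot edge (immigrant pollen is modelled separately
via `immigration_rate`, as unsampled external fathers drawn from the
current allele frequencies), strict maternal plastid inheritance, Mendelian
nuclear transmission without mutation, and replacement burn-in generations
so SGS can accumulate. Kernels are exponential-power
f(d) ∝ exp(−(d/a)^b): radial draws are a·G^(1/b), G ~ Gamma(2/b), giving
closed-form moments used by the recovery tests (axial σ = a√3 for b = 1).

The four-site study preset emulates the survey design the package was
built around: plots of 30/25/38/17 ha, adult densities 4.1/2.6/3.8/7.9
per ha, offspring cohorts of 243/295/237/282, ~0.5 gene diversity at 66
loci, selfing 0.01, seed-kernel medians of roughly 20–75 m, pollen-kernel
medians of roughly 130–290 m, and fecundity dispersion ranging from even
(0.2) to strongly skewed (2). Founding diversities (target He 0.56–0.60;
plastid pools of 9–18 haplotypes at founding diversity 0.75–0.85) were
calibrated once so that *realised* post-burn-in diversity lands in the
emulated ranges — drift during burn-in, amplified by fecundity skew, eats
a visible fraction of founding diversity in plots with only tens of
adults. Burn-in defaults to 5 generations (enough for clear SGS to build
under restricted kernels); generation time is not an estimate of any real
species' history, just a simulator knob.

What the simulator does *not* emulate: mutation, overlapping generations
or age structure beyond replacement, masting schedules, seed predation,
landscape heterogeneity, and genotyping artefacts other than the uniform
mis-scoring model. Passing recovery tests therefore demonstrates estimator
correctness under the model's own assumptions, not robustness to every
feature of real data.

## Numerical and testing choices

Problem sizes in the test and acceptance suites are chosen for a
single-CPU desk run: oracle-equivalence checks use ≤ 30 individuals and
≤ 5 loci at 1e−12; parentage recovery uses one site of ~200 offspring,
66 loci at H_E ≈ 0.5 with every parent sampled and ε = 0 (observed
recovery ≥ 99%, and 100% correct maternity among resolved trios);
σ_s recovery uses 20 replicates of ~150 adults after 40 burn-in
generations with equal fecundities, no selfing and no immigration, with
D_e set to the known census density — conditions under which the
drift–dispersal approximation should hold, and the mean estimate lands
within ±30% of the kernel's axial σ; permutation-test and bootstrap
calibration use 200–1000 replicates at 499–1000 resamples. Every
stochastic routine takes an explicit seed, restores the caller's RNG
state, and the study fixture is byte-reproducible for a given seed.

Known limitations: the g2→s conversion assumes inbreeding equilibrium;
the Sp inversions inherit the usual sensitivity to the assumed D_e (σ
scales as D_e^(−1/2)); calibration at the published default sizes (10,000
simulated offspring × 500 candidates) is expensive in pure R and the
pipeline default scales it down (500 × 100), which is adequate for the
strongly informative 66-locus panels the package targets; and exclusion
assignment with `max_mismatch` ≥ 1 loses power in small panels where
uniqueness fails, which is the intended conservative behaviour.
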