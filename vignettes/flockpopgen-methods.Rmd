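---
title: "Methods and models in flockpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models in flockpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`flockpopgen` analyses very young species flocks — sympatric radiations such
as the Midas cichlid (*Amphilophus*) flock of Lake Apoyo, Nicaragua — from
two complementary data types: genome-wide dominant binary markers
(AFLP-style band presence/absence) and mitochondrial control-region
sequences. This vignette explains the models behind each stage, the
parameters that matter, and the design decisions taken where the design was
genuinely open.

## Dominant markers as haploid Bernoulli characters

AFLP bands are dominant: a band is seen whether the underlying locus is
heterozygous or homozygous present, and band absence is the recessive
phenotype. Throughout this package a band is modelled as a **haploid
Bernoulli character** — one observation per locus per individual, with a
per-population band frequency. This single convention is used consistently
by the synthetic generator, the admixture model, the ancestry test, and the
default frequency estimates of the selection scans, which keeps every
parameter-recovery loop internally coherent: what the generator writes is
exactly what the models read.

The classical alternative treats band absence as a homozygous recessive
genotype and estimates allele frequencies as `q = sqrt(1 - band
frequency)` under Hardy–Weinberg. That estimator is available everywhere a
frequency is estimated (`freq_model = "sqrt"`), because real AFLP data are
diploid underneath; but it is not the default, since mixing a diploid
estimator with the haploid generator would make the package's own
validation loops inconsistent.

## The synthetic species flock

`flock_config()` / `simulate_flock()` generate a flock with known ground
truth. Defaults describe a six-species crater-lake radiation: sample sizes
18–22 per species (122 individuals), 2297 loci, 2% of loci under divergent
selection, three sampling locations, one introgressed subgroup of seven
individuals carrying four fixed private bands, and a generation time of two
years. Differentiation targets are `fst_neutral = 0.10` — the middle of the
0.036–0.141 range of published neutral pairwise estimates for such flocks —
and `fst_outlier = 0.55`, the level at which divergently selected dominant
loci stand out decisively from that background.

**Neutral drift model.** Each locus draws an ancestral band frequency
`p ~ U(0.1, 0.9)`; each species then draws its frequency from the
Balding–Nichols parameterisation `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose
among-population variance equals `F · p(1-p)`. This is precisely the
correlated allele-frequencies assumption of the admixture model, so the
clustering stage fits data generated under its own prior. Realized
Weir–Cockerham FST converges to `F` as loci accumulate (the test suite
checks |realized − target| < 0.01 at 5000 loci).

**Outlier loci.** Loci "under divergent selection" are drawn from the same
Balding–Nichols family at `fst_outlier`, but **conditioned on actually
diverging**: a draw is accepted only when the parametric FST of the drawn
frequencies, `var(p_s)/(p̄(1-p̄))`, reaches the target. An unconditioned
draw frequently lands all species near the same frequency — such a locus is
statistically indistinguishable from a neutral one, which would make
"fraction of planted outliers recovered" an ill-posed measure. Conditioning
encodes the biological definition: divergent selection *maintains*
divergence. The generator plants elevated-divergence loci only; it does not
simulate selection coefficients or trajectories.

**Hybrids and introgression.** A hybrid samples each band independently
from the ancestry-weighted mixture of parental frequencies (F1 = 1/2:1/2;
one grandparent = 3/4:1/4), with no linkage — consistent with treating loci
as unlinked everywhere else. The introgressed subgroup overwrites a chosen
set of neutral loci to be present in all its members and absent in everyone
else, emulating fixed private bands acquired from an outside source. mtDNA
is simulated per species (hybrids inherit the first parent's maternal
lineage); the species' genealogies are independent, which understates the
haplotype sharing real young flocks show — synthetic mtDNA is therefore
used for demographic parameter recovery, not for cross-species network
topology.

**What passing tests show — and don't.** Recovery on this generator
demonstrates internal consistency of estimator and model at realistic
sample sizes. Real AFLP data add genotyping noise, size homoplasy
(co-migrating non-homologous bands), linkage, and diploid dominance, none
of which are emulated; results on real matrices should be read with those
caveats.

## Sequence simulation and the mismatch distribution

`simulate_expansion_sequences()` runs a coalescent with one instantaneous
size change. Time is measured in mutational units (`tau = 2 u t` with `u`
the per-sequence per-year rate): going backwards, the pair-coalescence
hazard is `1/theta1` until `tau` and `1/theta0` beyond; `theta0 = 0`
collapses all remaining lineages at `tau`. Mutations fall on branches at
rate 1/2 per lineage per mutational unit, so an equilibrium pair carries
`theta` differences on average, and are placed under infinite sites —
violating placements fail loudly rather than silently re-using sites.

The expected mismatch distribution integrates Poisson differences over the
coalescence-time density, giving (with `a = (theta1+1)/theta1`,
`b = (theta0+1)/theta0`, and `P`/`Q` the regularized incomplete gamma
functions):

```
F_i = theta1^i/(theta1+1)^(i+1) P(i+1, a tau)
    + e^(tau/theta0 - tau/theta1) theta0^i/(theta0+1)^(i+1) Q(i+1, b tau)
```

with the second term degenerating to `e^(-tau/theta1) Pois(i; tau)` when
`theta0 = 0`. The test suite verifies this closed form against the
simulator by total-variation distance (< 0.03 at 4000 replicates).

`fit_sudden_expansion()` minimises the sum of squared deviations between
observed relative frequencies and `F_i` over `(tau, theta0, theta1)`: a
coarse grid (tau anchored at 0, the observed mean, and twice the mean)
followed by Nelder–Mead on log-transformed parameters. `theta1` is capped
at 99999 and the cap is flagged — spectra from ongoing expansions often
drive `theta1` to infinity, and the cap makes that degenerate fit explicit
and reproducible rather than an optimizer failure. Goodness of fit is a
parametric bootstrap (default 1000 replicates; the count is a package
choice): simulate at the fitted parameters with the same sample size, refit
(warm-started at the fitted optimum plus the grid), and report the fraction
of simulated SSDs at least as large as the observed. Raggedness is
`r = sum (x_i − x_{i−1})²` with a trailing zero class appended.

Time conversion is `t = tau / (2u)` with `u = mu_site · L / 1e6` for
`mu_site` in substitutions/site/My/lineage; the inverse (`implied_mu`)
supports consistency checks of published rate/time pairs. Generation time
enters only if rates are quoted per generation.

## Distances, trees, and hybridization diagnostics

Two similarity coefficients for band data: Jaccard `s = a/(a+b+c)` and the
band-sharing (Dice) coefficient `s = 2a/(2a+b+c)`, both used as `d = 1 - s`.
The Dice form is implemented as the `link` method — the band-sharing
measure used for dominant markers in older distance-based tree software; it
never exceeds the Jaccard distance for the same pair, and both are
first-class so results can be compared. Pairs sharing no band at all are an
error rather than a silent `d = 1`.

Trees are Saitou–Nei neighbor-joining (`ape::nj`), with negative branch
lengths clamped to zero and the deficit moved to the adjacent branch.
Bootstrapping resamples **loci** (columns), never individuals. Supports are
bipartition frequencies; bipartitions are canonicalised by the side not
containing the alphabetically first taxon, which makes matching after taxon
removal well-defined.

Three diagnostics target hybridization signal:

* **Leaf stability** — for each taxon, the mean over all quartets
  containing it of the most frequent of the three quartet resolutions
  across bootstrap trees; exactly 1 when every quartet resolves identically
  in every tree. Of the index variants in circulation, the quartet-frequency
  mean is implemented (the maximum-difference and entropy variants are not).
* **Lineage movement** — where a query clade attaches across bootstrap
  trees: outside the reference group (with only non-reference taxa),
  nested strictly inside it, at a mixed node ("basal"), or not
  monophyletic at all ("dispersed", reported separately rather than
  folded into the percentages).
* **Homoplasy-excess removal experiments** — remove a candidate hybrid,
  re-bootstrap, and report the support change for every original clade
  restricted to the retained taxa (clades that become trivial are `NA`).
  A hybrid's removal should raise support for clades containing its
  parents; removing a non-hybrid should change nothing beyond Monte-Carlo
  noise.

## F-statistics and AMOVA

All F-statistics are molecular-variance ratios on squared distances
(`Excoffier`-style AMOVA): pairwise statistics are the among-group
component of a two-group analysis, so the pairwise and full analyses are
internally consistent by construction. Supplied distances are interpreted
as squared molecular distances — the natural convention when `d` counts
differing loci between binary profiles (the squared Euclidean distance of
0/1 vectors); metric distances can be squared on entry. Significance is by
permutation of individuals (default 10,100 permutations) with sequential
Bonferroni (Holm) across pairs; negative variance-component estimates are
reported unclamped, and a pair with zero total variance yields statistic 0
with a warning. The nested two-level analysis uses the standard
expected-mean-squares coefficients and permutes whole subgroups among
groups for the top component.

`fst_change_summary()` implements the report arithmetic for paired
full/neutral tables: the PhiST excess is computed relative to PhiST
(`(Phi - F)/Phi`) — the only reading that reproduces the published
42 ± 2.6% from the printed values — and decreases after outlier removal
relative to the full-matrix value.

## Outlier scans

**Island-model scan** (`fdist_scan`). The baseline FST is the mean or the
30%-trimmed mean (the trim fraction is configurable) of per-locus
Weir–Cockerham estimates. Neutral loci are then simulated under
Balding–Nichols at the baseline with the observed sample sizes, ancestral
frequencies resampled from the data's own pooled frequencies so the
simulated heterozygosity spectrum matches the data. Observed loci are
flagged when they exceed the conditional `alpha` quantile of simulated FST
given heterozygosity (a 500-locus nearest-neighbour window on the
heterozygosity axis). The test is one-sided: loci at or below baseline are
never flagged; monomorphic loci are excluded and reported.

**Bayesian scan** (`bayes_scan`). The locus-population FST is decomposed on
the logistic scale, `logit(FST_ij) = alpha_i + beta_j`; species band counts
are beta-binomial around an ancestral frequency with precision
`(1-FST)/FST`. The locus effect carries a spike-and-slab indicator sampled
by a reversible-jump move whose proposal is the slab prior (N(0, 3)); prior
odds for neutrality default to 10. Bayes factors are posterior odds over
prior odds, and the 'decisive' call requires BF > 100 **and** posterior
probability > 0.99. Desk-scale defaults are 2000 burn-in + 8000 kept
sweeps; longer chains are a flag away. Split-chain disagreement of the
inclusion probabilities is reported as a convergence heuristic.

## Admixture, Evanno's delta-K, and ancestry tests

The clustering model is the admixture model with correlated allele
frequencies, adapted to haploid bands: per individual and locus a latent
cluster of origin `z_il ~ Q_i`, band `x_il ~ Bernoulli(P_{z,l})`, ancestry
`Q_i ~ Dirichlet(alpha)`, and cluster frequencies `P_kl` drawn around an
ancestral frequency `p_l` with per-cluster drift `F_k`. `z`, `Q`, `P` are
Gibbs-sampled; `p_l`, `F_k`, `alpha` and `lambda` (the Beta shape of the
ancestral-frequency prior) by Metropolis steps, with `alpha` and `lambda`
inferred from the data rather than fixed. The z-sweep — the hot loop — is
compiled code; hyperparameters are updated every fifth sweep (they mix
slowly, so the sparser schedule trades negligible efficiency for
substantial speed). The evidence estimate is the usual
`mean(lnL) − var(lnL)/2` over the post-burn-in z-marginalized likelihood
trace (the complete-data trace is also recorded; its sweep-to-sweep
variance is dominated by assignment churn at short chains). A replicate is
flagged non-converged when the fitted drift of its trace exceeds three
trace standard deviations — an automated version of inspecting
log-probability-vs-iteration plots. Chains start either from random
ancestry (`init = "random"`, the classical behaviour) or from a k-means
partition of PCA scores (`init = "kmeans"`, much faster to converge when
estimating Q at a known K). Desk-scale defaults (500 burn-in, 1500–2000
kept sweeps, 5 replicates) are sized for the bundled experiments;
study-scale chains (50k/250k, 20 replicates) are reached by arguments.
Label switching is handled at evaluation time by greedy cluster matching
(`match_clusters`).

`evanno_deltaK` uses the second difference of mean evidence across
consecutive K divided by the replicate SD at K; boundary K values are
undefined and a zero SD yields an infinite delta-K with a warning.
Replicates flagged non-converged are dropped per K, but never below two
survivors. A caveat from the package's own validation experiments: at
desk-scale chain lengths and replicate counts the delta-K argmax is
seed-sensitive — consecutive evidence gains around the true K are of the
same order as the estimator's noise, and the replicate-SD denominator has
few degrees of freedom — so reliable model choice by delta-K needs
replication at the scale the statistic was designed for (tens of long
replicate runs), while per-individual assignment at a given K is already
stable at desk scale.

The ancestry test enumerates hypotheses explicitly instead of sampling:
pure ancestry, or an immigrant ancestor from each other species at
generation `g = 0..gb` (individual, parent, grandparent), under which each
unlinked locus derives from the source with probability `2^-g`. The prior
gives `1 - nu` to purity and splits `nu` equally across source species,
with generation weights proportional to `2^-g` (a halving per generation
back; the exact split across generations is a package choice, documented
here, as the original model description leaves room for variants). Species
frequencies are posterior-mean (Beta-smoothed) estimates from the labeled
individuals, leave-one-out for the focal individual to avoid
self-assignment bias. Sensitivity to `nu` over {0.1, 0.05, 0.01} is part of
the test suite: clear cases move by less than 0.1.

## Numerical choices and degenerate inputs

* All stochastic operations take an explicit integer seed and restore the
  caller's RNG state; pipeline stages derive their seeds from one master
  seed.
* Tie-breaks are lexicographic everywhere (minimum-spanning-network edge
  classes, median-vector candidates, cluster matching), making network and
  tree construction deterministic given input order.
* The median-joining construction adds a median vector only when it
  strictly reduces the minimum-spanning weight of the node set, and prunes
  unobserved nodes below degree three; for sequence triplets whose sites
  show three distinct states the quasi-median expansion is capped (3^4
  candidates) — beyond that the triplet contributes no candidate.
* Monomorphic loci are allowed but flagged on input; they carry no signal
  for any statistic and are excluded from scans with a report.
* Comma decimal separators are accepted when reading published tables;
  all output uses dots. Site indices are 0-based internally, 1-based in
  reports.

## Problem sizes used by the bundled experiments

The package's own validation experiments are sized for a desk run: scan
calibration and power at 2000 loci × 6 species × 20 individuals; admixture
model choice at 500 loci × 6 species × 10 individuals with K = 1..8 and two
replicates per K; mismatch parameter recovery over 100 simulated samples of
60 sequences; homoplasy-excess at 500 loci and 1000 bootstrap replicates.
These sizes were chosen as the smallest at which the respective statistics
are stable; every experiment scales to study size (2297 loci, 122
individuals, 2000 bootstrap replicates, 10,100 permutations) through the
same function arguments.

## Known limitations

* Dominant-marker dominance is modelled only through the optional
  square-root frequency correction; there is no genotype-level error model.
* The mtDNA simulator gives species independent genealogies — no shared
  ancestral polymorphism or introgressed haplotypes.
* The median-joining implementation targets control-region-sized haplotype
  sets (tens of haplotypes); its candidate search is exhaustive over linked
  triplets and would be slow for thousands of haplotypes.
* The Bayesian scan implements a single prior-odds parameter, not a full
  prior-elicitation interface, and no hierarchical island models.
* No linkage model anywhere: every locus is exchangeable and independent.
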