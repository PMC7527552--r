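---
title: "Methods and design notes for zanpop"
author: "zanpop maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for zanpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`zanpop` implements a population-genomic inference pipeline for
reduced-representation (GBS) SNP panels from Chinese pepper
(*Zanthoxylum bungeanum* and *Z. armatum*) and comparable non-model
plants: genotype import and filtering, diversity and differentiation
statistics, folded site-frequency spectra (SFS), effective-population-size
histories, composite-likelihood demographic model fitting, f-statistics
and admixture graphs, and F~ST~ outlier scans.  A structured-coalescent
simulator generates data under explicit demographies so that every
inference stage is validated by parameter recovery rather than by
comparison against fixed reference files.

This vignette records the modelling assumptions, the tunable parameters
that matter, and the design decisions taken where the methodology left
genuine choices open.

# The data model

A `SNPMatrix` extends `SummarizedExperiment`: rows are SNP sites, columns
are accessions, and the `"GT"` assay holds alternate-allele dosages
(0/1/2, `NA` missing).  GBS data come as short "stacks" (restriction-site
loci of ~150 bp) carrying one or a few SNPs; the stack identifier is kept
in `rowData` and doubles as the CHROM column in the VCF dialect used for
I/O, since no chromosome-level assembly exists for these species.

Matrix-level filtering (`filterSites`) retains biallelic sites genotyped
in at least 60% of accessions by default (`maxMissing = 0.4`).  The
removal-reason priority (non-biallelic before missingness) is fixed so
that report counts are well defined.  Sites monomorphic within the loaded
panel are retained by default — they carry SFS information — with a flag
to drop them.  `thinOneSNPPerLocus` implements the one-random-SNP-per-stack
rule used before structure-sensitive analyses, to avoid sets of tightly
linked sites.

# The coalescent simulator

`simulateGenotypes` and `expectedSFSMC` share one structured-coalescent
engine (C++): demes with piecewise-exponential diploid sizes, backward
migration, and join events (forward-time splits).  Time is in
generations; a deme of diploid size $N$ gives haploid pairs coalescence
rate $1/(2N)$.

Mutation is infinite-sites, *conditioned on segregating*: each locus
carries exactly one SNP, placed uniformly on the total branch length of
its genealogy.  This makes `nLoci` equal the SNP count, mirroring a SNP
panel.  Two consequences matter downstream:

* The number of segregating sites carries no information about the
  mutation rate, so absolute population-size scales must come from
  elsewhere (see the stairway section).  The generator therefore records
  the mean genealogy length and the implied probability that a locus
  segregates, giving an *implied number of assayed sites*
  (`simInfo(x)$impliedTotalSites`) consistent with the calibration
  $\mu = 2.6\times10^{-9}$/site/yr and $g = 4$ yr.
* Loci sampled proportionally to polymorphism weight long genealogies,
  exactly as real SNP panels do.  This inflates ratio-of-sums
  Weir–Cockerham F~ST~ slightly above identity-probability expectations
  (tests bound the gap in absolute terms rather than claiming exact
  agreement).

Stacks exist only as grouping metadata: loci are unlinked, and multiple
SNPs assigned to one stack do **not** share a genealogy.  Missingness is
missing-completely-at-random, as no missingness mechanism is described
for the real panels.  All randomness derives from explicit seeds; the
same seed yields byte-identical VCF fixtures.

The study-scale fixture (`makeStudyFixture`) emulates the real design:
112 accessions in 6 clades and ~38,395 SNPs, generated under a composite
history (species split 12 mya-equivalent; *Z. bungeanum* clade splits at
221/219 kya-equivalents; a 50 kya-equivalent split for Clade IV, which
the original analyses do not date — a declared assumption; wild/cultivated
*Z. armatum* split 5,440 yr-equivalent with a 200-fold exponential
decline in the cultivated deme).  Absolute sizes are declared
assumptions (50,000 diploids for *Z. bungeanum* demes, 10,000 for
*Z. armatum* and the ancestors), overridable via `sizes=`.  Note that
with an ancestral size of 10,000 the 200-fold cultivated decline leaves a
present size of 50 diploids, which inflates the fixture's
wild–cultivated F~ST~ well above the value printed for the real panel;
the recovery experiments are calibrated on these stated sizes, not on
matching every real-data summary.

# Site-frequency spectra

`foldedSFS` builds 1D–3D spectra with hypergeometric projection: each
usable site contributes its exact projection mass over derived-count
classes, treating the observed copies as the urn.  Projection by
expectation (fractional mass) rather than by site subsampling keeps the
spectrum deterministic.  Sites with fewer observed copies than the
projection in any population are skipped.  The default projection, used
when the original easySFS settings are unknown, is 90% of the available
`2 × diploids` per population.

Joint spectra are folded over the *pooled* (global) minor allele —
required for consistency with two- and three-population model fitting.
Exact-half classes are counted once; ties between a cell and its
complement resolve to the lexicographically smaller cell.  Monomorphic
classes are recorded but excluded from likelihoods: with SNP-only GBS
data there is no callable invariant-site count, so composite likelihoods
condition on segregation.

`bootstrapSFS` resamples stacks (not SNPs) with replacement — the
exchangeable unit respecting within-stack linkage structure; the published
protocol does not state its resampling unit.

# Stairway-style Ne trajectories

`fitStairway` parameterizes the folded SFS through per-coalescent-interval
scaled sizes $\theta_k = 4 N_k \mu$ (for the period with $k$ ancestral
lineages), using the standard coefficients
$E[\xi_i] = \sum_k \theta_k \, p_{n,k}(i)/(k-1)$ with
$p_{n,k}(i) = \binom{n-i-1}{k-2}/\binom{n-1}{k-1}$, folded and
normalized into a multinomial composite likelihood.  Adjacent intervals
are grouped into a small number of free epochs, with group boundaries
log-spaced in the lineage count $k-1$: coalescent intervals are
geometrically spaced in time, so this gives the deep intervals (small
$k$) their own epochs instead of absorbing them into one recent-heavy
group — without it, the oldest epoch starts too recently and ancient
size changes are blended away.  The epoch number is chosen by a
training/validation split of site counts (2/3 training), with a
parsimony rule — the smallest epoch count within 2 log-likelihood units
of the best validation score — and a mild ridge on adjacent log-size
jumps (`smooth`, default 1) guards against degenerate near-zero epochs
that would compress the time axis.  These hyperparameters are package
defaults; no settings are published for this step.

Absolute scale: the multinomial shape identifies only relative sizes.
The per-site density of segregating sites, $S/L$ with $L$ the total
assayed length (`totalSites`), calibrates the absolute scale through
$\sum_k \theta_k/(k-1) = S/L$.  For synthetic data, `simInfo()` provides
the implied $L$.  For real panels $L$ should be the number of assayed
stacks times the stack length; if it is only approximate, *times and
sizes scale together* and ratios (e.g. the recovered twofold decline) are
unaffected.  Bootstrap replicates are refitted with the selected epoch
number and summarized as median, 75% and 95% envelopes; times rescale to
years via $g = 4$.

# Demographic model fitting

`fitModel` maximizes the multinomial composite log-likelihood of the
observed joint folded SFS against a Monte-Carlo expected SFS
(`expectedSFSMC`, expected branch lengths per joint class).  Design
choices:

* **Optimizer.** "Cycles of the Brent algorithm" is realized as cyclic
  coordinate-wise Brent line search (derivative-free), up to 50 cycles by
  default with early exit when a full cycle improves the likelihood by
  less than `tolLnL`.  Independent random starts (published protocol: 50;
  desk default 10) guard against local optima.
* **Common random numbers.** One seed drives every expected-SFS
  evaluation within a fit, making the Monte-Carlo likelihood surface a
  smooth deterministic function of the parameters.
* **Refinement stage.** The CRN surface at the search's Monte-Carlo size
  (default 10,000 genealogies; the published protocol used 100,000) is
  biased by its particular noise realization.  The best multi-start
  solution is therefore re-polished with a fresh seed at `refineSims`
  (default 4×) for a few cycles, which removes most of that bias at a
  fraction of the cost of running everything at high precision.
* **Model library.** `pepperModels` ships the models that the original
  analyses describe explicitly: isolation with exponential cultivated
  shrinkage (M9), with asymmetric migration (M11), with shrinkage in both
  demes (M12), the three-clade model in which Clades II and III split
  shortly after their ancestor split from Clade I (M13, plus the two
  alternative join orders M14/M15), and plain isolation ± migration
  (M1/M2) used for the interspecies split.  Other topologies are
  expressed through the declarative `demographicModel` constructor.  At
  desk scale the three-clade fits fix migration to zero and sizes to
  their stated values, leaving the two divergence times free — the
  quantities the recovery experiments score.
* **AIC.** `compareModels` uses the standard definition
  $AIC = 2k - 2\ln L$ and Akaike weights.  The original report ranks
  models with additional parameters as preferable despite similar
  likelihoods; under the standard definition equal likelihoods with more
  parameters give a *higher* AIC.  The standard definition is
  implemented, and this reading difference is simply documented here.

Parametric bootstrap (`parametricBootstrap`) resimulates SFS counts from
the fitted expected spectrum (multinomial with the fitted number of
segregating sites) and refits, giving percentile intervals — the interval
used by the recovery criteria.

# f-statistics and admixture graphs

All f-statistics are computed from per-population allele frequencies
with observed copy counts (`freqMatrix`).  The admixture-f3 uses the
heterozygosity bias correction $\hat h_C / k_C$ (required for
unbiasedness at finite sample size); outgroup-f3 is uncorrected, being a
ranking statistic.  Neither choice is stated in the published protocol.  D
uses the normalized ABBA–BABA form.  Standard errors come from a
weighted delete-one block jackknife over contiguous blocks of ~200 SNPs
in stack order — there is no chromosome map for this genome, so stack
order stands in for genomic order; block size is configurable.

The f3 scan adjusts one-sided p-values (negative direction) by
Benjamini–Hochberg and flags tests whose adjusted significance
corresponds to an adjusted Z at or below −1.96.  The figure caption this
mirrors reads "adjusted Z-score ≤ 1.96", which taken literally would flag
*positive* f3 values too; it is read here as ≤ −1.96 (significantly
negative), the only direction that signals admixture.

Admixture graphs predict f2 between leaves as
$\sum_e c_e (\mu_A(e) - \mu_B(e))^2$, where $\mu_L(e)$ is the expected
traversal weight of edge $e$ by a lineage from leaf $L$ (admixture nodes
mix parental paths by their proportions), and f3/f4 follow by the linear
identities.  Fitting minimizes SE-weighted squared residuals on the f2
spanning basis (a block-diagonal covariance approximation; the reference
implementation's internal objective is not documented), then reports
residual Z-scores over the *complete* enumerated f2/f3/f4 set — for 19
populations, exactly 14,706 statistics — and scores the fit by the
largest |Z|.  Only the sum of the two root-adjacent drift lengths is
identifiable, so one of them is pinned to zero before fitting; a
Jacobian rank check warns about other non-identifiable parameterizations.
Drift lengths are reported in the conventional drift units of
1000 × f2 (proportional to 1000 × F~ST~).

The incremental search starts from a skeleton of an outgroup plus three
populations (best of the three ingroup topologies) and adds the
remaining populations one at a time to every drift edge and (optionally)
every edge pair as a two-parent admixture, retaining the placement with
the smallest max|Z| — "a minimum |Z| value" is read as this worst-case
criterion, the same score the fit quality is quoted in.  Ties prefer
fewer admixture events.  Addition order is a configurable list, as the
original robustness analysis added cultivars in different orders;
admixture nodes are limited to two parents.

# Outlier scans

**FLK.**  The kinship matrix comes from a neighbor-joining tree of
Reynolds distances, midpoint-rooted (or outgroup-rooted on request).
For independently drifting populations the pairwise Reynolds coancestry
converges to $(f_i + f_j)/2$, so distances are doubled before tree
building to put tip branches on the $f$ scale required by the FLK
covariance $V = p_0(1-p_0)F$; without this factor the statistic is
inflated about twofold (its chi-square mean is checked on neutral island
data in the tests).  Sampling noise in the frequencies is deliberately
left inside the distances, so tip branches absorb it and the covariance
matches the variance of *observed* frequencies.  The ancestral frequency
$\hat p_0$ is the GLS (V-weighted) mean, per the FLK construction.
P-values use $\chi^2_{d-1}$; q-values use Benjamini–Hochberg with a
q < 0.05 outlier flag.

**Fdist.**  The null is a symmetric island model matched to the observed
multi-locus Weir–Cockerham F~ST~ *empirically*: Wright's identity
$F_{ST} = 1/(1 + 4Nm\,(d/(d-1))^2)$ seeds the migration rate, and two
pilot rounds recalibrate it so the realized SNP-ascertained F~ST~ of the
simulated null matches the observed value (the analytic identity alone
leaves a visible ascertainment gap).  Per-locus p-values are the add-one
empirical proportion of simulated loci in the same heterozygosity bin
with F~ST~ at least as large.  Because the empirical p-value cannot fall
below 1/(bin size + 1), genome-wide q-values cannot reach small
thresholds at feasible simulation sizes; the outlier *flag* therefore
uses the conventional envelope reading (p below `alpha`, default 0.01,
i.e. outside the 99% envelope) while q-values are still reported.  The
discreteness of single-SNP F~ST~ also makes the p-values conservative
(type-I error at or below nominal), which the calibration tests assert
as inequalities rather than exact uniformity.

**Consensus.**  `consensusOutliers` intersects any number of aligned
per-test flags — only FLK and the Fdist-style test are implemented here;
results from external methods can be merged in before intersection.
`selectionScan` wraps the two-stage published design: a two-species
contrast first, then within-species contrasts under supplied groupings.

# Reproducibility

Every stage derives its seed from one master seed via `deriveSeed`
(documented multiplicative hash, always below $2^{31}$), so stages are
independently reproducible and a pipeline re-run with an emitted report's
configuration reproduces all deterministic outputs.  `runPipeline`
executes the stages in dependency order and writes a JSON report with
versions, seeds and per-stage summaries.

# Known limitations

* The simulator has no recombination and no within-stack linkage; stacks
  are metadata.  Bootstrap-by-stack therefore exercises the mechanics,
  not real linkage.
* Selection is not simulated; outlier tests are exercised with post-hoc
  frequency perturbations ("planted" loci).
* Real-data values that depend on the deposited reads (the printed
  F~ST~ range, the real maximum log-likelihood, the 24-outlier consensus
  set, cultivar rankings) are out of reach of the synthetic world; green
  tests establish parameter recovery under the stated generating models,
  not agreement with those numbers.
* Composite likelihoods treat SNPs as independent; standard errors from
  the multinomial are anti-conservative for linked data, which is why
  interval statements rely on the parametric bootstrap instead.
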