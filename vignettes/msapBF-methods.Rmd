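---
title: "Methods: MS-AFLP methylation profiling and Bayesian log-linear association analysis"
author: "msapBF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MS-AFLP methylation profiling and Bayesian log-linear association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msapBF)
library(SummarizedExperiment)
```

## The scientific setting

Noninfectious bud-failure (BF) is an almond disorder in which vegetative
buds fail to develop; it is not caused by any pathogen, it is transmitted
through clonal propagation, and its severity tracks the age and propagation
history of the clonal source. That phenomenology suggests an epigenetic
mechanism, and the natural exploratory assay in a crop without a reference
genome is methylation-sensitive AFLP (MS-AFLP/MSAP): each genomic CCGG site
is interrogated with two parallel digests using the isoschizomers HpaII and
MspI, which recognize the same site but are blocked by different cytosine
methylation configurations. A fragment's presence/absence in the two
digests therefore encodes its methylation state.

`msapBF` implements the full analysis path for such a study on a panel of
22 almond accessions from 7 genotypes, each scored for BF exhibition on a
six-level ordinal scale (6, 5, 4, 3, 2, 1 for high, medium-to-high,
medium, low-to-medium, low, and no exhibition) and annotated with its
clonal age in decades (`accessionMetadata()`). The pipeline stages are:

1. band-matrix IO in the MSAP CSV convention;
2. four-state epigenotype calling and methylation-susceptible-locus (MSL)
   partitioning;
3. association statistics (2×2 and stratified independence tests, Kendall
   tau-b concordance, detection of perfectly BF-diagnostic bands);
4. ordination (binary distances, principal coordinates, UPGMA dendrograms);
5. Bayesian hierarchical log-linear model selection by reversible-jump
   MCMC, with maximum-likelihood effect summaries;
6. a synthetic band-matrix generator so that every stage, including the
   sampler, is testable end to end against known truth.

## Epigenotype calling

The isoschizomer logic maps the paired calls (HpaII, MspI) to four states:

| HPA | MSP | state |
|-----|-----|-------|
| 1 | 1 | demethylated |
| 1 | 0 | hemimethylated (external C) |
| 0 | 1 | internal cytosine methylation |
| 0 | 0 | full methylation |

`classifyPattern()` is this bijection; `classifyMatrix()` applies it
cell-wise and also fills the binary score `deMet01` (0 = demethylated,
1 = any methylated state) used by all downstream statistics. Joint absence
(0, 0) is scored as full methylation by default — the convention used in
the study's banding table — but `jointAbsence = "missing"` treats it as
uninformative instead, since absence in both digests can also mean the
CCGG target itself is absent. This ambiguity is intrinsic to dominant
MS-AFLP markers and is the main reason the four-state calls should be read
as banding classes, not molecular ground truth.

A band is an MSL (`partitionLoci()`) when the fraction of accessions with
a non-demethylated state exceeds an error threshold, 5% by default — the
conventional MSAP allowance for scoring error. The comparison is strict
(`>`), so the partition is monotone in the threshold. An MSL with at least
two distinct states across accessions is polymorphic
(`polymorphicLoci()`).

## Association statistics

`buildContingency2x2()` tallies every scored (band, accession) cell as
methylated/unmethylated against the accession's BF/NBF group.
Dichotomization (`bfGrouping()`) defaults to BF for score ≥ 4 ("Medium"
and above), which splits the 22-accession panel exactly 11/11 — the split
implied by the study's printed 2×2 margins. `pearsonChi2()` reports the
chi-square statistic, Pearson residuals \((O-E)/\sqrt{E}\) for mosaic
displays, and for 2×2 tables the phi coefficient
\(\phi = (n_{11}n_{22}-n_{12}n_{21})/\sqrt{n_{1\cdot}n_{2\cdot}n_{\cdot1}n_{\cdot2}}\),
which satisfies \(\chi^2 = N\phi^2\). No continuity correction is applied
by default, matching the residual-based presentation. Conditional
independence on 2×2×K strata uses the Cochran–Mantel–Haenszel statistic
(`cmhTest()`), computed from summed hypergeometric means and variances and
verified in the tests against `stats::mantelhaen.test`.

Concordance of methylation profiles between accessions uses Kendall's
tau-b, the tie-adjusted form
\(\tau_b = (C - D)/\sqrt{(n_0-n_1)(n_0-n_2)}\). For binary profiles tau-b
coincides with the phi coefficient of the pair's 2×2 cross-table, which
`kendallTauB()` uses as a closed form (general inputs fall back to pair
enumeration). Concordance is computed on the binary `deMet01` profiles,
not the four-state calls: ties dominate binary data and the tie-adjusted
denominator is exactly what makes tau meaningful there. Note one
interpretive subtlety: the genome-wide 2×2 aggregates (band, accession)
cells that are not independent observations (they share bands and
accessions), so its p-value should be read as descriptive, not as a
calibrated test — this motivates the model-based analysis below.

`perfectlyAssociatedBands()` reports bands methylated in every BF
accession and demethylated in every NBF accession (or the exact
complement, flagged by direction). No multiplicity control is applied:
perfect separation is reported descriptively, as a screening observation.

## Ordination

`binaryDistance()` defaults to the simple-matching (mismatch) proportion:
with methylation absence being a state in its own right, 0/0 agreement is
informative, unlike in presence/absence genotyping where Jaccard would be
preferred (also available). `pcoaOrdination()` is classical
multidimensional scaling — Gower double-centering
\(B = -\tfrac12 J D^2 J\), eigendecomposition, coordinates scaled by
\(\sqrt{\lambda}\) — with negative eigenvalues reported, not corrected: no
Cailliez/Lingoes adjustment is applied silently, so the user sees exactly
how non-Euclidean the chosen distance is. `upgmaTree()` performs
average-linkage clustering after sorting labels lexicographically, so
equal-distance ties break deterministically; the result is ultrametric by
construction and exportable as Newick via `ape`.

## Bayesian hierarchical log-linear model selection

The core engine analyses a complete contingency structure built from
records of (BF score, `deMet01`, `ChronoAge`, `GenotypeN`). Records
sharing identical covariates are collapsed (`loglinearCells()`) into cells
with summed response \(y\) and offset \(\log(\text{records})\), which
leaves the Poisson likelihood unchanged up to a constant: the model is

\[ y_i \sim \text{Poisson}(\mu_i), \qquad
   \log \mu_i = o_i + x_i^\top \beta_m , \]

with \(x_i\) the design row of hierarchical model \(m\): a downward-closed
set of terms over the factors (every sub-term of an included interaction
is included). `enumerateModels()` enumerates this model space — 5 models
for two factors; 9 for three factors with main effects forced — and the
sampler only accepts hierarchical candidates.

**Prior.** A generalized hyper-g prior: the intercept is flat; the
non-intercept coefficients get the unit-information normal
\(\tilde\beta \mid g \sim N\!\big(0,\; g\,N\,(\tilde X_c^\top \tilde
X_c)^{-1}\big)\) with \(\tilde X_c\) the column-centred design and \(N\)
the number of cells; and the shrinkage weight follows
\(g/(1+g) \sim \text{Beta}(1, (a-2)/2)\) with \(a = 4\), i.e. a uniform
prior on the shrinkage fraction, a standard default for this prior family.
Candidate models are equally probable a priori. These hyper-choices are
exposed through `mcmcSettings()`.

**Sampler.** `rjmcmc()` runs, per iteration: (i) a reversible-jump move
that picks uniformly among candidate models differing by exactly one term
and proposes a full redraw of the coefficient vector from a
prior-regularized Laplace approximation to the destination model's
posterior (full-vector independence proposals make dimension matching
exact, and give good between-model mixing on the small-to-moderate tables
this engine targets); (ii) a full-vector Metropolis random walk on
\(\beta\) preconditioned by the Laplace curvature with the usual
\(2.38/\sqrt{d}\) scaling; (iii) a log-scale random-walk update of \(g\)
(or a direct draw from the prior when the current model has no shrinkable
coefficients). Defaults mirror the study conditions: 12,500 iterations,
burn-in 2,500, no thinning. Chains are bit-reproducible given (seed,
settings, data). Reported diagnostics are the reversible-jump and
Metropolis acceptance percentages (with a single candidate model the RJ
rate is reported as 0% — no jumps are ever attempted), posterior model
probabilities, and per-parameter posterior summaries: inclusion
probability, mean, variance, and 95% highest-posterior-density limits
conditional on inclusion.

**Numerical choices.** HPD intervals use the Chen–Shao sweep (shortest
window containing \(\lceil 0.95 n \rceil\) sorted draws); the exported
`hpdInterval()` refuses fewer than 100 draws because shorter chains give
unstable interval endpoints. The posterior predictive p-value
(`bayesianPValue()`) uses the deviance
\(D = 2\sum_i [y_i \log(y_i/\mu_i) - (y_i - \mu_i)]\) as the discrepancy,
simulating one replicate table per retained draw; ties count toward
\(p_B\), so a saturated fit that reproduces the data exactly yields
\(p_B = 1\). `rankTermsByVariance()` ranks terms by the variance across
cells of their posterior-mean linear-predictor component, rank 1 being the
top contributor. Proposal construction uses a prior-regularized Newton
mode with step halving, so models with empty cells (where the unpenalized
MLE diverges) still get finite, usable proposals.

**Validation.** The sampler targets the exact posterior; its independent
oracle in the test suite integrates each model's marginal likelihood
numerically (Laplace over coefficients at fixed \(g\) via BFGS, trapezoid
quadrature over \(\log g\) — the integrand spans orders of magnitude in
\(g\), so quadrature on a natural-scale grid is badly biased, a pitfall
the test helper documents). Posterior model probabilities agree with the
oracle within three Monte-Carlo standard errors on 2×2 and 2×2×2 problems
across ten seeds, and a planted methylation-by-age interaction at 5,500
records is recovered (inclusion probability above 0.9 and truth inside the
95% HPD in at least 18 of 20 seeded replicates). These problem sizes were
chosen to make the oracle comparisons sharp while keeping the default test
run fast.

**Two response conventions.** The study's model formulas place the BF
score on the left of a contingency-table engine's formula, which makes the
ordinal score play the role of the count response. The engine therefore
supports exactly that: the record-level frame from `frameFromMatrix()` can
be aggregated and fitted with the BF score as the Poisson response
("table mode", the default path). For effect summaries on the probability
scale, the record-level logistic route (`fitGlm()` on a dichotomized
response) is the second convention; both are exposed because neither alone
reproduces every reported quantity.

## Effects and fit indices

`fitGlm()` fits the selected model by IRLS (relative deviance change below
1e-10, at most 100 iterations) via `stats::glm` and detects
complete/quasi-complete separation — the convergence pathology reported
for dichotomized BF fits — instead of returning divergent coefficients
silently. `mcfaddenAdjustedR2()` is \(1 - (\ell_m - k)/\ell_0\); adding a
useless parameter strictly decreases it. `oddsRatio()` exponentiates named
contrast sums; with the reported posterior means the per-age-unit odds
ratios are 0.89948 (demethylated) and 0.90489 (methylated). The reported
methylated-level slope of −0.099994 is inconsistent with the reported
components (−0.105934 + 0.005994 = −0.099940, whose exponential 0.90489
matches the reported odds ratio), so the package always computes from
coefficients rather than quoting a slope. One unit-label inconsistency is
carried over deliberately: ages are recorded in decades, yet the reported
"one-year increase" odds ratios are per one unit of the age covariate;
`effectCurves()` and `oddsRatio()` therefore work per covariate unit,
which reproduces the printed values exactly. `effectCurves()` returns
log-odds lines per methylation level (the slope gap equals the interaction
coefficient identically) and their logistic-transformed probabilities;
with the reported coefficient values both curves decrease and approach
zero by large clonal ages.

## The synthetic generator

The raw gel scores behind the study are unpublished, so
`generateBandMatrix()` emulates the study design: the packaged 22
accessions, nine primer combinations with the published per-primer band
counts (120, 136, 125, 161, 114, 214, 133, 121, 124; 1,248 bands — the
study's prose also mentions 1,251 fragments, a discrepancy the fixture
resolves in favour of the per-primer counts, which are self-consistent).
Each band is methylation-susceptible with probability 1238/1248 (the
published MSL fraction); a susceptible band's per-cell methylation
indicator follows a logistic model with a per-band baseline
\(N(-0.3, 2^2)\) plus BF-score, clonal-age and genotype effects; a
methylated cell is hemimethylated/internal-C/fully methylated with
probabilities (0.17, 0.20, 0.63), the approximate conditional composition
of the published banding table; states are inverted to calls by the
isoschizomer scheme, and each call is flipped independently with
probability 0.01 (so call errors can fabricate low-frequency states,
deliberately exercising the 5% MSL threshold).

Default effects are +0.12 log-odds of methylation per BF-score unit and
+0.02 per decade of clonal age. The BF effect is set well above the age
effect because the panel's ages and BF scores are negatively confounded —
its low-BF clones are among its oldest — and a weaker BF effect would let
the age term cancel the genome-wide methylation–BF direction that the
generator is meant to emulate (BF accessions more methylated). The
baseline spread lets a minority of susceptible loci sit near fixation, so
monomorphic MSLs occur, though the generator makes no attempt to reproduce
the published 91% polymorphism rate or per-accession band totals exactly;
nor does it model gel mobility, fragment sizes, primer sequence
specificity, spatial linkage along the genome, or correlated scoring
errors between adjacent bands. Passing tests on synthetic data therefore
demonstrate the statistical machinery, not the biology: in real data,
bands are not independent given the covariates, and scoring error is not
symmetric.

`plantPerfectBand()` overwrites one band to be fully diagnostic for BF
(the analogue of a perfectly associated band), and `simulateCountFrame()`
draws record-level Poisson frames from known log-linear coefficients for
parameter-recovery checks. Every generator output is bit-reproducible from
its seed, which the truth object records.

## Known limitations and open points

* The published group-conditional banding proportions and the printed 2×2
  counts cannot be reconciled under any single denominator stated in the
  source; the package computes both quantities from their own definitions
  (`methylationFractionTable()` vs `buildContingency2x2()`) and does not
  force agreement. Similarly, the four printed 2×2 cells sum to 24,792
  while the stated band total is 24,794; percentages are insensitive to
  the difference at the printed precision.
* The study reports model-space sizes ("five models", "three models") that
  no stated enumeration rule reproduces; `enumerateModels()` reports its
  own deterministic enumeration and the candidate list is always explicit
  in the output object.
* The study's Nonpareil-only analysis mentions nine clones, while the
  metadata table lists seven accessions labelled Nonpareil (plus four
  Stukey clones of Nonpareil seed origin); subsetting is left to the user
  via the genotype column.
* A reported 0% reversible-jump acceptance alongside \(p_B = 1\) indicates
  a chain that never left the saturated model; the engine reports the same
  diagnostics so that this situation is visible, but healthy runs on
  synthetic data mix across models.

## Session info

```{r}
sessionInfo()
```
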