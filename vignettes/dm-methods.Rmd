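---
title: "Detecting selection on DNA methylation with the Dm test: models and methods"
author: "dmtest authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection on DNA methylation with the Dm test: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmtest)
```

## The problem

Heritable gains and losses of cytosine methylation (epimutations) occur
orders of magnitude more often than point mutations, segregate in
populations as single methylation polymorphisms (SMPs), and can affect
fitness.  A locus whose methylation states are under selection should
show a distorted SMP frequency spectrum: directional pressure or a
recent epiallele turnover leaves an excess of rare epialleles, while a
maintained intermediate-frequency epiallele leaves an excess of common
ones.  The `Dm` statistic carries Tajima's *D* logic over to methylation
data, with two modifications that matter at epimutation rates: sites
have only **two** states (methylated/unmethylated), so recurrent changes
saturate, and the per-site rate is strongly **heterogeneous** across
cytosines.

## The two-state model

Methylation state at a site evolves as a symmetric two-state
(Cavender–Farris–Neyman) Markov chain with scaled rate
$\theta_m = 4N\mu_m$ per site.  Along a branch of length $T$ (in $4N$
generations) the state flips with probability
$\tfrac12\left(1 - e^{-2\theta_m T}\right)$.  At stationarity the
population frequency of the methylated state is
$\mathrm{Beta}(\theta_m, \theta_m)$, which gives the probability that a
sample of $n$ chromosomes is fixed for one particular state in closed
form,
$$p_{\mathrm{mono}} =
\frac{\Gamma(2\theta_m)\,\Gamma(\theta_m + n)}
     {\Gamma(\theta_m)\,\Gamma(2\theta_m + n)},$$
implemented with log-gamma throughout (`monomorphic_prob()`).  Among-site
rate variation follows a gamma distribution with shape $\alpha$ and mean
$\bar\theta_m$; small $\alpha$ means a few fast sites among many slow
ones.

Expanding $1 - 2\,p_{\mathrm{mono}}$ to second order and averaging over
the gamma density gives the expectations of the two observable
summaries, the segregating-site proportion $s_m$ and the mean pairwise
difference per site $\pi_m$:
$$E(s_m) \approx \frac{a_1\bar\theta_m}{1 + c_1\kappa\bar\theta_m},
\qquad
E(\pi_m) \approx \frac{\bar\theta_m}{1 + 2\kappa\bar\theta_m},
\qquad \kappa = \frac{\alpha+1}{\alpha},$$
with $a_1 = \sum_{i<n} 1/i$ and $c_1 = 2a_1 - 3a_3/a_1 =
(a_1^2+3a_2)/(2a_1)$.  The $c_1$ form is worth a note: we verified it
symbolically — the series expansion of the stationary-moment formula
gives the $O(\theta^2)$ coefficient $(K-1)^2a_1^2/2 + (K^2-1)a_2/2$ for
a symmetric $K$-state model, which reduces to exactly this $c_1$ at
$K = 2$ and to $c_{1,\mathrm{mod}} = (3a_1^2+5a_2)/(6a_1)$ at $K = 4$.
The four-state constants (with pairwise factor $4/3$ in place of $2$)
define the `Dmod` comparator; they were derived here with the same
machinery via symmetric-Dirichlet stationary moments rather than
transcribed, and the derivation is pinned by tests against numeric
series expansion.

## Estimators and the statistic

Two functional forms of the rate estimators are provided
(`theta_hats(form = ...)`):

* **`"series"`** (default): the first-order series inverses
  $\hat\theta_s = (s_m/a_1)(1 + c_1\kappa s_m/a_1)$ and
  $\hat\theta_\pi = \pi_m(1 + 2\kappa\pi_m)$.  These are pole-free and
  always defined; at large $\bar\theta_m$ and small $\alpha$,
  $\hat\theta_s$ progressively underestimates (site saturation) and both
  remain finite.  In this mode the two-state estimators track a
  simulated $\bar\theta_m$ more closely than the four-state or
  infinite-site ones at every grid point we test, with the gap growing
  in $\bar\theta_m$ — the behaviour the test suite asserts
  directionally.  Three structural facts make this the default: the
  underestimation behaviour just described, near-unit variance of the
  statistic under the neutral study conditions, and definedness on
  saturated data (e.g. strong-shrinkage demographies), none of which
  the exact inversions can provide.

* **`"inversion"`**: the exact algebraic inverses,
  $\hat\theta_s = s_m/(a_1 - c_1\kappa s_m)$ and
  $\hat\theta_\pi = \pi_m/(1 - 2\kappa\pi_m)$.  These satisfy the exact
  round-trip identity $\hat\theta(E(s_m), E(\pi_m)) = \bar\theta_m$ (a
  tested invariant), but each has a pole: when the observed summary
  reaches the correction scale ($\pi_m \ge 1/(2\kappa)$, or
  $s_m \ge a_1/(c_1\kappa)$) the estimate is undefined and is returned
  as flagged `NaN`, never a silent zero or truncation.

The statistic substitutes the estimators into Tajima's *D*: with
$\hat S_m = a_1\hat\theta_s L$,
$$D^m = \frac{(\hat\theta_\pi - \hat\theta_s)\,L}
{\sqrt{e_1\hat S_m + e_2\hat S_m(\hat S_m - 1)}},$$
where $e_1, e_2$ are the classic variance constants.  A switch
(`s_hat_scale = "raw"`) substitutes the observed $S$ instead of
$\hat S_m$; the default follows the estimator-based substitution.
Monomorphic loci, undefined estimators, and non-positive variance terms
yield `defined = FALSE`.  For $n \le 3$ on binary data the numerator and
the variance are both identically zero and the statistic is defined as 0.

Two properties of this construction deserve honesty.  Under the neutral
study conditions used throughout (n = 60, L = 1000,
$\bar\theta_m = 0.1$, $\alpha = 0.5$), the default series form has
near-unit sampling variance but a positive offset of the mean: the
second-order bias of the series estimators does not cancel between the
$\pi$ and $s$ sides at these rates.  The inversion form is the mirror
image — approximately centred, but with variance well above 1, because
the nonlinear inversions amplify genealogical fluctuations of $\pi_m$
(the pole at $\pi_m = 1/6$ for $\kappa = 3$ sits close to the observed
range) and the variance normalisation does not account for the
amplification.  Both effects shrink as $\bar\theta_m \to 0$, where all
three statistics coincide — these facts are computed by the test suite
and the acceptance script, not assumed.  No functional form we examined
removes both effects at once.  Empirical-null practice (ranking loci
against the genome-wide distribution of the same statistic) is
insensitive to a common offset or scale, which is how the test is meant
to be used on real data.

## Estimating the gamma shape

`estimate_alpha()` implements the parsimony moment method: build the
neighbor-joining tree of the samples from per-site mismatch distances
(Saitou–Nei, via ape), count the minimum number of state changes per
site on that tree (exact two-state small-parsimony dynamic programming,
root-invariant, checked against exhaustive enumeration and phangorn),
cap counts above 5 at 6, and match moments of the resulting counts to a
negative binomial: $\hat\alpha = m^2/(s^2 - m)$ with $m$ and $s^2$ the
sample mean and population variance (denominator $L$).  Two printed
special cases are kept exactly: $s^2 = 0$ returns $10^6$ (rate
homogeneity), and $s^2 < m$ uses the substitution
$1 - m/s^2 = e^{-m/s^2}$, i.e. $\hat\alpha = m^2/(s^2 e^{-m/s^2})$.
Note the substitution branch is discontinuous around $s^2 \approx m$
(it returns values near $m\,e$ rather than diverging), so estimates near
rate homogeneity are bimodal; the estimator is useful in the
low-$\alpha$ regime real methylation data occupy, and the recovery test
is run there.

## The simulator

Neutral data are generated natively: Kingman coalescent genealogies in
`ms` time conventions (time in $4N$ generations, $k$ lineages coalesce
at rate $k(k-1)$, so a sample pair has mean TMRCA 0.5), per-site rates
drawn from the gamma, and states evolved by the CFN flip probability
along each branch with the root state drawn 50/50.  Demographic
scenarios: instantaneous size change (rate multiplier in the older
epoch) and a symmetric two-deme island model (per-lineage migration
rate $M/2$).  No recombination in neutral runs.  One master seed derives
per-replicate substreams, so any replicate is independently
reproducible bitwise.

What the generator does **not** emulate: bisulfite conversion or
sequencing error, missing-data patterns (tests inject missingness
directly), methylation-context differences (CG/CHG/CHH are not
distinguished; the test is context-agnostic), linked selection in
neutral runs, and diploid genotype structure (haploid methylomes, as in
selfing *Arabidopsis* accessions).  Passing tests therefore validate the
statistical machinery, not robustness to technical noise in real
methylomes.

## Selection scenarios

Selection enters through deterministic population-epigenetic
trajectories in the style of Geoghegan & Spencer, followed by a
trajectory-conditioned structured coalescent (the `mssel` approach).

**Recursions.**  Each generation, offspring disperse into environment 1
with probability $r$; with probability $t$ their epiallele is reset to
the state induced by the local environment; viability selection then
acts and mating is random.  The reset-then-select order is not
arbitrary: with selection before resetting, an equilibrium epiallele
frequency of 0.0028 (the Model-2 Type-I anchor) is algebraically
impossible against a resetting influx of $t\,r = 0.02$ per generation,
whereas reset-then-select accommodates every published anchor.  Model 1
follows two epialleles under diploid epigenotype fitness; Model 2
follows four gamete classes (allele × epiallele) under multiplicative
gamete fitness with an allele-by-epiallele interaction, so the new
epiallele spreads with the allele it is favoured on.

**Calibration.**  The source scenarios specify $(r, t)$, the starting
state and the equilibrium reached, but not the fitness values, and no
single fitness setting reproduces all published equilibria under any
lifecycle order we tried.  Each scenario preset therefore carries its
own fitness setting, solved in closed form so the recursion's
equilibrium matches the published value exactly (e.g. $p_1 = 0.1093$ at
$r = 0.5$, $t = 0.1$; new-epiallele frequency 0.9972 and 0.2436 for the
Model-2 scenarios).  These equilibria are regression-anchored in the
test suite at four decimals.

**Conditioned coalescent.**  Backwards in time, lineages are labelled by
focal-site class; within a class of frequency $x$, pairs coalesce at
rate $2/x$; recombination (total rate $\rho = 4Nr(L-1)$, default 0.7992
across 1000 sites with the focal site at position 500) detaches the
non-focal side of a lineage, whose class is re-sampled from the current
frequency; when the new class's frequency reaches zero backwards, its
remaining lineages merge into the founding lineage and join the
ancestral class.  The per-generation transient is simulated generation
by generation with parent sampling in $2N$ sequences (exact for the very
fast frequency changes these recursions produce); constant-frequency
phases (equilibrium hold, pre-origination) use exponential waiting
times.  Sample configuration at the focal site is binomial in the
sampling-time frequency.  Marginal trees per recombination block are
assembled from the event log and states evolve per block.

**Time scale.**  The recursions advance per generation; the coalescent
is continuous with one generation $= 1/(4N)$.  Because the published
equilibria force strong per-generation selection, calibrated transients
last only ~10–170 generations, and the mapping's $N$ decides how much
coalescent time a scenario spans.  The scenario presets use $N = 500$,
chosen once so that the longest transient spans a non-negligible
fraction of coalescent time ($\approx 0.08 \cdot 4N$) while the
shortest still yields polymorphic samples; with a literal $N = 10^4$
every scenario compresses below $0.005 \cdot 4N$ and Model-2 samples
come out nearly monomorphic, which cannot reproduce the published
power values.  `N` is exposed on every simulation function.  This is
the largest reconstruction uncertainty in the package: the original
trajectory-to-coalescent mapping is not recoverable from the published
description, and residual disagreement between simulated and published
powers is reported by the acceptance tests rather than hidden.

## Power machinery and empirical nulls

`null_distribution()` simulates the standard neutral model and collects
defined statistics (dropped replicates are counted, never imputed).
`test_power()` uses type-7 empirical quantiles and strict inequality
beyond the critical value; undefined statistics never enter
denominators.  `empirical_scan()` applies the same quantile convention
to a genome-wide set of loci used as its own null — the practice that
absorbs demography and pervasive purifying selection — and reports rank
empirical p-values.  No multiple-testing correction is applied anywhere:
tails are raw 5% by design, and the scan documents this prominently.
`overlap_expectation()` computes the independence expectation for
SMP-/SNP-outlier overlap with an exact binomial test.

## Numerical and interface choices

* Coordinates are 1-based inclusive everywhere; BED input is converted
  on read by rtracklayer.
* A site enters the analysis only if every sample has a called state;
  `L` is the retained-site count.
* 450K beta values discretise at the printed thresholds
  ($\beta < 0.33$, $\beta > 0.66$, strict), boundaries falling in the
  heterozygous band.
* VCF genotypes are expanded to haplotype columns; multiallelic sites
  are skipped and counted.
* Unlinked-gene sampling measures the end-to-start gap (conservative
  for linkage decay) and is greedy in random order.
* No tolerance below $10^{-12}$ is asserted anywhere; log-gamma is used
  for all ratio-of-gamma expressions.

## Problem sizes used by the test suite

The suite regenerates everything it tests: 5000 neutral replicates at
the study conditions (shared across calibration, null, and power
checks), 1000 replicates per selection scenario, 250–300 replicates per
demographic scenario, and small exhaustive oracles (parsimony
enumeration up to 7 leaves, 100-matrix cross-checks of Tajima's *D*
against an independent implementation).  These sizes were chosen to
keep Monte-Carlo error well below the tolerances being asserted.

## Known limitations

* The `Dm` variance normalisation is approximate away from small
  $\bar\theta_m$ (see above); empirical-null usage, as recommended for
  real data, is insensitive to this.
* The selection-scenario time mapping is a reconstruction (see above).
* The α estimator inherits the printed formula's discontinuity near
  rate homogeneity.
* The two-parameter (asymmetric gain/loss) epimutation model is exposed
  only through the general transition machinery; all shipped analyses
  use the one-parameter symmetric model.
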