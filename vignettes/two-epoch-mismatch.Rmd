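---
title: "Two-epoch demography from pairwise mismatch distributions"
author: "snowcoal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-epoch demography from pairwise mismatch distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snowcoal)
```

## The scientific problem

Surveys of fast-evolving markers such as the nuclear rDNA ITS2 region
yield, for organisms like snow algae, thousands of unique sequence
variants ("phylotypes") whose geographic footprint ranges from a single
region to a cosmopolitan presence at both poles and the mid-latitudes. Two
questions recur. First, do cosmopolitan and endemic phylotypes carry
distinct demographic histories, or are "cosmopolitans" merely old
ancestral haplotypes shared by otherwise separate populations? Second, on
what time scale did the populations behind these phylotypes expand?

Both questions can be addressed with the *mismatch distribution*: the
histogram of the number of differing sites $K$ between randomly chosen
pairs of sequences. A population that suddenly expanded leaves a
characteristic unimodal "wave" in this histogram whose position moves with
the age of the expansion, whereas a stationary population leaves a
geometric (exponential-shaped) distribution. Classical treatments fit an
approximate solution curve to the histogram, which makes statistical
assessment awkward; `snowcoal` instead works with the exact likelihood of
mismatch counts under the coalescent, so estimation and model comparison
are ordinary (composite) maximum likelihood.

## Model

A population has effective size $N_0$ until $t_0$ generations ago and
$N_1$ afterwards. Backward in time, a pair of lineages coalesces at rate
$1/(2N_1)$ during the recent epoch and $1/(2N_0)$ during the ancestral
one, so the coalescence time $s$ has density

$$f(s) = \frac{1}{2N_1}e^{-s/(2N_1)} \;(s < t_0), \qquad
  f(s) = e^{-t_0/(2N_1)}\frac{1}{2N_0}e^{-(s-t_0)/(2N_0)} \;(s \ge t_0).$$

Conditional on $s$, the number of mismatched sites is Poisson with mean
$2us$ ($u$ = per-sequence per-generation mutation rate; mutations are
assumed never to strike the same site twice, an infinite-sites-like
idealisation that is reasonable while $E(K)$ is far below the sequence
length). Writing $\tau = 2ut_0$, $\theta_0 = 2N_0u$, $\theta_1 = 2N_1u$,
the marginal pmf integrates in closed form:

$$P(K=k) = \left(\frac{\theta_1}{1+\theta_1}\right)^{k}
  \frac{1}{1+\theta_1}\frac{1}{k!}\,
  \gamma\!\left(k+1, \tau\left(1+\tfrac{1}{\theta_1}\right)\right)
  + \left(\frac{\theta_0}{1+\theta_0}\right)^{k}
  \frac{1}{1+\theta_0}\frac{1}{k!}\,
  \Gamma\!\left(k+1, \tau\left(1+\tfrac{1}{\theta_0}\right)\right)
  e^{-\tau\left(\tfrac{1}{\theta_1}-\tfrac{1}{\theta_0}\right)}.$$

Here $\gamma(c,x)=\int_0^x e^{-z}z^{c-1}dz$ is the **lower** and
$\Gamma(c,x)=\int_x^\infty e^{-z}z^{c-1}dz$ the **upper** unregularised
incomplete gamma function. Conventions for $\gamma/\Gamma$ vary across the
literature and are easy to garble; we fixed ours by re-deriving the pmf
from the defining integral $\int_0^\infty f(s)\,e^{-2us}(2us)^k/k!\,ds$
and verifying the closed form against adaptive quadrature of that integral
to better than $10^{-15}$ over random parameter grids (this check is kept
as a permanent test and is recomputed by `scripts/acceptance.R`). Useful
identities, all tested: $\tau=0$ or $\theta_0=\theta_1$ collapse the pmf
to the geometric distribution of a constant-size population;
$\tau\to\infty$ gives the geometric in $\theta_1$; and
$E(K) = \theta_1 + (\theta_0-\theta_1)e^{-\tau/\theta_1}$, the familiar
expected pairwise difference under a sudden expansion.

## Numerical evaluation of the pmf

`mismatch_log_pmf()` evaluates each epoch term in log space and combines
them by log-sum-exp. The recent-epoch term uses
`pgamma(..., log.p = TRUE)` directly. The ancestral-epoch term cannot:
its incomplete-gamma argument $x_0=\tau(1+1/\theta_0)$ grows like
$\tau/\theta_0$, and the analytically exact cancellation
$-x_0 + \tau/\theta_0 = -\tau$ would then be performed numerically between
two numbers of magnitude up to $10^{12}$, leaving absolute noise far above
the pmf itself. (In an early version this noise inflated the pmf's total
mass to $1.000166$ at $\theta_0 = 10^{-12}$ — enough to create a phantom
likelihood gain that dragged every fitted $\hat\theta_0$ to zero.)
Because $k+1$ is a positive integer, the upper incomplete gamma is the
finite sum $\Gamma(k+1,x_0) = k!\,e^{-x_0}\sum_{j\le k} x_0^j/j!$, so the
cancellation is done symbolically and only the moderate prefix log-sum
$\log\sum_{j\le k}x_0^j/j!$ is computed. The pmf then sums to 1 within
$10^{-12}$ across the full parameter range, including
$\theta\to 0$.

Other numerical choices:

* scaled sizes below $10^{-12}$ are clamped to $10^{-12}$ before forming
  $1/\theta$, preserving the $\theta\to 0$ point-mass limit without
  overflow;
* tail sums (normalisation, moments) are truncated where the geometric
  envelope with ratio $\theta_{max}/(1+\theta_{max})$ bounds the remaining
  mass below $10^{-12}$ (`mismatch_kmax()`).

## Composite likelihood and optimisation

With $n$ phylotypes, a uniformly random permutation is split into
$\lfloor n/2\rfloor$ disjoint pairs and the composite log-likelihood
$\sum_i \log L(k_i;\theta_0,\theta_1,\tau)$ is maximised. Disjoint pairs
avoid the strongest dependence between overlapping pairs, but pairs may
still share genealogy, so this is a pseudo-likelihood: variances derived
from it can be optimistic, which is a known and accepted caveat of the
approach.

`fit_demography()` optimises in $(\log(\tau+10^{-12}), \log\theta_0,
\log\theta_1)$ — positivity without constraints — by Nelder–Mead from six
deterministic moment-matched starts (the sample mean $\bar k$ estimates
$E(K)$; the starts place $\bar k$ in constant-size, expansion, contraction
and boundary configurations), restarts the simplex from the incumbent
until improvement falls below $10^{-8}$ (plain Nelder–Mead stalls on the
ridges this surface has), and polishes with BFGS. Counts are aggregated to
unique values first, so a fit on $10^4$ pairs costs the same as one on the
few dozen distinct mismatch values they contain.

**Uncertainty.** Standard deviations come from the inverse observed
Fisher information (numerical Hessian, `pracma::hessian`, on the natural
scale). Two situations make them honestly unavailable rather than
numerical garbage: a singular or non-positive-definite Hessian, and a
*flat ridge*. For the latter, each parameter is scanned over a
$\pm 2$-decade grid (41 points) around its estimate with the others held
fixed; if the contiguous plateau within $10^{-6}$ log-likelihood units of
the optimum spans at least a decade, the parameter's sd is marked
unavailable and the plateau interval is reported. This reproduces the
canonical empirical situation where a population's diversity is so low
relative to the fitted expansion age that the ancestral epoch is simply
unobserved: the ancestral term of the pmf is suppressed by
$e^{-\tau/\theta_1}$ at machine level and $\theta_0$ can wander over
decades without changing the likelihood (the acceptance suite constructs
exactly this case and checks the diagnostic fires).

The same likelihood surface can have exactly equivalent representations —
geometric data fit equally well by $\tau = 0$ with free $\theta_0$ and by
large $\tau$ with free $\theta_0$ at $\theta_1$ fixed — so which parameter
is flagged flat can depend on the basin the optimiser lands in. Directed
`starts` make the diagnostic deterministic when a particular
representation is wanted.

## Model comparison and unit conversion

`compare_models()` fits one pooled model to all phylotypes and one model
per subset, and decides by raw composite log-likelihood: "separate" iff
the summed per-subset log-likelihood exceeds the pooled one. No
parameter-count penalty is applied — that is the field's criterion for
this analysis — but an AIC column is reported for transparency. When
subsets are supplied as sequences, the pooled fit re-pairs across the
entire pooled collection (pairs may straddle subsets); the two
configurations therefore need not contain the same number of pairs, and
pair counts are always reported alongside. With a single subset the
comparison degenerates and ties break toward "pooled".

`convert_units()` undoes the scaling: $t_0 = \tau/(2u)$ generations,
$N_i = \theta_i/(2u)$, years via the generation time. The defaults in
`rate_assumptions()` encode the study conditions for snow algae: a
mutation-accumulation rate for a unicellular green alga of
$2.08\times10^{-10}$ (95% CI $1.09\times10^{-10}$–$3.74\times10^{-10}$)
per site per generation, a 381-site ITS2 alignment (so
$u = 7.9\times10^{-8}$ per sequence), and a generation (doubling) time of
24 days with range 11–36 days — the annualised effective doubling time of
an alga that grows only during a roughly two-month melt season.
`propagate_ranges()` pushes the rate CI and the generation range through
to the expansion time by evaluating its four corner combinations; since
$t_{years} = \tau g/(730\,u)$ is monotone (decreasing in $u$, increasing
in $g$), the corners attain the exact extremes — a property the tests
verify against a dense grid. Human-readable reports round to 2 significant
figures; machine-readable outputs keep full precision.

## Classification rule

`classify_distribution()` folds detections into three macro-regions —
Antarctic, Arctic (accepting the subregions Svalbard, Greenland, Alaska),
and mid-latitude — and labels a phylotype *cosmopolitan* if present in all
three, *endemic* if present in exactly one, and *multi-region* otherwise
(two macro-regions, including "both poles only"). A stricter reading of
the rule requires a cosmopolitan to be detected in every named Arctic
subregion;
`strict_cosmopolitan = TRUE` implements it, and a phylotype failing only
the subregion requirement falls back to multi-region. Classification
always operates on unique sequences; read counts are carried as metadata
for reporting only, never as classification input.

**Gap handling.** Amplicon-survey practice is typically to delete
ambiguous sites globally before analysis. `build_mismatch_sample()`'s
default `"strict"` mode does that: any alignment column containing a gap or ambiguity code in
any sequence is removed collection-wide before counting. The alternative
`"pairwise"` mode deletes only the offending positions within each pair —
a defensible reading that retains more sites; both are exposed because
neither is uniquely implied by a global-deletion description. Comparison
is case-insensitive and U is read as T.

## The simulator: what it does and does not emulate

`simulate_mismatch_counts()` draws, per pair, a scaled coalescence time
from the two-epoch piecewise exponential (truncated-exponential mixture,
inverse-CDF in the recent epoch) and then a Poisson count — exactly the
generative model the likelihood assumes, parameterised directly by
$(\tau,\theta_0,\theta_1)$ so no mutation rate or census size is needed.
`emit_sequence_pairs()` realises counts as aligned pairs by mutating $k$
distinct random sites of a random ancestor, warning when any
$k > 0.2\,L$, where the no-multiple-hits idealisation becomes dubious.
`generate_phylotype_table()` emits region tables whose labels match
configured proportions exactly under largest-remainder rounding.

Passing tests on this simulator shows the estimator is correct *under the
model's own assumptions*. Real data differ in ways the simulator
deliberately does not emulate: pairs drawn from one genealogy are
correlated (the simulator's pairs are independent, so real-data variances
will be larger than composite-likelihood theory suggests); finite-sites
saturation and back-mutation; sequencing error and, in ancient ice-core
material, post-mortem substitutions such as cytosine-to-thymine; selection
and recombination. Conclusions about real data inherit those caveats.

## Calibration of the recovery check

The acceptance suite includes a parameter-recovery property: 20 seeded
replicates of $10^4$ pairs at $(\tau,\theta_0,\theta_1)=(5,0.5,10)$, a
regime with a 20-fold expansion $\tau/\theta_1 = 0.5$ coalescent units
ago. The tolerance on the median relative error was calibrated once by a
repeated-simulation oracle (200 independent replicates) *before* the check
was frozen: the composite MLE's median relative error is about 2% for
$\tau$ and $\theta_1$, but 18% (IQR 8–30%) for $\theta_0$ — the ancestral
size is intrinsically the hardest parameter, identified only through the
$e^{-\tau/\theta_1}$-weighted tail of pairs that survive into the
ancestral epoch, and its profile likelihood is nearly flat below the true
value. The frozen tolerances are therefore 15% for $\tau$ and $\theta_1$
and 30% (the calibrated 97.5th-percentile ceiling) for $\theta_0$. Every
replicate also checks MLE optimality: the fitted likelihood must be at
least the truth's.

## Problem sizes and degenerate inputs

The test and acceptance problem sizes — 50 random parameter points with
$k \le 60$ for the quadrature cross-check, $10^5$ pairs for the
total-variation check (threshold 0.01), $10^4$ pairs $\times$ 20
replicates for recovery, $2\times2000$ pairs $\times$ 20 replicates for
the model-comparison decision rate, 2000 pairs for the flat-ridge
construction — were chosen so the full suite runs in well under a minute
on one core while leaving each stochastic check's noise floor far from its
threshold.

Degenerate inputs behave predictably: an all-zero sample drives
$\hat\theta_1$ to the lower boundary with log-likelihood $\to 0^-$;
$\tau = 0$ converts to an expansion time of zero regardless of rates;
empty samples, undersized samples (fewer than `min_pairs` pairs),
inverted ranges, unknown region names, and counts exceeding the sequence
length are all rejected with informative errors rather than propagated.

## Known limitations

* Two epochs only; multi-epoch histories, recombination, and selection
  are out of scope.
* Composite-likelihood standard deviations ignore genealogical correlation
  among pairs and may understate uncertainty on real data.
* The Poisson mutation model has no finite-sites correction; treat fits
  with $E(K)$ approaching the alignment length with suspicion.
* $\theta_0$ is weakly identified whenever few pairs coalesce in the
  ancestral epoch; expect wide or unavailable standard deviations there —
  that is the method being honest, not failing.
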