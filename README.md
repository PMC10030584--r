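# snowcoal

Composite-likelihood inference of sudden-expansion demographic histories
from pairwise mismatch distributions of aligned marker sequences.

The package was built for the population genetics of snow-algal ITS2
phylotypes — unique marker-sequence variants surveyed across the Antarctic,
the Arctic, and mid-latitude mountain regions — where one wants to know
whether globally distributed (cosmopolitan) variants and regionally
restricted (endemic) variants experienced distinct demographic histories,
and when the populations expanded. It is equally usable for any haploid
marker where pairwise difference counts carry the demographic signal.

## The model

A population had constant effective size *N*₀ until *t*₀ generations ago
and size *N*₁ since ("two-epoch" or sudden-expansion demography). The
coalescence time *s* of two random lineages then has a piecewise
exponential density

f(s) = (1/2N₁) e^(−s/2N₁)            for s < t₀,
f(s) = e^(−t₀/2N₁) (1/2N₀) e^(−(s−t₀)/2N₀)   for s ≥ t₀,

and, given *s*, the number of mismatched sites *K* between the two
sequences is Poisson with mean 2*u*s, where *u* is the per-sequence
per-generation mutation rate. In the mutation-scaled parameters
τ = 2*u*t₀, θ₀ = 2*N*₀*u*, θ₁ = 2*N*₁*u* the marginal distribution of *K*
has a closed form built from incomplete gamma functions,

P(K = k) = (θ₁/(1+θ₁))ᵏ (1+θ₁)⁻¹ (1/k!) γ(k+1, τ(1+1/θ₁))
         + (θ₀/(1+θ₀))ᵏ (1+θ₀)⁻¹ (1/k!) Γ(k+1, τ(1+1/θ₀)) e^(−τ(1/θ₁−1/θ₀)),

with γ and Γ the unregularised lower and upper incomplete gamma functions;
its mean is the classic E(K) = θ₁ + (θ₀ − θ₁) e^(−τ/θ₁). The parameters
are estimated by maximising a composite log-likelihood over ⌊n/2⌋ disjoint
random pairs of phylotypes (disjoint, to avoid dependence between pairs
that share lineages), with standard deviations from the inverse observed
Fisher information and an explicit diagnostic for flat likelihood ridges,
where a standard deviation is honestly reported as unavailable.

On top of the estimator the package provides:

* pooled-versus-per-subset model comparison by raw composite
  log-likelihood (`compare_models()`), the criterion used to decide
  whether cosmopolitans and endemics share one demographic history;
* conversion of (τ, θ₀, θ₁) to years and effective sizes
  (`convert_units()`), with worst-case propagation of the mutation-rate
  confidence interval and the generation-time range
  (`propagate_ranges()`);
* the cosmopolitan / multi-region / endemic distribution-type classifier
  (`classify_distribution()`) over Antarctic, Arctic (optionally Svalbard,
  Greenland, Alaska) and mid-latitude detections;
* a FASTA-to-mismatch-sample pipeline (`read_phylotype_alignment()`,
  `build_mismatch_sample()`, `mismatch_histogram()`) with explicit gap and
  ambiguity handling;
* a seeded two-epoch coalescent simulator (`simulate_mismatch_counts()`,
  `emit_sequence_pairs()`, `generate_phylotype_table()`), so every stage is
  testable without any sequencing data.

## Worked example

```r
library(snowcoal)

truth <- demography_params(tau = 5, theta0 = 0.5, theta1 = 10)
s     <- simulate_mismatch_counts(truth, n_pairs = 5000, seed = 42)
fit_demography(s)
#> Two-epoch demographic fit (5000 pairs)
#>   tau    = 5.082      (sd 0.252)
#>   theta0 = 0.4084     (sd 0.211)
#>   theta1 = 10.24      (sd 0.428)
#>   composite log-likelihood = -11826.2616
```

The fit recovers the generating parameters within about one standard
deviation each: an expansion τ ≈ 5 mutational units ago, from a small
ancestral population (θ₀ ≈ 0.4) to a ~25-fold larger current one
(θ₁ ≈ 10).

Converting a scaled estimate to natural units — here τ = 33.8,
θ₀ = 0.108, θ₁ = 0.217 with the default rate assumptions (2.08 × 10⁻¹⁰
per site per generation over 381 sites, 24-day generations):

```r
convert_units(demography_params(33.8, 0.108, 0.217), rate_assumptions())
#> Demography in natural units:
#>   expansion time: 2.1e+08 generations = 1.4e+07 years
#>   N0 = 680000, N1 = 1400000 (2-fold change)

propagate_ranges(tau = 33.8)$reported
#> $min_years 3.6e+06
#> $max_years 4e+07
```

That is: the expansion happened ~1.4 × 10⁷ years ago (between 3.6 × 10⁶
and 4.0 × 10⁷ years once the mutation-rate CI and the 11–36-day
generation-time range are propagated), from an ancestral effective size of
~6.8 × 10⁵ to ~1.4 × 10⁶.

A command-line front end mirroring these functions (subcommands
`simulate`, `mismatch`, `classify`, `fit`, `compare`, `convert`) is
installed at `system.file("exec", "snowcoal", package = "snowcoal")`.

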