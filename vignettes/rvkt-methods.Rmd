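---
title: "Screening quantitative traits for rare-variant signatures with pedigree kinship"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening quantitative traits for rare-variant signatures with pedigree kinship}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The idea

In a family-based study, a rare allele with a modest-to-large effect on a
quantitative trait is carried disproportionately by the phenotypically most
extreme individuals, and — because rare alleles are concentrated in the
families that segregate them — those extreme individuals tend to be close
relatives. A purely polygenic trait also clusters in families, but far more
weakly at a fixed tail size. The screen implemented here exploits this: for
each trait it computes the **mean pairwise kinship coefficient** among the
individuals in a tail of the trait distribution and asks whether that mean
is larger than expected under a purely polygenic model.

The kinship coefficient $\varphi_{ij}$ is the probability that an allele
drawn at random from individual $i$ and one drawn from $j$ at an autosomal
locus are identical by descent through the known pedigree. For a tail
$T$ with $|T| = k$ members the statistic is

$$ S(T) \;=\; \binom{k}{2}^{-1} \sum_{\{i<j\} \subset T} \varphi_{ij}. $$

Only pedigree structure and phenotypes enter — no genotypes — so the screen
can rank dozens of traits (and produce a candidate list of individuals)
*before* any sequencing is bought.

## Null model and empirical null distribution

The null hypothesis is that the trait is purely polygenic: many additive,
independent loci of small effect plus independent environment. Conditional
on the pedigrees, a polygenic trait with narrow-sense heritability $h^2$
has covariance $2\Phi h^2 + I(1-h^2)$ between standardized trait values,
where $\Phi$ is the kinship matrix. The distribution of $S$ under this
model has no usable closed form (tail membership is an order statistic of a
correlated vector, and $S$ is discrete), so the null is simulated:
`build_null()` draws `N_null` replicate traits on the actual pedigrees,
recomputes the statistic for every requested tail size and side, and the
resulting empirical distribution is the reference for p-values
(`empirical_pvalue()`, the raw exceedance proportion) and for rejection
thresholds.

Polygenic replicates are generated by recursive Mendelian sampling rather
than by a Cholesky factor of $2\Phi h^2$: founders receive additive values
$\mathcal{N}(0, h^2)$; a non-founder with parents $f, m$ receives the
mid-parent mean plus a Mendelian deviation
$\mathcal{N}\!\big(0, \tfrac{h^2}{2}\,(1 - \tfrac{F_f + F_m}{2})\big)$,
where $F_x = 2\varphi_{xx} - 1$ is the inbreeding coefficient; environment
$\mathcal{N}(0, 1-h^2)$ is added independently. This is $O(n)$ per
replicate, exact for inbred pedigrees, and its equivalence to the
multivariate-normal formulation is verified by a test (empirical covariance
against $2\Phi h^2$, including an inbred individual), not assumed.

### Discreteness and rejection regions

On simple pedigrees the statistic lives on a coarse lattice (for a cohort
of sibling pairs, multiples of $0.25/\binom{k}{2}$), so a test of size
exactly $\alpha$ usually does not exist. `rejection_threshold()` returns
the smallest realized null value whose exceedance probability does not
exceed $\alpha$ — the region with size as close to $\alpha$ as possible
without exceeding it — and, when even the largest realized value occurs too
often, an infeasibility report carrying the minimum achievable size.
`null_support_summary()` counts distinct values in the top of the null CDF
as a diagnostic of this discreteness. Two consequences worth knowing:
empirical p-values are conservative (stochastically larger than uniform),
and for small cohorts of close relatives a nominal $\alpha = 0.01$ test can
be impossible.

These discreteness diagnostics are themselves noisy functionals of a
1,000-replicate null: the count of distinct values in a top quintile and
the frequency of the largest realized value both hinge on whether one or
two rare lattice points (per-replicate probability of order $10^{-3}$)
happen to be drawn. Across seeds the distinct-value count for a
1%-tail nuclear-family null varies over 4–6, and the minimum achievable
size for a sibling-pair cohort alternates between the two-sib-pair
frequency (~0.02) and, when a three-pair replicate appears, its raw
frequency (~0.001). The acceptance script therefore reports the modal
distinct-value count over ten seeds, and documents the min-size quantity as
seed-sensitive.

## The screen

`rvkt_screen()` runs, per trait:

1. **Transform** — rank-based inverse normal with the Blom offset
   $(r - 3/8)/(n + 1/4)$, applied when a Shapiro–Wilk check at 0.01 rejects
   normality (`transform = "auto"`, the default; `"always"` and `"never"`
   are available). Because only ranks enter tail selection, the statistic
   itself is invariant to monotone transforms; the transform matters only
   when covariates are adjusted afterwards.
2. **Adjust** — OLS residuals on the declared covariates, re-standardized.
   The order (transform, then adjust) is fixed and logged per trait.
3. **Test** — both sides of the distribution at tail sizes 1, 2, 4, 6, 8%
   by default, against a polygenic null at the trait's $h^2$ (a maximum
   likelihood estimate from the data via `estimate_h2()`, unless the user
   supplies one). Tail counts are round-half-up of fraction × the
   *non-missing* sample size, never below 2; boundary ties are broken by
   individual id and flagged.
4. **Summarize** — the minimum p-value per trait ($p_{\min}$) over sides
   and tail sizes, Bonferroni-corrected by the effective number of tests
   among the (correlated) traits: from the eigenvalues $\lambda_i$ of the
   trait correlation matrix,
   $M_{\mathrm{eff}} = \sum_i \big[ \mathbb{1}(|\lambda_i| \ge 1) +
   (|\lambda_i| - \lfloor|\lambda_i|\rfloor) \big]$, used as its ceiling.

Deliberately, **no correction is applied across the tail sizes and sides
searched within a trait**; the printed report says so. This mirrors
standard practice for this screen but means $p_{\min}$ is optimistically
biased as a standalone p-value; the cross-trait correction partially
absorbs, but does not remove, that optimism.

Heritability enters only through the null simulation. The ML estimator
profiles the mean and scale out of the polygenic variance-component
likelihood on a grid over $h^2 \in [0, 0.99]$ with local refinement (one
eigendecomposition of $2\Phi$ makes each grid point $O(n)$); its
parameter-recovery behaviour (bias below 0.05 at 500 sibling-pair
families) is part of the test suite. Users who have an external estimate
should pass it via `h2 =` — the screen's operating characteristics are not
sensitive to small errors in $h^2$.

## The alternative model and power

`simulate_trait()` adds a single additive biallelic locus: founder alleles
are Bernoulli($q$), transmitted by gene dropping (`drop_rare_variant()`),
and the trait is

$$ y \;=\; \pm a\,(c - 2q) \;+\; g \;+\; e, \qquad
   a = \sqrt{v / (2q(1-q))}, $$

with $c$ the copy count, $g$ residual polygenic with variance $h^2 - v$,
and $e$ environmental with variance $1 - h^2$, so the locus explains a
fraction $v$ of total variance under Hardy–Weinberg proportions and total
variance is 1 in expectation. Mean-centering the variant term does not
affect tail membership (ranks again) and keeps the variance bookkeeping
exact. `v_genetic` is accepted as an alternative parameterization
($v = v_\text{genetic} \cdot h^2$).

`estimate_power()` builds one null per (cohort, $h^2$), fixes per-tail
rejection thresholds at size $\le \alpha$, simulates `N_alt` replicates
under the alternative, and reports per tail: power, Monte-Carlo standard
error, achieved size, and the mean fraction of tail members carrying the
allele. Power is evaluated on the side matching the variant's direction
only; an applied screen always tests both sides. Power is expected to peak
when the tail size matches the carrier frequency
$2q(1-q) + q^2$ (`optimal_tail_fraction()`).

## What the synthetic cohorts do and do not emulate

`make_nuclear_families()` (two founder parents, two full sibs, all study
subjects) and `make_sibpair_families()` (sib pairs as study subjects,
parents as connectors) reproduce the two reference cohort designs used
throughout the tests: 371 nuclear families (1,484 individuals) and 741
sibling pairs (1,482 study subjects), with heritability 0.4 and variant
frequencies in the 0.5–4% range as the default study conditions. They are
deliberately idealized: disconnected families, no inbreeding, no
missingness, Hardy–Weinberg founders, a single biallelic locus, no
dominance, no shared-household environment, and no ascertainment. Passing
tests on these cohorts validates the machinery and its calibration; it
does not certify behaviour on deep, loopy real pedigrees (supported by the
code — the kinship recursion and Mendelian sampling are exact for them —
but not verified against any external reference here), nor robustness to
phenotyping artifacts.

## Numerical and design choices

- **Tail-count rule.** Round-half-up reproduces the canonical grid
  15/30/59/89/118 for 1,481 subjects at 1–8%. Published per-trait counts
  are not always consistent with any single rule (trait-specific
  missingness in the source data is the likely cause), so resolved counts
  are surfaced in every output rather than guessed.
- **Seeding.** Replicates are generated batch-wise from one seed with a
  fixed internal chunk size (memory control), so a run is reproducible as
  a whole; individual replicates are not separately re-derivable. All
  entry points take explicit seeds and record them in outputs.
- **Null caching.** Within a screen, nulls are cached in memory keyed by
  ($h^2$ rounded to 3 decimals, the trait's non-missing subject set);
  traits sharing both reuse one null. Nulls are rebuilt across runs —
  desk-scale cohorts rebuild in seconds, and no on-disk cache format has
  to be versioned.
- **Floating point.** Kinship values on pedigrees are dyadic rationals and
  sums of them are exact in doubles, but distinct-value counting and
  threshold selection still round to 12 significant digits, and exceedance
  comparisons use a $10^{-12}$ slack, to be safe under reordered
  summation.
- **Degenerate inputs.** Constant traits error in the transform; traits
  that are exact functions of covariates error after adjustment;
  all-identical trait values in tail selection fall back to id order with
  a warning; an infeasible rejection region is a report, not an exception.
- **Problem sizes.** The test suite runs the full-scale power experiment
  (10,000 null / 1,000 alternative replicates on 1,484 individuals) in
  well under a minute; property tests use $10^5$ replicate draws for
  moment checks and $10^5$ gene drops for the kinship oracle. These sizes
  give Monte-Carlo standard errors comfortably below the tolerances
  asserted.

## Known limitations

- The screen's power claim rests on within-family allelic homogeneity;
  many independent rare alleles spread across families dilute the
  kinship signal.
- $p_{\min}$ is not corrected for the within-trait search (above).
- The heritability estimator is a single-variance-component ML fit: no
  shared environment, no dominance, no covariate-by-strata interactions;
  its likelihood-ratio against $h^2 = 0$ is reported as a diagnostic only.
- X-linked kinship, identity coefficients beyond kinship, pedigree
  trimming and pedigree drawing are out of scope; inputs are assumed
  already trimmed to tractable families, and each family must be
  self-contained (cross-family parent references are rejected).
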