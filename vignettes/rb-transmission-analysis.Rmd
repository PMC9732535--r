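---
title: "Testing meiotic drive in multiple-Rb heterozygotes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing meiotic drive in multiple-Rb heterozygotes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbdrive)
```

## The question and the null model

Robertsonian (Rb) fusions join two telocentric chromosomes into one
metacentric, reducing the diploid number by one per fusion. In a
heterozygote carrying *n* fusions, meiosis I forms *n* trivalents — each
metacentric synapsed with its two homologous telocentrics — and each
trivalent transmits either the metacentric or both telocentrics to a
gamete. If segregation is Mendelian and trivalents are independent, the
number of Rb chromosomes an offspring inherits is Binomial(*n*, 0.5).
Meiotic drive — preferential retention of one chromosomal form, e.g. in
the egg rather than the polar body — would shift per-trivalent
transmission away from 0.5; other mechanisms (class-dependent embryonic
viability, segregation errors) can distort the *shape* of the offspring
distribution while leaving its mean near Mendelian.

`rbdrive` separates these questions. For a `segregation_model(n, p)` with
per-trivalent transmission probabilities `p`, `transmission_pmf()` gives
the exact Poisson-binomial distribution of the inherited count, computed
by iterative convolution: start from the point mass at zero and fold in
one Bernoulli(`p[i]`) at a time. This is exact in O(n²) arithmetic,
reduces to the binomial when `p` is homogeneous, and is preferred over
sampling or characteristic-function methods because *n* is small (8
here) and tests demand 1e-12 agreement with exhaustive enumeration.

```{r}
model <- segregation_model(8, 0.5)
round_half_up(100 * transmission_pmf(model), 2)
```

Percent tables use half-up rounding at 2 decimals (so 21.875 prints as
21.88), matching the convention of published karyotype tables and making
printed output byte-stable.

## The data and its contracts

An offspring table has one row per animal: heterozygous-parent sex,
inherited Rb count, diploid number, and optionally the 10 per-plate
counts it was called from. Two consistency rules are enforced at read
time. First, in this cross design `diploid_n = telocentric_base -
rb_count` with `telocentric_base = 40` (a parameter, so other cross
designs are supported). Second, an animal's karyotype is the *mode* of
its plate counts; a tie is an `rb_ambiguous_karyotype` error, never a
silent tie-break — a fabricated karyotype is worse than a missing one.

The packaged `offspring_counts.tsv` carries 139 offspring of reciprocal
crosses between 8-fusion heterozygotes and all-telocentric homozygotes;
`pericentromere_summary.tsv` carries per-animal mean CL/TL percentages
for one father–six-sons family. The measurement-level data behind those
means were never published, so raw-level behaviour is exercised through
the simulator instead. Two documented quirks of the published summaries:
the printed expected-frequency column for the female cohort is consistent
with N = 84 rather than the stated N = 83 (this package always computes
expectations from the exact N, e.g. 83 × 70/256 = 22.695 at k = 4, and
both choices round to the same test conclusion); and one descendant's
mean appears as 25.61 in one published table and 26.61 in another — the
fixture carries 25.61, and the exceedance count is 5 of 6 either way.

## Goodness-of-fit: asymptotic fidelity vs defensible defaults

`gof_test()` compares observed counts with Poisson-binomial expectations.
The `asymptotic` method is the classical chi-square with df = bins − 1
and **no pooling** by default, reproducing the convention of published
segregation analyses — even though tail expectations under Binomial(8,
0.5) are far below 5 at these cohort sizes (0.32 offspring at k = 0 for
N = 83), where the chi-square approximation is rough. Two statistically
defensible alternatives are built in and reported with a method tag so a
reader always knows which computation produced which p-value:

* `pool_below = x` merges tail bins inward until every retained bin's
  expected count reaches `x`, reducing df accordingly;
* `method = "monte_carlo"` draws resampled cohorts as multinomial(N, pmf)
  and uses the add-one estimator p = (1 + b)/(1 + B), which is never
  exactly zero and is exact-in-expectation regardless of expected counts.

```{r}
off <- rb_example_offspring()
fem <- observed_distribution(off, "female")
gof_test(fem, model)
gof_test(fem, model, pool_below = 5)
```

With a seed, Monte-Carlo p-values are bit-reproducible; the package-wide
seeding rule is R's Mersenne-Twister with inversion normals, applied via
an internal helper that restores the caller's RNG state.

`dispersion_test()` addresses a subtler question: the female cohort's
mean (3.08 of 8, 38.6%) is *below* one half, so its non-binomial fit is
not drive toward fixation — the distortion is in spread. The statistic
var(k) / (n·p̂·(1−p̂)) compares observed variance with the binomial
variance at the fitted mean; its two-sided p comes from a parametric
bootstrap under Binomial(n, p̂) with each resample refitted.

## Proportion machinery

`proportion_test()` implements the score z-test without continuity
correction (the default, because it reproduces the published convention
for the exceedance analysis: 5/6 vs 0.5 gives z = 1.633, one-sided
p = 0.0512) and the exact binomial tail as an alternative (same data:
7/64 = 0.1094). Two-sided p-values are defined as twice the smaller
one-sided tail, capped at 1 — a documented convention, chosen for
coherence between one- and two-sided reports. Every result carries a
two-sided 95% Wilson score interval, preferred over Wald for its
behaviour at small n and near-boundary proportions.

`estimate_transmission()` treats all n·N trivalent segregations in a
cohort as independent Bernoulli trials (256/664 = 0.386 for the female
cohort). That independence assumption — across trivalents *and* across
littermates — is flagged on the result: littermate correlation would
shrink the effective trial count and make intervals anticonservative.
`compare_transmission()` is the pooled two-proportion z-test on the same
aggregation; on the packaged data it gives z = −4.07 (female minus male),
two-sided p < 0.0001.

## What the simulator emulates, and what it does not

`simulate_offspring()` draws each offspring's Rb count from a
distribution proportional to PoissonBinomial(k; drive) × viability[k]:

* **drive** acts per trivalent at gamete formation;
* **viability** acts on the offspring's count class k — the minimal
  mechanism that reproduces the observed pattern of shape distortion
  with a near-Mendelian mean. Per-gamete or time-structured lethality is
  deliberately out of scope.

These two knobs are not identifiable from count data alone — a fact the
inference module makes no attempt to hide; the simulator exposes both so
users can see that different mechanisms produce the same likelihood.

Litters are zero-truncated Poisson (defaults: 83 offspring averaging 4.4
per litter for a female heterozygous parent, matching the emulated
experiment's design; the male cohort used 56 and 5.5). Litter ids are
generated but *not* used in inference, matching the pooled published
analysis; they exist so future litter-effect models have honest data.
Plate counts are `n_plates` copies of the true count with an optional
per-plate miscount probability (default 0).

`simulate_measurements()` emulates the morphometry design: a lognormal
per-plate compaction factor (cv = `compaction_cv`, default 0.3) scales
all lengths of a plate jointly; independent lognormal measurement noise
(cv = `measurement_cv`, default 0.05) then perturbs each chromatid and
the pericentromeric length. Because CL/TL×100 divides lengths from the
same chromosome, the ratio is exactly invariant to compaction — the
design rationale for the metric — and measurement noise induces only a
small positive bias, below 0.5·cv²·ratio, from noise in the denominator.
TL is defined as the *mean* of the two chromatid lengths (not the sum):
the packaged per-animal ratios of 21–26% are on that scale.

What passing simulator-based tests does **not** show about real data:
real plates have correlated miscounts, real litters share viability
environments, real chromosome measurements have segmentation artefacts
and operator effects, and real trivalents may interact (interchromosomal
effects). The simulator certifies the statistical machinery, not the
biology.

## Numerical and design choices

* Convolution accumulates at most n = 8–12 products of probabilities;
  error stays below 1e-12 against exhaustive 2ⁿ enumeration (tested).
* Expected-count sums are exact to 1e-9; a zero-expectation bin with a
  nonzero observation yields an infinite statistic (p = 0) rather than
  NaN.
* Exceedance uses strict inequality (an exactly-equal descendant does
  not count), the comparison implied by a binary greater-than column.
* Degenerate inputs fail loudly: empty cohorts for means/fractions,
  all-one-class cohorts for the dispersion statistic, modal ties for
  karyotype calls, all-zero viability masks.
* Problem sizes used by the validation suite were chosen to certify the
  claims at desk scale: type-I calibration over 2000 null cohorts of
  N = 56 with 1999 resamples each (p-granularity 1/2000), drive recovery
  at 200 replicates of N = 500, power of the viability alternative at
  500 replicates of N = 83.

## Known limitations

Counts collapse all eight metacentrics into one number, so per-chromosome
transmission cannot be tested; litter random effects are generated but
not modelled; gametic drive and post-zygotic viability selection are not
separable from these data; and the unpooled df = 8 chi-square is reported
for fidelity to the published convention despite its tail-bin fragility —
use `pool_below` or Monte-Carlo p-values for new analyses.
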