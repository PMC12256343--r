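---
title: "Scoring freshwater pesticide contamination, regulation and risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring freshwater pesticide contamination, regulation and risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestscore)
```

## Why a deviation score

Comparing pesticide pollution across countries with indices anchored to
safety thresholds (pollution indices, health-risk indices) fails for the
many compounds that have no agreed threshold. The score used here needs
only concentrations: each country (or region) is scored by how far its
site-level log10 concentrations sit from each pesticide's global central
tendency. The score is *relative* — it ranks countries against the current
global state of monitoring, it does not measure absolute risk.

## The contamination model

One observation is a site-level mean concentration of one pesticide in one
water body (surface or ground). Observations are log10-transformed;
environmental concentration data are heavy-tailed and closer to log-normal,
and the log scale makes "orders of magnitude above the global level" an
additive quantity.

For pesticide $n$, the global central tendency $\bar{L}_n$ is the flat mean
of log10 values over every site worldwide that reports it — each site
counts once, so well-monitored countries influence $\bar{L}_n$ in
proportion to their sites. A group's score is

$$S \;=\; \frac{1}{M}\sum_{m=1}^{M}\;\frac{1}{N_m}\sum_{n=1}^{N_m}
\left(\log_{10} C_{n,m} - \bar{L}_n\right)$$

with $M$ the group's sites and $N_m$ the pesticides usable at site $m$.

Decisions worth knowing about:

* **Per-site $N$.** Monitoring panels are heterogeneous; taking $N$
  per-site (rather than a fixed global panel) is the only reading that
  tolerates sites reporting different pesticide sets. A site's value is
  the mean deviation over whatever it reports.
* **Non-detects** enter at $\log_{10}(\mathrm{LOD})$, or
  $\log_{10}(\mathrm{LOQ})$ when no LOD is reported; non-detects carrying
  neither are excluded record-wise (the rest of the site is kept).
  This substitution biases censored values upward — a conservative choice
  shared by the deviation-score literature — and is exercised explicitly by
  the synthetic generator's censoring switch.
* **Duplicates.** Several rows for the same (site, pesticide) pair are
  collapsed to their geometric mean (detected rows win over duplicate
  non-detects), since the score operates on log10 values.
* **Sparse pesticides.** A pesticide reported at a single site contributes
  deviation zero there (its tendency equals itself); it is retained by
  default, with `min_sites` available to screen such terms out.
* **Bands.** $S \le 0$: at or below the global level; $0 < S < 2$: slightly
  higher; $S \ge 2$: orders of magnitude higher. The breakpoints sit
  exactly at 0 and 2 and are a step function of $S$ alone.
* **Regional transition.** `score_all(grouping = "region")` rescores
  admin-1 regions, by default against their own country's central
  tendencies (internal pollution pattern); a global reference is a flag
  away. Within a country, site-weighted regional scores then conserve
  to zero.

Scores are reported at full precision; round to two decimals only for
display.

## Bootstrap uncertainty

`bootstrap_score()` resamples a group's $M$ sites with replacement $B$
times (default $B = 1000$) and reports the percentile interval of the
replicate scores at the requested level (default 95%). The site is the
resampling unit because it is the score's atomic observation. Global
central tendencies are held fixed at their full-data values by default:
the interval then isolates within-group sampling variability, which is the
question the resampling answers; `recompute_ct = TRUE` rebuilds the
reference from each replicate for sensitivity analysis. BCa, jackknife and
studentized intervals are deliberately out of scope. With $M = 1$ the
bootstrap refuses rather than fabricating a zero-width interval.

## Regulation scores

Over a fixed panel (30 pesticides by convention, supplied as data since
panel membership is a curation decision):

* **CS** counts panel pesticides with any standard — coverage, not
  stringency.
* **NS₁** sums, over regulated pesticides, the probability that a standard
  drawn from the fitted log-normal cross-jurisdiction distribution exceeds
  the jurisdiction's own; it presumes log-normality, so
  `regulation_scores()` runs a per-pesticide Shapiro–Wilk screen on the
  log10 values and flags `ns1_valid = FALSE` when any tested pesticide
  rejects at 0.05. (Per-pesticide is the defensible granularity — pooling
  mixes scales; a pooled test remains available.)
* **NS₂** sums the min–max relative position of the log10 standard, 1 at
  the world's strictest value, 0 at the laxest, clamped to [0, 1]. When all
  jurisdictions share one value the term is set to the neutral 0.5 with a
  warning: dropping it would silently change the score's ceiling.
* **NS₃** is the mean log10 deviation from the global mean standard; lower
  is stricter.

When a jurisdiction maintains several standards systems for a medium, only
the most conservative enters: systems are compared by mean log10 value over
the pesticides common to all of them (each system's own rows when none are
shared), with a lexical tie-break for determinism. Selection runs *before*
bloc expansion (EU members inherit bloc rows only for pesticides they do
not regulate nationally), so inherited rows never compete with national
systems. The jurisdiction being scored is included in the global statistics
— the definitions contain no leave-one-out.

## Usage intensity, hazard quotients, exceedance

**PUI** is the mean over available years (2010–2021 by default) of annual
pesticide tonnes per km² of agricultural land. Years missing either
quantity are dropped and the mean renormalizes over the years present;
imputing zeros would understate intensity. FAOSTAT-style hectare inputs are
converted at read time.

**Hazard quotients** use the chronic drinking-water ingestion form
$\mathrm{CDI} = C \cdot \mathrm{IR} \cdot \mathrm{EF} \cdot \mathrm{ED} /
(\mathrm{BW} \cdot \mathrm{AT})$ (concentration internally converted
µg/L → mg/L), divided by the oral reference dose. Defaults are the standard
adult residential set — 2 L/day, 70 kg, 350 days/year, 30 years, AT = ED ×
365 — and are configurable because agencies differ. Screening is restricted
to groups whose contamination score exceeds 2 (the "orders of magnitude
above" band), and uses the maximum detected site mean per pesticide by
default (`statistic = "mean"` available): screening asks about the worst
documented exposure.

**Exceedance rates** compare records of five commonly detected and
regulated pesticides (aldrin, dieldrin, 2,4-D, heptachlor, lindane; CAS in
`drinking_water_panel()`) against national drinking-water standards, with
the WHO guideline as fallback. Comparison is strict (equal to the standard
does not exceed). Non-detects count in the denominator as non-exceeding —
unless their reporting limit itself exceeds the standard, in which case the
record answers neither way and is excluded as indeterminate. Countries
lacking both standards are excluded per pesticide and reported. The global
row pools included countries, so it equals the record-count-weighted mean
of country rates. An `exclude` argument supports dropping countries (e.g.
EU members, whose drinking water is treated rather than drawn raw).

## Association between score sets

`rank_difference()` ranks both sets from high to low (average ranks on
ties) over the groups present in both and maps the absolute difference;
`associate_scores()` adds Spearman's correlation (exact permutation p-value
for $n \le 9$, asymptotic otherwise, two-sided) and a simple OLS regression
of the second set on the first. Significance labels (p < 0.1 for
correlation, p < 0.05 for the slope) are attached, not enforced. Which
groups count as having "sufficient and balanced" sampling is a judgment
call; the functions take an explicit subset rather than inventing a
heuristic.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws site-level log10 concentrations from
$\mathcal{N}(\mu_n + \delta_j, \sigma_n)$: pesticide baselines $\mu_n$,
country offsets $\delta_j$, residual spread $\sigma_n$. Sites may skip
pesticides (`panel_coverage`) and the low tail of each distribution can be
reported as non-detects at a stated LOD (`censor_quantile`, which is
exactly the expected censored fraction). The defaults — five countries of
30 sites with offsets spanning ±1 log10 unit, five pesticides with
baselines from $10^{-1}$ to $10^{-3}$ µg/L and $\sigma = 0.3$ — describe a
modest, well-behaved monitoring network: 30 sites is a realistic national
campaign, ±1 offsets mirror the order-of-magnitude spread seen between
high- and low-scoring countries, and $\sigma = 0.3$ (a factor of 2 either
way) is typical within-country variability for site means.

Under full coverage and no censoring the expected score has the closed
form $\mathbb{E}[S_j] = \delta_j - \sum_k w_k \delta_k$ ($w_k$ = site
share), which `expected_scores()` returns and the test-suite uses for
recovery and coverage checks. The generator does **not** emulate spatial
clustering of sites, temporal trends, correlated pesticide panels,
laboratory-specific LODs or reporting heterogeneity — so passing recovery
tests demonstrates the estimator's correctness under the model's own
assumptions, not robustness to unbalanced real-world monitoring (the
score's main practical caveat).

`generate_wqs()` and `generate_usage()` provide matching standards and
usage tables (log-normal standards with configurable spread; noisy constant
intensities) to exercise the regulation and usage paths end to end.

## Numerical choices and degenerate inputs

* Detected records must have positive concentration; a non-positive detect
  is an error, never silently logged.
* A group with no usable site yields *no* score, not zero.
* Quantiles for bootstrap intervals use the R default (type 7).
* Bootstrap and generators save and restore the global RNG state; the same
  seed gives byte-identical output and an unseeded caller's stream is
  untouched.
* CAS numbers are check-digit validated; failures warn but keep the record
  (a typo in an identifier should not drop a measurement).
* Unknown units reject the row with a named reason; accepted units are
  µg/L, mg/L, ng/L, g/L, ppb (≡ µg/L) and ppm (≡ mg/L, density 1).

## Validation problem sizes

The shipped checks use 200 generator replicates of the default
configuration for estimator recovery (each country's mean estimate within
3 Monte-Carlo standard errors of its analytic expectation), and 300
datasets × 200 bootstrap replicates for interval coverage (observed
coverage within 95% ± 3%). These sizes give Monte-Carlo noise comfortably
below the tolerances they are compared against while keeping a full test
run under a minute for the stochastic parts.

## Limitations

* The score inherits the representativeness of the monitoring data;
  countries with two sites get a score, and the site count is reported
  precisely so readers can discount it.
* LOD substitution biases censored records upward; heavily censored
  datasets drift toward their reporting limits.
* Regulation scores measure what standards *say*, not how they are
  enforced.
* The hazard quotient covers chronic oral ingestion only — no dermal or
  inhalation routes, no carcinogenic slope factors, no mixtures.
* Usage intensity ignores crop structure and pesticide class.
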