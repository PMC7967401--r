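---
title: "Methods: benchmark anchoring, trend and seasonality of search interest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmark anchoring, trend and seasonality of search interest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skintrends)
```

## The problem

Google Trends reports search interest as a *relative search volume* (RSV):
an index from 0 to 100 where 100 marks the most popular month (or country)
of the queried set, not an absolute query count. Two consequences shape
everything in this package:

* RSV from different single-topic exports is **not comparable across
  topics** — each export has its own hidden scale.
* Values below 1% of the maximum are **censored** to the token `"<1"`, and
  regions with too little volume are masked entirely.

`skintrends` implements a complete analysis pipeline for a multi-topic
infodemiology study of dermatologic clinical signs (itch, hair loss, skin
rash, perspiration, and thirty others) under these constraints: cross-topic
popularity via benchmark anchoring, secular trends via the Seasonal
Mann–Kendall test and an OLS slope, and seasonality via an additive
decomposition with a periodic seasonal component. A seeded synthetic-data
generator reproduces the whole observation process with known ground truth,
so every stage is testable without any network access.

## Censored-value imputation

Before any statistic, raw tokens are made numeric: `"<1"` becomes **0.5**
(the centre of the censored interval) and `"0"` becomes **0.1** (a small
positive floor so ratios stay defined). The mapping preserves the token
order numerically: $0.1 < 0.5 < 1 \le$ any uncensored integer. The same
rule is applied to region-share tables; this choice is recorded in the
pipeline metadata. Imputation always happens after parsing and before
anchoring or inference.

## Benchmark anchoring

All topics are placed on one scale by comparing each against a fixed
reference topic (`scar` in the default registry — chosen because it has
measurable volume essentially everywhere, so the anchor exists in every
analyzable country).

**Time mode.** For a jointly scaled two-query export with imputed series
$x_t$ (topic) and $r_t$ (reference), the adjusted proportion is the ratio
of means over the whole period,

$$\hat\rho = \frac{\bar x}{\bar r}.$$

The joint export guarantees a common scale factor, which cancels in the
ratio, so $\hat\rho$ estimates the ratio of mean latent search volumes.
The ratio of means (rather than the mean of monthly ratios) is robust to
censored months: a censored month contributes a small bounded term to the
numerator instead of an ill-conditioned monthly quotient. The reference's
own row is emitted as exactly 1.00 by definition, not recomputed.

**Region mode.** The compared-breakdown export gives per-country shares
summing to 100. Rescaling each country so the reference sits at 50,

$$\text{RSV}_c = 50 \cdot \frac{s_{c,\text{topic}}}{s_{c,\text{ref}}},$$

makes countries comparable. Imputation guarantees the denominator is at
least 0.1. Countries are ranked by this anchored value; ties are broken by
registry order (and flagged), and the reference participates at 50.

**Exclusion rule.** A country is excluded when fewer than five topics have
a non-adjusted regional RSV above zero there (censored `"<1"` counts as
above zero). The boundary is strict: exactly five positive topics is
included. Masked countries are carried explicitly with a reason rather
than dropped, so exclusions remain auditable.

## Secular trend

**Seasonal Mann–Kendall.** For monthly data the seasons are the twelve
calendar months, so values are only compared with the same month of other
years — the seasonal cycle cannot masquerade as a trend. Within season $g$
with $n_g$ values ordered by year,

$$S_g = \sum_{i<j}\operatorname{sgn}(x_{g,j}-x_{g,i}), \qquad
\operatorname{Var}(S_g)=\frac{n_g(n_g-1)(2n_g+5)-\sum_k t_k(t_k-1)(2t_k+5)}{18},$$

with $t_k$ the tied-group sizes inside the season. Seasons are treated as
independent: $S=\sum_g S_g$, $\operatorname{Var}(S)=\sum_g
\operatorname{Var}(S_g)$. The normal approximation uses the continuity
correction $Z=(S\mp 1)/\sqrt{\operatorname{Var}(S)}$ and a two-sided
p-value; $\tau = S / \sum_g \binom{n_g}{2}$ uses the tie-unadjusted pair
count. The Hirsch–Slack between-season covariance correction for serial
dependence is deliberately not applied; it is a documented extension. The
test needs at least two complete cycles (one comparable pair per season).
If every season is fully tied the result is flagged degenerate with
$Z = 0$, $p = 1$.

**Slope.** The trend magnitude is an ordinary least-squares slope of RSV
on time in fractional years (month index / 12), so the coefficient reads
directly in RSV/year, with the standard t-test. Reports mark the slope
"n/a" when the Mann–Kendall test is not significant at the configured
level, matching the conditional-reporting convention; the sign-based test
decides presence, the regression quantifies magnitude.

## Seasonal decomposition

The additive split $x_t = T_t + S_t + R_t$ uses a **periodic seasonal
component**: one fixed value per calendar month, the form in which
per-topic seasonal summaries (peak month, trough month, amplitude) are
reported. The scheme alternates:

1. estimate the trend $T$ by a Loess fit to the series;
2. set the monthly component $m_j$ to the mean of the detrended values of
   calendar month $j$, centred so $\sum_j m_j = 0$;
3. re-estimate the trend on the deseasonalized series $x - S$; repeat.

The remainder is defined as $R = x - T - S$, so the additive identity
holds to machine precision on every input, and centring makes the monthly
components sum to zero by construction. The iteration has an exact fixed
point on noise-free trend-plus-periodic inputs and converges geometrically
(contraction ratio roughly 0.1 at default spans), so the default runs to
convergence (sup-norm change below 1e-10, at most 30 passes — typically
fewer than ten); a fixed pass count is available via `n_iterations`.

The Loess smoother is a direct implementation of local polynomial
regression: at each point, a weighted constant or linear fit over the
$q=\max(\text{degree}+1,\lceil \text{span}\cdot n\rceil)$ nearest
neighbours with tricube weights $w=(1-(d/d_{\max})^3)^3$. A local *linear*
fit reproduces straight lines exactly, which is what makes the
amplitude invariant (up to a small drift, bounded at 0.5 RSV in the
property tests) to any added linear trend. The default trend span is
$\max(0.2,\ 1.5\cdot\text{period}/n)$ — about 38 of 192 monthly points,
wide enough to not chase the seasonal cycle, narrow enough to follow a
changing secular trend; both the span and the iteration count are exposed.

**Summaries.** Amplitude is the maximum minus the minimum of the twelve
monthly components; peak/trough months are the argmax/argmin, with ties
resolved to the earliest calendar month and flagged. An all-zero (below
1e-9) component set is flagged degenerate.

**Seasonality presence.** Where forecasting studies often rely on a
state-space model (e.g. TBATS) merely to declare whether a 12-month
seasonal component exists, this package uses a transparent
harmonic-regression F-test: nested OLS fits of the series on a linear
trend alone versus trend plus the first two Fourier harmonics of the
annual period. Two harmonics capture the asymmetric single-peak annual
shapes seen in search data while keeping the null distribution exact under
iid Gaussian errors; the substitute is recorded in the pipeline metadata.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline's statistical guarantees are demonstrated.

**Latent model.** Each topic's search intensity on its own RSV-like scale
is

$$x_t = \max\!\big(\varepsilon,\ b + \beta\,t/12 + m_{\text{month}(t)} +
\delta\,\mathbf{1}[\text{Dec}] + \epsilon_t\big),
\qquad \epsilon_t \sim N(0, \sigma^2),$$

with baseline $b$, slope $\beta$ (RSV/year), a centred 12-month pattern
$m$, an optional December dip $\delta \le 0$, and iid Gaussian noise from
a seeded Mersenne–Twister stream (integer state, bit-identical across
platforms).

**Observation transform.** A single-topic export rescales by
$100/\max(x)$ and quantizes: integer rounding, `"<1"` for nonzero values
rounding below 1, `"0"` for exact zeros. A two-query export applies one
common factor $100/\max(x, r)$ to both series. Region exports emit
integer shares summing to 100 and masked rows for countries below a
volume threshold.

**Volume scaling for comparisons.** In pairwise mode a topic's series is
its noisy profile multiplied by its latent volume
($\rho \cdot 60/\overline{\text{profile}}$, with $\rho$ the popularity
ratio). Multiplying the *whole* profile — rather than shifting only the
baseline — is a deliberate design choice: it makes the ratio of mean
intensities exactly $\rho$ for the noise-free series, so the anchoring
estimand coincides with the generator parameter, and it makes noise scale
with volume, as relative sampling noise does. The single-topic transform
is scale-invariant, so volume never affects non-adjusted series.

**Ground truth on the observed scale.** The max-100 rescaling is part of
the observation process, so the generator reports each realized factor
$100/\max(x)$; the true slope and amplitude *in observed RSV units* are
the latent values times this factor. Recovery tests compare against these
observed-scale truths.

**Presets.** `study` encodes the study conditions: 34 dermatology
topics with popularity ratios spanning 0.01–2.21, positive slopes of
0.47–5.15 RSV/year, and warm-month-peaked seasonal patterns (December
troughs for most topics) built by cosine-arc interpolation through each
topic's preset peak and trough components — so the December holiday
lull is already part of each pattern and the separate `december_dip` knob
defaults to 0. `hair_loss` is the one aseasonal topic. Baselines are set
so each deterministic profile peaks at 100. `null` removes all trend and
seasonality (calibration runs); `southern` phase-shifts every pattern by
six months (opposite-hemisphere sensitivity analysis). The observation
noise default is $\sigma = 2$ RSV; 72 countries receive lognormal volumes
(about a tenth fall below the masking threshold), per-country topic
weights are $\rho \times$ volume $\times$ lognormal taste noise (sd 0.35
on the log scale), and rare topics are stochastically absent in small
countries, which is what exercises the five-topic exclusion rule.

**What the generator does *not* emulate**, and hence what passing tests do
not establish about real exports: Google's sampling jitter across repeated
downloads of the same query, autocorrelated or heavy-tailed noise,
abrupt news-driven interest spikes (such as a single anomalous month in an
otherwise aseasonal series), weekly granularity, and query-language
effects. Conclusions about those failure modes need real data.

## Numerical choices and degenerate inputs

* Month arithmetic uses `"YYYY-MM"` strings with a linear index; exports
  with day components (weekly data) are rejected rather than resampled.
* Equal anchored values are ranked by registry order and flagged as ties;
  a country where every topic ties is flagged degenerate.
* Zero Mann–Kendall variance (all seasons fully tied), all-zero monthly
  components, and all-zero latent series are explicit degenerate or error
  cases, not silent results.
* The imputed-scale ceiling tolerates float jitter of $10^{-6}$ at 100
  (from `100 * x / max(x)`).
* Report tables round to 2 decimals; machine-readable JSON mirrors keep
  full precision.

## Problem sizes in the test suite

The checks run at the study's native scale where that is cheap and at
reduced scale elsewhere: brute-force Mann–Kendall verification uses 200
random series of up to 24 points; null calibration uses 2,000 white-noise
series of 16 years × 12 months; recovery uses the full 34-topic,
192-month, 72-country world over 20 seeds; pipeline integration tests use
4-year worlds.

## Known limitations

* The amplitude estimator (max minus min of twelve noisy month means)
  carries a small-sample upward bias of order the extreme-value mean of
  the month-mean noise; at the default noise it is worth roughly +0.3–0.4
  RSV, which is negligible for large-amplitude topics but approaches 10%
  of the smallest fixture amplitudes (about 4.5 RSV). Recovery is
  therefore assessed on mean recovered amplitude across replicates.
* The Seasonal Mann–Kendall variance assumes independent seasons; monthly
  search series with strong serial dependence would need the
  between-season covariance correction, which is not implemented.
* Proportions for very rare topics (true ratio at or below about 0.01)
  are compressed by censoring: most of their pairwise series sits below
  the 1% censoring floor, and the 0.5 imputation dominates the numerator.
* The registry resolves a source-catalogue ambiguity (one topic listed
  twice with conflicting values) by carrying the topic once; the
  simulator uses the value consistent with that topic's reported
  country-level popularity.

## A worked run

```{r, eval = FALSE}
w <- make_world_fixture("study", seed = 42)
dir <- file.path(tempdir(), "study")
simulate_world_csvs(w, dir)
res <- run_pipeline(analysis_config(dir))
head(res$proportion_table)
res$trend_table[res$trend_table$topic_id == "cellulite", ]
table(res$country_table$winner)
```

The popularity table tops out with itch (estimated proportion about 2.21
against the reference's exact 1.00), every topic shows a significant
rising trend, and the seasonal table recovers May peaks and December
troughs where the generator put them.
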