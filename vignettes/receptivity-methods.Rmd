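---
title: "Estimating receptive exposure to news on social media: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating receptive exposure to news on social media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(receptr)
```

`receptr` estimates, per news article, the number of social-media users who
are both *exposed* to the article and *receptive* to believing it, and
simulates how platform interventions change that number as a function of
deployment delay. This vignette documents the models, the parameters that
matter, the synthetic data the tests run on, and the numerical and design
choices behind the implementation.

## 1. The estimand

For article $j$, let $x_{ij}$ be the number of unique users in ideology
category $i$ who were exposed, and $p_{ij}$ the proportion of surveyed
respondents in category $i$ who rated the article "true". The receptive
exposure is the expected count

$$ r_j = \sum_i x_{ij}\, p_{ij}. $$

Receptivity is an expectation over a population, not a causal claim about any
individual: $p_{ij}$ is measured on survey panels that never overlap the
platform users entering $x_{ij}$, and the only bridge between the two data
sources is the seven-category ideology scale. `estimate_receptivity()`
computes $r_j$ exactly (real-valued); a Bernoulli-realised integer count is
deliberately not the default because the expected value is the estimand the
downstream comparisons use.

The continuous ideology scale (negative = left-leaning) maps onto the seven
survey categories through fixed, evenly sized, left-open/right-closed bins:
Moderate is $(-0.5, 0.5]$, each neighbouring category spans one unit, scores
above $2.5$ are Very Conservative, and scores at or below $-2.5$ are Very
Liberal. The bins partition the real line, so every finite score belongs to
exactly one category; `bin_score(2.5)` is "Conservative" and
`bin_score(-0.5)` is "Somewhat Liberal" by the right-closed convention.

## 2. Cascade reconstruction

Platform exports attach every retweet to the *original* tweet, even when the
user actually saw an intermediate reshare. `build_cascades()` reconstructs
the diffusion forest per article with three ordered rules, applied to each
retweet or quote tweet in time order:

1. if the retweeter follows the original tweeter, the retweet is a direct
   child of the original share;
2. otherwise it is attached to the *friend who most recently shared* the same
   root strictly before the retweet;
3. otherwise (content reached the user outside their follow graph) it is
   attached to the original tweet.

Quote tweets are treated exactly like retweets; their followers' exposure
uses the quote's own timestamp. Two determinism choices the data do not
dictate: candidates sharing the same timestamp are broken toward the lowest
tweet id, and "earlier" means strictly before the retweet, so simultaneous
shares are never candidates. Retweets whose root is absent from the table are
dropped with a warning rather than aborting the article. The test suite
checks the reconstruction against an independent brute-force implementation
of the three rules on hundreds of random cascades, and verifies the forest
invariants (one parent per non-original tweet, friend-retweet parents
strictly earlier than children, acyclicity, invariance to input row order).

## 3. Ideology imputation

Scores come from an external scoring of accounts and are only partially
observed, so three tiers fill the gaps:

* **Sharers**: known score → mean of scored friends → population posterior
  mean (flagged and counted). The first two tiers are standard for
  follow-network ideology scoring; the final fallback is this package's
  choice for the (rare, low-follower) sharers with no scored friends, and it
  is flagged in the output so analysts can exclude them.
* **Population**: a normal $N(\mu_{pop}, \sigma_{pop})$ fitted to all known
  scores (subsampled without replacement above 500,000), with priors
  $\mu_{pop} \sim N(0, 2)$ and $\sigma_{pop} \sim \mathrm{Exp}(2)$, sampled
  with 2 chains, 1,000 warm-up iterations, and 3,000 retained draws by
  default.
* **Per-sharer followers**: a skew normal $SN(\mu_i, \sigma_i, \alpha_i)$ in
  the standard location/scale/shape parameterisation, fitted to the sharer's
  scored followers with 4 chains, 500 warm-up iterations, and 2,000 retained
  draws by default; $\alpha_i \sim N(0,1)$, so follower profiles are normal
  in prior expectation and skew left or right with equal probability.
  Sharers with *no* scored followers fall back to the prior with
  $\alpha_i = 0$: their followers are assumed to match the population.

### Prior propagation

The population posterior enters the per-sharer model as its prior. The
package centres both priors on the population posterior means and sets their
widths from the population's ideological *spread*:
$\mu_i \sim N(\mathrm{E}[\mu_{pop}], \mathrm{E}[\sigma_{pop}])$ and
$\sigma_i \sim N^+(\mathrm{E}[\sigma_{pop}], \mathrm{E}[\sigma_{pop}]/2)$
(zero-truncated). The alternative — using the Monte-Carlo uncertainty of
$\mu_{pop}$ as the prior width — looks natural but is degenerate in practice:
that uncertainty shrinks as $1/\sqrt{n_{pop}}$, so with hundreds of thousands
of scored users the prior would pin every sharer's follower distribution at
the population mean regardless of their actual followers. Centring on the
population while scaling by its spread preserves the intended behaviour at
both extremes: zero-data sharers reproduce the population distribution, and
sharers with many scored followers are dominated by their own likelihood.
Parameter-recovery and interval-coverage tests in the suite exercise both
regimes.

### Sampling

Both models are sampled with a No-U-Turn sampler implemented in the package
(recursive trajectory doubling with a slice variable, dual-averaging step
size adapted toward 0.8 acceptance — 0.9 for the skew model, whose geometry
is less forgiving at small follower counts; identity mass matrix, maximum
tree depth 10). The posteriors here are two- and three-dimensional with
cheap analytic gradients — the population model reduces to sufficient
statistics, so its gradient is $O(1)$ in the data — which is why a compact
implementation is both feasible and fast. Scale parameters are sampled on the
log scale with the Jacobian folded into the target; $\log\Phi$ terms and the
Mills ratio in the skew-normal gradient are computed in log space to survive
far-tail arguments. Split-$\hat R$ and divergent-transition counts are
recorded on every fit and a warning fires when divergences exceed 2% of
draws. The test suite cross-checks the sampler against an independent Gibbs
implementation (rjags) on the same data and priors.

Missing follower scores are drawn once per run from the sharer's fitted
distribution at its posterior-mean parameters and cached, so every downstream
consumer sees one consistent assignment; a `posterior_predictive` flag
switches to full posterior-predictive draws for uncertainty analyses. A
follower of several sharers is sampled from the model of the sharer with the
earliest tweet — a deterministic convention; any single consistent choice
works because the draw happens once per (user, run).

## 4. Exposure

Every follower of a sharer is assumed to eventually see the share — an
explicit upper bound on true impressions, adopted because impression data are
unavailable. Each (follower, tweet) pair receives a candidate exposure at
tweet time plus a delay drawn from a truncated normal with $\mu = 1$ h,
$\sigma = 2$ h, and lower bound 0 (mean delay $\approx 2.02$ h). Sampling is
inverse-CDF on the truncated region, so a seed fully determines the draws on
any platform. Exposure is a one-time event per (user, article): only the
earliest candidate survives deduplication. Sharers themselves are *not*
counted among the exposed by default — the accounting is follower-based — but
`include_sharers = TRUE` adds them at delay zero for sensitivity analyses.

`tabulate_exposures()` produces $x_{ij}$ and a cumulative time series
(default 30-minute bins). `receptivity_metrics()` derives the per-article
cumulative receptive curve normalised by its final value, the time-to-50% of
the receptive audience (computed from exact event times, not bin edges), and
the receptive fraction among newly exposed users per hourly bin — the
quantities used to compare how quickly receptive audiences accumulate.

## 5. Survey belief rates

$p_{ij}$ is the fraction of category-$i$ respondents who rated article $j$
"true" out of *all* ratings in that cell — "could not determine" responses
stay in the denominator, so only affirmative belief counts toward
receptivity. This is the conservative reading of the survey instrument;
excluding undecided respondents would inflate every rate. Empty
(article, category) cells fail fast by default because silently borrowing a
rate changes the estimand; an explicit `on_empty_cell = "pool"` falls back to
the article-wide pooled rate with a loud warning.

## 6. Intervention simulation

Three intervention families act on a reconstructed article at deployment
delay $t_{int}$ (hours after the article's first share):

| intervention | retweet removal | belief multiplier | exposure removal |
|---|---|---|---|
| fact-check label | 0.25 | 0.83 | — |
| sharing friction | 0.75 | — | — |
| visibility reduction (light) | — | — | 0.25 |
| visibility reduction (heavy) | — | — | 0.75 |

The sharing-focused rates come from published individual-level experiments;
the visibility rates are comparison values spanning mild and aggressive
downranking. Removing a retweet deletes its entire descendant subtree — a
reshare that never happened cannot itself be reshared. Visibility reduction
deletes candidate exposure events *before* earliest-exposure deduplication,
so a user who misses their first chance can still be exposed through a later
share; applying it after deduplication would understate residual exposure.
The belief discount applies to exposures after $t_{int}$ (a `global` flag
discounts everything, for sensitivity analysis). Quote tweets are subject to
removal like retweets; original shares are never removed.

Each (article, type, delay) is replicated (default 10×) with replicate $r$
seeded at $\texttt{seed} + r$, and every replicate is paired with a
no-intervention baseline run under the same seed, which removes a large share
of Monte-Carlo variance from the reported percent reductions (an unpaired
mode exists). Aggregates report the mean and the central 90% interval across
replicates × articles. Under pairing, a "none" intervention gives exactly
zero reduction — a useful identity the tests assert.

## 7. Synthetic data

The generator emulates the statistical structure the method relies on, at
scales where every stage can run in seconds:

* **Ideology**: a mixture of normals (default: a moderate bulk at 0 with
  left/right shoulders at $\mp 1.2$, common SD 0.8) — bimodality-with-centre
  is the shape reported for follow-network ideology scores.
* **Graph**: follower counts from a discrete power law (default exponent 2.5,
  capped), followers selected with probability proportional to a logistic
  kernel of ideological distance, $2\,\mathrm{plogis}(-h\,d)$; $h = 0$ gives
  distance-independent following (verified by a chi-squared independence
  test), larger $h$ shortens edge-level ideological distances. Above 10,000
  users the candidate pool per account is subsampled before the weighted
  draw; the kernel still governs selection within the pool.
* **Cascades**: independent-cascade spread from seed sharers chosen with
  probability proportional to squared follower count (viral articles start
  on large accounts), per-edge retweet probability, exponential waiting
  times, at most one share per user per article, true parent links recorded
  as ground truth.
* **Surveys**: balanced panels (default 90 respondents per article, within
  one of $n/7$ per category) with belief probability logistic in the product
  of category midpoint and article slant plus article quality — belief tracks
  ideological congruence, the dominant empirical pattern.

Demo scales: `tiny` (200 users, 1 article), `small` (5,000 users,
3 articles), `medium` (50,000 users, 10 articles); the tiny and small presets
use a slightly heavier-tailed degree distribution (exponent 2.2) and higher
retweet probabilities so cascades are non-degenerate at toy size. The same
seed yields a byte-identical bundle.

What the generator does **not** emulate — and therefore what passing tests do
not establish about real data: reciprocity and community structure in the
follow graph, bursty or circadian sharing times, feed-ranking effects on who
actually sees a share, article-specific belief heterogeneity beyond the
congruence-plus-quality model, and correlated missingness of ideology
scores (observability is independent of position in the graph). Tests on
synthetic data validate the *mechanics* of the estimator and simulator, not
the external validity of its assumptions.

## 8. Numerical and scale choices

* Problem sizes in the test suite are chosen to keep the full run in a few
  minutes: the end-to-end experiment uses the small bundle (3 articles, delay
  grid 0–24 h, 10 replicates) with reduced sampler settings (population
  2 × 300 warm-up/600 draws; per-sharer 2 × 150/300); Bayesian recovery uses
  the method's default settings at $n = 10{,}000$ (population) and
  $n = 1{,}000$ (per-sharer); interval coverage uses 50 repetitions at
  $n = 2{,}000$.
* Per-sharer models are fitted only for sharers with at least one unscored
  follower (`needed_only = TRUE`); a model whose draws would never be used is
  skipped.
* All randomness flows through explicit seeds; derived sub-seeds stay within
  32-bit integer range. Truncated-normal draws are inverse-CDF; skew-normal
  draws use the conditioning representation
  $\delta |Z_0| + \sqrt{1-\delta^2} Z_1$.
* Monte-Carlo rate checks (removal probabilities at 10,000 trials) are
  asserted within ±1 percentage point on means over several seeded runs.

## 9. Limitations

Exposure is potential exposure — an upper bound; ideology is the only
individual-level predictor of belief, and binning adds misclassification
noise at category boundaries; belief rates are measured once per article,
immediately after publication, so drift in belief as discussion evolves is
out of scope; combined or stacked interventions, accuracy nudges, and
prebunking are not modelled. Headline platform-scale totals from the original
139-article study require the deposited platform dataset and are not
reproducible at desk scale; the package's tests instead verify the method's
exact identities, oracle equivalences, statistical recovery, and the
qualitative delay-decay of intervention effectiveness on synthetic data.
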