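---
title: "Summed-score combinations in two-tier item factor models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summed-score combinations in two-tier item factor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lw25)
```

## The model

lw25 scores *two-tier* item factor models: `M` primary latent dimensions
$\eta$ shared by all items, and `N` specific dimensions $\xi_n$, each
measured by one non-overlapping item cluster.  The specific dimensions are
mutually independent given $\eta$, and each item loads on at most one of
them.  The bifactor model is the case $M = 1$; a correlated-traits MIRT
model is a two-tier model whose specific dimensions are empty.  Items are
dichotomous with the logistic response function

$$T_i(1 \mid \eta, \xi_n) =
  \frac{1}{1 + \exp\!\left[-(c_i + a_i^{0\prime}\eta + a_i^n \xi_n)\right]},$$

with known, fixed parameters — calibration is out of scope here, as it is
for any scoring engine.

All integrals are rectangular quadrature: `Q` equally spaced points per
dimension, weights proportional to the prior density ordinate at each
point, normalized to sum to one.  The primary prior may be any
(possibly correlated) multivariate normal; specific priors default to
standard normal per cluster.

## The recursions

**Stage I.** Within each cluster, the likelihood of every within-cluster
summed score given $(\eta, \xi_n)$ is accumulated one item at a time: the
table after item $i$ is the convolution of the table after item $i-1$ with
item $i$'s two category probabilities.  The specific dimension is then
integrated out, leaving $P_n(s_n \mid \eta)$.  Both the
$(\eta,\xi_n)$-conditioned and the marginalized tables are retained,
because the second stage needs both.

**Stage II.** Each cluster now behaves like a polytomous pseudo-item with
$I_n + 1$ categories, and the same recursion combines clusters into total
summed-score likelihoods $L(s \mid \eta)$.  Normalizing
$L(s \mid \eta)h(\eta)$ gives the summed-score EAP table
(`lw20_posteriors()`): marginal score probabilities, scale scores and
error variances for the primary dimension(s).

**Score combinations.** Running Stage II with cluster $n$ withheld yields
rest-score likelihoods $R_n(s_{(n)} \mid \eta)$.  For each pair
$(s_n, s_{(n)})$ of cluster score and rest score,

$$p(\eta, \xi_n \mid s_n, s_{(n)}) \propto
  P_n(s_n \mid \eta, \xi_n)\, R_n(s_{(n)} \mid \eta)\,
  g(\xi_n)\, h(\eta)$$

is a posterior over the primary dimensions *and* the focal specific
dimension; its normalizing constant is the probability of observing that
score combination.  `combo_posteriors()` computes, for every combination,
the probability and the posterior mean vector and covariance matrix by
quadrature — the currency of the three applications below.  Because
integration never involves more than the primary dimensions plus one
specific dimension, cost is independent of `N` (dimension reduction).

Note that with more than two clusters the primary-dimension estimates
depend on which cluster is focal: different decompositions of the total
score condition on different information, exactly as response patterns
and summed scores differ in unidimensional IRT.

## Worked example

The built-in `sixitem_fixture()` is a six-item bifactor scale (three
clusters of two items) whose every intermediate quantity is tabulated in
the literature on a deliberately coarse grid of five points at
$-2, \dots, 2$; the test suite reproduces those tables to the three
printed decimals.

```{r}
fx <- sixitem_fixture()
grid <- fixture_grid(fx)
ct <- combo_posteriors(fx$model, focal = 1, grid)
round(head(ct$combos), 3)
```

## Applications

**Growth classification** (`classify_regions()`): cut scores split a
latent scale into achievement regions; the probability of each region is
the mass of the combination's marginal posterior falling between cuts.
Two modes are provided because the choice is genuinely open: the default
sums the quadrature marginal's weights per region (each grid point owns
the cell reaching halfway to its neighbours, so a cut is effectively
snapped to the nearest cell boundary), and `method = "normal"` uses
normal-CDF differences under the moment-matched normal approximation.
On coarse grids the snapping error of the quadrature mode can reach a few
hundredths when the posterior standard deviation is comparable to the
grid spacing; the normal mode is then the better choice, and is what the
published contour plots of such posteriors depict.

**Score-combination percentiles** (`conditional_percentile()`): among
examinees with a given score on one test, the percentile standing of a
score on the other.  The default is the conventional percentile rank,
$100 \cdot P(s_{rest} < \mathrm{at} \mid s_n = \mathrm{given})$ — the
percentage scoring strictly below — which is the convention under which
the package reproduces the published growth-percentile illustration;
`"le"` and `"midpoint"` rules are selectable.

**Subscore screening** (`subscore_screen()`): a subscore earns reporting
when it is poorly predicted by the overall score.  The specific-dimension
EAP of each combination is regressed on the primary EAP, weighted by the
combination's probability, and a prediction band at `level` is drawn.
The band is the normal-quantile interval
$\hat\mu(x) \pm z_{(1+\mathrm{level})/2}\, s\sqrt{1 + h(x)}$, with the
probability weights normalized to sum one and rescaled by the number of
positive-probability combinations $K$, so that equal weights reduce
exactly to the ordinary least-squares prediction interval
($s^2 = \frac{K}{K-2}\sum_k w_k r_k^2$, $h(x)$ the usual leverage under
the rescaled weights).  No reference formula exists for this interval in
the scoring literature; this is the standard WLS construction.  For each
combination the proportion of its normal-approximated posterior volume
inside the band is computed — small proportions flag combinations whose
subscore adds information.

**Aberrance detection** (`hdr()`): the combination probabilities are
sorted descending and accumulated until coverage reaches `alpha`; the
accumulated set is the discrete high-density region, and combinations
outside it are rare patterns deserving attention.  Ties in probability
are broken lexicographically by `(s_n, s_rest)`, which makes the region
deterministic and minimal — including up to the first crossing combo and
no further, so a uniform table of `K` combinations yields exactly
`ceiling(alpha * K)` members.

## Numerical choices

* **Default grid:** `Q = 49` on $[-6, 6]$ per dimension — ample for
  scoring-length tests; the demonstration grid (`Q = 5` on $[-2, 2]$) is
  only for tracing arithmetic.  Both are configurable everywhere.
* **Linear-space accumulation.** Likelihood tables are carried in linear
  space.  Because each table's scores partition the response space, the
  values at any node sum to one exactly, so the table as a whole cannot
  underflow; only tail scores with likelihood below roughly `1e-300`
  flush to zero, which is irrelevant to posteriors at realistic test
  lengths (a hundred-odd items).  No rescaling machinery is therefore
  attached.
* **Empty specific dimensions.** A cluster whose items all have zero
  specific loading is computed on the primary grid alone — algebraically
  identical and essential for correlated-traits models at fine grids.
* **Moments before approximation.** All reported moments come from the
  discrete quadrature posterior; the normal approximation is a downstream
  convenience for band and region queries, never the source of moments.
* **Impossible combinations** keep their row with probability zero and
  `NaN` moments, so table shapes are predictable for lookup.
* **Band volumes** use the deterministic 2-D midpoint rule on a
  $201 \times 201$ box spanning $\pm 6$ posterior standard deviations;
  accuracy is limited by the cell size where a boundary cuts high
  density (about `1e-2` at the default resolution), which the tests
  cross-check against Monte Carlo.
* **Report rounding** is half-even to three decimals, mirroring the
  published tables; full precision is always retained internally and
  available via `full_precision = TRUE` / `--full-precision`.

## The synthetic generator, and what the tests do not show

`synth_model()` draws positive primary and specific slopes uniformly from
$[0.5, 2.5]$ and intercepts from $[-2, 2]$ — the magnitude range of the
calibrated educational and patient-reported-outcome parameter sets
shipped as fixtures.  Generated models exercise every recursion against a
response-pattern enumeration oracle (`brute_force_combo_probs()`), which
agrees with the recursions to near machine precision on any shared grid.

Synthetic models are clean by construction: parameters are exactly known,
items fit the model perfectly, and responses play no role (the algorithms
consume parameters only).  Passing tests therefore demonstrate the
correctness of the recursions and summaries, not robustness to
calibration error, item misfit, or multidimensionality violations in real
data.  Item parameter uncertainty in particular is taken as zero; users
who need to propagate calibration error should rerun the scoring over
plausible parameter draws.

Problem sizes used by the test suite — oracle checks at up to 12 items on
five-point grids, property sweeps over a few hundred generated cases, and
the 54-item operational fixture at `Q = 49` — were chosen so the whole
suite documents the algorithms at interactive speed.

## Known limitations

* Dichotomous source items only; polytomous items enter only as the
  pseudo-items Stage II itself creates.  (Recoding polytomous scales to
  binary, as is sometimes done in practice, is the user's call.)
* Weighted or non-integer item scores are not supported.
* The subscore-screening regression is defined for `M = 1`.
* No missing-data handling: the summed scores are assumed complete.
* Cut scores far outside the grid range are honoured but warn, since the
  quadrature marginal has no support there.
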