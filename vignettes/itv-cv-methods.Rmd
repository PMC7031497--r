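---
title: "Methods: low-bias CV estimation for intraspecific trait variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-bias CV estimation for intraspecific trait variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itvcv)
```

## The problem

Intraspecific trait variation (ITV) — the spread of a functional trait among
conspecific individuals — is usually summarised by the coefficient of
variation, $CV = \sigma/\mu$, because it is dimensionless and comparable
across traits and species. The estimator almost universally used in practice
is the plug-in ratio $CV_1 = s/\bar x$. At the sample sizes typical of trait
surveys (10–50 individuals per species), $CV_1$ systematically
*underestimates* the population CV, and the size of the deficit depends on
the skewness and kurtosis of the trait distribution, so two species sampled
with equal effort can be biased by different amounts. This package
implements corrected estimators, the normalizations that interact with them,
a simulator of realistic trait pools, and a resampling engine that measures
the bias directly.

## Estimators

With $N$ the sample size, $s$ the $n-1$ sample standard deviation, $g_1$ the
plug-in moment skewness $m_3/m_2^{3/2}$ and $g_2$ the plug-in *excess*
kurtosis $m_4/m_2^2 - 3$ (central moments $m_k$ with $1/N$):

$$CV_1 = s/\bar x, \qquad CV_2 = CV_1\!\left(1 + \tfrac{1}{4N}\right)$$

$$CV_3 = \frac{CV_1}{1 - \frac{CV_1}{N}\left(3\,CV_1 - 2 g_1\right)}, \qquad
CV_4 = CV_1 - \frac{CV_1^3}{N} + \frac{CV_1}{4N}
     + \frac{CV_1^2 g_1}{2N} + \frac{CV_1 g_2}{8N}$$

$$CV_5 = \tfrac{1}{2}(CV_3 + CV_4),\quad CV_6 = \tfrac{1}{2}(CV_2 + CV_4),
\quad CV_7 = \sqrt{CV_3\,CV_4},\quad CV_8 = \sqrt{CV_2\,CV_4}.$$

$CV_2$ removes the normal-theory bias $-CV/(4N)$. $CV_3$ and $CV_4$ use the
sample's own skewness and kurtosis, so they require no distributional
assumption; the composites average a distribution-free correction with a
normal-theory one and behave intermediately.

### Conventions that were genuinely open, and how they were fixed

The source formulas for $CV_3$ and $CV_4$ are ambiguous in two places, and
we fixed both with explicit evidence rather than typography:

1. **Does the $CV_3$ bracket divide or multiply?** A Monte-Carlo oracle
   (gamma samples with shapes 1, 4 and 9, whose population CV is the closed
   form $1/\sqrt{\beta_1}$, at $n = 10$ and $20$, $10^5$ paired replicates)
   shows the division form above cuts the absolute bias dramatically at
   $n = 10$ — e.g. from $-0.077$ to about $-0.001$ at shape 1 — while the
   multiplicative reading makes the bias *worse* in four of six cells. The
   division form is adopted. It is not uniformly dominant: at $n = 20$,
   shapes 4 and 9, it overshoots $CV_1$'s bias by about $4\times10^{-4}$, a
   known and accepted trade-off (the corresponding acceptance check is left
   failing rather than papered over).

2. **Raw or excess kurtosis in $CV_4$?** With excess kurtosis the formula is
   exactly the second-order analytic bias correction for $E[s/\bar x]$: the
   $g_1$ and $g_2$ terms vanish for normal data, leaving the pure $1/(4N)$
   correction. The same gamma oracle slightly prefers raw kurtosis at
   shape 1, $n = 10$ (an artifact of plug-in moment bias: sample kurtosis is
   bounded by roughly $n$ and badly underestimates heavy tails at $n = 10$),
   but raw kurtosis adds a spurious $+3\,CV/(8N)$ on near-normal data, which
   inverts the package's central comparative result — log-transformation
   would then *increase* the small-sample bias of $CV_4$ instead of reducing
   it. Excess kurtosis is used.

A related consequence worth knowing: with excess kurtosis, $CV_4$
slightly *over*estimates when the (possibly transformed) data are close to
normal, which is why $CV_6$ — its average with the normal-theory $CV_2$ —
is attractive for near-normal traits.

### Degenerate and pathological input

* Constant samples ($s = 0$) return 0 for every estimator, with a
  `degenerate` flag in the moments, so batch pipelines survive constant
  traits.
* A non-positive sample mean is an error: the CV is not meaningful there.
* If the $CV_3$ bracket is not strictly positive the scalar API raises a
  domain error naming the bracket value; the resampling engine drops and
  counts such replicates and aborts if they exceed 1% of draws.
* A negative $CV_4$ (possible at tiny $n$ with extreme moments) is clamped
  to 0 with a warning.

## Normalizations

Three normalizations interact with CV estimation (plus the identity):
natural log with an add-one shift rule (if any value of the vector is below
1, 1 is added to *all* values first), cube root, and min-max. The min-max
denominator is $x_{\max}$, not the conventional range $x_{\max}-x_{\min}$;
this matches the convention under study (the conventional form is available
via `minmax_range = TRUE`). All are monotone, so ranks are preserved.

In pool-based evaluation a transform is fitted on and applied to the
**entire pool** before any resampling (`transform_pool()`), and the
reference CV is recomputed on the transformed scale. Subsamples are never
re-normalized per draw; the fitted `transform_spec` freezes the shift
decision and the min/max references. The shift rule is applied per vector
being transformed ("that trait"), which for grouped tables means per
species-by-trait group.

Log-transformation matters because trait data are right-skewed with rare
extreme values that the CV is very sensitive to; the log pulls the tail in
(the test suite verifies the mean plug-in skewness of gamma samples drops
after the transform), which is what lets $CV_4$ reach the $\pm5\%$ band by
$k \approx 10$–20 on log scale.

## The simulated world

`simulate_pool()` builds a population of trait values for one virtual
species:

* 9,520 values from a gamma distribution with shape
  $\beta_1 \sim U(1, 10)$ and scale $\beta_2 \sim U(5, 30)$ (trait units) —
  positive, right-skewed, flexible enough to span observed trait shapes;
* 480 extreme large values at $t + \mathrm{Exp}(\lambda = 1)$, where
  $t = \bar x + 3\,\mathrm{sd}$ of the **base** values — emulating the
  ~4.8% of values beyond three standard deviations seen in large empirical
  trait datasets.

Choices a user should know:

* **Threshold moments.** The threshold uses the base (pre-contamination)
  values, because the extremes do not exist yet when the threshold is
  formed; `threshold_on = "pool"` provides the post-hoc reading (a
  fixed-point iteration on the contaminated pool's own moments).
* **$\lambda$ is a rate on the raw trait scale** (mean excess 1 trait
  unit); it does not scale with $\beta_2$. It is a config knob.
* **The reference CV (`cv_true`) is computed empirically from the full
  contaminated pool**, not from the analytic gamma CV, because
  contamination changes the population CV and bias must be measured against
  the pool's own CV. Consequently the ensemble of `cv_true` values over 200
  default pools spans roughly 0.35–1.1: the analytic lower limit
  $1/\sqrt{10} \approx 0.316$ (shape 10, no contamination) is not attainable
  because contamination strictly raises the CV.
* Extremes are shuffled into the pool so positional sampling cannot bias
  draws.

What a green test on this world does **not** establish: real trait data have
measurement error, spatial and environmental structure, and
non-gamma shapes (multimodality, censoring); the simulator makes no attempt
at these, so conclusions transfer only insofar as "right-skewed positive
values with a small heavy upper tail" describes the data at hand.

## Bias evaluation and the minimum sample size

For each sample size $k$ the engine draws replicates **with replacement**
(default 9,999; the acceptance workflow scales down to 2,000 and the TPB
sweep to 999 to fit its time budget) and reports per estimator the mean CV,
its standard error, the bias $B(i,k) = \overline{CV}_{i,k} - CV_{true}$ and
the proportional bias $PB = B/CV_{true}$. All eight estimators are computed
from the *same* draws, and within a pool the same draw indices are reused
across transforms, so comparisons are paired and their Monte-Carlo noise
largely cancels. A without-replacement option exists and is verified
against exhaustive enumeration of all $\binom{n}{2}$ pairs on tiny pools.

The total bias of an estimator is summarised as
$TPB(i) = \sum_k |PB(i,k)|$; the absolute-scale variant $\sum_k |B(i,k)|$
is also emitted (`tab` column), but the proportional form is the headline
because it is comparable across pools with different CVs.

The minimum sample size $k_{\min}$ for accuracy $a$ (default $\pm5\%$) is
the smallest tested $k$ whose $|PB|$ is within $a$ **and stays within $a$
at every larger tested $k$** (the "sustained" rule). The raw first
crossing is noisy at finite replicate counts — a curve can dip into the
band and leave again; the sustained rule converges to the first crossing as
the curves become monotone. `rule = "first"` gives the raw crossing.

## Known limitations

* $CV_3$'s division-form correction can inflate badly on heavily
  contaminated pools at small $k$ (the bracket approaches zero for draws
  that combine a large $CV_1$ with modest sample skewness). Its total bias
  on contaminated pools can exceed $CV_1$'s even though it is much less
  biased on clean gamma samples. Prefer $CV_4$ or the composites for
  contaminated data.
* Because no single kurtosis convention wins every comparison (see above),
  one cell of the gamma-oracle acceptance check and the two ranking clauses
  of the scaled comparative sweep are left failing by design, with the
  measured numbers in the test output.
* Regression-based CV estimators, confidence intervals for the CV, and
  non-random (stratified) sampling designs are out of scope.

## A worked example

```{r example}
set.seed(1)
pool <- simulate_pool()
pool

bp <- bias_profile(pool, grid = c(10, 20, 50), replicates = 999,
                   estimators = c(1, 4))
bp
min_sample_size(bp)
```

The negative `pb` values for `cv1` show the plug-in estimator's
underestimation at small sample sizes; `cv4` sits much closer to zero, and
its `k_min` is accordingly smaller.
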