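---
title: "Benchmarking the accuracy of sample means"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking the accuracy of sample means}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meanbench)
```

## The question

A balanced one-way experiment has $p$ conditions with true means
$\mu_1,\dots,\mu_p$, a common within-condition SD $\sigma$, and $n$
observations per condition.  The usual estimates of the condition means
are the per-condition sample means $\bar y_i$.  They are unbiased and
consistent — but with small effects and small samples they are also so
variable that deliberately *uninformative* estimators beat them on mean
squared error.  When that happens, reporting the pattern of sample means
overstates what the experiment measured.

`meanbench` implements two such benchmark estimators, the closed-form
MSE comparison between them and the sample means, the minimum sample
sizes implied by that comparison, and a Monte-Carlo engine to verify all
of it, including under non-normal and heteroscedastic noise.

Throughout, accuracy means total mean squared error over the $p$
condition means,
$$\mathrm{MSE}(\hat\mu) = E\Big[\sum_{i=1}^p (\hat\mu_i - \mu_i)^2\Big]
  = \sum_i \mathrm{Var}(\hat\mu_i) + \sum_i \big(E[\hat\mu_i]-\mu_i\big)^2,$$
the familiar variance-plus-squared-bias decomposition.  A biased
estimator can win by being much less variable.

## The two benchmarks

**Zero estimator.**  Every condition gets the grand mean $\bar G$ of all
$pn$ observations; every treatment effect is declared exactly zero.  Its
MSE is $\sigma^2/n + p f^2 \sigma^2$, where
$$f^2 = \frac{1}{p}\sum_i \frac{(\mu_i - \mu^*)^2}{\sigma^2}$$
is Cohen's noncentrality effect size ($\mu^*$ the population grand
mean).  The conventional calibrations are $f^2 = .01/.0625/.16$ for
small/medium/large.

**Random estimator.**  Draw $a_1,\dots,a_p$ iid uniform on $[-1,1]$ and
estimate
$$\hat\mu_i^{re} = \bar G + b\,a_i, \qquad
  b = \big(p - \sqrt{p(p-1)}\big)\,
      \frac{\sum_i a_i \alpha_i}{\sum_i a_i^2},$$
with $\alpha_i = \bar y_i - \bar G$.  The *pattern* — which conditions
are estimated high or low, and by how much — is pure noise; only the
*scale* is taken from the data, through the least-squares shrinkage
coefficient $b$.  Because $b$ may be negative, the random order can at
most be wholly reversed to fit the data; it is never re-sorted.  The
support $[-1,1]$ is a pure normalisation: any bounded interval symmetric
about zero yields the identical estimator after rescaling by $b$.

```{r}
d <- condition_sample_from_means(c(593, 626, 630, 756), n = 10)
random_estimate(d, a = c(-0.190, -0.973, 0.823, 0.600))
```

The estimates hug the grand mean (651.25 ms) in an order dictated by the
coefficient draw, not by the data.

## Closed forms and minimum sample sizes

The sample means have MSE $p\sigma^2/n$.  The random estimator trades
squared bias $(p-1)f^2\sigma^2$ for total variance
$$\frac{\sigma^2\big(p + (p-1)(p-\sqrt{p^2-p})^2\big)}{p\,n}
  + (p-1)\big(2p-1-2\sqrt{p^2-p}\big) f^2 \sigma^2 .$$
Setting the totals equal gives the crossing points, which are the
package's planning thresholds:

* sample means beat the **random** estimator only when
  $n \ge \sqrt{p(p-1)}/(p f^2)$;
* they beat the **zero** estimator only when $n \ge (p-1)/(p f^2)$.

The first threshold always exceeds the second by the factor
$\sqrt{p/(p-1)}$.  Both are distribution-free: nothing beyond a common
within-condition variance is assumed.

```{r}
min_n_random(5, 0.05)
accuracy_report(design_environment(4, 10, 100, mu = c(600, 620, 640, 660)))
```

Integer reporting uses the ceiling of the continuous threshold; an exact
tie at an integer boundary counts as "sample means acceptable", matching
the strict inequality under which the benchmark wins.  At $f^2 = 0$ the
thresholds are reported as `Inf` — a tagged "never" — rather than an
error, so planning tables render cleanly.

## Monte-Carlo verification

`simulate_mse()` replays an environment: per repetition it draws a fresh
dataset *and a fresh coefficient vector* (it is the estimator, not one
fixed assignment, that is under evaluation), computes each estimator's
summed squared error against the true means, and averages.  In the
four-condition reference environment ($\mu$ = 600/620/640/660 ms,
$\sigma$ = 100 ms, $n = 10$, so $f^2 = .05$ and a threshold of 17.3) the
closed forms give MSEs of 4000 (sample means), 3000 (zero) and 2823.1
(random) — a ratio of 1.417 against the sample means:

```{r}
env <- design_environment(4, 10, 100, mu = c(600, 620, 640, 660))
simulate_mse(env, reps = 10000, seed = 1)
```

The generator behind the engine (`generate_dataset()`) emulates balanced
one-way data with normal, centered-uniform, or shifted-exponential noise
scaled to the requested SD, optionally with per-condition SDs for
heterogeneity studies.  It emulates exactly what the closed forms
assume — iid noise within conditions, a fixed common scale — and none of
what real data add (dependence across trials, participant effects,
skewed RT tails beyond the exponential, outliers).  Passing tests
therefore certify the mathematics and the code, not the adequacy of the
one-way model for any particular dataset.

The test suite verifies the closed forms against this engine across
randomly drawn environments and all three noise families at $10^5$
repetitions within 4 Monte-Carlo standard errors, and checks the
heterogeneous-variance robustness of the threshold rule at $p = 3$ and
$5$ with SD profiles spanning a factor of 4.

## Power is not accuracy

`anova_power()` gives one-way ANOVA power through the noncentral $F$
distribution with $(p-1,\,p(n-1))$ degrees of freedom and noncentrality
$\lambda = f^2 N$, $N = pn$ (Cohen's convention; beware $\lambda = f^2
n$ variants elsewhere).  Two curves move in opposite directions as $p$
grows at fixed $f^2$: the minimal-accuracy $n$ *increases*, while the
$n$ for 50% power *decreases*.  A multi-condition design can therefore
be respectably powered while its sample means are less accurate than a
benchmark that scrambles the conditions:

```{r}
power_at_minimal_accuracy(p = 8, f2 = 0.0625)
anova_power(p = 8, n = min_n_for_power(8, 0.0625, target_power = 0.5),
            f2 = 0.0625)
```

## Hierarchical-Bayes estimation

The constructive recommendation behind the benchmarks is to replace raw
sample means with shrinkage estimators.  `hb_estimate()` fits
$$y_{k,i} \sim N(\mu^* + \alpha_i, \sigma^2), \quad
  \alpha_i \sim N(0, \tau^2), \quad
  \pi(\mu^*, \sigma^2) \propto 1/\sigma^2,$$
by a Gibbs sampler with conjugate updates (normal draws for $\mu^*$ and
the $\alpha_i$, a scaled inverse-$\chi^2$ draw for $\sigma^2$) and
returns posterior means of $\mu^* + \alpha_i$, which always lie between
each sample mean and the grand mean.

Design choices worth knowing:

* **Prior scale.**  $\tau$ (`prior_sd`, in DV units) is a fixed
  hyperparameter.  Its default is the observed SD of the condition
  sample means — an empirical calibration that pools more when the
  apparent spread is small — and it is always user-overridable.
  $\tau \to 0$ is complete pooling; $\tau \to \infty$ recovers the
  sample means.  Both limits are tested.
* **Chain settings.**  Defaults of 4,000 draws with 1,000 burn-in; a
  seed is required for reproducibility.  Convergence is not
  auto-diagnosed — these two-level conjugate models mix almost
  immediately at desk scale — but per-condition effective sample sizes
  are reported (`$ess`) so pathologies are visible.  Initialisation is
  at the method-of-moments values (grand mean, deviations, pooled
  variance), and a non-finite variance draw aborts with an explicit
  error rather than propagating NaNs.

The suite verifies, at 250 simulated replicates of the reference
environment with 1,200-draw chains, that pooling lowers the average
total squared error below that of the sample means.  Those sizes are
deliberately modest: the margin between the two estimators is large, so
a longer chain or more replicates adds nothing but runtime.

## Numerical and design notes

* $\sqrt{p^2-p}$ is computed once and reused so the closed-form equality
  at the Proposition-style thresholds is exact to rounding (the suite
  demands relative $10^{-9}$ on a $(p, f^2)$ grid).
* The simulation engine vectorises repetitions in chunks from a single
  seeded stream.  Results are a pure function of (configuration, seed) —
  reruns are bit-identical, which is the reproducibility contract the
  tests assert — but individual repetitions are not independently
  seeded streams, so results do change if `reps` changes.
* The per-repetition record is the summed squared error across
  conditions; its average over repetitions estimates the MSE.
* Exponential noise is shifted to mean 0 and scaled to SD $\sigma$, so
  an environment's $f^2$ is identical across noise families.
* The two-condition case never scrambles order ($b$'s sign always
  aligns the pair with the data), so there the zero-estimator comparison
  is the informative one.  More generally the rank correlation between
  the random-estimate order and the sample-mean order stays positive on
  average — $b$'s sign is fitted — and decays toward zero roughly like
  $1/\sqrt p$; the suite asserts the decay, not exact zero.
* The heterogeneity presets evaluate the threshold rule using the
  effect size computed from the *average* variance
  $\bar\sigma^2 = \mathrm{mean}(\sigma_i^2)$; their mean patterns and SD
  profiles are package defaults chosen to span a 4-fold SD range at
  $p = 3$ and $5$.

## Limitations

Only balanced one-way layouts are covered; unbalanced or multi-factor
designs are rejected at the door, not reweighted.  The benchmarks are
evaluated under squared-error loss exclusively, and for $p = 2$ the
random benchmark reduces to a relabelled sample-mean contrast.  The
hierarchical model assumes a common within-condition variance; it is a
recommendation demo, not a general mixed-model replacement (use a
dedicated multilevel package for real analyses with covariates or
repeated measures).
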