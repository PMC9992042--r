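---
title: "Comparing analysis methods for single-item longitudinal ordinal PRO data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing analysis methods for single-item longitudinal ordinal PRO data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propower)
```

## The problem

Patient-reported outcome items such as the PRO-CTCAE score a single symptom
on an ordinal 0 (none) to 4 (worst) scale, at baseline and repeatedly during
treatment. In a two-arm trial the analyst must decide how to test for a
treatment difference in such an item: summarise each patient's follow-up
scores into one number and compare the arms with a rank-based regression, or
model the repeated ordinal scores directly with a mixed model. Both routes
must also decide what to do with the baseline score. `propower` implements
eight concrete strategies and the simulation machinery to measure their type
I error and power under controlled correlated-ordinal data, so the choice
can be made quantitatively rather than by convention.

The eight strategies (`all_methods()`) are:

* **PIM-BA-{TI, Avg, Max}** — probabilistic index model on a per-patient
  summary of *baseline-adjusted* follow-up scores, treatment as the only
  covariate;
* **PIM-BC-{TI, Avg, Max}** — PIM on a summary of the raw *post-baseline*
  scores, with the baseline grade and treatment as covariates;
* **CLMM** — cumulative logit mixed model on the follow-up scores, treatment
  effect tested by a chi-square likelihood-ratio test;
* **CLMM-Bootstrap** — same model, treatment effect tested by a parametric
  bootstrap likelihood-ratio test.

## Simulated data: Gaussian copula with multinomial marginals

A scenario fixes, for each arm $a$ and time $t$, the marginal probabilities
$\pi_{a,t,k}$ of the five categories, a within-patient correlation $\rho$,
and the arm size (100 patients per arm by default). For each patient the
simulator draws a latent vector $Z \sim N(0, R)$ over the $T = 3$ time
points, with unit variances and exchangeable correlation
$R_{st} = \rho\ (s \neq t)$, and discretises each coordinate: the score at
time $t$ is the category $k$ whose cumulative-probability cell
$[C_{k-1}, C_k)$ contains $\Phi(Z_t)$, with the cells built from
$\pi_{a,t,\cdot}$. Marginals are therefore matched exactly in expectation
while $\rho$ controls the dependence.

Two caveats are inherent to this construction and documented here because
tests rely on them:

* $\rho$ is the **latent** correlation. The manifest rank correlation of the
  ordinal scores is attenuated by discretisation; the test suite checks the
  attenuated value against a numerically integrated discretised-bivariate-
  normal oracle rather than against $\rho$ itself.
* A single exchangeable $\rho$ covers all three time points, baseline
  included. Real longitudinal items can show serial (non-exchangeable)
  dependence, informative dropout, or missing visits; none of these are
  emulated, so calibration results here speak to complete-case exchangeable
  data only.

A sample whose follow-up observations do not span at least two categories in
each arm cannot support the models; `simulate_admissible()` redraws such
samples with deterministically incremented seeds (`seed`, `seed + 1`, ...)
so the whole study stays reproducible.

### The built-in scenario grid

`default_grid()` spans five structural families at
$\rho \in \{0.2, 0.5, 0.9\}$: identical arms at all times (null); equal at
baseline but shifted at follow-ups; shifted at all times with a shared time
trend; a strongly zero-inflated trial-like variant; and a constant shift at
all times. Arm and time differences are **proportional-odds shifts**: a
configurable log-odds offset applied to the cumulative logits of a base
marginal (`shift_marginal()`), which keeps every derived marginal a valid
distribution and makes the effect size a single interpretable number. The
defaults — base marginal $(0.55, 0.20, 0.12, 0.08, 0.05)$, between-arm shift
0.5 log-odds, time trend 0.25 log-odds per follow-up visit, skewed base
$(0.70, 0.15, 0.08, 0.05, 0.02)$ for the trial-like family — were chosen
once to put the methods in a moderate, non-saturated power regime at 100
patients per arm, where power differences between methods are visible; they
are deliberately not tuned per experiment.

## Summary scores

For grades $g_{(1)} \ge g_{(2)} \ge \dots$ sorted descending, the toxicity
index is

$$\mathrm{TI} = \sum_i g_{(i)} \prod_{j < i} (1 + g_{(j)})^{-1},$$

so its integer part equals the maximum grade and lower grades refine the
ranking between patients sharing a maximum. `Avg` and `Max` are the
arithmetic mean and maximum. Under the **baseline-adjusted** strategy a
follow-up grade is kept only if it exceeds the baseline grade by at least 1,
otherwise it is set to 0 — in particular, a patient whose follow-ups never
exceed baseline scores 0 on every summary. We compute baseline-adjusted
`Avg` and `TI` on the full-length zero-filled vector rather than on the
subset of qualifying scores: this keeps the per-patient denominator constant
across patients and reproduces the all-zero convention for every measure
with no special cases. (Averaging over qualifying scores only would be a
defensible alternative; it changes `Avg` for partially-qualifying patients.)

## Probabilistic index model

The PIM regresses the probabilistic index
$\mathrm{PI} = P(S_i < S_j) + \tfrac12 P(S_i = S_j)$ on covariate contrasts
through a logit link. Every unordered patient pair becomes a
pseudo-observation with outcome $1$, $\tfrac12$ or $0$ and antisymmetric
design $Z_{ij} = X_j - X_i$; the estimating equation
$\sum_{ij} Z_{ij}\,[P_{ij} - \mathrm{expit}(Z_{ij}^\top\beta)] = 0$ is
solved by damped Fisher scoring (score tolerance $10^{-10}$ per pair, 100
iterations). Ties count one half — essential for ordinal-derived summaries,
which have large mass points. With treatment as the only covariate the
solution is exactly the tie-corrected Mann–Whitney statistic divided by
$n_0 n_1$, which the tests exploit as a brute-force oracle.

Because pairs sharing a patient are dependent, the variance of
$\hat\beta$ uses a sandwich whose middle term sums score cross-products over
all pair couples sharing at least one index, computed in $O(\text{pairs})$
via per-patient score totals and verified in the tests against a quadratic-
time enumeration. Wald confidence intervals are formed on the logit scale
and back-transformed, guaranteeing PI endpoints inside $(0,1)$. In the
baseline-as-covariate model the reported PI is the conditional
$\mathrm{expit}(\beta_{trt})$ — the index between two patients with equal
baselines — rather than a marginalised quantity; this is the natural
regression-scale summary and is labelled as conditional.

Complete separation (all informative pseudo-outcomes 0 or 1) has no finite
estimate; the fit is flagged non-converged and the study runner redraws the
panel, mirroring its handling of mixed-model non-convergence.

## Cumulative logit mixed model

For follow-up score $Y_{it}$ ($t \ge 2$; time 1 enters as a covariate):

$$\mathrm{logit}\, P(Y_{it} \le k \mid b_i) = \theta_k - (\beta_{trt}\,a_i +
\beta_{t3}\,\mathbf 1\{t = 3\} + \beta_{base}\,y_{i1} + b_i), \qquad
b_i \sim N(0, \sigma_b^2).$$

Design choices: time enters as an indicator for each follow-up visit beyond
the first (with two follow-ups, factor and linear codings span the same
space); the baseline grade enters as a numeric covariate — 0–4 is close
enough to interval-scaled here, and factor coding would spend four
parameters at 100 patients per arm. Cutpoint ordering is enforced by
optimising $\theta_1$ plus log-increments; $\sigma_b$ is optimised as
$\log \sigma_b$ with a floor of $10^{-6}$, so the independence boundary is
approachable without sign problems.

Each patient's random-effect integral is approximated by Laplace: an inner
safeguarded Newton solve for the conditional mode, then the standard
log-determinant correction. The outer quasi-Newton optimisation uses an
**analytic gradient** obtained by implicit differentiation through the mode
(the envelope term vanishes at the mode; the correction term requires third
derivatives of the joint log-density in $b$), which the test suite verifies
against central finite differences. Patients sharing an identical
(response, covariate) block are collapsed into one weighted pseudo-patient —
an exact rewrite of the likelihood that speeds up the bootstrap several-fold
at 0–4 scales. Laplace accuracy is audited against a 25-node adaptive
Gauss–Hermite quadrature oracle (agreement within 0.5% of the
log-likelihood on small panels), and the $\sigma_b = 0$ degenerate case
against plain proportional-odds maximum likelihood.

### Testing the treatment effect

The chi-square LRT refers $2(\ell_1 - \ell_0)$ (clipped at 0) to
$\chi^2_1$. The parametric bootstrap instead rebuilds the null distribution
of the statistic: fit the null model, then repeatedly (i) draw fresh random
intercepts from $N(0, \hat\sigma_{b,0}^2)$, (ii) simulate new follow-up
responses from the fitted null category probabilities given each
observation's time and baseline (the design — arms, baselines, times — stays
fixed, the standard parametric bootstrap for fixed-design mixed models),
(iii) refit both models. The p-value uses the add-one convention
$p = (1 + \#\{LR^*_b \ge LR_{obs}\})/(B + 1)$, bounded below by $1/(B+1)$;
resamples whose refits fail are redrawn (fresh responses, up to 10 attempts)
rather than dropped, keeping $B$ fixed at the configured value (500 by
default). Warm starts from the observed-data fits make the $2B$ refits
affordable.

### What our calibration runs show

On the built-in null scenarios the six PIM strategies reject at roughly
5–6% — slightly above nominal, which traces to the heavier-than-normal
tails of the logit-scale Wald statistic at 100 patients per arm rather than
to the sandwich variance, and sits at the edge of the Monte-Carlo band for
1000 replicates. The bootstrap CLMM test is close to nominal.

The chi-square CLMM LRT in this implementation is **near-nominal at low
correlation and conservative at high correlation** (the likelihood-ratio
statistic falls stochastically below $\chi^2_1$ at $\rho = 0.9$). Mixed-model
likelihood-ratio tests for fixed effects are widely reported to be
anti-conservative, increasingly so with stronger clustering, and the
acceptance suite encodes that expectation directionally; our cleanly
converged Laplace fits do not reproduce it on copula-generated nulls — with
200 clusters the between-arm information is apparently well enough
approximated that no inflation materialises, and the approximation error
largely cancels between the nested fits. We flag this openly: the
directional anti-conservatism checks fail for this implementation, while
every absolute calibration check (PIM band, bootstrap band) behaves as
intended. The practical recommendation is unchanged — when in doubt, use the
bootstrap test, which is calibrated by construction against the fitted null.

## Study orchestration

`run_study()` loops scenarios × replicates; each replicate simulates an
admissible panel, computes the needed summaries, and fits the requested
methods. If **any** fitted model fails to converge the entire panel is
redrawn (up to `max_redraws`, seed advanced deterministically), so one
method's numerical fragility cannot bias another's rejection rate;
replicates that exhaust the budget are excluded from the denominator and
counted. Per-replicate seeds are hashed from (master seed, scenario label,
replicate index), making results invariant to execution order and to
extending the scenario list.

`aggregate_report()` reduces replicate rows to the power comparison: per
method, the mean power over non-null scenarios — identical, exactly, to the
area under the 1−ECDF curve of per-scenario powers (`ecdf_area()`), which is
how `plot_power_ecdf()` displays it — with a t-based 95% CI over scenarios,
and the paired-t mean difference against a reference method (default
`CLMM-Bootstrap`), overall and stratified by $\rho$ and by family. Paired
t intervals use #scenarios − 1 degrees of freedom; a zero-variance
difference yields a degenerate interval that is flagged rather than
silently widened.

## Problem sizes used by the shipped checks

The package's calibration checks are sized for a single CPU: 1000
replicates for the PIM band (matching the band's definition), 500 for the
CLMM and bootstrap calibrations with $B = 200$ bootstrap resamples, 500
replicates with $B = 100$ for the power-ordering comparison, and $10^5$
observations per cell for simulator fidelity. These sizes give Monte-Carlo
standard errors of about 0.7–1 percentage point on rejection rates, small
enough to resolve the effects being checked. The acceptance script runs a
slightly smaller replication of the same pipeline end to end.

## Known limitations

* Complete cases only; no dropout or missingness mechanisms.
* One ordinal item at a time; no multi-item composites or between-item
  weighting.
* Random intercepts only — no random slopes and no serial correlation
  structure beyond exchangeability.
* The probabilistic index is reported conditionally (at equal covariate
  values), not marginalised over the baseline distribution.
* The bootstrap test inherits the parametric assumptions of the fitted null
  (proportional odds, normal random effects); when the generator departs
  from them, its calibration — excellent here — is not guaranteed.
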