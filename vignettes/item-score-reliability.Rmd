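---
title: "Estimating the reliability of a single item score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the reliability of a single item score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itemrel)
```

## The estimand

Classical test theory writes an observed score as a true score plus random
error. For a test score $X = \sum_{i=1}^J X_i$ the reliability
$\rho_{XX'} = \sigma^2_T / \sigma^2_X$ is routine; this package targets the
same quantity for a *single item*,

$$
\rho_{ii'} \;=\; \frac{\sigma^2_{T_i}}{\sigma^2_{X_i}}
\;=\; \frac{\sum_{x=1}^m \sum_{y=1}^m
  \bigl[\pi_{x(i),y(i')} - \pi_{x(i)}\pi_{y(i)}\bigr]}{\sigma^2_{X_i}},
$$

where $\pi_{x(i)} = P(X_i \ge x)$ is a marginal cumulative probability and
$\pi_{x(i),y(i')} = P(X_i \ge x,\, X_{i'} \ge y)$ refers to two
*independent repetitions* of the same item. Item-score reliability matters
whenever one item has to carry measurement on its own — single-item scales
for job satisfaction or quality of life, item selection, person-fit
diagnostics.

The joint cumulative probabilities over repetitions are unobservable from a
single administration; every estimator in the package is a different
approximation $\tilde\pi_{x(i),y(i')}$ plugged into the formula above
(`reliability_from_approximation()`), except method CA, which reasons
through correlations instead.

Estimates are **never clipped** to $[0, 1]$: the bias/variability study is
about the raw sampling distribution, and values outside the unit interval
are informative.

## The four methods

**Method MS** (`ms_reliability()`). The $Jm$ item steps $(i, x)$ are sorted
by ascending $\pi_{x(i)}$ and the joint cumulative probabilities are laid
out in the ordered $Jm \times Jm$ "P(++)" matrix, whose same-item cells are
the unobservable targets. Under the double monotonicity model
(unidimensionality, local independence, monotone nonintersecting response
functions) rows and columns of this matrix are nondecreasing, so
neighboring observable cells approximate an unobservable one. For each
target cell the nearest observable entry in each of the four directions
(skipping other unobservable cells) contributes two candidate estimates:
a proportional rescaling within P(++), $\hat p = p_{\text{nb}} \cdot
\pi_{\text{target}} / \pi_{\text{nb}}$, and the analogous rescaling within
the complement matrix $P(X_i < x, X_j < y)$ mapped back — at most eight
candidates, averaged, then clipped to the interval between the
independence value $\pi_{x(i)}\pi_{y(i)}$ and the Fréchet upper bound
$\min(\pi_{x(i)}, \pi_{y(i)})$. Steps with marginal 0 or 1 are excluded;
their contribution to the numerator is identically zero. Ties among
marginals are pooled and averaged as tie sets. The scheme was locked, cell
by cell, against the test-score implementation in the `mokken` package
(25 random data sets, dichotomous and polytomous, with ties and unendorsed
categories, agreement to $10^{-10}$); the frozen comparison values live in
the test suite. The candidate generator is isolated in `ms_candidates()`
so the scheme can be audited in one place.

**Method λ6** (`lambda6_reliability()`). The squared multiple correlation
of item $i$ regressed on the other $J-1$ items:
$\lambda_{6i} = \sigma_i' \Sigma_{ii}^{-1} \sigma_i / \sigma^2_{X_i}$.
It fits the same framework through
$\tilde\pi^{\lambda6}_{x(i),y(i')} = \sigma_i'\Sigma_{ii}^{-1}\sigma_i/m^2
+ \pi_{x(i)}\pi_{y(i)}$, and the implementation verifies at run time that
the two routes agree to near machine precision. Since an item's true score
is generally not a linear function of the other items', the regression
residual overstates error variance: λ6 behaves as a lower bound and is
conservative everywhere in the study below. A near-singular $\Sigma_{ii}$
(reciprocal condition number below $10^{-12}$) raises a collinearity error
rather than silently pseudo-inverting, which would change the estimand.

**Method LCRC** (`lcrc_reliability()`). Fit an unconstrained latent class
model $P(X_1 = x_1, \dots, X_J = x_J) = \sum_k P(\xi = k) \prod_j
P(X_j = x_j \mid \xi = k)$ by EM, then use the model's own conditional
independence to build the repetition table:
$\tilde\pi^{LCRC}_{x(i),y(i')} = \sum_{u \ge x}\sum_{v \ge y}\sum_k
P(\xi = k) P(X_i = u \mid \xi = k) P(X_i = v \mid \xi = k)$. EM details
(the source text leaves them open): uniform Dirichlet random starts for
weights and response rows, convergence on relative log-likelihood change
$< 10^{-8}$ or 2000 iterations, default 25 starts, best final
log-likelihood wins; label switching needs no correction because the
assembly is invariant to class permutation; unobserved categories keep
probability 0 (the MLE — no smoothing). The number of classes $K$ is a
required user choice or `"bic"` (smallest BIC over $1..K_{\max}$, default
5). This choice is *logged in the report settings* because it drives the
answer: two models can fit the margins perfectly and still imply very
different reliabilities — the two-class model with weights (.4, .6) and
response probabilities (.5, .8) and the three-class model with weights
(.4, .3, .3) and probabilities (.5, .6, 1.0) both give
$\hat\pi_{1(i)} = .68$, yet $\hat\rho_{ii'} = .099$ versus $.210$:

```{r table5}
m2 <- latent_class_model(c(.4, .6), matrix(c(.5, .8), 1, 2))
m3 <- latent_class_model(c(.4, .3, .3), matrix(c(.5, .6, 1), 1, 3))
c(marginal = lcm_marginal(m2, 1), joint = lcrc_joint_approx(m2, 1)[1, 1],
  rho = round(lcrc_model_reliability(m2, 1), 3))
c(marginal = lcm_marginal(m3, 1), joint = lcrc_joint_approx(m3, 1)[1, 1],
  rho = round(lcrc_model_reliability(m3, 1), 3))
```

**Method CA** (`ca_reliability()`). Correct the item-criterion correlation
for the criterion's unreliability:
$\tilde\rho^{CA}_{ii'} = \rho^2_{X_i Y} / \alpha_Y$, assuming the two true
scores correlate 1. The default criterion is the rest score
$R(i) = X - X_i$ with $\alpha_Y$ computed on the $J-1$ remaining items; an
external criterion with user-supplied reliability is available for the
classic single-item use case. CA is exact when all items are essentially
τ-equivalent, and can exceed 1 in samples (reported as is).

## The simulator and what a green test establishes

`simulate_grm()` draws from the multidimensional graded response model
$P(X_i \ge x \mid \theta) = \text{logit}^{-1}\!\bigl(\sum_q \alpha_{iq}
(\theta_q - \delta_{ix})\bigr)$ with $\theta$ multivariate standard
normal. The six presets are the study's stated world, not tuning knobs:

| preset | deviation from `standard` |
|---|---|
| `standard` | $J=6$ dichotomous items, $Q=1$, $\alpha_i = 1$, $\delta$ equidistant $-1.5..1.5$, $N=1000$ |
| `polytomous` | $m = 4$, the four-column location grid |
| `unequal_alpha` | $\alpha$ alternating $0.5 / 2$ (intersecting response functions) |
| `two_dim` | $Q = 2$, loadings alternating dimensions, $\text{cor}(\theta_1,\theta_2) = .5$ |
| `long_test` | the six standard items appearing three times, $J = 18$ |
| `small_n` | $N = 200$ |

Scores are drawn with a single uniform per person-item against the nested
cumulative probabilities (a valid multinomial draw that also makes runs
bit-reproducible). The population reliability oracle
(`population_item_reliability()`) follows the stated recipe literally:
$T_i = \sum_x P(X_i \ge x \mid \theta)$ per simulee, $\text{Var}(T_i)$
divided by the variance of the *sampled* scores, one million simulees.
Across the four parameterized conditions the per-item values span
$[.05, .41]$.

The generator emulates logistic, conditionally independent, normally
distributed-trait response behavior. Real data bring unmodeled features —
guessing, local dependence, non-normal traits, missing responses — so a
green simulation test establishes correctness of the estimators *under the
model*, not robustness in the field.

`run_study()` replicates simulate–estimate–difference loops and pools
$s_r - \rho_{ii'}$ across items and replications; `summarize_differences()`
reports median bias, IQR and the percentage of points beyond 1.5 IQR from
the quartiles, under either Tukey hinges (the boxplot convention, default)
or linear-interpolation quantiles — outlier percentages are sensitive to
the convention, which is why both are exposed. Estimation failures inside
a replication are logged and counted, never silently dropped. Seeds: one
master seed, deterministic child streams per condition/replication, all
below $2^{31}$.

## Numerical choices

* Variances and covariances use denominator $N-1$ throughout. (The mokken
  test-score MS divides by the population-variance convention instead; the
  difference is $O(1/N)$ and the cross-implementation check accounts for
  it.)
* Tie-breaking in the item-step ordering is a stable sort with ties broken
  by item index then descending score category; configurable
  (`"item_asc_score"` reproduces the mokken ordering).
* Monotonicity violations of the sample P(++) matrix are counted and
  reported (`n_monotonicity_violations`), never corrected — the source
  model predicts monotone rows/columns but prescribes no remedy for sample
  violations.
* A P(++) cell with no available candidate (possible only in pathological
  tiny inputs) falls back to the independence value with a warning.
* EM log-likelihoods are computed with a log-sum-exp guard; the trace is
  kept and asserted nondecreasing in the tests.

## Known limitations and open findings

Two documented claims of the source study do not reproduce in this
implementation and are left as *failing* acceptance tests rather than
weakened:

1. **λ6 in the long test.** The claim that every method's IQR shrinks when
   $J$ grows from 6 to 18 holds here for MS and CA but not λ6: at full
   scale (R = 1000) λ6's pooled IQR is .0260 in the long test against
   .0221 in the standard condition, under both quartile conventions. At
   $J=18$ λ6 is far less biased (−.029 vs −.084) and the 17-predictor
   regression adds sampling noise; a .003 IQR difference is invisible in a
   boxplot, which is the form the original evidence takes.
2. **The LCRC outlier rate (6.4%).** The rate is extremely sensitive to
   how $K$ is chosen, which the source does not state. With BIC selection
   the fitted models are parsimonious and produce ≈ 0.5–1% outliers; with
   the reference implementation's default $K = J - 1 = 5$ they overfit and
   produce ≈ 9–10% plus a positive median bias. Both variants are computed
   in the acceptance test; neither lands on 6.4 ± 1.5 and choosing $K$ to
   hit the target would be tuning, so the test stays red.

Other limitations: no missing-data handling (inputs are rejected, not
imputed); one shared $m$ across items; no constrained/ordinal latent class
variants; no formal tests of double monotonicity; Heywood-style negative
true-score variances in λ6 are reported, not corrected.
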