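---
title: "Interval methods and sample-size planning for the agreement ICC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval methods and sample-size planning for the agreement ICC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iccagree)
```

## The model and the two coefficients

A reliability study in which each of $n$ participants is scored once by the
same $k$ raters is modelled by the balanced two-way random-effects ANOVA
without interaction,
$$y_{ij} = \mu + s_i + r_j + e_{ij},\qquad
  s_i \sim N(0,\sigma_s^2),\; r_j \sim N(0,\sigma_r^2),\;
  e_{ij} \sim N(0,\sigma_e^2),$$
all effects independent.  Rater effects are random because the inference is
meant to generalize to the population of raters.  With one observation per
cell the participant-by-rater interaction is not estimable and is absorbed
into the error.

The **ICC for agreement**
$$\rho = \frac{\sigma_s^2}{\sigma_s^2 + \sigma_r^2 + \sigma_e^2}$$
charges systematic rater differences ($\sigma_r^2$) against reliability and
is the coefficient of interest when the measured values themselves matter
(diagnosis, monitoring).  The **ICC for consistency**
$\rho_c = \sigma_s^2/(\sigma_s^2+\sigma_e^2)$ ignores rater shifts and only
reflects rank ordering; it is never smaller.  The package estimates both
(`icc_agreement()`, `icc_consistency()`) from the three mean squares MSS,
MSR, MSE, which under the model are independent scaled chi-squares with
expectations $k\sigma_s^2+\sigma_e^2$, $n\sigma_r^2+\sigma_e^2$ and
$\sigma_e^2$.

Two parameters govern everything downstream: the planned $\rho$ itself and
the **rater-to-error variance ratio** $R = \sigma_r^2/\sigma_e^2$, the key
nuisance parameter.  Empirically $R \le 1$ in most published reliability
studies, but interval performance degrades sharply as $R$ grows.

Point estimation inverts the expected mean squares
(`variance_components()`); negative moment estimates of $\sigma_s^2$ and
$\sigma_r^2$ are truncated at zero with a recorded flag, while the
untruncated values are retained for diagnostics.  The point estimate
$\hat\rho$ is *not* clipped to $[0,1]$: the interval methods differ in how
they treat the boundary, so clipping is a per-method decision.

## The seven interval methods

* **Wlog** (`ci_wlog`): delta-method variance of $\log\hat\rho$, Wald
  limits on the log scale, exponentiated.  Undefined when
  $\hat\rho \le 0$; the upper limit may exceed 1 (reported as computed).
* **Wmat** (`ci_wmat`): delta method applied to the matrix form of
  $\hat\rho$ built from $1'S1$, $\mathrm{tr}\,S$ and the rater-mean
  deviations $y_d'y_d$; limits use a $t_{n+1}$ reference distribution —
  an unusual choice, implemented as stated by its authors.
* **MLSA** (`ci_mlsa`): closed-form modified-large-sample limits for the
  monotone transformation $k\rho/(n(1-\rho))$, mapped back with
  $\max(0,\cdot)$ clamping; limits in $[0,1]$.
* **MLSG** (`ci_mlsg`): Fieller-type modified-large-sample interval (see
  the design notes below); limits in $[0,1]$ and the interval always
  contains $\hat\rho$.
* **GCI** (`ci_gci`): generalized confidence interval from the empirical
  quantiles of a generalized pivotal quantity, simulated by substituting
  fresh chi-squares for the sampling distributions of the observed mean
  squares.  Draws live in $[0,1)$.
* **VPF** (`ci_vpf`): variance-partitioning F interval; Satterthwaite
  chi-square approximations for $\hat\sigma_s^2$ and
  $\hat\sigma_E^2 = \hat\sigma_r^2+\hat\sigma_e^2$ give a scaled-F law for
  $\hat\rho$.  The estimated numerator degrees of freedom are floored at 1.
* **VPB** (`ci_vpb`): beta approximation to the distribution of
  $\hat\rho$ with moment-matched parameters and the two documented
  boundary fixes (U-shape conversion to J-shape; pinned parameters when
  the variance exceeds $\hat\rho(1-\hat\rho)$).

Defaults everywhere: two-sided intervals, $\alpha = 0.05$.

### Design notes and numerical choices

**MLSG construction.** The originating literature gives this interval only
through an appendix of elaborate closed-form expressions that are not
reproduced here.  We therefore implement the construction from first
principles: $\rho \ge \lambda$ exactly when
$W(\lambda) = n(1-\lambda)\theta_1 - \lambda k\theta_2 -
(n+\lambda(nk-n-k))\theta_3 \ge 0$, where $\theta$ are the expected mean
squares; Graybill–Wang modified-large-sample one-sided bounds on
$W(\lambda)$ (exact in the limiting cases of each variance component,
with the standard cross-product constants) are root-solved in $\lambda$
by bisection to $2^{-30}$.  The resulting interval reproduces the
published coverage behaviour of the method (over-coverage between 0.96
and 0.98 for $R=0.1$, $k\le 5$; near-nominal elsewhere) and its width
tracks the generalized interval through the $n \le 100$ study range.  In
the flat region of the width-versus-$n$ curve its widths run two to four
percent above the original closed form, which a width-targeted sample
size search amplifies; sample sizes derived from MLSG in that regime are
accordingly somewhat conservative.

**Wmat variance.** The published rendering of the matrix-form variance is
typographically ambiguous; we re-derived the delta-method expression from
the stated covariance matrix of $(1'S1, \mathrm{tr}\,S, y_d'y_d)$ (whose
entries use the $n+1$ and $k+1$ denominators of that construction).  The
resulting rater-mean term is
$2k^2\hat\rho^4(y_d'y_d)^2/\big((k+1)(1'S1-\mathrm{tr}S)^2\big)$.

**VPF covariances.** The component variances feeding the Satterthwaite
degrees of freedom exclude estimator covariance terms (the F method is
known to work better without them); the beta method's variance includes
them.  Both choices are switchable (`include_cov`).

**GCI quantile rule.** Inverse empirical CDF: the order statistic at
$\lceil qM\rceil$.  With a fixed `rng_seed` intervals are bit-for-bit
reproducible; at $M = 10^5$ draws independent runs agree to about
$\pm 0.002$.  $M = 10^5$ or more is recommended for final analyses
(harness defaults use $10^4$ inside replication loops).

**Beta-fix tie.** The published fixes split at $\hat\rho$ less or greater
than one half; $\hat\rho = 0.5$ is assigned to the lower branch,
consistent with the fix for nonpositive parameter estimates which is
stated with "$\le$".

**Undefined methods.** Wlog and VPB raise a classed condition
(`icc_method_undefined_error`) for nonpositive estimates rather than
returning an arbitrary interval; the evaluation harness records such
replicates in an `error_rate` and excludes them from coverage and width
summaries (they are rare for $\rho \ge 0.7$).

## The synthetic-data generator

`simulation_config()` fixes $\sigma_e^2 = 1$, sets $\sigma_r^2 = R$, and
derives $\sigma_s^2 = \rho(R+1)/(1-\rho)$ so that the generated data have
agreement ICC exactly $\rho$; `simulate_dataset()` draws the three normal
effect vectors and returns the complete $n\times k$ table (grand mean 0 —
the ICC is location- and scale-free, which the tests verify).
`simulate_mean_squares()` draws (MSS, MSR, MSE) directly from their exact
scaled chi-square joint law; because the mean squares are the sufficient
statistics for every method that consumes them, the two routes are
distributionally identical, and the test suite asserts their agreement.
The width and sample-size machinery uses the sufficient-statistic route
for speed.

The generator emulates exactly the assumptions of the model: normal,
homoscedastic, independent effects and a complete balanced design.  Real
ratings data can violate every one of these (skewed scales, rater-specific
variances, missingness); passing tests therefore certify correctness of
the methods *under the model*, not robustness to violations.  The methods
with the best model-based coverage are known not to be robust to
non-normality.

## Evaluating the methods

`evaluate_methods()` replicates the study design: per replicate one
dataset, all requested intervals, identical data across methods (paired
comparison); it reports empirical coverage of the true $\rho$ and average
width.  `classify_coverage_band()` encodes the distance-from-nominal bands
used to grade methods (within 0.01 of 0.95 is best; more than 0.05 off is
worst).  The headline patterns the acceptance tests reproduce at reduced
scale: the generalized interval holds between 0.94 and 0.96 everywhere in
the design grid; Wald-type and variance-partitioning intervals undercover
badly as $R$ grows (VPF falls below 0.90 at $R=2$); MLSA over-covers; and
width falls with $k$ and with $\rho$ but grows with $R$.  At
$(\rho{=}0.7, R{=}0.1, k{=}2, n{=}40)$ the generalized interval is about
twice as wide as the F interval.

## Sample-size determination by expected width

Both procedures search the smallest $n$ (or $k$) whose *expected* interval
width falls strictly below a target $\omega$ at planning values
$(\rho, R)$:

* **Purely simulation-based search** (`find_n_bisection`): the expected
  width of a closed-form interval (VPF, MLSG, MLSA) is averaged over
  $M = 10^4$ simulated replicates per candidate; a doubling bracket plus
  integer bisection finds the minimum over $[6, 500]$ by default.
* **Variance-reduced procedure** (`sample_size_dobbin_ionan`), for MLSA
  and GCI, searching $[6, 10^7]$ in a single bisection pass and meant to
  be repeated (default 100 times) with the mean of the per-repeat minima
  as the planning value:
  * the **MLSA width estimator** (`mlsa_width_estimator`, $10^5$ draws by
    default) uses dependent conditioning: the limits depend on the data
    only through $X_{SE} = \frac{MSS/(k\sigma_s^2+\sigma_e^2)}{MSE/\sigma_e^2}
    \sim F_{n-1,(n-1)(k-1)}$ and a dependent companion ratio $X_{RE}$;
    $x_{SE}$ is drawn from its marginal and the remaining randomness from
    its exact conditional law (the shared error chi-square given
    $x_{SE}$ is Gamma with shape $(\nu_1+\nu_3)/2$ and rate
    $(1+x\nu_1/\nu_3)/2$), the numeric route to the conditional expected
    limits;
  * the **GCI width estimator** (`gci_width_rb`, $10^3$ draws by default)
    uses inverse Rao-Blackwellization — with Monte Carlo pairs of the
    participant and error chi-squares, the conditional pivot CDF over the
    remaining rater chi-square is available in closed form (the rater
    term is a scaled inverse Gamma), and quantiles come from inverting
    the averaged conditional CDF — followed by a control-variate
    adjustment on $MSR/MSS$, whose exact moments
    (`ratio_moments`; $MSR/MSS$ is a scaled $F_{k-1,n-1}$, so the leading
    ratio is squared in the variance) are known.  The control variate's
    linear relationship with the limits is an approximation recommended
    for planned $\rho > 0.7$.  The adjustment removes most across-replicate
    spread; the residual repeat-to-repeat variability of the returned
    sample size stems from the Monte Carlo pairs shared within a search,
    which is why the procedure is repeated and summarized by mean and sd.

**Common random numbers.**  Within one search repeat every candidate size
reuses the same underlying uniform draws (transformed by the appropriate
quantile functions), so the empirical width is monotone in $n$ and the
bisection is well defined; the returned $n^\*$ provably passes the width
criterion while $n^\*-1$ fails it under the same draws.  How the original
procedures handled search noise is not documented; this is our choice.

**Feasibility.**  Because MSR keeps only $k-1$ degrees of freedom however
large $n$ grows, the expected width has a positive large-$n$ limit
whenever $R > 0$.  `asymptotic_width()` evaluates the width along an
increasing schedule ($10^3, 10^4, 10^5$ by default) with common random
numbers and requires stabilization within 0.005; searches are pre-checked
against it and report `feasible = FALSE` when $\omega$ is unattainable.
A caveat worth knowing: the large-$n$ limits of the MLSA and GCI
intervals coincide analytically — both reduce to
$\sigma_s^2/(\sigma_s^2+\sigma_e^2+\sigma_r^2 C_2/\chi^2_{k-1}(q))$
averaged over the data's rater chi-square $C_2$ — so the two methods'
reported asymptotic widths converge to the same number (for
$\rho{=}0.7, R{=}2, k{=}5$: 0.458 by quadrature of that limit, matching
the schedule-based evaluation at $n\le 10^5$ for MLSA).  Finite-$n$
evaluations of GCI approach this limit from below more slowly than the
$10^3$–$10^5$ schedule resolves.

**Strictness and limits.**  Width comparisons use strict "$< \omega$";
$n_{\min} = 6$ keeps every degree of freedom positive and the
control-variate variance finite ($n > 5$); caps default to 500
(simulation-based search) and $10^7$ (variance-reduced search).

## Problem sizes in the tests

The shipped test suite runs the full logic at reduced Monte Carlo scale,
chosen so that a binomial standard error still resolves the coverage
bands: 2 000–3 000 replicates per coverage point (SE about 0.004–0.005),
$5\cdot10^3$–$10^4$ pivot draws per generalized interval inside loops,
20 repeats for the MLSA sample-size searches and 3–10 for the GCI ones
(the tolerance there is the published repeat sd).  The acceptance script
uses the same sizes.  These are package choices balancing resolution
against desk-scale runtimes; all are arguments, so full-scale replication
($10^5$ replicates, 100 repeats) is a matter of larger values.

## Known limitations

* Complete balanced designs only; no missing cells, no unbalanced or
  incomplete blocks.
* No interaction term (not estimable with one score per cell), no fixed
  rater model, no REML/ML iterative estimation, no one-way designs.
* Normality and homoscedasticity are assumed throughout; no
  non-parametric fallback.
* One-sided intervals and assurance-probability sample sizing are out of
  scope.
* MLSG sample sizes in near-infeasible regimes are conservative (see the
  design note above).
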