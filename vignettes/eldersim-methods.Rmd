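---
title: "eldersim: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{eldersim: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eldersim)
```

`eldersim` turns the mathematical skeleton of a smart elder-care service
platform into executable, testable code. This vignette is the package's own
account of what it computes, which conventions it had to choose where the
underlying model family leaves things open, and what its green test suite
does and does not establish.

## 1. Health-state dynamics

The health of one individual is a scalar index $H(t)$, dimensionless and
standardised; we recommend interpreting values in roughly $[-3, 3]$ but the
package never clamps. Two model variants are exposed side by side, not
merged, because they embody different assumptions:

**Linear driver model** (`health_derivative_linear()`):
$$\frac{dH}{dt} = \alpha_1 S(t) + \alpha_2 P(t) + \alpha_3 E(t) - \beta C(t).$$
The derivative does not depend on $H$: there is no mean reversion, and with
a constant net drive the trajectory is the straight line $H_0 + gt$, drifting
without bound. That is a real property of the model, preserved literally and
used as a closed-form test oracle; users who need saturation should use the
closed-loop variant.

**Environment-suppressed resource model** (`health_derivative_env()`):
$$\frac{dH}{dt} = \frac{\alpha R_h(t)}{1 + \kappa E(t)} - \beta C(t),$$
where $\kappa \ge 0$ is the environmental inhibition coefficient: the worse
the environment, the smaller the health return on allocated resources. The
denominator must stay positive; inadmissible $E$ raises an error naming the
offending time point rather than returning a sign-flipped derivative.

### Closed-loop coupling

In closed loop the resources and the cost are recomputed at every integrator
evaluation from two feedback laws:

* logistic allocation $R_h = \lambda\,\sigma(\gamma H)$
  (`logistic_allocation()`), and
* social-capital cost $C = C_0\!\left(1 - \dfrac{\delta S_c}{1 + \eta R_m}\right)$
  (`behavior_cost()`).

The model family never states which observable signals feed $S_c$ and $R_m$
when the loop is closed. The package convention is: $S_c(t)$ is the social
support channel `S`, and $R_m(t)$ is the exogenous resource channel `R_exo`
(zero when absent). This is a convention, not a claim about the model.

### The sign of $\gamma$

As printed, $R_h = \lambda e^{\gamma H}/(1+e^{\gamma H})$ with $\gamma > 0$
gives *more* resources at *higher* health. The narrative intent — support the
frail — corresponds to $\gamma < 0$. The formula is implemented literally and
the sign is configuration; every shipped scenario configuration uses
$\gamma = -1$, which also makes the closed-loop equilibrium attracting
(negative feedback). `find_equilibrium()` returns
$H^* = \mathrm{logit}(q)/\gamma$ with
$q = \beta C (1+\kappa E)/(\alpha\lambda)$, and `NA` when $q \notin (0,1)$
(the sigmoid cannot balance the cost).

### Integration and calibration

The default integrator is fixed-step classical RK4 with one step per grid
interval: deterministic, reproducible, and accurate to $\ll 10^{-6}$ at step
0.1 for the smooth right-hand sides at hand. An adaptive step-doubling RK4
with Richardson extrapolation (`method = "adaptive"`) serves as the
independent high-accuracy reference in the test suite; it shares no code
path with the fixed-step route beyond the single-step kernel.

`calibrate_linear()` recovers $(\alpha_1,\alpha_2,\alpha_3,\beta)$ by
ordinary least squares of finite-difference derivatives (central in the
interior, one-sided at the ends) on the regressor matrix $[S, P, E, -C]$.
Rank-deficient regressors (e.g. constant drivers) raise an identifiability
error instead of returning arbitrary coefficients; the condition number and
residual RMS are reported. Derivative noise is the caller's concern: an
optional moving-average smoother exists but is off by default, because
silent smoothing would bias recovered gains.

## 2. Allocation

Utility of giving $R$ resources to individual $i$ is the saturating form
$U_i(R) = a_i R^{\theta_i}/(1 + b_i R^{\delta_i})$. It is *not* concave for
all exponent choices; `check_diminishing_returns()` verifies numerically
that marginal utility is non-increasing over the range of interest.
`allocate_budget()` then solves
$\max \sum_i U_i(R_i)$ s.t. $\sum_i R_i \le B$, $R_i \ge 0$:

* **Concave mode** (all individuals pass the check): bisection on the shared
  Lagrange multiplier $\mu$, inverting each individual's analytic marginal
  utility by root bracketing. KKT residuals are reported; at an interior
  optimum all marginal utilities equal $\mu$ to $10^{-5}$ or better.
  Identical individuals receive identical shares (the bisection is
  deterministic and symmetric, which also settles degenerate ties).
* **Non-concave fallback**: best of 20 seeded Nelder–Mead starts on
  projected feasible points, flagged `non_concave = TRUE`. No global
  optimality is claimed — the test suite only checks feasibility and
  dominance over random feasible points.

A floating-point detail worth recording: `logistic_allocation()` computes
the minority side of the sigmoid from $e^{-|\gamma H|}$ and quantises it to
a multiple of $\mathrm{ulp}(\lambda)$, which makes the symmetry
$R(H)+R(-H)=\lambda$ *bitwise exact* for $|\gamma H| \lesssim 36$; the cost
is precision loss confined to the far tail (below $\lambda 2^{-53}$), where
an open-interval clamp keeps the output strictly inside $(0, \lambda)$ up to
at least $|\gamma H| = 10^4$.

## 3. Economics

`total_benefit()` and `total_cost()` are exact weighted sums; weights are
not forced to sum to one (`normalize_weights()` exists but is never applied
implicitly). `cbr()` refuses non-positive weighted cost rather than emitting
`Inf`. Admissibility of the cost model ($\delta S_c/(1+\eta R_m) \le 1$) is
enforced at evaluation, not clamped: a negative behaviour cost indicates
misconfigured parameters and should fail loudly.

How the health benefit $E_h(T)$ is measured from a trajectory is not part
of the model family; the helper `health_benefit_from_trajectory()` adopts
the convention $E_h = \mathrm{mean}(H) - H_0$ and is documented as such.

## 4. Monitoring

**Gap imputation.** Short missing runs (at most `max_gap` points, default 5)
are filled with the posterior mean of a squared-exponential-kernel Gaussian
process conditioned on all observed points. Hyperparameters are fixed by
policy, not optimised: length-scale from `kernel_scale`, signal variance
equal to the sample variance of the observed points, observation noise
`noise_sd`, plus a $10^{-10}$ relative jitter for Cholesky stability.
Marginal-likelihood optimisation is a possible extension, deliberately left
out for desk-scale reproducibility. Long gaps are never invented: they stay
masked and are returned in a `long_gaps` table. Observed points pass through
bitwise unchanged.

**Emergency rule.** The alert rule is a strict conjunction: a significant
activity *drop* and heart-rate *rise* must occur simultaneously.
"Significant" is quantified as a windowed z-statistic: for each sliding
window of `window` points (default 12), the window mean is standardised
against the mean and standard deviation of the `baseline_window` points
(default 48) ending immediately *before* the window. Two design points
matter here:

* Averaging over the window, rather than testing single points, is what
  makes the default thresholds ($z \le -2$ and $z \ge +2$) operate at a
  practically zero false-alarm rate: two independent pointwise $|z|=2$
  exceedances co-occur about $5\times10^{-4}$ per grid point, far above any
  tolerable alarm budget, while the windowed mean has null standard
  deviation $\approx 1/\sqrt{12}$.
* Ending the baseline before the window (not before each point) prevents an
  ongoing event from contaminating its own baseline, which would otherwise
  roughly halve the effective z during the event.

Qualifying window positions closer than `window/2` apart merge into one
alert event; severity counts the escalation thresholds reached by the
maximum absolute windowed z. Note that the *count of merged events* is not
monotone in the thresholds (two events can fuse when thresholds relax); the
count of qualifying window positions is, and is exposed as the
`n_qualifying` attribute for exactly that reason. The pointwise
`rolling_zscores()` (trailing per-point baseline) remains available as the
elementary operation.

## 5. The synthetic world

`generate_population()` draws per-individual parameters from truncated
normal priors and simulates each individual under the linear driver model
with constant personal drivers (the closed form $H_0 + gt$ — exact, fast,
and sufficient for directional contrasts). Six scenarios ship with the
package, with the per-arm sample sizes of the emulated study design:
urban/rural (500 per arm), income (500), active/sedentary lifestyle (500),
diet (3 arms of 300), social activity (3 arms of 400), pollution (500).

The study design being emulated states only *directions* of contrast
(e.g. sedentary individuals fare worse), never effect sizes. The package
fixes the default effect at **0.5 prior standard deviations** on the
relevant parameters and maps qualitative risk factors onto model quantities
through a small dictionary (e.g. urban: larger $\beta$, less favourable
environment; active: larger $\alpha$ gains; low income: larger $\beta$,
lower $H_0$). In the generator, `E_env` is an environmental *favourability*
index (higher is better), consistent with its non-negative gain $\alpha_3$
in the linear model. All directions and magnitudes are configuration, and
the generator refuses inadmissible prior ranges before drawing anything.

Reproducibility: every generator is a pure function of `(spec, seed)`. A
global seed is split into per-stream seeds by hashing the stream label
(`derive_seed()`), so adding a new stream never perturbs existing ones.

What a green test establishes: that the implemented machinery reproduces
its own stated world — closed forms, oracle equivalences, directional
contrasts at the stated sample sizes, determinism. What it does not
establish: anything about real elderly cohorts. The synthetic streams are
Gaussian and stationary outside injected events; real wearable data have
diurnal structure, autocorrelated noise, and non-random missingness, none
of which are modelled.

## 6. Numerical conventions, degenerate inputs, known limitations

* Time is in arbitrary units (documentation uses days); grids must be
  strictly increasing, and dense driver series are interpolated linearly
  with constant extrapolation beyond their ends.
* Budget bisection runs to a relative interval of $10^{-14}$ and caps total
  allocation at the budget; `budget = 0` short-circuits to zero allocations.
* `gamma_sens = 0` is flagged (constant allocation $\lambda/2$) and refused
  by `find_equilibrium()` (no unique root).
* Zero-variance z-score baselines yield `NA` with one warning, never
  division by zero.
* Non-concave utilities get a flagged local search, not a global optimum.
* The linear driver model can drift unboundedly by construction; no
  clamping is applied anywhere.
* The multi-stakeholder game-theoretic extension and any deep-learning
  prediction layer are out of scope; the package is the deterministic /
  stochastic-simulation core only.
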