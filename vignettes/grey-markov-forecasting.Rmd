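---
title: "Grey-Markov forecasting of short count series: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey-Markov forecasting of short count series: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greycast)
```

greycast models annual incidence counts observed only a handful of times —
the regime where a series has four to a dozen points, a rough exponential
trend, and year-to-year fluctuation too strong for the trend alone to
explain. This vignette is the package's account of the underlying models,
of every estimation convention it fixes, and of the design decisions that
were genuinely open.

## The grey modelling idea

All grey models in this package operate on the first-order accumulated
(AGO) series $x^{(1)}(k) = \sum_{p \le k} x^{(0)}(p)$ rather than the raw
counts $x^{(0)}$. Cumulative summation monotonizes and smooths a positive
series; if the raw counts fluctuate around an exponential trend, the AGO
series is close to the solution of a first-order linear ODE, which is what
a grey model fits. Fitted and forecast AGO values are differenced back to
the original scale, and every model anchors its first fitted value at the
first observation, so corrections and errors refer to genuine
out-of-sample-style discrepancies rather than an arbitrary intercept.

The estimation device shared by all model forms is the *background value*
$z(k) = (x^{(1)}(k) + x^{(1)}(k-1))/2$, the adjacent mean that approximates
$\int_{k-1}^{k} x^{(1)}(t)\,dt$ in the discretized ODE. Its error is
$O(a^2)$ in the development coefficient $a$, which is why parameters
recovered from data generated by the exact continuous law carry a small,
deterministic bias (below one percent in the regimes the test suite
exercises, see "Synthetic ground truth" below).

### GM(1,1)

The univariate model is the whitening equation
$dx^{(1)}/dt + a\,x^{(1)} = b$. Least squares on
$x^{(0)}(k) = -a\,z(k) + b$, $k = 2..n$, gives $(a, b)$; the closed-form
solution $\hat x^{(1)}(k) = (x^{(0)}(1) - b/a)\,e^{-a(k-1)} + b/a$ produces
fitted values and forecasts. A development coefficient indistinguishable
from zero (constant trend) is reported as a degenerate-model error rather
than silently returning a near-singular fit.

### MGM(1,n): two forms, one default

With $n$ screened factor series the package offers two model forms.

The **factor-driven form** (default, `coupling = "driven"`) is the
classical multivariate grey convolution model: one whitening equation for
the dependent series with the factor AGO series as forcing terms,
$$\frac{dx_1^{(1)}}{dt} + a\,x_1^{(1)} = \sum_{i} b_i\,x_i^{(1)},$$
estimated by least squares of $x_1^{(0)}(k)$ on
$(-z_1(k),\, x_i^{(1)}(k))$ and fitted through the standard approximate
time-response function with the driver term frozen at each target time.
Out-of-sample forecasts extend each driver's AGO path with its own GM(1,1),
the usual device when future factor values are unknown.

The **coupled form** (`coupling = "coupled"`) promotes all $m = n + 1$
series to states of one affine system $d\tilde X^{(1)}/dt = A \tilde
X^{(1)} + B$. Each row of $[A|B]$ is estimated by least squares of
$x_i^{(0)}(k)$ on all background values plus a constant, and the solution
is evaluated at integer times through the exponential of the augmented
matrix $\left[\begin{smallmatrix}A & B\\ 0 & 0\end{smallmatrix}\right]$ —
no explicit $A^{-1}$, so a singular development matrix degrades gracefully.
The exponent is taken as $A\,(t-1)$, not $A\,t$: with the initial condition
imposed at $k = 1$, the time shift is what makes
$\tilde X^{(1)}(1) = X^{(1)}(1)$ hold exactly.

Why is the driven form the default? Identifiability. Each coupled-row
regression estimates $m + 1$ coefficients from $n - 1$ equations. On a
six-year panel with four factors that is six unknowns per row against five
equations: the least-squares stage is underdetermined, any solution
interpolates the data exactly, and the resulting $A$ typically has large
positive eigenvalues whose matrix exponential explodes within the sample.
The driven form estimates the same number of coefficients ($n + 1$) but
only for the dependent series, stays determined up to $n = 4$ factors on a
six-point panel, and is the form under which the packaged Michigan example
reproduces its reference fitted series. The coupled form remains fully
supported — it is the natural object for the synthetic-recovery tests,
collapses exactly to GM(1,1) at $m = 1$, and is appropriate when the panel
is long relative to the number of series.

When a requested dimension leaves the least-squares stage rank deficient
(the scan below deliberately visits such dimensions), the package solves it
anyway via the SVD pseudoinverse — the minimum-norm solution, flagged with
a classed warning — rather than refusing or inverting singular normal
equations. This choice is deterministic and documented, but results at
such dimensions are convention-dependent by nature and should not be
over-interpreted; on the Michigan panel the scan values at five and six
factors depend entirely on this convention while the selected dimension
does not.

## Grey relational screening

Factors enter the model in descending order of the Deng relational grade,
computed on dimensionless curves. Two conventions needed fixing:

* **Normalization.** Initial-value scaling (each series divided by its
  first element) is the default; mean scaling is available. Both remove
  scale, making grades invariant to multiplying any raw series by a
  positive constant (a tested property). Initial-value scaling is the
  convention under which the packaged Michigan example reproduces its
  reference grades (0.7750 for the median-crash factor down to 0.6189 for
  buses/trucks) and ranking; mean scaling produces a different, also
  defensible, ordering — the two agree on which factors are strong but not
  on every rank, which is why the choice is a config field and not a
  hard-coded constant.
* **Two-level extremes.** $\Delta_{min}$ and $\Delta_{max}$ are pooled over
  *all* comparison series jointly, not per factor, and the pointwise
  discrepancy is taken in absolute value — without the absolute value the
  coefficient can leave $(0, 1]$.

The distinguishing coefficient default $\rho = 0.5$ and the screening
threshold 0.7 are the field's conventional values. Ranking ties break by
original column order, keeping output deterministic.

## Markov residual correction

Relative residuals $\delta(k)$ of the selected fit are partitioned into
`n_states` equal-width intervals spanning $[\min\delta, \max\delta]$,
half-open $[L_j, U_j)$ with the last interval closed. The conventions, each
of which was an open choice:

* **Residual denominator**: $(x - \hat x)/x$ (actual) by default. The
  alternative $(x - \hat x)/\hat x$ is kept as `denominator = "fitted"`;
  it has the algebraic property that a midpoint-exact residual is corrected
  back to the actual value exactly (a tested identity), whereas the
  actual-value form recovers it to first order. The actual-value form is
  the one conventionally tabulated for count data and the one under which
  the packaged example reproduces its reference state sequence.
* **Reporting precision** (`round_fitted = TRUE`): fitted counts are
  rounded to integers, half away from zero, before residuals and error
  metrics. Count tables are published as integers; computing residual
  states from the rounded values keeps every intermediate reproducible
  from such a table. The raw real-valued fits are always retained on the
  fitted objects.
* **Transition estimation**: adjacent-pair counts normalized by row; the
  terminal state contributes no source count. A state never visited as a
  source receives a uniform row (with a classed warning) so that matrix
  powers stay row-stochastic. k-step matrices are matrix powers
  (Chapman–Kolmogorov), verified in the tests against a path-enumeration
  oracle.
* **Correction** multiplies every in-sample fitted value — including the
  first — by $1 + (L_j + U_j)/2$ of its state.
* **Forecasting** votes over the last `lookback` (default 3) observed
  states: step $k$ contributes the row of $P^k$ indexed by the state
  observed $k$ periods before the target; the modal state of the summed
  weights wins, ties resolved toward the lower state index with a warning.
  The corrected forecast multiplies a base value by one plus the modal
  state's midpoint. The default base is the last observed actual value
  (`forecast_base = "last_actual"`), which asks the correction to absorb
  one year of change; `"model_forecast"` instead corrects the grey model's
  own horizon-1 projection and is the principled alternative when the
  trend is steep.

With three states on a six-point panel every transition probability is a
dyadic rational (denominators 1, 2, 4, 8), so the test suite compares the
Michigan matrices exactly, with zero tolerance.

## Evaluation

MAPE (percent scale), MAE and RMSE are computed over all $n$ points,
including the anchored (zero-error) first point — the convention under
which a mean over six years matches a table of six printed errors. The
dimension scan fits MGM(1,n) for each candidate $n$ (factors in descending
grade order), records the dependent-series MAPE under the same reporting
convention, and selects the argmin, with failed candidates excluded and
noted. On the packaged example the scan selects four factors.

## Synthetic ground truth

`gen_linear_system_panel()` integrates a known affine system exactly at
integer times (same augmented-exponential code path as the coupled model,
which the tests cross-check against a high-precision ODE integrator),
differences to the original scale, and applies multiplicative lognormal
noise with a chosen coefficient of variation; `gen_gm11_series()` does the
analogue for the univariate law. Noise is multiplicative because counts
are positive and their fluctuation is proportional; additive noise can
produce negative counts at small magnitudes. True matrices are drawn with
spectral radius capped at 0.3 (hard limit 0.5) so the integer-sampling
discretization bias stays well below the 5% recovery tolerance the tests
assert. Draws yielding non-positive counts are rejected and redrawn, with
a bounded retry budget.

The generators emulate the *numerical* regime of short annual count panels
— magnitudes, trend, fluctuation — and nothing mechanistic about any
application domain (no exposure, severity or reporting processes). Passing
recovery tests therefore demonstrate the estimators' correctness on data
that exactly satisfy the model assumptions, not forecasting skill on real
data, where the true dynamics are neither linear nor noise-free.

Test problem sizes were chosen to keep each property cheap and sharp:
systems of two to four variables over eight to ten periods, twenty seeded
replicates per recovery property, and noise levels 0, 0.1 and 0.3 for the
error-monotonicity trend.

## Numerical choices

* All least squares through a rank-revealing SVD; minimum-norm solutions
  for rank-deficient designs, never inverted normal equations.
* Matrix exponentials by scaling-and-squaring (`Matrix::expm`) on the
  augmented matrix; never a truncated Taylor series, never $A^{-1}$.
* State-partition edges are pinned to the exact residual extremes and
  assignment tolerates $10^{-9}$-scale floating-point drift at the
  boundaries, so a maximum residual always lands in the top state.
* Rounding of displayed or reported counts is half away from zero
  (`round_half_up()`); base R's round-half-to-even is never applied to
  counts.
* Values are stored as doubles end to end; integer rounding is a reporting
  step, controlled by one config flag.

## Limitations

* Grey models assume quasi-exponential AGO dynamics; series with structural
  breaks, saturation or seasonality violate this, and no diagnostics beyond
  the error metrics are provided.
* The equal-width state partition inherits the sample's residual extremes;
  with very few points the partition is coarse and the correction can
  overfit the in-sample fluctuation pattern.
* Driven-form forecasts compound two models (the dependent equation and
  per-factor GM(1,1) extensions); their uncertainty is not quantified — the
  package reports point values only.
* Dimensions at which the estimation is underdetermined yield
  convention-dependent fits (documented above); treat scan values there as
  diagnostics, not results.
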