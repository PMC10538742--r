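# greycast

Grey–Markov forecasting for short, fluctuating incidence count series.

Annual counts of rare events — injury crashes at a new road layout,
occupational incidents, disease cases in a small region — often come as
panels of only four to a dozen observations, trending roughly exponentially
but fluctuating strongly from year to year. Classical time-series models
need far more data. Grey-system models were built for exactly this regime:
they smooth a raw series x⁽⁰⁾ into its cumulative (AGO) form
x⁽¹⁾(k) = Σₚ≤ₖ x⁽⁰⁾(p), fit a first-order differential equation on that
near-exponential scale, and difference the continuous solution back to
counts. greycast implements the full multivariate Grey–Markov workflow:

1. **Grey relational analysis** screens candidate factor series by the Deng
   relational grade rᵢ = mean over k of
   ζᵢ(k) = (Δmin + ρ·Δmax) / (|x₁(k) − xᵢ(k)| + ρ·Δmax),
   computed on dimensionless (initial-value normalized) curves with the
   two-level extremes Δmin, Δmax pooled over all factors and the
   distinguishing coefficient ρ = 0.5. Factors with grade below 0.7 are
   dropped.
2. **Grey models.** The GM(1,1) baseline fits
   dx⁽¹⁾/dt + a·x⁽¹⁾ = b to the dependent series alone; the multivariate
   MGM(1,n) jointly uses the top-n screened factors, by default through the
   factor-driven whitening equation
   dx₁⁽¹⁾/dt + a·x₁⁽¹⁾ = Σᵢ bᵢ·xᵢ⁽¹⁾ (a fully coupled system
   dX⁽¹⁾/dt = A·X⁽¹⁾ + B is also provided). Parameters come from least
   squares on adjacent-mean background values; the model dimension n is
   chosen by a MAPE scan.
3. **Markov residual correction.** Relative fitting errors are partitioned
   into equal-width states, a one-step transition matrix is estimated from
   the state sequence, every fitted value is rescaled by one plus its state
   midpoint, and the next period is forecast by voting the k-step
   transition rows of the last few observed states.
4. **Evaluation**: MAPE / MAE / RMSE for GM(1,1), MGM(1,n) and the
   corrected model, with tidy()/glance()/autoplot() methods throughout.

The package ships the Michigan roundabout crash panel (2016–2021, total
crashes plus eight factor series from police-reported crash counts) as its
worked example, together with seedable synthetic generators whose known
ground truth backs the parameter-recovery test suite.

## Worked example

```r
library(greycast)

panel <- michigan_roundabouts()
grey_relate(panel)
#> Grey relational analysis (rho = 0.5, initial normalization)
#>   1. X6   0.7750
#>   2. X3   0.7747
#>   3. X1   0.7683
#>   4. X2   0.7386
#>   5. X5   0.7317
#>   6. X8   0.7167
#>   7. X4   0.6407  (screened out)
#>   8. X7   0.6189  (screened out)
#> kept 6 of 8 factors (threshold 0.7)
```

Crashes in the road median (X6) and sideswipes (X3) track the total most
closely; distracted-driver (X4) and bus/truck (X7) counts fall below the
0.7 screen and are dropped. Fitting the four-factor model and correcting
its residuals:

```r
fit <- fit_mgm(panel, factors = c("X1", "X2", "X3", "X6"))
markov_correct(fit)
#> Markov correction of MGM(1,4) (3 states)
#> state bounds: -0.1013 / -0.0229 / 0.0554 / 0.1338
#> state sequence: S2 S3 S1 S1 S2 S2
#> one-step transition matrix:
#>      [,1] [,2] [,3]
#> [1,] 1/2  1/2    0
#> [2,]   0  1/2  1/2
#> [3,]   1    0   0
#> modal next state: S2; corrected forecast 1758.1 (base 1730)

compare_models(panel)
#> Model comparison
#> # A tibble: 3 × 4
#>   model            mape   mae  rmse
#> 1 GM(1,1)          8.3  128.  177.
#> 2 MGM(1,4)         4.47  68.7 105.
#> 3 MGM(1,4)-Markov  3.02  44.9  51.3
#> selected dimension: 4 factors; corrected forecast 1758
```

Reading the numbers: the univariate GM(1,1) misfits the fluctuating totals
(8.30% mean absolute percentage error); adding the four screened factors
more than halves that (4.47%); the Markov midpoint correction absorbs the
remaining systematic fluctuation (3.02%). The 2022 total is forecast by
multiplying the last observed value (1730) by one plus the modal state's
midpoint, giving ≈ 1758 crashes — a slight expected increase.

A command-line interface over the same functions is installed at
`inst/exec/greycast` (subcommands `gra`, `fit`, `forecast`, `compare`,
`simulate`):

```sh
Rscript inst/exec/greycast compare --input panel.csv --dependent total --out-dir out/
```

See `vignettes/grey-markov-forecasting.Rmd` for the model assumptions,
estimation conventions and design choices.

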