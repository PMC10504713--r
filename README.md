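# greytheta

Small-sample forecasting of annual demographic series with grey system
models, for analysts projecting population structure from short official
statistics (10–20 annual observations) — the regime where ARIMA-style
models have nothing to estimate.

## What it implements

The package centres on **GT-FGM**, a fractional-order grey model with a
Theta/SES residual correction:

1. **r-AGO.** The series $x^{(0)}$ is accumulated at fractional order
   $r$: $x^{(r)}(k) = \sum_{i\le k} C(k-i;\,r)\, x^{(0)}(i)$ with
   generalized binomial weights $C(m;r)=\Gamma(r+m)/(\Gamma(m+1)\Gamma(r))$.
   For $r\in(0,1)$ recent observations get the larger weights
   (new-information priority).
2. **Grey fit.** Background values $z(k)=\tfrac12(x^{(r)}(k)+x^{(r)}(k-1))$
   discretize $\mathrm{d}x/\mathrm{d}t + ax = b$; $(a,b)$ by least
   squares; fitted accumulated values follow
   $\hat x^{(r)}(k+1) = (x^{(0)}(1)-b/a)e^{-ak}+b/a$, restored by the
   inverse accumulation.
3. **Theta line.** $x_\theta(k)=\theta x^{(0)}(k)+(1-\theta)\hat x^{(0)}(k)$
   amplifies the grey residuals by the curvature $\theta \in (1,5]$.
4. **SES.** $\hat x_\theta(k+1)=\alpha x_\theta(k)+(1-\alpha)\hat x_\theta(k)$,
   $\alpha$ chosen on a 0.01 grid by minimizing the in-sample MAE.
5. **Recombination.**
   $\hat y(k)=\frac{\theta-1}{\theta}\hat x^{(0)}(k)+\frac{1}{\theta}\hat x_\theta(k)$.

$r$ and $\theta$ are selected by a seeded particle swarm (canonical
inertia/cognitive/social update, absorbing boundaries). Comparator models
(GM(1,1), plain FGM, grey Verhulst, logistic curve, standalone SES),
MAE/MAPE/RMSE evaluation with accuracy grading, a fit/hold-out benchmark
protocol, and the Shanghai 2006–2020 district panel (16 districts,
totals and 60+ counts, plus the city age-structure table) are included.
See `vignette("gtfgm-methods")` for assumptions, parameter conventions
and limitations.

## Worked example

Jing'an District totals, 2006–2020 (10^4 persons), full pipeline with
optimized hyperparameters:

```r
library(greytheta)
panel <- load_district_panel()
jing  <- panel_series(panel, "Jing'an", "totals")

fit <- gt_fgm(jing, seed = 1, horizon = 10)
fit
#> GT-FGM fit: r = 0.9491, theta = 5, alpha = 1.00
#>   combination weights: 0.8 * grey + 0.2 * smoothed theta line
#>   n = 15, in-sample MAE = 0.2793, MAPE = 0.2868%

fit$grey_fit
#> FGM(1,1) r=0.9491 (continuous form)
#>   a = 0.0169976, b = 97.1289, r = 0.949145
#>   n = 15, in-sample MAPE = 0.301%

round(as.numeric(predict(fit, 10)), 2)   # 2021-2030
#>  [1] 89.62 88.70 87.79 86.87 85.96 85.05 84.15 83.25 82.36 81.47
```

The swarm selects the accumulation order ≈ 0.9491 with a plain-grey
in-sample MAPE of 0.30%, picks the curvature at its admissible boundary
θ = 5, and projects the district's total population to decline from
90.53 (2020) to 81.47 ×10^4 by 2030. Hold-out comparison on the same
series (fit 2006–2016, score 2017–2020):

```r
run_benchmark(jing, 2006:2016, 2017:2020,
              models = c("gtfgm", "gm11", "ses"), seed = 1)
#> Benchmark: fit 2006-2016, test 2017-2020
#>  model block  mae mape rmse     grade
#>  gtfgm   fit 0.21 0.22 0.32 excellent
#>  gtfgm  test 1.46 1.60 1.55 excellent
#>   gm11   fit 0.32 0.33 0.42 excellent
#>   gm11  test 2.56 2.79 2.62 excellent
#>    ses   fit 0.53 0.54 0.66 excellent
#>    ses  test 2.99 3.26 3.21 excellent
```

The combined model roughly halves the four-year-ahead MAPE of GM(1,1)
(1.60% vs 2.79%) and beats flat exponential smoothing by a factor of two.

A thin command-line front end ships at `inst/cli/greytheta.R`
(`fit`, `benchmark`, `forecast-all` subcommands).

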