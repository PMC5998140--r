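# fertresp

Fertilizer response modelling for "3414"-design N–P₂O₅–K₂O field trials in
paddy rice: fit, test, classify, and recommend.

## What it does

Prescription fertilization builds a statistical response surface between
applied nutrient rates and grain yield from a designed field trial, then
reads the recommended rates off that surface. The standard trial is the
"3414" design — N, P₂O₅ and K₂O at four coded levels (0, 0.5, 1, 1.5 × a
locally recommended level-2 rate), 14 treatment combinations.

`fertresp` implements two response surfaces over such trials:

* the **ternary non-structural model** (the package's core),

  Y = A (N₀+N)(P₀+P)(K₀+K) e^(−c₁N − c₂P − c₃K),

  where N₀, P₀, K₀ are soil nutrient supply equivalents (kg/hm²), c₁…c₃
  yield-increase effect coefficients, and A a soil-fertility conversion
  coefficient — estimated by multi-start Levenberg–Marquardt nonlinear
  least squares;

* the classical **ternary quadratic polynomial**
  Y = b₀ + b₁N + b₂P + b₃K + b₄N² + b₅P² + b₆K² + b₇NP + b₈NK + b₉PK,
  estimated by OLS, as the reference model.

Around the fits it provides

* F/R² significance testing (df 6/7 for the non-structural model, 9/4 for
  the quadratic, on the 14 treatment means);
* **typicality classification** — NRSS (not significant), PS (wrong
  coefficient signs), Max (no global maximum; decided for the quadratic
  model by the Hessian's leading principal minors G₁<0, G₂>0, G₃<0), RF
  (recommendation extrapolates beyond the design range), or TYPICAL;
* **recommendations** by the marginal product derivative method: closed
  form N_max = 1/c₁ − N₀ (etc.) for the maximum, and economic rates
  solving N_eco = 1/(c₁ + α/Y_eco) − N₀ by fixed-point iteration, with
  α, β, γ the fertilizer/grain price ratios;
* a **synthetic-trial generator** and parameter-recovery / typicality-rate
  experiments;
* six built-in early-rice trials (two counties × three soil-fertility
  levels) as validation fixtures, and a CLI
  (`inst/cli/fertresp`) wrapping everything: `fit`, `classify`, `batch`,
  `recommend`, `simulate`, `recover`.

## Worked example

```r
library(fertresp)

tr <- builtin_trials()[["Pinghe-low"]]
fit <- fit_tnfm(tr, n_starts = 20, seed = 1)
fit
#> Fertilizer response fit: ternary non-structural model (NLS)
#>   site: Pinghe-low
#> Non-structural fertilizer response parameters:
#>          A         N0         P0         K0         c1         c2         c3
#> 1.1613e-03 1.6328e+02 1.7134e+02 1.3344e+02 3.0042e-03 3.8352e-03 4.3256e-03
#> R^2 = 0.983, F(6,7) = 67.5, P = 0.000

classify_tnfm(fit)
#> Typicality (non-structural model): TYPICAL
#>   significant Y | signs Y | maximum Y | in-range Y (price-free: maximum rates only)

recommend(fit, prices = price_spec(p_n = 4.3, p_p = 5.0, p_k = 5.2, p_y = 2.8))
#> Fertilization recommendation (non-structural model), kg/hm^2:
#>   maximum yield: N 170, P2O5 89, K2O 98 -> 6510 kg/hm^2
#>   economic:      N 145, P2O5 72, K2O 83 -> 6463 kg/hm^2
```

Reading it: the soil in this low-fertility trial supplies the equivalent
of 163 kg/hm² N, 171 kg/hm² P₂O₅ and 133 kg/hm² K₂O; yield peaks at
6510 kg/hm² when 170-89-98 kg/hm² of N-P₂O₅-K₂O are applied, and at the
given market prices the profit-optimal rates drop to 145-72-83. The fit is
highly significant and passes all four typicality gates, so the
recommendation is trustworthy within the design's tested range.

The same trial under the quadratic model (`fit_tpfm`) is also typical
here, but across the six built-in trials the quadratic model loses one
site to non-significance and two to saddle surfaces with no maximum,
while the non-structural model fits all six significantly — the
motivation for the model.

From the shell:

```sh
Rscript inst/cli/fertresp batch --builtin --family both --n-starts 20
```

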