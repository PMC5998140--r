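---
title: "Fertilizer response modelling for 3414 rice trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fertilizer response modelling for 3414 rice trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertresp)
```

## The problem

Metrological (prescription) fertilization for paddy rice rests on fitting a
response surface to the yields of a designed field trial and reading the
recommended N, P~2~O~5~ and K~2~O rates off that surface. The standard
trial layout is the "3414" design: three nutrients at four coded levels
(0, 0.5, 1 and 1.5 times a locally recommended level-2 rate), with 14
informative treatment combinations. The classical surface is the full
ternary quadratic polynomial (here `tpfm_*`),

$$Y = b_0 + b_1 N + b_2 P + b_3 K + b_4 N^2 + b_5 P^2 + b_6 K^2
      + b_7 NP + b_8 NK + b_9 PK,$$

fitted by OLS. In practice a large fraction of quadratic fits are
agronomically unusable — wrong coefficient signs, saddle surfaces with no
maximum, or recommendations extrapolating beyond the tested rates — partly
because the polynomial's symmetric curvature is a misspecification of real
yield response and its regressors are strongly collinear.

The package's central model is the ternary non-structural response surface
(`tnfm_*`),

$$Y = A\,(N_0+N)(P_0+P)(K_0+K)\,e^{-c_1 N - c_2 P - c_3 K},$$

where $N_0, P_0, K_0$ (kg/hm²) are *soil nutrient supply equivalents* —
the soil's intrinsic supply expressed on the fertilizer-rate scale — the
$c_i$ (1/(kg/hm²)) are yield-increase effect coefficients, and $A$ converts
the product of available nutrient supplies into grain yield. The surface is
zero whenever soil supply and applied rate of any one nutrient are both
zero (nutrients are not mutually substitutable), rises to an interior
maximum at

$$N_{\max} = 1/c_1 - N_0, \quad P_{\max} = 1/c_2 - P_0, \quad
  K_{\max} = 1/c_3 - K_0,$$

and declines under over-fertilization. Expanding each exponential factor
to first order and dropping the higher-order products collapses the
surface onto the full quadratic polynomial (`tnfm_to_quadratic()`), so the
quadratic model is a simplified special case; the reverse is not true.

## Estimation

`fit_tpfm()` solves the OLS problem on the 14 treatment *means* by QR
decomposition. The choice of means rather than replicate-level data
follows the published significance tests, which are only consistent with
n = 14 (residual df 4 for 10 coefficients). Replicate standard deviations
are carried for display and simulation only.

`fit_tnfm()` minimizes the residual sum of squares over
$(A, N_0, P_0, K_0, c_1, c_2, c_3)$ by Levenberg–Marquardt
(`minpack.lm::nls.lm`), unconstrained: negative estimates must be
reachable because wrong-sign fits are a recognized, classifiable outcome,
not an error. The objective is multimodal in principle, so the fit is
multi-start: the default start sets $N_0, P_0, K_0$ to the level-2 rates,
$c_i = 1/(2 \times \text{level-2 rate})$ (placing the implied optimum at
the recommended rate) and $A$ so the surface reproduces the unfertilized
control exactly; `n_starts - 1` further starts (default 20 in total)
perturb every component by independent log-normal factors with sdlog 0.5.
The best SSE wins. Results are bit-reproducible given the seed, and the
caller's RNG stream is left untouched. On the six built-in trials every
start basin-hops to the same optimum; 20 starts is deliberate
over-insurance for messier data.

Significance uses $F = \frac{(SST - SSE)/df_{reg}}{SSE/df_{res}}$ with SST
about the mean, $df_{reg} = 9$ (quadratic) or $6$ (non-structural) and
$df_{res} = n - df_{reg} - 1$. $R^2 = 1 - SSE/SST$, which can go negative
for fits worse than the mean. For the nonlinear model this mean-centred
SST convention reproduces the published F statistics from the published
$R^2$ to one decimal across all six trials, which is how the convention
was pinned down.

## Typicality classification

A fitted surface supports a fertilization recommendation only if it passes
four ordered gates (`classify_tpfm()`, `classify_tnfm()`); the verdict is
the first failing gate:

1. **NRSS** — the regression is not significant at $\alpha$ (default 0.05).
2. **PS** — unreasonable parameter signs. Quadratic: $b_1, b_2, b_3 > 0$
   and $b_4, b_5, b_6 < 0$ (interaction signs are unconstrained — they vary
   in sign even among published well-behaved fits). Non-structural: all
   seven parameters strictly positive.
3. **Max** — no global maximum. Quadratic: the gradient system must have a
   unique solution and the Hessian's leading principal minors must satisfy
   $G_1 < 0, G_2 > 0, G_3 < 0$ (negative definiteness). Non-structural:
   this gate passes automatically given PS, because all-positive
   parameters guarantee an interior maximum — the no-maximum class cannot
   occur for this family, which is one of its structural advantages.
4. **RF** — recommended rates extrapolate. Rates must lie inside the
   per-nutrient design range $[0, 1.5 \times \text{level-2 rate}]$,
   boundary inclusive. With prices supplied, both the maximum and the
   economic rates are checked; without prices the check covers the maximum
   rates only and the verdict is flagged price-free (market prices are
   site- and season-specific and are not part of the trial record).

`batch_classify()` applies one family to a collection of trials, each with
its own per-trial design range, and tabulates class counts and
percentages.

## Recommendations

`tnfm_max_rates()` is the closed form above. The economic rates equate
each marginal product to the fertilizer/grain price ratio
($\alpha = p_N/p_Y$ etc.), giving the implicit system

$$N_{eco} = \frac{1}{c_1 + \alpha/Y_{eco}} - N_0, \ldots$$

solved by fixed-point iteration (`tnfm_econ_rates()`): $Y_{eco}$ starts at
the maximum yield, rates are recomputed, $Y_{eco}$ is re-evaluated at those
rates, and the loop stops when no rate moves by more than `tol` (default
0.1 kg/hm², far below agronomic relevance) or after `max_iter` (default 5)
passes. At market-like price ratios for rice (roughly 1–3 on all three
nutrients) the iteration converges in at most 3 passes on all built-in
parameter sets, matching the rule of thumb that a handful of iterations
suffice. At extreme ratios (around 10) combined with large soil supplies
the economic rates dive far negative — deep extrapolation with no
agronomic meaning — and the contraction slows to need 6–8 passes at the
0.1 kg tolerance; the result is then flagged `converged = FALSE` with the
best iterate returned rather than silently iterating on.

For the quadratic family the analogous quantities are the critical point
(gates permitting) and the linear solve $\nabla Y = (\alpha, \beta,
\gamma)$. One numerical caution found while validating: the critical-point
solve amplifies rounding, so coefficients rounded to 4 significant digits
can shift the recommended N by tens of kg/hm². Recommendations should come
from full-precision fits, never from re-typed rounded coefficients. The
non-structural closed form has no such amplification.

Negative or out-of-range components are returned unclipped everywhere;
interpreting them is the classifier's job. Displayed tables round rates
and yields to whole kg/hm², matching publication convention; internal
precision is never rounded.

## Synthetic trials and what they can show

`generate_trial()` emulates the built-in trials' structure: a 14-treatment
"3414" layout, replicate yields drawn as the surface mean plus Gaussian
noise, summarized as mean and sd. Defaults are 3 replicates and a
replicate sd of 300 kg/hm², the mid-range of the replicate sds printed
for the six field trials. Negative draws are truncated at zero and the
truncation count is reported, so the (rare, low-yield) event is visible
rather than silent. `recovery_experiment()` simulates, fits both families,
classifies with the condition's own design range, and reports parameter
bias/RMSE and the percentage of TYPICAL verdicts per family, with one
derived seed per (condition, replicate) so conditions are independent and
the whole run is reproducible.

The generator draws i.i.d. Gaussian replicate noise. Real field plots have
spatially correlated errors, block effects, season-by-site heterogeneity
and occasionally skewed yield distributions; none of that is emulated.
Passing recovery tests therefore demonstrates the estimator's and
classifier's correctness under the design's information content, not
robustness to field-data pathologies.

One identifiability finding worth knowing: at the built-in design
(level-2 rates 165-75-105), with truth set to the first trial's fitted
surface and noise sd 300, the median absolute relative errors of $c_1$ and
$c_3$ sit near 10–14%, but $c_2$ recovers several-fold worse. The reason
is structural: the soil P supply equivalent (~171 kg/hm²) dwarfs the
largest applied P~2~O~5~ rate (112.5 kg/hm²), so the design barely bends
the surface along $c_2$ and the SSE surface is nearly flat in that
direction. High-supply soils need wider designed rate ranges before the
corresponding $c$ is estimated with useful precision.

## Numerical choices and degenerate inputs

* Exponent guard: `tnfm_predict()` refuses $|c_1 N + c_2 P + c_3 K| > 700$
  with an explicit error instead of silently over/underflowing.
* Critical-point singularity: the gradient system is declared singular
  when $|\det H| < 10^{-12}$ of its scale — structural singularity
  (e.g. an all-linear surface), not round-off.
* The quadratic reduction `tnfm_to_quadratic()` implements the first-order
  truncation exactly as derived, with no higher-order correction. It is a
  structural statement, accurate only where soil supplies are large
  against applied rates and the exponents are small; at the built-in
  trials' own parameter scales ($c_i \times$ rate $\approx 0.5$, and the
  dropped $N\!\cdot\!P\!\cdot\!K$ interaction alone near 8% of the
  surface) the truncation deviates by double-digit percentages on the
  design points. Tests exercise it in its validity regime.
* Rate/design consistency on CSV input tolerates 0.5 kg/hm² to absorb
  rounding in published rate tables.
* Zero control yield, constant response vectors, rank-deficient quadratic
  designs, empty files, missing or duplicate treatments all fail with
  errors naming the offending column, treatment or site.

## Problem sizes

The built-in analyses fit 14-point trials; a 20-start nonlinear fit takes
well under a second. The shipped typicality-rate experiment uses 200
simulated trials per condition at 5 starts each, and the property suites
use up to 1,000 random coefficient draws and a few $10^6$-point grid
searches as independent oracles. These sizes were chosen as comfortable
desk-scale experiments; all scale linearly if enlarged.

## Known limitations

* Fits use treatment means; replicate-level mixed modelling (block
  effects, heteroscedastic replicates) is out of scope.
* The unary and binary model variants are documented special cases, not
  separate code paths.
* Economic recommendations require user-supplied prices; no price database
  ships with the package.
* The six built-in trials are a validation set, not a calibration corpus;
  conclusions about regional typicality proportions require batch runs on
  a user-supplied multi-trial collection.
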