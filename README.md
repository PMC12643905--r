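# mnlfaAnchor

Anchor detection and differential item functioning (DIF) testing for
moderated nonlinear factor analysis (MNLFA) of ordinal (graded) responses.

## Who this is for

Psychometricians and applied researchers who need to test measurement
invariance of a polytomous scale (e.g., a 4-category depression screener)
against several covariates at once — binary and continuous — without knowing
in advance which items are safe anchors. The package jointly models:

* **uniform DIF**: covariate shifts of an item's thresholds
  (`tau_jc(x) = tau_jc0 + B[j,] x`),
* **non-uniform DIF**: covariate moderation of an item's loading
  (`lambda_j(x) = lambda_j0 + Gamma[j,] x`),
* **impact**: genuine latent-trait differences,
  `E(eta) = Omega x`, `V(eta) = exp(Kappa x)`,

under a graded response model with a logit link,
`logit P(y_ij >= c | eta) = lambda_j(x) eta - tau_jc(x)`, fitted by direct
marginal maximum likelihood with per-person adaptive Gauss–Hermite
quadrature (analytic gradients in C++).

Anchor selection uses a refined constrained-baseline procedure driven by
information criteria rather than likelihood-ratio tests:

1. **Conservative screen.** Every item is tested against the no-DIF
   baseline (its full rows of `B` and `Gamma` freed); the per-item
   differences `dIC_j = IC_baseline - IC_test_j` are standardized by a
   sandwich (robust) standard error under an intercept-zero model and items
   with `z_j > 1.65` are flagged. BIC first; if BIC flags nothing, the
   weighted criterion `WIC(lambda) = lambda AIC + (1 - lambda) BIC` is
   re-scored from the same fits along `lambda = 0.1, ..., 0.9` until
   something flags.
2. **Anchor confirmation.** The baseline is updated with all step-1
   candidates; surviving items are re-tested under AIC, which over-flags by
   design — items it still leaves alone are "pure" anchors.
3. **Final model.** Anchors constrained, every other item's DIF estimated,
   each coefficient Wald-tested at `alpha = .05`.

A simulation generator (`gen_covariates`, `gen_true_params`,
`gen_responses`, `run_condition`) reproduces the supported study designs
(N = 500/1000/2000, 10 or 20 items, 40%/70% anchors, three DIF scenarios,
covariates matching the motivating data's moments and correlations), and
`metrics_report()` scores detection output with confusion-matrix metrics:
hit rate, Type I/II error, power, absolute relative bias.

## Worked example

```r
library(mnlfaAnchor)

gp <- gen_true_params(10, 0.7, "one_dif", seed = 7)  # items 1-3 carry DIF
X  <- gen_covariates(1000, seed = 1)                  # sex, race, poverty
y  <- gen_responses(X, gp$params, seed = 2)           # 4-category GRM

out <- run_refined(y, X)
out$anchor_report
#> Refined constrained-baseline anchor report
#>   step-1 candidates: 1  (WIC lambda = 0.8)
#>   anchors: 5, 6, 7, 8, 9, 10
#>   DIF items: 1, 2, 3, 4
```

BIC flagged nothing, so the WIC ladder ran up to `lambda = 0.8` before item
1 stood out; the step-2 AIC re-test then pulled in items 2–4 and confirmed
items 5–10 as pure anchors. The final Wald table (`out$final_report`)
flags exactly the true effects — both DIF types from the poverty covariate
(x3) on items 1–3, estimates near the generating 0.5 (uniform) and 0.3
(non-uniform):

```
 item covariate       type   estimate         se        z            p flagged
    1         3    uniform  0.4638282 0.09185764 5.049424 4.431434e-07    TRUE
    1         3 nonuniform  0.3349487 0.11593214 2.889179 3.862488e-03    TRUE
    2         3    uniform  0.3418073 0.08983968 3.804637 1.420125e-04    TRUE
    2         3 nonuniform  0.3255863 0.12240208 2.659973 7.814683e-03    TRUE
    3         3    uniform  0.4663769 0.10313011 4.522218 6.119490e-06    TRUE
    3         3 nonuniform  0.3922969 0.16594227 2.364057 1.807606e-02    TRUE
```

Item 4 was carried into the final model but none of its six effects tested
significant — the procedure trades a little step-2 conservatism for Type I
control. A Monte-Carlo evaluation of the whole pipeline:

```r
cond <- sim_condition(500, 10, 0.7, "one_dif", reps = 20, seed = 1)
metrics_report(run_condition(cond))
```

## Command line

```sh
inst/cli/mnlfa-anchor simulate --config cond.json --out archive/
inst/cli/mnlfa-anchor detect   --responses y.csv --covariates x.csv --out report/
inst/cli/mnlfa-anchor evaluate --archive archive/ --out metrics.csv
```

Configs are JSON; `--seed`, `--workers`, `--quadrature`, `--z-threshold`
and `--alpha` override config fields. `detect` emits `anchor_report.json`,
`final_dif.csv`, `screening_trace.csv` (per-round delta-IC and z), the
final model report and a run log.

See the methods vignette (`vignettes/mnlfa-anchor-methods.Rmd`) for the
model, the numerical choices (adaptive quadrature, threshold
reparameterization, convergence rules), the synthetic-data design and its
documented divergences, and known limitations.
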