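# picsel — robust model selection with pseudodistance-based information criteria

`picsel` selects regression submodels with an information criterion whose fit
statistic is robust to outlying responses. Classical criteria (AIC, BIC, Cp)
score a candidate by its maximized Gaussian likelihood, so a few gross errors
can dominate every candidate's score and flip the selection. `picsel` instead
scores candidates by a minimum **pseudodistance** (γ-divergence) fit, in which
each observation enters through the bounded weight
`exp(-γ e_i² / 2σ²)` — outliers are downweighted exponentially rather than
squared.

It is aimed at statisticians and applied modellers doing all-subsets
covariate selection on small-to-moderate datasets where contamination is a
live concern (epidemiological and biomedical regressions, lab measurements
with instrument glitches).

## The method in brief

For a candidate linear model `Y = α + βᵗX + e`, `e ~ N(0, σ)`, the minimum
pseudodistance estimator of θ = (α, β, σ) at order γ > 0 minimizes

    Q(θ) = 1/(γ+1) · ln ∫ φ_σ^{γ+1}(e) de
         − 1/γ · ln [ 1/n Σ_i φ_σ^γ(Y_i − α − βᵗX_i) ]

which tends to the negative mean log-likelihood (and the estimator to OLS)
as γ → 0. The **Pseudodistance Information Criterion** corrects the
minimized statistic Q for its optimism, with d = p + 2 parameters:

    PIC = Q + (γ+1)²/(2γ+1)^{3/2} · d/n + (1 − √((γ+1)/(2γ+1))) · d/(2γn)

Lower is better; the candidate subset minimizing PIC is selected. The
influence function of the underlying statistic is bounded (gross-error
sensitivity 1/γ), whereas the AIC statistic's influence function
`((x−m)/σ)² − 1` is unbounded — that contrast is the formal robustness
argument, and `influence_pic()` / `influence_aic()` /
`gross_error_sensitivity()` compute it. AIC, BIC and the divergence-based
MDIC are included as comparators, plus a Monte Carlo harness for
selection-proportion studies under contaminated errors.

## Worked example: the cement data

The classical 13-observation Hald dataset (heat evolved by setting cement,
in calories per gram, against four ingredient amounts) ships with the
package. Its regressors are notoriously collinear, and single-variable
models are excluded on chemical grounds (`min_size = 2`):

```r
library(picsel)
d <- hald()
X <- as.matrix(d[, 1:4])

select_model(d$Y, X, "PIC", gamma = 0.2, min_size = 2)
#> PIC (tuning = 0.2) all-subsets selection over 11 candidates
#> Chosen model: X1,X2,X3
#>         model size    value
#> 1    X1,X2,X3    3 2.103937
#> 2    X1,X2,X4    3 2.107324
#> 3       X1,X2    2 2.110696
#> 4    X1,X3,X4    3 2.135837
#> 5 X1,X2,X3,X4    4 2.184668
#> ...
```

The top three candidates sit within 0.007 of each other — on data this
collinear the criterion ranks near-ties (the adjusted R² of the two leading
3-variable models agree to three decimals, both 0.976), so the ranking
matters more than the single winner. BIC, with its stronger penalty, picks
the sparser `X1,X2`; AIC picks `X1,X2,X4`. The robust fit itself:

```r
fit_regression_mpe(d$Y, X[, c(1, 2, 3)], gamma = 0.2)
#> Minimum pseudodistance fit (regression), gamma = 0.2, n = 13
#>   intercept = 48.2072, sigma = 1.94973
#>   slopes: 1.69577 0.65118 0.270681
#>   Q statistic = 1.6982635 (converged: TRUE, extra starts: 5)
```

and the robustness diagnostic:

```r
gross_error_sensitivity("pic", gamma = 0.2)  # 5  (= 1/gamma, finite)
gross_error_sensitivity("aic")               # Inf
```

A contamination study (percentage of 50 replicates in which each criterion
recovers the true model `Y = 1 + X1 + X2 + ε` among all 15 subsets of four
regressors, with 20% blended noise shift):

```r
cfg <- sim_config(n = 20, d1 = 0.8, replicates = 50,
                  gamma = c(0.1, 0.2, 0.3), seed = 1)
run_selection_study(cfg)
```

## Command-line tool

A thin wrapper over the same functions is installed at
`system.file("exec", "picsel", package = "picsel")`:

```sh
picsel select   --data hald.csv --response Y --criterion PIC --gamma 0.2 --min-size 2
picsel fit      --data hald.csv --response Y --covariates X1,X2 --gamma 0.1
picsel simulate --n 20 --d1 0.8 --gamma 0.1,0.2 --replicates 50 --seed 1
picsel influence --gamma 0.1,0.3 --out curves.tsv
```

All subcommands take `--seed` and emit tab-separated tables.

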