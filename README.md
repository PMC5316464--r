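# msvdcast

Decomposition-based multistep forecasting of nonstationary weekly count
series — for example, weekly counts of people injured in traffic
accidents, or comparable epidemiological surveillance series.

Such series mix a drifting level, a strong seasonal cycle and
autocorrelated short-term noise, and a single linear model fitted to the
raw values forecasts them poorly several weeks ahead.  `msvdcast`
implements the two-stage approach: first split the series `x` into
additive low- and high-frequency components, then forecast all horizons
jointly from lagged values of both components.

**The core decomposition** is a multilevel singular value decomposition
(MSVD) of a Hankel matrix.  One level embeds `x_1..x_N` into the
`2 x (N-1)` trajectory matrix

    H = [ x_1  x_2  ...  x_{N-1} ]
        [ x_2  x_3  ...  x_N     ]

takes its exact rank-2 SVD `H = λ₁u₁v₁' + λ₂u₂v₂'` (closed form, two-row
matrix), and maps each elementary matrix back to a series by anti-diagonal
averaging.  The leading term is the level's low-frequency part; the
pyramid recurses on it, accumulating the second terms into `c_H`.  The
depth `J` is chosen by the singular spectrum rate
`ΔR_j = R_j / R_{j+1}`, `R_j = λ₁/(λ₁+λ₂)`: recursion stops when ΔR
reaches its asymptote at 1.  Always, `c_L + c_H = x` to machine precision.

**Forecasting** uses the MIMO strategy: a `τ × 2P` coefficient matrix `β`
maps `P` lags of `c_L` and `P` lags of `c_H` to all horizons `1..τ` at
once, `x̂ = β z'`, fitted by Moore–Penrose least squares
(`fit_mimo_ar()`).  A three-layer sigmoid perceptron trained by
Levenberg–Marquardt (`train_mlp_lm()`) is the nonlinear baseline, and a
stationary (à trous) Daubechies-2 wavelet split (`swt_components()`) is
the baseline decomposition.  The lag order `P` comes from the Fourier
power spectrum against an AR(1) red-noise background
(`fourier_power_spectrum()`, `select_lag_order()`); skill is scored per
horizon by nRMSE, modified Nash–Sutcliffe efficiency (mNSE = 1 − SAE/SAD)
and the modified index of agreement (mIA).

## Worked example

```r
library(msvdcast)

# fifteen years of synthetic weekly injury counts: piecewise-linear trend,
# 26-week seasonality, AR(1) noise
x <- generate_injury_series(synthetic_series_config(seed = 42))

msvd(x)
#> Multilevel Hankel-SVD decomposition (N = 780)
#>   depth J = 31 (converged, tol = 0.0001 on |deltaR - 1|)
#>   deltaR at stopping level: 0.999901
#>   level-1 energy ratio R1 = 0.9763

fourier_power_spectrum(x)
#> Fourier power spectrum (N = 780, AR(1) alpha = 0.909)
#>   dominant period: 26 samples (significant at 95%)
#>   12 of 389 frequencies above the red-noise threshold

run_experiment(x, method = "msvd", model = "mimo_ar", tau = 14)
#> Forecast experiment: MSVD + MIMO_AR, P = 26, tau = 14, full mode
#> Forecast skill per horizon (tau = 14), in percent
#>    horizon    nrmse  mnse   mia
#>          1 0.002929 99.97 99.99
#>          2 0.035140 99.65 99.83
#>          ...
#>         14 2.477000 74.90 87.45
#>        Min 0.002929 74.90 87.45
#>        Max 2.477000 99.97 99.99
#>   Mean 1-8 0.888100 91.08 95.54
#>  Mean 1-13 1.349000 86.51 93.26
#>  Mean 1-14 1.429000 85.68 92.84
```

The decomposition stops at depth 31, where the singular-spectrum-rate
curve has flattened onto 1.  The spectrum correctly identifies the 26-week
cycle (so `P = 26` lags per component), and the linear MIMO model then
forecasts the held-out 30% of the series with mNSE above 85% and mIA above
92% averaged over horizons 1–14: near-perfect one week ahead, degrading
gracefully to fourteen weeks.  Note the default protocol extracts
components from the full series before the chronological split (and warns
about it); pass `leakage = "causal"` for strictly out-of-sample
regressors.

`compare_methods(x, c("msvd_ar", "swt_ar", "swt_ann"))` runs the
Hankel-SVD and wavelet pipelines side by side and reports relative gains
in both conventions (gain of mean scores, mean of per-horizon gains).

A thin command-line wrapper with `simulate`, `decompose`, `forecast`,
`evaluate` and `compare` subcommands is installed at
`system.file("cli/msvdcast.R", package = "msvdcast")`.

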