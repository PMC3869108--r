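# primsel — Bayesian model selection for movement-primitive extraction

Movement scientists decompose multi-joint kinematic recordings into a few
*movement primitives*: source time courses `S` mixed into the observed
signals `X` by weights `W`, optionally with a per-signal time delay. The
classical extraction methods — PCA, ICA, anechoic demixing — all require
choosing the model type, the number of sources `I`, and the amount of
temporal smoothness by hand. `primsel` turns those choices into Bayesian
model comparison:

* four blind-source-separation families as generative models —
  probabilistic PCA (**PPCA**), **ICA** with a `log cosh` contrast prior,
  smooth instantaneous mixtures (**SIM**) with a wave-kernel
  Gaussian-process source prior `k(t,t') = σ² sinc(2 f₀ |t−t'|)`, and
  anechoic mixtures (**AMM**) with exponential delay priors;
* two-phase MAP fitting (SVD / kurtosis-rotation / delay-scan
  initialization, then L-BFGS-B with analytic gradients, alternating with
  closed-form hyperparameter updates);
* the **LAP** criterion — a Laplace approximation to the log model
  evidence at the MAP point,
  `LAP = loglik + logprior + (F/2)·log 2π − ½·log|H|`
  (larger is better) — alongside BIC and AIC, with grid search over
  family × `I` × `f₀`;
* the synthetic ground-truth benchmark used to validate the criterion:
  band-limited sources (zero-phase 6th-order Butterworth, 5/10 Hz),
  uniform mixing weights on [−10, 10], exponential delays of mean 20
  samples, and signal-dependent Gaussian noise (`sd = α|x(t)|`)
  calibrated to a target noise level `1 − R²`;
* evaluation metrics (model-type classification rate, source-count error
  ΔI, smoothness error Δf₀) and a command-line experiment runner.

The audience is researchers in computational motor control and anyone
selecting the order and structure of linear latent time-series models
with soft regularity constraints.

## Worked example

Generate a noisy delayed mixture with known ground truth and let the
criteria pick the model:

```r
library(primsel)
# 10 trials of a 2-source delayed (anechoic) mixture, 15% noise
ds <- generate_dataset(family = "AMM", cutoff_hz = 5, I_true = 2,
                       noise_level = 0.15, J = 10, seed = 42)
sel <- select_model(ds$X_noisy,
                    families = c("PPCA", "SIM", "AMM"),
                    I_range  = 1:2,
                    f0_grid  = c(5, 10, Inf),
                    opts     = fit_options(seed = 1))
print(sel)
```

```
<selection_result> 12 candidates
  LAP winner: AMM, I = 2, f0 = 5 Hz
  BIC winner: AMM, I = 1, f0 = Inf Hz
  AIC winner: AMM, I = 2, f0 = Inf Hz
```

The top-scoring candidates:

```r
sel$candidates[order(-sel$candidates$lap)[1:5],
               c("family", "I", "f0_hz", "loglik", "lap", "bic", "aic")]
```

```
 family I f0_hz   loglik     lap    bic    aic
    AMM 2     5 -1272.36 -1500.8 4202.6 3024.7
    AMM 2    10 -1235.20 -1520.7 4128.3 2950.4
    AMM 2   Inf  -980.88 -1625.3 3619.6 2441.8
    AMM 1     5 -1514.24 -1631.3 3857.4 3268.5
    AMM 1    10 -1488.19 -1636.3 3805.3 3216.4
```

LAP recovers the generating model exactly: the delayed family, two
sources, and the 5 Hz smoothness cutoff. The likelihood-only criteria
behave as their penalties dictate: dropping the smoothness constraint
(`f0 = Inf`) always *raises* the likelihood, so BIC and AIC prefer the
unsmoothed variants — they cannot credit a soft constraint that costs no
integer parameter. LAP can, through its log-prior and posterior-volume
terms. `1 - r_squared(...)` on the dataset confirms the achieved noise
level (0.138 here, targeting 0.15).

A command-line wrapper covers the same workflow
(`exec/primsel generate|fit|select|evaluate|replicate-smoothness`), with a
YAML configuration whose defaults equal the benchmark design; see
`?run_command`.

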