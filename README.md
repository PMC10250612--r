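# snapfim

Distortion-corrected inference and experiment design for single-cell
snapshot data.

Single-cell assays (smFISH spot counting, flow cytometry, reporter
imaging) measure each cell once, at a fixed time, and every one of them
distorts the true molecule count: spots are missed, background adds false
positives, or only a noisy integrated intensity is recorded.  Fitting a
stochastic gene-expression model to distorted count histograms as if they
were exact gives tightly converged, *wrong* parameter estimates.
`snapfim` is for modellers who want to fit chemical master equation (CME)
models to such data while treating the measurement itself as part of the
model, and to choose measurement times that maximise the information a
distorted experiment can still deliver.

The package:

* solves the CME by finite state projection (FSP), with certified
  truncation error, together with the forward parameter-sensitivity
  system, `solve_cme()` / `solve_sensitivity()`;
* models measurement noise as a probabilistic distortion operator (PDO), a
  column-stochastic kernel `C[y, x] = Pr(observe y | true count x)`, so
  observed distributions are `p_Y = C p_X` — six families are bundled
  (`make_pdo()`), and operators can be calibrated from paired two-channel
  measurements with BIC model selection (`fit_pdo()`, `select_pdo()`);
* computes distortion-corrected likelihoods and maximum-likelihood or MAP
  fits (`fit_snapshot()`), and samples posteriors by Metropolis–Hastings
  with a proposal shaped by the inverse Fisher information
  (`metropolis_hastings()`);
* computes the Fisher information matrix (FIM) of distorted observables,
  `F[i,j] = sum_y s_i(y) s_j(y) / p(y)`, on linear or log10 parameter
  scale, and ranks experiment designs by D-optimality
  (`fim_for_model()`, `design_information()`, `search_design()`);
* generates synthetic distorted datasets with known ground truth and runs
  replicated estimator-validation studies (`sample_snapshot_dataset()`,
  `run_mle_ensemble()`, `run_fim_validation()`).

Two case-study models are bundled (`build_model()`): the random telegraph
gene and a three-state bursting HIV-1 reporter promoter with
triptolide-induced transcription shutoff.

## Worked example

Simulate one snapshot experiment from the telegraph model — five time
points at 30-minute spacing, 1000 cells each — where each cell's mRNA
count is thinned by the density-dependent lossy-counting operator
(detection probability `1/(1 + 0.01 j)`), then fit with and without
distortion correction:

```r
library(snapfim)

net  <- build_model("telegraph")          # study truth in net$default_theta
pdo  <- make_pdo("msvr", list(a = 0.01), x_max = 210)
des  <- experiment_design(times = (1:5) * 30, n_cells = 1000)
data <- sample_snapshot_dataset(net, net$default_theta, des,
                                pdo = pdo, seed = 11)

fit_corr  <- fit_snapshot(data, net, pdo = pdo)   # corrected likelihood
fit_naive <- fit_snapshot(data, net)              # ignores the distortion
summary(fit_corr)
fit_naive
```

```
MLE fit of 4 parameters to 5000 cells
           k_on    k_off    k_r    gamma
log10  -1.31200 -1.81700 0.7028 -1.30100
linear  0.04878  0.01525 5.0440  0.05001
log-likelihood: -18678.05 (converged, 1 simplex rounds)

FIM-based asymptotic standard errors (log10 scale):
      log10_estimate se_log10 estimate
k_on         -1.3120  0.01020  0.04878
k_off        -1.8170  0.02133  0.01525
k_r           0.7028  0.01030  5.04400
gamma        -1.3010  0.01255  0.05001

MLE fit of 4 parameters to 5000 cells
           k_on     k_off   k_r  gamma
log10  -1.27500 -2.071000 0.536 -1.143
linear  0.05306  0.008489 3.436  0.072
log-likelihood: -18722.223 (converged, 1 simplex rounds)
```

The true log10 values are `k_on = -1.30`, `k_off = -1.82`, `k_r = 0.699`,
`gamma = -1.30`.  The corrected fit recovers all four within about one
FIM-based standard error.  The naive fit is precisely wrong: it
underestimates the transcription rate by a factor of ~1.5 (`0.536` vs
`0.699` in log10, i.e. 3.4 vs 5 molecules/min), overestimates degradation
by ~44% (`0.072` vs `0.05` per min), and halves the slow switching rate
(`-2.07` vs `-1.82`) — biases that do not shrink with more cells, because
they reflect the unmodelled measurement loss, not sampling noise.

The same machinery ranks designs: `search_design()` sweeps candidate
measurement schedules and reports the expected uncertainty volume
`det(FIM^-1)` per candidate, averaged over posterior parameter draws.

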