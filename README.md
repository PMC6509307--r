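# ratemoments

Fast, accurate **non-equilibrium statistics for heterogeneous stochastic
firing-rate networks**.

Neural responses to fast stimuli are transient: means, variances and
covariances of activity move on the same timescale as the input, and the
common shortcut of evaluating the stationary solution at each instant (the
quasi-steady-state, QSS, approximation) gets them qualitatively wrong.
`ratemoments` is for computational neuroscientists (and anyone working
with coupled, noise-driven rate equations) who need the *complete*
time-varying first- and second-order statistics of a network without
paying for millions of Monte Carlo realizations.

## The model and the method

Each cell's activity follows a Wilson–Cowan type SDE

    tau_j dx_j/dt = -x_j + mu~_j(t) + sigma~_j(t) eta_j(t) + sum_k g_jk F_k(x_k),

with background noise white in time but correlated across cells
(`<eta_j eta_k> = c_jk δ(t−t')`), all-to-all signed coupling `g_jk`, and a
bounded sigmoid F-I curve `F(x) = 0.5 (1 + tanh((x − x_rev)/x_sp))`.
A pairwise-Gaussian moment closure of the associated Fokker–Planck
equation turns this into `N_c + N_c (N_c + 1)/2` nonlinear ODEs for the
means and second moments, closed by three Gaussian expectations of `F`
(`e1`, `e2`, and the mixed kernel `mf`, which reduces exactly to
`c_jk * m1`). Firing statistics (`nu_j = F_j(x_j)`: mean, variance,
covariance) follow by a Gaussian change of variables. The package also
provides the QSS baseline (`qss_trajectory`), a compiled Euler–Maruyama
ensemble simulator with grouped error bands as ground truth
(`simulate_ensemble`), the heterogeneous-network generator used by all
experiments (`sample_network`), and the average-absolute-error evaluation
layer (`error_report`, `coupling_sweep`).

## Worked example

A 3-cell heterogeneous network, weak coupling (`l = 1`), driven by a
common fast pulse in the background mean:

```r
library(ratemoments)

spec <- sample_network(3, coupling_scale = 1, seed = 42,
                       inputs = list(mu_bg = default_pulse()))
times <- seq(0, 10, by = 0.1)

closure <- integrate_closure(spec, closure_config(), times)   # the method
qss     <- qss_trajectory(spec, times)                        # baseline
mc      <- simulate_ensemble(spec, times, n_realizations = 20000,
                             dt = 0.01, seed = 7)             # ground truth

error_report(closure, mc$trajectory)
error_report(qss, mc$trajectory)
mc_noise_floor(mc)
```

Output (values printed by the code above):

```
<error_report> grand average absolute error: 0.005184
   mean_x     var_x     cov_x   mean_nu    var_nu    cov_nu
0.0065890 0.0123000 0.0077370 0.0025560 0.0007391 0.0011770

<error_report> grand average absolute error: 0.0533
  mean_x    var_x    cov_x  mean_nu   var_nu   cov_nu
0.211800 0.013350 0.009988 0.064370 0.015440 0.004830

MC noise floor: 0.004785
```

Reading it: the closure's pooled error (0.0052) sits essentially at the
Monte Carlo sampling floor of this 20 000-realization reference (0.0048) —
the method is tracking every statistic family about as well as this
ensemble can measure — while the QSS baseline is an order of magnitude
worse (0.053), failing hardest on the transient mean activity (0.21). The
closure's peak mean firing for cell 1 is 0.7770 at t = 4.8, against the
Monte Carlo 0.7750 ± 0.0106 (one grouped-band half-width). As a rule of
thumb, grand errors below 0.01 mean every family is captured well; errors
grow with coupling scale `l` as the weak-coupling Gaussian assumption
degrades (see `coupling_sweep`).

Trajectories are plain CSV tables (`write_trajectory`), configurations are
JSON (`run_config`, `run`), and a command-line front end is installed at
`inst/cli/ratemoments` (subcommands `sample-network`, `simulate`, `sweep`,
`validate`; see `?cli_main`).

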