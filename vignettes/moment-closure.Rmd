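---
title: "Non-equilibrium moment closure for noisy firing-rate networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-equilibrium moment closure for noisy firing-rate networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Each of $N_c$ cells carries a scalar activity $x_j$ (membrane voltage,
calcium concentration, a population rate — the model is agnostic) obeying a
Wilson–Cowan type stochastic differential equation

$$\tau_j\,\dot x_j \;=\; -x_j + \tilde\mu_j(t) + \tilde\sigma_j(t)\,\eta_j(t)
  + \sum_{k=1}^{N_c} g_{jk}\,F_k(x_k),$$

where the background noises $\eta_j$ are white in time but instantaneously
correlated across cells, $\langle\eta_j(t)\eta_k(t')\rangle =
c_{jk}\,\delta(t-t')$ with $c_{jk}\in(-1,1)$, $g_{jk}$ is the signed
coupling from presynaptic cell $k$, and the F-I curve is the bounded
sigmoid $F_j(x) = \tfrac12\bigl(1+\tanh((x - x_{\mathrm{rev},j})/
x_{\mathrm{sp},j})\bigr)\in[0,1]$. The quantities of interest are the six
time-varying statistic families: mean, variance and pairwise covariance of
the activity $x_j$ and of the firing $\nu_j = F_j(x_j)$.

When the drive $\tilde\mu_j(t)$ changes on a timescale comparable to or
faster than $\tau_j$, these statistics are genuinely non-equilibrium:
assuming the network instantaneously equilibrates (the quasi-steady-state,
QSS, approximation) misses the lag, smoothing and overshoot of the real
response.

## The closure

Multiplying the network's Fokker–Planck equation by $x_j$, $x_j^2$ and
$x_jx_k$ and integrating gives an exact but unclosed moment hierarchy. We
close it by assuming the activities are pairwise Gaussian — equivalent to
assuming weak coupling — with the joint correlation of a pair fixed at the
*input* correlation $c_{jk}$. Three Gaussian expectations then close every
term (with $\varrho_1$ the standard normal density and $\mu_k, \sigma_k$
the current mean and standard deviation of cell $k$):

* $E_1(k) = \int F_k(\sigma_k y + \mu_k)\,\varrho_1(y)\,dy$ — mean firing,
* $E_2(k) = \int F_k^2(\sigma_k y + \mu_k)\,\varrho_1(y)\,dy$,
* $M_F(j,k) = \iint F_k(\sigma_k y_1 + \mu_k)\,y_2\,
  \varrho_{j,k}(y_1,y_2)\,dy_1dy_2$, where $\varrho_{j,k}$ is the bivariate
  standard normal with correlation $c_{jk}$, replaced by $\varrho_1$ when
  $j=k$. Because $E[Y_2\mid Y_1]=c_{jk}Y_1$ under $\varrho_{j,k}$, this
  double integral reduces *exactly* to $c_{jk}\,M_1(k)$ with
  $M_1(k)=\int F_k(\sigma_k y+\mu_k)\,y\,\varrho_1(y)\,dy$; the package
  computes the reduction and keeps the literal 2-D integral as a test
  oracle (`mf_2d_oracle`).

The result is a closed ODE system in the $N_c$ means $\mu_j$ and the
$N_c(N_c+1)/2$ raw second moments $E_{j,k}$ (`closure_rhs`,
`integrate_closure`); the pair equation evaluated at $j=k$ *is* the
second-moment equation, and the implementation assembles both channels
from one symmetric matrix expression so that identity holds to round-off.
Firing statistics follow by the Gaussian change of variables
(`activity_to_firing`): $\nu_j = E_1(j)$, $\mathrm{Var}(\nu_j) = E_2(j) -
\nu_j^2$, and $\mathrm{Cov}(\nu_j,\nu_k) = \langle F_jF_k\rangle(\rho_{jk})
- \nu_j\nu_k$.

**Which correlation for the output covariance?** Inside the ODEs the
closure prescribes the static $c_{jk}$; for the *output* change of
variables no prescription exists, and using $c_{jk}$ there would make the
firing covariance blind to coupling-induced correlation changes. The
package therefore defaults to the dynamic activity correlation
$\rho_{jk}(t) = \mathrm{Cov}_{j,k}(t)/(\sigma_j\sigma_k)$ for outputs, with
`closure_config(firing_corr = "static_input")` selectable for ablation.
Neither convention is asserted as canonical; the default is the one with
the right qualitative behavior.

## Steady state and QSS

With constant inputs the system settles to a fixed point
(`solve_steady_state`): $\mu_j = \tilde\mu_j + \sum_k g_{jk}E_1(k)$, a
scalar quadratic for each $\sigma_j$ ($\sigma_j^2 =
\tilde\sigma_j^2/(2\tau_j) + \sigma_j\sum_k g_{jk}M_F(j,k)$, positive root
only — a missing positive root is reported as non-convergence, signalling
closure breakdown at strong coupling, never patched with an absolute
value), and an explicit covariance relation. The solver is a damped
fixed-point iteration (relaxation 0.5, contractive at weak coupling) with
a finite-difference Newton fallback. The QSS baseline (`qss_trajectory`)
re-solves this system at every requested time for the instantaneous input
values, warm-starting from the previous solution.

Uncoupled ($G=0$) the model is an Ornstein–Uhlenbeck process with closed
forms ($\mu_j=\tilde\mu_j$, $\sigma_j^2 = \tilde\sigma_j^2/(2\tau_j)$,
$\mathrm{Cov}_{j,k} = c_{jk}\tilde\sigma_j\tilde\sigma_k/(\tau_j+\tau_k)$,
and exponential transients with rates $1/\tau_j$, $2/\tau_j$ and
$1/\tau_j + 1/\tau_k$); these anchor the exactness tests.

## Monte Carlo ground truth

`simulate_ensemble` integrates the SDE ensemble by Euler–Maruyama (additive
noise, so the scheme is strong order 1.0; a higher-order scheme would buy
nothing) with correlated increments $L z$, $LL^\top = Cr$, using the
symmetric eigendecomposition square root with round-off-negative
eigenvalues clipped at zero. Defaults: $dt = 0.01\min\tau$ with a
halving check in the test suite; realizations start from the uncoupled
Gaussian steady state at the initial inputs and relax for a burn-in of
$5\max\tau$ before recording, so the recorded ensemble is equilibrated —
the validation experiments show flat pre-stimulus baselines by
construction. Statistics are accumulated in streaming form in compiled
code. Error bands use the grouped estimator: the band half-width $S$ is
the sample standard deviation across disjoint groups of 1000 realizations
of the per-group statistic, reported as $\bar X \pm S$; the standard error
of the pooled estimate is $S/\sqrt{n_\mathrm{groups}}$, which also yields
the *noise floor* `mc_noise_floor` — the average absolute error a perfect
method would still show against a finite ensemble,
$\sqrt{2/\pi}\,\bar S/\sqrt{n_\mathrm{groups}}$.

## The synthetic world

All experiments draw their networks from fixed heterogeneity
distributions (`sample_network`): $\tau_j \sim N(1, 0.1^2)$ (nonpositive
draws rejected and redrawn — a $\sim 10^{-23}$ event that would otherwise
invalidate the model), $\tilde\mu_j \sim U[0,1]-0.5$, $\tilde\sigma_j \sim
U[0,1]+1$, $x_{\mathrm{rev},j}\sim N(0,0.1^2)$, $x_{\mathrm{sp},j}\sim
0.35\,U[0,1]+0.05$. The input correlation matrix is a normalized Gram
matrix of a square Gaussian matrix with entry standard deviation 0.8
(symmetric, PSD, exact unit diagonal, approximately independent
off-diagonal entries); draws with an off-diagonal entry within $10^{-6}$
of $\pm1$ are rejected, since the model requires $c_{jk}\in(-1,1)$.
Coupling is all-to-all Gaussian, $g_{jk}\sim N(0,(l/10)^2)$, so
$E|g_{jk}| \to l/(5\sqrt{2\pi})$ for large networks; $l$ is the
coupling-strength dial of the accuracy experiments.

Two reference stimuli drive the background mean of every cell identically,
*replacing* the heterogeneous baseline (an additive mode is available; the
common-drive reading matches the validation design, and replacement keeps
the pre-stimulus state independent of the stimulus definition):

* a smooth double-sigmoid pulse $b + a[S((t-t_\mathrm{on})/r) -
  S((t-t_\mathrm{off})/r)]$, defaults $b=0$, $a=1$, $t_\mathrm{on}=2$,
  $t_\mathrm{off}=5$, $r=0.1$ — a rise time an order of magnitude faster
  than $\tau\approx 1$, i.e. deeply non-equilibrium, while remaining
  differentiable for the adaptive stepper;
* a sinusoid $b + a\sin(2\pi ft+\varphi)$, defaults $b=0$, $a=1$, period
  2 (comparable to $\tau$, fast enough that QSS fails visibly).

The exact amplitudes and timescales of the original experiments are not
recoverable; these values were chosen once as "fast relative to $\tau$"
and are never adjusted against test outcomes. What a green validation run
establishes is therefore: *for networks drawn from these distributions,
under these stimuli, at the stated coupling scales*, the closure tracks
Monte Carlo within the stated bounds. It does not establish accuracy for
sparse or structured connectivity, strong coupling, non-sigmoidal F-I
curves, or stimuli far outside these shapes — and no parameters are fitted
to any experimental recording.

## Numerical choices

* **Quadrature.** A fixed-order Gauss–Hermite rule is the obvious choice
  for the closure kernels and is provided (`gauss_hermite`, Golub–Welsch
  nodes polished by Newton steps on the orthonormal recurrence, Christoffel
  weights, so polynomial exactness holds to machine precision). But it is
  *not* the production path: with $x_{\mathrm{sp}}$ as small as 0.05 and
  $\sigma\approx 1.4$ the sigmoid is nearly a step on the noise scale, the
  integrand's poles sit close to the real axis, and order 40 stalls near
  $10^{-4}$ — far from the $10^{-8}$ oracle agreement the kernels must
  meet. The production kernels instead use composite 16-point
  Gauss–Legendre panels in the standardized variable with breakpoints on
  *both* length scales (the unit Gaussian scale and the transition
  $y^\ast = (x_\mathrm{rev}-\mu)/\sigma$ with width $x_\mathrm{sp}/\sigma$),
  which is accurate to near machine precision across the entire
  heterogeneity range at a few hundred evaluations per cell.
* **Bivariate firing expectations.** For $|\rho|\le 0.9$ the Mehler
  expansion $\langle F_jF_k\rangle = \sum_m \rho^m b_m(j)b_m(k)$ over
  normalized Hermite coefficients (truncated at $m=170$; the tail is
  bounded by $\rho^{171}\mathrm{Var}(F) \le 10^{-8}$) — one coefficient
  set per cell serves all its pairs, which keeps large-network output
  conversion cheap. For $|\rho|>0.9$, direct decorrelated panel
  integration; at $|\rho|=1$, the exact 1-D degenerate integral; interior
  $|\rho|$ clipped to $1-10^{-12}$.
* **Time stepping.** The system is smooth and non-stiff at weak coupling,
  so an embedded Dormand–Prince 5(4) pair with standard step control
  (tolerances $10^{-8}/10^{-10}$) integrates it; each unordered moment
  pair is integrated once, so symmetry of the second-moment matrix is
  exact. No library stepper is assumed by the package.
* **Degenerate inputs.** $\sigma = 0$ collapses every kernel to its point
  evaluation. Inside the right-hand side, derived variances in
  $[-10^{-8}, 0)$ are clamped to 0 (transient round-off); anything below
  $-10^{-8}$ raises an error rather than masking closure failure.
  A zero marginal spread combined with a nonzero covariance is rejected as
  inconsistent.
* **Initial conditions.** Never stated in the original experiments; the
  default is the steady state at the $t_0$ input values, so transients
  reflect only the drive. A user-supplied `moment_state` overrides.
* **Seeds.** One master seed fans out to named substreams
  (`derive_seed`), so toggling the Monte Carlo arm cannot perturb the
  sampled network.

## Evaluation

`average_absolute_error` is the accuracy metric: at each time, the mean of
$|X_\mathrm{method} - X_\mathrm{MC}|$ over the $M$ items of a family
($M = N_c$ for means/variances, $N_c(N_c-1)/2$ pairs for covariances).
The grand summary pools every (statistic, item, time) deviation with equal
weight — the weighting across families of unequal $M$ is not canonical, so
per-family means are always reported alongside, letting either convention
be recovered. `coupling_sweep` draws one network and rescales its coupling
matrix across $l$ values (so only the overall strength changes, matching
the "same network, stronger coupling" experimental design; independent
draws per $l$ are possible by calling the pieces directly). As a rule of
thumb validated by the acceptance suite, grand errors below 0.01 indicate
the closure is tracking every family well; errors above that signal that
at least some statistics (variances first) are drifting, which happens as
$l$ grows because the weak-coupling Gaussian assumption degrades.

## Known limitations

* Accuracy degrades with coupling strength; there is no internal error
  estimate beyond comparing against `simulate_ensemble`.
* The closure is second-order Gaussian: no skew, no heavy tails, no
  higher-order closures.
* The firing-covariance output convention (dynamic vs static correlation)
  is a genuine ambiguity; both are provided.
* Validation ensembles in the shipped tests are scaled down (ten- to
  fifty-fold) from the reference million realizations to fit a desktop
  time budget; thresholds are checked against the correspondingly larger
  noise floor, never loosened.
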