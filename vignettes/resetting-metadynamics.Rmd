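---
title: "Accelerating rare-event sampling by combining stochastic resetting with well-tempered metadynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerating rare-event sampling by combining stochastic resetting with well-tempered metadynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resetMetaD)
```

## The problem

Barrier-crossing events — conformational transitions, folding, nucleation —
are rare on the timescale accessible to molecular dynamics. Two acceleration
strategies with complementary strengths are combined in this package:

* **Well-tempered metadynamics (MetaD)** deposits repulsive Gaussian hills
  along a collective variable (CV), progressively filling the occupied
  basin. It is powerful when the CV captures the slow mode, and degrades —
  sometimes severely — when it does not.
* **Stochastic resetting (SR)** stops a trajectory at random (Poisson, rate
  $r$) or fixed (sharp, period $T$) times and restarts it from the initial
  state with fresh Maxwell–Boltzmann velocities. It needs no CV at all. A
  sufficient condition for SR to accelerate a process is that its
  first-passage-time (FPT) distribution is wider than exponential:
  $\mathrm{COV} = \sigma_\tau / \langle\tau\rangle > 1$.

The package simulates both, separately and combined, for a single Langevin
particle on analytic two-dimensional model potentials, and provides the
statistical machinery around them: FPT ensemble statistics, a closed-form
predictor of the mean FPT under Poisson resetting, and recovery of unbiased
kinetics from biased trajectories. When SR is combined with MetaD, every
resetting event also zeroes the accumulated bias, so the segments between
resets are independent short MetaD runs.

## Model potentials

Energies are expressed in units of $k_BT$ at 300 K, lengths in Å.

* `two_wells`: $V(x,y) = A_1 x^2 + A_2 y^2 + B e^{-C x^2}$ with
  $A_1 = 10^{-3}$, $A_2 = 10^{-2}$, $B = 5$, $C = 1.3$. A soft harmonic
  trap split by a Gaussian ridge: a barrier of $\approx 5\,k_BT$ at every
  $y$, minima near $x = \pm 2.6$ Å, walkers roaming tens of Å.
* `faradjian_elber`: $V(x,y) = A_1 (x^6 + y'^6) + A_2 e^{-x^2/\sigma_1^2}
  [1 - B e^{-y'^2/\sigma_2^2}]$, $y' = 0.1\,y$, with $A_1 = 1.2\times
  10^{-5}$, $A_2 = 12$, $B = 0.75$, $\sigma_1 = 1$, $\sigma_2 = 0.5$. The
  ridge is $\approx 12\,k_BT$ at large $|y|$ but has a narrow
  $\approx 3\,k_BT$ saddle at $y = 0$: the optimal CV is $x$, yet a
  trajectory must find the saddle, which rotated (suboptimal) CVs
  $s = x\cos\theta + y\sin\theta$ describe poorly.

`barrier_summary()` locates section minima and the intervening maximum by a
dense scan (default step $10^{-3}$ Å) plus golden-section refinement; the
analytic minima of the two-wells potential lie near $\pm 2.6$ Å, so the
conventional "states at $x = \pm 3$ Å" are used as the initial position and
stop threshold, not asserted to be stationary points.

```{r barriers}
barrier_summary(make_potential("two_wells"))$barrier_height
barrier_summary(make_potential("faradjian_elber"))$barrier_height
barrier_summary(make_potential("faradjian_elber"), y = 25)$barrier_height
```

## Dynamics

A single particle of mass 40 g/mol (argon-like) evolves under NVT Langevin
dynamics at 300 K with friction $\gamma = 0.01\ \mathrm{fs}^{-1}$ and
timestep 1 fs. The integrator is the BAOAB splitting — half kick, half
drift, exact Ornstein–Uhlenbeck velocity update, half drift, half kick —
chosen for its excellent configurational accuracy at finite timestep. Its
correctness is pinned by three oracles in the test suite: kinetic and
configurational equipartition in a harmonic well, the Einstein relation
$\langle \Delta x^2 \rangle = 2Dt$ with $D = k_BT/(m\gamma)$ for a free
particle, and a Boltzmann check of the in-well density. An independent
overdamped first-passage quadrature for the two-wells $x$-section gives
5.0 ns, and the moderate-friction barrier correction
($\gamma/\omega_b \approx 1.1$) brings the expected mean FPT to
$\approx 7.5$ ns, which the engine reproduces.

Internally the potential's reduced energies are converted with the fixed
unit $k_BT(300\,\mathrm{K}) = 2.4943\times 10^{-4}$ g Å² fs⁻² mol⁻¹, so the
model definition is independent of the thermostat setting.

First passage is declared the first step at which the committor-style
criterion on $x$ holds (checked every step, the finest unambiguous choice).
The FPT clock runs across resetting events; if a reset and a first passage
coincide on a step, the passage wins.

## Randomness

Each trajectory owns three independent xoshiro256++ streams derived from
`(seed, traj_id)` by splitmix64 mixing: dynamics noise, velocity
initialisation, and reset times. Turning resetting on therefore does not
perturb the dynamics stream — a trajectory that transits before its first
reset is bit-identical to its unreset twin, which the tests assert.
Poisson resetting pre-samples the next interval from $\mathrm{Exp}(r)$ and
rounds it up to the next integer step.

## Metadynamics details

Hills of initial height $0.5\,k_BT$ and width $\sigma$ (1.3 Å for the
two-wells model, 0.15 Å for the Faradjian–Elber model) are deposited every
`pace` steps along the linear CV, with the well-tempered scaling
$h \cdot \exp[-V_{bias}(s)/((\gamma_B - 1)k_BT)]$, $\gamma_B = 10$, using
the bias at the new hill's centre at deposition time (the standard
convention). A deposition rate in ns⁻¹ maps to `pace = round(1/(rate·dt))`;
$10^4$ ns⁻¹ is one hill per 100 steps.

Bias energy *and* its analytic derivative are accumulated on a grid
(spacing 0.01 Å, hills truncated at $6\sigma$) and linearly interpolated,
so force queries are $O(1)$ and free of finite-difference noise; the grid
derivative is the exact sum of the logged hill gradients. The grid spans
±500 Å by default: once a soft trap is partially filled, well-tempered
deposition lets walkers surf the bias front to excursions of hundreds of
Å before first passage (±285 Å was observed in pace-100 runs on the
two-wells model), and a CV value outside the grid raises an error rather
than clamping, so that a genuinely misconfigured grid cannot silently
corrupt the bias. After every reset the grid, the hill log and the
per-segment hill clock start from zero; the next hill comes `pace` steps
after the reset.

For kinetics inference the engine also accumulates, per segment, the
exposure integral $I = \sum_t \mathrm{d}t\, e^{V_{bias}(s(t),t)/k_BT}$ —
the standard acceleration-factor rescaling of infrequent metadynamics
(iMetaD). Bias is non-negative, so $I$ never falls below the real segment
duration.

## First-passage statistics and the resetting predictor

`fpt_summary()` reports the mean FPT, the population standard deviation
(so that an exponential ensemble has COV exactly 1), the SEM
$\sigma/\sqrt{N}$, and the COV. The mean FPT under Poisson resetting at
rate $r$ is predicted from FPT samples *without* resetting by
$$\langle\tau\rangle_r = \frac{1 - \tilde f(r)}{r \tilde f(r)}, \qquad
\tilde f(r) = \frac{1}{N}\sum_{j=1}^N e^{-r\tau_j},$$
with the $r \to 0$ limit (the sample mean) taken analytically.
Closed-form consequences are used as tests: an exponential ensemble is
invariant under resetting at any rate, a deterministic ensemble is always
slowed ($\langle\tau\rangle_r = (e^{r\tau_0}-1)/r \ge \tau_0$), and the
initial slope of the speedup curve has the sign of $\mathrm{COV} - 1$.
Note that $\mathrm{COV} < 1$ only pins the initial slope: a finite
resetting rate can still accelerate such a process, which is why the
predictor is worth evaluating either way. `optimal_reset_rate()` scans a
logarithmic grid (32 points per decade) and refines the argmax by
golden-section search to 1% in rate. Censored samples are rejected by
these estimators; censoring belongs to the survival-based inference layer.

```{r predictor}
mix <- synthesize_fpt_ensemble("mixture", n = 2000, rates = c(10, 0.1),
                               weights = c(0.9, 0.1), seed = 1)
fpt_summary(mix)$cov
optimal_reset_rate(mix, lower = 0.01, upper = 100)[c("r_star", "max_speedup")]
```

## Kinetics inference from biased, reset trajectories

Between resets, trajectories are ordinary iMetaD runs, and because
resetting erases both position and bias, segments are independent. Each
segment contributes its rescaled duration: as an event if the passage
occurred inside it, right-censored otherwise. The unbiased survival is
estimated by the Kaplan–Meier product limit (delegated to
`survival::survfit`; events precede censorings at ties), an exponential
decay is fitted to $\ln S$ by weighted least squares (weights = per-point
event counts), and $\langle\tau\rangle_{est} = 1/k$. The default fit
window keeps rescaled times where at least 20% of segments are still at
risk and excludes $t^* = 0$: over-deposition with suboptimal CVs corrupts
the long-time rescaled tail, while short rescaled times stay reliable —
the reason resetting improves the speedup/accuracy tradeoff in the first
place. The fit's $R^2$ and a Kolmogorov–Smirnov distance against the
fitted exponential are reported as reliability scores; a survival plateau
(an unreachable sub-population) shows up as a poor fit, not a silent
wrong answer. `tradeoff_scan()` drives the full pipeline over bias rates
and sharp-resetting periods and reports (speedup, prediction error) pairs,
with the error defined as
$|\langle\tau\rangle_{true} - \langle\tau\rangle_{est}| /
\langle\tau\rangle_{true}$.

## Problem sizes and numerical choices

Reference ensembles in the tests and the acceptance script use 100–1000
trajectories per condition (the original studies of these models used
$10^4$); all comparisons therefore carry SEM-aware tolerances, and sweep
argmaxes are only trusted to within a grid factor of 2. Direct
simulation of resetting rates far above the optimum is avoided on
purpose: at 500 ns⁻¹ the mean inter-reset interval (2 ps) is far below
any possible transit time of the two-wells barrier, so the resetting MFPT
grows beyond any desk-scale budget; sweeps bracket the optimum instead.
Trajectories exceeding `max_steps` (default $10^9$) are flagged censored
and excluded from moment statistics rather than dropped silently.

The synthetic-ensemble generator (`synthesize_fpt_ensemble()`) draws from
families with closed-form moments (exponential, deterministic, lognormal,
two-exponential mixture) to test the analytics without simulation. What
passing these tests shows is that the estimators are correct on clean
i.i.d. FPT samples; what they cannot show is robustness to features of
real molecular data — correlated replica batches, multi-state kinetics
with comparable timescales, or CVs whose quality varies along the path —
beyond the specific suboptimal-CV scenarios simulated here.

## Known limitations

* Single particle, two dimensions, analytic potentials only; no
  force-field or periodic-boundary support, and no all-atom systems.
* One-dimensional linear CVs only ($x\cos\theta + y\sin\theta$).
* No free-energy reconstruction: recovering free-energy surfaces from
  simulations with resetting is an open methodological problem, and MetaD
  reweighting without resetting is out of scope here.
* The exponential-survival assumption of the inference layer is exactly
  that — an assumption; the quality scores flag, but cannot repair, its
  failure.
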