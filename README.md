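# resetMetaD

Langevin-dynamics simulator and analysis toolkit for **combining stochastic
resetting (SR) with well-tempered metadynamics (MetaD)** on analytic 2D model
potentials, with first-passage statistics and unbiased-kinetics recovery.

## Who this is for

Researchers in enhanced sampling and rare-event kinetics who want a
self-contained, fully reproducible test bed for resetting-based
acceleration: how much speedup SR alone gives, how much MetaD alone gives,
what the combination adds, how the answer degrades with suboptimal
collective variables (CVs), and how to recover the unbiased mean
first-passage time (MFPT) from biased, reset trajectories.

## What it computes

A single particle (m = 40 g/mol) evolves under NVT Langevin dynamics
(T = 300 K, γ = 0.01 fs⁻¹, dt = 1 fs, BAOAB integrator) on one of two
analytic potentials (energies in units of k_BT at 300 K, lengths in Å):

* **two wells** — V(x,y) = A₁x² + A₂y² + B·exp(−Cx²): a soft trap split by
  a ~5 k_BT ridge at every y;
* **modified Faradjian–Elber** — a ~12 k_BT ridge with a narrow ~3 k_BT
  saddle at y = 0, where rotated CVs s = x·cosθ + y·sinθ become
  progressively suboptimal.

On top of the simulator:

* **Well-tempered MetaD** along a linear CV (height 0.5 k_BT, bias factor
  10, grid spacing 0.01 Å), with the bias **zeroed at every resetting
  event**;
* **First-passage statistics** — MFPT, SEM = σ/√N, COV = σ/⟨τ⟩ — and the
  closed-form predictor of the MFPT under Poisson resetting at rate r from
  samples *without* resetting:

  ⟨τ⟩_r = (1 − f̃(r)) / (r·f̃(r)),  f̃(r) = ⟨e^{−rτ}⟩ ≈ (1/N)Σⱼ e^{−rτⱼ},

  with optimal-rate search over a log grid (COV > 1 guarantees that a small
  resetting rate accelerates);
* **Kinetics inference** — per-segment iMetaD rescaling
  τ* = Σ dt·e^{V_bias/k_BT}, Kaplan–Meier survival over rescaled segment
  durations (reset-terminated segments are right-censored), exponential fit
  of ln S at short rescaled times, and the prediction error
  |⟨τ⟩_true − ⟨τ⟩_est| / ⟨τ⟩_true.

## Worked example

```r
library(resetMetaD)

pot  <- make_potential("two_wells")
th   <- thermo_config()                 # 300 K, 40 g/mol, 0.01 fs^-1, 1 fs
stop <- stop_criterion("le", -3)        # first passage: x <= -3 A

# unbiased baseline, 100 independent trajectories from (3, 0) A
base <- run_fpt_ensemble(100, pot, th, stop, c(3, 0), seed = 1)
fpt_summary(base)[c("mfpt", "sem", "cov")]
#> $mfpt
#> [1] 6.29292
#> $sem
#> [1] 0.6001457
#> $cov
#> [1] 0.953684

# where would Poisson resetting help most? (no further simulation needed)
optimal_reset_rate(base, lower = 1, upper = 1000)[c("r_star", "max_speedup")]
#> $r_star
#> [1] 20.47277
#> $max_speedup
#> [1] 2.370064

# MetaD along x (one hill per 100 steps), plus resetting at 125 ns^-1
cfg  <- metad_config(width = 1.3, pace = 100)
both <- run_fpt_ensemble(100, pot, th, stop, c(3, 0), metad = cfg,
                         schedule = reset_schedule("poisson", rate = 125),
                         seed = 2)
speedup(base, both)$speedup
#> [1] 113.7517
```

The baseline MFPT of 6.3 ± 0.6 ns is within sampling error of the 7.5 ns
reference value for this model; with only 100 trajectories the COV and the
predictor's optimal rate are still noisy (larger ensembles sharpen them
toward COV ≈ 1.05 and r* ≈ 50 ns⁻¹), which is exactly why the test suite
checks every such number against SEM-aware tolerances. Combining MetaD
with resetting yields a two-orders-of-magnitude speedup over the unbiased
baseline.

A thin CLI over the same functions lives at `inst/cli/resetmetad.R`
(subcommands `run`, `analyze`, `predict-speedup`, `infer`, `synth`; JSON
configs documented in the script header).

## Package layout

* `R/`, `src/` — potentials, BAOAB/MetaD/resetting engine (Rcpp), FPT
  statistics, resetting predictor, survival-based kinetics inference,
  experiment runner, synthetic-ensemble generator.
* `tests/testthat/` — unit and property tests (finite-difference gradient
  oracles, equipartition/Einstein-relation checks, closed-form resetting
  limits, hand-worked Kaplan–Meier tables, end-to-end acceptance checks).
* `vignettes/resetting-metadynamics.Rmd` — the methods vignette: model,
  assumptions, parameter meanings, numerical choices, limitations.
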