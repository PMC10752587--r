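# mtcoupler

Simulation and analysis of mechanically coupled microtubule growth.

During mitosis, kinetochore-attached microtubules grow as bundles (k-fibers)
whose plus-ends stay within a fraction of a micrometer of each other, even
though individual microtubules grow at intrinsically variable rates and pause
stochastically. One proposed coordination mechanism is purely mechanical:
when tips share a tensile load through an elastic linkage, a lagging tip
carries more tension, and tension accelerates growth and suppresses pausing,
so the laggard catches up. `mtcoupler` provides the computational side of
testing that idea: a zero-free-parameter stochastic model of coupled
microtubule pairs, and the trace-analysis statistics used to confront it
with dual-trap force-clamp recordings. It is aimed at single-molecule
biophysicists working with laser-trap recordings of microtubule dynamics,
and at modelers exploring load-sharing in filament bundles.

## The model

Two tips at positions x1, x2 are connected by identical Hookean springs
(stiffness kappa) to a massless coupler bearing a constant total tension
F_TOT. Static force balance gives, for N tips,

    F_i = F_TOT/N + kappa * (mean(x) - x_i),

so forces always sum to F_TOT and, for a pair, F1 - F2 = kappa (x2 - x1):
the lagging tip carries more tension.

Growth kinetics follow single-exponential (Bell-type) force laws

    k_EN(F)  = k_EN0 exp(F/F_EN)     pause entrance (F_EN < 0)
    k_EX(F)  = k_EX0 exp(F/F_EX)     pause exit
    v_RUN(F) = v_0   exp(F/F_RUN)    growth speed during runs
    v_g(F)   = v_g0  exp(F/F_g)      growth speed, non-pausing model

with defaults k_EN0 = 19.4 min⁻¹, F_EN = −4.6 pN, k_EX0 = 9.0 min⁻¹,
F_EX = 14.1 pN, v_0 = 0.52 µm·min⁻¹, F_RUN = 14.8 pN, F_g = 8.4 pN, taken
from force-clamp measurements of single kinetochore-attached microtubules.
Per-microtubule heterogeneity enters by drawing each simulated tip's
intrinsic unloaded speed from a pool of (speed, force) measurements,
extrapolated to zero load along the relevant law (draws above 30 nm/s
unloaded are rejected as outliers). Pairs are simulated with a modified
Gillespie scheme: all switching and termination events are Poisson at the
current forces, waiting times are capped at 1 s so force-dependent rates
stay locally constant, and forces are recomputed from positions at every
step.

The analysis half of the package mirrors the experimental pipeline:
sliding-window (2 s) velocity estimation, per-recording Gaussian-mixture
speed thresholds, run/pause segmentation with a 1-s minimum event duration,
force-binned rate estimation with exponential fits, tip-separation ensemble
statistics, Kaplan-Meier survival of separation-threshold exceedance with a
log-rank comparison, and a normalized-histogram likelihood comparison of
pausing versus non-pausing models.

## Worked example

```r
library(mtcoupler)

## forces on two coupled tips that have drifted 0.4 um apart
cfg <- coupler_config(kappa = 5, f_total = 8)
partition_force(c(0, 0.4), cfg)
#> [1] 5 3

## simulate a coupled pair with the pausing model
params <- synthetic_params()     # kinetic defaults + synthetic termination laws
pool <- gen_intrinsic_pool(356, params = params, law = "run", seed = 1)
v0 <- sample_intrinsic_speed(pool, params$run_speed$force_scale, n = 2, seed = 2)
traj <- simulate_pair(cfg, params = params, model = "pausing",
                      v0 = v0, duration = 400, seed = 3)
traj
#> Coupled-pair trajectory (pausing model): 131 grid points, censored at 130.2 s (detachment)

## ensemble comparison: soft (1 pN/um) vs stiff (5 pN/um) couplers
soft  <- gen_dual_trap_dataset(200, coupler_config(1, 8), params = params,
                               pool = pool, seed = 4)
stiff <- gen_dual_trap_dataset(200, coupler_config(5, 8), params = params,
                               pool = pool, seed = 5)
s_soft  <- lapply(soft, separation_series)
s_stiff <- lapply(stiff, separation_series)
m <- ensemble_mean_sem(s_soft);  m[m$time == 300, ]
#>     time mean_sep       sem  n
#> 301  300 1.052075 0.1206179 54
m2 <- ensemble_mean_sem(s_stiff); m2[m2$time == 300, ]
#>     time  mean_sep        sem  n
#> 301  300 0.5062095 0.05573086 58
```

At 300 s the stiff-coupled ensemble's mean tip separation (0.51 ± 0.06 µm
over the 58 pairs still growing) is about half the soft-coupled one
(1.05 ± 0.12 µm over 54 pairs): stiffer load-sharing keeps the tips
together. Survival analysis asks how often pairs stay within 0.8 µm:

```r
km_soft  <- km_curve(exceedance_table(s_soft, 0.8),  horizon = 400)
km_stiff <- km_curve(exceedance_table(s_stiff, 0.8), horizon = 400)
c(soft = km_soft$surv[km_soft$time == 400],
  stiff = km_stiff$surv[km_stiff$time == 400])
#>      soft     stiff
#> 0.4401719 0.6215646
logrank(exceedance_table(s_soft[1:50], 0.8),
        exceedance_table(s_stiff[1:43], 0.8))[c("chisq", "p")]
#> $chisq
#> [1] 2.798118
#> $p
#> [1] 0.09437502
```

62% of stiff-coupled pairs never exceed 0.8 µm within 400 s, against 44%
of soft-coupled pairs; the log-rank test compares the two exceedance
curves at dual-trap sample sizes (50 vs 43 pairs).

A synthetic force-clamp recording runs through the segmentation pipeline
the same way real traces do:

```r
rec <- gen_force_clamp_recording(force = 4, params = kinetic_params(),
                                 v0 = 0.6, duration = 300, seed = 6)
segment_recording(rec)$summary
#>     id force entrances exits time_run time_pause run_speed threshold
#> 1 <NA>     4        16    16  223.595     76.405 0.6780933 0.1040439
```

A thin command-line wrapper (`inst/cli/mtcoupler.R`) exposes the same
pipeline as `synth`, `simulate`, `segment`, `rates`, `pairs`, and
`survival` subcommands.

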