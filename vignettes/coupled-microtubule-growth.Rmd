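---
title: "Modeling and analyzing mechanically coupled microtubule growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and analyzing mechanically coupled microtubule growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtcoupler)
```

`mtcoupler` simulates pairs of growing microtubules that share a constant
tensile load through identical elastic linkages, and implements the trace
statistics used to compare such simulations with dual-trap laser-trap
recordings. This vignette explains the model and its assumptions, the
estimation procedures, the choices made where the design was genuinely
open, and what the package's synthetic data can and cannot tell you about
real recordings.

## The spring-coupler force partition

The kinetochore is modeled as a massless node connected to each microtubule
plus-end by a Hookean spring of stiffness $\kappa$ and bearing a constant
total tension $F_{TOT}$. Because k-fibers move slowly, viscous drag on the
node is neglected, so the spring tensions always balance the load. For $N$
tips at positions $x_i$ along a shared axis the unique static solution is

$$F_i = \frac{F_{TOT}}{N} + \kappa(\bar{x} - x_i),$$

implemented in `partition_force()`. For a pair this reduces to
$F_1 - F_2 = \kappa (x_2 - x_1)$: the lagging tip carries more tension.
The partition is purely linear; at large separations the leading tip's
force can reach zero and go negative. Real instruments cannot push through
a slack linkage, so `coupler_config()` exposes an optional per-tip force
floor, off by default because the model itself never clamps. Microtubules
are treated as incompressible and stationary except for plus-end growth,
so tip position is the only mechanical coordinate.

## Force-dependent kinetics

Every rate and speed follows a single-exponential force law
$y(F) = A \exp(F/F_s)$ (`exp_law()`, `eval_law()`), with the sign of the
characteristic force $F_s$ encoding the direction of sensitivity. The
bundled defaults (`kinetic_params()`) are the fitted values from a large
force-clamp dataset of single kinetochore-attached microtubules:

| quantity | amplitude | characteristic force |
|---|---|---|
| pause entrance $k_{EN}$ | 19.4 min⁻¹ | −4.6 pN |
| pause exit $k_{EX}$ | 9.0 min⁻¹ | 14.1 pN |
| run speed $v_{RUN}$ | 0.52 µm·min⁻¹ | 14.8 pN |
| growth speed (non-pausing) | per-microtubule | 8.4 pN |

Tension therefore suppresses pausing (slower entrance, faster exit) and
accelerates growth during runs. The laws were measured between 0.5 and
18 pN; evaluation outside that range warns rather than fails, because
coupled simulations can transiently leave it.

The rates at which growth episodes end — detachment, catastrophe, and a
force-independent "interruption" — were estimated in the original
force-clamp study but their values are not bundled here. They are
configuration inputs: simulations error if no termination law is supplied
unless termination is explicitly disabled, and
`synthetic_termination_laws()` provides clearly-labelled synthetic
stand-ins (detachment $0.05\,e^{F/18}$, catastrophe $0.05\,e^{-F/11}$,
interruption $0.03$ min⁻¹) whose magnitudes let most simulated pairs grow
for several minutes, comparable to the attrition seen in dual-trap
recordings.

### Intrinsic heterogeneity

Individual microtubules keep persistently different growth speeds for many
minutes. The models capture this by drawing, for each simulated
microtubule, one (speed, force) measurement from a pool and extrapolating
it to zero load along the relevant law (`extrapolate_unloaded()`,
`sample_intrinsic_speed()`). The pausing model draws from run-speed
measurements and rejects draws whose unloaded speed exceeds 30 nm/s
(1.8 µm·min⁻¹) as outliers; the non-pausing model draws from whole-trace
growth-speed measurements, unfiltered. The ergodic variant gives both tips
the run-speed law amplitude, isolating the variability contributed by
pausing alone.

## The modified Gillespie simulator

`simulate_single()` and `simulate_pair()` share one engine. All active
events (state switching plus any termination laws) are independent Poisson
processes at the current per-tip forces; one joint exponential waiting time
is drawn from the summed rates. Because the rates are force-dependent they
are only locally Poisson, so the step is capped at `dt_max` (default and
maximum 1 s) and at the next output grid point: if the drawn waiting time
exceeds the cap, the tips simply advance deterministically for the capped
interval and rates are re-evaluated. Between events a tip grows at its
current state's speed (zero in pause) with no subunit-level noise —
variability comes from switching and heterogeneity, matching the smooth
ramps seen in non-pausing traces. Pairs start side by side
($x_1 = x_2 = 0$), both in run, each carrying $F_{TOT}/2$; forces are
recomputed from positions after every step, effectively continuously
relative to the 1-s cap (instrument feedback latency is not modeled). The
first terminating event on either tip censors the pair's usable trace at
that moment; censored pairs contribute to ensemble statistics up to their
censoring time and are never discarded or resimulated. SEM over a single
surviving pair is reported as missing, not zero.

Determinism: every stochastic entry point takes a seed, and regeneration
under the same seed is bit-identical.

## Run/pause segmentation

Force-clamp recordings (nominally 200 Hz) are segmented in three steps,
mirroring the experimental analysis:

1. **Velocity.** `sliding_velocity()` computes, at every sample where a
   centered 2-s window fits, the OLS slope of position versus time over
   the window. Edge samples carry no estimate and inherit the adjacent
   interval's label.
2. **Threshold.** `pause_threshold()` builds a histogram of the
   instantaneous speeds (Freedman–Diaconis bin width, configurable) and
   fits it with sums of 2–6 Gaussian peaks by damped least squares. The
   original analysis used interactive multipeak fitting; the automatic
   rules here are: model order grows until the residual sum of squares
   improves by less than 5% (configurable); component standard deviations
   are bounded below by one bin width, because a peak narrower than the
   histogram's resolution is an artifact, not a kinetic state; the
   component with mean nearest zero and within 0.1 µm·min⁻¹ (configurable)
   is the pause peak, and a second component inside that tolerance counts
   as pause structure, not as a growth state. The threshold is the speed
   at which the pause peak's density intersects that of the lowest-mean
   qualifying component, between the two means (closed-form quadratic,
   midpoint fallback if the densities never cross). If no component
   qualifies as a pause peak the recording is a single run.
3. **Segmentation.** `segment_trace()` labels samples below the threshold
   as provisional pauses, then iteratively absorbs any interior interval
   shorter than 1 s into its flanking opposite-label intervals (three
   become one), shortest interval first so rare cascades resolve
   deterministically. Trace-boundary intervals may be shorter than 1 s;
   their opening/closing transitions are not counted as entrances or
   exits, though their time counts toward occupancy.

`recording_run_speed()` is the duration-weighted mean of per-interval mean
speeds over run intervals, $v_{run} = \sum_i v_i t_i / T$.

## Rate estimation and force-law fits

`bin_recordings()` groups recordings by their nominal clamp force into the
standard seven bins (edges 0.69, 1.94, 2.97, 3.999, 5.98, 7.99, 10.3,
18 pN) and computes per bin: $k_{EN}$ = entrances / time-in-run, $k_{EX}$
= exits / time-in-pause, counting SEMs $k/\sqrt{N_{events}}$, mean run
speed with SEM $\sigma/\sqrt{N_{recordings}}$, and force mean/SD.
`fit_rate_law()` fits $A\,e^{F/F_s}$ to the per-bin values against mean
bin force by Levenberg–Marquardt least squares, initialized from a
log-linear regression. Fits are unweighted (a 1/SEM² option exists but is
off, since the reference analysis reports plain least squares), and the
highest force bin is excluded by default for the entrance/exit rates
because of low statistics.

## Pair statistics, survival, and model comparison

`separation_series()` resamples $|x_1 - x_2|$ at 1-s intervals
(nearest-sample lookup, configurable by step); `ensemble_mean_sem()`
averages over pairs still growing at each time with SEM
$\sigma_t/\sqrt{N_t}$; `separation_rate()` fits the first 100 s to a line
(OLS, to which the damped iterative method reduces for a line) and
reports the slope in µm·min⁻¹ with a residual-based standard error.

`km_curve()` computes the product-limit estimate of the probability that
tip separation has not yet exceeded a threshold (0.4/0.6/0.8/1.2 µm by
convention), on a 1-s grid, with SEM
$S_t\sqrt{\sum_j d_j/(n_j(n_j-d_j))}$ (Greenwood's formula). Censorings
at the same integer second as events are processed after the events. When
$n_j = d_j$ the SEM term is singular and the SEM is missing from that time
on. `logrank()` sums observed and expected counts
($E_t = n_t d_{tot}/n_{tot}$) over the 400 1-s steps and refers
$\sum_g (O_g - E_g)^2 / E_g$ to $\chi^2_1$. `rank_sum_test()` is the
standard two-sided Wilcoxon–Mann–Whitney test (exact for small untied
samples, tie-corrected normal approximation otherwise).

`separation_histogram()` bins tip separations in 0.1-µm bins from zero and
normalizes to unit area; the likelihood of one measurement is
$L = w_{bin} P_{normalized}$ in its bin, and `total_log_likelihood()` sums
$\log_{10} L$. Empty model bins are floored at half a count
($0.5/(n\,w_{bin})$, configurable, zero to disable) so one unanticipated
observation does not drive the total to $-\infty$; the histogram support
extends to the larger of the model's and data's range, padded one bin.

## The synthetic-data generator

Because the deposited recordings are not bundled, `gen_force_clamp_recording()`,
`gen_intrinsic_pool()`, and `gen_dual_trap_dataset()` generate data with
the statistical structure the analysis assumes:

- **Force-clamp corpus** (`corpus_spec()`): recording counts per force bin
  default to the reference corpus occupancy (41, 85, 77, 60, 60, 25, 9;
  357 recordings), forces uniform within bins, durations equal to the
  reference corpus' mean observed time per recording in each bin (89–447 s),
  two-state trajectories from the Gillespie engine, 200-Hz sampling, and
  i.i.d. Gaussian position noise (SD 0.01 µm — a realistic bead-tracking
  noise floor; real trap noise is colored, but the 2-s regression window
  suppresses high-frequency structure, so white noise is an adequate
  stand-in for segmentation purposes).
- **Intrinsic speeds**: per-microtubule heterogeneity is a log-normal
  multiplier on the run-speed law with coefficient of variation 0.5 (the
  spread visible in run-speed scatter at fixed force) and **unit mean**.
  Unit mean, rather than unit median, keeps the generator self-consistent
  with the estimator, which recovers per-bin *mean* run speeds; a
  median-tied multiplier at CV 0.5 would build in a +12% bias on the
  recovered amplitude. The whole-trace growth-speed pool used by the
  non-pausing model is generated the way such datasets arise in practice:
  each entry is the total displacement over duration of a simulated
  two-state trace, so its spread combines intrinsic heterogeneity with
  pause-occupancy fluctuations.
- **Dual-trap datasets**: coupled-pair simulations with noise added on the
  1-s grid, censoring from the synthetic termination laws, and soft/stiff
  condition labels.

Generated artifacts carry their ground truth (true switch times,
intrinsic speeds, seeds) as attributes, and regeneration is bit-identical
under the same seed. The generator does **not** emulate bead–trap
mechanics, feedback latency, drift, colored noise, shortening episodes, or
the true (unknown) shape of the intrinsic-speed distribution.

## What passing tests show — and known limitations

The test suite verifies the force partition against numeric equilibrium
oracles, the simulator's dwell-time distributions and stationary occupancy
against two-state theory, the survival and rank statistics against
independent implementations (`survival::survfit`/`survdiff`, exhaustive
enumeration), and the full generate → segment → bin → fit chain at the
default corpus scale. Ensemble sizes in tests and in
`scripts/acceptance.R` (1000–1500 pairs, 357-recording corpora) were
chosen so Monte-Carlo error is small relative to the effects checked while
a full run stays within a few minutes on one CPU.

Two limitations deserve emphasis:

- **Segmentation attenuates switching rates.** A 2-s velocity window and a
  1-s minimum event duration cannot detect dwells much shorter than ~1 s.
  With the default kinetics (mean dwells of roughly 3–22 s depending on
  force and state), a noticeable fraction of true events is undetected;
  missed pauses also inflate time-in-run, and window ramps contaminate
  interval speed means near boundaries. Re-measuring simulated data
  through the pipeline therefore recovers the force-sensitivity *signs and
  scales* well but systematically underestimates the rate *amplitudes*
  (running `scripts/acceptance.R` quantifies this against the known
  generating values). The same attenuation necessarily affected the
  original measurements, so the bundled default parameters should be read
  as "rates as seen through this segmentation procedure", not as true
  microscopic switching rates — and re-fitting simulated data is expected
  to land below them. Conclusions that rest on force-dependence directions
  and relative changes are robust to this; absolute rate comparisons
  across different segmentation settings are not.
- **Model discrimination depends on the data's information content.** The
  pausing and non-pausing models, both fed by measurement pools of the
  default spread, predict similar tip-separation distributions at 100 and
  200 s under both coupler stiffnesses. The histogram-likelihood machinery
  correctly prefers the generating model *on average*, but at dual-trap
  sample sizes (~93 pairs) the preference is not near-certain on any
  single replicate. Large likelihood gaps arise when a model genuinely
  misfits the data, not between near-equivalent models.
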