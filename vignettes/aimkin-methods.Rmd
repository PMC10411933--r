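---
title: "Methods: task logic, synthetic performer, and kinematic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task logic, synthetic performer, and kinematic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the modelling and numerical decisions behind
`aimkin`. It is the reference for *why* the package behaves the way it does;
function-level documentation covers *what* each function computes.

## 1. The task

The package implements the logic of a centre-out shooting task of the kind
used to study aiming in first-person-shooter (FPS) style interfaces. A cursor
starts at a central position; a circular target (diameter 0.2 arbitrary
units, "au") appears at a prescribed distance and angle; the participant
moves the cursor into the target and clicks before a per-trial time limit.

Two visuomotor **contexts** are equated so that the same physical hand
movement produces the same effective cursor path:

- **Point**: hand displacements translate the cursor on a plane
  (`point_step()`).
- **Look**: hand displacements pan/tilt a camera; the cursor is the centre of
  the view projected onto the same plane (`look_pose_for_cursor()`,
  `cursor_for_look_pose()`).

`scene_config()` fixes the geometry: a 60° vertical field of view and a
plane distance chosen so the view exactly spans the scene,
`plane_distance = scene_height / 2 / tan(fov/2)`. The equating is exact by
construction — `effective_cursor_path()` maps a hand trajectory through
either context and lands on identical plane coordinates — and the test suite
asserts bitwise identity of the two paths over thousands of random
trajectories. This is a design decision: the contexts differ only in the
*control* mapping presented to the performer (and, in the synthetic
performer, in small latency penalties), never in geometry.

Two session types are supported:

- **Experiment 1** (`exp1_block()`, `simulate_experiment1()`): 320 trials
  per context, 40 cycles of the 8 angles (0–315° in 45° steps) at 1 au.
  The per-trial time limit is driven by two interleaved one-up/one-down
  **staircases** starting at 300 and 1,500 ms with a fixed 30 ms step,
  scheduled in balanced random pairs so neither staircase runs ahead. The
  one-up/one-down rule converges on the time limit yielding 50% success;
  the **asymptotic limit** is summarised as the median limit over the last
  40 trials of each staircase (80 trials pooled).
- **Experiment 2** (`exp2_round()`, `simulate_experiment2()`): 20 rounds of
  48 targets. Each round is two cycles of the 24 combinations of distance
  {0.4, 0.6, 0.8} au × 8 angles, each target placed relative to the
  *previous* target (chained displacements) under a 1 au workspace cap.

### Target sequencing by per-cycle rejection

Because each cycle's 24 displacement vectors sum to zero, a cycle is a
closed loop returning to the centre. `exp2_round()` therefore shuffles and
tests **one cycle at a time**, rejecting any shuffle whose running position
leaves the 1 au disc. Measured acceptance needs ~600 shuffles per cycle on
average, so a round generates in milliseconds; rejection over whole rounds
would be dramatically slower for no statistical benefit, and per-cycle
rejection preserves the marginal uniformity of orderings within the
feasible set of each cycle independently.

## 2. The synthetic performer

`simulate_trial()` produces a cursor trajectory from a generative movement
model. The generator is first-class, tested code, not a test fixture: it is
the package's substitute for deposited raw data, and the analysis pipeline
is validated against its analytically known ground truth.

### Primary movement: minimum-jerk kernel

The primary movement follows the minimum-jerk position profile
$s(\tau) = D\,(10\tau^3 - 15\tau^4 + 6\tau^5)$, $\tau = t/T$, whose speed is
bell-shaped with peak $1.875\,D/T$ at $\tau = 0.5$. Movement duration is
linear in amplitude, $T = \text{mt\_intercept} + \text{mt\_slope} \cdot D$.

**Duration uses the *intended* amplitude, not the realised (noisy) one.**
If duration were recomputed from the noisy amplitude, peak speed
($1.875\,D/T$) would partially cancel the amplitude noise and peak-speed
variability would *shrink* with distance — the opposite of
signal-dependent noise. Planning duration from the intended amplitude
keeps peak-speed SD increasing with distance, as required of
signal-dependent motor noise.

### Noise, undershoot and corrections

- Extent noise is multiplicative: SD $= \text{extent\_cv}\cdot D$
  (signal-dependent). Direction noise has fixed SD `angle_sd` = 2°.
- The primary movement aims at `undershoot_frac` × D (default **0.92**).
  Values ≥ ~0.9 with a 0.1 au target radius put the noiseless endpoint of a
  1 au movement essentially on the target boundary; 0.92 places it 0.08 au
  inside, so the noiseless generator reliably enters the target with the
  primary movement alone. Undershooting-then-correcting is the classic
  speed–accuracy strategy for rapid aiming.
- If the cursor is outside the target after a movement ends, a corrective
  submovement starts after `corr_latency` (120 ms), covering
  `corr_gain` (0.75) of the remaining error with proportional noise, up to
  `max_submovements` (10) times. The click follows a lognormal dwell
  (median 160 ms) after final target entry.

### Reaction time and context penalties

Reaction time is shifted-lognormal: `rt_shift` (150 ms, an explicit
non-decision floor added so the RT distribution has a realistic lower bound)
plus a lognormal with median 130 ms. The Look context adds small penalties
(`look_rt_penalty` = 25 ms to RT, `look_corr_penalty` = 24 ms to corrective
latency), reflecting the empirically slower camera-pan context; these
penalties are the *only* behavioural difference between contexts in the
generator.

### Learning

Practice effects follow a dual-rate multiplier
$m(r) = 1 + a_f e^{-\lambda_f (r-1)} + a_s e^{-\lambda_s (r-1)}$
(defaults $a_f = 0.45$, $\lambda_f = 0.4$, $a_s = 0.25$,
$\lambda_s = 0.05$) applied per round/cycle: latencies and noise scales get
the full multiplier (log-additively for lognormal locations); movement-time
parameters get only the slow component, since tempo improves more slowly
than latency. Early improvement is steep, late improvement shallow.

### Default parameters

| Parameter | Default | Rationale |
|---|---|---|
| `rt_shift`, `rt_location`, `rt_scale` | 150 ms, log(130), 0.25 | shifted-lognormal simple RT; median ≈ 280 ms |
| `mt_intercept`, `mt_slope` | 120 ms, 380 ms/au | linear amplitude–duration scaling; 1 au movement ≈ 500 ms |
| `extent_cv` | 0.08 | signal-dependent extent noise, ~8% CV |
| `angle_sd` | 2° | directional noise, roughly isotropic error at short range |
| `undershoot_frac` | 0.92 | primary endpoint inside the target in the noiseless case (see above) |
| `corr_latency`, `corr_gain` | 120 ms, 0.75 | iterative corrections with partial error reduction |
| `dwell_location`, `dwell_scale` | log(160), 0.3 | verification dwell before the click |
| `look_rt_penalty`, `look_corr_penalty` | 25 ms, 24 ms | context cost of camera control |
| `amp_fast`/`learn_fast`, `amp_slow`/`learn_slow` | 0.45/0.4, 0.25/0.05 | dual-rate practice curve |
| `frame_rate` | 60 Hz | sampling grid; ≥ 30 enforced |
| `max_submovements` | 10 | hard cap against pathological correction loops |

Validation in `performer_params()` enforces internal consistency (e.g.
`corr_gain` ∈ (0, 1], `frame_rate` ≥ 30, and extent noise dominating
angular noise when both are nonzero).

### What the generator does and does not emulate

Emulated: bell-shaped speed profiles, amplitude–duration scaling,
signal-dependent noise, undershoot-and-correct structure, context latency
costs, dual-rate learning, frame-quantised sampling, staircase-driven
success/failure.

Not emulated: online (within-movement) feedback corrections, endpoint noise
with an additive floor (noise is purely multiplicative, so the Fitts
**effective index of difficulty is near-constant across distances** — W~e~
scales with D — and an effective-ID gradient must come from real data),
fatigue, anticipatory strategies, frame-time jitter, and device-specific
transfer functions. `fitts_fit()` is therefore exercised on constructed
data in the tests, and on the generator only for sanity, not for slope
recovery.

## 3. Ground truth and segmentation

Every simulated trial carries a `ground_truth` table computed
**analytically** from the continuous minimum-jerk model, independent of the
discrete sampling pipeline:

- onset/offset = exact crossings of speed = 0.5 au/s, found by `uniroot`
  on the closed-form speed;
- target entries = roots of $|p(s) - \text{target}| = r$ along the straight
  movement line (a quadratic in arc length), mapped back to time through
  the position profile.

One subtlety: with undershoot, the last analytic target entry can precede
the primary-movement end. The pipeline's convention (and the ground
truth's) is then `correction = 0` and dwell measured from the later of the
two boundaries, preserving the exact identity
`reaction + primary_mt + correction + dwell = acquire`.

The discrete pipeline (`segment_trial()`) mirrors standard kinematic
practice:

- speeds by central differences, smoothed by a 3-sample moving average
  (window on speeds only, positions untouched);
- onset = first sample with radial speed strictly above 0.5 au/s after
  target onset;
- primary end = after the tangential-speed peak, the first local minimum
  below 50% of the peak or the first drop below the onset threshold,
  whichever comes first; the click time as fallback;
- target entries use an inclusive boundary (radius 0.1 au); an unclosed
  final interval gets `exit_t = NA`.

The acceptance tests require the discrete pipeline to recover every
analytic boundary to within one frame (16.7 ms at 60 Hz) over 1,000
noiseless trials; in practice recovery is ~6 ms.

## 4. Metrics and statistical choices

- **Aligned endpoints** rotate each endpoint by (90° − target angle) so the
  target direction maps to +y; on-axis error is the aligned y coordinate.
- **Linearity** = maximum perpendicular deviation from the start–target
  chord, divided by D (an alternative path-length ratio is available via
  `method = "path_ratio"`). The maximum-deviation form is chosen as the
  primary definition because it is scale-free, insensitive to sampling
  density, and exactly 0.5 for a semicircular detour.
- **Error ellipses** use the sample covariance eigendecomposition with
  semi-axes $\sqrt{\chi^2_{2,\text{cov}}\lambda_i}$ (95% coverage default)
  and aspect ratio $\sqrt{\lambda_1/\lambda_2}$.
- **Effective Fitts index**: $W_e = 4.133\,\mathrm{SD}(\text{on-axis})$,
  $ID_e = \log_2(D_e/W_e + 1)$ (Shannon formulation with the standard
  4.133 factor mapping SD to a 96% width); `fitts_fit()` is ordinary least
  squares of MT on $ID_e$, wrapped with `tidy()`/`glance()`/`autoplot()`.
- Temporal phase summaries use **medians** (skewed distributions);
  spatial summaries use mean ± SD (near-Gaussian by construction).
- **Asymptotic staircase limit** = median over the last 40 trials of each
  staircase, pooled (80 values). Pooling is chosen over averaging
  per-staircase medians because both staircases target the same 50% point
  and pooling halves the summary's variance without bias once converged.

## 5. Screening

`screen_session()` applies data-quality rules before analysis:

- frame rate: mean fps < 30 in any context/round fails; a between-context
  difference (Experiment 1) or first-to-last-round drop (Experiment 2)
  above 10 fps fails;
- staircase stabilisation: late-window success rate outside 0.5 ± 0.10
  fails (strict inequality);
- outliers: median ± 3 MAD with consistency constant 1.4826
  (`mad_outliers()`); a degenerate MAD of zero flags *any* deviation from
  the median rather than nothing.

## 6. Numerical and testing choices

- `uniroot` with default tolerances on analytically bracketed intervals;
  crossings are guaranteed single-rooted within each bracket.
- Session files are single plain-text files (`[header]`/`[trials]`/
  `[samples]`/`[events]`/`[ground_truth]` TSV sections) and round-trip
  losslessly; `validate_session()` enforces strictly increasing timestamps,
  delta/position consistency to 1e-9 au, and click-inside-entry for every
  successful trial.
- Tests run scaled-down problem sizes (e.g. 8–10 cycles instead of 40,
  1–10 rounds instead of 20) wherever the property under test is
  size-invariant; full-size runs are reserved for the staircase-convergence
  and segmentation-recovery acceptance tests (100 seeds × 320 trials;
  1,000 noiseless trials).
- The deposited raw data of the motivating studies are not mirrored here;
  `read_osf_session()` is an explicit not-implemented adapter stub marking
  where ingest of such a deposit would plug into the session layout.
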