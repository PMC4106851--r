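---
title: "The embodied T-maze model: controller, detection and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The embodied T-maze model: controller, detection and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtemaze)
```

vtemaze simulates a differential-drive robot learning a cued T-maze task
under a plastic Hebbian controller, and provides the measurement stack used
to study vicarious trial-and-error (VTE) in that setting. This vignette is
the package's account of the model itself: the equations, the parameters
that matter, the places where the design was genuinely open and what was
chosen there, and what the simulation does and does not tell you about
real animals.

## The arena and the robot

The T-maze is a stem corridor (default 120 x 40 cm) joined to a cross
corridor (two arms of 120 x 40 cm each), dimensions scaled to the e-puck
robot (body radius 3.7 cm, axle width 5.3 cm). The coordinate origin sits
at the junction centre; the stem extends toward negative `y`. The distal
10 cm of one cross arm is the reward zone, the opposite end the punishment
zone, and the rewarded side (with the tactile cue on the same side, always)
switches after every fifth trial of a session. A cylindrical post of 2 cm
radius at the junction corner on the cued side is the tactile cue. The
entire distal wall of the cross corridor — the top of the T — is black;
every other surface is white or transparent. The corridor width (40 cm)
together with the 20 cm whiskers means the cue is felt only when the robot
is near the junction, which is the property the arena needs.

The geometry defaults are package choices within this constraint set and
all of them are configurable in `maze_config()`. The default start pose —
stem centreline, 10 cm from the closed end, facing the junction — is
likewise a configurable default.

Four sensory channels feed the controller:

* 32 binary whiskers (16 per body side, 20 cm long) that sense only the
  cue post;
* a 20-pixel omnidirectional camera, each pixel an 18 degree bearing bin
  that reads 1 exactly when part of its visible field is the black wall.
  Visibility is computed exactly: between consecutive wall-endpoint
  bearings the first-hit wall is constant, so one ray per critical-angle
  interval decides the whole interval, with occlusion handled for free;
* 6 infrared proximity sensors across the front half, reading
  `max(0, 1 - d / 10cm)` — the proportional IR constant is fixed at 1
  rather than evolved;
* a reward channel that is +1 inside the reward zone, -1 inside the
  punishment zone, 0 elsewhere.

Motion follows the standard differential-drive mix. With motor output
`u` in [0, 1], wheel speeds are `V -/+ c (2u - 1)`, so forward speed is
the constant `V`, angular velocity is `2c(2u - 1) / axle`, and `u > 0.5`
turns the robot left (counter-clockwise). Integration is explicit Euler at
one environment step; `step_kinematics()` also accepts a smaller `dt`,
under which trajectories converge to the analytic circular arc of radius
`V * axle / (2c(2u - 1))` — the closed form the tests check against.
Collisions are resolved by sliding: the motion component into a wall is
cancelled, rotation is always allowed, and wall contact never ends a
maze-solving trial (the robot may ride the back wall and continue). During
familiarization, by contrast, wall contact ends the episode and resets the
robot, per the protocol below.

## The two-unit Hebbian controller

Five modules — tactile (32 neurons), vision (20), IR (6), reward (1),
motor (1) — are connected by directed weight matrices `W[j->i]`. Each
neuron carries two units. The *state* unit `s` mirrors the raw signal
(`k_touch * whiskers`, `k_light * camera`, the IR reading, `k_reward *
reward`, and the currently held motor output for the motor module). The
*virtual* unit `v` carries internally propagated signals and is what
drives behaviour. Once per neural step (every `delta` environment steps,
`delta` an integer in [10, 30]):

1. the sensor frame is loaded into the state units;
2. every enabled weight matrix updates by the modified Hebbian rule

   `W[j->i] <- W[j->i] + eta * (ds_i %o% s_j) - zeta * W[j->i]`

   where `ds_i = s_i(t) - s_i(t - tau)` is the postsynaptic state *change*
   over a lag of `tau` neural steps. Weights grow when presynaptic
   activity and postsynaptic change coincide — change, not level, because
   change carries the sensorimotor information (a motor state correlates
   with optical flow, not with a static image). With no change, each
   weight decays geometrically at `(1 - zeta)` per neural step — a closed
   form the tests assert exactly;
3. the virtual units update synchronously:

   `v_i = sigmoid( sum_j W[j->i] %*% (v_j - s_j) )`,
   `sigmoid(x) = 1 / (1 + exp(-a x))`,

   except the reward module, whose virtual unit is pinned at 1;
4. the motor output is `u = v_motor`, held until the next tick while wheel
   speeds are recomputed from it every environment step.

The separation of the two pathways is the load-bearing design: virtual
units never enter the learning rule, which removes the runaway positive
feedback of plain Hebbian dynamics (co-firing strengthening a synapse,
which produces more co-firing). The propagated quantity is the *error*
`v - s`; since `v_reward` is pinned at 1, the reward module broadcasts a
standing "make the reward state become 1" drive, which is the mechanism
that pulls the robot toward the previously rewarded arm, while learned
tactile-to-motor weights pull it toward the currently cued arm. The
conflict between those two pathways just after a reward switch is where
body oscillations — the model's VTE — arise.

Design points that were genuinely open, and the choices made:

* The exact update-rule forms were reconstructed from the architecture's
  published description: outer-product potentiation with linear forgetting,
  and sigmoid propagation of the summed weighted errors. Both are isolated
  behind `hebbian_update()` and `virtual_update()` so alternatives can be
  swapped in one place.
* Incoming signals from modules of very different sizes are summed
  plainly by default; `normalize_input = TRUE` scales each source by
  `1/size(j)`. The evolved gain constants absorb scale either way, so the
  plain sum is the default.
* A single shared sigmoid slope is used; per-module slopes would break the
  49-parameter budget of the genome (below).
* `tau` counts neural steps, not environment steps, so the state change
  is measured at the cadence at which the controller actually acts; its
  gene spans [1, 5].
* Self-pairs (`j == i`) carry no weights — exactly the choice that makes
  the pair count 20 and the rate count 40.
* When the delay history is shorter than `tau` (phase start), missing
  history reads as zeros.
* The motor module's state unit is the *held* output, so after a
  suppression override (below) the learning pathway sees the overridden
  motor state, as the intervention intends.

`controller_pairs("minimal")` gives the minimally connected variant:
only touch-vision, IR-motor, touch-motor, reward-vision and vision-motor
are enabled — the pathways with identifiable task roles — and weight
storage for disabled pairs simply does not exist.

## Protocol: familiarization, sessions, resets

A familiarization phase precedes every maze-solving session: 20 episodes
with cue and reward deactivated and the motor output clamped alternately
to a right-turning and a left-turning value (defaults 0.2 and 0.8 — the
published values are not recoverable, so these are symmetric defaults),
switching at each wall-contact reset. Hebbian learning runs throughout;
this is where the basic IR-vision-motor correlations (wall avoidance,
visual anchoring) are laid down. Episodes are capped at the trial step
budget in case a parameter set never reaches a wall.

A maze-solving session is `n_trials` (default 100) trials from a fixed
start; each trial ends at the first entry into a reward or punishment
zone, or times out at exactly 4000 environment steps. Three reset rules
matter and deserve their rationale:

* *Weights carry from familiarization into the session.* A full reset at
  the session boundary would discard everything familiarization built and
  make the phase pointless; `reset_phase()` therefore supports both a full
  reset (used at familiarization entry) and a virtual-units-only reset
  with `carry_weights = TRUE` (used at the session boundary).
* *Virtual units, state history and the held output re-initialize at each
  trial start; weights persist across trials.* This makes a trial a
  function of the weight state alone, which is what lets the
  learning-off replay analysis reproduce individual baseline trials
  exactly, and keeps per-trial neural series independently analyzable.
* *On zone entry, the controller receives one final tick with the
  reward-bearing frame before the trial closes.* Ending the instant the
  zone is touched would mean the reward channel never reaches the Hebbian
  rule (the controller only samples between-tick states), and no
  reward-vision-motor association could ever form.

The whole simulation is noise-free: identical controller, maze and start
produce bit-identical trajectories and logs, which the suite asserts.

## The genome and the genetic algorithm

The 49 evolvable scalars are: learning and forgetting rates for the 20
ordered pairs (40), `delta`, `tau`, the sigmoid slope, the per-phase motor
conversion constants, the shared forward velocity `V`, and the three input
gains (light, touch, reward) — the unique decomposition consistent with
the published parameter list and total. `genome_layout()` documents the
gene order; `decode_genome()` maps genes in [0, 1] affinely onto their
ranges (rates in [0, 1], slope in [0.1, 10], speeds and gains in
[0.1, 5], `delta` rounded into [10, 30]). Gene ranges other than `delta`
are package defaults, configurable at the decoding layer.

Fitness is the summed per-outcome reward over the full protocol
(familiarization plus a 100-trial session from the fixed start): +5 per
rewarded trial and 0 otherwise by default, so a perfect controller scores
500. The published account fixes only that maximum; the per-outcome table
is the minimal reconstruction consistent with it and is configurable.

`evolve()` implements the standard GA: population 100, tournament
selection (size 3 — unstated in the source, a conventional default),
single-point crossover with probability 0.7, per-gene uniform-redraw
mutation at rate 0.01, and elitism copying the five best unchanged. With
deterministic evaluation, elitism makes the best-fitness history
non-decreasing, which is asserted. On the separable toy fitness
`sum(genes)` this operator set reaches about 96% of the optimum in 200
generations at population 50 and crosses 99% by 1000 generations — the
uniform-redraw mutation is deliberate (it matches the 1% published rate
semantics) and is the slow-but-steady part of that curve. Reference-scale
controller evolution (100 x 1000 with 100-trial evaluations) is far
beyond a test suite; the suite instead runs a scaled-down smoke GA
(population 6, 2 generations, 3 trials per evaluation, 800-step timeout)
asserting mechanics, not convergence.

## VTE detection, counting and suppression

Let `m = 2u - 1` be the signed turning command. A VTE event is a filtered
sign change of `m`. The default detector is a Schmitt trigger with band
`theta` (default 0.1; the published value is behind an unreadable
placeholder, so the threshold is always reported alongside counts): an
event fires when `m` crosses from beyond `+theta` to beyond `-theta` or
vice versa since the last event. Hysteresis was chosen over a per-step
`|dm| > 2 theta` rule because the detector's stated purpose is filtering
noisy fluctuation around zero turning, which is exactly what hysteresis
does; the per-step rule remains available (`rule = "delta"`) and is
covered by the same brute-force-oracle tests. Counting runs over whole
trajectories — the fixed forward velocity means oscillations concentrate
after the cue contact anyway — with a choice-point-windowed variant
(`choice_point_radius`) for comparison with rodent protocols.

`suppress_vte_session()` is the intervention: detection runs online at the
motor level, and each would-be event overrides that neural step's output
to `u = 0.5` (zero angular velocity), with the learning pathway seeing the
override. `theta = 1` can never arm the trigger (sigmoid outputs never
leave (0, 1)), so it reproduces the unsuppressed session bit-exactly —
asserted — and `theta = 0` treats every sign change as VTE.

`classify_vte_pattern()` stands in for the by-eye classification of
per-trial VTE profiles and is labelled plumbing: with `early` the mean
over trials 1-20 and `late` the mean over the last half, it reports
rat-like `HL` when `early >= 2 * late` with a peak above the floor
(default 2 events/trial), `H` for persistently high, `L` for persistently
low, and always ships the three summary statistics with the label.

## Maximum Lyapunov exponents from short series

Per trial and module, the analyzed series are the quantities that drive
behaviour: the motor output itself (the motor virtual unit) and, for
sensory modules, the mean over the module of `v - s`. Trials span roughly
15-150 neural steps, so the estimates read as *transient-chaos* divergence
rates rather than attractor exponents.

`mle_rosenstein()` implements the small-data algorithm: delay-embed with
dimension `m` and lag `J`; pair each embedded point with its Euclidean
nearest neighbour under a temporal exclusion of one mean period, the mean
period taken as the reciprocal of the power-weighted mean frequency of the
FFT spectrum (the dominant-peak alternative is a switch); average the
log-distance curve over pairs; and fit the first `fit_len` points by least
squares. The slope is accepted as the exponent only when the fit's
R-squared exceeds 0.8; negative slopes are reported as 0.0, and rejected
fits also report 0.0 — the published sentinel for the rejected branch is
unreadable, and 0.0 keeps the two rules consistent. Reported exponents are
therefore always non-negative, which is asserted on every output. Zero
distances are floored at machine epsilon times the series scale;
uniformly zero-variance series are rejected outright.

The embedding defaults `m = 5`, `J = 1`, `fit_len = 10` stand in for
unreadable published values; in place of fixed numbers, the suite asserts
the published robustness property — the module ranking of mean exponents
is preserved across an `(m, J)` grid. Accuracy is anchored by an analytic
oracle: on the r = 4 logistic map (exponent `log 2`), the estimator lands
within 0.05 on 5000-point series (0.0005 in practice) and within about
0.1 at 150 points, degrading gracefully as series shorten.

## Perturbation harnesses

`robustness_grid()` re-runs the whole protocol (familiarization included,
from the perturbed position — the perturbation applies to the protocol,
not just the session; switchable) from each of a grid of start positions
in the central arm, default 7 lateral x 40 longitudinal = 280 cells, and
reports per-position success rates in percent with their mean and
variance; the variance over positions is the robustness statistic, on the
percentage scale that makes variances in the hundreds directly
comparable. `maze_size_sweep()` repeats this across scaled arenas,
`reward_distance_sweep()` lengthens the rewarded branch so reflexive
cue-followers and reward-position trackers separate, and
`learning_onoff_replay()` replays each trial's starting weight set with
learning frozen versus active. `compare_group_variances()` runs the
group-level comparison (Welch t-test by default, permutation test as the
alternative).

## Fixtures, tests, and what they do and do not show

The package generates all test inputs in code (`make_fixture()`): a
ground-truth oracle policy that always reaches the reward (pinning the
protocol ceiling of 500), a circling policy that always times out (pinning
the 4000-step budget), a zig-zag policy with an exactly programmed
crossing count (pinning the detector and the suppression counter), canned
genomes, and logistic/sine series with known exponents. These fixtures
validate the *machinery* under the study's conditions. They do not show
that any particular evolved robot reproduces the published group-level
comparisons (VTE peaking at the sixth or seventh trial, the variance
separation between pattern groups, the per-module exponent separation):
those depend on evolving and hand-classifying a specific cohort of robots
at a compute scale far beyond a test suite, and the package deliberately
asserts the property-level contracts instead. The simulation is also
noise-free by construction, so nothing here speaks to sensor noise or
motor stochasticity in real animals or robots.

Problem sizes used by the default test run, chosen to keep the suite deep
but quick: sessions of 3-12 trials with 400-1500-step budgets wherever a
full session is not itself the claim; the full 4000-step budget and the
full 100-trial, 280-cell arities wherever it is; 1000 random series for
the detector oracle; 2000-5000 points for the exponent oracle; and the
smoke GA above.

## Known limitations

* 2-D kinematics only: no wheel slip, no 3-D physics, no sensor noise.
* The exact published values of several constants (maze dimensions, start
  pose, familiarization clamps, detector threshold, embedding parameters)
  are not machine-recoverable; all are explicit configurable defaults
  chosen under the documented constraints, and serialized configs always
  contain them.
* The by-hand robot-pattern classification is replaced by a documented
  heuristic that should be treated as plumbing, not as a scientific claim.
* Reference-scale evolution is supported but not exercised by the tests;
  expect hours of compute for 100 x 1000 GA budgets in this pure-R
  implementation.
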