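# vtemaze

An embodied simulation of vicarious trial-and-error (VTE) in a T-maze.

Rats pausing at a maze junction and swinging their heads between the
options — VTE — are taken as behavioral evidence of deliberation. vtemaze
implements a minimal embodied model of that phenomenon for computational
neuroscientists and evolutionary-robotics researchers: an e-puck-scale
differential-drive robot, a plastic neural controller whose only learning
mechanism is a modified Hebbian rule, and a cued T-maze in which the
rewarded side (and its tactile cue) switches every five trials. Body
oscillations emerge, or fail to emerge, purely from the sensorimotor loop;
the package then measures them, suppresses them online, quantifies the
chaoticity of the underlying neural activity, and stress-tests the learned
behavior under perturbations.

## The model

A five-module controller (tactile 32, vision 20, IR 6, reward 1, motor 1
neurons) connects modules with directed weight matrices `W[j->i]`. Each
neuron has a *state* unit `s` mirroring the raw signal and a *virtual*
unit `v` carrying propagated internal signals; the separation prevents
Hebbian runaway. Per neural step (every `delta` environment steps):

```
W[j->i] <- W[j->i] + eta[j->i] * (ds_i %o% s_j) - zeta[j->i] * W[j->i],   ds_i = s_i(t) - s_i(t - tau)
v_i     <- sigmoid( sum_j W[j->i] %*% (v_j - s_j) ),                      v_reward = 1 (pinned)
u       <- v_motor
```

and the wheels mix as `v_L,R = V -/+ c (2u - 1)` (so `u > 0.5` turns
left). The 49 free scalars — 40 pair rates, `delta`, `tau`, the sigmoid
slope, per-phase `c`, `V`, three input gains — are evolved by a standard
GA (tournament selection, 70% single-point crossover, 1% mutation,
5-elite) whose fitness is +5 per rewarded trial over a 100-trial protocol
(maximum 500).

On top of the simulator:

* **VTE metrics** — Schmitt-trigger counting of threshold-crossing sign
  changes of `2u - 1`, online suppression (detected events reset the
  angular velocity to zero), and a documented profile heuristic
  (high-to-low / low / high).
* **Chaos quantification** — the Rosenstein small-data maximum-Lyapunov
  estimator (FFT mean-period neighbor exclusion, log-divergence slope,
  R-squared > 0.8 acceptance gate, negative estimates reported as 0) on
  the short per-trial, per-module neural series.
* **Perturbation harnesses** — a 280-cell start-position robustness grid,
  maze-size and reward-distance sweeps, learning-on/off replays from
  per-trial weight snapshots, and group-level variance comparisons.

## Worked example

```r
library(vtemaze)

maze <- maze_config()
maze
#> T-maze (120x40 stem, 2x120x40 cross, cm)
#>   reward/cue side: left, zone depth 10 cm, timeout 4000 steps
#>   start pose: (0, -130) heading 1.571 rad

params <- controller_params(eta = 0.5, zeta = 0.01, delta = 10, tau = 2,
                            slope = 1, V = 1.5,
                            c_familiarization = 0.8, c_maze = 0.8)
ctrl <- hebbian_controller(params)
fam  <- run_familiarization(ctrl, maze)        # 20 clamped episodes
sess <- run_session(fam$controller, maze, n_trials = 20)
sess
#> session of 20 trials: success rate 50%
#>   outcomes: reward=10, punishment=2, timeout=8, wall_reset=0

session_vte_counts(sess, theta = 0.1)
#>  [1]  38 363 208 326 290  50 335 119  53 103 156 264 143 308 241  83  87  62  84
#> [20]  26

session_mle(sess, m = 5, J = 1, fit_len = 10)$summary
#>    module    mean     sd n_accepted n_trials
#> 1 tactile 0.10118 0.0553         18       20
#> 2  vision 0.08128 0.0565         15       20
#> 3      ir 0.10579 0.0492         17       20
#> 4  reward 0.00568 0.0156         12       20
#> 5   motor 0.17362 0.0631         19       20
```

This hand-picked (not evolved) controller solves the maze half the time,
oscillates heavily (hundreds of detected VTE events per trial at
`theta = 0.1` — counts are always reported together with the threshold),
and shows positive divergence rates in most modules, strongest in the
motor pathway: exactly the chaotic-activity signature the VTE analysis is
built to measure. The estimator itself is anchored by an analytic oracle:

```r
mle_rosenstein(make_fixture("logistic_series", n = 5000), m = 2, J = 1, fit_len = 10)
#> MLE estimate: lambda1 = 0.6936 per step (R^2 = 1.000, accepted; n = 5000, m = 2, J = 1, fit 10)
```

against the logistic map's exact `log(2) = 0.6931`.

Evolving controllers and running the full pipeline:

```r
ga <- evolve(maze = maze_config(), pop_size = 100, generations = 1000)  # reference budget; hours
cfg <- default_run_config()
cfg$controller$genome <- ga$best_genome
cfg$analysis$stages <- c("session", "vte", "mle")
bundle <- run_pipeline(cfg)
```

or from a shell, via the thin wrapper:

```sh
Rscript exec/vterobot vte --seed 3 --trials 100 --out out/
Rscript exec/vterobot mle --config my_config.json --out out/
```

## Package layout

* `R/maze.R`, `R/sensors.R`, `R/kinematics.R` — arena, sensing, motion
* `R/controller.R` — the two-unit Hebbian controller
* `R/trial.R` — trial/familiarization/session engine
* `R/ga.R` — genome codec and genetic algorithm
* `R/vte.R`, `R/lyapunov.R` — VTE metrics and the Rosenstein estimator
* `R/harness.R` — perturbation experiments
* `R/fixtures.R`, `R/pipeline.R` — fixtures, config I/O, orchestration
* `vignettes/vte-tmaze-model.Rmd` — the methods vignette (model,
  parameters, design decisions, limitations)
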