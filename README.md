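# activegaze

Active-inference simulation of gaze during action observation.

## What this is

When an observer watches an actor reach for one of two objects — a big
ball grasped with the whole hand, or a small ball picked up between thumb
and index — their eyes can arrive at the target *before the hand does*,
but only when the actor's hand preshapes informatively during the reach.
With an uninformative fist, gaze falls back to reactively tracking the
hand. `activegaze` implements a complete computational observer that
reproduces this proactive/reactive dichotomy, for researchers in
computational neuroscience, active vision and motor cognition who want a
runnable, testable model of *gaze as hypothesis testing*.

The observer maintains two goal hypotheses, `G ∈ {SMALL, BIG}`, and four
forward sub-models — echo-state reservoirs with Bayesian readouts giving
Gaussian predictive densities `p_G(hPos(t+1) | hPos(1:t))` and
`p_G(hShape(t+1) | hShape(1:t))` over next-frame hand position and the 16
dataglove joint angles. Evidence accumulates by Bayesian filtering into a
shape posterior `(w1, w2) = p(G | hShape(1:t))` and a full posterior
`(w3, w4) = p(G | OBS(1:t))`. Saccades are drawn from a salience map

```
S_k  = S − min S                      (differential epistemic value)
R_k  = Σ_j w_j ρ(·; c_j) + a·R_{k−1}  (belief-weighted components, a = 1/2)
S̄_k = S_k + R_k                      → 16 × 16 centre-surround grid
```

where `S` is the exact mutual information between `G` and a foveal sample
(a 6-symbol discrete channel), the `c_j` are the predicted hand positions
under each hypothesis and the two object positions, the hand weights are
`(w1, w2)`, and each object weight is the posterior times a Gaussian
density `N(hPos; gPos, σ)` of hand–object distance whose `σ` tracks
posterior uncertainty. The eye fixates the argmax cell with a fixed
16 × 12 = 192 ms saccade; a landing within 0.06 image units of an object
*is* the decision — there is no confidence threshold. A trial is a
six-frame movie over six saccade epochs; the signed **arrival time** is
eye landing minus hand landing (negative = anticipatory).

All stimuli are synthetic and generated by the package: four
counterbalanced target layouts, minimum-jerk reach paths through a shared
transport waypoint (early hand position is uninformative by construction),
and 16-channel joint-angle trajectories built from posture templates, 300
training movements per sub-model (6 actors × 50 per grip). See the
vignette `vignettes/action-observation-model.Rmd` for the full model
description and every numerical choice.

## Worked example

```r
library(activegaze)
cfg      <- default_config()
training <- generate_training_set(cfg$n_actors, cfg$n_moves_per_actor,
                                  seed = 1, cfg = cfg)
models   <- train_submodels(training, cfg)
exp      <- run_experiment(50, seed_base = 1, cfg = cfg, models = models)
print(exp)
```

```
<activegaze experiment> 50 trials/condition

       condition  n n_none mean_arrival_ms sd_arrival_ms frac_anticipatory accuracy
    no-shape-big 50      0         -172.80      88.87873              0.88     1.00
  no-shape-small 50      0         -111.36     116.94997              0.52     1.00
   pre-shape-big 50      0         -349.44      74.51288              1.00     0.94
 pre-shape-small 50      0         -295.68     111.14496              1.00     1.00

Contrasts (Welch):
                          contrast mean_diff_ms      p_value
     pre-shape-big vs no-shape-big      -176.64 3.742610e-18
 pre-shape-small vs no-shape-small      -184.32 1.752288e-12
  pre-shape-big vs pre-shape-small       -53.76 5.620601e-03
    no-shape-big vs no-shape-small       -61.44 3.945224e-03
```

Reading this: with preshape the eye reaches the target about 350 ms
(power grasp) and 296 ms (precision grip) before the hand, every trial
anticipatory; without preshape arrival is far later and often at or after
hand contact. The preshape advantage is ~180 ms for both grips (Welch
p < 1e-11), and the big target is discriminated ~54 ms earlier than the
small one under preshape. `plot_arrival_times(exp)` draws the four-bar
summary; `write_experiment_csv(exp, "out/")` exports per-trial records.

A command-line interface wraps the same functions
(`inst/scripts/activegaze.R`): `generate-data`, `train`, `run-trial`,
`run-experiment`, and `export-maps` (per-epoch 16 × 16 salience maps of a
single trial as CSV).

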