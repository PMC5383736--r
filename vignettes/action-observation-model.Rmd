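---
title: "Gaze as hypothesis testing: the model behind activegaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze as hypothesis testing: the model behind activegaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activegaze)
```

## The problem

When people watch someone else reach for an object, their eyes do not
passively follow the moving hand: given enough information, gaze jumps to
the *target* of the action before the hand arrives. The informative cue is
the hand's *preshape* - the anticipatory finger configuration that
distinguishes a whole-hand power grasp (directed at a large object) from a
thumb-index precision grip (directed at a small one). When the actor moves
with a closed fist (no preshape), observers instead fall back on reactively
tracking the hand, and their gaze reaches the target late.

`activegaze` implements a complete observer that reproduces this behaviour
as *active inference*: perception is sequential Bayesian hypothesis testing
between two goal hypotheses (BIG vs SMALL), and saccades are chosen to
maximize the information a foveal sample is expected to yield about those
hypotheses, summed with pragmatic, belief-weighted map components. The
decision is not thresholded: the trial ends when the most salient location
happens to be one of the objects.

## Architecture

One trial is a six-frame movie watched over six saccade epochs. Each epoch:

1. a foveal sample of the current frame is taken at the current gaze
   (Gaussian window, sd `window_sd` = 0.08 image units);
2. the two posteriors are updated with the frame's kinematic observables:
   the *shape posterior* `(w1, w2)` from the 16 joint angles alone, and the
   *full posterior* `(w3, w4)` from position and angles jointly;
3. the salience map is rebuilt (below) and downsampled to the 16 x 16
   sensor grid;
4. the most salient grid cell is fixated by a saccade of fixed duration
   16 iterations x 12 ms = 192 ms, executed by a proportional controller
   that suppresses the error between gaze and target (gain 0.35/iteration,
   settling below 0.01 image units within the epoch).

The first saccade of every trial is forced to the hand's rest position
(mirroring the instructed pre-trial fixation) and excluded from analysis.
If a saccade lands within `decision_radius` (0.06, about one grid cell) of
an object, the trial terminates and that object is the observer's decision.

### Forward sub-models (echo-state Gaussian process readouts)

Four sub-models predict the next frame under each hypothesis: two for hand
position, two for hand shape. Each is an echo-state reservoir (100 leaky
tanh units, spectral radius 0.9, leak 0.5, input scaling 0.5 - standard
echo-state settings; the spectral radius below one guarantees fading
memory) with a Bayesian ridge readout from `[1, input, state]` to the next
frame. The readout posterior gives a Gaussian predictive distribution whose
variance is the observation-noise floor plus the weight-uncertainty term.

Two design choices matter and are worth stating plainly:

* **Both hypotheses of a modality share one reservoir.** The observed
  history is the same for both models; sharing the fixed random weights
  means the competition is carried entirely by the learned readouts, not by
  accidents of two random reservoirs.
* **The predictive distribution reverts to a shared prior off the training
  manifold.** A plain linear readout extrapolates wildly on histories
  unlike anything it was trained on - exactly the no-shape condition, where
  the hand never preshapes. Scored at the noise floor, such extrapolations
  produce enormous, arbitrary log-likelihood differences and the posterior
  saturates on the first frame. A Gaussian-process readout does not behave
  this way: far from the data its prediction falls back to the prior mean
  with prior variance. We restore that property explicitly: a novelty
  coefficient rises from 0 to 1 as the distance from the current feature
  vector to its nearest training feature exceeds the 99th percentile of the
  in-sample spacing, and it blends the ridge prediction toward a prior mean
  and variance *pooled across the two grips* (`novelty_scale` = 6 marginal
  target sds). The pooled prior encodes that the range of plausible hand
  configurations is a property of the scene, not of either hypothesis: a
  movement neither model has seen is equally surprising under both. On
  held-out matched data the novelty term is inactive and standardized
  residuals have variance within 1 +/- 0.2 (the calibration test).
* **The position sub-models are trained on the pooled corpus.** The
  counterbalanced layouts make hand position carry no information about
  the goal; per-grip position models would rediscover goal information
  through incidental timing differences between the two reaches, which the
  modelled task treats as uninformative. Two position models still exist
  and are queried independently; they simply share training data.

### The salience map

Per saccade `k`:

* the **epistemic map** `S` assigns each candidate fixation the exact
  mutual information (bits) between the goal hypothesis and a discrete
  foveal symbol drawn from the six-symbol alphabet {hand-POW, hand-PRE,
  hand-FIST, big-object, small-object, background}. Emission probabilities
  are Gaussian-window overlaps with each scene item; under hypothesis G the
  hand sits at that hypothesis's predicted next position and emits hand
  symbols according to a soft classification of the predicted joint angles
  (scale `class_kappa` = 20 degrees, so a near-neutral prediction splits
  its mass between the two grips instead of feigning certainty). The map is
  bounded by the posterior entropy and vanishes under a degenerate belief;
* the **differential salience** is `S_k = S - min(S)`;
* the **component map** is
  `R_k = sum_j w_j G(.; c_j, rho_sd) + a R_{k-1}` with unit-peak Gaussian
  bumps (sd 1/16 of the image), decay `a = 1/2`, hand components at the two
  predicted next hand positions weighted by the shape posterior `(w1, w2)`,
  and object components at the object positions weighted by the full
  posterior times a hand-object proximity density (below);
* the combined map `S_k + R_k` is renormalized to max 1 (argmax-invariant)
  and downsampled by on-off centre-surround sampling - a
  difference-of-Gaussians (centre sd half a cell, surround twice that),
  rectified at zero and block-averaged to 16 x 16.

**The object proximity term.** Each object's weight is the posterior times
a two-dimensional Gaussian *density* of the current hand position centred
on the object, with dispersion tied to the posterior uncertainty:
`sigma_obj = 0.17 + 0.13 * H(w3, w4)` image units. Confidence therefore
narrows and *heightens* the object attractor. The density form matters:
with a unit-peak bump capped at the posterior weight, the object could
never outcompete a hand component until the hand was effectively on the
object, so the map would only ever produce hand-time decisions and the
anticipatory regime - the phenomenon the model exists to capture - would
be unreachable. The range 0.17-0.30 was chosen so that a confident
observer's object attractor wins roughly when the hand is within ~0.3
image units of the target (epoch 3 of a typical trial), while an uncertain
observer's does not; it was then frozen.

## The synthetic stimulus generator

No external data are used. The generator emulates the modelled study's
materials:

* **Layouts.** Four counterbalanced arrangements: a big and a small object
  left/right (the big object left in layouts 1 and 4), rest position below,
  all separations at least 0.2. Seeded jitter (sd 0.01) varies positions.
* **Hand paths.** A quadratic Bezier from rest through a shared transport
  waypoint above the objects' midpoint, traversed with a minimum-jerk time
  profile. The tangent at onset points at the shared waypoint, so early
  hand position is uninformative by construction (mutual information with
  target side < 0.05 bits over pooled trials). The time profile is
  compressed for power grasps and stretched for precision grips
  (exponents 0.85 and 1.30 on the min-jerk progress), reflecting the
  well-known speed cost of precision: reaches to smaller targets are
  slower. Both reaches still land (within `decision_radius`) at frame 5.
* **Joint angles.** 16 channels (3 per finger plus wrist). Four posture
  templates: NEUTRAL (rest), FIST, and the two grip preshapes, constructed
  so that POW and PRE are *exactly* equidistant from both NEUTRAL and FIST
  - both grips progress the same distance along the open/close axis and
  the same distance along orthogonal, grip-specific posture directions
  (excursion 14 degrees). An unchanging fist is then equally implausible
  under either hypothesis by construction. Preshape trials interpolate
  NEUTRAL toward the grip template with the precision opposition leading
  the reach (exponent 0.5) and the power closure lagging (1.5); no-shape
  trials hold FIST throughout. Gaussian noise (sd 2.5 degrees, both grips)
  and per-actor constant offsets (sd 2 degrees) model within- and
  between-actor variability. The full training corpus is 6 actors x 50
  movements per grip = 300 trajectories per sub-model.
* **Frames.** 128 x 128 intensity images with three blobs; the hand blob's
  local pattern encodes the visible aperture class (two wide lobes for
  POW, two narrow lobes for PRE, one compact blob for FIST) and is
  linearly discriminable at full resolution.

What the generator does *not* emulate: 3D kinematics, photorealistic
appearance, occlusion of the target by the hand, biological movement
variability beyond Gaussian noise, or oculomotor noise. Passing tests
therefore demonstrate that the inference-and-salience machinery produces
the qualitative gaze phenomena under controlled kinematics; they do not
certify performance on real video.

## Where the behavioural effects come from

* **Preshape advantage.** With preshape, the shape stream identifies the
  goal by frames 2-3; the confident posterior powers the object attractor
  and the saccade leaves the hand for the target around epoch 3-4, one to
  two epochs before the hand lands (arrival times of roughly -350 to -250
  ms on the epoch clock). Without preshape the shape likelihoods are
  novelty-tempered and near-symmetric, the posterior hovers near 0.5, the
  epistemic value of the hand stays high, and gaze keeps tracking the hand
  until the hand itself approaches the target (arrival around -170 to
  -100 ms with many late or zero-lag decisions).
* **Big before small.** The faster power-grasp transport means the hand is
  measurably closer to the big object at epochs 3-4 than it is to the
  small object in precision trials, so the object gate opens about half an
  epoch earlier on average. This kinematic-timing account replaces an
  account based on asymmetric model uncertainty: in this implementation,
  any noise asymmetry between the grips leaks through the partially
  tempered no-shape likelihoods and biases a condition that should remain
  neutral, so the grips share one noise level and the asymmetry lives in
  the transport kinematics, where the fist conceals nothing.
* **Decisions without thresholds.** Because the decision is just a fixation
  landing on an object, decided trials exist at modest confidence (the
  tests assert decisions with `max(w3, w4) < 0.95`), and removing the
  object components abolishes proactive object fixations entirely.

## Timing conventions

Frame `k` and saccade `k` complete on the same clock tick `k x 192` ms
(the saccade's landing is its onset `(k-1) x 192` plus its fixed duration).
The hand "lands" at the first frame within `decision_radius` of the target,
the eye at its deciding saccade; the signed arrival time is the
difference. Using one clock for both avoids building a constant one-epoch
bias into every arrival time.

## Numerical choices

* Posterior updates run in log space with max-subtraction; if both
  likelihoods vanish the update falls back to uniform with a warning.
* Ties in the coarse-map argmax break to the lowest row-major index.
* A degenerate (0/1) belief yields a null epistemic map; the pragmatic
  components still apply, so behaviour remains defined.
* The ridge prior (`ridge_lambda` = 0.5) guarantees solvability even for
  degenerate reservoir states (a warning is logged).
* All randomness flows from one master seed through labelled substreams
  (layouts, actors, movements, reservoirs, priors), so every artefact is
  independently reproducible and byte-identical across runs.

## Problem sizes

The shipped experiment uses 50 trials per condition (200 trials plus a
biased-prior rerun), trained on the full 300-trajectory corpus; this runs
in well under a minute on a laptop core. The test suite uses a reduced
corpus (2 actors x 10 movements) for unit tests and the full corpus for
the statistical checks.

## Known limitations

* The belief update consumes the frame's kinematic observables directly;
  foveation gates the *salience* computation but not the observation
  noise, so peripheral vision is effectively as sharp as foveal vision for
  evidence accumulation. Making observation precision gaze-contingent is
  the natural next step and would strengthen the reactive-tracking regime.
* Two hypotheses only; the types generalize but the experiment fixes N=2.
* The discrete six-symbol foveal channel is an idealization of continuous
  appearance; it makes the information gain exact and testable at the cost
  of realism.
* No inhibition of return is implemented or needed: fading component
  memory (`a = 1/2`) plus belief dynamics move the argmax on their own.

## A worked example

```{r example, eval = FALSE}
cfg <- default_config()
training <- generate_training_set(cfg$n_actors, cfg$n_moves_per_actor,
                                  seed = 1, cfg = cfg)
models <- train_submodels(training, cfg)
exp <- run_experiment(50, seed_base = 1, cfg = cfg, models = models)
print(exp)
plot_arrival_times(exp)
```
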