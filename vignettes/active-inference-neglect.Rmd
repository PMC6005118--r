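---
title: "An active-inference model of the saccadic cancellation task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An active-inference model of the saccadic cancellation task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neglectr)
library(dplyr)
```

## The task and the model

Hemispatial neglect is routinely assessed at the bedside with cancellation
tasks: the patient must mark every target in an array, and neglect shows up
as targets missed on one side (typically the left). `neglectr` simulates a
saccadic version of this task. Targets sit on an 8 × 8 grid; fixating a
target "cancels" it, turning it from black to red. The simulated subject is
a discrete-state active-inference agent: a partially observed Markov
decision process in which both perception and saccade selection minimise
(expected) variational free energy.

The generative model has one hidden factor — the currently fixated location
(64 states) — and, in the flat variant, two outcome modalities:

* **proprioception**: a fixed identity mapping from location to outcome, so
  the agent is never uncertain where it is looking;
* **vision**: white (empty), black (target), or red (cancelled target),
  with a *learnable* likelihood mapping parameterised by Dirichlet counts
  `a`. The expected likelihood is the column-normalised count matrix
  (`normalize_counts()`), and observing outcome `i` while believing the
  state is `j` adds `eta * posterior_j` to `a[i, j]`
  (`accumulate_counts()`).

Saccades are deterministic and location-independent: action `u` is "saccade
to `u`", so each of the 64 transition matrices has every column equal to
the unit vector at the destination.

A single-saccade policy `u` is scored by its expected free energy

```
G(u) = expected cost(u) - salience(u) - novelty(u)
```

* **Expected cost** is the negative expected log-preference of the
  predicted outcomes. Preferences are log-space vectors `C` per modality,
  log-softmaxed before use; the defaults (white 0, black +4, red −4) make
  uncancelled targets attractive and cancelled ones aversive.
* **Salience** is the expected information gain about the hidden state.
  Because proprioception is an identity mapping, the predicted state under
  any saccade is already certain, and this term is exactly zero for every
  policy — a structural property of the task model that the test suite
  asserts, not an approximation.
* **Novelty** is the expected information gain about the likelihood
  mapping itself: the expected KL divergence from the current Dirichlet
  belief to the belief after one observation, computed in closed form from
  log-gamma/digamma functions (`dirichlet_novelty()`). Locations with
  small counts promise large belief updates and so attract saccades; this
  is the epistemic drive that produces orderly search, and its count
  dependence is what two of the three lesions exploit.

Policies are re-evaluated after every fixation and the next saccade is
drawn from `softmax(ln E − γ·G)` (`policy_posterior()`), where `E` is a
baseline policy prior (uniform when healthy) and the precision `γ` an
inverse temperature.

## Fixation epochs, learning, and memory

Each fixation epoch emits two visual observations: the cell as it looked on
arrival (onset) and again after the cancellation rule has applied (offset).
Both drive Dirichlet learning, so after one visit to a target the agent has
evidence for black *and* red at that location; the red evidence raises the
expected cost of refixating it and the accumulated mass lowers its novelty.
This within-trial count accumulation is the model's working memory for
where it has already been — there is no separate memory store. Counts reset
between trials, and learning touches only the visual modalities (the
proprioceptive identity is fixed knowledge about the body, not plastic).

For *planning*, expected free energy is evaluated per future fixation with
a single predicted outcome per modality — the standard one-outcome-per-step
convention; the onset/offset split is an environment timing detail that
matters for learning, not for the one-step-ahead prediction.

Two conventions were genuinely open and are fixed as follows. Policy depth
is 1: the agent may saccade anywhere at any time, so all the behaviour of
interest is expressible per saccade, and a depth-`d` policy space (64^d
policies) would buy nothing here; the config validates `depth = 1` rather
than pretending otherwise. Precision `γ` is fixed at 1: the dynamic
precision updates that accompany this model family elsewhere are out of
scope, and every result below is stated under fixed `γ`.

## Belief updating and its validation

`update_state_beliefs()` iterates forward–backward message-passing sweeps —
log-likelihood messages combined with transition-propagated forward and
backward messages — until the posteriors stop changing. On a chain this
fixed point is the exact smoothing posterior, which is what the test suite
demands: posteriors on random ≤ 6-state, ≤ 3-step models must match
brute-force enumeration over all state sequences to 1e−6.

`free_energy()` evaluates the mean-field free energy of a set of per-time
beliefs. It upper-bounds surprise `−ln P(o)` for any normalised beliefs;
the bound is tight exactly when the beliefs can represent the joint
posterior, so the equality check in the tests uses single-step models
(where the marginal *is* the joint) and multi-step models assert the bound
only. Numerics: `1e−16` is added inside logarithms, convergence is declared
when no posterior entry moves by more than `1e−8`, and updating aborts with
an error after 16 sweeps (which only degenerate inputs reach; the sweep
itself converges in one pass, and a zero-probability observation stream is
reported as such rather than silently renormalised).

## Defaults and what they mean

| parameter | default | meaning |
|---|---|---|
| `e0` | 0.25 | baseline Dirichlet count per outcome; small → one-shot learning |
| `e1` | 0.25 | extra count on each column's true outcome — "very weak but accurate" knowledge of the target layout |
| `c_black`, `c_red` | +4, −4 | log-preference for uncancelled / cancelled targets |
| `gamma` | 1 | policy precision |
| `eta` | 1 | count mass added per observation; 0 disables learning |
| `n_saccades` | 20 | trial length (40 in the model-comparison experiment) |
| start | (3, 3) | initial fixation; near-centre, chosen once (the task does not specify one) |

Displays used throughout are balanced 16-target layouts (8 per hemifield),
which keep left/right comparisons interpretable; `generate_display()` also
offers uniform-random and explicit-CSV layouts.

## The three lesions

All three lesions act on the agent's priors, never on the display, and all
bias sampling toward the intact (right) side:

* **A1 (likelihood counts)** — multiply the Dirichlet counts of
  neglected-side columns by `κ` (default 100). The likelihood itself is
  unchanged (count scaling cancels in the normalisation — asserted in the
  tests), but the neglected side becomes *familiar*: its novelty vanishes
  and only the intact side retains epistemic pull.
* **E (policy prior)** — add `b = 4` to `ln E` of intact-side
  destinations: a habitual bias of policy selection.
* **C2 (proprioceptive preference)** — set the proprioceptive
  log-preference of intact-side locations to 4: the agent *expects* to
  find itself looking right, and policies that fulfil that expectation
  have lower cost.

In the multiscale model the 64 locations are factorised as quadrant ×
subquadrant × cell (each 0–3, ordered UL/UR/LL/LR at every level — the
ordering is a convention the tests pin down). Vision arrives at three
resolutions: quadrant target density (0–16), subquadrant density (0–4),
and the fine white/black/red outcome; the densities are colour-blind
(cancelling never changes them), so only fine vision can support the
cancellation memory. Proprioception becomes three identity sub-modalities,
one per factor. A lesion then takes a `scale`, and its side predicate is
evaluated on that factor alone. For the A1 lesion the counts of *all*
learnable modalities over the neglected columns at that scale are inflated:
the lesion renders those locations familiar in toto. Scaling only the
matching-resolution density modality was considered and rejected — it
leaves most of the novelty gradient (the other two modalities) intact and
produces only a weak, non-clinical bias, which contradicts the strong
scale-specific patterns the model is meant to exhibit. The result is the
egocentric/allocentric dissociation: a coarse-scale lesion shifts the
global hemifield fraction to ~0.9 while within-subquadrant laterality
stays near 0.5, and a fine-scale lesion does the converse.

### Calibration notes, and one honest failure

With exact Dirichlet-KL novelty, the per-location novelty of the flat
3-outcome visual modality is bounded by roughly the predictive outcome
entropy (~0.5–1 nat at the default counts). The A1 lesion removes at most
that much from the neglected side's policy log-weights, and `κ = 100`
already removes essentially all of it — so the flat A1 bias *saturates*
near a rightward fraction of ~0.6 and cannot be pushed to the severe
neglect the other two lesions show (their `e^4` bias gives fractions near
1.0) by any choice of `κ`. In the multiscale model the three visual
modalities stack (~2.2 nats) and the coarse A1 lesion does produce severe
egocentric neglect. We report the flat A1 laterality as the model produces
it rather than inflating preferences, precision, or the novelty
approximation to force a stronger phenotype.

## Lesion decoding

`replay_log_evidence()` scores a recorded scanpath under a candidate model
by replaying it in open loop: the candidate receives exactly the
observation stream the recorded agent saw (reconstructed deterministically
from the display and the fixation sequence), accumulates its own Dirichlet
counts, but has its actions clamped to the recorded saccades; the log
evidence is the summed log posterior probability of each recorded saccade.
This replay-with-learning protocol is the only one under which the A1
model's novelty dynamics can influence its action probabilities, which is
what makes that lesion identifiable. With no free parameters the log
evidence is the model's log likelihood, and `model_posteriors()` is a
softmax over candidates under a uniform model prior, applied to
seed-averaged evidence.

`confusion_experiment()` runs the full design (default: multiscale models,
coarse lesions, 40 saccades, 10 seeds, a fresh balanced display per seed).
Healthy data and A1 data are recovered essentially perfectly. The E and C2
rows are classified as abnormal (healthy + A1 posterior mass ≈ 0.01) but
split *exactly* 50/50 between E and C2 — and this is a theorem, not a
sample-size limitation: under fixed `γ` and depth-1 policies, adding `b`
to `ln E` of intact-side policies and subtracting `b/γ` from their
expected cost produce identical policy posteriors term by term, so with
equal default magnitudes the two lesioned models define the same action
distribution and no amount of behavioural data can separate them. A
tie-break between them would have to come from mechanisms outside this
model (e.g. dynamic precision), or from another data modality.

## What the synthetic environment does and does not show

The simulator *is* the study environment: displays, outcomes and scanpaths
are all generated by the package, so passing tests show internal
consistency of the model and the claimed qualitative phenomena
(healthy bilateral search, three rightward-biased lesions, scale
dissociation, decodability of health vs A1 vs E/C2-class pathology). They
do not show anything about real eye-tracking data: there are no fixation
durations, no saccade kinematics or amplitude costs, no proximity prior
(real subjects prefer nearby targets), no perceptual noise on outcomes,
and the head is assumed fixed so proprioception needs no coordinate
transform. Problem sizes (20-seed medians, 20-saccade trials, 10-seed
confusion runs) were chosen as the smallest that make the medians stable.

## A worked run

```{r example, eval = FALSE}
display <- generate_display(16, mode = "balanced", seed = 1)
healthy <- build_flat_model(display)
lesioned <- apply_lesion(healthy, lesion_spec("E"))

tr <- run_trial(lesioned, display, n_saccades = 20, seed = 1)
laterality_stats(tr)
autoplot(tr)

conf <- confusion_experiment(n_saccades = 40, n_seeds = 10, seed = 1)
conf$posterior
autoplot(conf)
```
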