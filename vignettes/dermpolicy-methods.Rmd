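---
title: "Reward-based decision policies for skin lesion classifiers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-based decision policies for skin lesion classifiers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermpolicy)
```

## The problem

A multiclass dermatoscopy classifier emits, for every lesion, a probability
vector over seven diagnoses — melanoma (MEL), basal cell carcinoma (BCC),
actinic keratosis / intraepidermal carcinoma (AKIEC), benign keratinocytic
lesion (BKL), nevus (NV), dermatofibroma (DF) and vascular lesion (VASC) —
together with the logits and the penultimate feature vector behind them.
Turning those outputs into a *management decision* (dismiss, monitor, treat
locally, excise) is not a pure accuracy problem: overlooking a melanoma is
far more harmful than excising a nevus, and the relative harms differ by
cancer type and by clinical scenario. `dermpolicy` implements a decision
layer that encodes such preferences as **reward tables** — matrices of
benefits and penalties indexed by (true diagnosis, predicted diagnosis or
action) — and learns a management policy from them with deep Q-learning,
alongside three reference policies:

* **naive**: take the top-1 predicted class and apply its textbook-optimal
  management (excise MEL/BCC, treat AKIEC locally where available, dismiss
  benign classes);
* **threshold hierarchy**: ordered probability cut-offs (melanoma →
  overall malignancy → BCC → AKIEC → monitoring), each escalating the
  management when strictly exceeded;
* **Bayes (expected reward)**: `argmax_a sum_d p(d) R[d, a]`, the optimal
  rule when the probabilities are calibrated; it is the analytic oracle
  against which the learned policy is validated.

## The Q-learning model

The state of a lesion is the concatenation of its feature vector, logits
and class probabilities. The Q-network is a small multilayer perceptron:
a 256-unit fully connected ReLU layer processes the feature vector, its
output is concatenated with the logits and probabilities, and a linear
output layer produces one Q-value per action. Dropout (0.05) acts on the
hidden layer during training only. Training follows the classic deep
Q-learning recipe: constant epsilon-greedy exploration (epsilon = 0.2), a
10,000-transition FIFO replay buffer, a single minibatch gradient update
every 4 environment steps, a target network copied every 8,000 steps
(35 and 5,800 in the patient-centered scenario), Huber loss on the
temporal-difference residual and Adam updates with learning rate 0.025.

Two modelling points deserve explanation.

**Discount.** The default discount is `gamma = 0`: the reward of a
management decision is earned immediately, and the action taken for one
lesion does not influence which lesion is presented next. Under
`gamma = 0` the Q-function of a converged run is exactly the conditional
expected reward `E[R[d, a] | state]`, which is what the Bayes policy
maximizes — this is what makes oracle validation possible. The machinery
for `gamma > 0` (target-network bootstrap over the next drawn lesion) is
implemented and configurable.

**Why the probabilities feed the linear head.** The expected-reward
surface is *linear* in the class probabilities. If the linear head saw
only the logits, the network would have to re-derive the softmax
nonlinearity through the feature branch, which measurably and
persistently depresses agreement with the Bayes policy even when
trained on noise-free expected-reward targets. With the probabilities
present, the Bayes solution is exactly representable (`Q = P R` is a
linear map), and the acceptance suite verifies that converged policies
then agree with the oracle on well over 95% of held-out calibrated
states. The state carries probabilities anyway, so this is a wiring
choice, not an information change.

**Loss width.** The Huber transition width defaults to the largest reward
magnitude in the table. A fixed width of 1 on rewards spanning ±6 turns
the fit into a robust location estimate of the per-(state, action) reward
distribution rather than its mean, and the greedy policy of such a fit is
not Bayes-consistent — oracle agreement drops by several points under
otherwise identical conditions. With the width at the reward range the
loss is quadratic over all attainable residuals while still bounding
gradients against outliers in `gamma > 0` configurations. A smaller width
can be set explicitly when robust fitting is wanted.

**Checkpoint selection.** Training holds out 20% of the lesions (whole
patients in the patient-centered scenario) as a validation split and
tracks the greedy policy's mean reward there. Because Adam with a
constant 0.025 step size never settles — the parameters random-walk
around the optimum — the trainer also maintains a tail (Polyak) average
of the parameters over the last 60% of training. At the end, the final,
best-checkpoint and tail-averaged parameter sets are compared on the
validation split and the best one is returned; in practice the tail
average wins almost always. Early stopping on a validation plateau is
available (`patience`) but effectively off by default, since the
validation metric saturates long before the averaged fit stops
improving.

## Patient-centered episodes

In the monitoring scenario decisions are patient-level: each training
episode consists of all lesions of one patient, state vectors are divided
position-wise by the mean state vector of that patient (the "ugly
duckling" normalization — a lesion is suspicious relative to its
patient's other lesions), and lesions are ordered by descending overall
malignancy probability within the episode. Two numerical safeguards
apply to the normalization: positions whose cross-lesion mean magnitude
is below 1e-8 are left unscaled, and normalized values are clipped to
[-20, 20] — a rare-class probability position can have a per-patient
mean orders of magnitude below one suspicious lesion's value, and the
unbounded ratio would dwarf every other input (and the training loss)
while meaning nothing more than "far above the patient mean".
Descending order was chosen (the most suspicious lesion first); the
alternative ascending order changes nothing at `gamma = 0` because
episode return is additive. Evaluation uses patient-grouped
cross-validation (20 folds by default) so no patient contributes to both
training and evaluation.

## The synthetic classifier simulator

The package does not need images or a trained CNN: the `synth` module
emulates classifier outputs with a fully known generative model. Each
class has an isotropic unit-variance Gaussian feature distribution in
`feature_dim` dimensions (default 16), with means at distance
`class_separation` along orthogonal coordinate axes. Selected class
pairs can be made confusable by pulling their means toward the common
midpoint (`confusion_pairs`); the default pulls MEL and NV together with
overlap 0.5, emulating the hard melanoma-versus-nevus boundary of real
dermatoscopy classifiers. Logits are the exact Gaussian log-posteriors,
so with `temperature = 1` and `label_noise = 0` the emitted probabilities
are perfectly calibrated under the generative model — which makes the
Bayes action computable in closed form and turns oracle equivalence into
a testable property. The `temperature` knob sharpens or flattens the
probabilities (miscalibration), and `label_noise` resamples a fraction of
true labels uniformly among the other classes, breaking calibration
without touching the state.

Default class priors follow the composition of a benign-dominated
dermatoscopic test population (60% nevi). The default separation (3.1)
and MEL–NV overlap (0.5) were chosen so that the naive top-1 policy's
melanoma sensitivity on the test fixture sits near 60%, matching the
regime in which supervised dermatoscopy classifiers typically operate;
all knobs are exposed.

Two fixtures reproduce published dataset compositions exactly:

* `make_isic_fixture()` — 1,511 lesions with per-class counts MEL 171,
  BCC 93, AKIEC 43, BKL 217, NV 908, DF 44, VASC 35;
* `sample_cohort()` in `exact_paper` mode — 524 patients, 7,375 lesions
  (55 noninvasive/microinvasive melanomas; 7,213 nevi, 56 BKL, 31 DF,
  20 VASC; the three published "other benign" lesions are mapped to BKL
  so labels stay within the seven-class vocabulary), per-patient lesion
  counts drawn from a truncated negative binomial on [6, 51] tuned to a
  median near 12 and then adjusted lesion-by-lesion to the exact total.

The cohort generator defaults to `monitoring_priors()` — class priors
matching the monitoring population itself (0.75% melanoma, 98% nevi,
absent classes floored at 1e-4) — rather than the referral test-set
priors. This matters: a posterior computed under an 11%-melanoma prior
is badly miscalibrated for a 0.75%-melanoma population, and the policy
that maximizes *realized* reward there is "dismiss everything", which
says nothing about the decision layer. With population-consistent
priors the emitted probabilities are calibrated for the cohort and the
expected-reward oracle is again the right benchmark.

What the simulator does **not** model: feature distributions of real
CNNs are neither Gaussian nor isotropic, their probabilities are
typically overconfident rather than calibrated, and class difficulty is
not symmetric. Passing tests on the simulator therefore demonstrate the
*decision layer's* correctness (Bayes consistency, threshold identities,
composition handling), not image-level performance claims.

## Expert inputs

Reward tables and threshold specifications arrive as CSV or JSON files;
multiple expert versions are aggregated cell-wise (or field-wise) by
median — the midpoint of the two central values for an even count — or
by minimum for the deliberately aggressive low-threshold configuration.
The files shipped under `inst/extdata/` are *synthetic stand-ins written
by the package authors* (real elicited values are not publicly printed);
they follow the documented qualitative structure: overlooking a melanoma
carries the largest penalty, monitoring a melanoma a moderate one,
excising a benign lesion a mild one, and rewards are asymmetric across
cancer types. Replace them with elicited tables for real use.

Threshold comparisons are strict (`>`, "exceeds"); boundary cases
therefore fall through to the next rule. The fallback action when no
cut-off fires is DISMISS, since the hierarchy enumerates only escalation
conditions. Ties in expected reward or Q-values resolve toward the more
cautious action (higher safety rank: EXCISE > TREAT_LOCALLY > MONITOR >
DISMISS); diagnosis ties resolve toward the lower canonical class index
for determinism.

## Numerical and design choices

* Canonical class order MEL, BCC, AKIEC, BKL, NV, DF, VASC fixes all
  vector and matrix indexing; file loaders canonicalize label order.
* Overall malignancy probability is `p[MEL] + p[BCC] + p[AKIEC]`.
* "Average accuracy" is the unweighted mean of per-class recalls
  (balanced accuracy) over nonempty classes; plain accuracy is reported
  separately.
* Proportion confidence intervals use the Wilson score interval; paired
  proportions use McNemar's chi-square with continuity correction, or
  the exact binomial version when fewer than 25 discordant pairs exist.
* The empirical ROC curve sweeps every observed score as a cut-off with
  the same strict `>` convention as the threshold policy, so a
  threshold-policy operating point lies exactly on the curve by
  construction.
* The predictive distribution of a diagnosis policy is the normalized
  exponential (softmax) of its Q-vector. This is one reasonable readout
  of Q-values as class beliefs, not a claim about how any particular
  production system derives its displayed probabilities.
* Training episodes in lesion-level scenarios draw `episode_length`
  lesions (default 50) uniformly with replacement from the training
  pool; episode length has no effect at `gamma = 0` beyond bookkeeping,
  consistent with reports that it matters marginally.
* A single global seed fans out to named substream seeds (data,
  training, evaluation) so each pipeline stage can be reproduced in
  isolation; every report records the seed, a configuration hash and the
  class-order fingerprint.

## Problem sizes

Scenario runs default to a 10,000-state training pool (the scale of the
HAM10000 training set), the 1,511-lesion test fixture, and 100,000
training steps (25,000 gradient updates); one such training takes on the
order of a minute on a single CPU. The test suite and the acceptance
script use these sizes for the convergence-sensitive checks and smaller
sizes for mechanical checks.

## Known limitations

* The Gaussian simulator is a test harness, not a skin-image model; no
  conclusion about CNN-level sensitivity transfers from it.
* Reward tables shipped with the package are synthetic stand-ins; all
  downstream numbers depend on the chosen rewards and thresholds.
* The Q-network is a deliberately small MLP trained on one CPU; no GPU
  path, prioritized replay, or double/dueling variants are provided.
* With `gamma > 0` the Huber width default (reward range) no longer
  bounds the bootstrap residuals tightly; set an explicit width there.
* Human-reader interaction (how clinicians respond to displayed model
  output) is outside the package's scope.
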