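---
title: "Fuzzy deep learning for cyborg moth flight control: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy deep learning for cyborg moth flight control: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A cyborg moth carries four ultraviolet micro-lamps (UVA and UVB on each of
the left and right sides) and is steered noninvasively: light stimulation
induces flight responses rather than electrical implants forcing them.
Closing this control loop needs two models. A *behavior learner* — the
forward model — predicts, from 80 variables (32 lamp-stimulus settings, 34
ambient conditions, and 14 flight-history values on a 200 ms grid), the
seven flight parameters that describe the next step of flight: horizontal
and vertical deflection angles and angular velocities, and the three axis
accelerations, all normalized to [0, 1]. A *control learner* — the inverse
model — maps a required flight behavior back to the lamp settings expected
to produce it. Ambient wind is assumed below 1.5 m/s; stronger wind makes
light-based steering ineffective, and records violating the cap are
rejected at the schema level.

Moth responses are noisy, individual, and heterogeneous: different moths
respond with different gains and signs, but cluster into groups with
similar stress behavior. The stack in this package addresses that
structure directly.

## Interval-valued Pythagorean fuzzy numbers

All network parameters are interval-valued Pythagorean fuzzy numbers
(PFNs): a membership interval $[\mu_{lo}, \mu_{hi}]$ and a non-membership
interval $[\nu_{lo}, \nu_{hi}]$ with $\mu_{hi}^2 + \nu_{hi}^2 \le 1$, so
each connection expresses both how an input contributes and how it does
not, with hesitancy $\pi = \sqrt{1 - \mu^2 - \nu^2}$ absorbing the rest.
Distances operate at the uniform-density centroid (the interval midpoint):

* crisp-to-fuzzy: $|\alpha, \beta| = \sqrt{(c_\mu - \alpha)^2/2 + c_\nu^2}$.
  The typeset source of this formula admits two readings; the alternative
  $\sqrt{((c_\mu-\alpha)^2 + c_\nu^2)/2}$ sits behind the `variant`
  argument. Both agree whenever $c_\nu = 0$.
* fuzzy-to-fuzzy: Euclidean distance in $(\mu^2, \nu^2, \pi^2)$ space
  scaled by $1/\sqrt 2$, which makes it a genuine metric with range [0, 1].
* vectors aggregate as a root-mean-square over coordinates, keeping
  distances dimension-free.

Crisp features enter the fuzzy domain through the declared convention
$x \mapsto P(x, 1-x)$ (`fuzzify()`), which round-trips through the
centroid.

The algebra (algebraic sum, scalar law, `exp`-style activation) follows the
standard Pythagorean operational laws applied bound-wise; both laws are
closed under the constraint, and `project_valid()` restores the invariants
after any unconstrained arithmetic (idempotently, by radial rescaling at the
upper bounds).

## Water wave optimization

Training is derivative-free throughout: water wave optimization (WWO)
evolves a small population of candidate parameter vectors with three
operators — propagation (wavelength-scaled random moves), refraction
(stalled waves re-drawn toward the best solution), and breaking
(single-coordinate local search around new bests). Defaults: population 8,
$h_{max} = 6$, wavelength base $\alpha = 1.0026$, initial wavelength 0.5,
breaking coefficient annealed 0.25 → 0.001.

Three implementation choices matter and deviate from the textbook
presentation; each was adopted because the textbook form demonstrably
stalls:

* the refraction wavelength rescaling uses the minimization-correct fitness
  ratio (new/old), so wavelengths shrink on improvement;
* the breaking coefficient anneals geometrically rather than linearly, so
  the local search refines at the same relative rate as the wavelengths;
* above 24 dimensions, propagation perturbs each coordinate with
  probability $24/D$ instead of all at once — full-vector moves in a
  200+-dimensional genome are almost never improving.

With these, the optimizer drives a 10-D sphere to ~1e-23 in 20,000
evaluations where random search stalls around 10. The per-layer early stop
(quit when the best value improves by less than 1e-6) uses a 250-evaluation
window; a 50-evaluation window was tried first and regularly cut training
at a fifth of its budget in genome spaces.

## Fuzzy denoising autoencoder layers

A fuzzy layer encodes a crisp vector $x \in [0,1]^D$ as
$y_i = s(\oplus_d\, x_d \otimes W_{id} \oplus b_i)$ under the operational
laws, with $s$ the exponential-style squashing $\mu \mapsto e^{\mu - 1}$,
$\nu \mapsto 1 - e^{-\nu}$ followed by projection. The decoder applies the
transposed weights to the defuzzified (centroid-$\mu$) hidden vector, so
every layer input stays in $[0,1]^D$. Denoising uses masking corruption
(each coordinate zeroed with probability 0.2 by default); the training
objective averages a small number of fixed corruption masks (4 by default)
so that the optimizer sees a deterministic objective yet cannot fit one
particular mask pattern. The loss is the mean squared RMS crisp-fuzzy
reconstruction distance.

WWO searches a gene box $[0,1]^{4P}$; genes map to valid PFNs by
construction. Two parameterisation choices are load-bearing:

* **Fan-in scaling of the membership channel.** The algebraic sum only
  accumulates: summing 80 terms drives $\mu \to 1$ and every hidden unit
  saturates. Genes therefore decode through a fan-in exponent,
  $\mu_{hi} = \sqrt{1 - (1-g^2)^{1/(D+1)}}$ — the fuzzy analogue of
  fan-in-scaled initialisation. The non-membership channel is *not*
  scaled ($\nu_{hi} = g_3\sqrt{1 - \mu_{hi}^2}$): its product law already
  contracts, and scaling it flattens the gene-to-$\nu$ map so badly
  ($0.5^{1/13} \approx 0.95$) that the optimizer cannot reduce the
  $\nu$-part of the loss at all.
* **Contrast renormalization between stacked layers.** The fuzzy affine
  map is strongly contractive (one-directional weights, fan-in dilution,
  squashing); stacking three to five layers collapses the defuzzified
  features to numerical constants. Each layer therefore stores a
  per-feature affine map rescaling its training-batch hidden activations
  to [0, 1], applied during stacking and prediction — the role
  normalization layers play in crisp deep networks.

## Grouping: Pythagorean fuzzy c-means

Moths are grouped on *stimulus-response profiles*: the three shape
features (wing span, body length, mass) concatenated with the topmost
common-layer representation of the moth's response to each of 36 probes
(3 ambient presets × 12 lamp presets covering intensity, duration,
laterality, and band extremes). Probing presents the stimulus and takes
the moth's noise-free response as the flight-history input, so profiles
differ only through the individual. With no hardware in the loop, the
responder is the cohort's ground-truth dynamics; externally measured
responses can be supplied instead.

Clustering is the classical alternating fuzzy c-means scheme under the
Pythagorean metric (defaults $c = 5$, $m = 2$, membership floor
$u_L = 0.1$, tolerance 1e-5). Because the metric is Euclidean in squared
degrees, the centroid update is a weighted mean of $(\mu^2, \nu^2)$ — the
exact Fréchet mean, which keeps the objective monotone and makes the
algorithm *provably equivalent* to classical FCM run in the transformed
coordinates $(\mu^2, \nu^2, \pi^2)/\sqrt2$; the test suite verifies the
partition agreement against an independent FCM implementation. Initial
centroids can be searched by WWO (each candidate scored by a short
clustering run), which lowers the variance of the final objective across
seeds. Centroids are degenerate-interval PFNs; membership of a point
coinciding with centroids splits equally among them.

## The three-hierarchy behavior learner

1. **Common hierarchy** (widths 80/46/26): pretrained unsupervised on all
   records.
2. **Group hierarchy** (26/15/9, one stack per cluster): pretrained on the
   topmost common representations of the records of moths with membership
   above $u_L$, each record's loss weighted by its moth's membership.
3. **Individual hierarchy** (9/6/7 per moth + linear head): the input is
   the membership-weighted mixture of group-stack outputs (memberships are
   used unrenormalized after the floor cut; a flag renormalizes). After
   unsupervised pretraining, a multivariable linear regression head maps
   the defuzzified topmost vector to the seven flight parameters by
   ordinary least squares (per-dimension, since the weighted loss
   decouples; a 1e-6 ridge catches rank deficiency), and outputs are
   clipped to [0, 1].

The reported error is the weighted regression loss
$\sum_d w_d (y_d - \hat y_d)^2$ with weights
(0.24, 0.2, 0.2, 0.15, 0.07, 0.07, 0.07) reflecting how much each
parameter matters to flight actions — note the per-dimension least-squares
fits themselves are unaffected by the weights; they matter for reporting
and model selection. The 14 history variables are the previous step plus
an exponentially weighted accumulation over the previous three steps
(decay 0.5, normalized — weights 4:2:1), a declared stand-in for the
memory network the original design delegates to.

The architecture-ablation comparator (`monolithic_learner()`) is a single
integrated stack of comparable parameter count (80/46/26/9/7) with one
shared head: it cannot absorb group-level response differences or per-moth
offsets, which is precisely what the hierarchy's per-moth heads do.

## The control learner

Control inputs concatenate the required behavior (7), ambient conditions
(34), flight history (14), and the moth's membership vector ($c$), width
$55 + c$; the stack defaults to 75/49/35/32 and substitutes the actual
input width for the first layer when they differ. Training:

1. pretrain the stack unsupervised on control inputs;
2. initialise the regression head by *inverse regression* on rollout
   pairs — random stimuli under instruction-like contexts, the behavior
   they produce (from the ground-truth responder for a 0.1 fraction,
   otherwise from the behavior learner), inverted by least squares from
   the topmost representation back to the stimulus;
3. fine-tune the head with WWO on the mixed loss
   $J_c = (\sum_{T_p}\|x, o_p \circ o_c(x)\| + w_m \sum_{T_m}\|x, o_m \circ
   o_c(x)\|)/|T_c|$, where $\|\cdot\|$ is the RMS deviation across the
   seven normalized parameters and $w_m = 1 - \sum_j J_R(j)/|T_m|$
   discounts model feedback by the behavior learner's own per-moth errors
   (clipped into [0, 1] with a warning).

An instruction succeeds when every *relevant* parameter — the ones the
instruction actually sets (a horizontal turn sets two, a vertical maneuver
two, an acceleration command three, a full instruction seven) — deviates
from the required value by less than 15% of the normalized parameter
range. Range-relative deviation avoids dividing by near-zero required
values; an expected-relative variant sits behind a flag.

## The synthetic cohort generator

No flight-record corpus is publicly deposited, so the generator emulates
the structure the learners assume; its defaults define the study
conditions used throughout the tests:

* groups enter through per-group response matrices acting on 7
  interpretable stimulus summaries (left-right intensity and duration
  contrasts, overall intensity/duration/velocity/distance levels, UVA-UVB
  contrast), blended with a shared base so a `separation` knob moves
  continuously from identical groups (0) to well-separated ones (1,
  default); shape features get group means scaled by the same knob;
* the horizontal deflection row responds only to left-right contrasts, so
  symmetric stimulation yields a normalized deflection of exactly 0.5;
* responses pass through a logistic squashing (gain 2.2), plus per-moth
  offsets (sd 0.05), plus observation noise (sd 0.05), clipped to [0, 1];
* stimuli and ambient conditions are low-rank-plus-noise (half uniform,
  half mixed latent factors), wind is stored in m/s and capped at 1.5;
* the default 36 moths × 304 records echo the scale of a laboratory
  campaign (~10,900 rows); tests run 12 moths × 100-300 records.

Because the stimulus acts through 7 summaries, the stimulus-to-behavior
map is injective on those summaries and inverse control is well posed —
deliberately so, since the closed-loop evaluation would otherwise
conflate controller quality with dynamical non-invertibility. What the
generator does *not* emulate: aerodynamics, temporal autocorrelation of
ambient conditions, sensor drift, non-stationary habituation. Passing
tests therefore demonstrate the pipeline's statistical machinery, not
field performance on real moths.

## Numerical choices

* Hesitancy is computed as $\sqrt{\max(0, 1 - \mu^2 - \nu^2)}$ (tolerance
  1e-12 for floating-point negatives); constructor checks allow 1e-9
  slack.
* Zero distances in the membership update split membership equally among
  coincident centroids (the limit of the update formula).
* Dead clusters re-seed at a random data point with a message.
* Non-finite objective values become $+\infty$ with a warning; wavelengths
  are kept in [1e-12, 2].
* Problem sizes in the bundled checks: 10,000 random fuzzy numbers for
  metric and closure properties; 20 optimizer seeds at 20,000 evaluations;
  clustering instances of 20-60 points; autoencoder fixtures of 40 samples
  in 12 dimensions (rank 3; one off-center mixture where random parameters
  have the most to learn, one common-factor-dominated set matching the
  stimulus generator's structure); cohorts of 12 moths in 3 groups with
  100-300 records per moth and pretraining budgets of 1,000-2,400
  evaluations; 200 held-out control instructions.

## Known limitations

* WWO budgets at these problem sizes leave the autoencoder layers far from
  their reconstruction optimum: reconstructions track per-coordinate means
  rather than individual inputs. One documented consequence: denoising
  pretraining and plain pretraining yield statistically indistinguishable
  held-out reconstruction on corrupted inputs at these budgets — for a
  reconstructor that barely depends on its input, training-time corruption
  cannot change robustness. The denoising contrast should be read as a
  property that emerges with much larger budgets and datasets than the
  bundled checks use.
* The hierarchy's predictive power flows mostly through the per-moth
  regression heads; the unsupervised stacks act as fixed nonlinear
  features. This matches the architecture's division of labor but caps
  per-record accuracy.
* Group recovery depends on the separation/noise ratio of the cohort; at
  `separation = 0` the grouping is uninformative by design, and the
  clustering stage recovers nothing (the two-sided check in the tests).
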