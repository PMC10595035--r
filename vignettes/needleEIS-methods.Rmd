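---
title: "Methods: impedance-based tissue identification and stop-at-target control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: impedance-based tissue identification and stop-at-target control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needleEIS)
```

## The problem

A spinal needle advanced through the lumbar soft tissues must stop
almost immediately after entering the subarachnoid space: the dorsal CSF
layer is only 2–3 mm wide, so the *comfortable travel distance* (CTD) —
how far the tip travels past first contact with the target layer before
stopping — must stay under 2 mm. `needleEIS` implements the sensing and
decision software for a one-degree-of-freedom insertion robot that
identifies the tissue at the needle tip from its electrical impedance
spectrum and issues the stop command, and exercises the whole loop on a
synthetic layered phantom.

## Conductivity remapping

The probe reports impedance magnitude $|Z|$ (Ω) at 15 fixed frequencies
between 1 and 349 kHz. $|Z|$ confounds tissue properties with electrode
geometry and manufacturing tolerance; tissue conductivity $\sigma$ does
not. Saline conductivity depends only on concentration, so measuring the
probe in eight solutions of known conductivity
$\sigma_S \in \{5, 200, 1987, 3850, 5650, 7450, 9238, 16000\}$ µS/cm
yields, per frequency, a set of $(|Z_S|, \sigma_S)$ nodes forming a
strictly decreasing function. Each node is the median over repeated
measurements (the package's `build_remap_table()` enforces
strict monotonicity and names the offending frequency otherwise). An
unknown spectrum is remapped per frequency by linear interpolation of
$\sigma$ against $|Z|$ through these nodes — linear in the raw
coordinates, not log-transformed, because that is how the calibration is
defined; the 15 resulting conductivities are the classifier features.

Numerical choices:

* **Extrapolation.** Queries more resistive than distilled water clamp
  to 5 µS/cm; queries more conductive than 0.9 % saline clamp to
  16,000 µS/cm. Both set a per-frequency `out_of_range` flag rather than
  failing or extrapolating: clamping keeps classifier inputs bounded,
  and the flag preserves the information.
* **Magnitude, not complex impedance.** The analyzer output is treated
  as $|Z|$; phase is not modelled.
* **Units** are fixed at Ω and µS/cm throughout.
* The span between the distilled-water node and the 0.01 % node covers
  an order of magnitude of impedance with a single linear segment;
  conductivities in that region are correspondingly coarse. None of the
  four tissue classes lives there.

## The Bayesian neural-network classifier

A fully connected 15–10–10–4 network (ReLU hidden layers, softmax
output) whose every weight and bias carries an independent Gaussian
variational posterior $\mathcal N(\mu, s^2)$ with a standard-normal
prior. Training minimises

$$\mathrm{cost} = \mathrm{CE} + \tfrac{1}{\text{batch\_size}}
  \mathrm{KL}\!\left(q \,\|\, \mathcal N(0,1)\right),$$

with the whole dataset as a single batch (so the KL multiplier is
$1/526$ for the default class counts 150/81/149/146), iterated 2,000
epochs. The KL is the analytic Gaussian–Gaussian closed form, never
sampled. Each epoch draws one weight sample through the
reparameterisation $w = \mu + s\,\varepsilon$ and backpropagates both
the cross-entropy and the KL gradient.

Choices the architecture leaves open, and what this package does:

* **Optimizer**: Adam, learning rate 0.01, default moment parameters —
  the conventional default for small variational networks; plain SGD
  also converges but slower.
* **Spread parameterisation**: $s = \mathrm{softplus}(\rho)$,
  initialised so $s \approx 0.1$. Small initial spread stabilises early
  training while the prior remains $\mathcal N(0,1)$.
* **Feature standardisation**: conductivities span decades, so features
  enter the network as standardised log-conductivities; the fitted
  centre/scale is stored in the model and applied at prediction time.
* **Prediction**: 30 posterior draws (configurable); the predicted class
  is the argmax of the mean softmax output, and the *spread of the
  maximum* — the standard deviation across draws of the winning class's
  probability — is the confidence indicator. The underlying notion of
  "the error of the maximum mean output" is not operationally defined in
  the source material; spread-over-draws is this package's
  interpretation.
* **Convergence** is asserted as a trend (50-epoch moving averages of
  the cost), not per step: the single-sample cost is Monte-Carlo noisy
  by construction.
* No train/test split is required for fitting, but the package always
  evaluates on a freshly generated synthetic test set.

## The synthetic phantom

There is no desk-reproducible tissue dataset: the published per-class
spectra exist only as a qualitative figure. The generator therefore
defines a *stated world* of log-normal templates,
$|Z| \sim \exp\{\mathcal N(\text{log-mean}, \text{log-sd}^2)\}$ per
frequency (multiplicative sensor noise keeps impedances positive),
anchored to the calibration table:

* **CSF** = the 0.9 % saline column exactly (CSF conductivity
  approximates physiological saline, 16,000 µS/cm), log-sd 0.03 — a
  homogeneous fluid varies far less than heterogeneous tissue. Because
  this template sits exactly on the most-conductive calibration node,
  about half of its draws land just beyond the table and clamp
  (flagged) to 16,000 µS/cm, which is the physically correct value
  there. The no-flags guarantee therefore applies to the three tissue
  classes, not to CSF.
* **fat** = a 0.6/0.4 geometric mix of the 0.01 % and 0.1 % columns,
  log-sd 0.08: the least conductive, most resistive class. It is kept
  this far below the distilled-water column because at high frequencies
  that column is only ~12 % above the 0.01 % one, and ±3 sd of draws
  must stay interpolable at every frequency.
* **skin** and **ligament** = geometric means of the 0.1 %/0.2 % and
  0.3 %/0.4 % columns respectively, log-sd 0.08.

These constants are configuration, not ground truth. Class
separations are several within-class standard deviations at most
frequencies, and a Bayes-optimal likelihood-ratio classifier built from
the true templates achieves ≥ 0.98 accuracy — certifying that the task
is learnable before any conclusion is drawn about the network. A green
classifier test therefore establishes that the pipeline *recovers a
separable stated world*, not that it would reach the same accuracy on
real tissue, where spectra overlap more, drift with temperature and
electrode fouling, and are not log-normal.

The phantom stack stacks layers skin 3 mm, subcutaneous fat 10 mm,
ligament 15 mm, epidural fat 4 mm, CSF 3 mm (the dorsal CSF width
reported across patients is 2–3 mm); subcutaneous and epidural fat
share one template, differing only by position. Within 0.3 mm of an
interface the two adjacent templates are mixed log-linearly by
penetration fraction, emulating the electrode sensing both tissues; the
true label still switches exactly at the geometric boundary.

## Closed-loop control

The simulated robot advances one motor step $H_s$ per cycle
(0.08–0.22 mm; 0.08 mm is the finest mode and the default), measures,
remaps, classifies, and stops when the policy is satisfied. Step counts
are integers and depth is always $N \cdot H_s$, so the CTD bookkeeping
$\Delta = (N_2 - N_1) H_s$ is exact; the impulse counter (+1 forward,
−1 backward) makes homing exactly symmetric.

* **Debouncing**: the stop requires the target to be predicted for
  `consecutive_hits` consecutive steps (default 2) so a single
  misclassification near a boundary cannot trigger a premature stop.
  With a perfect classifier and no boundary blending the overshoot is
  bounded by `consecutive_hits * Hs`.
* **Arming rule**: for epidural injection the target (fat) also occurs
  subcutaneously. The published system used a time delay to skip it;
  simulation has no wall clock, so the package implements the same
  intent deterministically: fat detections are ignored until ligament
  has been predicted at least once (optionally also until a minimum
  depth). With an oracle classifier this provably never stops shallower
  than the ligament layer.
* **Failure reporting**: exhausting the stack without satisfying the
  policy yields stop reason `"not found"` in the trace, not an
  exception; needle mechanics (bending, bias) are out of scope.
* One measurement is taken per motor step; the measurement cadence of
  the physical system is not modelled.

## What the tests establish

The suite checks: node-exact remapping at all 120 calibration nodes and
equivalence with a brute-force two-point interpolation oracle on random
queries; closed-form KL against numeric quadrature; determinism of
training and prediction under a fixed seed; posterior-predictive
normalisation; the convergence trend; ≥ 0.9 per-class recall of the
trained network on fresh synthetic data; stop-policy geometry with an
oracle classifier, exhaustively over boundary/step alignments; and a
mean overshoot ≤ 2 mm over 20 seeded full-pipeline insertions at
$H_s = 0.08$ mm (typical value ≈ 0.32 mm, dominated by the 2-hit
debounce and the 0.3 mm boundary blend). The published ex vivo results
(8/10 phantom successes, the confusion matrix of the real dataset) are
not desk-reproducible and are deliberately not claimed.

## Known limitations

* Synthetic templates are qualitative stand-ins; no quantitative
  fidelity to animal-tissue spectra is claimed.
* No complex-impedance phase, no Cole–Cole/Fricke–Morse dispersion
  modelling, no electromagnetic field simulation.
* No respiratory/cardiac motion, needle deflection, or real-time
  guarantees; hardware drivers and the GUI of the physical system are
  out of scope.
* Variational inference with one sample per step and a mean-field
  Gaussian posterior underestimates posterior correlations; the
  confidence spread is a relative indicator, not a calibrated
  probability.
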