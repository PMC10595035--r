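# needleEIS

Bioimpedance tissue identification for robot-assisted needle insertion.

During a lumbar puncture the needle crosses skin, subcutaneous fat and
ligament before reaching the cerebrospinal-fluid (CSF) filled
subarachnoid space — a layer only 2–3 mm wide, so the needle must stop
within ~2 mm of first contact. `needleEIS` implements, in R, the
software side of an impedance-sensing robot that solves this problem on a
simulated phantom:

1. **Conductivity remapping.** The probe measures impedance magnitude
   |Z| (Ω) at 15 frequencies from 1 to 349 kHz. Raw |Z| depends on probe
   manufacturing tolerances, so each value is remapped per frequency to a
   conductivity σ (µS/cm) by piecewise-linear interpolation through a
   calibration table of eight saline solutions of known conductivity
   (5 – 16,000 µS/cm). The 15 conductivities are the classifier features.
2. **Bayesian neural-network classifier.** A 15–10–10–4 network whose
   weights carry Gaussian variational posteriors `N(µ, s²)` with a
   standard-normal prior, trained full-batch for 2,000 epochs on the cost

   `cost = CE + KL(q ‖ N(0,1)) / batch_size`

   where CE is the softmax cross-entropy. Prediction averages the softmax
   over posterior weight draws; the standard deviation of the winning
   class probability across draws is the confidence indicator.
3. **Closed-loop insertion control.** A simulated stepper motor advances
   the needle `Hs` mm per step (0.08–0.22 mm) through a layered phantom
   (skin 3 / fat 10 / ligament 15 / epidural fat 4 / CSF 3 mm); each step
   is measured, remapped and classified, and the needle stops when the
   target tissue is detected for `consecutive_hits` steps. The
   comfortable travel distance (overshoot past the target boundary) is
   `Δ = H2 − H1 = (N2 − N1)·Hs`.

For epidural steroid injection the same loop stops in *epidural* fat: an
arming rule ignores fat detections until ligament has been seen, so
subcutaneous fat cannot trigger the stop.

Everything runs on a synthetic phantom: log-normal spectrum templates
anchored to the calibration table stand in for ex vivo tissue
measurements (see the methods vignette for what this does and does not
establish).

## Worked example

```r
library(needleEIS)

table <- default_remap_table()          # 8 saline solutions x 15 frequencies

# a spectrum measured in 0.1 % saline remaps to its known conductivity
sig <- remap_spectrum(impedance_spectrum(table$node_impedance_ohm[, 3]), table)
sig$sigma_us_cm[1]
#> [1] 1987

# train the classifier on the default synthetic dataset (526 spectra:
# 150 skin, 81 fat, 149 ligament, 146 CSF)
ds  <- generate_dataset(seed = 42)
dm  <- dataset_matrix(ds)
fit <- train_bnn(remap_matrix(dm$z, table)$sigma, dm$labels,
                 bnn_config(epochs = 2000, seed = 7))

# closed-loop lumbar-puncture simulation: stop on CSF
trace <- run_insertion(default_stack(), fit, table, stop_policy("CSF"),
                       motor_config(0.08), seed = 1)
trace
#> Insertion trace: 404 steps of 0.08 mm
#>   stopped at step 404 (32.32 mm) in 'CSF' (target 'CSF')
evaluate_trace(trace)$overshoot_mm      # CSF entry is at 32 mm
#> [1] 0.32
```

The 0.32 mm overshoot is well inside the < 2 mm requirement. The CTD
arithmetic of the physical robot is available directly: a mean step
difference of 21.65 at the finest step mode gives
`compute_ctd(0, 21.65, 0.08)$delta_mm` = 1.732 mm.

## Command line

```sh
Rscript inst/cli/needleEIS.R generate --out data.csv --seed 2
Rscript inst/cli/needleEIS.R train --dataset data.csv --out model.json
Rscript inst/cli/needleEIS.R simulate --model model.json --target CSF --log log.csv
Rscript inst/cli/needleEIS.R classify --model model.json --spectrum spec.csv
```

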