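# respnet

Respiratory-phase classification and lung tumor displacement prediction
from chest-wall surrogate motion.

## What this is for

During lung radiotherapy the tumor moves with breathing, mostly along the
head–toe axis. Clinics track an external surrogate — a marker block on the
xiphoid process — and need two things derived from it: the **respiratory
phase** (one of ten equal-duration bins of the breathing cycle, the labels
that respiration-resolved CT sorts by and that beam gating keys on) and
the **longitudinal tumor displacement** in millimetres. `respnet` is for
medical-physics and biomedical-signal researchers who want an open,
inspectable implementation of a time-series deep-learning scheme for both
tasks, plus a pseudopatient breathing simulator to study it with.

## The model

Every prediction uses three time-lagged snapshots of the input at
T₀, T₋₁, T₋₂ (one phase bin apart). A snapshot is an 11-vector: marker
(x, y, z) plus eight subject specifics (age, weight, height, breaths/min,
heart rate, tumor midpoint x, y, z). The network is a chain of seven tanh
hidden layers (widths 8, 10, 8, 10, 8, 10, 5) in which a **single shared
11×8 weight matrix** injects T₋₂ into hidden layer 1 and adds the
projections of T₋₁ and T₀ into the pre-activations of hidden layers 3
and 5. The head is Softmax over ten phase nodes (classification) or one
ReLU node (regression in mm). Training is explicit backpropagation with
seeded mini-batch gradient descent at a fixed rate (α = 0.1), an L1
penalty on weights, and divergence-based early stopping; the shared
matrix's gradient is the sum over its three injection sites.

Evaluation follows the field's conventions: per-phase one-vs-rest
TP/FP/FN, precision/recall/F1 in percent, **total accuracy** defined as
the macro mean of the ten F1 scores, and MSE/MAE/R² for regression (the
percent error figures are normalized-scale values × 100).

## Worked example

```r
library(respnet)
library(dplyr)

cohort  <- generate_cohort(n_regular = 6, n_irregular = 0, repeats = 5, seed = 11)
windows <- phase_cohort(cohort)   # 300 phase-level samples, split 200/100

clf <- fit_phase_classifier(windows, seed = 12)   # alpha 0.1, <= 1000 epochs
evaluate_classifier(clf, filter(windows, split == "test"))
#> <classification_report> 100 samples, total accuracy 100.00%
#> # A tibble: 10 × 7
#>    phase    tp    fp    fn precision recall    f1
#>    <int> <int> <int> <int>     <dbl>  <dbl> <dbl>
#>  1     0    10     0     0       100    100   100
#>  2     1    10     0     0       100    100   100
#>  ...                                  (all ten phases at 100)

reg <- fit_disp_regressor(windows, seed = 13)     # alpha 0.1, <= 5000 epochs
evaluate_regressor(reg, filter(windows, split == "test"))
#> <regression_report> 100 samples | MSE 0.029% MAE 1.305% R^2 0.9961
#>   millimetre scale: MSE 0.0679 mm^2, MAE 0.1981 mm
```

Reading the output: every held-out window of this clean regular-breathing
cohort is assigned its correct phase (all per-phase F1 = 100%, so the
macro total accuracy is 100%), and the regressor explains 99.6% of the
held-out displacement variance with a mean absolute error of about
0.2 mm — around the 0.2 mm noise floor the simulator put on the coupling.

Simulated traces, windows, fitted models and reports all round-trip
through plain-text formats (`write_trace()`/CSV, `write_model()`/JSON,
`write_manifest()`/YAML), and each result type has an `autoplot()`,
`tidy()` and `glance()` method. A thin command-line front end over the
same functions is installed at `inst/cli/respnet.R`
(`generate | phase | train | predict | evaluate | run-experiment`).

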