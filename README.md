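# erppls

Simulation, preprocessing and multivariate statistics for event-related
potential (ERP) studies of contextual-congruency processing.

## The problem

When a spoken description contradicts a picture it accompanies, the brain's
response shows two characteristic ERP deflections: a negativity peaking near
400 ms post-stimulus (the **N400**, linked to semantic processing) and a
later positivity in the 500–800 ms range (the **P600**, linked to
integration and conflict monitoring). Comparing these components between
autistic and typically developing children, and between congruent and
incongruent stimulus categories, requires a chain of steps — artifact
cleaning, epoching, trial rejection, averaging — followed by a statistical
test that treats a whole component window as one multivariate observation
rather than testing 150 time points one by one.

`erppls` implements that chain end to end for a three-condition paradigm
(congruent, incongruent-semantic, incongruent-pragmatic; ~1/3 of trials
each) recorded from six scalp electrodes (F7, Fz, F8, Cz, CP5, Pz) plus two
EOG channels at 500 Hz, together with a synthetic-study generator with known
ground truth, so every stage is testable without access to any recording.

## The statistics

Per subject, condition and electrode, the ERP samples of a fixed a-priori
component window — N400 `[200, 500)` ms, P600 `[500, 800)` ms, each exactly
150 samples at 500 Hz — form a feature vector. Subjects are stacked by
design cell (group and/or condition) into a feature matrix, and the k × 150
matrix `M` of cell means is grand-mean centered to `M_c`.

- **Mean-Centered PLS** decomposes `M_c = U S Vᵀ`; each left singular
  vector is a data-driven *overall contrast* across the design cells, and
  the tested statistic is the first singular value.
- **Contrast PLS** fixes a unit contrast `c` a priori and tests
  `‖M_cᵀ c‖`.

Either statistic is referred to a permutation null — group labels permuted
across subjects for between-group questions, condition labels permuted
within subjects for repeated-measures questions — with the add-one p-value
`(1 + #{null ≥ observed}) / (1 + n_perm)`, giving **one p-value per
contrast for the entire component window**.

Two standard analysis batteries are provided: a condition battery
(2 groups × 2 components × 6 electrodes = 24 mean-centered analyses over
the 3 conditions within a group) and a group battery (2 condition sets × 2
components × 6 electrodes = 24 analyses; 2 cells for the congruent set, 4
cells — group × incongruent sub-category — for the incongruent set).

## Worked example

```r
library(erppls)

truth <- ground_truth(n_subjects = c(ASD = 6, TD = 8))   # known ground truth
study <- generate_study(truth, seed = 42, level = "erp")
prep  <- preprocess_study(study)                          # inclusion rule applied
plan  <- plan_condition_battery(study_design(electrodes = c("Cz", "Pz")))
report <- run_plan(plan, prep, seed = 1, n_perm = 1000)
report[, c("comparison","component","electrode","observed","p_value","significant")]
```

```
      comparison component electrode observed  p_value significant
1 ASD conditions      N400        Cz     3.47 0.758242       FALSE
2 ASD conditions      N400        Pz     3.18 0.814186       FALSE
3 ASD conditions      P600        Cz     3.63 0.235764       FALSE
4 ASD conditions      P600        Pz     4.25 0.207792       FALSE
5  TD conditions      N400        Cz    10.79 0.001998        TRUE
6  TD conditions      N400        Pz     9.01 0.000999        TRUE
7  TD conditions      P600        Cz    12.83 0.001998        TRUE
8  TD conditions      P600        Pz    13.54 0.000999        TRUE
```

The generator's default ground truth plants incongruency effects (N400 and
a 2 μV P600 effect) in the TD-like group only: the TD condition analyses
reject decisively (p ≈ 0.001 is the smallest value 1000 permutations can
produce) while the ASD-like group, which carries no condition effect, stays
at chance. `write_report()` saves any report as a wide TSV (electrodes as
columns, significance flags) with a JSON provenance sidecar.

The full continuous-signal path is available with
`generate_study(truth, seed, level = "continuous")`, whose recordings run
through `preprocess_subject()`: 1–25 Hz zero-phase band-pass, regression of
1–7 Hz-filtered EOG out of every scalp channel, linear detrending, epoching
to `[-200, 800)` ms, baseline correction over `[-200, 0)` ms, ±150 μV
median-amplitude trial rejection, and correct-response selection. Subjects
enter analysis only with > 20 correct trials, < 60 incorrect-or-missing
trials, and IQ ≥ 70.

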