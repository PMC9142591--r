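---
title: "ERP component analysis with Mean-Centered and Contrast PLS: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ERP component analysis with Mean-Centered and Contrast PLS: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(erppls)
```

This vignette is the package's account of its science: the generative model
behind the synthetic studies, the preprocessing chain and its parameters,
the PLS statistics and their permutation tests, and the places where a
genuine design decision had to be made.

## The paradigm being modelled

The target design is an audio-visual congruency task for children: a
picture appears together with a spoken two-word description that either
matches it (*congruent*) or contradicts it, the contradiction being either
grammatically well-formed (*incongruent-pragmatic*) or semantically
anomalous (*incongruent-semantic*). The three categories each make up about
a third of the trials. EEG is recorded at 500 Hz from six scalp electrodes
(F7, Fz, F8, Cz, CP5, Pz) and two periocular EOG channels; subjects press a
key to judge congruency, and accuracy and reaction times are logged. Two
ERP components carry the questions of interest: a negativity near 400 ms
(N400, analysed over 200–500 ms) and a late positivity (P600, analysed over
500–800 ms). The cohorts are unbalanced: 15 subjects in the ASD-like group
and 37 typically developing controls.

## The synthetic-data generator

No public recordings exist for this paradigm, so the generator is a
first-class module with known ground truth, and every downstream stage is
validated against what was planted.

**Signal model.** An ERP component is a Gaussian bump in time,
$a\,\exp(-(t - \mu)^2 / 2\sigma^2)$, scaled per channel by a fixed
topography gain in $[0, 1]$. Nothing in the target literature pins down the
waveform shape — only peak latencies and analysis windows — and a Gaussian
bump is the simplest template with a controllable peak and width. Defaults:
N400 centered at 400 ms ($\sigma$ = 60 ms, centro-parietally weighted),
P600 at 650 ms ($\sigma$ = 80 ms, strongest at Cz/CP5/Pz). Background noise
is 1/f-shaped Gaussian noise rather than white noise: EEG spectra are
approximately 1/f, and spectrally coloured noise actually exercises the
band-pass filter. Blinks are positive raised-cosine pulses of 300 ms at the
EOG channels (standard blink morphology, and smooth enough that the
regression stage is cleanly testable), arriving as a Poisson process at
0.25 events/s and leaking into the scalp channels with frontally weighted
mixing coefficients (0.40 at F7/F8, 0.30 at Fz, down to 0.05 at Pz).

**Default ground truth.** The component amplitude table plants the effects
the package's simulation suites probe: the N400 is $-4\,\mu V$ everywhere
except TD-incongruent ($-6\,\mu V$), and the P600 is $3\,\mu V$ everywhere
except TD-incongruent ($5\,\mu V$) — a 2 μV incongruency effect in the
TD-like group only, absent in the ASD-like group. Between-subject
variability is a per-component amplitude offset, $N(0, 1.5\,\mu V)$, shared
across conditions within a subject (so it cancels in within-subject
contrasts, as individual ERP-magnitude differences largely do). Responses
are correct with probability 0.8; non-correct trials are no-response with
probability 0.25; reaction times are lognormal with mean ≈ 1.65 s (measured
from the end of the spoken description). Synthetic IQ is $N(100, 15)$
truncated to $[40, 160]$, so the IQ < 70 exclusion rule has something to
exclude.

**Trials per condition.** The generator defaults to 80 trials per category
(240 per subject). With ~80 % accuracy this leaves ≈ 64 retained trials per
condition and ≈ 48 bad trials per subject — comfortably inside the strict
inclusion thresholds (> 20 correct, < 60 incorrect-or-missing). A regime of
~100+ trials per category at the same accuracy would put the expected bad
count on the exclusion boundary and remove half of every simulated cohort,
which is not a regime under which group comparisons can be studied; 80 is
the package's choice of a realistic, includable default.

**Two generation levels.** `generate_study(..., level = "continuous")`
produces full recordings — noise, blinks, EOG mixing — for the
preprocessing chain. `level = "erp"` draws each subject's *trial-averaged*
ERP directly: per condition, the retained-trial count is
Binomial(80, 0.8) and the subject ERP is template plus band-limited
(1–25 Hz) 1/f noise with per-sample SD $\sigma/\sqrt{n_\text{retained}}$.
This is the model of what reaches the statistics after preprocessing, and
it is what the large repeated-simulation suites (type-I error, power) use;
one replicate costs milliseconds instead of a minute. The continuous path,
including blink generation and removal, is validated separately. The
ERP-level shortcut does not emulate artifacts, so it can say nothing about
the cleaning stages — and neither level emulates real-data features such as
non-stationary noise, heterogeneous topographies across subjects,
lateralised blinks, or RT-locked components. Passing tests demonstrate
internal correctness and calibration under this generative model, not
fidelity to any particular dataset.

## Preprocessing chain

The order is fixed: band-pass → channel drop → EOG regression → detrend →
epoch → baseline → amplitude rejection → response selection.

- **Filtering.** 1–25 Hz for scalp channels, 1–7 Hz for the EOG
  regressors. The realization is a 4th-order Butterworth applied
  forward–backward (zero phase), implemented as a cascade of high-pass and
  low-pass sections — numerically safer than a single band-pass transfer
  function when the low edge (1 Hz) sits at 0.4 % of Nyquist. Zero-phase
  filtering matters here: a causal filter's group delay would shift
  component latencies into the wrong analysis window. Filter order and type
  are configuration defaults, not claims about any particular lab's
  settings.
- **Ocular regression.** Both filtered EOG channels are regressed jointly
  (multiple regression, with intercept) out of each scalp channel, on the
  *continuous* signals: 500-sample epochs would give unstable per-epoch
  coefficient estimates. Being a least-squares projection, the step can
  only reduce channel variance, and its residuals are exactly uncorrelated
  with the regressors. Zero-variance regressors are skipped with a warning.
- **Bad channels** are a per-subject configuration list applied before
  regression; there is no automated detection (the field often does this
  visually, which a pipeline cannot reproduce).
- **Detrending** is linear, per channel, on the continuous record, before
  epoching.
- **Epochs** span `[-200, 800)` ms around stimulus onset — exactly 500
  samples at 500 Hz — with baseline correction over `[-200, 0)` ms. All
  windows in the package are half-open: `[200, 500)` and `[500, 800)` each
  contain exactly 150 samples and share no boundary sample, which is the
  only convention under which a 300 ms window at 500 Hz has the canonical
  150 features.
- **Amplitude rejection** flags a trial when the *median* of the signed
  sample values on any scalp channel falls outside ±150 μV — the literal
  reading of a median-amplitude criterion. A median is insensitive to brief
  excursions, so a `"peak"` alternative (any single sample beyond the
  limit) is exposed as a configuration option. EOG channels are not
  considered: they are regressors, not data, though this is a choice the
  user can revisit by changing channel roles.
- **Inclusion** requires strictly more than 20 correct trials, strictly
  fewer than 60 incorrect-or-missing trials, and IQ ≥ 70. The inequalities
  are deliberately strict — "more than 20" excludes exactly 20 — and each
  failed criterion is reported.

## PLS statistics

Let $X$ be the feature matrix (subjects stacked by design cell × 150
window samples), $M$ the $k \times 150$ matrix of cell means and
$M_c$ its grand-mean-centered version (column means across cells removed).

**Mean-Centered PLS** is the SVD $M_c = USV^\top$. Columns of $U$ are
data-driven contrasts across cells ("overall contrasts"), columns of $V$
the corresponding feature saliences. Only the first latent variable is
tested — its singular value is the observed statistic — because the
analysis convention being reproduced reports a single p-value per analysis.
Sign of each salience pair is fixed so the largest-magnitude element of the
design salience is positive, making output reproducible across LAPACK
implementations.

**Contrast PLS** takes a unit-normalized a-priori cell contrast $c$ and
tests $\|M_c^\top c\|$. When $k = 2$ and $c = (1, -1)/\sqrt{2}$, this
equals the mean-centered first singular value exactly (a property the test
suite checks), so the two variants disagree only for richer designs.

**Permutation test.** Group questions permute group labels *across
subjects* (each subject keeps its conditions); condition questions permute
condition labels *within each subject* (conditions are repeated measures,
so subjects are the exchangeable-within unit). The default is 1000
permutations, and the p-value uses the add-one correction
$(1 + \#\{s_\text{null} \ge s_\text{obs}\})/(1 + n_\text{perm})$, so the
smallest attainable p-value is $1/1001$ and p is never exactly zero. Which
scheme ran is recorded in every result.

**Contrast presets.** For the four-cell incongruent group analysis, cells
are fixed in the order (ASD-semantic, ASD-pragmatic, TD-semantic,
TD-pragmatic). Two presets ship: the literal `(1, 1, -1, 1)` vector as the
default, and the sign-balanced `(1, 1, -1, -1)` variant — the literal
vector's asymmetry is preserved as published usage rather than silently
"corrected", while the symmetric form is one keyword away. The two-cell
congruent contrast is `(1, -1)`. All contrasts are configuration values,
not constants.

## Batteries and reports

`plan_condition_battery()` enumerates 2 groups × 2 components × 6
electrodes = 24 mean-centered analyses, each across the 3 conditions within
one group with within-subject permutations. `plan_group_battery()`
enumerates 2 condition sets × 2 components × 6 electrodes = 24 analyses
with between-subject permutations (2 cells congruent, 4 cells incongruent).
`run_plan()` derives one seed per analysis from the master seed via
`derive_seed()` (a fixed multiplicative mixing of seed and counter), so any
single analysis is re-runnable in isolation and whole runs are
deterministic given (study seed, analysis seed, configuration).

Reports flag p < α with α = 0.05 and apply **no multiple-comparisons
correction across the 24 analyses by default** — each permutation p-value
already covers its 150 features at once, and the reproduced reporting
convention is per-analysis uncorrected values. A Benjamini–Hochberg option
exists in `write_report()`, and the JSON sidecar records which mode ran,
along with seed, permutation count and package version.

## Numerical choices and degenerate inputs

- Singular values below $10^{-12}$ are treated as an all-zero centered
  matrix: the p-value is fixed at 1 with a warning instead of permuting
  noise-free zeros.
- Grand-mean centering makes $\mathrm{rank}(M_c) \le k - 1$; the trailing
  singular value is structurally zero and is not interpreted.
- An empty design cell is an error naming the cell; a cell with a single
  subject is refused by the feature-matrix builder (no variance, and a
  cell mean equal to one subject).
- Trials whose epoch window exceeds the recording are dropped with a
  logged count rather than padded.
- Ties in the permutation null count in favour of the null (the $\ge$ in
  the p-value), keeping the test valid for discrete statistics.
- The minimum onset asynchrony accepted by the schedule generator is 2 s
  (1 s epoch support + 1 s response window), so epochs never overlap a
  neighbouring trial's response period.

## Simulation suite sizes

The calibration and sensitivity suites run at sizes chosen to make their
Monte-Carlo error small relative to the bands they check: the type-I suite
uses 500 independent null studies (two groups of 8, 200 permutations each)
and checks the rejection count against the central 95 % band of
Binomial(500, 0.05); the power suite uses 200 replicates of the full
default design (15 + 37 subjects, 80 trials/condition) and requires ≥ 80 %
rejection in the TD-like group at Cz/CP5/Pz with the no-effect group inside
the central 99 % band of Binomial(200, 0.05). Both use the ERP-level
generator described above.

## Known limitations

- The generator's topographies are shared across subjects; real cohorts
  vary in component topography and latency, which fixed a-priori windows
  ignore by design (no peak-latency or adaptive-window measurement is
  provided, deliberately).
- The ocular model covers blinks only — no saccades, no lateral eye
  movements — and the regression assumes stationary mixing.
- No ICA, bad-channel interpolation or re-referencing: the recording
  reference is taken as given.
- Behavioural measures are summarised, not tested: the statistical surface
  is the ERP analyses.
- Permutation modes assume exchangeability within the permuted unit;
  strong per-subject heteroscedasticity across *groups* (not modelled
  here) would stress the between-subject scheme, as it does any
  permutation test.

## A minimal run

```{r example, eval = FALSE}
truth <- ground_truth(n_subjects = c(ASD = 6, TD = 8))
study <- generate_study(truth, seed = 42, level = "erp")
prep <- preprocess_study(study)
plot(prep$erps[[1]], channel = "Cz")

report <- run_plan(plan_condition_battery(), prep, seed = 1, n_perm = 1000)
write_report(report, "condition_battery.tsv")
```
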