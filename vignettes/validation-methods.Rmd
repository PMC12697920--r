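---
title: "Validating actigraphy sleep-wake scoring against polysomnography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating actigraphy sleep-wake scoring against polysomnography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actisleep)
```

## The problem

Wrist actigraphy summarizes movement as per-epoch activity counts and
infers sleep from stillness; polysomnography (PSG) records sleep directly
and serves as ground truth. Validating an actigraphy scoring algorithm
means pairing the two recordings epoch by epoch over one night, scoring
the counts, and quantifying agreement. `actisleep` implements that study
design end to end: scoring, rescoring, epoch harmonization, night-level
sleep metrics, and the agreement/inference suite, plus a synthetic cohort
generator so every stage can be exercised with known truth.

## The scoring model

Cole-Kripke, UCSD, Kripke 2010 and Philips-Respironics are linear
weighted-window operators on the 30-second count series: the raw score of
epoch $i$ is $P\sum_k w_k A_{i+k}$ over a fixed window of signed offsets
$k$, followed by a threshold decision. Cole-Kripke, UCSD and Kripke 2010
score sleep when $D < 1$; Philips scores wake when total activity $A$
exceeds a wake threshold $T \in \{20, 40, 80\}$, giving three variants.
Sadeh's discriminant is nonlinear:
$PS = 7.601 - 0.065\,\mathrm{AVG} - 1.08\,\mathrm{NATS} -
0.056\,\mathrm{SD} - 0.703\,\mathrm{LG}$ over an 11-epoch window, sleep
when $PS \ge 0$, with counts clipped at 300 before feature extraction.

Window positions falling outside the recording contribute zero activity
for every algorithm. The published Sadeh description states this
missing-as-zero policy explicitly; we apply it uniformly because it is the
only choice that keeps all five operators defined at the record edges.

All weights, scales, thresholds and decision rules live in a JSON registry
(`inst/extdata/algorithms.json`), loaded by `algorithm_registry()`, so a
corrected weight is a data edit, not a code change. Three published
weights are typographically ambiguous in their sources, and the registry
ships the readings most consistent with the surrounding terms:

* Cole-Kripke's center weight is printed in some sources with an `l`/`1`
  glyph ambiguity ("12l"); we ship **121**.
* Kripke 2010's final weight is printed ".100" amid four-decimal
  neighbours; we ship **0.0100**, matching the magnitude of the adjacent
  terms.
* The Philips nine-term window is printed with the offset `+2` term
  duplicated; we ship the final term at **+4**, completing the symmetric
  ±4 window.

These are flagged as decisions, not assertions about the original intent;
anyone who disagrees can point `registry_path` at an amended file.

Two further Sadeh choices: `LG` is computed as $\ln(\text{count} + 1)$ so
that zero-activity epochs stay finite (the registry's `log_offset`), and
the decision threshold defaults to $PS \ge 0$; the alternative $PS > -4$
convention found in derived literature is available by overriding the
registry threshold. `SD` uses the sample standard deviation (denominator
$n-1$) of the six window epochs at offsets $-5$ through $0$.

## Epoch harmonization

Scoring happens at 30 seconds; comparison happens at 1 minute. Raw
actigraphy scores are collapsed by **summing** the two constituent 30-s
scores and applying the original per-epoch threshold unchanged to the
minute sum (`collapse_scores_to_minutes()` then `classify()`). This
doubles the effective score scale relative to per-epoch thresholding,
which is why the pipeline also offers `collapse_mode =
"classify_then_pair"` (threshold at 30 s, then wake-wins on the binary
labels) for sensitivity analyses; the summed path is the default because
it is the study procedure being reproduced. PSG labels are collapsed by
the **wake-wins** rule: a minute is sleep only if both halves are sleep.
Pairs are formed from epoch 0 — i.e. (0,1), (2,3), … — and an unpaired
trailing epoch is dropped and reported. `pair_distribution()` audits how
often adjacent PSG pairs disagree, which bounds how much the wake-wins
collapse can distort the label stream.

## Webster rescoring

The five rules convert short sleep runs adjacent to long wake runs into
wake (rule 1: after ≥ 4 wake minutes, the next 1 sleep minute; rule 2:
after ≥ 10, the next 3; rule 3: after ≥ 15, the next 4; rules 4–5: sleep
bouts ≤ 6 or ≤ 10 minutes surrounded by ≥ 10 or ≥ 20 wake minutes on both
sides). They are applied sequentially, 1 through 5, each on the output of
the previous rule. Within one rule's pass, run lengths are read from the
series as it stood at the start of that pass and all changes are applied
together. The alternative — updating in place while sweeping left to
right — would let every rescored minute extend the preceding wake run, so
rule 1 alone would consume any sleep run that follows four wake minutes;
that cannot be the published behaviour, so the snapshot semantics are
used. "After at least $N$ minutes wake" means a *maximal* wake run of
length ≥ $N$ immediately precedes the sleep minutes in question, and a
sleep run at the record boundary (no flanking wake run) is never touched
by rules 4–5. Rescoring can only create wake, so the sleep set after is
always a subset of the sleep set before — a property the test suite
checks on randomized inputs. Idempotence is *not* asserted (earlier rules
can enable later ones); instead `webster_rescore()` reports whether a
second full pass would be a fixed point.

## Sleep metrics

`compute_night_metrics()` takes the minute hypnogram cropped to the
in-bed interval: onset is the **first minute scored sleep** (no
consecutive-minutes criterion — the study's metric definitions are written
in terms of first sleep onset; a run-of-$N$ rule is available via
`onset_run` for sensitivity checks), offset is the last sleep minute, TST
and WASO are the sleep and wake minutes between them, and sleep efficiency
is $100 \cdot \mathrm{TST}/\text{in-bed}$ with the in-bed duration taken
from the synchronization record, not inferred. A night with no sleep
minute returns zeros with a `no_sleep` flag rather than an error. The
identity $\mathrm{TST} + \mathrm{WASO} = \text{offset} - \text{onset} + 1$
holds on every input.

## Agreement and inference

Sleep is the positive class throughout (sensitivity = sleep detection),
PSG is the actual class, actigraphy the predicted class. Cohen's κ
corrects observed agreement for marginal chance agreement; MCC is
algebraically the Pearson correlation of the two binary vectors, which the
tests verify to 1e-12. Metrics with degenerate denominators (a constant
predictor, single-class truth) are reported as `NA` with a reason code,
never silently as zero.

ROC curves sweep every unique raw minute score. Algorithms whose rule is
"sleep when the score is low" are negated before the sweep so the sweep is
always sleep-positive; Sadeh's PS is used as-is (`score_orientation()`).
AUC is the trapezoidal integral, which equals the Mann-Whitney
$U/(n_+ n_-)$ rank statistic — an identity the tests check to 1e-10.
Pooled summaries across participants weight each participant by compared
epochs; the weighted SD uses the weight-normalized form
$\sqrt{\sum w (x-\bar x_w)^2 / \sum w}$, so a singleton pool has SD 0.

The between-algorithm stage is a one-way within-subject ANOVA on the
per-participant metric values (participants × algorithm variants).
Greenhouse-Geisser $\varepsilon$ is computed from the orthonormally
contrasted covariance, $\varepsilon = \operatorname{tr}(E)^2 / ((k-1)
\operatorname{tr}(E^2))$, clamped to $[1/(k-1), 1]$; it equals 1 exactly
for compound-symmetric covariance and for $k = 2$. Mauchly's W uses the
chi-square approximation with the second-order term, following the
coefficient convention of `stats::mauchly.test` so results line up with
base R output digit for digit. Adjusted degrees of freedom and p values
are reported alongside uncorrected ones, with generalized eta squared
$SS_\text{effect}/(SS_\text{effect} + SS_\text{subject} + SS_\text{error})$.
Post hocs are paired t tests (the base test is not dictated by the study
design; paired t is the conventional default and is configurable through
`posthoc_pairs()`), Bonferroni-corrected as $\min(1, p \cdot m)$. Hedges'
$g$ uses the **averaged condition SD** standardizer
$\sqrt{(s_1^2 + s_2^2)/2}$ with small-sample factor $J = 1 - 3/(4(n-1)-1)$
— not the SD of difference scores, which would inflate $g$ for highly
correlated conditions — labelled by the 0.2 / 0.5 / 0.8 convention.

Bland-Altman analysis takes differences (actigraphy − PSG), reports mean
difference, SD, limits of agreement $MD \pm 1.96\,SD$, and proportional
bias as the OLS regression of differences on pair means (slope, $R^2$,
two-sided p).

The outlier sensitivity analysis works on raw 30-second counts, in two
tiers: participants whose count IQR falls outside the Tukey fences
(1.5 IQR) of the sample's distribution of participant IQRs, plus
participants whose mean count has $|z| \ge 2$ against the sample of
participant means. The published description of the IQR rule is garbled
("1.5 times below the first quartile and above the first quartile"); Tukey
fences on the participant-IQR distribution are the only reading consistent
with both the "1.5 times" factor and the use of quartiles, and that is
what is implemented. Flagged participants are removed, the pooled metrics
recomputed, and relative changes tabulated against a 5% criterion.

## The synthetic cohort generator

`simulate_night()` builds a ground-truth hypnogram at 1-minute resolution
— gamma-distributed sleep-onset latency, a sleep period interrupted by
wake bouts from a two-state run-length process, and a terminal wake
segment — then replicates it to 30-second epochs and samples counts
conditional on state: wake counts from a gamma distribution, sleep counts
from a zero-inflated gamma burst model (movement implies wake is exactly
the assumption the scoring algorithms encode, so this is the structure
they are entitled to see). Defaults, chosen once as typical of one-night
community recordings of older adults: 480 in-bed minutes, latency mean 15
min (shape 2), 1.5 wake bouts per hour of mean 2 min, terminal wake mean 5
min, wake counts gamma with mean 150 (shape 1), sleep counts zero with
probability 0.85 else gamma mean 20. Phenotypes adjust fragmentation:
`fragmented` (4 bouts/h, mean 4 min; labelled `apnea` in cohort bundles)
and `long_latency` (mean 45 min; labelled `insomnia`), with cohort
fractions 7% and 6% mirroring the prevalence of reported sleep problems in
community samples. Every night has a private RNG stream derived from the
config seed and participant index, so cohorts are byte-reproducible and
individual nights can be regenerated in isolation.

What the generator deliberately does **not** emulate: sleep stages,
circadian structure across nights, device-specific count modes, scorer
disagreement, or sub-minute label transitions — the truth hypnogram lives
at minute resolution, so adjacent 30-s PSG pairs never disagree and the
wake-wins collapse reconstructs the truth exactly. The pair-distribution
audit therefore reports 0% mixed pairs on synthetic cohorts, where real
recordings show a small mixed fraction. Passing tests on this generator
demonstrates that the pipeline machinery is correct, not that any
algorithm performs at a particular level on clinical data.

## Numerical and design notes

* Epochs are 0-based and cover half-open intervals
  $[\text{start} + i\,\ell, \text{start} + (i+1)\,\ell)$; synchronization
  offsets are signed counts of 30-s epochs (positive = PSG starts later),
  applied before cropping to the overlap and, optionally, the in-bed
  interval. Alignment is explicit (one sync record per participant); no
  automatic cross-correlation alignment is attempted.
* CSV round-trips write doubles with 17 significant digits, so
  `read_epoch_series(write_epoch_series(x))` reproduces values exactly.
* Threshold comparisons are exact as published: strict `<` for the D-type
  rules, `<=` for Philips (wake strictly above T), `>=` for Sadeh. Scores
  landing exactly on a threshold therefore classify deterministically.
* The noiseless recovery configuration (`noiseless_config()`: wake counts
  fixed at 200, sleep counts 0, fixed 10-minute latency, consolidated
  sleep) isolates scoring mechanics. With perfectly separated counts each
  algorithm still misclassifies a shoulder of epochs at every wake↔sleep
  transition — the window reaches across the boundary — costing roughly 1
  minute (UCSD) to 5 minutes (Kripke 2010, whose window looks back 10
  epochs) of TST at the onset transition. A consolidated night is used so
  recovery error is bounded by that single-transition shoulder; with
  fragmented truth the same per-transition cost accrues at every bout
  boundary, which is a property of the published algorithms, not of the
  implementation.
* Test problem sizes (1,000-series scoring oracles, 10,000-epoch
  threshold sweeps, 2,000-replicate ANOVA calibration, 50-night
  end-to-end cohorts) were chosen so the full suite runs in well under a
  minute on one CPU while keeping Monte-Carlo bands several standard
  errors wide.

## Limitations

The package validates algorithms against *binarized* PSG only; staging,
inter-scorer reliability, and acquisition of real cohort data are out of
scope. The synthetic generator's count distributions are qualitative
stand-ins, not fitted to any device; absolute agreement numbers obtained
on synthetic cohorts characterize the pipeline, not the algorithms'
clinical performance. Rescoring criteria are applied as published, not
re-fitted.
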