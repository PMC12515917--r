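---
title: "Dual-modal CTG analysis with ctgkit: models, rules, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-modal CTG analysis with ctgkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgkit)
```

## The problem

Intrapartum cardiotocography (CTG) records two signals on a paper strip:
the fetal heart rate (FHR, beats per minute) and the uterine contraction
pressure (UC, mmHg). Obstetricians interpret the *joint* behaviour of the
two channels — in particular the timing of FHR decelerations relative to
contraction peaks — to grade a record into three tiers (Class I normal,
Class II indeterminate, Class III pathological). Interpretation is
subjective and inter-reader variability is high, which motivates automated
pipelines that (a) recover clean signals from scanned strips, (b) apply
the consensus rules deterministically, and (c) learn a classifier over the
chart images themselves.

`ctgkit` implements that full loop with no external data: a simulator
that generates paired FHR/UC records carrying the standard event
vocabulary and renders them into two-band chart images; a digitizer that
recovers the signals from chart rasters; a deterministic rule engine; a
densely connected convolutional classifier with selective-kernel (SK)
channel attention trained with focal loss; and an evaluation suite with a
cross-center generalization decay rate (GDR). Because every downstream
module consumes the simulator's output, every claim the package makes is
testable against known ground truth.

## The simulator (and what it does not model)

A record is sampled at 4 Hz. The FHR channel is a constant baseline
(population prior: 142 bpm, the mean of the target cohort; normal range
110–160) plus band-limited variability noise: beat-scale jitter at
0.5–1.5 Hz plus slow wander at 0.01–0.1 Hz, rescaled so that the *median
per-minute peak-to-trough amplitude* equals the requested variability
exactly. That quantity — not a spectral density — is what the clinical
definition of variability measures, so matching it exactly makes the rule
engine's variability classes recoverable by construction. The UC channel
is a resting tone (10 mmHg) plus raised-cosine contraction bumps
(amplitude 40–70 mmHg, duration 60–90 s, about 3 per 10 min by default);
clinical strips show smooth unimodal pressure waves, and a raised cosine
is the simplest shape with continuous derivatives at both ends.

Events are injected parametrically, following the standard definitions:

* accelerations rise abruptly (onset-to-peak under 30 s) and must exceed
  15 bpm for 15 s–2 min at or after 32 weeks gestation (10 bpm / 10 s
  before 32 weeks);
* early decelerations (ED) are gradual dips (onset-to-nadir at least
  30 s) whose nadir coincides with a contraction peak;
* late decelerations (LD) are the same shape with the nadir strictly
  after the peak;
* variable decelerations (VD) drop abruptly (onset-to-nadir under 30 s)
  by at least 15 bpm for 15 s to under 2 min;
* sinusoidal patterns replace variability with a smooth 3–5 cycles/min
  oscillation for at least 20 min with no accelerations.

Injectors reject requests violating those constraints, as well as
overlapping FHR events. Gaps (signal loss) are masks, never interpolated
values — the package's no-interpolation policy is absolute, because
interpolation would manufacture physiology that was never recorded.

Not modeled: maternal heart-rate artifacts, transducer physics, twin
traces, paper skew, or demographic covariates. A passing test suite
therefore shows that the algorithms are correct *on clean two-band
charts*, not that they are robust to every artifact of real scans.

## Chart geometry and digitization

The default layout reproduces a 1,653 × 2,339 px hospital strip: the FHR
band occupies rows 281–569 and maps affinely onto 60–210 bpm, the UC band
rows 628–770 onto 0–100 mmHg (row indices 0-based, band bounds inclusive;
scanned strips carry no universal origin convention, so it is
configurable). One pixel column holds 0.25 s of signal — one 4 Hz sample
— which is also configurable because no chart speed is stated anywhere;
at that speed one strip holds about 9.7 min.

Digitization is deliberately simple and fully invertible:

1. grayscale by unweighted channel mean;
2. binarize at a fixed threshold τ = 50. Selecting pixels *above* the
   threshold keeps the trace only on light-on-dark scans; on the usual
   dark-trace strip it would keep the background instead. The package
   defaults to the dark-trace convention (foreground = gray < τ) and
   exposes the complementary one as `polarity = "light_trace"`. The comparison is strict in both
   conventions, so gray = τ is always background;
3. per column, average the band's affine template over the foreground
   rows. The template is the two-point line through (band top, range max)
   and (band bottom, range min): closed forms written with an additive
   compensation constant do not in general hit both endpoints, so the
   package uses the two-point form, which preserves the intended
   reflection (values decrease as rows increase) and both clinical
   ranges exactly;
4. an empty column is a gap (`NA` + mask). A paper-faithful mode instead
   returns the ε-guarded 0 (`sum / (count + 10⁻⁶)`), reproducing that guarded
   arithmetic for pipelines that expect a dense series.

The renderer draws traces through the exact inverse of those templates,
with the grid at intensity 200 — on the background side of τ — so
thresholding removes it. This yields a provable round-trip bound: the
only loss is row quantization, so extracted values sit within half a row
step of the truth (FHR: 150/288 ≈ 0.52 bpm; UC: 100/142 ≈ 0.70 mmHg per
row), and gap columns survive exactly. The tests assert one full step as
the tolerance.

## The rule engine

The clinical definitions specify criteria, not algorithms; the package
commits to the following concrete procedures.

**Baseline.** A 10-min rolling median gives a provisional baseline curve;
samples deviating more than 7 bpm from it (grown by hysteresis to
2.5 bpm) are candidate event excursions and are excluded; the baseline is
the mean over the remaining stable segments of at least 2 min. When
frequent decelerations leave no 2-min stable segment, progressively
shorter segments (1 min, 30 s) are used and the estimate is flagged as a
fallback; fewer than 10 min of valid signal makes the estimate
indeterminate. Tachycardia/bradycardia are flagged when the rolling
baseline stays above 160 / below 110 bpm for 10 min.

**Variability** is the median over 1-min windows of the peak-to-trough
amplitude of valid, non-excursion samples: absent < 2 bpm, minimal ≤ 5,
moderate 5–25, marked > 25. The marked level extends the three clinical
labels because amplitudes above 25 bpm are not "moderate"; only moderate
variability satisfies Class I. Whether variability should be computed per
10-min window rather than over the whole strip is unspecified in the
consensus definitions; the package uses the whole strip, which is the
stricter reading for Class I.

**Events.** Excursions against the rolling baseline are screened by a
core threshold (60% of the height rule for accelerations, 8 bpm for
decelerations), extended outward to a 1-bpm crossing (capped), and then
typed: peak height is measured on the raw trace (so exact-threshold
fixtures behave exactly), timing on a 5-s smoothed trace. A dip is VD if
onset-to-nadir < 30 s, otherwise it is gradual and must be timed against
a detected contraction: within ±10 s of the peak it is ED, later than
10 s it is LD. The ±10 s tolerance operationalizes "coincident", which has no
quantitative tolerance in clinical guidance. A gradual dip with no usable contraction is
returned *untyped* with a warning — this is precisely the unimodal
failure mode that motivates dual-channel analysis, and removing the UC
channel from an ED fixture reproducibly flips it to untyped.

**Sinusoidal** detection is per-minute spectral concentration: a 1-min
window qualifies when at least 60% of its non-DC FFT power lies in the
3–5 cycles/min bins and its amplitude is 3–35 bpm; the pattern is present
when 20 consecutive windows qualify with no acceleration inside the run.
A 19-min sinusoid therefore fails, as it must.

**Recurrence** ("recurrent" late/variable decelerations) is defined as at
least half of detected contractions carrying the deceleration type, with
a minimum of two — the convention used in practice, since clinical guidance
uses the word without a quantitative definition. Class III is absent variability
with recurrent LD, recurrent VD, or bradycardia, or a sinusoidal pattern;
Class I requires a determinate 110–160 baseline, moderate variability,
and no LD/VD/untyped dips; everything else — including records with
indeterminate components — is Class II. The default binary policy maps
Class I to normal and II/III to abnormal; unset gestational age defaults
to 34 weeks (post-32 thresholds).

## The classifier

The backbone is a densely connected network: each layer applies
BN→ReLU→1×1 bottleneck→BN→ReLU→3×3 convolution and concatenates its K
new channels onto everything before it; transitions halve channels and
pool. With the reference configuration (K = 32, blocks 6-12-24-16,
bottleneck 4, compression 0.5, 7×7/2 stem, 1000-class head) the builder
counts 7,978,856 trainable parameters, matching the canonical DenseNet121.

The SK attention module is inserted after each dense layer, operating on
that layer's K-channel output before concatenation. It computes two
branches — 3×3 dilation 1, and 3×3 dilation 2 standing in for 5×5 —
fuses them by summation, global-average-pools to a channel statistic,
compresses to `d = max(C/r, L)` dimensions (r = 16, floor L = 32), and
gates the branches per channel through a two-way softmax, so the gates
sum to one by construction. The branch convolutions are grouped with 8
groups: on the 32-channel operand this gives 5,568 parameters per module
and 322,944 (≈ 0.32M) over the 58 dense layers, for 8,301,800 ≈ 8.3M
total — the published budget, which per-block insertion on wide feature
maps cannot meet. The exact branch configuration behind that budget is
not derivable from the text; grouped convolution is the SK-literature
reading compatible with it.

The whole engine — convolution by shifted-slab GEMM, batch norm, pooling,
the SK algebra, focal loss `-α(1-p_t)^γ log p_t` (γ = 2, α = 0.25, the
standard default), and Adam — is
implemented natively in R against BLAS, with backpropagation verified
against finite differences in the test suite. Charts enter the network
intensity-inverted (trace = 1) and optionally UC-masked, which blanks the
UC band before resizing and is the "FHR-only" ablation.

## Desk-scale study design

Training DenseNet121 at 224 × 224 is not meaningful at desk scale, so the
validation studies use the same code path with a smaller configuration,
chosen once:

* **Smoke separability** (`run_smoke_training`): 200 charts at 48 × 72 px
  (480 s per strip), classes drawn from the Class I and Class III
  recipes, split 7:3 stratified, trained with the published recipe (Adam,
  learning rate 0.001, batch 32, focal loss) for 10 epochs on a
  growth-rate-6, two-block network. Expected: held-out accuracy above
  0.9.
* **Bimodal value** (`run_bimodal_study`): a timing-defined dataset in
  which normal records carry early and abnormal records late
  decelerations. Deceleration nadir times, depths, and lags are drawn by
  an identical procedure for both classes and the *contraction bumps*
  are placed either at the nadirs (early) or 35–60 s ahead of them
  (late), so the FHR channel is class-independent by construction and a
  UC-masked model can only guess. Getting this right matters: earlier
  designs that injected decelerations against randomly placed
  contractions leaked class information through deceleration counts and
  edge positions, and a masked model learned the leak instead. Charts
  are 32 × 120 px over 600 s — 5 s per column, so the lag spans 7–12
  columns, and the shallow raster keeps the two bands within the
  network's early receptive fields. Per seed (160 records, 7:3 split,
  15 epochs, growth rate 8), two identically configured networks are
  trained, one on the full chart and one UC-masked. Expected: the
  bimodal AUC exceeds the masked AUC on every seed — a directional claim
  about the value of the second channel, not a reproduction of any
  published magnitude.

The stratified 7:3 split uses largest-remainder rounding (326 records
give 228/98; per-stratum 157/71 normals/abnormals in training), model
predictions are logit argmax, and the ROC score is the normal-class
probability. Checkpoint selection is by validation accuracy, the split
ratio being the only stated constraint.

## Numerical choices and degenerate inputs

* Binarization and both templates are exact arithmetic; the only
  digitization error source is row rounding.
* `roc_auc` sweeps distinct scores so ties cross simultaneously; the AUC
  equals the pairwise-comparison probability with ties counted ½
  (verified against an O(n²) oracle to 10⁻⁹).
* GDR = (AUC_train − AUC_ext)/AUC_train × 100, rejecting non-positive
  training AUC; decay beyond 15 points flags domain adaptation.
* Empty columns, all-gap channels, one-class ROC inputs, zero-layer
  blocks, and zero-variability records all have defined behaviour
  (gap/indeterminate/rejection/identity/constant), each pinned by a test.
* Batch norm keeps running statistics (momentum 0.1) for evaluation-mode
  forwards; probabilities are clamped at 10⁻¹² inside the focal loss.

## Known limitations

The digitizer assumes an axis-aligned, single-trace chart with known band
geometry — no de-skewing, OCR, or multi-trace disambiguation. The rule
engine's thresholds (excursion hysteresis, ED tolerance, recurrence
definition) are fixed operationalizations of prose criteria; other
readings are defensible. The desk-scale network shares code, not
capacity, with the full model: results at 48 × 72 px say nothing about
224 × 224 performance on clinical data. Class II recipes cover only two
of the many presentations that tier admits. And since the cohort the
binary labels mirror is private, `make_dataset` is a synthetic stand-in
whose class recipes, not expert annotation, define the ground truth.

```{r example, eval = FALSE}
# one full loop, desk scale
rec <- simulate_record(sim_params(duration_s = 480, seed = 7))
lay <- compact_layout(96, 64, 480)
sig <- extract_signals(render_chart(rec, lay), lay)
cls <- classify_ctg(simulate_record(sim_params(duration_s = 1800, seed = 7)))
sm  <- run_smoke_training(n_records = 200, seed = 1, epochs = 10)
```
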