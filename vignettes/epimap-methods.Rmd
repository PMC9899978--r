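---
title: "Methods: activation-recovery mapping of early ischemic repolarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activation-recovery mapping of early ischemic repolarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

During the first minutes of a coronary occlusion, ventricular repolarization
changes before almost anything else: action potential duration transiently
*lengthens* — most clearly at the rim of the ischemic region — before the
familiar ischemic shortening takes over. Because this happens within one or
two minutes, it can only be studied with dense epicardial contact mapping:
tens of unipolar electrograms recorded simultaneously from a flexible
electrode plate sutured over the ventricles, together with the surface ECG.

`epimap` implements the complete analysis chain for such experiments:

1. **measure** — per-beat fiducials on every lead: activation time (AT),
   repolarization time (RT), and the derived intervals;
2. **map** — spatial classification of leads into core / border / remote
   ischemic zones and cross-lead summary metrics per animal and time-point;
3. **stats** — association of those summaries with early-phase
   ventricular fibrillation (VF) outcomes;
4. **simulate** — a fully ground-truthed synthetic cohort emulating the
   porcine occlusion experiment, so every stage above is testable without
   access to raw recordings.

## Fiducial definitions and their estimation

On a unipolar electrogram the standard markers are derivative extrema:

* **AT** — the instant of the steepest *negative* slope (dV/dt minimum)
  during the QRS complex: the intrinsic deflection of local depolarization.
* **RT** — the instant of the steepest *positive* slope (dV/dt maximum)
  during the T wave (the Wyatt method). This rule is polarity-independent:
  it lands on the terminal limb of an inverted T wave and the ascending limb
  of an upright one.
* **ARI** = RT − AT, the activation–recovery interval, a surrogate for local
  action potential duration. ARIc is its Bazett-corrected value,
  ARI / sqrt(RR in seconds); the same correction is applied to QT and QTp on
  ECG leads. RTc maps are AT + ARIc.

Estimating a derivative extremum from sampled data requires smoothing, and
the choice matters more than it looks: kernel smoothing (moving average,
Gaussian, Butterworth low-pass) *shifts* the extremum of an asymmetric
derivative by roughly half the squared kernel width over the feature scale
— at 4 kHz that is easily 0.5 ms, which would defeat sample-accurate
validation. `epimap` therefore estimates derivatives with Savitzky–Golay
local cubic fits (`sg_derivative()`): a zero-phase low-pass FIR that
reproduces any locally-cubic signal exactly, hence does not displace
extremum locations of smooth waveforms, while still averaging out
sample-to-sample noise.

Windows and defaults (all configurable):

| quantity | rule | default |
|---|---|---|
| QRS onset | first instant the rectified derivative exceeds 10% of its beat maximum, searched backward from the global derivative extremum | 31 ms derivative window |
| AT | derivative argmin in [onset, onset + 80 ms]; ties to the earliest sample | 9 ms window |
| RT | two-stage: argmax of a 35 ms-window derivative over [AT + 100 ms, 0.9 RR], refined by the 9 ms-window derivative within ±0.75 ms | |
| Tpeak (ECG) | largest absolute deflection from the isoelectric level (mean of the 40 ms PR segment) | window [onset + 120 ms, 0.9 RR] |
| Tend (ECG) | tangent method: steepest-tangent line after the apex intersected with the isoelectric level | 35 ms derivative window, tangent searched within 100 ms of the apex |

The two-stage RT rule deserves a note. A single light smoothing window is
exact on clean data but noise-fragile (the T-wave derivative peak is broad);
a single heavy window is robust but biased by ~0.3–0.5 ms. The coarse
window localizes the upstroke; the fine window then decides the sample
within ±0.75 ms (the two stages never disagree by more than 0.5 ms on
noiseless beats, so the refinement span always contains the fine optimum). On a noiseless beat both stages agree with the global fine
argmax, so exactness is preserved, and under noise the error is capped by
the coarse stage's robustness. The onset uses a heavier (31 ms) window
because a threshold crossing on a flank — unlike an extremum — is not
protected by curvature against noise, and the Savitzky–Golay fit does not
bias flank positions appreciably.

Rate correction uses the same beat's preceding RR. A failed lead (flat
trace, unmeasurable window) is recorded as missing and logged, never
imputed, and every summary metric excludes missing leads per metric.

## Zone classification and map summaries

Core ischemic leads are those whose AT during ischemia exceeds their own
baseline AT by **strictly more than 5 ms** at any of the early ischemic
snapshots (1, 2.5 or 5 min); border leads are the non-core leads
grid-adjacent (4-neighbourhood) to the core; everything else is remote. A
relative mode (delay > 20% of baseline AT) is provided because the
criterion's printed form is ambiguous between an absolute and a relative
reading; the absolute rule is the default and the two agree at typical
baseline ATs (20% of ~25 ms ≈ 5 ms). 8-neighbourhood adjacency is a flag.

Per animal and time-point, `summarize_timepoint()` computes the cross-lead
summaries used in the outcome stage: maximal AT; dispersion of
repolarization (DOR = max RT − min RT over epicardial leads, natural RT by
default); minimal / mean / maximal ARIc; maximal QT and QTc; minimal QTp
and QTp_c; and the global Tpeak–Tend interval (latest T end − earliest
T apex across ECG leads), natural and corrected. An animal is flagged as
showing **early repolarization prolongation** when its maximal ARIc exceeds
baseline by strictly more than 10 ms at 1 and/or 2.5 min.

## Outcome statistics

All models are univariate, matching the design of small occlusion cohorts:

* repeated measures: Friedman test across time-points, then pairwise
  Wilcoxon signed-rank against baseline with a Bonferroni multiplier equal
  to the number of pairwise tests;
* logistic regression of VF on each covariate (OR per ms, Wald 95% CI on
  the log scale; complete separation detected and flagged, not reported);
* OLS regression between electrophysiological and ECG summaries;
* ROC analysis where the AUC *is* the Mann–Whitney pairwise-concordance
  probability with ties counted ½, the curve is traced over all observed
  thresholds with the "positive if > cutoff" rule, and the operating point
  maximizes the Youden index (ties resolved toward the lower cutoff);
* Cox proportional hazards (Efron ties) for VF times;
* Kaplan–Meier curves with the 1-df log-rank test for the dichotomized
  cohort (categorical QTc cutoff 460 ms by default, any user value
  accepted);
* Pearson chi-square without continuity correction for VF incidence by
  occlusion site.

Repeated time-points enter the default regressions as one row per animal
per time-point; this pools within-animal correlation and is flagged as
unclustered in every output row. An alternative per-animal
maximum-over-period mode is provided. Neither mode claims to reproduce any
published coefficient — with n = 18 animals the point estimates are
dominated by sampling noise; the package's validation is property-based
(see below).

Standard fits are delegated: `stats::glm`, `stats::lm`,
`stats::friedman.test`, `stats::wilcox.test`, `stats::chisq.test`,
`survival::coxph`, `survival::survfit`, `survival::survdiff`. The ROC/AUC
machinery is implemented in the package because its tie and cutoff
semantics are part of the contract, and it is cross-checked against `pROC`
in the test suite.

## The synthetic cohort

`generate_cohort()` simulates the full experiment with known ground truth.
Defaults are the study conditions: 18 animals; 48 epicardial leads on a
6 × 8 plate at 4 kHz; 12 ECG leads at 1028 Hz; snapshots at 0, 1, 2.5, 5
and 10 min after occlusion; alternating LAD/LCX occlusion sites.

Interval structure, per animal:

* RR ~ lognormal(534, 97) ms between animals (clamped to 400–850 ms),
  with 1.5% within-animal drift across time-points;
* per-lead baseline AT ~ N(24, 5) ms truncated to [19.5, 42] (the parametric
  QRS needs the upstroke and the intrinsic deflection separable), baseline
  ARIc ~ N(330, 12) ms; true ARI = ARIc · sqrt(RR) so beats remain
  geometrically feasible at short cycle lengths;
* a contiguous core patch covering 20–40% of the plate (random frontier
  growth), its 4-neighbourhood frontier as the border zone;
* time-course profiles (ms added to the beat): core AT delay
  {0, 6, 25, 30, 35}; border ARI delta {0, +24, +24, −10, −30} — the
  biphasic border-zone dynamic with the +24 ms early prolongation used as
  the default magnitude; core ARI delta {0, +10, −15, −40, −60}; ECG QT
  delta {0, +20, +18, −8, −20};
* per-ECG-lead baseline QTc ~ N(430, 12) ms plus a between-animal random
  effect of SD 35 ms, reproducing a ±35 ms between-animal spread of the
  maximal QTc;
* a per-animal lognormal "susceptibility" factor (SD 0.3 on the log scale)
  scales all ischemic deltas, coupling ARI and QT prolongation within
  animal — this is what makes maximal ARIc and maximal QTc correlate;
* core leads get an ST plateau of +0.25 mV (border: half), T polarity is
  mixed 50/50, and white noise of SD 0.01 mV is added to the waveforms.

The VF outcome is drawn per animal from
logit P(VF) = intercept + slope · maxQTc(2.5 min), with slope
log(1.024) per ms by default and the intercept centred at the generator's
expected maximal QTc (474 ms) so an average animal has ≈50% risk; VF times are uniform on 1–8 min, VF-free animals are
censored at 10 min (only the observed range of event times is known, so a
uniform draw is the least-committal choice).

Setting `noise_sd = 0` produces a *fully deterministic* cohort — waveform
noise, RR drift and per-lead jitter are all disabled — so that "null
dynamics" configurations give exactly constant ARIc across time-points.

### The beat model

Each beat is built from smooth parametric components whose
smoothed-derivative extrema sit exactly at the requested fiducials
(`make_beat_waveform()`). The QRS is designed in derivative space as three
separated lobes, integrated analytically to `pnorm` steps: a steep upstroke
(carrying the global derivative extremum the onset rule walks back from), a
downstroke step whose steepest point is AT, and a slow recovery step. The
upstroke width scales with the onset-to-AT gap, so delayed activation comes
with QRS widening, as in ischemia. The T wave is a Gaussian bump placed so
its steepest same-sign slope falls at RT for either polarity; the ST
segment is a logistic plateau whose ramps stay outside the detection
windows. ECG beats use the same machinery parameterized by QT, with the
T apex at QT − 2σ so that the tangent through the inflection point meets
the isoelectric level exactly at QT.

Because the onset is itself a rule (10% threshold crossing), the generator
runs that rule on its own noiseless waveform — after two calibration
passes: one scales the upstroke until its smoothed-derivative peak
dominates the downstroke's by at least 35% (derivative smoothing attenuates
the narrower upstroke lobe more, and the onset rule must stay anchored to
the upstroke), and one slides it so the crossing lands on the nominal
reference — and reports ground truth relative to the result. Generator truth and
detector thus share one time reference to sub-sample accuracy, which is
what makes exact round-trip tests possible.

### What the generator does *not* emulate

Fractionated electrograms, drifting baselines, ectopy, electrode motion,
conduction block, VF waveforms themselves, and any biophysical
(ionic-current) mechanism. Passing tests on this cohort demonstrate that
the measurement and statistics chain is correct *given* beats whose
morphology satisfies the fiducial definitions — not that the detectors are
robust to every pathology of real recordings.

## Numerical choices and degenerate inputs

* Derivative ties resolve to the earliest sample; Youden ties to the lower
  cutoff.
* Time convention: fiducials in ms relative to the QRS onset; sample
  indices are 0-based in time (`t = index / fs · 1000`).
* A beat whose AT + ARI + T-width exceeds 90% of RR is rejected at
  construction (the RT search window ends at 0.9 RR).
* Flat traces, empty windows, single-class outcomes, constant covariates
  and empty groups raise informative errors; inside `measure_cohort()` a
  failing lead degrades to per-lead missingness instead.
* Validation problem sizes: oracle equivalence on 1,000 noiseless beats;
  noise robustness on 1,000 beats at SNR 20 dB; zone recovery on 50
  animals; flag operating characteristics on 2 × 200 single-animal
  replicates; Wald-coverage of the outcome model on 500 cohorts of n = 200.

## Known limitations

* Univariate statistics only; repeated time-points are pooled without
  mixed-effects correction (flagged in the output).
* The zone criterion's "(20%)" ambiguity is resolved by defaulting to the
  absolute 5 ms rule; both modes are available but they can disagree for
  leads with unusually long baseline AT.
* DOR uses natural RT by default; whether rate-corrected RT should enter
  the dispersion is left as an option (`rtc_map()` provides the corrected
  map).
* The synthetic beat family is idealized (see above); SNR in the noise
  criteria refers to white noise against the RMS of the mean-removed beat.
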