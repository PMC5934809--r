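---
title: "Rule-based rhythm analysis of long-term single-lead ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based rhythm analysis of long-term single-lead ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgflow)
```

`ecgflow` screens long-term single-lead ECG for five rhythm categories:
normal sinus beats (NB), atrial premature beats (APB), ventricular
premature beats (VPB), and the repetitive ventricular rhythms bigeminy
(BG) and trigeminy (TG). This vignette explains the model behind each
stage, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical choices that make
the pipeline deterministic.

## Signal model and preprocessing

The input is a uniformly sampled voltage series in millivolts with a known
sampling frequency; the native profile is a wearable Holter recording at
150 Hz. Since attachment and detachment leave unstable signal at the
record edges, `trim_edges()` removes the first and last 2 minutes of
long recordings (`run_pipeline()` trims automatically only for records
longer than 10 minutes, so short laboratory records pass through intact).

`bandpass_filter()` applies an order-3 Butterworth band-pass with cutoffs
at 0.5 and 40 Hz, run forward–backward (`signal::filtfilt`). The band
keeps the QRS energy (roughly 5–25 Hz) while removing baseline wander
(below 0.5 Hz), EMG-type high-frequency noise, and 50/60 Hz powerline
interference, which lies above the upper cutoff — no separate notch is
needed. The forward–backward realization matters: a causal IIR filter
would delay the R peak by a frequency-dependent amount and bias every RR
interval, whereas the zero-phase version leaves fiducial timing untouched.
This is why beat timing downstream can be trusted to single-sample
precision on clean signals.

Artifact handling is deliberately coarse-grained: `detect_artifacts()`
cuts the record into non-overlapping 2-s windows and compares each
window's peak-to-peak range against a running median *M* of the previous
30 windows (the global median during the cold start, to avoid spurious
flags at record onset). A window is masked when its range exceeds
`burst_k * M` (default 4; motion or electrode-pop bursts), falls below
`flat_mv` (default 0.05 mV; flatline or lead-off), or any sample comes
within 1% of the recorder's full-scale bound (`full_scale_mv`, default
5 mV; saturation clipping). Masked segments are *abandoned*, not
repaired: beats whose QRS span touches a masked segment carry no label
and are excluded from template building and scoring. On a clean synthetic
record the mask is empty except, occasionally, genuinely silent windows.

## R-peak enhancement and detection

`morphological_transform()` uses flat grayscale morphology. Opening
(erosion then dilation) with a structuring element *longer* than a QRS
(default 0.2 s) removes the QRS spike and follows the residual baseline;
averaging opening-then-closing with closing-then-opening makes the
estimate symmetric for upward and downward excursions. Subtracting it and
applying a top-hat with an element *shorter* than a QRS (default 0.06 s)
then suppresses the wide P and T waves — a flat top-hat of a unimodal bump
has support no wider than its element — while passing the narrow R spike
nearly unchanged. The absolute value makes the output polarity-free.
Element lengths are converted to the nearest odd sample count so the
operators stay centered.

`detect_r_peaks()` scans the local maxima of the enhanced series with a
dynamic threshold: 0.4x the median of the last 8 accepted peak
amplitudes, initialized from the 98th percentile of the first 10 s. A
200-ms refractory period rejects double-triggering on one complex; when
the gap since the last accepted peak exceeds 1.5x the running average RR,
the gap is re-scanned with the threshold halved (search-back), which
recovers occasional low-amplitude beats without lowering the global
threshold. All state updates are causal and deterministic: identical
input gives identical output, and delaying the signal delays the peak
list by the same amount.

## QRS delineation and the width measurement

Nominal QRS boundaries are placed 50 ms before and 80 ms after each R
peak. Millisecond values convert to samples by round-half-up
(7.5 samples at 150 Hz rounds to 8), a fixed documented rule so
delineation cannot depend on the platform's rounding mode.

The classification rules need a *variable* QRS width, and fixed 50/80-ms
boundaries would make every width a constant 130 ms. `delineate_qrs()`
therefore measures width independently: within R ± 100 ms it estimates a
local baseline as the median of an annulus 107–180 ms either side of R
(robust to the low-frequency undershoot that large ventricular beats
leave after high-pass filtering, which would otherwise spill into
neighbouring beats' windows), and takes the span between the first and
last samples whose baseline-corrected magnitude exceeds 10% of the R
magnitude. Taking the first/last crossing rather than a contiguous run
bridges the zero-crossings between Q, R and S. On the synthetic beats
this yields ~47 ms for narrow complexes and ~140 ms for wide ventricular
ones, comfortably either side of the 120-ms rule boundary.

## Features: the running-average RR window

Each beat carries its previous and next RR interval and a causal
running-average RR (`running_avg_rr()`), the mean of the previous
`avg_window` intervals excluding the current one; the cold start uses
whatever history exists. First/last beats have explicit `NA` neighbours
and are never labeled APB or VPB (they default to NB when narrow).

The window length is the one genuinely open design choice, and it decides
whether sustained runs are classifiable at all. The default is **24
intervals**, for two reasons:

* *Period matching.* Bigeminy repeats with period 2 (coupling, pause) and
  trigeminy with period 3. Over a window that is a common multiple of
  both, the average equals the cycle mean exactly, so inside a steady run
  the VPB rule's compensatory test compares the couplet sum against a
  stable reference. With a window of 8 — not divisible by 3 — the average
  inside trigeminy oscillates by up to ±50 ms with the run phase, and the
  compensatory sum falls below 2x the average for *every* in-run VPB:
  sustained trigeminy would be structurally undetectable.
* *Smoothing.* 24 intervals (~24 s at 60 beats/min) is ordinary Holter
  practice for a local rate reference — long enough to ride out single
  ectopic disturbances, short enough to track genuine rate drift.

The averages are computed by direct window sums rather than
cumulative-sum differences: the VPB rule compares `rr_prev + rr_next >=
2 * avg`, and inside bigeminy the two sides are *mathematically equal*, so
even a 1-ulp rounding residue from a cumulative sum flips the comparison.
With direct sums, interval values that are exact in floating point (all
run intervals are multiples of 20 ms = 3 samples at 150 Hz) give an exact
average and a deterministic comparison.

## Classification rules and run detection

`classify_beats()` applies the judgment rules with strict inequalities as
stated — a width of exactly 120 ms is neither narrow nor wide and yields
`UNCLASSIFIED`, and the rules partition: at most one of NB/APB/VPB can
fire for any feature vector (asserted by an exhaustive grid test).

`detect_rhythm_events()` finds maximal alternation runs: bigeminy as a
VPB alternating with one sinus-conducted beat (at least 3 VPBs, clinical
convention that a single couplet is not yet a rhythm) and trigeminy as
repeated sinus–sinus–VPB triplets (at least 2). The sinus slot accepts an
NB label *or a narrow UNCLASSIFIED beat* when widths are available. This
is deliberate: inside a run, the beat after each VPB sits on the
compensatory pause, so its RR interval exceeds 1.2x the average and the
NB rule cannot fire — a literal NB/VPB alternation test would never match
real bigeminy. Keying the sinus slot on narrow-complex morphology keeps
the beat labels faithful to the rules while letting run detection work.
Events never relabel their member beats; beat labels and events are
reported separately so beat-level metrics stay well-defined.

`template_correct()` demotes abnormal labels whose waveform (R ± 100 ms)
has normalized cross-correlation ≥ 0.9 with the normal-beat template
(mean of up to the first 50 noise-free NB beats, amplitude-normalized).
Demotion applies to VPB labels by default: a VPB claim asserts abnormal
*morphology*, which the template can refute. An APB conducts through the
normal ventricular pathway — its QRS is the template, and correlating it
against the template is uninformative (measured NCC ≈ 1), so demoting
APBs would erase the class; the timing rules remain their arbiter. The
stricter behaviour is available via `classes = c("APB", "VPB")`.
Correction is demotion-only and therefore idempotent.

## The synthetic generator

`generate_record()` emulates a bedside patient simulator feeding a
single-lead recorder: beats are sums of Gaussian bumps (P, Q, R, S, T)
with fixed morphologies — narrow complexes span 80 ms from Q onset to S
offset, wide ventricular complexes 160 ms with an inverted T — placed on
a timing grid:

* sinus RR = 1000 ms (60 beats/min) with Gaussian jitter (sd 10 ms,
  clamped at 3 sd) applied only between consecutive plain sinus beats;
* APB: coupling 0.6x base, following interval 1.1x base, so the
  non-compensatory sum is 1.7x base, well below the 2x rule line;
* VPB: coupling 0.6x base with a slightly over-complete compensatory
  pause of 1.44x base (sum 2.04x base). A pause of exactly 2x base would
  put every isolated VPB *on* the rule boundary, where sinus jitter in the
  running average misclassifies half of them; the 40-ms surplus is within
  physiological variation and keeps the comparison decisively above the
  line. Inside steady bigeminy the couplet sum equals 2x the running
  average *exactly* (a structural identity of periodic runs), which is
  why the rule's `>=` is inclusive and why run intervals are built on the
  20-ms grid that makes their millisecond values floating-point exact;
* runs: a BG instruction emits VPB–NB couplets, a TG instruction
  NB–NB–VPB triplets, with per-couplet/triplet ground-truth event
  instances.

The 40-record evaluation profile (`generate_fixture_set()`) lays out each
5-minute record as: sinus warm-up, six isolated APBs and six isolated
VPBs with sinus recovery, a 15-couplet bigeminy run, a 10-triplet
trigeminy run, and sinus padding — with a 24-interval sinus spacer before
each run so the running average has settled when the run begins (a stray
post-extrasystolic pause inside the averaging window would bias it).
Summed over 40 records the ground truth is exactly 3120 scored NB, 240
APB, 240 VPB, 600 BG and 400 TG instances. Because roughly half of each
record is sinus padding and run-internal conducted beats, the scored NB
subset is a fixed per-record quota of 78 padding beats drawn from the
tail of the final sinus block; `nb_quota = NA` scores every plain sinus
beat instead.

What the generator does **not** emulate: respiratory modulation, heart
rate variability spectra, morphology drift, multi-lead projection, or the
electrode-contact noise of real wearables. Passing the fixture therefore
demonstrates the *logic* of the pipeline — detection, delineation, rules,
run bookkeeping, scoring — under controlled conditions, not field
performance on ambulatory recordings, which is dominated by noise
robustness the mask only partially addresses.

## Scoring

`score_annotations()` scores one-vs-rest over the scored ground-truth
instances. Predicted beats are paired with truth beats by greedy
nearest-neighbour matching within 75 ms (half the common 150-ms
acceptance window; the tolerance is configurable). A truth beat's
predicted class is its matched beat's label; a detection miss counts
against the truth class. A truth rhythm event is predicted positive when
any predicted event of the same kind overlaps its sample span. With this
universe, TPOS + FNEG equals the number of scored truth instances per
class and the four counts always total the universe, so accuracy,
sensitivity and specificity (with explicit `NA` for empty denominators)
are all well-defined, for events as well as beats. `pool_reports()` sums
per-record counts before recomputing rates, so pooled results weight
records by their instance counts.

## Problem sizes and determinism

The bundled tests and the acceptance script run the full 40-record,
5-minute fixture (12,000 beats, 1.8 M samples) plus property checks
(exhaustive rule grid; run-detector equivalence against a regex oracle
over all label strings up to length 12; naive/vectorized backend
equivalence over 20 seeds on 60-s records). Everything is seeded and
deterministic: the generator restores the caller's RNG state, fixture
instance counts are seed-invariant, and both execution backends produce
bit-identical annotations — the backends differ only in how the running
min/max of the morphology stage is evaluated (explicit loop vs
shift-and-pmin), an exact selection either way.

## Known limitations

* The rules classify only the five target rhythms; fibrillation, flutter,
  and conduction abnormalities are out of scope and will surface as
  `UNCLASSIFIED` beats or spurious NB labels.
* Width measurement assumes a dominant R deflection within ±100 ms;
  extreme axis or very low-amplitude QRS would degrade it.
* The artifact rule is a practical stand-in with three interpretable
  triggers; it is not a validated noise classifier, and its 2-s windows
  quantize mask boundaries.
* WFDB support covers single-channel extraction from format 16 and 212
  header/signal pairs — enough for arrhythmia-database records — not the
  full format zoo.
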