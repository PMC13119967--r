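---
title: "Sit-to-stand side-asymmetry analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sit-to-stand side-asymmetry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stsmap)
```

## What the package computes

`stsmap` analyses sit-to-stand (STS) trials recorded with synchronized
optical motion capture (100 Hz marker trajectories) and bilateral surface
EMG (1 kHz, seven trunk/hip muscles per side), with the goal of comparing
the more-impaired (MI) and less-impaired (LI) body sides of hemiparetic
participants over the *whole movement cycle* rather than at scalar summary
points. The chain is:

1. **Event segmentation.** Marker trajectories are smoothed with a
   zero-phase 4th-order Butterworth filter (20 Hz cutoff). Within each
   repetition window, *Start* is the first instant the anteroposterior C7
   speed reaches 10% of its in-window peak, *Lift-off* the first instant
   the greater-trochanter markers (left/right averaged) have risen by 10%
   of their total vertical displacement, *Stand* the C7 vertical maximum,
   and *End* the last instant C7 speed is still at or above the 10%
   threshold. Movement duration is End − Start.
2. **Angles.** Trunk inclination from the trunk vector (C7 − sacrum)
   projected on the sagittal and frontal planes,
   $\theta_{sag} = \mathrm{atan2}(X, Y)$ and
   $\theta_{front} = \mathrm{atan2}(Z, Y)$; hip, knee and ankle angles from
   planar marker-vector geometry per side.
3. **EMG envelopes.** Spike clipping, 40–450 Hz linear-phase FIR band-pass,
   full-wave rectification, 4 Hz low-pass; windowing from 500 ms before
   Start to 500 ms after End; time normalization to 101 nodes; amplitude
   normalization to each participant's per-muscle maximum.
4. **Inference.** Repetitions are averaged into one representative curve
   per subject/side/variable/condition; each variable is tested MI vs LI
   with an exhaustive sign-flip permutation SPM (cluster-level inference);
   Benjamini–Hochberg FDR is applied across the variables of each family
   (3 joint angles; 7 muscles) within each condition.

## The permutation SPM model

For $n$ paired subjects with difference curves
$d_i(k),\ k = 0,\dots,100$, the pointwise paired statistic is

$$t(k) = \frac{\bar d(k)}{s_d(k)/\sqrt{n}},$$

with the sample ($n-1$) standard deviation. Nodes with zero variance give
$t = 0$ when the mean is also zero, and $\pm\infty$ sentinels otherwise;
sentinels order above any finite $t$.

Under the null hypothesis of exchangeable sides, the $2^n$ sign assignments
$(\pm d_1, \dots, \pm d_n)$ are equally likely. The engine enumerates all of
them and:

* takes the **cluster-forming threshold** $t^\*$ as the $(1-\alpha)$
  quantile of the permutation distribution of $\max_k |t(k)|$. Forming
  clusters on $|t|$ against this two-sided maximum statistic is what keeps
  the *whole-curve* false-positive rate at or below $\alpha$ — verified
  empirically in the acceptance suite (the exact level at $n = 7$,
  $\alpha = 0.05$ is $3/64 \approx 0.047$ because of the quantile's
  discreteness);
* assigns each observed supra-threshold cluster a p-value by **directional
  counting**: the fraction of permutations whose longest run of *signed* t
  above the threshold (in the cluster's direction) is at least as long as
  the observed cluster. Every p is then a multiple of $1/2^n$ and the
  smallest attainable value is exactly $1/2^n$ — 0.0078 (printed 0.008) at
  $n = 7$, 0.0156 (printed 0.016) at $n = 6$. This granularity is the
  hallmark of exhaustive small-sample permutation tests: at $n = 4$ the
  smallest possible p is $1/16 > 0.05$, so no effect can ever reach
  significance. An inclusive two-sided counting variant (minimum $2/2^n$)
  is available via `counting = "two_sided"`; the directional convention is
  the default because it is the only one whose attainable minima match the
  granularity expected of exhaustive paired designs at these sample sizes.

A consequence worth knowing: with 7 muscles in the FDR family and $n = 7$,
a *solitary* effect can never survive Benjamini–Hochberg at
$\alpha = 0.05$, because $7/2^7 = 0.055 > 0.05$. Rejections at these sample
sizes require either several co-significant variables (which lower each
other's adjusted values) or a smaller family (`muscles =` argument).

## Key parameters

| parameter | default | unit | notes |
|---|---|---|---|
| marker smoothing cutoff | 20 | Hz | 4th-order Butterworth, zero-phase |
| speed/displacement event thresholds | 10 | % of peak | per repetition window |
| sustained-crossing hold | 0.1 | s | rejects noise blips at the 10% threshold |
| clip threshold | 5 | robust SD | robust SD = 1.4826 × MAD |
| clip replacement window | 20 | ms | median of rectified neighbourhood |
| EMG band-pass | 40–450 | Hz | FIR, ≥3 periods of the low edge, Hamming |
| envelope low-pass | 4 | Hz | 2nd-order Butterworth, zero-phase |
| analysis window padding | 500 | ms | each side of Start–End |
| nodes per cycle | 101 | — | nearest-neighbour resampling |
| `alpha` | 0.05 | — | threshold quantile and FDR level |

Nearest-neighbour time normalization deliberately performs *no
interpolation* (`round` half away from zero for tie-exactness): every
output value occurs in the input, so envelope nonnegativity and amplitude
normalization commute with it exactly.

## The synthetic generator

No public recordings of this kind exist, so validation runs on synthetic
cohorts with known ground truth (`generate_trial()`, `generate_cohort()`).

**Kinematics.** Each repetition is a planar (sagittal) chain — foot, shank,
thigh, trunk — embedded in 3D. Trunk-sagittal, knee and ankle angle curves
are monotone cubic splines (Fritsch–Carlson) through keypoints placed at
the phase boundaries of a 20/30/30/20% preparatory/rising/lowering/final
cycle structure; keypoint values are drawn per subject inside
physiologically typical ranges (peak trunk flexion 20–45°, preparatory
ankle dorsiflexion 5–15°, seated knee ≈ 90°). The hip angle follows from
the chain closure (hip = trunk + knee − ankle), which keeps the whole
marker model kinematically consistent; a small frontal-plane trunk
oscillation (< 10°, zero at the cycle ends) gives the frontal angle
non-trivial content. Duplicated keypoints just inside the cycle ends force
zero entry/exit velocity, so the 10%-speed event rules are well posed.
Repetitions are separated by ≥ 1 s of seated rest, making repetition
splitting and the 500 ms analysis padding well defined. Ground-truth event
times are computed by applying the event definitions to the clean
(pre-noise) trajectories.

**EMG.** Each muscle/side envelope is a sum of Gaussian bursts centred at
30% and 70% of the cycle (amplitudes 1 and 0.45, width 0.07 cycle), matching
the biphasic trunk-muscle activation typical of stand-up-then-sit-down
cycles. The raw signal is that envelope modulating a band-limited
(80–300 Hz) unit-RMS noise carrier — realistic spectral content for the
40–450 Hz band-pass — plus a 5% noise floor and optional artifact spikes.
Side effects are planted either as per-muscle MI amplitude/duration
multipliers or as a localized raised-cosine surplus over a cycle-fraction
window; both are recorded in `$truth` for recovery testing.

**Reproducibility.** All draws flow from one root seed through named
substreams (per subject, per trial, per channel), so any trial can be
regenerated in isolation. A short burn-in after each re-seed avoids the
correlated leading draws that Mersenne–Twister states seeded with nearby
integers can produce.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: ground-reaction forces and true dynamics,
motor-unit physiology, soft-tissue artifact, marker occlusion/gaps,
arm-strategy differences between conditions, electrode crosstalk, and
non-stationary (fatigue-related) EMG spectra. The planar angle computation
is likewise a structural stand-in, not a musculoskeletal model: recovered
curves match the generator's commands to within 2° RMS, but absolute
values on real data would differ from model-based inverse kinematics.

## Numerical choices

* **Zero-phase filtering** everywhere timing matters (events must not be
  lag-biased). The in-package implementation odd-reflects the signal about
  its end points and removes the leading value before the forward–backward
  pass, so start-up transients decay inside the padding; DC is preserved
  to machine precision. The FIR band-pass is instead applied in a single
  pass and re-aligned by its integer group delay, preserving the designed
  (not squared) passband.
* **Sustained crossings.** The 10%-of-peak speed rule is applied to runs of
  at least 100 ms. Threshold rules on speed are fragile at realistic noise:
  with ≈1 mm marker noise the central-difference C7 velocity noise after
  the 20 Hz smoother approaches the 10% threshold of slow movers, which is
  why the generator's default marker noise is 0.2 mm (typical optical
  capture precision) and why events are specified to ±2 samples only on
  noise-free input.
* **Repetition boundaries** sit mid-way through the seated span between
  standing C7 peaks (trochanter height within 10% of its between-peak
  range). The C7 vertical minimum itself is unsuitable: deep trunk flexion
  lowers C7 below its seated height.
* **Commensurate sampling caveat.** A test tone at an exact divisor of the
  sampling rate (100 Hz at 1 kHz) hits only ten phases; its sampled
  rectified mean is 0.6156, not $2/\pi$. Signal-chain checks therefore use
  an incommensurate in-band tone (97 Hz).
* **Problem sizes.** The validation suite runs cohorts of 1–7 subjects
  with 1–5 repetitions; type-I control is estimated from 1000 (test suite)
  and 4000 (acceptance script) null cohorts of envelope-shaped curves,
  enough to resolve the 0.047 exact level against the 0.05 + 2SE bound.
  The planted-surplus recovery magnitude (0.25 relative units over cycle
  fractions 0.5–0.8) was fixed once by a pilot power sweep; recovery
  saturates from ≈0.25 upward.

## Decisions where the conventions were open

* "C7 speed" is the absolute central-difference velocity of the X
  coordinate; a signed reading cannot yield both a Start and an End in a
  full stand-and-sit cycle.
* The trunk vector is C7 minus sacrum — the only two axial-spine markers
  in the set.
* The right side is labelled more-impaired, per the right-hemiparesis
  convention of the target population.
* Envelope amplitude normalization is scoped per participant × muscle ×
  side across *all* conditions and repetitions (switchable to median or
  baseline scopes). Per-side scoping preserves side-vs-side *temporal*
  comparisons while removing electrode-gain differences; absolute
  amplitude comparisons between sides are not meaningful under any
  within-session normalization.
* The lowering/final phase boundary (seat contact) mirrors the Lift-off
  rule: the first post-Stand instant the trochanter is back within 10% of
  its seated baseline.

## Limitations

Exhaustive enumeration is capped at $2^{20}$ assignments; larger cohorts
should switch to the Monte-Carlo mode (`exhaustive = FALSE`, seeded).
Cluster boundaries are reported at node resolution (no sub-node
interpolation). Between-condition statistics are intentionally absent —
the design compares sides within participants; conditions only replicate
the comparison. Marker gap filling and C3D ingestion are out of scope;
trials exchange as plain TSV.
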