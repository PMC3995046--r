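---
title: "ERP processing with erpkit: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ERP processing with erpkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpkit)
```

# What the package computes

An event-related potential is the scalp voltage deflection time-locked to a
stimulus or response, buried in ongoing EEG an order of magnitude larger.
The estimator is the arithmetic mean over repeated epochs, and everything in
this package serves that estimator: deciding which events to average
together, which epochs to discard, how to recombine channels and bins, how
to filter without corrupting the time course, and how to reduce the averaged
waveform to a small number of amplitudes and latencies.

Data live in three containers: `erp_continuous` (channels × samples matrix
of microvolts, with sampling rate, channel labels, an event list, boundary
markers at discontinuities, and a command history), `erp_epochs`
(epochs × channels × samples, with per-epoch bin assignments and artifact
flags), and `erp_set` (bins × channels × samples averages with per-bin
accepted/rejected counts). Onsets are stored in seconds; every user-facing
window is in milliseconds; internally, sample indexing is 0-based and all
windows are half-open `[start, end)`, so sample counts are unambiguous:
an event at `onset` maps to sample `round(onset * srate)`, and an epoch
holds exactly `round((tmax - tmin) * srate / 1000)` samples. These are
package conventions, chosen once, and the text formats round-trip them
losslessly.

# Bin descriptors

A *bin* is the set of time-locking events averaged together. The descriptor
language expresses one bin as a pattern over the event stream: optional
pre-items, a dot, the home item, optional post-items, each item a set of
alternative codes, optionally constrained by a latency window `t<min-max>`
measured from the *immediately preceding* item's matched event (for the
first post-item, from the home event), with inclusive endpoints. Post-items
can capture their latency relative to the home event as a named reaction
time.

Two semantic choices were genuinely open:

* **Adjacency.** Items match strictly consecutive *enabled* events; a
  latency window constrains the latency but never licenses skipping events.
  Both canonical examples are consistent with this reading (the response is
  the next event), and strict adjacency is the only semantics under which a
  brute-force window-enumeration oracle is well defined, which is how the
  matcher is tested. The practical consequence: in a stream where every
  stimulus is followed by its response, "rare preceded by frequent" is
  written `{11;12}{101}.{21;22}{...}` — the previous trial's response is
  part of the context.
* **Re-runs.** `assign_bins()` clears previous assignments first, so it is
  idempotent and reproducible.

The parser accepts the typographic characters that appear in print (en-dash
in latency windows; the equation language likewise accepts U+2212 minus and
U+02C6 circumflex), because descriptor files get copy-pasted from documents.

# Artifact detection

Detectors are tailored to artifact morphology rather than one absolute
threshold: moving-window peak-to-peak (blinks; robust to slow drift),
the step statistic `|mean(second half) − mean(first half)|` over a moving
window — the cross-covariance with a ±1 step template divided by the
half-window length — for saccades, a range-within-tolerance run for
amplifier blocking ("nearly but not perfectly constant" is operationalized
as: some run of at least `min_duration_ms` whose total range stays within
the tolerance), maximum sample-to-sample difference for spikes, and the
classic absolute window. Window positions advance by `step_ms` and always
include a final position flush with the window end, so the epoch edge has
no blind spot.

Flag 1 is reserved as the master artifact flag; each detector additionally
sets a user-chosen flag 2–8, and mirrors both onto the home event in the
event list. Epochs are marked, never deleted; averaging can exclude marked
epochs, ignore the marks, or average *only* the marked epochs (to inspect
what is being thrown away). The rejection report's default subject-exclusion
criterion is a rejection proportion above 0.25 — a preset policy, applied
before looking at condition effects, so post hoc subject exclusion cannot
inflate Type I error.

Continuous-data rejection (for gross artifacts like movement during breaks)
deletes merged supra-threshold spans and inserts a boundary marker at each
splice; epoching skips, rather than truncates, any epoch crossing a
boundary — a discontinuity must never be averaged as if continuous, and a
truncated epoch would silently change the estimator.

# The equation language

Channel and bin recombinations are single-line equations over `chanN` /
`binN` operands with `+ - * / ^`, `sqrt`, `abs`, and `avgchan(ranges)`.
Two evaluation modes exist because two use cases exist:

* `chanK = ...` evaluates sequentially against the working copy — later
  equations see earlier results — which is what you want when building up
  derived channels step by step.
* `newchanK = ...` evaluates against a snapshot taken before the equation
  list runs, and replaces channel K (or appends at K = n+1). This is the
  only semantics under which whole-montage re-referencing is correct: when
  every channel subtracts `avgchan(all)`, each subtraction must see the
  *original* channels, and the result then has exact zero mean across
  channels. The reference assistant emits equations in this form and never
  applies them itself — the re-referencing scheme stays visible and
  editable.

Division by zero is an error rather than ±Inf: microvolt arrays must stay
finite, and every public operation asserts that invariant.

Electrode groups (`bin1@Left + bin2@Right`) pair channels positionally for
contralateral/ipsilateral difference waves. Since all bins of a set share
one channel axis, a call whose equations use groups returns a set whose
channel axis is the first group's channels (existing bins carried subset to
those channels); grouped operands read from the pre-call snapshot. A
derived bin's accepted-trial count is the minimum over its operands — the
most conservative interpretation for downstream weighting.

# Filtering

Filters are specified by the **half-amplitude cutoff of the overall
forward–backward response** and its roll-off. Since zero-phase filtering
applies the kernel twice, the composite amplitude is the squared single-pass
magnitude; for a Butterworth of order n that is
`1/(1 + (f/f_c)^(2n))` (low-pass), which equals ½ exactly at the design
cutoff — so the single-pass design cutoff *is* the composite half-amplitude
point, with no correction factor. Quoted roll-offs name the composite
asymptotic slope, hence 12/24/36/48 dB/octave map to orders 1–4 (12n
dB/octave two-pass). The half-power equivalent is
`f_c·(√2−1)^(1/2n)` (low-pass; divide for high-pass) — reported so users
can state unambiguously which cutoff convention a paper quotes.

Implementation: coefficients from the bilinear-transform Butterworth design
(`signal::butter`, prewarped); band-pass as a high-pass/low-pass cascade;
application is forward–backward with odd-reflection padding of 3× the
coefficient length and steady-state initial conditions scaled to the first
padded sample (the standard construction that leaves a constant input with
no transient at all). The compiled direct-form-II-transposed inner loop
lives in `src/iir.cpp`. Frequency responses of Butterworth designs are
evaluated from the exact closed-form digital magnitude
`x = tan(πf/fs)/tan(πf_c/fs)` rather than from the coefficient polynomials,
which stays numerically exact at cutoffs as low as 0.01 Hz at 1000 Hz
sampling, where polynomial evaluation loses all precision. FIR designs are
windowed-sinc/Hamming with the design cutoff found by bisection so the
*composite* response is half-amplitude at the request.

Two options matter for DC-coupled recordings: `remove_dc` subtracts each
filtered segment's mean first (a 200 µV offset otherwise meets the implicit
zero outside the data and rings); `per_block` splits at boundary markers
and filters blocks independently. A 200 µV offset step at a block gap,
band-passed 0.01–20 Hz as one piece, produces an artifact exceeding 1 µV
for tens of seconds on both sides of the gap (time constant ≈ 1/(2π·0.01 Hz)
≈ 16 s); filtered per block, the residual at the boundary is below 1 µV.
The tests reproduce exactly this contrast at 250 Hz with two 60 s blocks.

# Measurement

All algorithms operate on the stored waveform (baseline correction is an
upstream, explicit step) over samples whose times lie in `[start, end)`.

* **Mean amplitude** — the linear, noise-unbiased workhorse.
* **Area** — `Δt · Σ f(x)` with `f` restricting to the positive region, the
  negative region (returned as a positive magnitude; the signed quantity is
  the `integral` mode, and positive − negative ≡ integral holds to 1e−9),
  the rectified sum, or the signed integral. Restricting polarity lets a
  broad window capture a component without opposite-polarity neighbors
  canceling it: in the synthetic N2-between-P2-and-P3 test, widening the
  window by ±50 ms changes negative-mode area by under 5% while changing
  the signed integral by more than 20%.
* **Peaks** — extreme sample in the window; with `local_points = k`, a peak
  must also exceed the mean of its k neighbors on each side (neighbors may
  leave the window but not the epoch), preventing a clipped rising edge
  from posing as a peak. If nothing qualifies, the absolute extreme is
  returned with a warning rather than an error — a measurement table with a
  flagged fallback is more useful than a hole. Ties break earliest, for
  determinism.
* **Fractional-area latency** — cumulative area across the window, linearly
  interpolated inside the straddling sample; at 50% it is the area
  midpoint, directly comparable to a median RT; at 20% an onset estimator.
* **Fractional-peak latency** — backward scan from the peak to the first
  sample at or below `fraction·peak`, linearly interpolated; misses (the
  criterion never met before the epoch start) return `NA` with a warning.
  When an interpolation factor is given, the waveform is spline-upsampled
  *first* and the scan runs on the interpolated waveform, so the crossing
  and the peak come from the same curve.

Spline upsampling (`stats::spline`, which reproduces the original samples
exactly) mitigates sampling-grid quantization — worth its cost chiefly for
jackknifed measurements, where other error sources are already tiny.
Jackknife support: N leave-one-out grand averages (mean equal to the full
grand average by linearity) and the `statistic/(N−1)` rescaling for
t-family statistics computed across them. Grand averages weight subjects
equally by default; weighting by accepted-trial counts is opt-in, since
equal subject weighting is the conventional estimator.

# The synthetic oddball session

The generator emulates the running example the rest of the package is
tested against: frequent standards (codes 11/12) and rare oddballs (21/22,
p = 0.2), each followed by response code 101 after a truncated-normal RT
(mean 450, SD 120, bounds 200–1000 ms); SOA 1500 ± 200 ms; two trial blocks
with boundary markers and DC offsets (0/50 µV by default); Gaussian
stimulus-locked components with per-channel topographies — by default a
small P1/N1 complex and a P3 at 450 ms (σ = 60 ms) of 10 µV at Pz for rare
vs 2 µV for frequent stimuli, i.e. a designed 8 µV effect; AR(1) noise
(φ = 0.95, marginal SD 5 µV — roughly the temporal smoothness and amplitude
of resting EEG at 500 Hz) plus a 2 µV 10 Hz alpha sinusoid; raised-cosine
250 ms blinks at 4/min on VEOG (200 µV, scaled frontal leakage), step-like
saccade excursions on HEOG, and short "blocking" segments held nearly
constant. Events are snapped to the sample grid, as acquisition hardware
does, which also makes the noise-free recording *identical* to the analytic
component model returned by `expected_erp()` (both use one shared
truncated-Gaussian construction with integer-sample support).

These defaults are the study conditions for the end-to-end tests: 400
trials, 5 µV noise. The acceptance-level recovery test asserts the designed
8 µV effect within ±1 µV (peak at Pz), the 450 ms latency within ±20 ms
(50% fractional-area), and blink flagging with ≥95% recall / ≤5% false
alarms against the generator's contamination labels (a trial is labeled
contaminated when a blink peak falls inside its epoch window). A secondary
consistency check compares the measured mean amplitude of the difference
wave against the same measurement applied to `expected_erp()`; its
tolerance is set at 3 standard deviations of that estimator's own sampling
noise (≈0.6 µV given the AR(1) parameters, baseline correction, and ~60
rare trials), i.e. 2 µV.

What the simulator deliberately does *not* model: realistic 1/f spectra,
volume-conduction topographies from a head model, latency jitter across
trials, or overlapping-component deconvolution. Passing tests therefore
demonstrate the correctness of the *processing* — sorting, flagging,
averaging, filtering, measuring — not the physiological fidelity of any
waveform.

# Problem sizes and shape of the test suite

The suite runs the matcher-equivalence property on 1,000 random streams of
up to 40 events with random two-sided descriptors, the permutation-null
property on 500 seeded permutations of 40 epochs, the full recovery
pipeline on one 400-trial session (about 10 minutes of simulated EEG at
500 Hz), and the block-gap filtering contrast on two 60 s blocks at 250 Hz
— sizes chosen so the entire suite completes in well under a minute on one
core while leaving each property enough room to fail informatively. The
package is organized as S3 classes over numeric arrays (the natural shape
for multichannel time series) with tibbles for every genuinely tabular
result — RT tables, rejection reports, measurement tables, `as_tibble()`
long-format views — and ggplot2 `plot_waveforms()`/`autoplot()` for
figures.

# Known limitations

ICA-based artifact *correction* is out of scope (rejection only); no
proprietary vendor formats (the plain-text EVENTLIST and ERP interchange
formats, plus programmatic construction, are the boundary); no notch or
causal/online filtering; boundary-crossing epochs are always skipped, never
truncated; the descriptor language implements the documented grammar only
(no wildcards or flag predicates); and the equation language evaluates on
one object at a time — cross-subject algebra goes through `grand_average()`
and `jackknife_set()`.
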