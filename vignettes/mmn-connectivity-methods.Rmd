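---
title: "Methods: gamma-band phase-lag networks for the auditory MMN"
author: "mmnnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gamma-band phase-lag networks for the auditory MMN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmnnet)
```

## The scientific question and the analysis model

The auditory mismatch negativity (MMN) is the negative difference wave
obtained by subtracting the averaged response to frequent *standard* tones
from the response to rare *deviant* tones in an oddball paradigm; it peaks
around 100--200 ms after the tone over fronto-central scalp.  Under the
global-workspace view, the cognitively more demanding deviant should
transiently recruit *long-distance* synchronization among remote cortical
areas, and an anesthetic that suppresses higher-order processing should
abolish that recruitment while leaving low-level auditory responses largely
intact.  The package operationalizes this as a contrast of network
statistics between stimulus conditions (standard vs deviant) and
consciousness states (awake vs anesthesia).

The chain is:

1. **Preprocessing.** Band-pass 0.5--40 Hz (zero-phase), epochs from 100 ms
   before to 700 ms after tone onset, baseline correction on the first
   100 ms, automated peak-to-peak artifact rejection (default 100 uV), and
   selection of deviants preceded by at least three consecutive standards.
   The MMN wave is the deviant-minus-standard average; its most negative
   point at Fz inside 100--250 ms defines a subject-specific 100 ms
   analysis window, `[peak - 50, peak + 50)` ms.  The window detected in
   the awake state is applied **verbatim** to the anesthesia recordings of
   the same subject (anesthetics attenuate ERP amplitude but not latency,
   and no MMN is detectable under deep sedation to center a window on).
2. **Source space.** A weighted minimum-norm estimate
   `K = W L' (L W L' + lambda I)^-1` with depth weights
   `W = diag(||l_j||^(-2 gamma))`, `gamma = 0.5`, projects sensor epochs
   onto cortical sources; sources are averaged within each of the 148
   Destrieux-scheme ROIs.  The leadfield `L` is an input, never computed.
3. **Connectivity.** Signals are gamma-band filtered (30--40 Hz; long-range
   integration effects concentrate in this band), instantaneous phases are
   taken from the FFT analytic signal, and every ROI pair's weighted phase
   lag index (wPLI) is computed over the analysis window.
4. **Network.** The 148 x 148 matrix is thresholded to a target edge
   density; edges within one of 14 coarse areas (ventral/dorsal prefrontal,
   central, temporal, parietal, occipital, cingulate, per hemisphere) are
   *short-distance*, edges between areas *long-distance*.  Per area `k`,
   `S_k` and `L_k` sum the kept weights; `L_all = sum(L_k)`,
   `S_all = sum(S_k)`, `Ratio = L_all / S_all`.
5. **Statistics.** Paired two-sided t-tests across subjects, alpha 0.05,
   uncorrected by default (14 per-area tests mirror the original design;
   Benjamini--Hochberg is available behind a flag).

## The wPLI estimator

With `d(t, s)` the phase difference of a pair at trial `t`, sample `s`, the
package's default estimator pools all observations of the window:

$$\mathrm{wPLI} = \frac{\left|\sum_{t,s} \sin d(t,s)\right|}
                       {\sum_{t,s} |\sin d(t,s)|} \in [0, 1].$$

This is the magnitude-weighted average *sign* of the phase difference: it
is exactly 1 when one signal consistently leads (or lags) the other by any
nonzero phase, tends to 0 when the phase difference is completely random
across trials, and gives zero weight to exact zero-lag differences -- the
signature of volume conduction, which is why the index is preferred for
EEG source connectivity.  A within-trial variant (the same ratio per trial,
averaged across trials; `method = "trial"`) is provided, but note that it
cannot detect cross-trial phase randomness when the lag is constant within
trials, which is precisely the regime the oddball design creates; the
pooled form is therefore the default and the one whose boundary behavior
(1 for constant lag, ~0 for random lags) the acceptance checks exercise.
A trial whose window has all `sin d = 0` (pure zero lag) contributes zero,
so the degenerate 0/0 case is defined as 0 -- zero-lag coupling is exactly
what the index is built to discount.

Two numerical choices matter.  The analytic signal is computed on the
*full* epoch and then cropped to the 100 ms window, so the window itself is
free of Hilbert edge artifacts.  And because the estimator's small-sample
positive bias scales like `1/sqrt(n_trials)`, all condition and state
contrasts are computed at **equal trial counts**: each valid deviant is
paired with the standard immediately preceding it, and counts are equalized
across the four subject cells (capped at 28 by default).  Without this,
trial-count differences masquerade as connectivity differences and the
paired null is no longer exchangeable.

## Density thresholding

Network integrity requires an average degree above `2 ln N`, i.e. a
density floor `2 ln(N)/(N - 1)` -- about 0.068 for `N = 148`, displayed by
convention as the truncated integer percent "6%" (truncation, not
rounding, reproduces the conventional figure).  Metrics are computed over
a density sweep from 6% to 90% in 1% steps and summarized as the grid
mean; both the per-density table and the summary are returned, since no
single canonical density exists.  Ties at the threshold break
lexicographically on the ROI index pair, making every run deterministic.
Two structural identities document the bookkeeping: every inter-area edge
contributes to *both* endpoint areas' `L_k` (so `L_all` counts each such
edge twice), and at every density
`S_all + L_all / 2 = total kept weight`.  When a thresholded graph has no
intra-area edge, `Ratio` is undefined and reported as `NA` with a warning,
never as infinity.

## What the synthetic generator emulates

No public recordings accompany this analysis, so the package ships a
first-class simulator of the study conditions:

* **Stimuli.** Blocks of 300 randomly ordered tones -- 200 standards
  (500 Hz) and 50 + 50 deviants (450/550 Hz) -- of 75 ms with a 1000 ms
  inter-stimulus interval.  The ISI is interpreted offset-to-onset
  (onset asynchrony 1075 ms), the standard ERP convention.  Tone acoustics
  are not synthesized; only the event labels matter downstream, and the
  two deviant pitches are pooled into one deviant condition (labels are
  retained).
* **ROI signals.** Per trial, every ROI carries a gamma-band cosine with an
  independent uniform starting phase plus white noise (`noise_sd = 0.5` on
  a unit-amplitude carrier -- a moderate single-trial SNR).  The trial's
  carrier frequency is drawn from the DFT-resolved frequencies inside
  30--40 Hz and shared by all ROIs, so within-trial phase relations are
  exactly constant and the analytic signal of a noise-free trial is exact
  to machine precision.
* **Couplings.** A coupled pair locks the follower's phase to
  driver + lag + wrapped-normal jitter with standard deviation
  `(1 - strength) * pi`, constant within a trial.  Strength 1 is a perfect
  constant lag (wPLI 1); strength 0 is indistinguishable from independence.
  This jitter parameterization was chosen over a lock-probability mixture
  because attenuated couplings then decay to near-baseline wPLI instead of
  leaving a residual proportional to the attenuation -- under the default
  anesthesia attenuation of 0.3 a strength-0.95 coupling falls below the
  small-sample noise floor, which is what "abolished" should mean.
* **Cohort ground truth.** The default coupling scheme has a
  condition-independent backbone (one intra-area and one homotopic pair
  per area, strength 0.7) and a deviant-only "ignition" tier: hub ROIs in
  the bilateral prefrontal, central, temporal and parietal areas drive 76
  distinct followers across the MMN network at strength 0.95.  The tier
  size follows a design-stage power analysis: with 12 subjects and ~25
  trials per condition, the deviant effect on the grid-mean Ratio must be
  on the order of one between-subject standard deviation to be reliably
  detected against the estimation noise of 10878 ROI pairs, which a
  sparse effect of a few tens of couplings cannot achieve.  Emulating the
  workspace account, ignition is brain-wide rather than a single pair.
* **Sensor recordings.** For end-to-end tests of the preprocessing and
  inverse stages, a continuous recording is built as
  `leadfield x white-noise sources + evoked components + sensor noise`.
  Evoked components are Gaussian bumps with a fronto-central scalp
  weighting: every tone receives an N1-like -2 uV component at 100 ms;
  deviants in the awake state additionally receive a -3 uV component at
  160 ms, so the difference wave shows an MMN-like trough there.  In the
  anesthesia state no deviant component is injected and coupling strengths
  are attenuated.  The leadfield itself is a random matrix with controlled
  condition number -- a test fixture, not a head model.

All randomness flows from one seed through labeled substreams
(`derive_seed`), so any stage can be rerun in isolation and every output
is bit-reproducible; the random stream is deliberately independent of the
state label, making "attenuation 1" produce bit-identical awake and
anesthesia signals.

What passing tests on this generator do *not* show: real EEG has 1/f
background, non-stationary coupling, correlated sensor noise, volume
conduction with realistic leadfields, eye/muscle artifacts, and
between-subject anatomical variability.  The simulator demonstrates that
the pipeline recovers known ground truth under its stated assumptions, not
that those assumptions hold for any particular recording.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| broadband band | 0.5--40 | Hz | drift and line-noise removal before ERP analysis |
| gamma band | 30--40 | Hz | the band carrying long-range integration effects |
| epoch window | [-100, 700) | ms | covers baseline and the full ERP |
| baseline | [-100, 0) | ms | pre-stimulus mean removal |
| rejection threshold | 100 | uV peak-to-peak | automated stand-in for manual cleaning |
| preceding standards | 3 | tones | guards deviants against deviant-wake effects |
| peak search window | 100--250 | ms | brackets the expected MMN latency |
| MMN presence criterion | trough <= -0.5 uV and negative window mean | uV | the original exclusion rule is unstated; this one is explicit and configurable |
| depth weighting gamma | 0.5 | -- | conventional wMNE depth compensation |
| lambda | trace(L W L')/(sensors * SNR^2), SNR 3 | -- | standard discrepancy-based default |
| density grid | 6--90% by 1% | -- | from the 2 ln N floor to near-complete graphs |
| alpha | 0.05 | -- | uncorrected, mirroring the original design |

## Filter realization

Band-pass filtering uses a Hamming windowed-sinc FIR (designed with the
`signal` package), transition width 25% of the lower band edge, applied by
FFT convolution with reflection padding and exact group-delay
compensation.  A symmetric FIR applied this way is zero-phase -- the
property that matters for phase metrics -- while staying `O(n log n)`, so
the very long kernel demanded by the 0.5 Hz edge remains affordable on
continuous recordings.  Kernel length is capped below the signal length;
edge intervals of half a kernel length carry transients, which is one
reason phases are never read near epoch edges.

## Degenerate inputs and tie-breaks

* all-zero signal in a trial/ROI: phase undefined, error naming the trial
  and ROI;
* equal MMN minima: earliest latency wins;
* equal weights at a density threshold: lexicographic (i, j) order;
* `S_all = 0`: Ratio `NA` plus warning;
* zero-variance paired differences, unequal or incomplete subject sets:
  errors, never silent repair;
* mixing outputs of different configurations in the stats stage: refused
  via the config hash embedded in every output file.

## Problem sizes used by the shipped simulations

Cohort simulations run on directly simulated ROI epochs of [-100, 260) ms
(the analysis window plus generous analytic-signal context) with up to 28
trials per condition -- the yield of one 300-tone block after deviant
validation.  The parameter-recovery study uses 20 replicates of 12-subject
cohorts on the full 148-ROI atlas; the type-I-error study uses 200
replicates on a reduced 56-ROI/14-area parcellation with 12 trials per
condition, since the test's size is a property of the statistics stage and
does not depend on network scale.  The sensor-route demonstration uses
shortened blocks (40 tones) with 16 sensors and 148 sources.  These sizes
are the package's choices for routine verification; every stage accepts
full-scale inputs.

## Known limitations

* The 14-area assignment of Destrieux regions is a keyword-based default
  shipped as an editable CSV; no canonical table exists.
* The wMNE stage assumes identity noise covariance and fixed-orientation
  sources; `lambda` is a simple SNR-based default.
* "Number of connections" is everywhere the *summed wPLI weight* of the
  edge class, not an edge count -- consistent with the weighted definition
  of the statistics (and with their non-integer values).
* The per-trial wPLI variant is provided for completeness but is blind to
  constant-lag cross-trial randomness (see above); results from the two
  variants are not comparable.
* EDF and HDF5 interop are out of scope in this environment; raw
  recordings and array containers use the package's documented text/JSON
  formats instead.

## A worked micro-example

```{r example}
cfg <- sim_config(
  tones_per_block = 60, n_standard = 40, n_deviant_low = 10,
  n_deviant_high = 10, n_rois = 8, epoch_window_ms = c(-100, 300),
  coupling_spec = data.frame(roi_i = 1, roi_j = 5, phase_lag = pi / 4,
                             strength = 0.95, condition = "deviant"),
  seed = 7)
ev <- generate_event_sequence(cfg)
rs <- simulate_roi_signals(cfg, ev)
w_dev <- connectivity_matrix(subset_trials(rs, rs$condition == "deviant"),
                             c(110, 210))
w_std <- connectivity_matrix(subset_trials(rs, rs$condition == "standard"),
                             c(110, 210))
round(c(deviant = w_dev$w[1, 5], standard = w_std$w[1, 5]), 3)
```

The deviant-only coupling between ROIs 1 and 5 appears in the deviant
trials' matrix and stays at the small-sample noise floor in the standard
trials -- the elementary contrast the full pipeline aggregates into the
Ratio tables.
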