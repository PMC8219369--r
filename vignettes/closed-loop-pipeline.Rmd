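---
title: "Models and methods behind szloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind szloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(szloop)
```

# Scope

`szloop` implements the computational core of a closed-loop optogenetics
workflow for chronic epilepsy models: online electrographic seizure
detection from hippocampal local field potentials (LFP), randomized
closed-loop stimulation, quantification of stimulation-locked oscillatory
entrainment, and the endpoint statistics on seizure-duration distributions.
Because no in-vivo recordings ship with the package, a seeded synthetic LFP
generator provides inputs with known ground truth; every claim the test
suite makes is therefore a claim about recovery of *generator* truth, not
about animals.

# The synthetic LFP generator

## Background model

Background LFP is the sum of two unit-variance processes scaled to a total
standard deviation `sd` (default 100 µV):

* **Broadband noise** with power-law spectrum \(S(f) \propto f^{-\alpha}\)
  (default \(\alpha = 2\)), produced by frequency-domain shaping of white
  Gaussian noise. \(\alpha = 2\) approximates the steep high-frequency
  roll-off of hippocampal LFP; it also keeps the per-sample step size small,
  which matters because the coastline feature integrates exactly those
  steps.
* **A theta oscillation** (default 7 Hz) carrying a fraction `theta_power`
  (default 0.3) of the variance. Its phase diffuses as a Wiener process with
  a Lorentzian linewidth `theta_linewidth` (default 0.5 Hz), so theta is
  phase-coherent over roughly `1/linewidth` seconds only. This matters: a
  phase-stable sinusoid would be spuriously coherent **across** stimulation
  trials spaced 120 s apart (120 s times any integer-valued frequency is a
  whole number of cycles), inflating baseline phase-locking values and
  masking weak locking. Real theta dephases in seconds; the generator must
  too.

## Stimulation-locked component

The entrainment sessions follow the standard protocol: 120 epochs of 10-ms
square pulses at 10 Hz for 30 s, with 90 s between epochs (labs run this
protocol with anywhere from 90 s to 2 min between epochs; all such variants
are expressible, 90 s is the default). During each epoch the LFP receives an
extra sinusoid
at the pulse rate whose phase lag to the LED fundamental is drawn once per
epoch from a von Mises law with concentration \(\kappa\)
(`locking_strength`), constant within the epoch — matching the trial-wise
structure of the phase-locking statistic, which measures clustering of the
lag *across* trials.

The component's amplitude is coupled to the locking strength as
\(A(\kappa) = A_{\max}\, r(\kappa)\) with
\(r(\kappa) = I_1(\kappa)/I_0(\kappa)\), the mean resultant length of the
von Mises law. Two considerations force this coupling:

1. \(\kappa = 0\) must be a true null for **both** statistics. An unlocked
   component of fixed amplitude would leave the phase-locking value at its
   chance level but would still inflate the entrainment power ratio, which
   is phase-blind.
2. Physically, locking strength and entrained power co-vary: a weak
   opsin-mediated drive entrains little power *and* locks phase poorly. A
   single drive-strength axis, mapped through \(r(\kappa)\), reproduces
   that covariation, and makes both the baseline-subtracted PLV and the
   entrainment efficiency strictly increasing in \(\kappa\) — the pattern
   an opsin-vs-control contrast shows.

\(A_{\max}\) defaults to `locked_rel_amp = 2` background SDs, a strong but
not saturating drive: the fully locked condition reaches a
baseline-subtracted PLV near 0.75 rather than 1, because broadband
background still jitters the instantaneous phase, as it does in vivo.

## Seizures

Electrographic seizures are trains of alternating-sign biphasic
raised-cosine spikes (25 ms per lobe, small timing jitter) at `spike_rate`
(default 8 Hz), with peak amplitude `spike_amplitude` (default 5) background
SDs and 1-s linear on/off ramps. Discrete large deflections — rather than,
say, filtered noise — are what drive all four detector features the way real
discharges do: spikiness and coherence specifically reward isolated
large-amplitude deflections.

Event onsets form a Poisson process (default 20 events/hour, a realistic
rate for the frequent short electrographic discharges of intrahippocampal
kainate epilepsy); durations are log-normal (median 30 s, log-sd 0.4),
heavy-tailed as in chronic models; overlapping draws are merged. The
duration median must exceed 3 s so that events can span the three
consecutive detector intervals required for a timestamp.

The generator does **not** model: biophysical network dynamics, behavioural
(video) correlates, electrode artefacts, state-dependent seizure
probability, or hippocampal-sclerosis anatomy. Passing tests therefore show
that the analysis code recovers known structure from signals with the right
first- and second-order statistics — not that the detector would perform
identically on any particular animal.

# The online detector

Each non-overlapping 1-s interval yields four features:

* **coastline** — the sum of absolute sample-to-sample changes (µV);
* **intermittency** — the fraction of the coastline contributed by the
  largest `ceiling(0.10 × n_steps)` steps (`ceiling` guarantees at least one
  step counts);
* **spikiness** — the maximum voltage range over 19.6-ms bins divided by the
  median bin range; bins are `floor(0.0196 × fs)` samples (10 at 512 Hz),
  the trailing remainder dropped, which is deterministic at any sampling
  rate;
* **coherence** — the fraction of the voltage area under the curve (sum of
  absolute mean-referenced voltages) occupied by the 10 largest peak–trough
  pairs. The mean-centred interval is segmented at its local extrema
  (endpoints included); adjacent extrema form disjoint pairs, each owning
  the samples up to the next pair's first extremum — one full deflection
  cycle — and pairs are ranked by the voltage difference between their
  extrema. Worked limits: a pure sine with at most 10 full cycles in the
  interval scores ≈ 1, a 60-cycle sine ≈ 10/60, a monotone ramp exactly 1.
  Mean-referencing makes the metric offset-invariant; it, the pair span, and
  the treatment of endpoint extrema are the package's own resolutions of an
  under-specified verbal definition.

Degenerate inputs (flat intervals) return flagged neutral values (0 for
intermittency and coherence, 1 for spikiness) instead of errors, since a
streaming detector must survive amplifier dropouts.

Raw features pass through per-feature logistic maps
\(x \mapsto 1/(1+e^{-(x-c)/s})\). Deployed detectors of this family carry
hand-tuned sigmoid constants in their firmware configuration; the package
instead fits them from data:
\(c\) is the midpoint of the baseline and seizure medians and \(s\) is half
the mean of the two interquartile ranges — chosen so baseline intervals map
mostly below 0.5 and seizure intervals mostly above, while staying strictly
inside (0, 1). The calibration is persisted with the library.

A bounded vector is seizure-positive when some library entry lies within the
similarity threshold (0.1) on **every** metric simultaneously — a per-metric
Chebyshev rule, boundary inclusive, reading "similarity across all metrics"
as a conjunction. Three consecutive positive intervals produce a timestamp;
the event onset is the start of the run, and the offline offset extends to
the last positive interval before a gap of more than
`gap_tolerance_intervals` (default 2) negatives. The gap rule is an
automated surrogate for the offline expert review that usually assigns
seizure durations in this kind of experiment.

# The closed-loop controller

On every timestamp the controller consumes one draw from a Bernoulli(0.5)
stream seeded in the configuration, so assignment is reproducible and
independent of wall-clock. A positive draw emits a 30-s train of 10-ms/10-Hz
pulses. Trains never overlap: the refractory period defaults to the train
length, and a draw landing inside it is consumed but not acted on (the
source system's re-trigger behaviour is undocumented; this is the package's
documented choice). Decisions are strictly causal — each feature depends
only on its own interval and the decision state only on past intervals — and
the test suite verifies that truncating the stream never changes earlier
decisions.

The stimulated-seizure effect used in end-to-end simulations truncates the
remaining duration after train onset by a multiplier (0.6 in the demo),
leaving unstimulated seizures untouched; multiplier 1 is an exact null.

# Entrainment quantification

Phase is the angle of the FFT-constructed analytic signal of the
mean-removed trace, computed on the **whole** recording and then sliced into
30-s trials (computing it per-window would put transform edge artefacts
inside every trial). The per-timepoint phase-locking value is the modulus of
the trial-averaged unit phasor of the LED−LFP phase difference; its
time-average over the stimulation epochs, minus the same quantity over the
immediately preceding 30-s baselines, is the summary statistic. For
independent phases the expected PLV is the Rayleigh mean
\(\sqrt{\pi}/(2\sqrt{n_{\text{trials}}})\) ≈ 0.081 at 120 trials, the
package's calibration anchor.

Spectra are rectangular-window periodograms of mean-removed 30-s segments
with density scaling, so summed power times the bin width equals the
variance (Parseval; verified to 1e-9 in tests). The entrainment ratio is
cumulative power within ±1 Hz of the 10 Hz stimulation frequency divided by
cumulative power in 3–13 Hz, endpoints inclusive, bins assigned by centre
frequency; the efficiency is the median over epochs of the paired
stimulation-minus-baseline ratio difference. A flat spectrum gives the
bandwidth fraction ≈ 0.2, a second calibration anchor.

# Endpoint statistics

Per animal, stimulated and unstimulated duration distributions are compared
with a two-sample two-sided Kolmogorov–Smirnov test; per-animal medians
across a cohort with a paired two-sided Wilcoxon signed-rank test (exact for
up to 25 informative pairs — small-n fidelity matters at n = 7, where the
two-sided exact rejection region at α = 0.05 has probability 6/128 ≈ 0.047 —
normal approximation with continuity correction above); normalized changes
\((\mathrm{med}_{on}-\mathrm{med}_{off})/\mathrm{med}_{off}\) between
cohorts with a two-sample t-test (Welch form by default, safer at 7 vs 4
animals; the pooled form is a flag); the interval following each seizure is
assigned to that seizure's condition and per-animal median interseizure
intervals are compared with the paired Wilcoxon; per-animal median Racine
scores with a paired t-test. Degenerate cases (all-zero differences) report
p = 1 rather than erroring, and all tests are two-sided and
order-invariant.

# Problem sizes and numerical choices

Simulation sizes used by the shipped tests are the package's own desk-scale
choices: entrainment sessions of 40 epochs with 8 replicates per
locking-strength level; detector evaluation on three 1-h recordings against
a library built from a separate 30-min cohort recording; the two-cohort demo
(`run_demo`) with 7 opsin and 4 control animals at 5 h each (≈ 100 seizures
per animal — the source animals contributed 37–196); type-I calibration with
1000 replicates at the statistics level, since under a multiplier of 1 the
endpoint tests see only durations and assignment flags.

Other numerical choices: seeds split deterministically from one master seed
per component (background, event times, lags, controller draws) via a
Lehmer-style map, so any sub-stream is reproducible in isolation;
von Mises sampling by Best–Fisher rejection; the LED fundamental's constant
phase offset at epoch onset is irrelevant because the PLV is invariant to
constant offsets; intervals are aligned to the recording start and
non-overlapping.

# Known limitations

* Detector durations quantize to 1-s intervals and extend through short
  gaps, so very fragmented seizures read as single events.
* The library-matching rule is as good as the library: a library built from
  low-amplitude seizures generalizes poorly to morphologies the generator
  never produced. Tests cover the generator's morphology only.
* The entrainment statistics assume the LED channel carries a clean pulse
  train; a noisy or clipped LED channel will distort the reference phase.
* The severity model is a plausibility device (longer seizures tend to score
  higher on the six-point Racine scale) for exercising the severity test,
  not a behavioural model.
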