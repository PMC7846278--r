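---
title: "Models and methods behind spontnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spontnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spontnet)
```

spontnet analyzes spontaneous network activity in the developing sensory
cortex and models its modulation by a neuropeptide that depolarizes
somatostatin-positive (SST⁺) interneurons. The package covers four stages —
wide-field event detection, two-photon population correlations, patch-clamp
feature extraction, and a recurrent spiking-network model — plus seeded
synthetic-data generators that stand in for raw recordings. This vignette
explains the models, the defaults, and the reasoning behind choices the
underlying procedures leave open.

## Wide-field network events

A raw movie is converted to ΔF/F0 with a per-pixel moving-average baseline
over 500 frames (25 s at 20 Hz). The window is *centered* and truncated
symmetrically at the movie edges: a trailing window would bias F0 upward
right after an event and systematically clip onsets. Network events are
defined on the thresholded stack (pixels below 12% ΔF/F0 zeroed) as
connected components of at least 300 voxels in `(t, y, x)`. "Connected in
time and/or space" is implemented as 26-connectivity — the 3D default of the
common image-processing toolchains — with 6-connectivity selectable; the two
only differ for diagonal contacts, which are rare for blob-shaped events.
Detected counts are insensitive to the minimum size over roughly 200–800
voxels for events of realistic extent, which is the robustness check the
detection criterion is designed to satisfy.

Because wide-field optics scatter light, the suprathreshold footprint
overstates the activated area; the reported restricted area keeps only
pixels reaching 67% of the event's peak ΔF/F0. The per-pixel area for a
7.68-µm pixel is 58.9824 µm²; the `"rounded"` mode reports 59 µm² so
worked examples match the printed integer bit-exactly, and an `"exact"` mode
is available. Event amplitude is the maximum ΔF/F0 over the event's voxels
(no formula is standard; the maximum is robust for unimodal events), and
events are assigned to a region when the majority of their restricted
footprint lies inside the region mask.

One quantitative consequence of the moving-average baseline is worth noting:
an event contributes to its own F0, so the recovered peak of a noiseless
synthetic event with a 1-s decay is ≈5% below the injected peak
(`(1 + 0.30) / (1 + f) − 1` with `f ≈ 1.2%` the event's share of the
500-frame window). The tests pin the conversion to a brute-force
moving-average oracle rather than to the nominal injected value.

For awake recordings only 1D traces are analyzed: a 4th-order zero-phase
Butterworth low-pass (default cutoff 2 Hz, well below the 10-Hz Nyquist at
20 Hz) removes movement artifacts, then local maxima are kept by topographic
prominence and height. The prominence/height values are deliberately
required arguments: they are tuned per dataset on the baseline epoch and
must then stay fixed within a recording.

## Two-photon population analysis

Pairwise Pearson correlations are computed on the continuous ΔF/F0 traces
(not on binarized event rasters) in sliding 7-min windows; the window step
defaults to 60 s, a choice that trades temporal resolution against the
number of effectively independent windows. All `N(N−1)/2` unordered pairs
enter; a cell with zero variance inside a window drops its pairs from that
window's mean, with the count recorded. Windows straddling the application
time are labeled `"boundary"` and excluded from epoch summaries, so baseline
and post estimates never share frames.

Event detection per ROI uses a threshold of 2× the noise SD, where the noise
SD is estimated robustly as `1.4826 · MAD(diff(x)) / sqrt(2)`: first
differences suppress the slow transients and the MAD ignores the sparse
large excursions they leave, approximating the SD "in the absence of events"
without manual annotation. A plain 2σ crossing rule would fire constantly on
Gaussian noise, so an onset must stay suprathreshold for 3 consecutive
frames (600 ms at 5 Hz, far shorter than a calcium transient), detection
runs on a 3-frame boxcar-smoothed copy, and hysteresis requires the trace to
fall below half the threshold before re-arming. Transients closer than the
decay-to-re-arm time (≈5 s at the default kinetics) merge; the tests compare
against ground truth collapsed at that resolution limit.

The distance analysis summarizes each pair by its epoch-average correlation,
the difference `post − baseline`, and the percent change for pairs with
`|baseline| ≥ 0.01` (smaller baselines make percent change numerically
meaningless; excluded pairs are counted). It reports OLS fits of both delta
and percent change against interneuronal distance and the per-dataset
Pearson correlation between distance and percent change.

`classify_modulation()` contrasts two one-parameter models: a shift
`post = base − c` and a scaling `post = a·base`, both by least squares, with
the label decided by AIC (equivalent to comparing residual sums of squares
here); `"mixed"` is returned when |ΔAIC| < 2 and `"indeterminate"` when the
baseline correlations are all equal. A subtractive change on a
distance-decaying baseline profile automatically makes the *percent* change
largest for distal pairs, which is the geometry the distance analysis is
designed to exhibit.

The correlation-matrix distance statistic is
`MSD(t) = Σ_ij (c_ij(t) − c_ij^BL)²`, with `c^BL` computed over the full
45-min baseline span. The sum runs over all `N²` entries (the diagonal
contributes zero); summing unordered pairs differs by an exact factor of 2
and is selectable — it is immaterial after normalization. The raw series is
detrended by an OLS line fitted on the baseline windows and extrapolated to
all time points (removing slow drift that predates the application), then
z-scored by the mean and SD of the detrended baseline. Two estimator
properties matter for interpretation: baseline windows overlap the span that
defines `c^BL`, so their raw MSD is slightly depressed relative to post
windows even for stationary data (small for a 7-min window inside a 45-min
baseline); and the z-scale inherits the noise of the baseline SD estimated
from ~40 overlapping windows. Both are shared by any analysis of this form
and are why the sustained-elevation signature is evaluated against a
3-baseline-SD bar rather than a parametric null.

Across-animal dispersion offers both `σ̂/√N` (standard SEM, the default) and
`σ̂/N`; the latter convention appears in some reports and is provided for
comparability, but nothing in the package asserts one over the other.

## Synthetic ROI populations

The generator's contract is stated in correlation space: cells are placed
uniformly in a 300-µm field; the target baseline correlation of a pair at
distance `d` is `0.25 + 0.45 · exp(−d² / (2·100²))`, and after the
application time every pair's target drops by `subtractive_shift`, floored
at the feasibility minimum. The profile endpoints (0.7 proximal, 0.25
distal) are typical of bolus-loaded populations before eye opening, and the
100-µm scale matches the decay observed across such fields of view.

Mechanistically, population events occur at Poisson times (0.18 Hz) and each
cell participates in an event with probability q = 0.175, so the per-cell
event frequency is 0.0315 Hz, matching the ~0.03 Hz baseline frequency of
spontaneous calcium events in the immature visual cortex. Participation is
drawn by thresholding a latent multivariate normal at `qnorm(1 − q)`. Two
analytic maps connect the latent correlations to the observable ones:

1. the tetrachoric relation between a latent correlation and the Pearson
   correlation of the two participation indicators (inverted numerically by
   `uniroot` on a one-dimensional integral of the bivariate normal density);
2. a shot-noise map from indicator correlation to trace correlation,
   `ρ_trace = (q² + q(1 − q)·ρ_bin) / (q + w)`, where
   `w = σ_n² / (a² p_e K₂)` is the relative white-noise power under the
   exponential calcium kernel (`K₂` its power sum, `p_e` the per-frame event
   probability). The `q²` offset is the correlation all cells share simply
   by firing at common event times.

Both maps are inverted per pair so the traces hit the target matrix; the
resulting latent matrix is projected to the nearest positive-semidefinite
correlation matrix by eigenvalue clipping when needed (an exactly
subtractive change genuinely requires some negative latent co-fluctuation,
which can leave the pairwise-inverted matrix slightly indefinite). The
achieved targets after projection are returned as ground truth; residual
calibration error is ≈1%.

Two variance-reduction choices stabilize epoch-level estimates without
changing any event's marginal or pairwise law. Events are drawn in
*antithetic* pairs (`η`, `−η`): each latent vector is still standard normal
by symmetry, but the global event-size mode — the dominant source of
coherent drift in epoch correlation estimates — cancels between partners.
Antithetic partners are assigned to *shuffled* frame positions: placed at
adjacent times, their anticorrelated participations would overlap through
the calcium kernel and visibly attenuate trace covariances. And the same
latent sequence drives both epochs (common random numbers), pairing the
conditions so that post-minus-baseline contrasts are not dominated by
event-sampling noise. The sparse-participation decomposition
(0.18 Hz × 0.175 rather than, say, 0.09 Hz × 0.35) keeps ~470 events per
45-min epoch; with half as many events the modulation-type identification
becomes unreliable at realistic noise, defeating the generator's purpose as
a recovery benchmark.

What the generator does *not* emulate: motion artifacts, neuropil
contamination, photobleaching, cell-size and amplitude heterogeneity,
non-stationary event rates, and negative-going artifacts. Passing recovery
tests on these fixtures therefore demonstrates correctness of the analysis
chain under the stated statistical structure, not robustness to every
failure mode of real two-photon data.

## Synthetic wide-field movies

Events are spatial Gaussians (SD 40 µm) multiplied by a temporal kernel that
rises linearly over 0.1 s and decays exponentially with a 1-s constant
(GCaMP6s-like). The raw movie is `1000 · (1 + ΔF/F0) + noise` with a
constant 1000 a.u. baseline, making the ΔF/F0 round trip exact; the default
noise SD (0.03) keeps the 12% threshold at 4× the noise SD. Event counts are
Poisson at 0.042 Hz per region; onset frames are redrawn until the occupied
spans are pairwise disjoint, which guarantees non-overlapping ground-truth
voxel sets (at the default rate the rejection correction to the count
distribution is negligible). Event centers keep 2 spatial SDs away from the
field edge so suprathreshold footprints (radius ≈1.35 SD) are never clipped;
region masks supplied by the user are honored as-is. Ground-truth voxel sets
are defined *after* the same moving-average ΔF/F0 conversion the detector
applies (on the noiseless movie), so the noiseless round trip recovers every
event with IoU exactly 1 and noisy detection is compared against an
attainable reference.

## Synthetic electrophysiology

PSCs are biexponential, `exp(−t/τ_d) − exp(−t/τ_r)` normalized to unit peak,
at Poisson times with fixed amplitude; the analytic 20–80% rise time comes
from root-finding on the closed form. APs are parametric: a slow linear
depolarization from rest to threshold over `dtime` (slope kept below the
dV/dt criterion), then a triangular spike whose half-width has the closed
form `amp/2 · (1/rise + 1/fall)`; the apex is written onto the nearest
sample so the sampled peak equals the nominal one on any grid.

## Patch-clamp feature extraction

The AP threshold is the first sample where dV/dt reaches 20 mV/ms — a common
convention, configurable, since no universal definition exists. The
derivative uses the *forward* difference so the threshold sample is the one
from which the suprathreshold rise departs; a backward difference would
report the threshold one sample late, which at steep spike slopes biases the
threshold voltage by several mV. Overshoot is the peak above 0 mV (reported
`NA` for peaks below 0), amplitude is peak minus threshold voltage,
half-width interpolates the crossings at half amplitude, and ΔTime is pulse
onset to threshold crossing.

PSC detection is template-free: a boxcar-smoothed derivative thresholded at
4 robust SDs marks onsets; amplitude is measured from a local pre-onset
median baseline to the peak in a 10-ms window, and the 20–80% rise time
interpolates fractional crossings on the rising phase. The originating
toolchain's detector is unpublished, so any detector that recovers the
synthetic fixtures' ground truth is considered conformant; the identity
`rise_rate × rise_time = amplitude` holds exactly by construction.

The ramp protocol (−100 to 140 pA at 96 pA/s, hence 2.5 s and 14 full
175-ms bins plus a remainder bin flagged `partial`) assigns each inter-spike
interval to the bin containing its first spike — the assignment is not
standardized, and this choice keeps every ISI in exactly one bin — and
reports `1/mean(ISI)` against the bin's mean injected current. Baseline
membrane potential uses the per-bin *median* after removing ±5 ms around
suprathreshold samples, which is insensitive to residual spike remnants.
Series-resistance QC fails a recording when any measurement exceeds 30 MΩ or
deviates more than 30% from the first measurement. Cells lacking a
depolarization are only logged, not silently dropped: the original exclusion
magnitude is unstated, so the package reports the rate and leaves exclusion
to the analyst.

## The spiking-network model

The network is a single 2D sheet (400 µm, periodic boundaries to avoid edge
effects) of current-based leaky integrate-and-fire neurons, 80% excitatory
and 20% inhibitory with a quarter of the inhibitory population SST⁺.
Membrane dynamics are `C dV/dt = g_L (V_rest − V) + I` (units mV, pA, nS,
pF, ms), integrated by forward Euler at 0.1 ms with exponential synaptic
currents (τ_e = 5 ms, τ_i = 10 ms) and a 1.5-ms conduction delay handled by
a ring buffer. Spikes reset to `V_reset` with an absolute refractory period;
the isolated-neuron rate has the closed form
`1000 / (t_ref + τ_m ln((V∞ − V_reset)/(V∞ − V_th)))`, which the simulator
matches within 1% and which serves as the f–I oracle in the tests.

Connection probability decays as `p₀ exp(−d² / 2σ_c²)` under the toroidal
metric, with `p₀` and `σ_c` per projection; inhibitory axons reach further
laterally (σ = 140–180 µm vs 100 µm excitatory) than excitatory ones,
consistent with the lateral-inhibition geometry of SST⁺ cells.

Anchored parameters: external currents of 50 pA to excitatory and 40 pA to
SST⁺ neurons, a sinusoidal background to the excitatory population, SST
resting potential −60.8 mV at baseline and −56.3 mV under the neuropeptide
(the 4.5-mV depolarization measured in current clamp), 25% SST fraction, and
60 s per condition at full scale. Free parameters were calibrated once to
place the network in the intended operating regime and are all exposed in
`model_config()`:

* SST leak 2 nS with threshold −40 mV puts the baseline SST rheobase at
  41.6 pA, just above the 40-pA drive, so baseline SST firing is sparse and
  recurrently driven while the depolarized condition (rheobase 32.6 pA)
  recruits tonic ~23 Hz firing — the f–I separation seen in current clamp.
* Per-population noise (SD 120 pA on E, 60/40 pA on interneurons as
  per-step white current) makes excitatory cells the event trigger: their
  voltage fluctuates ~3 mV around an operating point 5 mV below threshold.
* The sinusoidal background is deliberately weak (6 pA at 0.5 Hz): an
  injected common current correlates all voltages identically regardless of
  distance, so the distance structure of the correlations must come from
  recurrent activity, with the sinusoid only providing slow envelope
  modulation.
* Recurrent weights (w_e = 25 pA, w_i = −60 pA) put the excitatory network
  near the regime where noise-triggered local events spread through the
  E→E kernel; tonic SST firing under the neuropeptide adds a wide inhibitory
  blanket that both suppresses excitatory firing and, because proximal pairs
  retain shared local drive while long-range co-activation is curtailed,
  reduces voltage correlations with a magnitude that grows with distance.

Voltage correlations are computed between the recorded excitatory units'
traces (sampled at 1 kHz, unclipped by default since the underlying methods
specify plain voltage traces; spike clipping is selectable), after
discarding a 1-s burn-in — all cells share the deterministic relaxation from
rest to their operating point, which would otherwise inflate every pair.
Correlations are averaged in toroidal-distance bins and differenced between
conditions.

The tests and the acceptance analysis run a scaled model — 500 neurons and
20 s per condition — which the package treats as its standard benchmark
size; the qualitative signatures (suppressed excitatory rate, increased SST
rate, reduced voltage correlations with |Δ| non-decreasing over distance)
are stable across seeds at this size, while absolute rates and correlation
magnitudes do change with scale and are not asserted. No canonical published
values exist for the intrinsic and synaptic parameters of a network like
this at these ages, so the model is validated by its closed-form oracle and
by those directional signatures rather than by matching absolute numbers.

## Numerical conventions and degenerate inputs

All times are seconds, distances µm, currents pA, voltages mV, and ΔF/F0 a
dimensionless fraction internally; percent appears only in presentation.
Zero-variance traces raise errors (event detection) or are excluded with a
count (windowed correlations, voltage correlations). `percent_change`
rejects zero baselines. The MSD detrend is skipped with a warning below 3
baseline windows, and normalization falls back to zeros with a flag when the
baseline SD vanishes. Event catalogs may be empty; frequency time courses
reject bins longer than the recording. Connectivity construction errors when
`p(d) > 1`, and the integrator aborts when a subthreshold voltage exceeds
200 mV in magnitude. TIFF round trips are bit-exact for integer-valued
movies (storage is uint16); CSV round trips write 17 significant digits so
doubles survive exactly.

## Known limitations

The generators define the benchmark conditions; they do not attempt optical
realism (no scattered light beyond the restricted-area rationale, no
hemodynamics, no motion), and the network model is a minimal single-sheet
cortical caricature — no conductance-based synapses, no plasticity, no
thalamic circuitry, free parameters chosen for regime rather than fitted to
data. Results on real recordings will additionally depend on registration,
neuropil correction and indicator nonlinearity, all of which are upstream of
this package's scope.
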