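---
title: "Quantifying ripple-band phase precession during hippocampal replay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ripple-band phase precession during hippocampal replay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripplephase)
```

## The analysis problem

During movement, hippocampal place cells fire at progressively earlier phases
of the 6–12 Hz theta oscillation as the animal crosses their place field —
theta phase precession. During rest, the hippocampus re-expresses compressed
spatial trajectories ("replay") inside sharp-wave ripple events, transient
150–250 Hz oscillations of the local field potential (LFP). The question this
package operationalizes is whether replayed spikes show the same kind of
phase organization relative to the *ripple* oscillation: does a cell's ripple
firing phase shift systematically earlier as the decoded trajectory passes
through its place field?

Answering that requires a chain of standard but fiddly steps, each of which
this package implements as a tested, reusable unit:

1. band-limited filtering and analytic (Hilbert) phase/amplitude extraction,
   with a session-wide phase normalization that puts the population's mean
   preferred firing phase at π rad;
2. candidate replay event detection from multi-unit activity (MUA) or from
   ripple-band power;
3. directional firing-rate maps and place fields on a linearized Z-track;
4. Bayesian decoding of position from population spike counts (independent
   Poisson likelihood per cell), linear trajectory fitting through the
   posterior, and significance by cell-identity shuffling;
5. circular–linear regression of firing phase on normalized time or relative
   field position, successive-spike phase shifts, phase autocorrelograms and
   permutation phase locking;
6. theta and ripple "sweeps": phase-binned median distance between the
   represented position and the nearest field peak.

Because real recordings carry no ground truth, the package also ships a
synthetic session generator that produces data with *known* precession
slopes, field geometry and replay trajectories, used throughout the test
suite for parameter recovery.

## The decoding model

For each time bin of width $T$ the posterior over track positions $x$ given
the spike count vector $K = (k_1,\dots,k_N)$ is

$$
P(x \mid K) \propto \prod_{i=1}^{N}
  \frac{\big(T\,\alpha_i(x)\big)^{k_i}}{k_i!}\,
  e^{-T\,\alpha_i(x)},
$$

with $\alpha_i(x)$ the cell's directional firing-rate map (2 cm bins,
Gaussian-smoothed with SD 5 bins, speed-filtered at ≥ 10 cm/s, with the final
10 cm at each track end and ±5 cm around each corner excluded). A small rate
floor $\varepsilon = 0.01$ Hz is added to every map inside the product so a
single stray spike from a silent cell cannot zero out the posterior; the
floor is configurable and its only effect is to regularize log-likelihoods.

Replay events are decoded in $T = 10$ ms bins starting at the event's first
spike; bins with no spikes are left undecoded. The replay trajectory is the
line (origin × signed speed, speeds 100–5000 cm/s in 50 cm/s steps, all
origin bins) that maximizes the mean posterior mass inside a 15-bin (30 cm)
window centred on the line per decoded bin, the window clipped at the track
ends. Ties prefer the lower |speed| and then the earlier origin. Note a
consequence of this scoring that matters when validating against point-mass
posteriors: for short events every line within roughly half a window width of
the truth captures a unit point mass perfectly, so a *band* of speeds ties at
score 1 and the tie-break returns its slowest member. Discrimination among
nearby speeds comes from the spread of real posteriors, not from the window
geometry. Significance uses 100 shuffles of the map identities of the active
cells (the identity assignment is excluded; when fewer than 100 distinct
non-identity orderings exist they are enumerated and sampled without
replacement — 5 active cells admit 5! = 120 orderings); an event is
significant when the true fit score exceeds the 95th percentile of the
shuffle scores. Percentiles of permutation distributions are computed the way
MATLAB's `prctile` defines them (R `quantile(type = 5)`), the convention of
the ecosystem in which these analyses are conventionally run. Under an
exchangeable null the 95th-percentile rule at 100-shuffle granularity has a
measured false-positive rate near 6%, not 5% — an inherent property of
thresholding on a finite shuffle sample that the test suite checks against a
7% bound.

## Circular statistics

Phase precession is quantified with circular–linear regression: the slope
$\hat a$ maximizes the resultant length of the residual angles
$\theta_j - a\,x_j$ over a dense slope grid (default ±3 cycles per unit of
the covariate in 0.01 rad steps; the grid is anchored so that a zero slope is
always a candidate, and ties prefer the smaller |slope|). The intercept is
the circular mean of the residuals at the optimum. With very few spikes the
slope is aliased — with three spikes at normalized times 0, ½, 1 any slope
change of 4π fits identically — so wide bounds are a reporting convention,
not a resolution claim. Successive-spike phase shifts are wrapped to
(−π, π]. The Rayleigh test uses $Z = nR^2$ with the standard small-sample
exponential approximation for $p$ (measured size ≈ 4.9–5.2% at α = 0.05
for n ≥ 50). Phase locking (PLV, the resultant length of spike phases) is
assessed against surrogates built by circularly time-shifting the spike
train by at least 30 s, 1000 times, thresholding at the 99th percentile; note
that such surrogates only decorrelate when the underlying oscillation's
phase actually drifts, so the test-suite nulls use band-limited noise rather
than pure tones.

## Signal processing choices

Filtering uses Hamming-window FIR design (`signal::fir1`) applied with exact
group-delay compensation, so filtered features are not time-shifted — phase
analyses require zero phase distortion. The default order scales with sample
rate as `round(400 * fs / 4800)` taps, but is raised to
`ceiling(6.6 * fs / band_low)` when that scaling would leave a narrow band
unprotected: at any practical sample rate a 400-tap-equivalent filter has a
transition band of tens of Hz, which cannot both pass 6 Hz and attenuate
3 Hz. The package therefore guarantees the functional contract — in-band
tones pass with gain ≥ 0.9 and tones one octave outside are attenuated by
≥ 20 dB — rather than a literal tap count. Instantaneous phase and envelope
come from the FFT-constructed analytic signal; phase is in [0, 2π) with 0 at
the oscillation's positive peak (cosine convention). Phase at spike times is
obtained by phasor interpolation between samples (interpolating the unit
vectors, then taking the angle), which removes the ±0.6 rad quantization a
nearest-sample lookup would incur for a 200 Hz ripple sampled at 1 kHz.
Event-locked spectrograms use 5-cycle analytic Morlet wavelets normalized to
unit passband gain, log-transformed, averaged across events and baseline
corrected with the central 0.4 s of inter-event gaps ≥ 2.4 s. Because the
wavelet noise bandwidth grows with frequency, the baseline-corrected peak of
a tone-on-noise transient sits slightly (≈ σ_f²/f) below the tone — a
property of this standard estimator, not a bug.

## Event detection

Candidate replay events follow a single morphology chain applied to a
z-scored activation trace — the 1 ms MUA histogram smoothed with a 5 ms SD
Gaussian kernel, or the 5 ms-smoothed Hilbert envelope of the 150–250 Hz
filtered LFP: contiguous periods of Z ≥ 0 containing a peak Z ≥ 3, merged
across gaps ≤ 40 ms, then filtered by duration (> 40 ms, ≤ 0.5 s),
participation (≥ max(5, 15% of pyramidal cells) active) and median running
speed (≤ 10 cm/s). The z-scoring baseline is the whole epoch. On sparse
background spiking the Z ≥ 3 criterion sits close to the peak produced by a
single spike, so the false-alarm rate of the MUA detector is a steep
function of population rate; tests therefore validate false alarms against a
Monte-Carlo null computed by the same detector on background-only sessions
rather than against a fixed count.

## The synthetic session generator

The generator emulates a Z-track session (sections 190 + 220 + 190 cm,
linearized): a RUN epoch of constant-speed shuttle runs (default 10 per
direction at 50 ± 5 cm/s, 2 s pauses; 50 Hz tracking) followed by an
immobile REST epoch. Each of the default 30 cells has one Gaussian place
field (40 cm extent, SD = width/4, 8 Hz peak) active in both running
directions. Spikes are drawn as an inhomogeneous Poisson process on the
spatial envelope; each spike is assigned a target phase
$\pi + s\,(d - \tfrac12)$ (d ∈ [0,1] the relative distance through the field
along the movement direction, s the per-cell precession slope, default
−2.77 rad/field for theta and −0.5 rad/field for ripple, matching the scale
of precession these analyses are designed to detect) plus wrapped-normal
noise (SD 0.4 rad), and the spike time is then snapped to the moment within
the current oscillation cycle at which the LFP phase equals the target. The
LFP (default 1 kHz; all filters scale with sample rate) is a theta cosine
plus white noise during RUN, and white noise plus tapered ripple-frequency
transients during REST. Replay events place spikes where a constant-speed
trajectory crosses each field, with phases from the same within-field model;
event start times are aligned to the LFP sample grid so the injected phase
convention holds exactly, and spikes are confined to the flat part of the
amplitude taper (the phase of a transient is only measurable where the
transient has amplitude). Background REST spiking is homogeneous Poisson at
0.5 Hz per cell; an optional >10 Hz "distractor" cell exercises the
putative-interneuron exclusion applied at load time (mean session rate
≤ 10 Hz). Every spike is attributable in the ground-truth record to its run,
replay event or background origin.

What the generator does *not* emulate: bursting and refractoriness, rate
remapping between directions, theta-frequency drift and asymmetric cycles,
multiple fields per cell, behavioural variability in running speed within a
run, and non-stationary noise. Recovery tests passing on this generator
therefore validate the *estimators* (given data obeying the assumed phase
model, the pipeline recovers its parameters at the stated tolerances), not
the biological claim itself.

One calibration subtlety is deliberate: detected place fields (contiguous
bins above the map mean) are systematically wider than the generative 40 cm
envelope, because the above-mean criterion reaches into the field's tails.
A slope expressed per *detected* field width is therefore scaled by a purely
geometric factor relative to the injected slope. Parameter-recovery tests
normalize spike positions by the ground-truth field extent so that they test
the fit machinery and phase measurement, while field *detection* accuracy
(peak location, width threshold behaviour) is tested separately.

## Sweeps

For each theta cycle within a movement event, the first spike of each active
cell contributes the signed distance (along the movement direction) from the
animal's mean position in the cycle to the peak of that cell's nearest
same-direction field; distances are binned into 10 equal theta phase bins,
and the per-bin medians are regressed on phase over [0, 7π/5] rad. The sweep
range is slope × (7π/5) and the equivalent speed divides the range by the
event's mean measured cycle duration — the measured duration, not the
band-centre period, is what makes a range-per-cycle and a speed mutually
consistent. Ripple sweeps are analogous with 5 phase bins over [2π/5, 2π],
the decoded per-cycle location as the reference position and all spikes
included (first-spike-per-cycle is available as an option). Events whose
spikes come from fewer than two distinct fields, or that occupy fewer than
two phase bins in the regression range, are excluded as degenerate.

## Problem sizes and tolerances in the test suite

The test suite builds every fixture programmatically at run time. The
sessions used are deliberately compact — 8–30 cells, 4–15 runs per
direction, REST epochs of 150–1150 s with 10–500 injected replay events —
chosen so that each recovery target has the sample size its tolerance
presumes: ≥ 200 in-field first-per-cycle spikes for the ±15% theta-slope
recovery, ≥ 30 significant events for the ±0.2 rad ripple-slope recovery,
≥ 500 spike pairs for the ±0.05 rad per-spike shift recovery, 1500 events
for the shuffle false-positive bound, 1000 replicates for the Rayleigh and
PLV calibrations. Determinism is enforced end to end: the same seed
reproduces byte-identical session bundles and report files.

## Known limitations

* The MUA detector's Z ≥ 3 criterion is knife-edged at low population rates
  (a single spike can cross it); with few cells, background false alarms are
  expected and must be judged against the detector's own Monte-Carlo null.
* Circular–linear slopes from 3-spike events alias at 4π rad per unit and
  are only meaningful in aggregate.
* The trajectory fit cannot distinguish speeds closer than the posterior
  spread divided by the event duration; for point-mass posteriors a ±½
  window band of speeds ties exactly.
* The generator's phase model is noiseless in time (phases are imposed, not
  emergent), so it cannot probe estimator behaviour under cycle skipping or
  phase-amplitude coupling.
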