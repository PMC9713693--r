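---
title: "Methods: joint analysis of calcium imaging and tetrode LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint analysis of calcium imaging and tetrode LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caephys)
```

# The problem

Implants that combine a GRIN relay lens with tetrodes on its periphery
record two views of the same neural population at once: per-ROI calcium
fluorescence (ΔF/F, a slow proxy of spiking at single-cell resolution) and
extracellular voltage (the local field potential, LFP, plus spikes, at
millisecond resolution but poor cell resolution). The scientific question
the analysis addresses is how much these two views overlap: does a cell's
ΔF/F co-fluctuate with the LFP power around it, can a sorted single unit be
matched to one of the imaged cells, and do cells carry distinguishable
spatial firing maps in a freely moving animal?

`caephys` implements that analysis chain — band-power extraction,
correlation with permutation nulls, spike–calcium matching, spatial maps —
together with a synthetic session generator with known ground truth, and
the optical quality-control procedures used to characterize the imaging
system itself.

# The synthetic session generator

Because every downstream stage needs inputs with *known* coupling, the
generator is a first-class, tested module, not a test fixture. Its model:

* **Band latents.** Each canonical band $b$ (theta 6–14 Hz, beta 15–30 Hz,
  low gamma 35–55 Hz, high gamma 65–95 Hz) carries one latent drive
  $l_b(t) = e_b(t)\,\sin(2\pi f_b t + \phi_b)$, a sinusoidal carrier
  (defaults 10, 22, 45, 80 Hz) amplitude-modulated by a rectified
  Ornstein–Uhlenbeck envelope $e_b$ with a 1-s time constant. The envelope
  time constant matters: it makes band *power* fluctuate on the same
  timescale as calcium transients, which is what gives ΔF/F–power
  correlations something to latch onto.
* **Electrode voltage.** Each electrode mixes all four latents with weights
  drawn once per session (uniform 0.4–1), scaled to ~100 µV, plus
  $1/f$-shaped noise (exponent 1, configurable). The shared latents across
  electrodes emulate volume conduction: all electrodes see correlated band
  power, as real tetrodes around one lens do. Voltage is quantized to the
  0.195 µV/count int16 grid at generation time so file round trips are
  exact.
* **Spiking and ΔF/F.** ROI $i$ fires as an inhomogeneous Poisson process
  with rate $\mathrm{base} \cdot \mathrm{place}_i(t) + g \sum_b C_{ib}\,
  \max(l_b(t), 0)$, where $C$ is the configured ROI × band coupling matrix
  in $[0,1]$, $g$ = 10 Hz per unit coupling, and $\mathrm{place}_i$ is a
  Gaussian bump of distance to the ROI's place-field center when centers
  are configured. ΔF/F is the per-frame spike count passed through a
  single-exponential kernel ($\tau$ = 0.7 s, a GCaMP6s-scale decay) plus
  Gaussian noise. A single-exponential (no rise time) keeps the generator
  consistent with the spike-matching convolution, which uses the same
  kernel.
* **Behavior.** A reflecting random walk with AR(1) velocity (~90 px/s RMS)
  in a configurable arena, at 30 fps, in video pixel convention (origin
  top-left, y down).
* **Synchronization.** The ephys stream carries a trigger channel with one
  pulse per imaging frame, so the trigger-edge detector can be tested
  against the generator's own frame times.

All randomness flows from one seed through a counter-based splitting
scheme (`splitSeed`), so each component (latents, weights, noise, track,
spikes) has its own reproducible stream and identical config + seed gives
bit-identical sessions.

**What the generator does not emulate:** indicator rise time and
saturation, motion artifacts, neuropil contamination, spike waveform shape,
biophysical LFP forward models, or realistic place-cell remapping. Passing
tests therefore show the *analysis* is correct and calibrated under a
plausible coupling model — not that real recordings satisfy that model.

Defaults mirror the head-fixed study scale: 100 ROIs, 16 electrodes in 4
tetrodes, 10-minute sessions, 15 Hz imaging frames (a typical two-photon
resonant-relay rate; the frame rate is configurable). The generator default
for the ephys clock is 1 kHz; the package's own simulations analyze LFP at
250 Hz, a standard decimated-LFP rate that keeps the full 1–100 Hz band
below Nyquist.

# Band power

Raw voltage is conditioned to the LFP with a zero-phase 4th-order
Butterworth band-pass (1–100 Hz, forward–backward). Spectrograms use an
analytic Morlet wavelet with 6 cycles ($\sigma_f = f/6$), the field's
default when only "wavelet" is specified, evaluated on a 1-Hz grid;
band-power traces average the in-band rows of that grid, then average
within each inter-frame interval to produce one value per imaging frame.
Interval means (not instantaneous samples) suppress aliasing of power
fluctuations faster than the frame rate. The first and last second of each
recording fall inside the wavelet cone of influence; those frames are
flagged invalid and excluded from all correlations.

Numerically, the band-power kernel (C++) computes each wavelet coefficient
by frequency-domain multiplication and inverse FFT. Two devices keep the
10-minute × 16-electrode workload fast without changing definitions beyond
floating-point precision: single-precision FFTs (band power averages
thousands of samples, so float round-off is far below any tolerance used),
and, for bands whose wavelet support fits in half the spectrum, exact
stride-2 coefficient sampling via spectral folding (the aliased half-length
inverse FFT reproduces every second coefficient exactly; the interval mean
then uses those samples).

# Correlation analysis

The headline statistic is the zero-lag Pearson coefficient between every
ΔF/F trace and every electrode's band-power trace — ROI × electrode × band.
Constant traces yield `NA` (undefined), never 0, and are excluded from
histograms and fractions.

The null model must respect autocorrelation: both ΔF/F and band power are
strongly autocorrelated, so a parametric Pearson test would be wildly
anticonservative. The package therefore builds a per-pair permutation null
by circularly shifting each ΔF/F trace 100 times, with the shift drawn
uniformly from $[\lceil L/10 \rceil, L - \lceil L/10 \rceil]$ — the minimum
shift of a tenth of the trace keeps the shifted copy from overlapping its
own neighborhood. The two-sided empirical p-value is
$(1 + \#\{|\rho_{null}| \ge |\rho|\})/(1 + n_{shuffle})$, never exactly
zero. This choice (permutation rather than parametric p-values feeding the
FDR step) is the package's design decision; both the shuffle count and the
minimum-shift fraction are parameters.

Benjamini–Hochberg runs at $q = 0.05$ within each band across all ROI ×
electrode pairs (per-band fractions are the quantity of interest); a
`pool_bands` switch adjusts across all bands jointly. The "shuffled
dataset" fractions treat shuffle 1 of each trace as the observation and the
remaining shuffles as its null, so original and shuffled datasets get an
identical pipeline. Original versus shuffled coefficient distributions are
compared per band with the two-sample Kolmogorov–Smirnov test (asymptotic
p). Correlations are computed on linear power; a log transform before
correlation is a caller choice (transform the band matrix first), as the
appropriate scale is genuinely open.

Calibration is tested, not assumed: on zero-coupling sessions at full study
scale the fraction of pairs with $p < 0.05$ must match 0.05 within 3
binomial SDs (pooled across 20 sessions — per-session fractions have
inflated variance because all pairs share 64 band-power regressors), and
the BH fractions must average below $q$.

# Spike–calcium matching

A sorted unit's spike train is binned to imaging frames (binary by default:
a frame with ≥1 spike gets 1; `count = TRUE` keeps counts) and convolved
with the same exponential decay kernel the calcium model uses. The
convolution is implemented as an exact first-order recursive filter
($y_k = x_k + e^{-\Delta t/\tau} y_{k-1}$), which equals convolution with
the *untruncated* kernel at machine precision; an explicitly truncated
kernel was considered and rejected since the recursion is both exact and
O(n). The pseudo-trace is then Pearson-correlated against every ROI;
Pearson's scale invariance makes the arbitrary spike-trace amplitude
irrelevant. The decay constant must match the one used for source
extraction on real data; the default 0.7 s is GCaMP6s-scale.

# Spatial maps

Freely-moving analyses bin the arena into 25 × 25 px cells. Occupancy comes
from the video-rate track (seconds per bin); activity is the summed ΔF/F
assigned by the animal's interpolated position at each imaging frame; the
normalized map is activity/occupancy, Gaussian-smoothed with σ = 62.5 px
using a kernel renormalized over the visited support. Unvisited bins stay
`NA` — zero-filling would fabricate silent locations and bias both the
smoothing and the map comparisons.

Transient onsets are upward crossings of median + 3 robust SDs (scaled
MAD); the threshold is configurable since "transient" has no universal
definition. The onset position is the track sample nearest in time on the
imaging clock; the video-to-imaging map is affine (offset + drift factor)
fixed by the first/last laser-light anchor frames, generalizing a pure
offset to tolerate camera clock drift. The ephys clock is the master clock
throughout.

Maps are compared with a two-sample 2-D Kolmogorov–Smirnov test in the
Fasano–Franceschini form: the statistic is the maximum over all data
points, over the four quadrants anchored there, of the difference in
empirical quadrant CDFs. Because that test is defined on point sets, each
map is converted to one: bin centers are sampled with probability
proportional to normalized activity and jittered uniformly within the bin
(500 points per map by default). The p-value is a permutation p over
relabelings of the pooled points. Each map's resample depends only on (map,
seed), so a map compared against itself under one seed yields D = 0
exactly. Pairwise comparisons across maps are BH-adjusted.

# Optics QC

The characterization procedures operate on calibration images — synthetic
ones from the package's generators, or real TIFFs read by the user:

* **Magnification**: the grid period in pixels is the first off-zero peak
  of the mean line profile's autocorrelation, refined by parabolic
  interpolation; M is the ratio of pixels-per-µm through the system to the
  reference calibration. An autocorrelation peak below 3× the noise floor
  is rejected as "no periodic structure".
* **FOV**: rolling-minimum baseline subtraction (window = one grid period),
  then count local maxima above 10% of the profile maximum with a minimum
  separation of half a period; FOV = count × 50 µm. The
  count-times-spacing rule is the default because it reproduces 8 → 400 µm
  and 7 → 350 µm; the alternative reading (distance between extreme
  peaks) is available as `method = "span"`.
* **Lateral/axial FWHM**: beads are detected as 8-neighborhood local maxima
  above background + 5 robust SDs (detection on the z-mean projection for
  stacks — a separable Gaussian keeps its lateral σ under z-averaging
  while noise shrinks), five are sampled per estimate (seeded, without
  replacement), and a 1-D Gaussian with free offset is fitted to each
  bead's line or z profile (Levenberg–Marquardt). FWHM
  $= 2\sqrt{2\ln 2}\,\sigma$, corrected by $1/M$ laterally and $1/M^2$
  axially. Beads truncated by the stack boundary are skipped with a
  warning.

# Problem sizes and tolerances used by the test suite

The package's simulations run at the study scale where the property being
checked demands it, and smaller where it does not: calibration uses 20
zero-coupling sessions of 100 ROIs × 16 electrodes × 10 min at 15 Hz
frames and 100 shuffles; the coupled-detection contrast uses 20 sessions of
32 ROIs × 16 electrodes × 4 min with half the ROIs coupled at 0.5 to
theta (a size at which the effect is decisive); spike-match recovery uses
8-ROI 2-minute sessions over 20 seeds; optics fixtures are single images.
LFP analysis in all of these runs at 250 Hz. On white noise the per-frame
band-power coefficient of variation is 0.52–0.65 with these wavelet
parameters; the steadiness test bounds it at 0.8 (calibrated once from
pilot runs at a stated seed) and additionally requires half-session means
to agree within 10%.

# Known limitations

* The coupling model is a stand-in: the true generative relationship
  between somatic calcium and nearby LFP is unknown, and only qualitative
  conclusions (skew, calibration, ordering) transfer.
* Empirical p-values are bounded below by $1/(n_{shuffle}+1)$; with 100
  shuffles the smallest attainable p is ≈ 0.0099.
* The 2-D KS comparison depends on the activity-weighted resampling
  construction; other translations of an image into a point set (e.g.
  thresholded super-level sets) would give different D values.
* Vendor ephys formats (Intan RHD, Neuralynx) and NWB are out of scope;
  sessions enter through the plain-file layout or in memory.
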