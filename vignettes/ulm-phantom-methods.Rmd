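---
title: "Simulating and analysing microvascular flow phantoms with ULM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing microvascular flow phantoms with ULM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulmphantom)
```

## What the package models

Ultrasound localization microscopy (ULM) reconstructs vascular maps below
the diffraction limit by localizing individual microbubble (MB) contrast
agents over thousands of ultrafast frames and linking them into tracks.
`ulmphantom` pairs a complete ULM analysis chain with a synthetic phantom
simulator, so that every stage — clutter filtering, localization, tracking,
velocimetry and saturation-time statistics — can be verified against known
ground truth without any experimental data.

The simulated object is a planar network of rectangular channels
(100–500 µm wide, 300 µm high) through which diluted MBs are pumped at
0.01–0.03 mL/min, imaged at 250 Hz in contrast-pulse-sequence (CPS) or
B-mode.

## Flow model

Mean channel velocities follow conservation of mass for an incompressible
fluid: $A_{in} V_{in} = \sum_k A_k V_k$ with $A = w h$ the rectangular
cross-section and $V = Q/A$. Over the design grid of widths
$\{100, 200, 300, 500\}\,\mu m \times 300\,\mu m$ and flow rates
$\{0.01, 0.02, 0.03\}$ mL/min this spans mean velocities of about
1–17 mm/s.

```{r}
expected_velocity(0.02, cross_section_area(300, 300))
```

At a junction, flow divides by one of two rules:

* **symmetric** — equal mean velocity in all daughters ($Q_k \propto A_k$),
  which reduces to an exact half/third split for equal-area bifurcations and
  trifurcations;
* **resistance** — $Q_k \propto 1/R_k$ with $R_k \propto L_k/(w_k^3 h_k)$,
  the rectangular-slit (plane-Poiseuille) resistance. This is the package's
  own model for unequal daughters; the physical experiments it emulates did
  not measure the delivered split, so the asymmetric-split magnitudes below
  are model predictions, not measured values. When daughter areas are equal
  the resistance rule degenerates to the symmetric split.

Across the imaged width the in-plane profile is a plane-Poiseuille
parabola, $v(u) = 1.5\,V_{mean}(1 - u^2)$ for lateral offset
$u \in [-1, 1]$; the unimaged height dimension is absorbed into the mean.
The 1.5× centreline factor is the standard parallel-plate result; the
experiments report parabolic profiles but no peak factor.

## The simulator

`generate_sequence()` runs a seed → advect → render loop:

* **Arrivals.** Detectable-MB arrivals are a thinned Poisson process with
  rate $\lambda = C \times Q \times f_{det}$. At the clinically typical
  concentration $C = 6.4\times10^6$ MB/mL and $Q = 0.02$ mL/min the raw
  arrival rate $CQ \approx 2133\,s^{-1}$ would put thousands of overlapping
  bubbles in a millimetre-scale channel; ULM, however, operates on sparse,
  isolated echoes, and measured saturation times of order one second imply a
  localizable-event rate far below $CQ$. The default detectable fraction
  `detect_fraction = 0.02` encodes this: only a small subpopulation of the
  polydisperse bolus (bubbles near resonance, large enough, and not
  overlapping) yields a localizable nonlinear echo. Entry offsets are
  flux-weighted ($p(u) \propto 1 - u^2$), which is the mass-consistent
  choice: faster streamlines carry proportionally more bubbles, so the mean
  speed over tracks is $1.2\,V_{mean}$ (`flux_weighted_mean_speed()`).
* **Advection.** Bubbles keep their streamline offset, move at
  $v(u)\,\Delta t$ per frame, choose daughters at junctions with
  probability proportional to daughter flow, and leave at outlets.
  Optionally, a constant acoustic-radiation-force drift pushes bubbles
  towards the far (+z) wall, where they may stick permanently and appear as
  static echoes — an effect observed in physical phantoms. Its magnitude and
  sticking rate are not calibrated; the defaults are illustrative and the
  feature is off unless requested.
* **Rendering.** Every source contributes an isotropic Gaussian PSF
  (default σ = 1.5 px at 25 µm pixels, comparable to imaging at a 20 MHz
  receive frequency). In CPS mode the three-pulse weights (0.5, −1, 0.5)
  are summed over the linear responses explicitly, so linear scatterers
  cancel *exactly* (to the last floating-point bit), and bubbles contribute
  a nonlinear residual of configurable amplitude; no oscillation physics is
  modelled. B-mode keeps both. Additive Gaussian noise (default sd 0.01
  relative to unit bubble amplitude) is applied last, clipped at zero.

The default grid is 128 × 128 px at 25 µm (tiny test fixtures use 64 × 64),
which keeps the 100–500 µm channels 4–20 px wide. One seeded generator
drives every stochastic draw in a sequence, so stacks are bit-reproducible
from the seed.

What the simulator deliberately does **not** model: RF beamforming and
plane-wave compounding (frames are synthesised post-beamformed), bubble
resonance/destruction physics, attenuation, speed-of-sound aberration,
elastic walls, or red-blood-cell crowding. Passing tests therefore
demonstrate the correctness of the analysis chain under idealised
image-formation assumptions, not robustness to every artefact of real
acquisitions.

## The ULM chain

`ulm_localize()` follows the standard processing order: 2× upsampling →
SVD clutter filter → temporal high-pass → adaptive peak detection →
weighted-centroid localization.

* **Upsampling** is deterministic bicubic (Catmull–Rom) interpolation. A
  pretrained learned super-resolution network is a drop-in alternative
  behind the same interface, but untestable weights are not part of this
  package; bicubic preserves grid geometry exactly and reproduces
  constants.
* **SVD filter.** The Casorati matrix (pixels × frames) has its first two
  singular components removed by default; these capture static and
  slowly varying clutter. The implementation obtains the top right-singular
  subspace from the frames × frames Gram matrix, which is exact and far
  cheaper than a full SVD of the tall matrix. Long acquisitions are
  processed in consecutive blocks (`block_size`), mirroring block-wise
  continuous recording.
* **Temporal high-pass.** Second-order Butterworth applied forward and
  backward (zero phase) so localizations are not delayed — a lag would bias
  every velocity. The cutoff is deliberately low, 0.01 × Nyquist (1.25 Hz
  at 250 Hz). The reasoning: a bubble crossing its own PSF (≈ 75 µm) at
  1 mm/s — the bottom of the design velocity range — produces a per-pixel
  transient concentrated around 2 Hz, so a cutoff much above ~1 Hz removes
  the slowest real flows along with the clutter. Whether the original
  processing filtered in time or space, and at what cutoff, is not
  documented; temporal filtering is standard ULM practice and the cutoff is
  configurable.
* **Detection.** Local maxima of the frame magnitude above a robust
  adaptive threshold, median + k·MAD (default k = 4). The threshold
  statistics are computed on the *signed* filtered frame, whose MAD is a
  consistent robust estimate of the noise sd (the MAD of a magnitude image
  underestimates it by about half, which floods the detector with false
  positives at moderate SNR). Minimum separation is 4 upsampled
  pixels: PSFs closer than about four pixels cannot be separated reliably,
  so among conflicting maxima only the brightest survives (ties broken by
  lexicographic (row, col) order for determinism).
* **Localization.** Intensity-weighted centroid of a 5-px window after
  subtracting the window minimum. On noise-free isolated bubbles the RMS
  error is below 0.25 upsampled px; the residual sawtooth bias of truncated
  centroids averages out of displacement-based velocities.

## Tracking and maps

Localizations in consecutive frames are paired greedily in ascending
distance order (mutual nearest neighbours), gated at twice the expected
per-frame displacement (`link_gate()`); unmatched detections start new
tracks, and a missed frame always terminates a track. Only tracks longer
than 10 consecutive frames (≥ 11 localizations, strict) enter the velocity
analysis. Step speed is Euclidean displacement × frame rate. Density maps
count localizations per upsampled cell; velocity maps average step speeds
painted along each step's Bresenham line so maps stay contiguous at
250 Hz. `velocity_profile()` averages 25 successive cross-sections
perpendicular to a channel axis.

An ungated mode (`max_link_distance = NULL`) exists because it is not
documented whether the original minimum-distance association was gated at
all.

## Saturation-time statistics

The saturation fraction in a 25 × 25 px ROI is the share of vessel pixels
(the mask of the one vessel passing through the ROI) with at least one
localization by time t, normalized by its maximum over the analysed window
(3000 frames at full scale). The curve is fit by least squares to the
single-parameter form $S(t) = 1 - e^{-t/\tau}$, so τ is the time to 63%
($1 - 1/e$) of the final value by construction; fits with $R^2 < 0.98$ are
flagged. Replicate τs are compared with an unpaired two-tailed pooled-
variance t-test at α = 0.05, and the channel-width effect is summarised as
a percent increase of the branch τ over the main-channel τ — both as the
ratio of means and per-replicate, since either average is defensible.

```{r}
t <- seq(1, 3000) / 250
fit <- fit_exponential(tibble::tibble(time_s = t,
                                      fraction = 1 - exp(-t / 2.15)))
glance(fit)
```

## Numerical and design choices

* Degenerate inputs error early with the offending field named: zero-length
  segments, angles outside (0°, 90°), empty vessel masks, non-monotone
  saturation curves, too-short stacks for the high-pass.
* The 1-parameter exponential fit is solved by golden-section search on
  log τ over a generous bracket; a grid-search oracle agrees to the grid
  resolution in tests.
* Junctions are ideal zero-length nodes; no secondary flows at bends.
* Equal-intensity detection ties and equidistant link candidates are broken
  lexicographically, making the whole chain deterministic: identical stacks
  give identical tables.
* Problem sizes in the test suite are the package's tiny scale — 64 × 64 px
  grids, 300–450-frame velocity runs, 3000-frame saturation windows in
  750-frame processing blocks — chosen so the full suite and the
  reproduction script each run in minutes while every statistical check
  retains enough events (≥ 50 tracks, ≥ 200 vessel pixels per ROI) to be
  meaningful.

## Known limitations

* The detectable-fraction and CPS-residual parameters set the density of
  localizable events; they are phenomenological, not derived from bubble
  acoustics.
* With the resistance split, a 100 µm branch off a 300 µm main receives
  1/28 of the flow; over a finite analysis window its saturation curve is
  normalized by a maximum that may precede full coverage, which compresses
  fitted τ values toward the window scale. The *direction* of the
  width effect (branch slower) is robust in simulation; its printed
  magnitude in the emulated experiments depends on the physically delivered
  split, which the resistance rule only approximates.
* Radiation-force drift and sticking are qualitative switches for testing
  the analysis chain's response (static echoes removed by the SVD filter),
  not a calibrated force model.
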