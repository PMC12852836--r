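---
title: "Models and methods behind dcpam"
author: "dcpam authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dcpam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcpam)
```

dcpam is a desk-scale, in silico counterpart of a dual-channel
optical-resolution photoacoustic microscope whose two excitation beams are
steered by opposite facets of one rotating hexagon mirror. This vignette
records the models the package implements, the conventions and defaults it
fixes, and the reasoning behind the choices that were genuinely open --
in the spirit of a methods section, so that a green test suite can be read
for what it does and does not establish.

## The scanner geometry model

A regular hexagon of circumscribed radius $R$ rotates by the scan angle
$\omega$; facet $k$ carries the outward normal at angle $\omega + 60^\circ k$
in the lab frame. The two fixed incident beams are mirror-symmetric: both
travel horizontally, on opposite sides of the polygon, offset by the same
orthogonal distance $d$ from its center *on the same lab-frame side*. The
initial angle

$$\theta_0 = \cos^{-1}(d/R)$$

is the rotation at which a vertex crosses an incident beam. With the
incidence angles $\theta_1, \theta_2$ measured from the facet normal (the
standard optics convention), a mirror-reflection ray trace yields the two
steering regimes

$$\theta_1 + \theta_2 = 60^\circ \quad (60^\circ - \theta_0 < \omega < \theta_0),
\qquad \theta_1 + \theta_2 = 120^\circ \quad (\omega \ge \theta_0),$$

with facet crossings landing exactly on the regime boundaries. Both
conventions above are forced: point-symmetric beams give
$\theta_1 = \theta_2$ identically, and measuring from the facet plane swaps
the two sums. We verified the conventions numerically before freezing them.

Three facts worth recording:

* **Operating band.** The regime sum rules characterize
  $\theta_0 \in [30^\circ, 60^\circ]$, i.e. $R/2 \le d \le R\cos 30^\circ$.
  Outside this band a beam works a different facet pair and the sums are
  no longer 60/120 (for very small $d$ both beams hit near-parallel facets;
  for $d > R\cos 30^\circ$ the beam can even miss the polygon at some
  rotations, which `channelAngles()` reports as a `"no-intersection"`
  state). The ray trace itself is valid everywhere; only the regime
  reduction is band-limited. The shipped geometry ($R = 7$ mm from the
  14-mm polygon diameter, read as circumscribed; $d = 5$ mm, a value the
  hardware description does not print) sits inside the band.
* **Facet transitions.** Scan angles at or below $60^\circ - \theta_0$
  (after reduction modulo $60^\circ$) are flagged `"facet-transition"`
  rather than classified, following the regime inequalities; geometrically
  the sum there continues the $120^\circ$ branch.
* **Angle-to-position mapping.** The focusing optics' prescription (focal
  length, working distance) is not part of the model, so
  `focusTrajectory()` normalizes the reflected-ray rotation -- linear in
  $\omega$ at twice the polygon rate while a beam stays on one facet --
  so that one full facet pass spans exactly `channelRangeMm` (14 mm per
  channel), with the pass center at the range midpoint. Channel 2 is
  mirrored so both channels raster the overlap band in the same sense.
  Likewise the rotary-arc depth distortion is a normalized cosine sagitta,
  `arcSagMm` at the pass edges (default 0.3 mm, a few hundred micrometres
  as polygon-scanner systems exhibit), zero at the center; the depth
  correction subtracts exactly this model, so the flat-target acceptance
  checks the correction machinery, not an independently derived optical
  path.

## Acquisition timing

`timingSummary()` implements the design identities: scan time
$(\mathrm{FOV}_{slow}/\Delta y)/f_B$; average fast step
$L\,f_B/f_{rep}$; B-scan rate $(\mathrm{rpm}/60)\,n_{facets}$; A-lines
per B-scan $f_{rep}/f_B$; overlap fraction $100\,\mathrm{overlap}/L$.
With the in vivo settings (22.5 mm slow FOV, 5 um step, 300 Hz B-scan
rate, 500 kHz per-wavelength repetition rate, 14 mm channel range, 4 mm
overlap) these give 15 s, 8.4 um, and a 28.6% overlap fraction; at the
motor's 10,000 rpm ceiling the six facets give a 1 kHz line rate.

The two-wavelength excitation is time-multiplexed: the 558-nm pulse lags
the 532-nm pulse by 450 ns, i.e. $\Delta t\,c = 0.675$ mm of acoustic
path at 1500 m/s -- larger than the 0.221-mm optical depth of focus, so
the two wavelengths' echoes from in-focus tissue cannot overlap within
one A-line. `ScanConfig` validity enforces this inequality (and
`overlap < channelRange`, and positivity) at construction, so an invalid
configuration fails before any simulation.

## Forward model

The acoustic pressure record of one laser pulse is modeled as

$$s(t) = \sum_z \mu_a(z)\, h(t - z/c - \delta_\lambda),$$

where $\mu_a(z)$ is the Beer-Lambert absorption profile along the beam
column, weighted laterally by a Gaussian aperture of FWHM equal to the
7.5-um lateral resolution; $h$ is the transducer impulse response, a
Gaussian-modulated sinusoid at the 30-MHz center frequency whose envelope
FWHM maps to the 33-um axial resolution (the bandwidth is otherwise
unspecified); $\delta_\lambda$ is 0 for 532 nm and the 450-ns lag for
558 nm; travel time is one-way ($t = z/c$) because the photoacoustic
source is the absorber itself. Fluence is uniform at the focal plane and
the Grueneisen coefficient is a global constant absorbed into the
amplitude units: amplitudes are relative, which is sufficient for the
sO~2~ ratio. Records are digitized at 250 MHz with sample $k$ (0-based)
at $t = k\,\Delta t_s$; the record length covers the configured depth
range plus the arc sagitta, the wavelength separation and the impulse
response tails.

`simulateScan()` rasters both channels concurrently (one facet pass per
B-scan and channel, A-lines on a uniform scan-angle grid), steps the slow
axis, applies the injected per-facet offsets/gains and the sinusoidal
in-B-scan wobble to the *actual* sampling positions while reconstruction
only ever sees the nominal trajectory, adds the arc depth offset, and
finally white Gaussian noise at a stated SNR (defined against the mean
signal power of the stack). All injected truth rides along in the
returned object.

One consequence of anchoring the record at the $z = 0$ arrival: content
shallower than the impulse-response support (about 19 samples, 0.11 mm)
has its leading pulse tail clipped by the record start, which breaks the
exact 532/558 proportionality for that A-line. The vessel generator
therefore keeps centerlines below a 0.15-mm depth floor (a reflective
random walk in depth); flat-target and point phantoms leave the depth to
the caller.

## Synthetic phantoms: the stated world

The vessel generator states, rather than fits, its world: random-walk
tubes with radii drawn from 15-60 um (tests use 30-60 um), uniform total
hemoglobin of 2.3 mmol/L (about 150 g/L whole blood) inside vessels and
zero outside, and per-vessel saturations assigned either explicitly or by
the artery/vein alternation 0.97/0.70. Tube walls carry a one-voxel
anti-aliasing ramp but hard support, so sums over a vessel are exactly
computable; generation is a pure function of the `PhantomSpec`, including
its seed. The extinction table shipped as CSV approximates a standard
tabulated hemoglobin compilation; it is configuration, not constants --
only the 532- and 558-nm rows enter the pipeline, and every round trip
uses the same table on both legs, so its absolute accuracy is not
load-bearing. Real tissue differs in ways the generator does not attempt:
no melanin or other chromophores, no fluence heterogeneity or optical
scattering, no depth-dependent attenuation, no physiological motion.

## Demultiplexing and reconstruction

Gating is surface-anchored per A-line, honoring uneven surfaces. The
surface time is the first sample of the boxcar-smoothed envelope (window
of about one pulse width) above `median + 5 MAD` of the record -- the
median term matters because the noise envelope has a positive mean, and
the smoothing keeps single noise samples from faking a surface. The
532-nm gate is $[t_{surf}, t_{surf} + W)$ with
$W = \lfloor \Delta t f_s \rfloor - g$, where the guard $g$ is the
8-sigma impulse-response extent: without it the other wavelength's pulse
tail enters the gate and biases amplitude ratios at the $10^{-4}$ level.
The 558-nm gate is the same interval after the record is advanced by the
*exact* (fractional, 112.5-sample) lag via Fourier resampling, so both
windows sample identical waveforms and no half-sample phase error enters
the ratio. The raw signal is gated first and each window enveloped
separately (FFT Hilbert): inside a gate the record is, to the pulse's
Gaussian decay, a scaled copy of the same waveform at both wavelengths,
whereas enveloping the full record first would leak the slowly decaying
($1/t$) analytic-signal tails of one wavelength into the other's window.
An A-line with no supra-threshold sample -- or an isolated too-late
crossing that leaves no room for a gate (a noise spike) -- is flagged
empty; the hard overrun error is reserved for the systemic case (more
than 20% of A-lines), which indicates a misconfigured depth range.

Depth correction removes the arc sagitta per A-line (integer part into
the surface anchor, fractional part by linear re-interpolation) and marks
the object corrected, so re-application is a no-op. Volumes assemble by
nearest-bin scatter onto a 5-um default lattice with *mean* on collisions
(keeping the forward/inverse round trip linear); dropped positions are
counted. Coordinates are x = fast, y = slow, z = depth; indices 0-based
in documentation; intervals half-open. Stitching places channel 2
`channelRange - overlap` to the right of channel 1 and blends the shared
band with a linear ramp (cosine available); outside the band pixels are
copied verbatim, so two 14-mm channels with 4-mm overlap yield exactly
24 mm. A practical note: if the lattice is much finer than the A-line
step, the empty-bin comb dominates image correlation; choose the lattice
near the average fast step (or upsample) before registering assembled
images.

## Registration, stabilization, upsampling

Facet misalignment is modeled as one rigid 2-D translation per facet --
the minimal model consistent with displaced scanning paths; gains are an
optional extension, affine transforms are out of scope. Estimation is
normalized cross-correlation with sub-pixel refinement by a local
upsampled DFT (0.02-px grid), zero-padded to linear correlation so large
shifts do not alias, after a broad Gaussian high-pass (sigma 8 px) of
both images -- without it, the coupling between an image's finite
support and its DC content skews the interpolated correlation peak by
several tenths of a pixel. Because the facets sample interleaved slow-axis
rows, the reference stack is first resampled onto the target facet's row
positions; without this, oblique vessels convert the interleave offset
into a fast-axis bias. Frame stabilization uses *phase* correlation
(sharp delta, robust to the intensity and cropping differences between
frames) against the first frame, flagging frames whose peak falls below
a confidence threshold. The residual limiter of facet registration is
structure noise -- facets genuinely see different rows -- which averages
out with field size: the parameter-recovery trials therefore use a
0.96 x 1.92 mm, 24-vessel field (64 rows per facet) at the 5-um in vivo
slow pitch, a fixture-realism choice standing in for the much larger
scenes the instrument images; the 0.5-px / 95% bar itself is untouched.

`upsampleImage()` is a classical separable cubic-spline interpolator
behind the interface where a learned upsampler could be slotted in later;
values at original sites are preserved and linear structures reproduced
exactly. It makes no attempt to reproduce a deep model's behavior.

## Spectral unmixing and region metrics

Per pixel, the two-wavelength system
$[a_{532}; a_{558}] = \ln 10 \cdot E\,[C_{HbO_2}; C_{HbR}]$ is solved
with the 2x2 molar-extinction matrix, and
$sO_2 = C_{HbO_2}/(C_{HbO_2}+C_{HbR})$, clipped to $[0,1]$. The $\ln 10$
base-10 convention factor is applied explicitly for consistency with the
forward model; it cancels in the ratio. The validity mask requires
supra-threshold amplitude at both wavelengths (3 background MADs by
default) and positive total hemoglobin; a configurable scalar on
$a_{558}$ absorbs any dual-wavelength pulse-energy imbalance (1 by
default, as the simulator is balanced). `regionMetric()` reports masked
means per frame: mean envelope amplitude as the perfusion proxy (other
statistics are easily built on top), mean valid sO~2~ for saturation.

Per-vessel recovery is measured on *eroded exclusive* masks
(`vesselProjectionMasks()`): pixels whose phantom column contains one
vessel only, at least 40 um from any other vessel's projection, so the
lateral-aperture blur of a neighbor with different saturation cannot
contaminate the measurement.

## What the green suite establishes -- and what it does not

The tests establish that the steering geometry reproduces the regime
sums and a brute-force ray trace to $10^{-9}$ degrees inside the
operating band; that the timing identities hold symbolically; that the
full simulate-reconstruct-unmix chain is the identity on assigned
per-vessel sO~2~ to $10^{-6}$ noise-free and to 0.02 at 20-dB SNR; that
depth correction flattens a full facet pass to under the 33-um axial
resolution; and that facet offsets up to +-10 px are recovered within
0.5 px in at least 95% of seeded trials. They do not establish anything
about real tissue: the animal physiology the instrument was built for
(hypoxia cycles, perfusion redistribution, light-induced sO~2~ rises) is
outside the model, and is covered only by the surrogate check that
region metrics faithfully track injected step changes in simulated time
series.

## Known limitations

* No optical fluence model, scattering, or acoustic attenuation; no full
  wave propagation. Amplitudes are relative.
* The angle-to-position and arc-sagitta mappings are normalized, not
  derived from a lens prescription (none is available).
* Content shallower than the impulse-response support is clipped at the
  record start (see the depth floor above).
* The learned upsampler of the original processing chain is replaced by
  splines behind the same interface.
* Persistence uses RDS/TSV/JSON rather than HDF5/TIFF containers, which
  the available toolchain does not guarantee.
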