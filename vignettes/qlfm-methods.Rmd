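---
title: "Complete-space multiscale scattering reconstruction for light-field microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complete-space multiscale scattering reconstruction for light-field microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(qlfm)
```

This vignette documents the science in `qlfm`: the forward model and its
assumptions, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Imaging model

A light-field microscope inserts a microlens array (MLA, pitch $p$, focal
length $f$) at the image plane of a wide-field fluorescence microscope and
relays the MLA back focal plane onto the camera. Each microlens covers an
odd number of sensor pixels per axis (`pixels_per_lens`, 13 for the
reference 40x/1.0 NA geometry), and pixel realignment regroups the raw
frame into phase-space views $y_{uv}$ — one image on the microlens grid
per angular component $(u, v)$. Realignment with integral lens origins is
a pure permutation, so photon counts are conserved exactly; fractional
origins are handled by bilinear resampling (monotone and
non-negativity-preserving, chosen over cubic for exactly those two
properties).

The measurement model is linear in the volumetric emission density $I$
(units: photons per µm³ per exposure, up to a global gain):

$$y_{uv} = \sum_z H_{uv,z} * \big[(I_z + S_z)\,\Delta V_z\big],$$

where $H_{uv,z}$ is a lateral convolution kernel per angular component and
depth (the *phase-space PSF*) and $S$ is scattered light (Section 3).
Using per-angle, laterally shift-invariant kernels on the lens grid is the
phase-space approximation: spatial variation of the PSF *within* a
lenslet is absorbed into the angular index, which is exactly what makes a
lateral sampling interval of one lens pitch (2.15 µm at the sample for the
reference geometry) sufficient — a dense camera-pixel-rate grid, as
required by spatially variant single-scale models, is never formed.

### Effective magnification

The nominal 40x objective maps the 100 µm pitch to a 2.15 µm sample-plane
cell, i.e. an effective magnification of ~46.5x. Because this mismatch
between nominal and effective magnification is common (tube-lens focal
lengths differ between vendors), `optical_config()` carries
`effective_magnification` as an explicit field used by both the PSF model
and the realignment geometry; the nominal magnification is only used for
the NA-matching sanity check ($\mathrm{NA}/M \approx p/2f$ within 20%,
warning only).

## 2. Phase-space PSF

Near focus the kernels come from scalar wave optics:

1. pupil field $P(\rho) = \exp\!\big[i(\phi_{\mathrm{defocus}} +
   \phi_{\mathrm{aberration}})\big]$ on the disk $\rho \le 1$, with
   $\phi_{\mathrm{defocus}} = k n z \sqrt{1 - (\mathrm{NA}\rho/n)^2}$ and
   the aberration phase a Noll-indexed Zernike expansion (coefficients in
   emission wavelengths; piston ignored);
2. Fourier transform to the image plane, multiplication by the tiled
   thin-lens quadratic phase of the MLA (100% fill factor, square
   apertures — the instrument specification gives only pitch and focal
   length, so an ideal thin lens is assumed);
3. Fresnel propagation over one MLA focal length to the sensor plane;
4. squared modulus, box integration over camera pixels (3x3 sub-samples
   per pixel by default), and realignment into per-angle kernels.

Intensities of distinct source points add (incoherent imaging), so these
kernels fully specify the linear forward operator.

The simulation grid spans `sim_lenses` lenslets (default 31; the pupil
diameter is then sampled by roughly 120–250 frequency samples depending on
the configuration — kernels change by well under 1% when the grid is
enlarged further). The wave path is used for $|z| \le z_{\mathrm{wave}}$,
chosen automatically so the geometric blur fits comfortably inside the
simulated field of view. Beyond it, the blur diameter (over 100 µm at
$|z| > 100\ \mu m$ for NA 1.0) dwarfs both diffraction and the kernel
sampling interval, and each angular component reduces to its geometric
sub-aperture image: a Gaussian at displacement $z \tan\theta_{uv}$ with
width $|z|\,\sigma_{\tan}$ plus a diffraction floor, weighted by the pupil
area of the patch. Patch moments ($\tan\theta_{uv}$, $\sigma_{\tan}$,
weights) are computed numerically over each pupil patch clipped by the
pupil rim — edge patches are pulled inward exactly as the wave model shows.
Far-field kernels are generated natively at the coarse slab sampling
(band-limited by construction) rather than by downsampling fine wave
kernels, which would require an impractically large simulated sensor.

Energy bookkeeping: per-depth kernel totals are normalized to the
in-focus total and stay within $[0.9, 1.0]$ of it across the complete
space (asserted in the tests).

Two caveats worth knowing. First, exact point-wise mirror symmetry between
$+z$ and $-z$ holds only approximately: the MLA quadratic phase is
traversed before the intermediate focus on one side and after it on the
other, so the diffraction detail differs by ~10–15% at moderate defocus
even though per-view energies and centroid geometry mirror correctly.
Second, the model is scalar: no polarization, no field-dependent
aberrations, no coherence.

## 3. Incoherent first-Born scattering

Scattered photons are modeled as a single-scattering (first Born)
redistribution of emitted light,

$$I^{(s)}(\mathbf r) = \tfrac12 \int F(\mathbf r')\, I(\mathbf r')\,
\frac{1}{\lVert \mathbf r - \mathbf r' \rVert^2}\, d^3 r',$$

with $F \ge 0$ the scattering potential; scattered light is imaged through
the same PSF as direct fluorescence (it is ordinary fluorescence by the
time it reaches the objective) and is never re-scattered. Discretely this
is a 3D convolution of $F \cdot I \cdot \Delta V$ with
$1/\lVert\Delta\mathbf r\rVert^2$; the singular self-voxel takes the
kernel value at half the voxel diagonal, which keeps the operator finite
and grid-convergent, and the kernel is truncated where it falls below
$10^{-4}$ of its nearest-neighbour value. On a uniform grid the FFT
implementation matches direct double summation to $10^{-6}$ relative
(tested on $8^3$); on multiscale grids the product is evaluated on a
uniform auxiliary grid (lateral factor 2, twice the fine axial step) with
mass-preserving resampling both ways.

An identifiability caveat: $F$ enters only through the product
$F \cdot I$, so the potential is unobservable wherever the emission is
(near) zero. In a sparse bead phantom no estimator can recover a
volume-wide $F$ map; the parameter-recovery test therefore uses a phantom
with emission support everywhere (a uniform offset plus beads) and
verifies that ten projected-gradient updates recover a smooth $F$ blob
with correlation above 0.8. In the joint reconstruction, $F$ functions as
a physically structured absorber of the scattered halo rather than as a
quantitatively calibrated map.

## 4. Multiscale complete space

Both lateral and axial LFM resolution degrade with distance from the
native objective plane; the grid follows an exponential fit
$R(z) = \alpha e^{\beta |z|} + \gamma$ to FWHM-vs-depth curves. The
default curves are generated from the instrument's own sub-aperture
geometry — near-focus widths floored at twice the lens sampling (the
native sampling limit), far-field growth at the sub-aperture cone angle —
sampled densely near focus and over about four doubling depths, and
fitted with relative weights so $R(0)$ is tight. This is the far-field
envelope of the simulated PSF's width curve and avoids a wave-optics sweep
at grid-build time.

Slabs tile the axial range with no gaps; the sampling interval is $R/2$
(Nyquist with respect to the modeled resolution), transitions occur only
at power-of-two ratios, and the interval may double at most once per
transition. Power-of-two ratios make resampling exact for constant fields
and cheap in general; interpolation is mass-preserving (the forward model
sums photons) with coverage-weighted averaging at footprint edges so
constants survive grid changes. For the 40x geometry over ±500 µm the
multiscale grid holds under 10% of the voxels of the dense single-scale
grid (camera-pixel lateral sampling, fine axial step everywhere) that a
spatially variant PSF model would require.

## 5. Reconstruction

The emission update is multiplicative (Richardson–Lucy):

$$I \leftarrow I \cdot
\frac{B_u\!\big[y_u / (A_u I + b_u + \varepsilon)\big]}{B_u[\mathbf 1]},$$

with $A_u$/$B_u$ the per-angle forward/adjoint operators (the adjoint is
the exact transpose of the discrete forward model — verified to
$10^{-16}$ — which the multiplicative normalization relies on),
$b_u$ the PSF-imaged scattered contribution of the current $(I, F)$, and
$\varepsilon = 10^{-8} \max y$ a division guard. Updates are cycled over
angular components in a center-out spiral (low-angle views carry most
energy and stabilize early iterations; the ordering changes early
iterates, hence it is fixed and documented). Sequential cycling can
oscillate on data dominated by out-of-focus background — each angle then
rescales the whole volume in turn — so every cycle is accepted only if the
Poisson loss does not increase; on an increase the cycle is redone with
the simultaneous all-angle update (classical RL, monotone) and the run
stays in that mode. The initial iterate is the non-negative
back-projection of the views scaled to total counts.

The joint problem alternates (a) RL emission cycles with the scattered
background held fixed, (b) one backtracking projected-gradient step on
$\lVert A(I + S(I,F)) - y\rVert^2 + \lambda_F \lVert F\rVert^2$
($\lambda_F = 10^{-3}$ by default), and (c) scaled-dual non-negativity
consensus with penalty $\rho = 1$ — largely inert here because both
updates already preserve feasibility, but kept so the splitting is
explicit and tunable. The outer data misfit is monitored; an iterate that
increases it is rejected, and three consecutive rejections abort with
diagnostics. Whether the emission update should be Poisson (RL) or
least-squares inside the splitting is genuinely open; RL was chosen for
its built-in positivity, and the least-squares path exists internally via
the same projector.

### Axial scanning

Scanned acquisitions are treated as one inverse problem: a single global
multiscale grid spans all scan positions plus out-of-focus margins, the
forward model for scan position $s$ uses depth-shifted kernels
($z \to z - s$), and each *angular focal stack* — one angular component
across all scan positions — is the unit over which the RL error map is
aggregated. No per-position sub-volumes are reconstructed or stitched,
which is what removes stitching artifacts and intensity seams. A scan
step much larger than the high-resolution axial range triggers a warning.
The scattering update inside the scanned loop uses the frame nearest
focus only (a cheap, backtracking-guarded choice). With a single
unshifted frame the routine reduces exactly to the snapshot
reconstruction.

## 6. Aberration calibration

A wavefront error $W$ (in wavelengths) tilts each pupil sub-aperture
locally and displaces that angular view by
$\Delta x = -(\lambda/\mathrm{NA})\, \partial W/\partial \rho$ µm at the
sample plane (Fourier shift theorem applied to the windowed pupil).
Calibration inverts this: per-angle displacements between the captured
bead views and the simulated PSF (normalized cross-correlation, integer
search plus parabolic sub-pixel interpolation; angles with peak
correlation below 0.2 are excluded, and at least 60% must survive) are
zonally integrated by least squares on the angular lattice, the mean
displacement is removed first (a global translation is indistinguishable
from bead position), piston is removed after, and the zonal surface is
fitted with Noll modes 1..15 (through secondary spherical) by default.

The fit is fed back into the wave-optics model and the loop repeats. Two
stabilizers matter: corrections are damped by a gain of 0.7 (the raw
fixed-point iteration has loop gain slightly above one for low-order
modes and oscillates), and iteration stops either when the RMS Zernike
change drops below $\lambda/50$ or when the mean per-angle correlation —
which is monitored every iteration — passes its peak, in which case the
previous iterate is returned. On synthetic frames with 0.3 waves of
astigmatism and 0.5 waves of spherical aberration this converges in four
iterations with both coefficients recovered within 15% (asserted in the
acceptance tests); tip/tilt are reported but excluded from the PSF model
since they only translate the image.

## 7. Synthetic data

The generator emulates the validation experiments end to end:
fluorescent beads (spheres rendered with exact axial chords and
supersampled lateral occupancy, so per-bead mass matches the analytic
integral within 2%) placed uniformly at random in the fine region; a
smooth non-negative scattering potential (low-pass-filtered Gaussian
noise scaled to a mean level, default 0.05); a nonuniform out-of-focus
background confined to the coarse slabs (default density 2% of the bead
interior — individually dim voxels whose integrated mass exceeds the bead
mass by two orders of magnitude, as in densely labelled tissue); and the
capture chain forward projection → inverse realignment → Poisson shot
noise → Gaussian read noise (default 1.6 counts, a typical sCMOS figure).

For the signal-to-background study the ground truth is generated on its
own grid with lateral factors capped at 2, so the background carries
lateral structure that neither reconstruction grid trivially represents —
real out-of-focus tissue is not aligned with anyone's reconstruction
grid. The study conditions are: 15×15 lenses with 5×5 angular components,
ten 2 µm beads within ±60 µm, background slabs to ±300 µm, brightest
sensor pixel at 1000 counts. Signal ROIs are 8×8×10 µm³ boxes at the true
bead positions; the background ROI is the candidate position farthest
from every bead within the bead-bearing axial range (±0.9 of the fine
half-range) — "background without samples", measured where the samples
live. Both reconstructions use 4 outer × 12 inner iterations; the
reported quantity is the ratio of SBRs.

What passing these tests does *not* show: the generator contains no
biological structure (vasculature, neurites), no depth-dependent
attenuation, no anisotropic phase function (the inverse-square kernel is
isotropic), no sample motion, and the capture simulator shares its PSF
code with the reconstruction (a deliberate inverse-crime component that
isolates the *model-class* comparison — complete vs incomplete space —
from PSF mis-calibration, which is exercised separately by the
calibration tests).

## 8. Numerical choices and problem sizes

* Convolutions: FFT with zero-padding to the full linear-convolution size
  (sizes rounded up to products of 2·3·5); boundary condition is zero
  outside the field; kernel FFTs are precomputed per (plane, angle).
* All stacks on disk are 32-bit TIFF samples in [0, 1] with a
  power-of-two scale in a JSON sidecar; storage quantization is
  $2^{-32}$ of the scale.
* Degenerate inputs: all-zero views return a zero volume with a warning;
  zero-variance series make the Pearson correlation error; flat profiles
  make the FWHM error; a zero-background SBR is flagged infinite rather
  than crashing.
* Test problem sizes were chosen as the smallest that still exercise
  every mechanism: 15×15 lenses, 5×5 angles and ≤ 60 axial planes for
  reconstruction; 13×13 angles for calibration (low-order Zernike modes
  need the angular resolution); the full SBR study runs in a few minutes
  on one CPU.

## 9. Known limitations

* The phase-space (per-angle shift-invariant) approximation discards
  sub-lenslet spatial detail; resolution is bounded by the lens pitch at
  the sample plane.
* Single scattering only; no anisotropy; $F$ is a nuisance field rather
  than a calibrated material property (Section 3).
* The exponential resolution model is a fit, not a law; its main job is
  to place slab transitions, and the grid API accepts measured FWHM
  curves (`fit_resolution_model`) when characterization data exist.
* ADMM here is an alternating scheme with inexact proximal steps; it
  inherits RL's slow convergence for weak features on strong backgrounds,
  and the iteration counts in `recon_options()` trade accuracy for time.
* Aberrations are assumed constant across the field of view.
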