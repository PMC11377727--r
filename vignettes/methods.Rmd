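---
title: "Methods: wavelength-scanning diffraction tomography in wstomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelength-scanning diffraction tomography in wstomo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wstomo)
```

This vignette records the mathematical conventions, parameter defaults,
generator design, and numerical choices behind `wstomo`, so that every
number the package produces can be traced to a stated rule. It is the
methods companion to the reference manual; the worked end-to-end example
lives in the README.

## 1. Physical model and conventions

### Units and frequency convention

All lengths are in micrometres (µm). Spatial frequencies use the
*reduced* convention, in cycles per µm: a plane wave is
$\exp(2\pi i\,\mathbf{k}\cdot\mathbf{r})$ and the wavenumber of the
immersion medium is $k_m = n_m/\lambda$ (no factor of $2\pi$ inside
$k$). Every occurrence of a frequency in the package — grid spacings
`dk = 1/(N·pitch)`, the Ewald radius `ewald_radius()`, propagation
kernels — follows this convention, and factors of $2\pi$ appear
explicitly in phases.

### Scattering potential

The object is described by its refractive index $n(\mathbf{r})$ in a
medium $n_m$. The scattering potential is Wolf's object function

$$V(\mathbf{r}) = \left(\frac{2\pi}{\lambda}\right)^2
  \bigl(n^2(\mathbf{r}) - n_m^2\bigr),$$

implemented by `scattering_potential()`. $V$ depends on $\lambda$ only
through the $(2\pi/\lambda)^2$ prefactor, so a dispersion-free sample
needs a single 3D FFT; per-wavelength spectra are rescalings of it
(`simulate_scan()` exploits this, and `wavelength_transition()` is the
corresponding exact $(\lambda_i/\lambda_{i+1})^2$ map between
wavelengths, an exact group action with no interpolation).

### Fourier transforms

All transforms are *centered*: `ft_nd(x, pitch)` computes
`fftshift(fft(ifftshift(x))) * prod(pitch)` so that the DC bin sits at
index `N %/% 2 + 1` on every axis and the transform approximates the
continuous integral (the `prod(pitch)` factor carries the volume
element). `ift_nd` is its exact inverse. Grids therefore must have even
dimensions, which `frequency_grid()` enforces.

### Ewald-shell geometry

Under on-axis plane-wave illumination at wavelength $\lambda$, the first
Born/Rytov scattered field at the detector constrains the object
spectrum $\hat V$ on a *shifted semi-spherical cap*: the set
$\{(k_x, k_y, k_z - k_m)\;:\;k_x^2+k_y^2+k_z^2 = k_m^2,\;k_z>0\}$.
`build_shell()` samples this cap on the lateral frequency grid: every
in-support lateral sample $(k_x,k_y)$ with $k_T = \sqrt{k_x^2+k_y^2} <
k_m$ gets the exact axial coordinate $k_z = \sqrt{k_m^2 - k_T^2}$, used
*exactly* in all phase factors, and is assigned to the *nearest axial
voxel* only for 3D indexing. Because each lateral sample has a unique
$(k_x,k_y)$ index pair, target voxels never collide on this geometry;
the averaging path in `remap_to_shell()` (weighted by multiplicity) is
nevertheless implemented and tested, as the correct contract should a
future geometry introduce collisions.

The field-side mapping carries the envelope prefactor

$$\frac{i}{4\pi k_z}\,\exp\!\bigl(2\pi i (k_z - k_m)\, z_D\bigr),$$

relating a shell sample of $\hat V$ to the 2D lateral spectrum of the
*envelope* of the first-order scattered field at defocus $z_D$ (the
carrier $\exp(2\pi i k_m z)$ is divided out everywhere, which keeps
phases slowly varying on the grid). The $+i$ sign is fixed by the
package's $\exp(+2\pi i \mathbf{k}\cdot\mathbf{r})$ forward-transform
convention; the DC limit $i/(4\pi k_m)$ is pinned by a unit test.

### Rytov intensity and the measurement

The total field is modelled as $U = U_{in}\exp(U_{s1})$ with complex
Rytov exponent $U_{s1}$; with a unit-normalized input field the
intensity is $I = \exp(2\,\mathrm{Re}\,U_{s1})$ (`rytov_intensity()`).
Phase of $U_{s1}$ is invisible in intensity — the fact the iterative
solver must overcome. The sensor under-samples: `bin_pixels()` averages
$s\times s$ blocks of the high-resolution intensity (the
pixel-super-resolution, PSR, forward operator).

## 2. The inverse solver

`wsfpdt()` implements the iterative non-interferometric reconstruction:

1. Initialize $\hat V \equiv 0$ (medium everywhere) and a zero fill
   weight (`init_spectrum()`).
2. For each scheduled wavelength: *extract* the current shell estimate
   into a high-resolution field (`first_order_field()`), form the model
   intensity, and apply the intensity constraint
   (`intensity_constraint()`): the measured sensor-pitch amplitude
   replaces the binned model amplitude with relaxation $\alpha$,
   distributed back to the fine grid as a multiplicative per-block
   amplitude correction, so the model's intra-block structure is kept —
   this is where resolution beyond the sensor pitch is recovered.
   At $\alpha = 0$ the constraint is the identity; consistent data are a
   fixed point. Phase is always kept from the model.
3. *Remap* the corrected field onto the shell (`remap_to_shell()`,
   dividing out the envelope prefactor), overwriting shell voxels and
   incrementing the fill weight.
4. Transition the spectrum to the next wavelength
   (`wavelength_transition()`) and continue; multiple passes sweep the
   schedule repeatedly, stopping early when the median residual improves
   by less than $10^{-3}$ relatively.

Because frames are matched to the schedule by wavelength, the input
order of frames is irrelevant (tested bit-exactly).

### Missing-cone regularization

On-axis transmission leaves a cone of low-axial-frequency voxels
unmeasured, causing axial elongation and refractive-index
underestimation. `hybrid_fill()` runs a Gerchberg–Papoulis loop: inverse
transform, apply non-negativity of the real contrast
(`nonneg_project()`) and a few sweeps of gradient-descent total
variation denoising (`tv_denoise()`), forward transform, and *re-impose
the measured shell voxels bit-exactly* (only unmeasured voxels are ever
filled in). Fidelity to data is therefore exact by construction, and
each pass can only act on the missing region.

The recovered potential is finally converted to refractive index via
$n = \sqrt{n_m^2 + \mathrm{Re}(V)\,(\lambda_{ref}/2\pi)^2}$, clipping
negative radicands to $n_m$ and flooring at 1; the ratio of imaginary
to real contrast is reported as a model-consistency diagnostic
(`$im_ratio`).

## 3. Preprocessing

`normalize_intensity()` divides a frame by its border-median background,
so unit background is restored exactly for frames whose margin is
object-free; it is idempotent.

`autofocus()` estimates $z_D$ by back-propagating the *contrast
hologram* $\sqrt{I/I_{bg}} - 1$ (background = border median) with the
envelope angular-spectrum kernel over a scan of distances and maximizing
the Tamura coefficient (sd/mean) of the gradient magnitude — an
edge-sparsity sharpness score that peaks where the twin-image fringes
collapse. Criteria based on minimizing sharpness of the raw amplitude
were found to drift monotonically over wide scan ranges and were
rejected; the contrast-hologram maximization is stable over a 300–750 µm
scan in the tests. The score is scale-invariant by construction.

## 4. Phantoms and generator realism

- `bead_phantom()` voxelizes spheres by exact center-distance
  thresholding; a 20-voxel-diameter bead matches the analytic
  $\pi d^3/6$ volume within 2%. Beads must fit the volume and exceed
  twice the voxel pitch (sampling floor).
- `usaf_phase_target()` draws three-bar USAF-1951 elements with the
  standard line-width law $w = 500\cdot 2^{-(G+(E-1)/6)}$ µm
  (`usaf_linewidth()`), as a thin phase slab of selectable thickness,
  contrast, and tilt (≤ 45°); tilting distributes bar voxels across
  axial slabs by rotating the slab's plane.
- `cell_phantom()` places non-overlapping cell-like bodies with nucleus
  and cytoplasm contrast at three morphological stages (I: spherical,
  II: elongated/budding, III: strongly aspherical), seeded and
  deterministic, with a per-cell analytic annotation (centers, volumes,
  sphericity) used as ground truth by the morphology tests.

## 5. Metrics and calibrations

- `fwhm()` measures full width at half maximum by linear interpolation
  of the half-crossings; `moment_elongation()` is the intensity-weighted
  second-moment anisotropy $\sqrt{\sigma_z^2/\bar\sigma_{xy}^2}$. The
  acceptance criterion for de-elongation uses the moment metric because
  the unregularized axial profile is oscillatory, which makes a
  central-lobe FWHM ratio uninformative there.
- `throughput_numbers()` evaluates the closed-form field-of-view,
  Nyquist ratio, voxel volume, imaged volume and effective-voxel
  figures from the five printed inputs.
- `cell_morphology()` labels connected contrast components (6-connected
  flood fill), reports volume, surface area and sphericity
  $\Psi = \pi^{1/3}(6V)^{2/3}/A$ with $A$ estimated by exposed-face
  counting, and assigns stages by thresholding $\Psi$.

**Stage-cut calibration.** Face-counting overestimates the area of
smooth surfaces (a digitized ball measures $\Psi \approx 0.68$, not 1 —
the staircase bias; a unit cube is exact at $\Psi = 0.806$). The stage
thresholds (I ≥ 0.62 > II ≥ 0.45 > III) are therefore calibrated against
digitized reference shapes under the *same* estimator, not against
analytic sphericity. An optional axial-elongation correction divides
the axial extent by a supplied factor before volume reporting.

## 6. Tiling and stitching

`plan_tiles()` covers a large sensor frame with fixed-size tiles at a
minimum overlap, flush at both ends, distributing surplus overlap one
pixel at a time to the earlier gaps. `alpha_blend()` recombines
reconstructed tiles with separable linear ramps over the actual
overlaps, forming an exact partition of unity — tiles cut from one
ground truth reassemble to it to $10^{-10}$, in 2D and layer-wise in 3D.

## 7. Parameter defaults

`scan_config()` encodes the platform defaults: 57 wavelengths spanning
0.43–1.20 µm, medium index 1.33, sensor pitch 1.67 µm, upsampling
$s = 4$ (axial step `dz = sensor_pitch/4`), defocus 414 µm, relaxation
$\alpha = 0.5$, 4 outer passes, 20 regularization passes (TV weight
0.002, 5 inner iterations, non-negativity on), 500-pixel tiles with
50-pixel minimum overlap, and optional Poisson + Gaussian-read noise
(photon budget 10 000, read sd 2 counts) under a recorded seed.
Configurations load from YAML or JSON (`load_config()`), with
`wavelengths_nm` converted to µm and unknown keys warned about;
validation aggregates all violations into one message.

## 8. Numerical choices and limitations

- **Exact $k_z$, nearest-voxel indexing.** Phases use the exact cap
  coordinate; only the 3D *index* is rounded. This preserves the defocus
  phase to machine precision at the cost of a sub-voxel axial assignment
  error bounded by `dk_z/2`.
- **Truncated caps warn.** If the axial frequency extent cannot hold the
  full cap (coarse `dz` or short volumes), the out-of-range samples are
  dropped with a warning rather than wrapped.
- **Periodic wrap-around.** The FFT-based forward model is periodic in
  all three axes; fields diffracted past the lateral boundary re-enter
  on the opposite side. Keep objects small relative to the field of view
  (as the tests do) or tile with sufficient margin. No guard band is
  added implicitly.
- **Weak-scattering validity.** The model is first-order (Rytov);
  strongly scattering or optically thick objects violate it, and the
  residual and `im_ratio` diagnostics are the indicators to watch.
- **Evanescent cutoff.** Propagation kernels zero out growing evanescent
  components; lateral frequencies beyond $k_m$ carry no information and
  are excluded from every shell.
- **Volume I/O.** Volumes are stored as 32-bit-float multi-page TIFF
  with a JSON sidecar. TIFF float samples are only well defined in
  $[0,1]$, so an affine map of the data is stored and the offset/range
  recorded in the sidecar (`data_min`, `data_range`); readers invert it.
  Complex volumes interleave real/imaginary pages. 16-bit intensity
  stacks record their quantization scale so normalization is exactly
  invertible.
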