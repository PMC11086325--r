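---
title: "Simulating and benchmarking large-dynamic-range Shack-Hartmann ocular aberrometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and benchmarking large-dynamic-range Shack-Hartmann ocular aberrometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A Shack-Hartmann wavefront sensor (SHWFS) samples an incoming wavefront with
a square array of small lenses. Each lenslet focuses its patch of the
wavefront to a spot on a detector, and the spot's displacement from the
lenslet's optical axis is proportional to the local wavefront slope. The
classical reconstruction pipeline — per-sub-aperture centroiding followed by
a least-squares modal fit of Zernike coefficients — is accurate while every
spot stays inside the detector cell assigned to its lenslet. Human eyes,
however, routinely carry enough defocus and astigmatism to push spots across
cell boundaries (or off the detector entirely), at which point centroids are
attributed to the wrong lenslet and the classical fit collapses. The
dynamic range of the sensor, not its sensitivity, is then the binding
constraint for ocular aberrometry.

`shwfsr` implements the full study of this problem: a physical-optics
simulator of the sensor, statistical generators of ocular and turbulent
aberrations, the classical reconstructor, a convolutional network that
regresses Zernike coefficients directly from the raw spot pattern (and so
has no concept of a "home cell" to violate), and a protocol that measures
the dynamic range of any reconstructor and the relative improvement of one
over another.

## Wavefront representation

Wavefronts are expanded in Zernike polynomials on the unit disk under
OSA/ANSI single indexing with Noll normalization, so the disk average of
$Z_j^2$ is 1 and the wavefront RMS is simply the Euclidean norm of the
coefficient vector. The working set is $j = 1..44$ (radial orders 1-8, 44
output channels of the network); piston is excluded, and tilt/tip are
modeled and fitted but excluded from reported RMS values, the convention for
quoting ocular aberrations. Coefficients are in waves at 840 nm throughout.
Modes are stored internally as exact bivariate monomial expansions, which
makes evaluation and analytic differentiation exact everywhere including
the pupil center.

## The forward model

The simulated field starts as $U_0 = \exp(i 2\pi W) P$ on an oversampled
grid spanning the lenslet-array aperture ($P$ the pupil function),
propagates to the lenslet array, is multiplied by the tiled per-lenslet
thin-lens phase $\exp(-i k r_\mathrm{loc}^2 / 2f)$, propagates one focal
length to the detector, and is recorded as $|U|^2$, binned to detector
pixels. Key numerical choices:

* **Propagator.** Fresnel propagation is implemented in transfer-function
  (angular-spectrum) form, which preserves the sample pitch and is exactly
  unitary; its sampling condition $\lambda f / L < \Delta x$ holds for all
  shipped geometries at the default 2x oversampling. It is verified against
  the closed-form Gaussian-beam pair in the tests.
* **One coherent field.** All lenslet contributions are summed coherently,
  so cross-talk and interference between neighbouring spots are part of the
  rendered image, exactly as in the instrument.
* **Padding and cropping.** The propagation window is zero-padded beyond
  the detector by an estimate of the worst-case ray displacement, so spots
  that leave the detector are cropped (as in the instrument), never wrapped
  around by the FFT. The retained energy fraction is recorded on every
  rendered image.
* **Nyquist guard.** The maximum per-sample wavefront increment is checked
  on every render; a violation doubles the oversampling (up to a bound)
  rather than silently aliasing. Strong defocus at the full 6 mm pupil is
  exactly the case that trips this.
* **Pupil conjugation.** The geometry parameter `aperture_to_mla_mm`
  controls the free-space distance between the pupil plane and the lenslet
  array. The default is 0: relay optics conjugate the eye pupil onto the
  lenslet array, which is how ophthalmic aberrometers are built. A nonzero
  distance inserts a real Fresnel step; under defocus this magnifies or
  shrinks the beam by $1 - z/R_c$ (beam curvature radius $R_c$), a
  systematic response change that any slope-calibrated reconstructor then
  misreads. We verified this effect quantitatively (it is exactly the
  curvature magnification predicted by Gaussian optics) and chose the
  pupil-conjugate layout as the default study condition, because it is the
  configuration in which the textbook spot-displacement relation
  $\Delta = f \lambda \nabla W$ — the basis of every classical calibration —
  is exact.
* **Pupil shape.** The default circular pupil leaves the boundary lenslets
  partially illuminated; diffraction from the pupil edge biases their spot
  centroids by up to a few tenths of a pixel. This is physics, not
  estimator error, so the symmetric "all spots centered to 0.05 px" checks
  run on the fully illuminated square-aperture configuration
  (`pupil_shape = "square"`) and on sub-apertures at least two rings from
  the illumination edge, where the residual ripple is below 0.01 px.

## Aberration statistics

**Ocular population.** Ocular Zernike statistics are modeled as a 44-mode
multivariate Gaussian. The published clinical fit behind the original
study is not available, so the package ships a documented stand-in with the
qualitative structure all ocular population studies agree on: defocus
dominates (SD 3 waves at 840 nm over a 6 mm pupil, roughly a 2 D myopia
spread), astigmatism next (SD 1 wave), higher orders decaying steeply to
5e-3 waves at order 8, a slight myopic mean (-0.5 waves of defocus), small
tilt variability (SD 0.2 waves), and no inter-mode correlation. Under this
model the modes up to $Z_9$ carry more than 95% of the non-tilt power
(`order_proportion()`), which is why dynamic-range sweeps concentrate on
$Z_3$-$Z_9$. Every statistical claim in the package is conditional on this
configured model, and `read_eye_model()` swaps in any other fit.

**Turbulence.** The generalization test draws coefficients from Kolmogorov
statistics via the classical gamma-function covariance (variances
proportional to $(D/r_0)^{5/3}$; only modes sharing a signed azimuthal
frequency covary). The implementation reproduces the tabulated per-order
constants (0.448, 0.0232, 0.0062, ... rad$^2$ at $D/r_0 = 1$), which the
tests assert as an independent oracle.

## Classical reconstruction

Centroiding subtracts a configurable fraction (default 0.1) of the per-cell
maximum as background, clamps negatives, and takes the center of mass of the
46 px cell; cells whose post-threshold energy falls below 1% of the mean
cell energy are flagged spotless and dropped from the fit rather than
zero-filled. Slopes convert to normalized pupil units through
$s = d\,p_\mathrm{px} R / (f\lambda)$ and are fitted by least squares
against sub-aperture-averaged analytic mode gradients (11x11 sub-grid per
cell — point sampling at cell centers is not accurate enough at radial
order 8 on an 8x8 or 20x20 array). A fit with fewer than half the in-pupil
cells valid is returned flagged low-confidence instead of erroring: a
failing sensor must still produce its (wrong) answer so the dynamic-range
protocol can observe the failure.

## The convolutional regressor

The network is a ConvNeXt-style regressor: a patchify stem, four stages of
inverted-bottleneck blocks (depthwise 7x7 convolution, layer normalization
over channels, pointwise expansion x4, GELU, pointwise projection, residual
with a learned per-channel scale), patch-merging downsampling between
stages, global average pooling, and a 44-channel linear head. Two profiles
are configured: `"paper"` (depths 3:3:9:3, widths 96/192/384/768, 200 px
input — the full-scale recipe, constructible and trainable but sized for
GPU-class hardware) and `"desk"` (2:2:4:2, 32/64/128/256, 64 px input),
which all shipped experiments use. The implementation is native R/Rcpp with
hand-written backpropagation, verified against finite differences in the
test suite.

Training uses AdamW (decoupled weight decay on weights only, default 0.05)
with a per-epoch cosine schedule decaying to $10^{-6}$ of the initial rate,
batch size 8, mean-squared coefficient error as the loss, shuffled training
and validation order, and a best-validation checkpoint. Two additions make
small-data CPU training stable and are the package's own engineering
choices: an optional linear learning-rate warmup (a few epochs), and
per-mode label standardization (stored in the fit and undone automatically
at prediction). Standardization matters because the physical coefficient
variances span three orders of magnitude between defocus and order-8 modes;
it changes the optimization path, not the minimizer. The desk recipe used
by the experiments is lr0 = 1e-3 with 2-10 warmup epochs; the full-scale
profile documents the published recipe (lr0 = 3e-4, 500 epochs).

## Dynamic-range protocol

For a reconstructor and a single mode $j$, the protocol renders $a_j = a$
(all other modes zero), reconstructs, and records the residual wavefront
RMS (tilt/tip excluded). A coarse scan (default 0.5-wave steps) from zero
finds the first amplitude whose residual exceeds the threshold, and
bisection narrows the bracket to $10^{-3}$ waves. The threshold is the
protocol's literal constant 0.0894 waves — the Marechal criterion $1/14$
with a 25% tolerance, as printed in the source study. The first-crossing
convention resolves non-monotone residual curves: dynamic range means the
largest amplitude below which measurement is *continuously* reliable. A
reconstructor that never fails inside the scan bound is reported unbounded
at `a_max`. Improvements are quoted as
$\delta_{DR} = (CV_\mathrm{cand} - CV_\mathrm{ref})/CV_\mathrm{ref}$,
comparing magnitudes per direction against the first (baseline)
reconstructor of a sweep.

The geometric failure oracle used to validate the protocol is the
half-pitch crossing: the modal method's defocus critical value should sit
near the amplitude at which the outermost in-pupil cell's predicted spot
displacement equals half the cell pitch (23 px at 46 px cells). The
crossing amplitude itself is sign-symmetric, but the measured critical
values are not exactly so: converging (negative) defocus pushes the
crossing spot into an *occupied* inner cell and corrupts two slope
measurements at once, while diverging defocus pushes it into a dark
out-of-pupil cell. The negative direction therefore fails somewhat earlier
(we measure about 2.5 vs 2.0 waves at the 8x8 mini geometry, both within
15% of the geometric oracle), and the package validates each direction
against the symmetric oracle rather than demanding mutual symmetry.

## Study conditions and scale

The shipped experiments run at three geometry profiles:

| profile | lenslets | cell px | detector | used for |
|---|---|---|---|---|
| `table1` | 20x20 | 46 | 920 px | analytic bookkeeping, forward-physics checks |
| `mini` | 8x8 | 46 | 368 px | classical recovery, dynamic-range protocol |
| `micro` | 8x8 | 16 | 128 px | CNN training experiments (64 px network input) |

The desk-scale CNN study trains on 500-600 rendered samples for 10-12
epochs and evaluates against the modal baseline on a 200-sample abnormal
slice (eye-model draws in which at least 10% of in-pupil spots leave their
home cells). These sizes are the package's chosen desk conditions; the
full-scale profile (24,000/8,000/8,000 samples, 500 epochs, 200 px input)
is expressible with the same functions. What the desk-scale pass does show:
the learned regressor extracts coefficients from spot patterns the
classical method cannot attribute, at the geometry's native failure
amplitudes. What it does not show: the absolute accuracy figures of a
full-scale training run, detector noise robustness (the default render is
noiseless; Poisson/read noise are available behind options), or transfer to
real sensor data.

## Degenerate inputs and tie-breaks

* Empty cells, spotless cells and reconstructor exceptions all map to
  defined outcomes (invalid flags, low-confidence fits, infinite residual)
  rather than errors, because the failure regime is the object of study.
* `order_proportion()` excludes all-zero samples with a warning (division
  by zero) and is nondecreasing in its cutoff by construction.
* Two equal spots in one cell centroid to their midpoint — documented
  cross-talk behaviour of center-of-mass estimation.
* Covariance matrices are accepted down to eigenvalues of $-10^{-10}$
  (clipped to zero) to absorb floating-point asymmetry; anything more
  negative is rejected.
* The per-image max normalization of network inputs is stored with each
  dataset so training and inference always agree.

## Known limitations

* The eye-population parameters are a stand-in, not a clinical fit; all
  population-conditional numbers (e.g. the order-proportion curve) move
  with them.
* Monochromatic light, unit fill factor, no detector MTF, no extended
  source: the simulator models the idealized instrument.
* The modal baseline is implemented with the conventional centroiding and
  least-squares choices; spot-matching extensions of the classical method
  are out of scope as comparators.
* Training at the full published scale is supported by the code but not by
  CPU-class hardware; the desk profile is the supported study condition.
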