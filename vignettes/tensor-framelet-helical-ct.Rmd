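---
title: "Tensor-framelet regularized reconstruction for helical CT: models and methods"
author: "helicalTF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tensor-framelet regularized reconstruction for helical CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helicalTF)
```

## The reconstruction problem

Multislice helical (spiral) CT acquires projection data while the X-ray source
rotates and the table translates, tracing a helix around the patient.  The
image $x$ (a 3D attenuation map, mm$^{-1}$, on an $N_x \times N_y \times N_z$
voxel grid) is related to the measured line integrals $y$ through the system
operator $A$, and iterative reconstruction solves

$$ \hat x = \arg\min_x \tfrac12 \lVert Ax - y \rVert_2^2 + \lambda R(x), $$

where $R$ is a sparsity-promoting regularizer.  This package implements the
tensor-framelet (TF) choice of $R$: a redundant tight-frame transform $W$ with
$W^{\mathsf T} W = I$, penalized through a weighted isotropic $\ell_1$ norm
$\lVert Wx \rVert_{1,\lambda}$.  Total variation (TV) is recovered as a
special weight configuration, and a simplified helical FDK provides the
analytic baseline.

## Scan geometry and the projector pair

`scanGeometry()` models a flat equispaced detector panel rigidly mounted on
the gantry, a source at radius $R$ from the isocenter, counter-clockwise
rotation from $+x$, and table advance $\Delta z = p\,C/V$ per view (pitch $p$,
collimation $C$ = detector z-extent scaled to the isocenter, $V$ views per
rotation).  A flying focal spot is modeled as a deterministic per-view source
offset table (`ffsAlternatingZ()` builds the usual alternating $\pm\delta z$
schedule); the offsets move the source only, the detector stays on the
gantry.  No offset magnitudes are published for the scanner protocol this
emulates, so the schedule is fully configurable and off by default.

`forwardProject()` is a Joseph-style ray-driven projector: one infinitely
narrow ray per detector cell, stepped across the slices of its driving axis
with bilinear interpolation in each slice.  `backProject()` scatters the same
interpolation weights, so it is the exact numerical transpose — the
dot-product identity $\langle Ax, y\rangle = \langle x, A^{\mathsf T}y\rangle$
holds to rounding error, which the iterative solver requires.  Joseph
interpolation was chosen over exact voxel-intersection (Siddon) tracing
because its adjoint is smoother and it is the standard choice for iterative
reconstruction.  Rays that miss the grid contribute zero; a curved detector,
bowtie filtration, polychromatic spectra and scatter are out of scope.  All
lengths are mm, attenuation is mm$^{-1}$, voxel indices are 0-based with the
voxel-center convention.

## The tensor-framelet transform

The 1D piecewise-linear tight frame uses the refinement masks
$\omega_0 = \tfrac14[1\;2\;1]$ (average), $\omega_1 =
\tfrac{\sqrt2}{4}[1\;0\;-1]$ (first difference) and $\omega_2 =
\tfrac14[-1\;2\;-1]$ (second difference); their autocorrelations sum to a
delta, which is what makes the frame tight.  Level-$l$ masks insert
$2^{l-1}-1$ zeros between the taps (the à-trous construction), and the
transform is undecimated, so every sub-volume keeps the full grid size.

The 3D transform filters each axis unfolding independently and combines the
three axes with weight $1/\sqrt3$: band $(l, j)$ consists of the triple
$\frac{1}{\sqrt3}\,\omega_j^l * x^{l-1}_a$, $a \in \{x, y, z\}$, where each
axis carries its own lowpass chain $x^l_a = \omega_0^l * x^{l-1}_a$.  Two
representation choices deserve comment:

* **Per-axis lowpass chain.** Maintaining one joint (3D-smoothed) lowpass
  volume is incompatible with a tight frame when the detail bands are
  per-axis triples — no single-volume operator has
  $T^{\mathsf T}T = \tfrac13\sum_a \omega_0^{\mathsf T}\omega_0$ along each
  axis.  The per-axis construction makes $W^{\mathsf T}W = I$ exact, at the
  cost of storing the final lowpass as a 3-component triple, giving $6L + 3$
  grid-sized sub-volumes at level $L$.  For $L = 1$ the lowpass triple is
  exactly the uni-level averaging ($j = 0$) band.
* **Detail bands filter the previous level's lowpass.**  The recursion
  computes level-$l$ bands from the level-$(l-1)$ lowpass — the only reading
  under which perfect reconstruction holds; `tfAdjoint(tfForward(x, L))`
  returns `x` to $10^{-15}$ for any `L` (a tested invariant).

Boundary handling is periodic (circular) convolution, so the tight-frame
identity holds exactly without boundary correction.

The regularizer is the weighted isotropic norm
$$\lVert Wx\rVert_{1,\lambda} = \sum_{l,j} \lambda_{l,j} \sum_v
\sqrt{c_x^2 + c_y^2 + c_z^2} + \lambda_{L,0}\sum_v |c^L|,$$
with the per-voxel magnitude taken jointly over the three axis components.
With $L = 1$, $\lambda_{1,1} > 0$ and all other weights zero it equals the
isotropic central-difference TV norm times $1/\sqrt6$ (also tested to
$10^{-10}$).  Penalizing the lowpass $\ell_1$ ($\lambda_{L,0}$) is unusual
and disabled by default.  The proximal map of the norm is the isotropic
shrinkage `tfShrink()`: each band triple is soft-thresholded in magnitude,
preserving direction.

## The ADMM (split-Bregman) solver

`admmReconstruct()` introduces auxiliaries $d$ (shrinkage target) and $v$
(multiplier) and alternates three steps:

1. **x-update** — because $W^{\mathsf T}W = I$, the quadratic subproblem
   reduces to $(A^{\mathsf T}A + \mu I)\,x = A^{\mathsf T}y + \mu
   W^{\mathsf T}(d - v)$, solved by conjugate gradients warm-started from the
   previous outer iterate (this reduction is the computational advantage of
   TF over TV, where $W^{\mathsf T}W \ne I$);
2. **d-update** — isotropic shrinkage of $Wx + v$ with thresholds
   $\lambda_{l,j}/\mu$;
3. **multiplier update** — $v \leftarrow v + Wx - d$.

Numerical choices: the sinogram is normalized internally so
$\max|y| = 1$ (quoted $\lambda$, $\mu$ values refer to that scale; the
returned volume is rescaled); initialization is $x^0 = 0$, $d^0 = Wx^0$,
$v^0 = 0$, with an optional FDK warm start; the iteration count is fixed
(default 30 outer, 20 CG inner) rather than adaptive, for reproducibility —
a relative-change early stop (`relTolerance`) exists but is off by default.
No published $\lambda$, $\mu$ or iteration counts exist for this method's
clinical experiments; all defaults here are this package's own.  Identical
configurations produce bit-identical traces.  Split-Bregman is not strictly
monotone, so the objective trace is only required (and tested) to be
non-increasing after a short burn-in, with tiny relative upticks tolerated.
Conjugate gradients is monotone in the energy norm of the error, not in the
2-norm of the residual; the tests assert the former.

`tvReconstruct()` delegates to the same solver with $L = 1$ and the TV weight
pattern.  `fdkReconstruct()` is the analytic baseline: cosine weighting on a
virtual detector through the isocenter, row-wise frequency-domain ramp
filtering with a Hann rolloff (zero-padded to avoid circular wrap), and
distance-weighted voxel-driven backprojection over the views whose detector
window covers each voxel, normalized per voxel by its angular coverage.  It
deliberately omits Parker/Tam redundancy weighting and ignores flying focal
spot offsets — it is meant to be a credible FDK baseline, not a vendor
implementation.

## The scan simulator

`simulateScan()` produces projection data from analytic ellipsoid phantoms.
The noiseless path is exactly `forwardProject(rasterize(...))`.  The noisy
path draws per-cell transmission counts $N \sim \mathrm{Poisson}(I_0
e^{-p})$, optionally adds Gaussian electronic noise, clamps at one count
(photon starvation beyond 1 % of cells triggers a warning) and returns
$\hat p = \log(I_0/N)$.  Dose is parameterized by the incident photon count
$I_0$ per cell — scanner kV/mAs settings are machine-specific, so
`dosePreset()` simply maps the four tube-voltage labels 80/100/120/140 kV
onto $I_0 = 0.5,\ 1,\ 2,\ 4 \times 10^5$ photons, spanning the factor-of-five
effective dose range of a typical accreditation-phantom protocol.  The delta
method gives $\mathrm{Var}(\hat p) \approx e^{p}/I_0$, a tested property.

`subsampleViews()` implements the sparse-view protocol: keeping every
`step`-th view and rescaling views-per-rotation, equivalent to rotating and
translating `step` times faster.  The clinical 2304-view protocol yields
576, 288 and 144 views per rotation at steps 4, 8 and 16.

What the simulator does **not** emulate: beam hardening, scatter, detector
cross-talk, anatomical (anthropomorphic) structure, and the vendor's raw-data
preprocessing.  Passing tests therefore demonstrate algorithmic correctness
and the expected desk-scale quality ordering of the methods, not clinical
image quality.

## The desk-scale study conditions

`deskPreset()` is a scaled replica of a 64-row clinical protocol
(512×512×88 voxels at 0.9766/2 mm, 2304 views per rotation, pitch 1):
a 64×64×32 grid at 1×1×2 mm, 16 detector rows at 2 mm (isocenter scale,
matching the slice thickness), 144 channels at 0.75 mm, 96 views per
rotation, pitch 1, three rotations.  The in-plane detector pitch is kept
finer than the voxel pitch, as in the clinical system — with coarser
channels, high-frequency image modes are invisible to the projector and the
noiseless problem becomes badly non-unique.

The tested study conditions are: (i) noiseless fully-sampled two-ellipsoid
recovery with small $\lambda = 10^{-5}$ (TF, $L = 2$, $\mu = 1$, 30 outer ×
10 CG iterations) reaching below 3 % relative RMSE; and (ii) an 8×-subsampled
scan at the 100 kV dose preset, reconstructed by FDK, TV and TF with matched
regularization strength $\lambda = 2\times10^{-3}$ — matched because the TV
configuration is literally the $L = 1$ weight pattern of the TF norm, so
equal $\lambda$ compares the transforms rather than the tuning.  Under these
conditions TF attains lower RMSE and higher UQI than TV, which in turn beats
FDK, mirroring the sparse-view ordering reported for the clinical data this
package's method derives from.  Problem sizes were chosen so the full study
runs in minutes on one CPU.

## Image-quality metrics

All ROI statistics use population (divisor-$n$) standard deviations.

* `uqi()` — the Universal Quality Index, the product of a
  correlation/contrast factor and a luminance factor,
  $\frac{4\,\mathrm{Cov}(\mu,\mu_t)}{\sigma^2+\sigma_t^2}\cdot
  \frac{\bar\mu\bar\mu_t}{\bar\mu^2+\bar\mu_t^2}$, computed over an ROI.  It
  equals 1 exactly for identical non-constant ROIs.  The general formula
  ranges over $[-1, 1]$ (anti-correlated inputs go negative); for
  reconstruction-vs-truth comparisons the relevant range is $[0, 1]$.
  Constant-vs-constant ROIs are signaled as undefined rather than returned
  as 0.
* `snr()`, `cnr()` — ROI mean over ROI standard deviation, and absolute ROI
  mean difference over the root of the summed variances.  The CNR
  denominator is read as $\sqrt{\sigma^2_{\mathrm{ROI}} +
  \sigma^2_{\mathrm{air}}}$, the standard definition.
* `mtfFromEdge()` — samples the edge spread function along a line profile
  (bilinear interpolation), differentiates between adjacent samples, takes
  the discrete Fourier magnitude and normalizes MTF(0) = 1.  Adjacent-sample
  (half-sample-offset) differencing is used rather than central differences:
  an ideal discrete step then yields a single-impulse LSF and an exactly
  flat MTF, and a Gaussian edge of $\sigma = 2$ samples reproduces its
  analytic Fourier pair $e^{-2\pi^2\sigma^2 f^2}$ within 0.02 absolute down
  to MTF = 0.1 (a central-difference LSF fails both properties: its
  $|\mathrm{sinc}|$-shaped frequency response forces the MTF of an ideal
  step to zero at Nyquist).  An optional 3-tap pre-smoothing of the ESF is
  available for noisy data and is off by default so that ideal edges are
  left untouched.
* `normalizeVolume()` — divides by the 99.9th-percentile robust maximum,
  the normalization convention applied before computing metrics on
  reconstructed volumes.

## File formats and the command line

Geometry and run configurations are flat `key = value` text files.
Sinograms and framelet coefficients are stored in a single-file
self-describing container (plain-text header with named datasets and
geometry attributes, followed by little-endian float32 payloads); volumes
are written both as NIfTI (spacing in the header) and as raw float32 with a
text sidecar.  All writes are atomic (write-then-rename).  The
`inst/cli/helict.R` script exposes `simulate`, `subsample`, `reconstruct`,
`evaluate` and `run` subcommands over these formats; `runPipeline()` writes
a reproducibility manifest that can itself be re-run to reproduce identical
outputs.

## Known limitations

* The FDK baseline's simple per-voxel angular normalization is approximate
  for helical trajectories; cone-angle artifacts grow with pitch and
  collimation.
* Periodic framelet boundaries can wrap structure across opposing faces of
  the grid; for the padded, air-surrounded phantoms used here the effect is
  negligible.
* The solver exposes no automatic regularization-parameter selection;
  $\lambda$ and $\mu$ are data-scale-relative and must be chosen per
  protocol.
* Exact (Katsevich-type) helical reconstruction, ordered-subsets
  acceleration and GPU execution are out of scope.
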