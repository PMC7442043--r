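---
title: "Methods: wave-optics simulation and CSC localization for light-field microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wave-optics simulation and CSC localization for light-field microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A microlens-array (MLA) light-field microscope records, in a single camera
exposure, both where light arrives (which lenslet) and from which direction
(which pixel behind that lenslet). A compact fluorescent source — a bead, or
the soma of a neuron — therefore leaves a depth-dependent signature in the
raw frame, and its 3D position can in principle be read from one snapshot.
`lfmepi` implements the full chain that does this: a scalar wave-optics
simulator of the instrument, automatic geometric calibration, decoding of the
raw frame into the two-plane-parameterized 4D light-field
$I_{4D}(i,j,k,l)$, construction of epipolar-plane images (EPIs), synthesis of
a depth-aware EPI dictionary, and localization by convolutional sparse coding
(CSC) solved with ADMM in the Fourier domain.

The key geometric fact is that a point source traces a tilted line in an EPI
(one angular axis $i$, one spatial axis $k$): the deeper the source, the more
tilted the line, while a lateral shift of the source translates the line
along the spatial axis without changing its tilt. Depth therefore becomes a
*pattern identity* (which dictionary atom matches) and lateral position a
*pattern location* (where the coefficient map peaks) — exactly the structure
convolutional sparse coding exploits.

# The forward model

For an ideal point emitter at $\mathbf p=(p_1,p_2,p_3)$ (object space, µm,
$p_3=0$ at the native focal plane, positive deeper) the sensor point-spread
function is

$$ h(\mathbf x,\mathbf p) \;=\;
   \mathcal F^{-1}\!\left\{\,\mathcal F\{U_i(\mathbf x,\mathbf p)\,
   \Phi(\mathbf x)\}\; G(\hat{\mathbf x})\,\right\}, $$

with three ingredients:

* **Objective wavefront** $U_i(\mathbf x,\mathbf p) = U_o(-\mathbf x/M,\mathbf p)$,
  the inverted, $M$-times magnified copy of the Debye wavefront at the native
  object plane. `debye_wavefront()` evaluates the scalar circular-aperture
  Debye integral over the cone half-angle $\alpha=\arcsin(\mathrm{NA}/n)$,
  with apodization $\sqrt{\cos\theta}$ and defocus phase
  $\exp\!\left(i k n p_3(1-\cos\theta)\right)$, $k = 2\pi/\lambda$. Because
  the integral is radially symmetric it is computed once per depth as a 1D
  profile (trapezoidal rule on a $\theta$ grid sized to the fastest phase
  oscillation) and interpolated onto the 2D grid; profiles are cached per
  depth.
* **MLA phase mask** $\Phi$: a pitch-$d$ lattice of square lenslet cells,
  each carrying the thin-lens phase
  $\exp(-i\pi\lVert \mathbf x_{loc}\rVert^2/(\lambda f_{ML}))$; the mask is
  phase-only so it conserves energy.
* **Fresnel propagation** over the MLA focal length $f_{ML}$ with the
  unitary paraxial transfer function
  $G(\mathbf f)=\exp(-i\pi\lambda z\lVert\mathbf f\rVert^2)$ applied in the
  Fourier domain. Unit modulus makes the step exactly energy-conserving
  (Parseval), which the tests assert to $10^{-10}$ relative.

Extended sources are incoherent:
$f(\mathbf x)=\sum_{\mathbf p} |h(\mathbf x,\mathbf p)|^2\, g(\mathbf p)$,
exactly linear in the emitter intensities $g$. A neuron-like source is a
uniform ball (default 10 µm diameter) discretized on a cubic lattice
(`discretize_ball()`).

## Numerical choices in the simulator

* **Field grid.** The complex field is sampled `oversample`× finer than the
  sensor pixels and intensities are integrated (binned) back onto pixels.
  The object-side spacing must resolve the aperture band limit: a hard error
  is raised above the amplitude Nyquist bound $\lambda/(2\,\mathrm{NA})$;
  staying at or below $\lambda/(4\,\mathrm{NA})$ (the default 4× oversampling)
  additionally keeps the *intensity* alias-free. The desk preset
  (below) uses 2× oversampling, whose 0.132 µm object-side spacing sits just
  above the intensity bound; the residual aliasing is far below the
  localization quantum and is accepted for speed.
* **Lateral snapping.** Source lateral coordinates are snapped to the
  object-space projection of the field grid
  ($d/(N_i\,o\,M)$ ≈ 0.066–0.13 µm, i.e. 40–75× finer than the 5 µm lateral
  sampling of the method). Snapped positions make laterally shifted sources
  reuse identical wavefront samples, enabling an exact result cache.
* **Symmetry orbits.** On the centred square geometry the PSF obeys exact
  mirror and transpose equivariances
  ($h_{-p_1,p_2}$ is the column-reversed $h_{p_1,p_2}$, etc.), so only one
  representative per dihedral orbit is ever propagated; the rest are
  index permutations of the cached image. Ball renders at a given depth
  thereby cost roughly an eighth of the naive point count.
* **Periodic lateral boundary (`wrap_shift`).** The MLA makes the system
  exactly periodic under lateral source shifts of one lenslet pitch
  ($d/M$ = 5 µm object side, one micro-image on the sensor). With
  `wrap_shift = TRUE` (the fixture generator's default) the shift is applied
  as a circular shift of the cached near-axis PSF. This is exact except at
  the sensor border, where content wraps around instead of leaving the
  simulated field of view; the measured interior discrepancy is below
  $10^{-4}$ of the peak. The open-boundary path (`wrap_shift = FALSE`)
  remains the default of `render_lightfield()`.
* **Axial range.** The simulated grid covers 15 lenslets per side at desk
  scale; beyond ≈ 35 µm depth the defocused wavefront is clipped by the grid
  edge. Dictionary atoms and observations are clipped identically, so
  matching remains consistent, but the absolute PSF tails at the deepest
  depths are truncated — a field-of-view limitation of the desk preset, not
  of the method.

## The desk-scale preset

The instrument described by `optical_config()` is a 25×/NA 1.0
water-immersion fluorescence microscope ($n=1.33$, $\lambda = 0.52$ µm green
emission) with an f/10 MLA of 125 µm pitch ($f_{ML}=1250$ µm) and 19 × 19
sensor pixels per lenslet. `desk_config()` restricts the simulated sensor to
15 × 15 lenslets (285 × 285 px) with 2× field oversampling so that the whole
pipeline — dictionary, twenty bead recoveries, calibration and scattering
experiments — runs in minutes on one CPU. The experiments in the tests and
in `scripts/acceptance.R` discretize the 10 µm ball at 2 µm (57 lattice
points; `discretize_ball()`'s default is 1 µm) — the EPI of the smooth ball
is visually indistinguishable between the two steps, and the coarser lattice
keeps each depth render under a minute.

# Calibration

Raw frames are calibrated from an ordinary out-of-focus exposure, without a
white image:

1. **Rotation** (`detect_rotation_angle()`): the image is rotated over a
   coarse angle grid (±5° in 0.1° steps); at each angle the columns are
   summed, the profile is high-pass filtered (Butterworth order 3, cutoff at
   half the lenslet frequency — the filter family is fixed, the parameters
   are this package's choice) and the contrast max − min recorded. The
   grid-aligned angle maximizes contrast; a fine pass at 0.01° over ±1°
   around the coarse argmax refines it. Bilinear interpolation with edge
   replication avoids dark-border artefacts in the column sums.
2. **Pitch** (`detect_pitch()`): the column-sum profile of the rotation-
   corrected image is near-periodic with the lenslet pitch; the dominant
   spectral peak above the scene-envelope band (periods longer than ⅛ of the
   image width are excluded) gives the frequency, refined on a 16× zero-
   padded spectrum plus parabolic interpolation to ≈ 0.01 px.
3. **Centres** (`detect_centers()`): the image is binarized (Otsu by
   default, threshold overridable), convolved with a disc kernel whose
   diameter equals the pitch — or a 3 × 3 multi-disc kernel that exploits
   neighbourhood structure — and centres are found by marching a window of
   one pitch from the global response maximum, snapping to the local maximum
   within ±pitch/4. Because the kernel disc is as wide as the lenslet, the
   response has a flat plateau around each true centre; the sub-pixel
   estimate is the plateau centroid of the *single-disc* response, whose
   aligned-overlap term is an even function of the offset and therefore stays
   centred even for edge lenslets (the multi-disc response grows
   monotonically toward the interior at the border and is used only for the
   robust integer march). Finally coordinates are averaged along each grid
   row and column, weighted by the single-disc response and discarding cells
   whose estimate strays more than pitch/4 from the rigid-grid prediction —
   this is what makes 20 % darkened lenslets harmless.

All three detectors are deterministic.

# Decoding and EPIs

`decode_4d()` extracts the $N_i\times N_j$ window centred (rounded to the
nearest pixel — no resampling, preserving photometry) on each calibrated
lenslet centre into $I_{4D}(i,j,k,l)$, zero-filling and flagging vignetted
edge lenslets. Sub-aperture images are the $(k,l)$ slices at fixed $(i,j)$;
a *horizontal* EPI fixes $(j,l)$ and spans $(i,k)$, a *vertical* EPI fixes
$(i,k)$ and spans $(j,l)$ (axis 1 angular, axis 2 spatial). For
localization the EPI pair through the brightest lenslet of the central
sub-aperture view is used (`extract_localization_epis()`).

For scattering tissue, all $N_iN_j$ sub-aperture images are vectorized into
the columns of a matrix $A$ and the leading singular triplet
$B = u_{\max}\sigma_{\max}v_{\max}^{\top}$ is subtracted
(`remove_background()`): the diffuse background is nearly identical across
viewing directions, hence nearly rank one, while a localized source moves
with parallax and survives. Perturbation analysis (reproduced in the tests)
shows the subtraction restores a localized spot's own intensity to
$1-v_j^2$ (≪ 5 % at the 361-view geometry) while an irreducible
$\mathcal O(1/\sqrt{n_{\text{views}}})$ leakage spreads along the spot's
pixel row — this is why the purification quality criterion is evaluated on
the spot value. Max-projection profiles of an EPI are provided as a
diagnostic but are not applied before CSC, which retains more structure from
the 2D EPI. Denoising is intentionally absent: sparsity makes the decoder
robust to the residual noise.

# The depth-aware dictionary

`build_dictionary()` renders the 10 µm ball on the optical axis at each depth
of a sweep (default 0–48 µm every 4 µm — the granularity of the experimental
depth sweep; the spacing is configurable), decodes it, extracts the central
EPI, crops all EPIs to a common atom window (tight bounding box of the
epipolar line at the deepest depth plus a 2-sample margin) and normalizes
each atom to unit $\ell_2$ norm (standard CSC practice, so that map energies
are comparable across atoms). `depth_lookup()` maps the selected atom index
back to depth; reported depths are atom depths — no interpolation — so the
dictionary spacing bounds the axial quantization error at ±2 µm. For the
centred simulated ball the horizontal and vertical atoms coincide, which the
tests assert.

# CSC localization

Given a (vectorized) EPI $\mathbf Y$ and atoms $\{\mathbf d_m\}$ the
coefficient maps solve

$$ \min_{\{\mathbf z_m\}} \tfrac12\bigl\lVert \mathbf Y -
   \textstyle\sum_m \mathbf d_m * \mathbf z_m \bigr\rVert_2^2
   + \beta \sum_m \lVert \mathbf z_m\rVert_1 . $$

ADMM splits this into (i) a quadratic $\mathbf Z$-update, solved in the
Fourier domain where convolution is elementwise and the per-frequency normal
matrix $\hat{\mathbf d}^*\hat{\mathbf d}^{\top}+\mu I$ is diagonal plus rank
one, inverted in closed form by the Sherman–Morrison identity; (ii) a
$\mathbf T$-update, the elementwise soft-threshold
$S_{\beta/\mu}(x)=\operatorname{sign}(x)(|x|-\beta/\mu)_+$; (iii) the dual
update $\boldsymbol\gamma \leftarrow \boldsymbol\gamma+\mu(\mathbf Z-\mathbf T)$.
Initialization is zero everywhere, so the solver is deterministic.

Tunables, all chosen by this package (with units and defaults):

* $\beta$ (`"auto"`): $0.05\cdot\max_m\lVert \mathbf Y \star \mathbf d_m
  \rVert_\infty$ — proportional to the strongest atom correlation, hence
  invariant to rescaling the EPI.
* $\mu$: $10\beta / \max_m\lVert \mathbf Y \star \mathbf d_m\rVert_\infty
  = 0.5$. The shrinkage threshold $\beta/\mu$ then equals one tenth of the
  correlation scale. (A penalty proportional to $\beta$ alone would make the
  threshold an *absolute* number: on dimly scaled EPIs every coefficient
  would be shrunk to zero and the splitting would stall with a unit primal
  residual — observed, and the reason for this parameterization. With
  unit-norm atoms the quadratic term has $\mathcal O(1)$ curvature, so
  $\mu = 0.5$ also conditions the $\mathbf Z$-solve well.)
* 200 iterations maximum, stopping at relative primal residual
  $\lVert\mathbf Z-\mathbf T\rVert/\lVert\mathbf Z\rVert < 10^{-4}$.
* Boundary: the Fourier solver implies circular convolution, so the EPI is
  zero-padded by the atom size on each border and padded positions are
  masked out of source selection.

**Selection, weights, fusion.** Map energies $e_m = \lVert\mathbf
z_m\rVert_2^2$ are ranked; the $S$ largest are taken, skipping atoms within
one dictionary step of an already selected depth so one physical source
cannot claim two adjacent atoms ($S$ is a required input; an energy-gap
estimator `estimate_source_count()` is available but off by default). Each
selected map's peak gives the source's position along the EPI's spatial
axis, converted to object micrometres via the lateral quantum $d/M$ (sign
flipped for the 4-f image inversion); the fixed EPI index supplies the other
lateral coordinate. Per-EPI reliability weights
$w = \lVert \mathbf Z_{:,\Omega}\rVert_F^2 / \lVert\mathbf Z\rVert_F^2$
quantify how much coefficient energy the selected atoms captured, and the
horizontal/vertical estimates (paired greedily by nearest depth, ties broken
by lateral proximity) are fused as
$\mathbf p = (w_h\mathbf p_h + w_v\mathbf p_v)/(w_h+w_v)$. The
renormalization makes the fusion a convex combination — a plain weighted sum
would scale positions by the arbitrary total weight.

# The synthetic-data generator

`make_fixture()` renders ground-truthed raw frames and corrupts them in a
controlled order: depth-scaled Gaussian blur of the foreground (a scattering
surrogate), grid rotation, a smooth rank-one background (outer product of
two broad 1D profiles, scaled to a fraction of the clean peak — the
structure the SVD purification is designed to remove), and seeded additive
Gaussian read noise. With all corruption at zero the output equals the plain
render exactly, and a fixed seed reproduces frames byte for byte.

What the generator does *not* emulate: photon (Poisson) statistics at
calibrated gain, optical aberrations beyond defocus, multiple anisotropic
scattering (the rank-one background plus blur is a first-order surrogate),
and sources outside the simulated field of view. Passing tests therefore
demonstrate correctness of the algorithms under the stated forward model and
robustness to these stylized corruptions — not performance on any particular
real microscope.

`evaluate_localization()` matches predictions to truth greedily by 3D
nearest neighbour and reports per-axis RMSE and the depth-accuracy fraction
(axial error within half a dictionary step); unmatched sources are reported,
never dropped.

# Problem sizes used by the tests and acceptance script

Dictionary: 13 atoms, 0–48 µm every 4 µm, ball lattice 2 µm, desk preset.
Recovery experiment: 20 single-bead fixtures at seeded on-grid depths and
lateral positions on the 5 µm lenslet grid within ±2 lenslets; the same
twenty beads are re-localized under 20 dB additive Gaussian noise.
Calibration: analytic 285 × 285 px disc-grid fixtures (15 × 15 lenslets of
19 px) for angle/pitch/centre recovery, plus a rendered out-of-focus emitter
lattice for the full chain. Solver cross-check: ten random 1D instances
($N \le 64$, $M \le 3$) against an independent dense-matrix ISTA solver of
the same functional, agreement to $10^{-4}$ relative in objective.

# Known limitations

* Depth is quantized to the dictionary grid; sub-step axial precision would
  need atom interpolation, deliberately out of scope.
* Lateral positions are quantized to the lenslet pitch $d/M$ (5 µm); the
  super-resolved step $d/(MN_i)$ (0.26 µm) is reported by
  `transverse_sampling()` for comparison but this decoder does not attempt
  super-resolution.
* The scalar Debye model ignores polarization; at NA 1.0 vectorial effects
  alter the fine PSF structure. Dictionary and observations share the
  model, so localization on simulated data is unaffected; applying the
  package to real frames inherits the usual scalar-model approximation.
* Multiple sources are resolved only when they separate in depth (distinct
  atoms) or appear in distinct EPIs; two sources on the same epipolar line
  at the same depth merge.
* Desk-scale field of view truncates the PSF beyond ≈ 35 µm depth (see
  above); full-frame configurations remove this at proportional cost.
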