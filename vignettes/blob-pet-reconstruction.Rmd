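---
title: "Blob-basis PET reconstruction on a polar grid: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blob-basis PET reconstruction on a polar grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The reconstruction model

`blobpet` reconstructs fully 3D PET data with a maximum-likelihood
expectation-maximisation (ML-EM) algorithm in which the radiotracer
distribution is modelled as a linear combination of overlapping,
spherically symmetric basis functions ("blobs") rather than cubic voxels:

$$\hat f(\mathbf r) = \sum_{i=1}^{N} c_i\, \psi(\mathbf r - \mathbf r_i),$$

where the $c_i$ are non-negative coefficients and the $\mathbf r_i$ form a
cylindrical polar placement grid. The basis function is the generalised
Kaiser–Bessel blob

$$\psi_{m,a,\alpha}(r) = \frac{1}{I_m(\alpha)}
  \Big[\textstyle\sqrt{1-(r/a)^2}\Big]^{m}
  I_m\!\big(\alpha\sqrt{1-(r/a)^2}\big), \qquad 0 \le r \le a,$$

zero beyond the support radius $a$. Blobs overlap, so the expansion is
smooth everywhere; this trades a much denser system matrix for better
noise behaviour than disjoint voxels. The data model is the standard
Poisson one: the expected counts in crystal pair (line of response, LOR)
$d$ are $q_d = \sum_b p_{d,b} c_b$, with $p_{d,b}$ the stored system
response matrix (SRM).

### Blob parameters

| parameter | meaning | default | why |
|---|---|---|---|
| $m$ | Bessel order | 2 | first derivative continuous at $r=a$ |
| $a$ | support radius | $1.994\,\Delta$ | frequency-space optimum for grid spacing $\Delta$ |
| $\alpha$ | taper | 10.4 | frequency-space optimum |
| $\Delta$ | grid spacing (mm) | 0.5 | see *Open choices* below |

Blobs are deliberately **not** normalised to unit integral: the
coefficients carry the activity scale, matching the expansion as written
above. ML-EM is invariant to any global rescaling of the SRM because the
scale cancels between the sensitivity normaliser and the backprojected
ratio.

## Scanner geometry and the symmetry group

The geometry model is a polygonal ring of flat modules, each a dual-layer
array of rectangular crystals; the default reproduces a small-animal
scanner with 18 modules, two layers of 4 × 8 crystals (front
2 × 2 × 6 mm, rear 2 × 2 × 8 mm), front faces at 35.5 mm radius and an
18.1 mm axial field of view — 1,152 crystals and 662,976 unordered crystal
pairs. The two discrete layers give depth-of-interaction information,
which mitigates the parallax blurring of off-centre sources.

An 18-module ring admits 18 rotations, a transaxial mirror and an axial
mirror: 72 symmetry transforms. The package exploits them by *folding* the
SRM: detection weights are stored only for the blobs of one canonical
wedge (one representative per orbit, chosen as the minimum flat index),
and a look-up table regenerates any element via
$p_{T(d),T(b)} = p_{d,b}$. For a commensurate grid this divides both the
build time and the file size of the SRM by the group order.

Two placement details make the folding *exact* rather than approximate:

* blob centres sit at half-integer angles $2\pi(j+\tfrac12)/n_\text{ang}$
  (the centres of polar voxels, i.e. body-centred placement). With
  $2n_\text{mod} \mid n_\text{ang}$ no centre lies on a mirror plane, every
  orbit has the full 72 members, and the wedge is exactly $N/72$;
* the chords used by the analytic projector are sampled on centred,
  sign-symmetric face grids, so the chord set of a transformed LOR is the
  transformed chord set, element by element.

The package validates the fold against a brute-force no-symmetry build on
a 6-module test ring; agreement is at double precision (relative to the
matrix scale), far below the 1e-12 documented tolerance.

## Building the system matrix

Physics-free geometric projectors replace Monte-Carlo particle transport;
attenuation, scatter, accidentals, positron range and photon
noncollinearity are all out of scope, matching a back-to-back
true-coincidence simulation model.

**Analytic footprint projector** (`analytic_srm_wedge()`). The line
integral of a blob along a chord at perpendicular distance $s$ has the
closed form $\frac{a}{I_m(\alpha)} \sqrt{2\pi/\alpha}\, u^{m+1/2}
I_{m+1/2}(\alpha u)$ with $u = \sqrt{1-(s/a)^2}$; the implementation is
validated against adaptive quadrature at 1e-8 relative (the SRM inherits
this accuracy). $p_{d,b}$ is the mean footprint over a stratified set of
chords between the two crystal faces (default 16), with the geometric
acceptance factor set to 1 — absorbed by the sensitivity, to which ML-EM
is invariant. Entries below a configurable floor (default 1e-9) are
dropped. The build is deterministic: identical configurations give
bit-identical matrices.

**Etendue normalisation.** With `normalization = "etendue"` each chord is
weighted by $\cos\theta_1 \cos\theta_2 / r_{12}^2$ and scaled by
$A_1 A_2 / (2\pi W)$ ($W$ = blob volume integral), turning the same sum
into the *probability per emission* that an isotropic back-to-back pair
crosses both entrance faces. This is the quantity the geometric Monte
Carlo projector estimates, which gives the package a genuinely independent
cross-check between its two SRM routes.

**Geometric Monte Carlo projector** (`mc_srm_wedge()`). Emissions are
drawn inside each wedge blob with density $\propto \psi$, an isotropic
back-to-back pair is traced, and a coincidence is tallied for the crystal
pair struck. `detect = "volume"` (default) hits the first crystal box a
ray intersects — with dual layers the first-intersected layer wins, as in
a real scanner; `detect = "face"` counts only entrance-face crossings,
the event the etendue-normalised analytic projector integrates, and is
the mode used in the cross-validation test (on a thin-crystal ring where
the two detection models coincide). The seed is mandatory; builds are
reproducible.

The two normalisations are *not* interchangeable numbers: the default
footprint mode yields mm-weighted line integrals, the etendue/MC pair
yields probabilities. Both give identical reconstructions because ML-EM
only sees their ratio structure.

## ML-EM and the two backprojection orderings

The update is the classic multiplicative EM step

$$c_b' = \frac{c_b}{s_b} \sum_d p_{d,b} \frac{y_d}{q_d},
  \qquad s_b = \sum_d p_{d,b},$$

run from a uniform positive start (init-independence in the limit; zeros
in the start are preserved, which also freezes blobs with zero
sensitivity). Three exact identities are enforced by tests at every
iteration: non-negativity, weighted count conservation
$\sum_b s_b c_b' = \sum_d y_d$, and monotone Poisson log-likelihood.

Forward projection is a *gathering* operation over the LOR-ordered folded
matrix (each LOR sums wedge columns across all 72 transforms).
Backprojection is a *scattering* operation and is offered in two
strategies that must agree within floating summation order:

* `"transpose"` iterates the blob-ordered (transposed) SRM, making every
  output element a private consecutive reduction — no write hazards;
* `"scatter"` iterates the LOR-ordered SRM in row chunks with chunk-local
  accumulators merged by summation — the contract that guarantees no lost
  updates when chunks run independently. An optional seeded random chunk
  order decorrelates spatially adjacent LORs; results are order-invariant
  within tolerance.

All accumulation is double precision, which removes the mixed-precision
confound when comparing strategy outputs at desk scale. LORs with counts
but vanishing projection ($q_d < 10^{-300}$) are excluded from the update
and reported, never clamped — clamping would silently bias the image.

## Synthetic data

`make_image_quality_phantom()` builds the noise/contrast phantom: a warm
cylinder (30 mm radius, 20 mm long, concentration 1) with a hot rod
(10 mm radius, concentration 3; the 3:1 hot:warm ratio) and a cold rod
(concentration 0). The rods' transaxial positions are not part of the
defining ratios; the defaults put them at ±15 mm on the x axis.
`make_resolution_phantom()` builds the resolution phantom: a warm
ellipsoid (35 × 20 mm transaxially, 2 mm long, offset 12.5 mm) with six
200:1 point sources spaced 5 mm apart radially and six cold 1.5 mm
spheres. Point sources are modelled as 0.5 mm spheres (one display voxel)
to keep the activity integrable; the warm background mitigates the
resolution overshoot caused by the non-negativity constraint.

Counts are simulated by forward-projecting the true coefficients through
the *same* SRM used for reconstruction, scaling to a total-count budget
(default 4.5e7 for the image-quality study), and drawing independent
Poisson counts per LOR. This is an inverse-crime design on purpose: it
isolates the algorithmic properties (symmetry folding, adjointness,
EM convergence, strategy equivalence) from model mismatch. Consequently,
passing tests say nothing about attenuation, scatter, randoms, detector
blur or count-rate effects in real data, and absolute noise levels
(CV/CNR trajectories) and absolute resolution (FWHM values) at full
scanner scale are *not* reproduced — those depend on a transport-level
SRM with ~1e10 simulated events and are outside what a desk-scale build
can honestly claim. What is preserved and checked qualitatively is the
physics-driven trend that resolution degrades with radial distance
(parallax).

## Figures of merit

On rasterised volumes the package computes, with the sample ($n-1$)
standard deviation throughout (the estimator is not otherwise pinned
down): the coefficient of variation $\mathrm{CV} = \sigma_s/\mu_s$ in a
box ROI (default 8 × 9 × 0.5 mm, voxel membership by centre with
half-open bounds); the contrast-to-noise ratio
$\mathrm{CNR} = (\mu_s-\mu_b)/\sqrt{(\sigma_s^2+\sigma_b^2)/2}$; the
Pearson correlation CC over whole volumes, computed with mean-centred
sums in double precision (CC = 1 for identical images; CC = −1 is perfect
*anti*-correlation, the mathematically correct reading); and the FWHM of
point-source profiles extracted by trilinear interpolation, with the
half-maximum crossings located by linear interpolation on both flanks.
Because the resolution phantom's sources sit on a 200:1 warm background,
FWHM subtracts a baseline (the profile minimum) before halving;
`baseline = "none"` restores the raw convention.

## Problem sizes used by the test-suite studies

The package's own studies run at desk scale, chosen so the whole suite
and the acceptance pipeline complete in minutes while every contract is
still exercised at its documented tolerance:

* *mini ring* for dense oracles: 6 modules × 1 layer × 2 × 2 crystals
  (24 crystals, 276 LORs), 3 × 12 × 2 polar grid at Δ = 2 mm, group
  order 24 — small enough to compare against full brute-force matrices;
* *scaled-down image-quality study*: the full 18-module transaxial
  geometry with one layer and two axial rows (144 crystals, 10,296 LORs),
  16 × 72 × 2 grid at Δ = 2 mm (2,304 blobs, 32-blob wedge), 2e6 Poisson
  coincidences, 300 ML-EM iterations. The recovered hot:warm ROI contrast
  sits within a few percent of the true 3:1.

## Open choices and their resolutions

* **Grid spacing Δ.** The reference description fixes 0.5 mm only for the
  cubic-voxel comparison grid, not for the blob grid; the package adopts
  Δ = 0.5 mm as the default and treats it as configuration.
* **Wedge size.** The reference wedge of 8,740 blobs corresponds to an
  unstated $(n_r, n_\text{ang}, n_z)$; the package treats the wedge count
  as a derived quantity of the configured grid rather than a constant,
  and uses a constant angular count per ring so the fold stays exact.
* **Angular half-offset.** On-axis angles would put blobs on mirror
  planes, shrinking some orbits and breaking the $N/72$ wedge arithmetic;
  body-centred (half-offset) placement removes every fixed point. This is
  the package's reading of "body-centred placement on polar voxels".
* **SRM value dtype.** Values are stored as little-endian float64 so that
  write-then-read is exactly lossless; float32 storage would halve the
  file at the cost of breaking exact round-trips.
* **Normalisation semantics.** Stored weights are per-emission quantities
  (footprint means by default, probabilities in etendue/MC modes); the
  ambiguity between per-decay and per-detected-coincidence conventions is
  resolved to per-emission and documented here.
* **Crystal pitch.** Inter-crystal gaps are not modelled by default
  (tangential pitch = crystal width); both pitches are configurable.
* **Subsets.** Ordered-subsets EM is deliberately not implemented; subset
  choice couples speed with image quality, and the package's scope is the
  plain ML-EM fixed point.

## Known limitations

The projectors are geometric: no attenuation, scatter, randoms, energy or
timing windows, dead-time, positron range or noncollinearity. The
polygonal geometry assumes flat modules with identical crystal arrays and
no module offsets. Orbit folding requires the angular count to be a
multiple of $2n_\text{mod}$; incommensurate grids are rejected rather
than approximated. `activity_to_coefficients(mode = "lstsq")` builds a
dense basis matrix and is intended for small calibration grids, not
production-size problems.
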