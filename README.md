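# blobpet

Fully 3D PET image reconstruction with overlapping Kaiser–Bessel basis
functions ("blobs") on a cylindrical polar grid, for people studying
iterative reconstruction algorithms on small-animal scanner geometries:
a complete, desk-scale pipeline from scanner model to figures of merit,
with every algebraic contract (symmetry folding, projector adjointness,
EM guarantees) tested against independent brute-force oracles.

## The model

The activity distribution is expanded as

$$\hat f(\mathbf r) = \sum_i c_i\, \psi(\mathbf r - \mathbf r_i), \qquad
  \psi_{m,a,\alpha}(r) = \frac{[\sqrt{1-(r/a)^2}]^{m}}{I_m(\alpha)}
  I_m\!\big(\alpha\sqrt{1-(r/a)^2}\big)\ (r \le a),$$

with blob centres $\mathbf r_i$ body-centred on a polar grid and the
frequency-optimal parameters $m = 2$, $a = 1.994\Delta$, $\alpha = 10.4$.
Coefficients are estimated by ML-EM,

$$c_b^{(k+1)} = \frac{c_b^{(k)}}{\sum_d p_{d,b}}
  \sum_d p_{d,b}\, \frac{y_d}{\sum_{b'} p_{d,b'} c_{b'}^{(k)}},$$

where $y_d$ are coincidence counts per line of response (LOR) and
$p_{d,b}$ is a sparse system response matrix (SRM). The polygonal
scanner's rotation/reflection group (order 72 for the default 18-module
ring) folds the SRM onto one angular–axial wedge of blobs: storage and
build cost drop by the group order, and a look-up table regenerates any
element exactly. Backprojection comes in two strategies — a blob-ordered
transposed matrix, and chunked scatter accumulation over the LOR-ordered
matrix — which agree to floating summation order.

What is deliberately *not* here: attenuation, scatter, randoms, positron
range, noncollinearity, ordered subsets, GPU/MPI code. The projectors are
geometric (analytic blob footprints, or a geometric Monte Carlo ray
tracer), so studies are inverse-crime by design; see the methods vignette
(`vignettes/blob-pet-reconstruction.Rmd`) for what that does and does not
demonstrate.

## Worked example

A scaled-down image-quality study: the full 18-module transaxial geometry
with one crystal layer and two axial rows, a 2 mm polar grid, the 3:1:0
hot/warm/cold rod phantom, 2 million Poisson coincidences and 300 ML-EM
iterations (about a minute end to end):

```r
library(blobpet)
spec <- scanner_spec(n_modules = 18, n_layers = 1, crystals_tangential = 4,
                     crystals_axial = 2, crystal_size_mm = list(c(2, 2, 6)),
                     layer_face_radius_mm = 35.5, axial_pitch_mm = 18.1 / 8)
grid <- build_polar_grid(16, 72, 2, delta = 2, n_modules = 18)
lut  <- build_symmetry_lut(spec, grid, lor_records = FALSE)
srm  <- analytic_srm_wedge(spec, grid, lut)
srm
#> <sparse_srm> lor-ordered, 10,296 LORs x 32 wedge blobs, nnz 27,091 (fill 0.0822)

phantom <- make_image_quality_phantom()    # hot 3 : warm 1 : cold 0
c_true  <- activity_to_coefficients(phantom, grid)
y   <- simulate_counts(c_true, srm, lut, total_counts = 2e6, seed = 42)
fit <- run_mlem(y, srm, lut, n_iter = 300, log_every = 100)
tidy(fit)
#> # A tibble: 3 x 3
#>   iteration log_likelihood n_excluded
#>       <int>          <dbl>      <int>
#> 1       100      10022959.          0
#> 2       200      10023095.          0
#> 3       300      10023151.          0

vol  <- rasterize(fit$image, voxel_grid(140, 140, 8, 0.5))
hot  <- roi_spec(c(15, 0, 0), label = "hot")     # 8 x 9 x 0.5 mm boxes
warm <- roi_spec(c(0, 15, 0), label = "warm")
cold <- roi_spec(c(-15, 0, 0), label = "cold")
roi_stats(vol, list(hot, warm, cold))
#> # A tibble: 3 x 5
#>   label n_voxels   mean     sd    cv
#>   <chr>    <int>  <dbl>  <dbl> <dbl>
#> 1 hot        288 21.5   3.62   0.168
#> 2 warm       288  7.33  1.58   0.216
#> 3 cold       288  0.148 0.0605 0.408
```

The log-likelihood climbs monotonically (an EM guarantee the tests
enforce at every iteration). The ROI means recover the simulated
contrasts: hot/warm = 21.5/7.33 ≈ 2.94 against the true 3.0, the cold rod
sits near zero, and the coefficient of variation is lowest in the hot
region and highest in the cold one, the expected ML-EM noise ordering.
`cnr(vol, hot, warm)` evaluates to 5.08 for this run.

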