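#' Geometric phantom specifications
#'
#' A phantom is an ordered list of geometric components — cylinders,
#' ellipsoids, spheres, point sources — each carrying a relative activity
#' concentration (dimensionless). Components are evaluated in order and
#' later components override earlier ones where they overlap, so a cold
#' insert is simply a late component with concentration 0. Absolute
#' activities are not modelled: reconstruction consumes counts, and the
#' total-count budget is set at simulation time ([simulate_counts()]).
#'
#' @param components list of components; build them with
#'   [phantom_cylinder()], [phantom_ellipsoid()], [phantom_sphere()].
#' @param label free-text description.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(components, label = "") {
  stopifnot(is.list(components), length(components) >= 1L)
  for (cmp in components) {
    if (!is.function(cmp$inside) || is.null(cmp$value) || cmp$value < 0)
      stop("each component needs an `inside` predicate and a concentration >= 0",
           call. = FALSE)
  }
  structure(list(components = components, label = label), class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param centre component centre (x, y, z) in mm.
#' @param radius radius in mm (cylinders, spheres).
#' @param length axial extent in mm (cylinders).
#' @param value relative activity concentration (>= 0).
#' @param name component label.
#' @export
phantom_cylinder <- function(centre, radius, length, value, name = "cylinder") {
  force(centre); force(radius); force(length)
  list(name = name, type = "cylinder", centre = centre, radius = radius,
       length = length, value = value,
       inside = function(x, y, z)
         (x - centre[1])^2 + (y - centre[2])^2 <= radius^2 &
         abs(z - centre[3]) <= length / 2)
}

#' @rdname phantom_spec
#' @param semi_axes ellipsoid semi-axes (x, y, z) in mm.
#' @export
phantom_ellipsoid <- function(centre, semi_axes, value, name = "ellipsoid") {
  force(centre); force(semi_axes)
  list(name = name, type = "ellipsoid", centre = centre, semi_axes = semi_axes,
       value = value,
       inside = function(x, y, z)
         ((x - centre[1]) / semi_axes[1])^2 + ((y - centre[2]) / semi_axes[2])^2 +
         ((z - centre[3]) / semi_axes[3])^2 <= 1)
}

#' @rdname phantom_spec
#' @export
phantom_sphere <- function(centre, radius, value, name = "sphere") {
  force(centre); force(radius)
  list(name = name, type = "sphere", centre = centre, radius = radius,
       value = value,
       inside = function(x, y, z)
         (x - centre[1])^2 + (y - centre[2])^2 + (z - centre[3])^2 <= radius^2)
}

#' Evaluate a phantom as an activity field
#'
#' @param phantom a [phantom_spec()].
#' @return a function `A(x, y, z)` (vectorised) returning the relative
#'   concentration, 0 outside every component.
#' @export
activity_map <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_spec"))
  comps <- phantom$components
  function(x, y, z) {
    out <- numeric(length(x))
    for (cmp in comps) {
      sel <- cmp$inside(x, y, z)
      out[sel] <- cmp$value
    }
    out
  }
}

#' The image-quality phantom: hot and cold rods in a warm cylinder
#'
#' A homogeneously filled warm cylinder (20 mm long, 30 mm radius,
#' concentration 1) holding a hot rod (same length, 10 mm radius,
#' concentration 3 — the 3:1 hot:warm ratio) and a cold rod (same size,
#' concentration 0), both parallel to the axis and placed symmetrically
#' off-centre. The transaxial rod positions are configuration defaults
#' (`+/- rod_offset` on the x axis), as they are not part of the phantom's
#' defining ratios.
#'
#' @param scale global geometric scale factor (1 = nominal dimensions).
#' @param rod_offset transaxial rod offset in mm (before scaling).
#' @param warm_radius warm cylinder radius in mm (before scaling).
#' @return a [phantom_spec()].
#' @export
make_image_quality_phantom <- function(scale = 1, rod_offset = 15,
                                       warm_radius = 30) {
  assert_positive(scale, "scale")
  phantom_spec(list(
    phantom_cylinder(c(0, 0, 0) * scale, warm_radius * scale, 20 * scale,
                     value = 1, name = "warm"),
    phantom_cylinder(c(rod_offset, 0, 0) * scale, 10 * scale, 20 * scale,
                     value = 3, name = "hot"),
    phantom_cylinder(c(-rod_offset, 0, 0) * scale, 10 * scale, 20 * scale,
                     value = 0, name = "cold")),
    label = "image-quality phantom (hot 3 : warm 1 : cold 0)")
}

#' The resolution phantom: point sources in a warm ellipsoid
#'
#' A warm ellipsoid (35 x 20 mm transaxially, 2 mm long, concentration 1)
#' placed 12.5 mm off-centre, holding six hot point sources at 200:1
#' concentration spaced 5 mm apart radially (source 1 nearest the scanner
#' centre) and six cold spheres of 1.5 mm diameter. Point sources are
#' modelled as 0.5 mm diameter spheres (one display voxel) so the activity
#' stays integrable. The warm background mitigates the resolution
#' overshoot of the ML-EM non-negativity constraint.
#'
#' @param scale global geometric scale factor.
#' @param source_value point-source concentration (default 200).
#' @return a [phantom_spec()].
#' @export
make_resolution_phantom <- function(scale = 1, source_value = 200) {
  assert_positive(scale, "scale")
  xs <- (0:5) * 5                       # 5 mm spacing, radially outward
  comps <- list(
    phantom_ellipsoid(c(12.5, 0, 0) * scale, c(17.5, 10, 1) * scale,
                      value = 1, name = "warm"))
  for (i in seq_along(xs))
    comps[[length(comps) + 1L]] <-
      phantom_sphere(c(xs[i], 0, 0) * scale, 0.25 * scale, value = source_value,
                     name = sprintf("hot_ps_%d", i))
  for (i in seq_along(xs))
    comps[[length(comps) + 1L]] <-
      phantom_sphere(c(xs[i], -5, 0) * scale, 0.75 * scale, value = 0,
                     name = sprintf("cold_sphere_%d", i))
  phantom_spec(comps, label = "resolution phantom (200:1 point sources)")
}

#' Convert an activity field to blob coefficients
#'
#' Mode `"sample"` evaluates the activity at each blob centre — fast, and
#' exact for regions that are constant over a blob's support. Mode
#' `"lstsq"` finds non-negative coefficients minimising the voxel-wise
#' mismatch between the rasterised blob expansion and the activity map on
#' a reference voxel grid (non-negative least squares).
#'
#' @param phantom a [phantom_spec()].
#' @param grid a [build_polar_grid()] grid.
#' @param mode `"sample"` or `"lstsq"`.
#' @param vg reference [voxel_grid()] for `"lstsq"`; keep it modest, the
#'   design matrix is dense.
#' @return a [blob_image()].
#' @export
activity_to_coefficients <- function(phantom, grid, mode = c("sample", "lstsq"),
                                     vg = NULL) {
  mode <- match.arg(mode)
  A <- activity_map(phantom)
  if (mode == "sample") {
    cf <- A(grid$centres[, 1], grid$centres[, 2], grid$centres[, 3])
  } else {
    if (is.null(vg)) stop("`vg` is required for mode = 'lstsq'", call. = FALSE)
    ax <- voxel_axes(vg)
    pts <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z))
    target <- A(pts[, 1], pts[, 2], pts[, 3])
    basis <- vapply(seq_len(grid$n_blobs), function(i) {
      d <- sqrt((pts[, 1] - grid$centres[i, 1])^2 +
                  (pts[, 2] - grid$centres[i, 2])^2 +
                  (pts[, 3] - grid$centres[i, 3])^2)
      kb_profile(pmin(d, grid$params$a), grid$params)
    }, numeric(nrow(pts)))
    cf <- pracma::lsqnonneg(basis, target)$x
  }
  if (all(cf == 0))
    warning("all coefficients are zero: the phantom does not overlap the grid")
  blob_image(cf, grid)
}

#' Simulate Poisson coincidence data
#'
#' Forward-projects the true coefficients through the system matrix,
#' rescales the intensities so they sum to `total_counts`, and draws
#' independent Poisson counts per LOR — noiseless geometry, Poisson
#' statistics, no randoms or scatter, matching the back-to-back
#' true-coincidence simulation model of the SRM.
#'
#' @param c_true true coefficients ([blob_image()] or vector).
#' @param srm,lut as in [forward_project()].
#' @param total_counts expected total number of coincidences.
#' @param seed mandatory RNG seed.
#' @return a [lor_histogram()] with provenance in `meta`.
#' @export
simulate_counts <- function(c_true, srm, lut, total_counts, seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  assert_positive(total_counts, "total_counts")
  lambda <- forward_project(c_true, srm, lut)
  s <- sum(lambda)
  if (s <= 0) stop("the forward projection is identically zero", call. = FALSE)
  lambda <- lambda * (total_counts / s)
  y <- with_local_seed(seed, rpois(length(lambda), lambda))
  lor_histogram(y, meta = list(total_counts = total_counts, seed = seed,
                               srm_projector = srm$meta$projector))
}
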