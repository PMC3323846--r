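#' Kaiser-Bessel blob parameters
#'
#' The image is represented as a sum of overlapping, spherically symmetric,
#' compactly supported Kaiser-Bessel basis functions ("blobs"),
#' \deqn{\psi_{m,a,\alpha}(r) = \frac{1}{I_m(\alpha)}
#'   \left[\sqrt{1 - (r/a)^2}\right]^{m} I_m\!\big(\alpha\sqrt{1-(r/a)^2}\big),
#'   \quad 0 \le r \le a,}
#' and 0 beyond the blob radius `a`. `m` is the order of the modified
#' Bessel function, `a` the support radius in mm and `alpha` the taper.
#' The defaults `m = 2`, `a = 1.994 * delta` and `alpha = 10.4` are the
#' frequency-space optimum for a grid of spacing `delta`; `m = 2` makes the
#' first derivative continuous at the support boundary.
#'
#' Blobs are not normalised to unit integral: the coefficients carry the
#' activity scale.
#'
#' @param delta grid spacing in mm.
#' @param m Bessel order (non-negative integer).
#' @param a blob support radius in mm.
#' @param alpha taper parameter (dimensionless, >= 0).
#' @return an object of class `blob_params`.
#' @export
blob_params <- function(delta = 0.5, m = 2L, a = 1.994 * delta, alpha = 10.4) {
  assert_positive(delta, "delta")
  m <- assert_count(m, "m", min = 0L)
  assert_positive(a, "a")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("`alpha` must be a single number >= 0", call. = FALSE)
  structure(list(delta = delta, m = m, a = a, alpha = alpha),
            class = "blob_params")
}

#' Kaiser-Bessel radial profile
#'
#' Evaluates the blob profile \eqn{\psi_{m,a,\alpha}(r)} (see
#' [blob_params()]). \eqn{\psi(0) = 1} and \eqn{\psi(r) = 0} for
#' \eqn{r \ge a} (compact support; exactly 0 at `r = a` for `m >= 1`).
#'
#' @param r radial distance(s) in mm, `>= 0`.
#' @param params a [blob_params()].
#' @return dimensionless profile values.
#' @export
kb_profile <- function(r, params) {
  stopifnot(inherits(params, "blob_params"))
  if (any(r < 0)) stop("`r` must be >= 0", call. = FALSE)
  u2 <- pmax(0, 1 - (r / params$a)^2)
  u <- sqrt(u2)
  u^params$m * besselI(params$alpha * u, params$m) /
    besselI(params$alpha, params$m)
}

#' Line integral (footprint) of a Kaiser-Bessel blob
#'
#' The integral of [kb_profile()] along a straight line at perpendicular
#' distance `s` from the blob centre has the closed form
#' \deqn{p(s) = \frac{a}{I_m(\alpha)} \sqrt{\frac{2\pi}{\alpha}}\,
#'   u^{m + 1/2}\, I_{m+1/2}(\alpha u), \qquad u = \sqrt{1 - (s/a)^2},}
#' an order `m + 1/2` modified Bessel function; it is 0 for `|s| >= a`,
#' even in `s`, and carries units of mm (it weights the mm of path length
#' through the blob). For `alpha = 0` it degenerates to the chord-length
#' integral of \eqn{(1-(r/a)^2)^{m/2}}, evaluated by quadrature.
#'
#' @param s signed perpendicular distance(s) in mm; only `|s|` matters.
#' @param params a [blob_params()].
#' @return footprint values in mm.
#' @export
kb_footprint <- function(s, params) {
  stopifnot(inherits(params, "blob_params"))
  if (any(!is.finite(s))) stop("`s` must be finite", call. = FALSE)
  a <- params$a; m <- params$m; alpha <- params$alpha
  u2 <- pmax(0, 1 - (s / a)^2)
  u <- sqrt(u2)
  if (alpha == 0) {
    return(vapply(u, function(ui) {
      if (ui == 0) return(0)
      L <- a * ui
      2 * integrate(function(t) (pmax(0, ui^2 - (t / a)^2))^(m / 2), 0, L,
                    rel.tol = 1e-12)$value
    }, numeric(1)))
  }
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- (a / besselI(alpha, m)) * sqrt(2 * pi / alpha) *
    u[pos]^(m + 0.5) * besselI(alpha * u[pos], m + 0.5)
  out
}

# Integral of psi over all space (mm^3): 4*pi * int_0^a r^2 psi(r) dr.
kb_volume_integral <- function(params) {
  4 * pi * integrate(function(r) r^2 * kb_profile(r, params), 0, params$a,
                     rel.tol = 1e-10)$value
}

#' Build a polar grid of blob centres
#'
#' Blob centres are placed body-centred on a cylindrical polar voxelisation:
#' radii `(k + 1/2) * delta` for `k = 0, ..., n_radial - 1`, angles
#' `2 * pi * (j + 1/2) / n_angular` (the half-step offset puts centres at
#' polar-voxel centres and keeps every angular orbit of the mirror/rotation
#' group full), and axial planes spaced `delta`, centred on the scanner
#' mid-plane. Blob flat ids are 0-based with the radial index fastest, then
#' angular, then axial.
#'
#' @param n_radial,n_angular,n_axial grid dimensions.
#' @param delta grid spacing in mm.
#' @param params a [blob_params()]; defaults to `blob_params(delta)`.
#' @param n_modules module count of the paired scanner; when given,
#'   `n_angular` must be divisible by `2 * n_modules` (required for exact
#'   wedge folding) and is validated here.
#' @return an object of class `polar_blob_grid` with fields `centres`
#'   (an `n_blobs` x 3 matrix of mm coordinates), counts and `params`.
#' @examples
#' g <- build_polar_grid(4, 72, 4, delta = 0.5, n_modules = 18)
#' g$n_blobs  # 1152
#' @export
build_polar_grid <- function(n_radial, n_angular, n_axial, delta,
                             params = blob_params(delta), n_modules = NULL) {
  n_radial <- assert_count(n_radial, "n_radial")
  n_angular <- assert_count(n_angular, "n_angular")
  n_axial <- assert_count(n_axial, "n_axial")
  assert_positive(delta, "delta")
  stopifnot(inherits(params, "blob_params"))
  if (!is.null(n_modules)) {
    n_modules <- assert_count(n_modules, "n_modules")
    if (n_angular %% (2L * n_modules) != 0L)
      stop(sprintf("n_angular = %d must be divisible by 2 * n_modules = %d",
                   n_angular, 2L * n_modules), call. = FALSE)
  }
  ids <- 0:(n_radial * n_angular * n_axial - 1L)
  kr <- ids %% n_radial
  j <- (ids %/% n_radial) %% n_angular
  kz <- ids %/% (n_radial * n_angular)
  rad <- (kr + 0.5) * delta
  th <- 2 * pi * (j + 0.5) / n_angular
  centres <- cbind(x = rad * cos(th), y = rad * sin(th),
                   z = (kz - (n_axial - 1) / 2) * delta)
  structure(list(n_radial = n_radial, n_angular = n_angular, n_axial = n_axial,
                 delta = delta, params = params, n_modules = n_modules,
                 n_blobs = length(ids), centres = centres),
            class = "polar_blob_grid")
}

#' @export
print.polar_blob_grid <- function(x, ...) {
  cat(sprintf("<polar_blob_grid> %d x %d x %d (radial x angular x axial) = %d blobs, delta %.3g mm\n",
              x$n_radial, x$n_angular, x$n_axial, x$n_blobs, x$delta))
  invisible(x)
}

#' Blob coefficient image
#'
#' A vector of blob coefficients `c` paired with its grid. Coefficients
#' carry the activity scale (see [blob_params()]); after ML-EM updates they
#' are finite and non-negative.
#'
#' @param c numeric coefficient vector, length `grid$n_blobs`.
#' @param grid a [build_polar_grid()] grid.
#' @return an object of class `blob_image`.
#' @export
blob_image <- function(c, grid) {
  stopifnot(inherits(grid, "polar_blob_grid"))
  if (length(c) != grid$n_blobs)
    stop("coefficient length does not match the grid", call. = FALSE)
  if (any(!is.finite(c))) stop("coefficients must be finite", call. = FALSE)
  structure(list(c = as.numeric(c), grid = grid), class = "blob_image")
}

#' Define a voxel grid for rasterisation
#'
#' @param nx,ny,nz voxel counts; defaults mirror a 140 x 140 x 40 display
#'   grid at 0.5 mm isotropic.
#' @param voxel_mm isotropic voxel edge in mm.
#' @param origin corner of the grid in mm (length 3); defaults to centring
#'   the grid on the scanner origin. Voxel centres sit at
#'   `origin + (i + 1/2) * voxel_mm`, 0-based `i`.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(nx = 140L, ny = 140L, nz = 40L, voxel_mm = 0.5,
                       origin = NULL) {
  nx <- assert_count(nx, "nx"); ny <- assert_count(ny, "ny"); nz <- assert_count(nz, "nz")
  assert_positive(voxel_mm, "voxel_mm")
  origin <- origin %||% (-c(nx, ny, nz) * voxel_mm / 2)
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  structure(list(nx = nx, ny = ny, nz = nz, voxel_mm = voxel_mm,
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

voxel_axes <- function(vg) {
  list(x = vg$origin[1] + (seq_len(vg$nx) - 0.5) * vg$voxel_mm,
       y = vg$origin[2] + (seq_len(vg$ny) - 0.5) * vg$voxel_mm,
       z = vg$origin[3] + (seq_len(vg$nz) - 0.5) * vg$voxel_mm)
}

#' Rasterise a blob image onto a voxel grid
#'
#' Each voxel takes the value \eqn{\sum_i c_i \psi(\|v - r_i\|)} at its
#' centre `v` — the blob-basis expansion of the activity estimate.
#' The operation is linear in the coefficients.
#'
#' @param image a [blob_image()].
#' @param vg a [voxel_grid()].
#' @return a 3-D array of class `blob_volume` with the grid attached as
#'   attribute `voxel_grid`.
#' @export
rasterize <- function(image, vg) {
  stopifnot(inherits(image, "blob_image"), inherits(vg, "voxel_grid"))
  ax <- voxel_axes(vg)
  vol <- array(0, dim = c(vg$nx, vg$ny, vg$nz))
  a <- image$grid$params$a
  cen <- image$grid$centres
  cf <- image$c
  act <- which(cf != 0)
  for (i in act) {
    ix <- which(abs(ax$x - cen[i, 1]) < a)
    iy <- which(abs(ax$y - cen[i, 2]) < a)
    iz <- which(abs(ax$z - cen[i, 3]) < a)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (ax$x[ix] - cen[i, 1])^2
    dy2 <- (ax$y[iy] - cen[i, 2])^2
    dz2 <- (ax$z[iz] - cen[i, 3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    vol[ix, iy, iz] <- vol[ix, iy, iz] +
      cf[i] * kb_profile(sqrt(pmin(d2, a^2)), image$grid$params)
  }
  structure(vol, voxel_grid = vg, class = c("blob_volume", "array"))
}

#' @export
print.blob_volume <- function(x, ...) {
  vg <- attr(x, "voxel_grid")
  cat(sprintf("<blob_volume> %d x %d x %d voxels at %.3g mm; range [%.4g, %.4g]\n",
              vg$nx, vg$ny, vg$nz, vg$voxel_mm, min(x), max(x)))
  invisible(x)
}
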