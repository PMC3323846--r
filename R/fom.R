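#' Box region of interest
#'
#' An axis-aligned box ROI; the default 8 x 9 x 0.5 mm size matches the
#' noise-assessment ROIs used on the image-quality phantom. A voxel
#' belongs to the ROI when its centre lies inside the half-open box
#' `[centre - dim/2, centre + dim/2)`.
#'
#' @param centre box centre (x, y, z) in mm.
#' @param dim box edge lengths in mm.
#' @param label ROI name.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(centre, dim = c(8, 9, 0.5), label = "roi") {
  stopifnot(length(centre) == 3L, all(is.finite(centre)))
  assert_positive(dim, "dim", n = 3L)
  structure(list(centre = as.numeric(centre), dim = as.numeric(dim),
                 label = label), class = "roi_spec")
}

roi_values <- function(volume, roi) {
  stopifnot(inherits(volume, "blob_volume"), inherits(roi, "roi_spec"))
  vg <- attr(volume, "voxel_grid")
  ax <- voxel_axes(vg)
  lo <- roi$centre - roi$dim / 2
  hi <- roi$centre + roi$dim / 2
  ix <- which(ax$x >= lo[1] & ax$x < hi[1])
  iy <- which(ax$y >= lo[2] & ax$y < hi[2])
  iz <- which(ax$z >= lo[3] & ax$z < hi[3])
  vals <- volume[ix, iy, iz]
  if (length(vals) < 2L)
    stop(sprintf("ROI '%s' covers fewer than 2 voxels at this resolution", roi$label),
         call. = FALSE)
  as.numeric(vals)
}

#' ROI mean and spread
#'
#' @param volume a rasterised `blob_volume`.
#' @param roi a [roi_spec()], or a list of them.
#' @return a tibble with `label`, `n_voxels`, `mean`, `sd` (sample,
#'   `n - 1` denominator) and `cv`.
#' @export
roi_stats <- function(volume, roi) {
  rois <- if (inherits(roi, "roi_spec")) list(roi) else roi
  do.call(rbind, lapply(rois, function(r) {
    v <- roi_values(volume, r)
    tibble::tibble(label = r$label, n_voxels = length(v),
                   mean = mean(v), sd = sd(v),
                   cv = if (mean(v) != 0) sd(v) / mean(v) else NA_real_)
  }))
}

#' Coefficient of variation in an ROI
#'
#' \eqn{CV = \sigma_s / \mu_s}: a normalised noise measure over the ROI
#' voxels, with \eqn{\sigma_s} the sample (n - 1) standard deviation.
#' Invariant under positive rescaling of the volume.
#'
#' @param volume a rasterised `blob_volume`.
#' @param roi a [roi_spec()].
#' @return dimensionless CV.
#' @export
cv <- function(volume, roi) {
  v <- roi_values(volume, roi)
  m <- mean(v)
  if (m == 0) stop("CV is undefined for a zero-mean ROI", call. = FALSE)
  sd(v) / m
}

#' Contrast-to-noise ratio between two ROIs
#'
#' \eqn{CNR = (\mu_s - \mu_b) / \sqrt{(\sigma_s^2 + \sigma_b^2)/2}} with
#' `roi_s` the signal and `roi_b` the background region. Antisymmetric
#' under swapping the two ROIs.
#'
#' @param volume a rasterised `blob_volume`.
#' @param roi_s,roi_b signal and background [roi_spec()]s.
#' @return dimensionless CNR.
#' @export
cnr <- function(volume, roi_s, roi_b) {
  vs <- roi_values(volume, roi_s)
  vb <- roi_values(volume, roi_b)
  den <- sqrt((var(vs) + var(vb)) / 2)
  if (den == 0) stop("CNR is undefined when both ROIs are constant", call. = FALSE)
  (mean(vs) - mean(vb)) / den
}

#' Correlation coefficient between two volumes
#'
#' Pearson correlation over all voxels, computed in double precision with
#' mean-centred sums. 1 means perfectly correlated images; -1 is perfect
#' anti-correlation (the value an image and its intensity inversion
#' attain).
#'
#' @param volume_a,volume_b arrays of identical shape.
#' @return CC in `[-1, 1]`.
#' @export
cc <- function(volume_a, volume_b) {
  if (!identical(dim(volume_a), dim(volume_b)))
    stop("volumes must have identical shapes", call. = FALSE)
  a <- as.numeric(volume_a) - mean(volume_a)
  b <- as.numeric(volume_b) - mean(volume_b)
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0)
    stop("CC is undefined for a constant volume", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Extract a straight-line profile from a volume
#'
#' Samples the volume by trilinear interpolation at `n` uniformly spaced
#' positions from `p0` to `p1` (both in mm). Positions are reported as the
#' signed distance from `p0`.
#'
#' @param volume a rasterised `blob_volume`.
#' @param p0,p1 segment endpoints in mm (length-3).
#' @param n number of samples (>= 2).
#' @return a tibble of class `blob_profile` with columns `position`
#'   (mm) and `value`; the uniform spacing is attached as attribute
#'   `spacing`.
#' @export
extract_profile <- function(volume, p0, p1, n = 201L) {
  stopifnot(inherits(volume, "blob_volume"), length(p0) == 3L, length(p1) == 3L)
  n <- assert_count(n, "n", min = 2L)
  vg <- attr(volume, "voxel_grid")
  tt <- seq(0, 1, length.out = n)
  pts <- cbind(p0[1] + tt * (p1[1] - p0[1]),
               p0[2] + tt * (p1[2] - p0[2]),
               p0[3] + tt * (p1[3] - p0[3]))
  vals <- trilinear(volume, vg, pts)
  if (any(is.na(vals)))
    stop("the segment leaves the interpolable interior of the volume", call. = FALSE)
  len <- sqrt(sum((p1 - p0)^2))
  structure(tibble::tibble(position = tt * len, value = vals),
            spacing = len / (n - 1), class = c("blob_profile", class(tibble::tibble())))
}

# Trilinear interpolation at mm points; NA outside the centre-to-centre hull.
trilinear <- function(volume, vg, pts) {
  gx <- (pts[, 1] - vg$origin[1]) / vg$voxel_mm - 0.5
  gy <- (pts[, 2] - vg$origin[2]) / vg$voxel_mm - 0.5
  gz <- (pts[, 3] - vg$origin[3]) / vg$voxel_mm - 0.5
  out <- rep(NA_real_, nrow(pts))
  ok <- gx >= 0 & gx <= vg$nx - 1 & gy >= 0 & gy <= vg$ny - 1 &
    gz >= 0 & gz <= vg$nz - 1
  if (!any(ok)) return(out)
  i0 <- pmin(floor(gx[ok]), vg$nx - 2); fx <- gx[ok] - i0
  j0 <- pmin(floor(gy[ok]), vg$ny - 2); fy <- gy[ok] - j0
  k0 <- pmin(floor(gz[ok]), vg$nz - 2); fz <- gz[ok] - k0
  # handle flat axes (n = 1): collapse the interpolation weight
  if (vg$nx == 1) { i0 <- 0; fx <- 0 }
  if (vg$ny == 1) { j0 <- 0; fy <- 0 }
  if (vg$nz == 1) { k0 <- 0; fz <- 0 }
  at <- function(di, dj, dk)
    volume[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * at(0, 0, 0) +
    fx * (1 - fy) * (1 - fz) * at(min(1, vg$nx - 1), 0, 0) +
    (1 - fx) * fy * (1 - fz) * at(0, min(1, vg$ny - 1), 0) +
    (1 - fx) * (1 - fy) * fz * at(0, 0, min(1, vg$nz - 1)) +
    fx * fy * (1 - fz) * at(min(1, vg$nx - 1), min(1, vg$ny - 1), 0) +
    fx * (1 - fy) * fz * at(min(1, vg$nx - 1), 0, min(1, vg$nz - 1)) +
    (1 - fx) * fy * fz * at(0, min(1, vg$ny - 1), min(1, vg$nz - 1)) +
    fx * fy * fz * at(min(1, vg$nx - 1), min(1, vg$ny - 1), min(1, vg$nz - 1))
  out[ok] <- v
  out
}

#' Full width at half maximum of a profile peak
#'
#' Takes the highest interior peak of the profile, subtracts the baseline
#' (the profile minimum by default — appropriate for point sources sitting
#' on a warm background), locates the half-maximum crossings on both
#' flanks by linear interpolation, and returns their distance in mm.
#'
#' @param profile a [extract_profile()] result, or anything with
#'   `position` and `value` columns.
#' @param baseline `"min"` subtracts the profile minimum before halving;
#'   `"none"` uses the raw half maximum.
#' @return FWHM in mm.
#' @export
fwhm <- function(profile, baseline = c("min", "none")) {
  baseline <- match.arg(baseline)
  pos <- profile$position; val <- profile$value
  if (length(val) < 3L) stop("profile too short", call. = FALSE)
  base <- if (baseline == "min") min(val) else 0
  ipk <- which.max(val)
  if (ipk == 1L || ipk == length(val))
    stop("no interior maximum: the profile is monotone at its peak", call. = FALSE)
  peak <- val[ipk]
  if (peak <= base) stop("flat profile: no peak above baseline", call. = FALSE)
  half <- base + (peak - base) / 2
  cross <- function(idx_seq) {
    for (i in idx_seq) {
      v1 <- val[i]; v2 <- val[i + 1]
      lohi <- range(v1, v2)
      if (half >= lohi[1] && half <= lohi[2] && v1 != v2) {
        f <- (half - v1) / (v2 - v1)
        return(pos[i] + f * (pos[i + 1] - pos[i]))
      }
    }
    NA_real_
  }
  left <- cross(rev(seq_len(ipk - 1L)))
  right <- cross(ipk:(length(val) - 1L))
  if (is.na(left) || is.na(right))
    stop("half-maximum crossing not found on both flanks", call. = FALSE)
  right - left
}

#' Plot a profile
#'
#' @param object a `blob_profile` from [extract_profile()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot blob_profile
#' @export
autoplot.blob_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position along profile [mm]", y = "value") +
    ggplot2::theme_minimal()
}

#' Figure-of-merit report for a volume
#'
#' Per-ROI statistics plus all pairwise contrast-to-noise ratios, and
#' optionally the correlation against a reference volume.
#'
#' @param volume a rasterised `blob_volume`.
#' @param rois list of [roi_spec()]s.
#' @param reference optional volume for a whole-image CC.
#' @return a list with tibbles `roi` and `cnr`, and scalar `cc`
#'   (NA without a reference).
#' @export
fom_report <- function(volume, rois, reference = NULL) {
  stats <- roi_stats(volume, rois)
  pairs <- if (length(rois) >= 2L) {
    idx <- utils::combn(length(rois), 2L)
    do.call(rbind, lapply(seq_len(ncol(idx)), function(k) {
      i <- idx[1, k]; j <- idx[2, k]
      tibble::tibble(signal = rois[[i]]$label, background = rois[[j]]$label,
                     cnr = cnr(volume, rois[[i]], rois[[j]]))
    }))
  } else tibble::tibble(signal = character(), background = character(),
                        cnr = numeric())
  list(roi = stats, cnr = pairs,
       cc = if (is.null(reference)) NA_real_ else cc(volume, reference))
}
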