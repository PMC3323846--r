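#' Sparse system response matrix (SRM)
#'
#' The SRM holds the detection weights \eqn{p_{d,b}}: the contribution of
#' basis element (blob) `b` to the expected counts in crystal pair (LOR)
#' `d`. Wedge-folded matrices store columns only for the canonical wedge
#' blobs of a [build_symmetry_lut()]; all other elements are regenerated by
#' symmetry. Storage is compressed-sparse-row in the order named by
#' `ordering`: `"lor"` rows are LORs (the natural order for forward
#' projection, a gathering operation), `"blob"` rows are wedge blobs (the
#' transposed matrix, the natural order for backprojection).
#'
#' @name sparse_srm
#' @return `sparse_srm` objects carry `ordering`, `n_rows`, `n_cols`,
#'   `row_ptr` (0-based offsets, length `n_rows + 1`), `col_idx` (0-based),
#'   `values` (non-negative weights), `n_lor`, `n_wedge`, `wedge_folded`
#'   and a `meta` provenance list.
NULL

new_sparse_srm <- function(mat, ordering, n_lor, n_wedge, meta,
                           wedge_folded = TRUE) {
  # `mat` is a dgCMatrix with dim (n_lor, n_wedge), whatever the ordering
  mat <- methods::as(mat, "CsparseMatrix")
  if (ordering == "lor") {
    tm <- Matrix::t(mat)       # CSC of t(mat) == CSR of mat
    row_ptr <- tm@p; col_idx <- tm@i; values <- tm@x
    n_rows <- n_lor; n_cols <- n_wedge
  } else {
    row_ptr <- mat@p; col_idx <- mat@i; values <- mat@x
    n_rows <- n_wedge; n_cols <- n_lor
  }
  srm <- list(ordering = ordering, n_rows = n_rows, n_cols = n_cols,
              row_ptr = as.numeric(row_ptr), col_idx = as.integer(col_idx),
              values = as.numeric(values),
              n_lor = n_lor, n_wedge = n_wedge, wedge_folded = wedge_folded,
              meta = meta, cache = new.env(parent = emptyenv()))
  srm$cache$mat <- mat
  class(srm) <- "sparse_srm"
  srm
}

#' @export
print.sparse_srm <- function(x, ...) {
  cat(sprintf("<sparse_srm> %s-ordered, %s LORs x %d wedge blobs, nnz %s (fill %.3g)\n",
              x$ordering, format(x$n_lor, big.mark = ","), x$n_wedge,
              format(length(x$values), big.mark = ","),
              length(x$values) / (x$n_lor * x$n_wedge)))
  invisible(x)
}

# dgCMatrix view with dim (n_lor, n_wedge), independent of storage ordering.
srm_as_matrix <- function(srm) {
  stopifnot(inherits(srm, "sparse_srm"))
  if (!is.null(srm$cache$mat)) return(srm$cache$mat)
  rows <- rep(seq_len(srm$n_rows), diff(srm$row_ptr))
  m <- if (srm$ordering == "lor") {
    Matrix::sparseMatrix(i = rows, j = srm$col_idx + 1L, x = srm$values,
                         dims = c(srm$n_lor, srm$n_wedge))
  } else {
    Matrix::sparseMatrix(i = srm$col_idx + 1L, j = rows, x = srm$values,
                         dims = c(srm$n_lor, srm$n_wedge))
  }
  srm$cache$mat <- m
  m
}

# Per-crystal face frames used by both projectors.
crystal_frames <- function(spec) {
  tab <- build_crystal_table(spec)
  fr <- module_frame(spec, tab$module)
  size <- spec$crystal_size_mm[tab$layer + 1L, , drop = FALSE]
  list(face = cbind(tab$x, tab$y, tab$z),
       that = cbind(fr$tx, fr$ty, 0),        # tangential unit vector
       rhat = cbind(fr$rx, fr$ry, 0),        # outward radial unit vector
       w_t = size[, "tangential"], w_z = size[, "axial"],
       depth = size[, "radial"])
}

# Stratified centred offsets used for face sampling; symmetric under sign
# flips so that the chord set is exactly equivariant under the mirror group.
face_offsets <- function(k) {
  o <- ((seq_len(k) - 0.5) / k) - 0.5
  as.matrix(expand.grid(u = o, v = o))
}

#' Build the wedge-folded SRM with the analytic footprint projector
#'
#' For every LOR `d` and every canonical wedge blob `b`, averages the
#' Kaiser-Bessel line-integral footprint ([kb_footprint()]) over a set of
#' chords sampled between the two crystal entrance faces. The stratified,
#' centred face sampling makes the chord set exactly equivariant under the
#' symmetry group, so the folded matrix reproduces an unfolded build to
#' floating precision. Entries below `floor` are dropped; the result is
#' stored LOR-ordered.
#'
#' @param spec a [scanner_spec()].
#' @param grid a [build_polar_grid()] grid.
#' @param lut the matching [build_symmetry_lut()].
#' @param n_rays chords per LOR for `pairing = "matched"` (a perfect
#'   square; offsets are paired grid-point to grid-point), or points per
#'   face for `pairing = "all"` (giving `n_rays^2` chords, a denser 4-D
#'   sampling used when chord-space coverage matters).
#' @param pairing chord sampling scheme, see `n_rays`.
#' @param floor sparsity floor: entries `< floor` are dropped.
#' @param normalization `"footprint"` (default): `p` is the plain mean
#'   footprint over chords, units mm; the geometric acceptance is absorbed
#'   into the sensitivity, to which ML-EM is invariant. `"etendue"`:
#'   `p` is the probability per emission that a back-to-back pair crosses
#'   both faces, obtained by weighting each chord with
#'   `cos(theta1) * cos(theta2) / r12^2` and normalising by
#'   `A1 * A2 / (2 * pi * W)` with `W` the blob volume integral — the
#'   estimator the geometric Monte Carlo builder ([mc_srm_wedge()])
#'   converges to.
#' @return a LOR-ordered, wedge-folded [sparse_srm].
#' @export
analytic_srm_wedge <- function(spec, grid, lut, n_rays = 16L,
                               pairing = c("matched", "all"),
                               floor = 1e-9,
                               normalization = c("footprint", "etendue")) {
  pairing <- match.arg(pairing)
  normalization <- match.arg(normalization)
  stopifnot(inherits(lut, "symmetry_lut"))
  n_rays <- assert_count(n_rays, "n_rays")
  k <- as.integer(round(sqrt(n_rays)))
  if (k * k != n_rays)
    stop("`n_rays` must be a perfect square (stratified k x k face grid)", call. = FALSE)
  fr <- crystal_frames(spec)
  n_lor <- lut$n_lor
  pr <- lor_unindex(0:(n_lor - 1))
  i1 <- pr$c1 + 1L; i2 <- pr$c2 + 1L
  offs <- face_offsets(k)
  chords <- if (pairing == "matched") {
    lapply(seq_len(nrow(offs)), function(r) cbind(offs[r, 1], offs[r, 2],
                                                  offs[r, 1], offs[r, 2]))
  } else {
    idx <- expand.grid(r1 = seq_len(nrow(offs)), r2 = seq_len(nrow(offs)))
    lapply(seq_len(nrow(idx)), function(r)
      cbind(offs[idx$r1[r], 1], offs[idx$r1[r], 2],
            offs[idx$r2[r], 1], offs[idx$r2[r], 2]))
  }
  wedge <- lut$wedge_ids
  acc <- matrix(0, n_lor, length(wedge))
  params <- grid$params
  for (ch in chords) {
    A <- fr$face[i1, ] + ch[, 1] * fr$w_t[i1] * fr$that[i1, ] +
      cbind(0, 0, ch[, 2] * fr$w_z[i1])
    B <- fr$face[i2, ] + ch[, 3] * fr$w_t[i2] * fr$that[i2, ] +
      cbind(0, 0, ch[, 4] * fr$w_z[i2])
    D <- B - A
    dd <- rowSums(D * D)
    w <- if (normalization == "etendue") {
      cos1 <- abs(rowSums(D * fr$rhat[i1, ])) / sqrt(dd)
      cos2 <- abs(rowSums(D * fr$rhat[i2, ])) / sqrt(dd)
      cos1 * cos2 / dd
    } else 1
    for (wi in seq_along(wedge)) {
      cen <- grid$centres[wedge[wi] + 1L, ]
      cx <- cen[1] - A[, 1]; cy <- cen[2] - A[, 2]; cz <- cen[3] - A[, 3]
      t <- pmin(1, pmax(0, (cx * D[, 1] + cy * D[, 2] + cz * D[, 3]) / dd))
      s2 <- (cx - t * D[, 1])^2 + (cy - t * D[, 2])^2 + (cz - t * D[, 3])^2
      near <- which(s2 < params$a^2)
      if (length(near))
        acc[near, wi] <- acc[near, wi] +
          kb_footprint(sqrt(s2[near]), params) * (if (length(w) > 1) w[near] else w)
    }
  }
  p <- acc / length(chords)
  if (normalization == "etendue") {
    W <- kb_volume_integral(params)
    area <- fr$w_t * fr$w_z
    p <- p * (area[i1] * area[i2]) / (2 * pi * W)
  }
  p[p < floor] <- 0
  if (all(p == 0))
    stop("empty SRM: no chord of any LOR passes within a blob radius of a wedge blob",
         call. = FALSE)
  mat <- methods::as(Matrix::Matrix(p, sparse = TRUE), "CsparseMatrix")
  meta <- list(projector = "analytic", n_rays = n_rays, pairing = pairing,
               floor = floor, normalization = normalization,
               spec_hash = object_hash(unclass(spec)),
               grid_hash = object_hash(unclass(grid)[c("n_radial", "n_angular",
                                                       "n_axial", "delta")]))
  new_sparse_srm(mat, "lor", n_lor, length(wedge), meta)
}

#' Build the wedge-folded SRM by geometric Monte Carlo
#'
#' Emission positions are drawn inside each canonical wedge blob with
#' density proportional to the blob profile; each emission launches an
#' isotropic back-to-back photon pair (no positron range, noncollinearity,
#' attenuation or scatter — a pure geometry tracer), and a coincidence is
#' tallied for the crystal pair the two rays strike. `p = counts / n_events`
#' per emission.
#'
#' @param spec,grid,lut as in [analytic_srm_wedge()].
#' @param n_events emissions per wedge blob; 0 yields an empty matrix.
#' @param seed mandatory RNG seed; the build is reproducible given the seed.
#' @param detect `"volume"` (default): a ray hits the first crystal box it
#'   intersects (first-intersected layer wins). `"face"`: a ray hits a
#'   crystal only by crossing its entrance face — the event the
#'   etendue-normalised analytic projector integrates.
#' @param floor sparsity floor on the estimated `p`.
#' @param batch_size events simulated per vectorised batch.
#' @return a LOR-ordered, wedge-folded [sparse_srm].
#' @export
mc_srm_wedge <- function(spec, grid, lut, n_events, seed,
                         detect = c("volume", "face"),
                         floor = 0, batch_size = 100000L) {
  detect <- match.arg(detect)
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  n_events <- assert_count(n_events, "n_events", min = 0L)
  stopifnot(inherits(lut, "symmetry_lut"))
  fr <- crystal_frames(spec)
  nc <- nrow(fr$face)
  centre <- fr$face + (fr$depth / 2) * fr$rhat
  wedge <- lut$wedge_ids
  n_lor <- lut$n_lor
  params <- grid$params
  counts <- matrix(0, n_lor, length(wedge))
  if (n_events > 0) with_local_seed(seed, {
    for (wi in seq_along(wedge)) {
      cen <- grid$centres[wedge[wi] + 1L, ]
      done <- 0L
      while (done < n_events) {
        m <- min(batch_size, n_events - done)
        pts <- sample_blob_points(m, params)
        done <- done + m
        x <- sweep(pts, 2, cen, `+`)
        cz <- runif(m, -1, 1)
        ph <- runif(m, 0, 2 * pi)
        sz <- sqrt(1 - cz^2)
        omega <- cbind(sz * cos(ph), sz * sin(ph), cz)
        hit <- trace_coincidences(x, omega, fr, centre, detect)
        ok <- !is.na(hit$pos) & !is.na(hit$neg)
        if (any(ok)) {
          d <- lor_index(hit$pos[ok] - 1L, hit$neg[ok] - 1L)
          tb <- tabulate(d + 1L, nbins = n_lor)
          counts[, wi] <- counts[, wi] + tb
        }
      }
    }
  })
  p <- counts / max(n_events, 1L)
  p[p < floor] <- 0
  mat <- methods::as(Matrix::Matrix(p, sparse = TRUE), "CsparseMatrix")
  meta <- list(projector = "mc", n_events = n_events, seed = seed,
               detect = detect, floor = floor,
               spec_hash = object_hash(unclass(spec)))
  new_sparse_srm(mat, "lor", n_lor, length(wedge), meta)
}

# Rejection-sample m points with density prop. to the blob profile,
# centred on the origin. psi(0) = 1 bounds the density.
sample_blob_points <- function(m, params) {
  out <- matrix(0, 0, 3)
  a <- params$a
  while (nrow(out) < m) {
    k <- max(2L * (m - nrow(out)), 1000L)
    r <- a * runif(k)^(1 / 3)
    cz <- runif(k, -1, 1)
    ph <- runif(k, 0, 2 * pi)
    keep <- runif(k) < kb_profile(r, params)
    if (any(keep)) {
      r <- r[keep]; cz <- cz[keep]; ph <- ph[keep]
      sz <- sqrt(1 - cz^2)
      out <- rbind(out, cbind(r * sz * cos(ph), r * sz * sin(ph), r * cz))
    }
  }
  out[seq_len(m), , drop = FALSE]
}

# For each event, the 1-based crystal id first struck by the +omega ray
# (pos) and by the -omega ray (neg); NA when a ray escapes.
trace_coincidences <- function(x, omega, fr, centre, detect) {
  m <- nrow(x)
  nc <- nrow(fr$face)
  best_pos <- rep(Inf, m); id_pos <- rep(NA_integer_, m)
  best_neg <- rep(-Inf, m); id_neg <- rep(NA_integer_, m)
  zhat <- c(0, 0, 1)
  for (ci in seq_len(nc)) {
    if (detect == "face") {
      p1 <- (x[, 1] - fr$face[ci, 1]) * fr$rhat[ci, 1] +
        (x[, 2] - fr$face[ci, 2]) * fr$rhat[ci, 2]
      d1 <- omega[, 1] * fr$rhat[ci, 1] + omega[, 2] * fr$rhat[ci, 2]
      t <- ifelse(abs(d1) < 1e-14, NA_real_, -p1 / d1)
      px <- x[, 1] + t * omega[, 1] - fr$face[ci, 1]
      py <- x[, 2] + t * omega[, 2] - fr$face[ci, 2]
      pz <- x[, 3] + t * omega[, 3] - fr$face[ci, 3]
      u <- px * fr$that[ci, 1] + py * fr$that[ci, 2]
      ok <- !is.na(t) & abs(u) <= fr$w_t[ci] / 2 & abs(pz) <= fr$w_z[ci] / 2
      tmin <- ifelse(ok, t, NA_real_); tmax <- tmin
    } else {
      lo <- rep(-Inf, m); hi <- rep(Inf, m)
      axes <- rbind(fr$rhat[ci, ], fr$that[ci, ], zhat)
      half <- c(fr$depth[ci] / 2, fr$w_t[ci] / 2, fr$w_z[ci] / 2)
      for (ax in 1:3) {
        p <- (x[, 1] - centre[ci, 1]) * axes[ax, 1] +
          (x[, 2] - centre[ci, 2]) * axes[ax, 2] +
          (x[, 3] - centre[ci, 3]) * axes[ax, 3]
        d <- omega[, 1] * axes[ax, 1] + omega[, 2] * axes[ax, 2] +
          omega[, 3] * axes[ax, 3]
        par <- abs(d) < 1e-14
        t1 <- (-half[ax] - p) / d
        t2 <- (half[ax] - p) / d
        alo <- pmin(t1, t2); ahi <- pmax(t1, t2)
        alo[par] <- ifelse(abs(p[par]) <= half[ax], -Inf, Inf)
        ahi[par] <- ifelse(abs(p[par]) <= half[ax], Inf, -Inf)
        lo <- pmax(lo, alo); hi <- pmin(hi, ahi)
      }
      hitb <- hi > lo
      tmin <- ifelse(hitb, lo, NA_real_)
      tmax <- ifelse(hitb, hi, NA_real_)
    }
    upd <- !is.na(tmin) & tmin > 0 & tmin < best_pos
    best_pos[upd] <- tmin[upd]; id_pos[upd] <- ci
    upd <- !is.na(tmax) & tmax < 0 & tmax > best_neg
    best_neg[upd] <- tmax[upd]; id_neg[upd] <- ci
  }
  list(pos = id_pos, neg = id_neg)
}

#' Transpose a sparse SRM between LOR and blob ordering
#'
#' Flips the storage ordering: the blob-ordered matrix is the transpose of
#' the LOR-ordered one, stored so that backprojection reads consecutive
#' elements. Values and the nonzero pattern are preserved exactly;
#' transposing twice returns the original ordering.
#'
#' @param srm a [sparse_srm].
#' @return the same matrix with `ordering` flipped.
#' @export
transpose_srm <- function(srm) {
  stopifnot(inherits(srm, "sparse_srm"))
  new_sparse_srm(srm_as_matrix(srm),
                 if (srm$ordering == "lor") "blob" else "lor",
                 srm$n_lor, srm$n_wedge, srm$meta, srm$wedge_folded)
}

#' Look up an unfolded SRM element
#'
#' Returns \eqn{p_{d,b}} for any LOR `d` and any blob `b` of the full grid:
#' `b` is mapped to its canonical wedge blob via the stored transform `T`
#' and the element is read at `(T^{-1}(d), canonical(b))`. Absent elements
#' are 0. By construction the lookup is invariant under the group:
#' `unfold_lookup(T(d), T(b)) == unfold_lookup(d, b)`.
#'
#' @param srm a wedge-folded [sparse_srm].
#' @param lut the matching [build_symmetry_lut()].
#' @param d 0-based LOR index (vectorised, recycled against `b`).
#' @param b 0-based blob index on the full grid.
#' @return numeric vector of detection weights.
#' @export
unfold_lookup <- function(srm, lut, d, b) {
  stopifnot(inherits(srm, "sparse_srm"), srm$wedge_folded,
            inherits(lut, "symmetry_lut"))
  n <- max(length(d), length(b))
  d <- rep_len(as.numeric(d), n); b <- rep_len(as.integer(b), n)
  if (any(d < 0 | d >= lut$n_lor)) stop("LOR index out of range", call. = FALSE)
  if (any(b < 0 | b >= lut$n_blob)) stop("blob index out of range", call. = FALSE)
  canon <- lut$blob_canon[b + 1L]
  tr <- lut$blob_trans[b + 1L]
  col <- lut$wedge_col[canon + 1L]
  dd <- numeric(n)
  for (t in unique(tr)) {
    inv <- invert_transform(lut$spec, t)
    perm <- lor_permutation(lut, inv)
    sel <- tr == t
    dd[sel] <- perm[d[sel] + 1L]
  }
  M <- srm_as_matrix(srm)
  M[cbind(dd + 1L, col)]
}

#' Validate a sparse SRM
#'
#' Checks the structural invariants (non-negative finite values, in-range
#' column indices, non-decreasing row pointers, consistent lengths) and
#' summarises the sparsity.
#'
#' @param srm a [sparse_srm].
#' @return an object of class `srm_report`: a list with `failures`
#'   (character vector, empty when valid), `nnz`, `fill_fraction` and
#'   `row_stats` (tibble of per-row nonzero-count summaries).
#' @export
validate_srm <- function(srm) {
  stopifnot(inherits(srm, "sparse_srm"))
  failures <- character()
  if (any(!is.finite(srm$values))) failures <- c(failures, "non-finite values")
  if (any(srm$values < 0)) failures <- c(failures, "negative values")
  if (any(diff(srm$row_ptr) < 0)) failures <- c(failures, "row_ptr not non-decreasing")
  if (length(srm$row_ptr) != srm$n_rows + 1L)
    failures <- c(failures, "row_ptr length != n_rows + 1")
  if (length(srm$col_idx) != length(srm$values))
    failures <- c(failures, "col_idx/values length mismatch")
  if (length(srm$col_idx) && (min(srm$col_idx) < 0 || max(srm$col_idx) >= srm$n_cols))
    failures <- c(failures, "col_idx out of range")
  if (utils::tail(srm$row_ptr, 1) != length(srm$values))
    failures <- c(failures, "row_ptr end != nnz")
  per_row <- diff(srm$row_ptr)
  structure(list(
    failures = failures,
    nnz = length(srm$values),
    fill_fraction = length(srm$values) / (srm$n_rows * srm$n_cols),
    row_stats = tibble::tibble(
      min_nnz = if (length(per_row)) min(per_row) else 0,
      median_nnz = if (length(per_row)) stats::median(per_row) else 0,
      max_nnz = if (length(per_row)) max(per_row) else 0,
      empty_rows = sum(per_row == 0))),
    class = "srm_report")
}

#' @export
print.srm_report <- function(x, ...) {
  if (length(x$failures)) {
    cat("SRM INVALID:\n")
    for (f in x$failures) cat("  - ", f, "\n", sep = "")
  } else cat("SRM valid.\n")
  cat(sprintf("nnz %s, fill %.4g; per-row nnz min/median/max %g/%g/%g, %d empty rows\n",
              format(x$nnz, big.mark = ","), x$fill_fraction,
              x$row_stats$min_nnz, x$row_stats$median_nnz, x$row_stats$max_nnz,
              x$row_stats$empty_rows))
  invisible(x)
}
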