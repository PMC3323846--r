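#' Symmetry transforms of a polygonal scanner
#'
#' A scanner with `n` modules admits `n` rotational symmetries (module
#' steps), a transaxial mirror (reflection through the plane containing the
#' scanner axis and the centre of module 0) and an axial mirror (reflection
#' through the central transaxial plane), generating a group of up to `4n`
#' transforms (72 for the default 18-module scanner). A transform is
#' identified by a flat id in `[0, 4n)` encoding
#' `id = rot + n * mirror_t + 2n * mirror_z`; mirrors act first, then the
#' rotation. The identity has id 0.
#'
#' @param spec a [scanner_spec()].
#' @param id transform id(s) in `[0, 4 * n_modules)`.
#' @return `transform_params()`: a tibble with columns `id`, `rot`,
#'   `mirror_t`, `mirror_z`.
#' @export
transform_params <- function(spec, id) {
  n <- spec$n_modules
  if (any(id < 0 | id >= 4 * n)) stop("transform id out of range", call. = FALSE)
  id <- as.integer(id)
  tibble::tibble(id = id, rot = id %% n,
                 mirror_t = (id %/% n) %% 2L,
                 mirror_z = id %/% (2L * n))
}

transform_id <- function(spec, rot, mirror_t, mirror_z) {
  n <- spec$n_modules
  as.integer((rot %% n) + n * (mirror_t %% 2L) + 2L * n * (mirror_z %% 2L))
}

#' Compose and invert symmetry transforms
#'
#' `compose_transform(spec, t1, t2)` returns the transform acting as
#' "apply `t2`, then `t1`". The transaxial part follows the dihedral
#' relation `m r^k = r^(-k) m`; the axial mirror commutes with everything.
#'
#' @param spec a [scanner_spec()].
#' @param t1,t2,t transform ids.
#' @return a transform id.
#' @export
compose_transform <- function(spec, t1, t2) {
  n <- spec$n_modules
  p1 <- transform_params(spec, t1); p2 <- transform_params(spec, t2)
  rot <- (p1$rot + ifelse(p1$mirror_t == 1L, -p2$rot, p2$rot)) %% n
  transform_id(spec, rot, xor(p1$mirror_t == 1L, p2$mirror_t == 1L),
               xor(p1$mirror_z == 1L, p2$mirror_z == 1L))
}

#' @rdname compose_transform
#' @export
invert_transform <- function(spec, t) {
  p <- transform_params(spec, t)
  rot <- ifelse(p$mirror_t == 1L, p$rot, (-p$rot) %% spec$n_modules)
  transform_id(spec, rot, p$mirror_t, p$mirror_z)
}

# -- group action on index spaces -------------------------------------------

apply_transform_crystal <- function(spec, t, crystal) {
  p <- transform_params(spec, t)
  stopifnot(nrow(p) == 1L)
  tp <- crystal_tuple(spec, crystal)
  z <- if (p$mirror_z == 1L) spec$crystals_axial - 1L - tp$axial else tp$axial
  m <- tp$module; tt <- tp$tangential
  if (p$mirror_t == 1L) {
    m <- (spec$n_modules - m) %% spec$n_modules
    tt <- spec$crystals_tangential - 1L - tt
  }
  m <- (m + p$rot) %% spec$n_modules
  crystal_flat_id(spec, m, tp$layer, tt, z)
}

apply_transform_lor <- function(spec, t, d) {
  pr <- lor_unindex(d)
  lor_index(apply_transform_crystal(spec, t, pr$c1),
            apply_transform_crystal(spec, t, pr$c2))
}

apply_transform_blob <- function(grid, t, b, spec = NULL) {
  n <- if (!is.null(spec)) spec$n_modules else grid$n_modules
  if (is.null(n)) stop("blob transforms need the paired scanner's module count", call. = FALSE)
  nr <- grid$n_radial; na <- grid$n_angular; nz <- grid$n_axial
  if (any(b < 0 | b >= nr * na * nz)) stop("blob id out of range", call. = FALSE)
  if (na %% n != 0) stop("angular count not commensurate with the module count", call. = FALSE)
  step <- na %/% n
  rot <- t %% n; mt <- (t %/% n) %% 2L; mz <- t %/% (2L * n)
  b <- as.integer(b)
  kr <- b %% nr; j <- (b %/% nr) %% na; kz <- b %/% (nr * na)
  if (mz == 1L) kz <- nz - 1L - kz
  if (mt == 1L) j <- (na - 1L - j) %% na   # centres at 2*pi*(j + 1/2)/na
  j <- (j + rot * step) %% na
  as.integer(kr + nr * (j + na * kz))
}

#' Apply a symmetry transform to a crystal, LOR or blob index
#'
#' Rotation increments the module index modulo `n_modules`; the transaxial
#' mirror reverses the module order about the wedge axis and flips the
#' tangential index within a module; the axial mirror reverses the axial
#' index. An LOR transform maps both endpoint crystals and re-canonicalises
#' the pair; a blob transform acts on the polar-grid indices.
#'
#' @param t a transform id (see [transform_params()]).
#' @param x 0-based index/indices of the kind given.
#' @param kind one of `"crystal"`, `"lor"`, `"blob"`.
#' @param spec a [scanner_spec()] (required for all kinds).
#' @param grid a [build_polar_grid()] grid (required for `kind = "blob"`).
#' @return transformed indices of the same kind.
#' @export
apply_transform <- function(t, x, kind = c("crystal", "lor", "blob"),
                            spec = NULL, grid = NULL) {
  kind <- match.arg(kind)
  if (is.null(spec)) stop("`spec` is required", call. = FALSE)
  p <- transform_params(spec, t)  # validates range
  switch(kind,
         crystal = apply_transform_crystal(spec, t, x),
         lor = {
           if (any(x < 0 | x >= lor_count(spec))) stop("LOR index out of range", call. = FALSE)
           apply_transform_lor(spec, t, x)
         },
         blob = {
           if (is.null(grid)) stop("`grid` is required for blob transforms", call. = FALSE)
           apply_transform_blob(grid, t, x, spec = spec)
         })
}

#' Enumerate the symmetry group of a scanner
#'
#' Builds the closure of the generator set (one module-step rotation, the
#' transaxial mirror, the axial mirror) under composition and returns all
#' distinct elements. For an `n`-module scanner the group has order `4n`
#' (72 for the default spec).
#'
#' @param spec a [scanner_spec()].
#' @return a tibble of group elements (columns as [transform_params()]),
#'   sorted by id; the identity (id 0) comes first.
#' @examples
#' nrow(symmetry_group(scanner_spec()))  # 72
#' @export
symmetry_group <- function(spec) {
  n <- spec$n_modules
  gens <- unique(c(if (n > 1L) 1L else integer(), n, 2L * n))
  elems <- 0L
  repeat {
    new <- unique(as.integer(outer(elems, gens,
                                   function(a, b) compose_transform(spec, a, b))))
    grown <- union(elems, new)
    if (length(grown) == length(elems)) break
    elems <- grown
  }
  transform_params(spec, sort(elems))
}

#' Fold/unfold look-up table for the scanner symmetry group
#'
#' For every blob of a polar grid (and optionally every LOR), finds the
#' canonical representative of its orbit under the full symmetry group
#' (the orbit member with the minimum flat index) and one transform that
#' maps the canonical element onto it. The canonical blobs form the
#' "wedge": the folded system matrix stores detection weights only for
#' wedge blobs, and this table regenerates all other elements, visiting
#' each real blob exactly once (orbits smaller than the group order are
#' handled by the unique stored decomposition, never by weighting).
#'
#' @param spec a [scanner_spec()].
#' @param grid a [build_polar_grid()] grid; its angular count must be
#'   divisible by `2 * n_modules`.
#' @param lor_records also compute per-LOR canonical/transform records
#'   (costs one pass over all LORs per transform; switch off for very
#'   large scanners when only blob folding is needed).
#' @return an object of class `symmetry_lut` with fields `blob_canon`,
#'   `blob_trans` (0-based, per blob), `wedge_ids` (sorted canonical blob
#'   ids), `n_transforms`, and optionally `lor_canon`, `lor_trans`.
#' @export
build_symmetry_lut <- function(spec, grid, lor_records = TRUE) {
  stopifnot(inherits(spec, "scanner_spec"), inherits(grid, "polar_blob_grid"))
  n <- spec$n_modules
  if (grid$n_angular %% (2L * n) != 0L)
    stop(sprintf(paste("grid is incommensurate with the symmetry wedge:",
                       "n_angular = %d is not divisible by 2 * n_modules = %d"),
                 grid$n_angular, 2L * n), call. = FALSE)
  n_tr <- 4L * n
  n_blob <- grid$n_blobs
  ids <- 0:(n_blob - 1L)
  P <- vapply(0:(n_tr - 1L), function(t) apply_transform_blob(grid, t, ids, spec = spec),
              integer(n_blob))
  blob_canon <- ids
  for (t in seq_len(n_tr)) blob_canon <- pmin(blob_canon, P[, t])
  blob_trans <- rep(NA_integer_, n_blob)
  for (t in seq_len(n_tr)) {
    hit <- is.na(blob_trans) & (P[cbind(blob_canon + 1L, t)] == ids)
    blob_trans[hit] <- t - 1L
  }
  wedge_ids <- sort(unique(blob_canon))
  wedge_col <- rep(NA_integer_, n_blob)
  wedge_col[wedge_ids + 1L] <- seq_along(wedge_ids)
  # blob_by_transform[w, t+1]: the blob that transform t generates from wedge blob w
  blob_by_transform <- matrix(NA_integer_, length(wedge_ids), n_tr)
  blob_by_transform[cbind(wedge_col[blob_canon + 1L], blob_trans + 1L)] <- ids
  lut <- list(spec = spec, grid = grid, n_transforms = n_tr,
              n_lor = lor_count(spec), n_blob = n_blob,
              blob_canon = blob_canon, blob_trans = blob_trans,
              wedge_ids = wedge_ids, wedge_col = wedge_col,
              blob_by_transform = blob_by_transform,
              lor_canon = NULL, lor_trans = NULL,
              cache = new.env(parent = emptyenv()))
  class(lut) <- "symmetry_lut"
  if (lor_records) {
    n_lor <- lut$n_lor
    d <- 0:(n_lor - 1L)
    lor_canon <- d
    for (t in 0:(n_tr - 1L)) lor_canon <- pmin(lor_canon, lor_permutation(lut, t))
    lor_trans <- rep(NA_integer_, n_lor)
    for (t in 0:(n_tr - 1L)) {
      perm <- lor_permutation(lut, t)
      hit <- is.na(lor_trans) & (perm[lor_canon + 1L] == d)
      lor_trans[hit] <- t
    }
    lut$lor_canon <- lor_canon
    lut$lor_trans <- lor_trans
  }
  lut
}

#' @export
print.symmetry_lut <- function(x, ...) {
  cat(sprintf("<symmetry_lut> %d transforms; %d blobs -> %d wedge blobs; %s LORs\n",
              x$n_transforms, x$n_blob, length(x$wedge_ids),
              format(x$n_lor, big.mark = ",")))
  invisible(x)
}

# Permutation of LOR indices under transform t: perm[d + 1] = t(d) (0-based).
# Cached per transform; derived from the crystal-level action.
lor_permutation <- function(lut, t) {
  key <- paste0("lor", t)
  if (!is.null(lut$cache[[key]])) return(lut$cache[[key]])
  spec <- lut$spec
  if (is.null(lut$cache$pairs)) {
    lut$cache$pairs <- lor_unindex(0:(lut$n_lor - 1L))
    nc <- n_crystals(spec)
    lut$cache$cperm <- vapply(0:(lut$n_transforms - 1L),
                              function(tt) apply_transform_crystal(spec, tt, 0:(nc - 1L)),
                              integer(nc))
  }
  cp <- lut$cache$cperm[, t + 1L]
  perm <- lor_index(cp[lut$cache$pairs$c1 + 1L], cp[lut$cache$pairs$c2 + 1L])
  perm <- as.integer(perm)
  lut$cache[[key]] <- perm
  perm
}
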