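#' File formats
#'
#' All binary containers are little-endian with a 4-byte magic and an
#' int32 format version, paired with a `<path>.json` sidecar describing
#' dimensions, dtypes and provenance. Reads cross-check the sidecar
#' against the array lengths and fail loudly on truncation or mismatch.
#'
#' \describe{
#'   \item{SRM (`BSRM` v1)}{header: magic, version, n_rows, n_cols (int32),
#'     nnz (int64); arrays: row_ptr (int64, n_rows + 1), col_idx (int32,
#'     nnz), values (float64, nnz). Ordering, wedge dimensions and
#'     provenance live in the sidecar.}
#'   \item{LOR histogram (`BLHI` v1)}{header: magic, version, n (int32);
#'     array: counts (int32, non-negative).}
#'   \item{Coefficients (`BCOF` v1)}{header: magic, version, n (int32);
#'     array: c (float64).}
#' }
#' @name blobpet_formats
NULL

write_i64 <- function(con, x) {
  # little-endian int64 emitted as two uint32 words (values < 2^53 exact)
  lo <- as.integer(x %% 2^32 - (x %% 2^32 >= 2^31) * 2^32)
  hi <- as.integer(x %/% 2^32)
  inter <- integer(2L * length(x))
  inter[seq(1, length(inter), 2)] <- lo
  inter[seq(2, length(inter), 2)] <- hi
  writeBin(inter, con, size = 4L, endian = "little")
}

read_i64 <- function(con, n) {
  w <- readBin(con, "integer", n = 2L * n, size = 4L, endian = "little")
  if (length(w) < 2L * n) stop("truncated file: int64 array short", call. = FALSE)
  lo <- w[seq(1, length(w), 2)]
  hi <- w[seq(2, length(w), 2)]
  (as.numeric(lo) %% 2^32) + as.numeric(hi) * 2^32
}

read_exact <- function(con, what, n, size) {
  x <- readBin(con, what, n = n, size = size, endian = "little")
  if (length(x) < n) stop("truncated file: array shorter than declared", call. = FALSE)
  x
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, info) {
  jsonlite::write_json(info, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop(sprintf("sidecar '%s' is missing", sc), call. = FALSE)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' Write / read a sparse SRM
#'
#' Lossless round trip of a [sparse_srm] through the `BSRM` binary format
#' plus JSON sidecar (see [blobpet_formats]).
#'
#' @param srm a [sparse_srm].
#' @param path output file; the sidecar goes to `paste0(path, ".json")`.
#' @return `write_srm()`: the path, invisibly. `read_srm()`: the SRM.
#' @export
write_srm <- function(srm, path) {
  stopifnot(inherits(srm, "sparse_srm"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BSRM"), con)
  writeBin(as.integer(c(1L, srm$n_rows, srm$n_cols)), con, size = 4L,
           endian = "little")
  write_i64(con, length(srm$values))
  write_i64(con, srm$row_ptr)
  writeBin(srm$col_idx, con, size = 4L, endian = "little")
  writeBin(srm$values, con, size = 8L, endian = "little")
  write_sidecar(path, list(
    format = "BSRM", version = 1L, ordering = srm$ordering,
    n_rows = srm$n_rows, n_cols = srm$n_cols, nnz = length(srm$values),
    n_lor = srm$n_lor, n_wedge = srm$n_wedge, wedge_folded = srm$wedge_folded,
    dtypes = list(row_ptr = "int64le", col_idx = "int32le", values = "float64le"),
    meta = srm$meta))
  invisible(path)
}

#' @rdname write_srm
#' @export
read_srm <- function(path) {
  info <- read_sidecar(path)
  if (!identical(info$format, "BSRM") || info$version != 1L)
    stop("not a BSRM v1 file (sidecar format/version mismatch)", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic), "BSRM")) stop("bad magic: not a BSRM file", call. = FALSE)
  hdr <- read_exact(con, "integer", 3L, 4L)
  if (hdr[1] != 1L) stop("unsupported BSRM version", call. = FALSE)
  n_rows <- hdr[2]; n_cols <- hdr[3]
  nnz <- read_i64(con, 1L)
  if (n_rows != info$n_rows || n_cols != info$n_cols || nnz != info$nnz)
    stop("sidecar dimensions disagree with the binary header", call. = FALSE)
  row_ptr <- read_i64(con, n_rows + 1L)
  col_idx <- read_exact(con, "integer", nnz, 4L)
  values <- read_exact(con, "numeric", nnz, 8L)
  if (utils::tail(row_ptr, 1) != nnz)
    stop("row_ptr end disagrees with nnz", call. = FALSE)
  if (nnz > 0 && (min(col_idx) < 0 || max(col_idx) >= n_cols))
    stop("col_idx out of range", call. = FALSE)
  ordering <- info$ordering
  n_lor <- info$n_lor; n_wedge <- info$n_wedge
  rows <- rep(seq_len(n_rows), diff(row_ptr))
  mat <- if (ordering == "lor") {
    Matrix::sparseMatrix(i = rows, j = col_idx + 1L, x = values,
                         dims = c(n_lor, n_wedge))
  } else {
    Matrix::sparseMatrix(i = col_idx + 1L, j = rows, x = values,
                         dims = c(n_lor, n_wedge))
  }
  new_sparse_srm(mat, ordering, n_lor, n_wedge, info$meta,
                 isTRUE(info$wedge_folded))
}

#' Write / read a LOR histogram
#'
#' @param hist a [lor_histogram()].
#' @param path output file (sidecar at `paste0(path, ".json")`).
#' @param spec optional [scanner_spec()]; on read, the histogram length is
#'   checked against its LOR count.
#' @return `write_histogram()`: the path, invisibly. `read_histogram()`:
#'   the histogram.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "lor_histogram"))
  if (any(hist$counts >= 2^31))
    stop("counts exceed the int32 range of the BLHI format", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BLHI"), con)
  writeBin(c(1L, length(hist$counts)), con, size = 4L, endian = "little")
  writeBin(as.integer(hist$counts), con, size = 4L, endian = "little")
  write_sidecar(path, list(format = "BLHI", version = 1L,
                           n = length(hist$counts),
                           total = sum(hist$counts), meta = hist$meta))
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path, spec = NULL) {
  info <- read_sidecar(path)
  if (!identical(info$format, "BLHI") || info$version != 1L)
    stop("not a BLHI v1 file", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic), "BLHI")) stop("bad magic: not a BLHI file", call. = FALSE)
  hdr <- read_exact(con, "integer", 2L, 4L)
  if (hdr[1] != 1L) stop("unsupported BLHI version", call. = FALSE)
  n <- hdr[2]
  if (n != info$n) stop("sidecar length disagrees with the binary header", call. = FALSE)
  counts <- read_exact(con, "integer", n, 4L)
  if (any(counts < 0)) stop("negative counts in histogram file", call. = FALSE)
  if (!is.null(spec) && n != lor_count(spec))
    stop(sprintf("histogram length %d does not match the scanner's %d LORs",
                 n, lor_count(spec)), call. = FALSE)
  lor_histogram(counts, meta = info$meta)
}

#' Write / read a blob coefficient vector
#'
#' @param image a [blob_image()] or numeric vector.
#' @param path output file.
#' @param meta optional provenance list.
#' @return `write_coefficients()`: the path, invisibly.
#'   `read_coefficients()`: a numeric vector with the sidecar `meta`
#'   attached as an attribute.
#' @export
write_coefficients <- function(image, path, meta = list()) {
  cf <- if (inherits(image, "blob_image")) image$c else as.numeric(image)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BCOF"), con)
  writeBin(c(1L, length(cf)), con, size = 4L, endian = "little")
  writeBin(cf, con, size = 8L, endian = "little")
  write_sidecar(path, list(format = "BCOF", version = 1L, n = length(cf),
                           meta = meta))
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  info <- read_sidecar(path)
  if (!identical(info$format, "BCOF") || info$version != 1L)
    stop("not a BCOF v1 file", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic), "BCOF")) stop("bad magic: not a BCOF file", call. = FALSE)
  hdr <- read_exact(con, "integer", 2L, 4L)
  n <- hdr[2]
  if (n != info$n) stop("sidecar length disagrees with the binary header", call. = FALSE)
  cf <- read_exact(con, "numeric", n, 8L)
  attr(cf, "meta") <- info$meta
  cf
}

#' Export a rasterised volume
#'
#' `write_volume_nifti()` writes NIfTI-1 with the isotropic voxel size in
#' the header; `write_volume_raw()` writes raw little-endian float32 plus
#' a JSON sidecar with the grid.
#'
#' @param volume a `blob_volume` from [rasterize()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  vg <- attr(volume, "voxel_grid")
  img <- RNifti::asNifti(unclass(volume) + 0)
  RNifti::pixdim(img) <- rep(vg$voxel_mm, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
write_volume_raw <- function(volume, path) {
  vg <- attr(volume, "voxel_grid")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(volume), con, size = 4L, endian = "little")
  write_sidecar(path, list(format = "RAWVOL", version = 1L,
                           dim = c(vg$nx, vg$ny, vg$nz),
                           voxel_mm = vg$voxel_mm, origin = vg$origin,
                           dtype = "float32le", order = "x-fastest"))
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

#' Default run configuration
#'
#' The nested configuration consumed by [run_cli()] and the config-driven
#' builders. Every block is optional in user files; omitted fields take
#' these defaults. The defaults describe the full-size scanner and the
#' nominal study: MADPET-II geometry, 0.5 mm grid spacing with the optimal
#' blob parameters, a 16-chord analytic projector, the image-quality
#' phantom at 4.5e7 total coincidences and 300 ML-EM iterations.
#'
#' @return a nested list.
#' @export
default_run_config <- function() {
  list(
    scanner = list(n_modules = 18L, n_layers = 2L, crystals_tangential = 4L,
                   crystals_axial = 8L,
                   crystal_size_mm = list(c(2, 2, 6), c(2, 2, 8)),
                   layer_face_radius_mm = c(35.5, 41.5),
                   axial_pitch_mm = 18.1 / 8, tangential_pitch_mm = NULL),
    grid = list(n_radial = 64L, n_angular = 108L, n_axial = 36L, delta = 0.5,
                m = 2L, a = NULL, alpha = 10.4),
    srm = list(projector = "analytic", n_rays = 16L, pairing = "matched",
               n_events = 100000L, floor = 1e-9, seed = NULL,
               normalization = "footprint"),
    simulate = list(phantom = "image_quality", total_counts = 4.5e7,
                    seed = NULL, scale = 1, rod_offset = 15),
    recon = list(iters = 300L, strategy = "transpose", init = 1.0,
                 log_every = 10L),
    raster = list(nx = 140L, ny = 140L, nz = 40L, voxel_mm = 0.5),
    fom = list(rois = list(
      list(label = "hot", centre = c(15, 0, 0), dim = c(8, 9, 0.5)),
      list(label = "warm", centre = c(0, 15, 0), dim = c(8, 9, 0.5)),
      list(label = "cold", centre = c(-15, 0, 0), dim = c(8, 9, 0.5)))))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; missing blocks/fields fall back to
#'   [default_run_config()].
#' @return the merged configuration list.
#' @export
read_run_config <- function(path) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  merge_config(default_run_config(), user %||% list())
}

#' Hash a configuration for provenance
#'
#' @param cfg a configuration list.
#' @return md5 hex string of the canonical JSON rendering.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(f))
}

# Config-block builders shared by the CLI and scripts.
scanner_from_config <- function(cfg) {
  s <- cfg$scanner
  scanner_spec(n_modules = s$n_modules, n_layers = s$n_layers,
               crystals_tangential = s$crystals_tangential,
               crystals_axial = s$crystals_axial,
               crystal_size_mm = s$crystal_size_mm,
               layer_face_radius_mm = s$layer_face_radius_mm,
               axial_pitch_mm = s$axial_pitch_mm,
               tangential_pitch_mm = s$tangential_pitch_mm)
}

grid_from_config <- function(cfg) {
  g <- cfg$grid
  params <- blob_params(delta = g$delta, m = g$m,
                        a = g$a %||% (1.994 * g$delta), alpha = g$alpha)
  build_polar_grid(g$n_radial, g$n_angular, g$n_axial, g$delta,
                   params = params, n_modules = cfg$scanner$n_modules)
}

#' @rdname write_volume_nifti
#' @export
read_volume_raw <- function(path) {
  info <- read_sidecar(path)
  if (!identical(info$format, "RAWVOL") || info$version != 1L)
    stop("not a RAWVOL v1 file", call. = FALSE)
  dm <- as.integer(info$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- read_exact(con, "numeric", prod(dm), 4L)
  vg <- voxel_grid(dm[1], dm[2], dm[3], info$voxel_mm,
                   origin = as.numeric(info$origin))
  structure(array(vals, dim = dm), voxel_grid = vg,
            class = c("blob_volume", "array"))
}

voxel_grid_from_config <- function(cfg) {
  r <- cfg$raster
  voxel_grid(r$nx, r$ny, r$nz, r$voxel_mm)
}
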