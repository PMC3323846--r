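#' Describe a polygonal dual-layer PET scanner
#'
#' A scanner is a ring of `n_modules` flat detector modules, each holding
#' `n_layers` layers of `crystals_tangential` x `crystals_axial` crystals.
#' The default reproduces the MADPET-II small-animal scanner: 18 modules,
#' two LYSO layers of 4 x 8 crystals each, front crystals 2 x 2 x 6 mm
#' (tangential x axial x radial), rear crystals 2 x 2 x 8 mm, front faces
#' at 35.5 mm radius (71 mm bore diameter) and an 18.1 mm axial field of
#' view. Dual layers give two discrete depths of interaction, which
#' mitigates parallax error for off-centre sources.
#'
#' Inter-crystal gaps are not modelled by default: the tangential pitch
#' equals the crystal width and the axial pitch spreads the crystals over
#' the axial field of view. Both are configurable.
#'
#' @param n_modules number of polygon sides (flat modules) in the ring.
#' @param n_layers number of radial crystal layers per module.
#' @param crystals_tangential,crystals_axial crystals per module per layer.
#' @param crystal_size_mm list (length `n_layers`) of
#'   `(tangential, axial, radial)` crystal dimensions in mm.
#' @param layer_face_radius_mm radius of each layer's entrance face in mm.
#' @param axial_pitch_mm centre-to-centre axial crystal spacing in mm.
#' @param tangential_pitch_mm centre-to-centre tangential spacing in mm;
#'   defaults to the tangential width of the first layer's crystals (no gap).
#' @return An object of class `scanner_spec`.
#' @examples
#' sp <- scanner_spec()
#' n_crystals(sp)   # 1152
#' @export
scanner_spec <- function(n_modules = 18L, n_layers = 2L,
                         crystals_tangential = 4L, crystals_axial = 8L,
                         crystal_size_mm = list(c(2, 2, 6), c(2, 2, 8)),
                         layer_face_radius_mm = c(35.5, 41.5),
                         axial_pitch_mm = 18.1 / 8,
                         tangential_pitch_mm = NULL) {
  n_modules <- assert_count(n_modules, "n_modules", min = 1L)
  n_layers <- assert_count(n_layers, "n_layers", min = 1L)
  crystals_tangential <- assert_count(crystals_tangential, "crystals_tangential")
  crystals_axial <- assert_count(crystals_axial, "crystals_axial")
  if (is.matrix(crystal_size_mm)) {
    crystal_size_mm <- lapply(seq_len(nrow(crystal_size_mm)),
                              function(i) crystal_size_mm[i, ])
  }
  if (!is.list(crystal_size_mm) || length(crystal_size_mm) != n_layers)
    stop("`crystal_size_mm` must list one (tangential, axial, radial) triple per layer",
         call. = FALSE)
  size <- do.call(rbind, lapply(crystal_size_mm, function(s) {
    assert_positive(s, "crystal_size_mm", n = 3L)
  }))
  colnames(size) <- c("tangential", "axial", "radial")
  layer_face_radius_mm <- assert_positive(layer_face_radius_mm,
                                          "layer_face_radius_mm", n = n_layers)
  axial_pitch_mm <- assert_positive(axial_pitch_mm, "axial_pitch_mm")
  tangential_pitch_mm <- assert_positive(
    tangential_pitch_mm %||% size[1L, "tangential"], "tangential_pitch_mm")
  structure(
    list(n_modules = n_modules, n_layers = n_layers,
         crystals_tangential = crystals_tangential,
         crystals_axial = crystals_axial,
         crystal_size_mm = size,
         layer_face_radius_mm = as.numeric(layer_face_radius_mm),
         axial_pitch_mm = as.numeric(axial_pitch_mm),
         tangential_pitch_mm = as.numeric(tangential_pitch_mm)),
    class = "scanner_spec")
}

#' @export
print.scanner_spec <- function(x, ...) {
  cat(sprintf("<scanner_spec> %d modules x %d layers x %d x %d crystals (%d total)\n",
              x$n_modules, x$n_layers, x$crystals_tangential, x$crystals_axial,
              n_crystals(x)))
  cat(sprintf("  face radii %s mm; axial FOV %.3f mm\n",
              paste(format(x$layer_face_radius_mm), collapse = ", "),
              x$crystals_axial * x$axial_pitch_mm))
  invisible(x)
}

#' Total number of crystals of a scanner
#' @param spec a [scanner_spec()].
#' @return integer crystal count.
#' @export
n_crystals <- function(spec) {
  stopifnot(inherits(spec, "scanner_spec"))
  spec$n_modules * spec$n_layers * spec$crystals_tangential * spec$crystals_axial
}

# Flat crystal id (0-based) <-> (module, layer, tangential, axial), all 0-based.
# Axial index varies fastest, then tangential, then layer, then module.
crystal_tuple <- function(spec, id) {
  nz <- spec$crystals_axial; nt <- spec$crystals_tangential; nl <- spec$n_layers
  if (any(id < 0 | id >= n_crystals(spec))) stop("crystal id out of range", call. = FALSE)
  id <- as.integer(id)
  list(module = id %/% (nz * nt * nl),
       layer = (id %/% (nz * nt)) %% nl,
       tangential = (id %/% nz) %% nt,
       axial = id %% nz)
}

crystal_flat_id <- function(spec, module, layer, tangential, axial) {
  nz <- spec$crystals_axial; nt <- spec$crystals_tangential; nl <- spec$n_layers
  as.integer(axial + nz * (tangential + nt * (layer + nl * module)))
}

# Per-module frame: phi in radians; rhat points outward, that tangential.
module_frame <- function(spec, module) {
  phi <- 2 * pi * module / spec$n_modules
  list(phi = phi, rx = cos(phi), ry = sin(phi), tx = -sin(phi), ty = cos(phi))
}

#' Build the per-crystal geometry table
#'
#' Enumerates every crystal of the scanner and records its indices, the
#' centre of its entrance face in mm, and its inward-pointing unit normal.
#' Modules sit at angles `2*pi*k/n_modules`; within a module, crystals are
#' laid out symmetrically about the module centre.
#'
#' @param spec a [scanner_spec()].
#' @return A tibble with one row per crystal: `id` (0-based flat index),
#'   `module`, `layer`, `tangential`, `axial` (0-based indices),
#'   `x`, `y`, `z` (face-centre, mm) and `nx`, `ny`, `nz` (inward normal).
#' @examples
#' nrow(build_crystal_table(scanner_spec()))  # 1152
#' @export
build_crystal_table <- function(spec) {
  stopifnot(inherits(spec, "scanner_spec"))
  ids <- 0:(n_crystals(spec) - 1L)
  tp <- crystal_tuple(spec, ids)
  fr <- module_frame(spec, tp$module)
  u <- (tp$tangential - (spec$crystals_tangential - 1) / 2) * spec$tangential_pitch_mm
  zc <- (tp$axial - (spec$crystals_axial - 1) / 2) * spec$axial_pitch_mm
  R <- spec$layer_face_radius_mm[tp$layer + 1L]
  tibble::tibble(
    id = ids, module = tp$module, layer = tp$layer,
    tangential = tp$tangential, axial = tp$axial,
    x = R * fr$rx + u * fr$tx,
    y = R * fr$ry + u * fr$ty,
    z = zc,
    nx = -fr$rx, ny = -fr$ry, nz = 0)
}

#' Flat index of a line of response (LOR)
#'
#' An LOR is an unordered pair of distinct crystals. The flat index follows
#' the dense triangular convention `d = c2 * (c2 - 1) / 2 + c1` with
#' `c1 < c2` and all indices 0-based, so `d` runs over
#' `[0, C * (C - 1) / 2)` for `C` crystals.
#'
#' @param c1,c2 0-based crystal ids (vectorised); order is irrelevant.
#' @return 0-based LOR index (double, exact for any realistic scanner).
#' @examples
#' lor_index(0, 1)         # 0
#' lor_index(1150, 1151)   # 662975
#' @export
lor_index <- function(c1, c2) {
  if (any(c1 == c2)) stop("an LOR needs two distinct crystals", call. = FALSE)
  if (any(c1 < 0) || any(c2 < 0)) stop("crystal ids must be >= 0", call. = FALSE)
  lo <- pmin(c1, c2); hi <- pmax(c1, c2)
  hi * (hi - 1) / 2 + lo
}

#' @rdname lor_index
#' @param d 0-based LOR index (vectorised).
#' @return `lor_unindex()`: a list with components `c1 < c2`.
#' @export
lor_unindex <- function(d) {
  if (any(d < 0)) stop("LOR index must be >= 0", call. = FALSE)
  d <- as.numeric(d)
  hi <- floor((1 + sqrt(1 + 8 * d)) / 2)
  # guard against floating error in the square root
  hi <- hi - (hi * (hi - 1) / 2 > d)
  hi <- hi + ((hi + 1) * hi / 2 <= d)
  list(c1 = as.integer(d - hi * (hi - 1) / 2), c2 = as.integer(hi))
}

#' Number of LORs of a scanner
#'
#' @param spec a [scanner_spec()], or an integer crystal count.
#' @return `C * (C - 1) / 2` for `C` crystals.
#' @examples
#' lor_count(scanner_spec())  # 662976
#' @export
lor_count <- function(spec) {
  C <- if (inherits(spec, "scanner_spec")) n_crystals(spec) else assert_count(spec, "spec", 1L)
  C * (C - 1) / 2
}

#' Export a crystal table as CSV
#'
#' @param spec a [scanner_spec()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_crystal_csv <- function(spec, path) {
  tab <- build_crystal_table(spec)
  write.csv(tab[, c("id", "module", "layer", "tangential", "axial", "x", "y", "z")],
            path, row.names = FALSE)
  invisible(path)
}
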