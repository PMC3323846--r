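# Shared fixtures, built once per test run and cached.
#
# The "mini" scanner is a 6-module single-layer ring of 2 x 2 crystal
# modules (4 x 4 x 2 mm crystals, faces at 16 mm): 24 crystals, 276 LORs,
# symmetry group of order 24 - small enough for dense brute-force oracles.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

mini_spec <- function() fixture("mini_spec", function() {
  scanner_spec(n_modules = 6, n_layers = 1, crystals_tangential = 2,
               crystals_axial = 2, crystal_size_mm = list(c(4, 4, 2)),
               layer_face_radius_mm = 16, axial_pitch_mm = 4)
})

mini_grid <- function() fixture("mini_grid", function() {
  build_polar_grid(3, 12, 2, delta = 2, n_modules = 6)
})

mini_lut <- function() fixture("mini_lut", function() {
  build_symmetry_lut(mini_spec(), mini_grid())
})

# Analytic folded SRM on the mini scanner, no sparsity floor.
mini_srm <- function() fixture("mini_srm", function() {
  analytic_srm_wedge(mini_spec(), mini_grid(), mini_lut(), n_rays = 16, floor = 0)
})

# Independent brute-force oracle: the full (unfolded) footprint SRM built
# by direct loops over every LOR, every blob and every chord, using no
# symmetry machinery. Mirrors the projector definition only.
brute_force_srm <- function(spec, grid, n_rays = 16) {
  tab <- build_crystal_table(spec)
  k <- sqrt(n_rays)
  offs <- as.matrix(expand.grid(u = ((seq_len(k) - 0.5) / k) - 0.5,
                                v = ((seq_len(k) - 0.5) / k) - 0.5))
  n_lor <- lor_count(spec)
  pr <- lor_unindex(0:(n_lor - 1))
  Fc <- cbind(tab$x, tab$y, tab$z)
  phi <- 2 * pi * tab$module / spec$n_modules
  that <- cbind(-sin(phi), cos(phi), 0)
  wt <- spec$crystal_size_mm[tab$layer + 1L, "tangential"]
  wz <- spec$crystal_size_mm[tab$layer + 1L, "axial"]
  out <- matrix(0, n_lor, grid$n_blobs)
  one <- rep(1, n_lor)
  for (r in seq_len(nrow(offs))) {
    A <- Fc[pr$c1 + 1, ] + offs[r, 1] * wt[pr$c1 + 1] * that[pr$c1 + 1, ] +
      cbind(0 * one, 0 * one, offs[r, 2] * wz[pr$c1 + 1])
    B <- Fc[pr$c2 + 1, ] + offs[r, 1] * wt[pr$c2 + 1] * that[pr$c2 + 1, ] +
      cbind(0 * one, 0 * one, offs[r, 2] * wz[pr$c2 + 1])
    D <- B - A
    dd <- rowSums(D * D)
    for (b in seq_len(grid$n_blobs)) {
      cen <- grid$centres[b, ]
      cx <- cen[1] - A[, 1]; cy <- cen[2] - A[, 2]; cz <- cen[3] - A[, 3]
      t <- pmin(1, pmax(0, (cx * D[, 1] + cy * D[, 2] + cz * D[, 3]) / dd))
      s <- sqrt((cx - t * D[, 1])^2 + (cy - t * D[, 2])^2 + (cz - t * D[, 3])^2)
      out[, b] <- out[, b] + kb_footprint(s, grid$params)
    }
  }
  out / nrow(offs)
}

mini_brute <- function() fixture("mini_brute", function() {
  brute_force_srm(mini_spec(), mini_grid(), n_rays = 16)
})

# Dense unfolded view of the folded mini SRM, via the look-up table.
mini_unfolded <- function() fixture("mini_unfolded", function() {
  spec <- mini_spec(); grid <- mini_grid(); lut <- mini_lut(); srm <- mini_srm()
  n_lor <- lor_count(spec)
  vapply(0:(grid$n_blobs - 1),
         function(b) unfold_lookup(srm, lut, 0:(n_lor - 1), rep(b, n_lor)),
         numeric(n_lor))
})

# Scaled-down image-quality study: full-bore 18-module ring reduced to one
# layer and two axial crystal rows, with a 2 mm polar grid covering the
# 30 mm phantom. Used by the phantom-recovery tests.
iq_study <- function() fixture("iq_study", function() {
  spec <- scanner_spec(n_modules = 18, n_layers = 1, crystals_tangential = 4,
                       crystals_axial = 2, crystal_size_mm = list(c(2, 2, 6)),
                       layer_face_radius_mm = 35.5, axial_pitch_mm = 18.1 / 8)
  grid <- build_polar_grid(16, 72, 2, delta = 2, n_modules = 18)
  lut <- build_symmetry_lut(spec, grid, lor_records = FALSE)
  srm <- analytic_srm_wedge(spec, grid, lut)
  list(spec = spec, grid = grid, lut = lut, srm = srm)
})

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}

# tiny helper: a tempfile cleaned at the end of the test
withr_local_file <- function(name, env = parent.frame()) {
  path <- file.path(tempdir(), paste0(sample.int(1e9, 1), "_", name))
  withr::defer(unlink(c(path, paste0(path, ".json"))), envir = env)
  path
}
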