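test_that("the folded analytic SRM unfolds to the brute-force no-symmetry build", {
  brute <- mini_brute()
  unf <- mini_unfolded()
  scale <- max(brute)
  expect_lt(max(abs(unf - brute)) / scale, 1e-12)
  big <- brute > 1e-3 * scale
  expect_lt(max(abs(unf - brute)[big] / brute[big]), 1e-12)
})

test_that("stored elements are equivariant under every group transform", {
  spec <- mini_spec(); grid <- mini_grid(); lut <- mini_lut(); srm <- mini_srm()
  set.seed(21)
  d <- sample(0:(lut$n_lor - 1), 200, replace = TRUE)
  b <- sample(0:(grid$n_blobs - 1), 200, replace = TRUE)
  base <- unfold_lookup(srm, lut, d, b)
  for (t in c(3L, spec$n_modules + 1L, 2L * spec$n_modules,
              3L * spec$n_modules + 4L)) {
    td <- apply_transform(t, d, "lor", spec)
    tb <- apply_transform(t, b, "blob", spec, grid)
    expect_equal(unfold_lookup(srm, lut, td, tb), base, tolerance = 1e-12)
  }
})

test_that("compact support makes distant (LOR, blob) pairs structurally zero", {
  spec <- mini_spec(); grid <- mini_grid(); lut <- mini_lut(); srm <- mini_srm()
  # an LOR between tangentially adjacent crystals of one module never
  # enters the field of view: its whole row must be empty
  d_adj <- lor_index(0, blobpet:::crystal_flat_id(spec, 0L, 0L, 1L, 0L))
  vals <- unfold_lookup(srm, lut, rep(d_adj, grid$n_blobs), 0:(grid$n_blobs - 1))
  expect_true(all(vals == 0))
  # and the brute-force oracle agrees the row is geometrically empty
  expect_true(all(mini_brute()[d_adj + 1, ] == 0))
})

test_that("a single face-centre chord reproduces the direct footprint evaluation", {
  spec <- mini_spec(); grid <- mini_grid(); lut <- mini_lut()
  srm1 <- analytic_srm_wedge(spec, grid, lut, n_rays = 1, floor = 0)
  tab <- build_crystal_table(spec)
  set.seed(5)
  for (w in lut$wedge_ids[1:2]) {
    cen <- grid$centres[w + 1, ]
    d <- sample(0:(lut$n_lor - 1), 40)
    pr <- lor_unindex(d)
    got <- unfold_lookup(srm1, lut, d, rep(w, 40))
    expected <- vapply(seq_along(d), function(i) {
      A <- unlist(tab[pr$c1[i] + 1, c("x", "y", "z")])
      B <- unlist(tab[pr$c2[i] + 1, c("x", "y", "z")])
      D <- B - A
      t <- min(1, max(0, sum((cen - A) * D) / sum(D * D)))
      kb_footprint(sqrt(sum((cen - A - t * D)^2)), grid$params)
    }, numeric(1))
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("the analytic build is deterministic and fails loudly when empty", {
  spec <- mini_spec(); grid <- mini_grid(); lut <- mini_lut()
  a <- analytic_srm_wedge(spec, grid, lut, n_rays = 4, floor = 1e-9)
  b <- analytic_srm_wedge(spec, grid, lut, n_rays = 4, floor = 1e-9)
  expect_identical(a$values, b$values)
  expect_identical(a$row_ptr, b$row_ptr)
  expect_identical(a$col_idx, b$col_idx)
  expect_error(analytic_srm_wedge(spec, grid, lut, n_rays = 4, floor = 1e9),
               "empty SRM")
})

test_that("transposition is an involution that preserves every element", {
  srm <- mini_srm()
  tt <- transpose_srm(srm)
  expect_equal(tt$ordering, "blob")
  expect_equal(length(tt$values), length(srm$values))  # nnz preserved
  back <- transpose_srm(tt)
  expect_equal(back$ordering, "lor")
  expect_identical(back$values, srm$values)
  expect_identical(back$col_idx, srm$col_idx)
  expect_identical(back$row_ptr, srm$row_ptr)
  # random spot-check of elements against the original via dense lookup
  A <- as.matrix(blobpet:::srm_as_matrix(srm))
  B <- as.matrix(blobpet:::srm_as_matrix(tt))
  set.seed(9)
  i <- sample(nrow(A), 1000, replace = TRUE)
  j <- sample(ncol(A), 1000, replace = TRUE)
  expect_identical(A[cbind(i, j)], B[cbind(i, j)])
})

test_that("validate_srm reports structural violations and sparsity", {
  srm <- mini_srm()
  rep0 <- validate_srm(srm)
  expect_length(rep0$failures, 0)
  expect_equal(rep0$nnz, length(srm$values))
  bad <- srm
  bad$values[5] <- -1
  rep1 <- validate_srm(bad)
  expect_equal(rep1$failures, "negative values")
})

test_that("the geometric Monte Carlo SRM is seeded, reproducible and bounded", {
  spec <- mini_spec(); grid <- mini_grid(); lut <- mini_lut()
  expect_error(mc_srm_wedge(spec, grid, lut, n_events = 10), "seed")
  empty <- mc_srm_wedge(spec, grid, lut, n_events = 0, seed = 1)
  expect_equal(length(empty$values), 0L)
  m1 <- mc_srm_wedge(spec, grid, lut, n_events = 2000, seed = 31)
  m2 <- mc_srm_wedge(spec, grid, lut, n_events = 2000, seed = 31)
  expect_identical(m1$values, m2$values)
  expect_identical(m1$col_idx, m2$col_idx)
  expect_true(all(m1$values >= 0 & m1$values <= 1))
  # face-mode detection under the same seed can only lose coincidences
  # relative to volume-mode (any face crossing also enters the box)
  mf <- mc_srm_wedge(spec, grid, lut, n_events = 2000, seed = 31, detect = "face")
  expect_lte(sum(mf$values), sum(m1$values))
})

test_that("Monte Carlo detection converges to the etendue-normalised analytic projector", {
  # radially thin crystals so that entrance-face crossing ~ volume crossing,
  # making the two estimators target the same probability
  spec <- scanner_spec(n_modules = 6, n_layers = 1, crystals_tangential = 2,
                       crystals_axial = 2, crystal_size_mm = list(c(4, 4, 1)),
                       layer_face_radius_mm = 16, axial_pitch_mm = 4)
  grid <- build_polar_grid(2, 12, 2, delta = 2, n_modules = 6)
  lut <- build_symmetry_lut(spec, grid)
  an <- analytic_srm_wedge(spec, grid, lut, n_rays = 64, pairing = "all",
                           floor = 0, normalization = "etendue")
  n_events <- 1e6
  mc <- mc_srm_wedge(spec, grid, lut, n_events = n_events, seed = 7,
                     detect = "face")
  A <- as.matrix(blobpet:::srm_as_matrix(an))
  M <- as.matrix(blobpet:::srm_as_matrix(mc))
  sel <- A > 1e-4
  z <- (M[sel] - A[sel]) / sqrt(A[sel] * (1 - A[sel]) / n_events)
  # binomial sampling band with a familywise (Bonferroni) limit for the
  # max statistic, plus the plain 3-SE coverage expected elementwise
  z_crit <- qnorm(1 - 0.001 / (2 * sum(sel)))
  expect_lt(max(abs(z)), z_crit)
  expect_gte(mean(abs(z) <= 3), 0.99)
})
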