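test_that("forward projection equals the dense unfolded matrix-vector product", {
  spec <- mini_spec(); grid <- mini_grid(); lut <- mini_lut(); srm <- mini_srm()
  expect_equal(forward_project(numeric(grid$n_blobs), srm, lut),
               numeric(lut$n_lor))
  dense <- mini_unfolded()
  # a unit impulse at blob b picks out column b of the unfolded matrix
  for (b in c(0L, 13L, 44L)) {
    delta <- numeric(grid$n_blobs); delta[b + 1] <- 1
    expect_equal(forward_project(delta, srm, lut), unname(dense[, b + 1]),
                 tolerance = 1e-12)
  }
  set.seed(4)
  cf <- runif(grid$n_blobs)
  expect_rel_equal(forward_project(cf, srm, lut), as.numeric(dense %*% cf), 1e-12)
  expect_error(forward_project(cf[-1], srm, lut), "length")
})

test_that("backprojection satisfies the adjoint identity for both strategies", {
  grid <- mini_grid(); lut <- mini_lut(); srm <- mini_srm()
  expect_equal(back_project(numeric(lut$n_lor), srm, lut), numeric(grid$n_blobs))
  set.seed(8)
  for (rep in 1:5) {
    cf <- runif(grid$n_blobs)
    r <- runif(lut$n_lor)
    q <- forward_project(cf, srm, lut)
    for (strategy in c("transpose", "scatter")) {
      bp <- back_project(r, srm, lut, strategy = strategy)
      lhs <- sum(q * r); rhs <- sum(cf * bp)
      expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
    }
  }
})

test_that("transpose and scatter strategies agree elementwise", {
  lut <- mini_lut(); srm <- mini_srm()
  set.seed(12)
  r <- rpois(lut$n_lor, 3) + runif(lut$n_lor)
  bt <- back_project(r, srm, lut, "transpose")
  bs <- back_project(r, srm, lut, "scatter", chunk_size = 17)
  expect_lt(max(abs(bt - bs)) / max(abs(bt)), 1e-9)
  # random chunk ordering is seeded, reproducible and order-invariant
  expect_error(back_project(r, srm, lut, "scatter", chunk_order = "random"),
               "seed")
  br1 <- back_project(r, srm, lut, "scatter", chunk_size = 17,
                      chunk_order = "random", seed = 2)
  br2 <- back_project(r, srm, lut, "scatter", chunk_size = 17,
                      chunk_order = "random", seed = 2)
  expect_identical(br1, br2)
  br3 <- back_project(r, srm, lut, "scatter", chunk_size = 17,
                      chunk_order = "random", seed = 99)
  expect_lt(max(abs(br1 - br3)) / max(abs(br1)), 1e-9)
})

test_that("sensitivity is the backprojection of ones and symmetry-invariant", {
  spec <- mini_spec(); grid <- mini_grid(); lut <- mini_lut(); srm <- mini_srm()
  s <- sensitivity(srm, lut)
  expect_equal(s, back_project(rep(1, lut$n_lor), srm, lut))
  expect_true(all(s > 0))   # every mini-scanner blob sits inside the FOV
  ids <- 0:(grid$n_blobs - 1)
  for (t in c(1L, spec$n_modules, 2L * spec$n_modules)) {
    mapped <- apply_transform(t, ids, "blob", spec, grid)
    expect_equal(s[mapped + 1], s, tolerance = 1e-12)
  }
})

test_that("the ML-EM update has the expected fixed point and conservation law", {
  grid <- mini_grid(); lut <- mini_lut(); srm <- mini_srm()
  sens <- sensitivity(srm, lut)
  set.seed(14)
  c0 <- runif(grid$n_blobs, 0.5, 2)
  y_exact <- forward_project(c0, srm, lut)
  up <- mlem_update(c0, y_exact, srm, lut, sens = sens)
  expect_rel_equal(up$c, c0, 1e-12)          # fixed point when data = projection
  expect_equal(up$n_excluded, 0L)
  y <- rpois(lut$n_lor, y_exact * 50)
  up2 <- mlem_update(c0, y, srm, lut, sens = sens)
  expect_true(all(up2$c >= 0))
  # weighted count conservation: sum_b s_b c'_b == sum_d y_d (included d)
  expect_lt(abs(sum(sens * up2$c) - sum(y)) / sum(y), 1e-10)
})

test_that("counts on structurally empty LORs are excluded, not clamped", {
  spec <- mini_spec(); grid <- mini_grid(); lut <- mini_lut(); srm <- mini_srm()
  sens <- sensitivity(srm, lut)
  d_adj <- lor_index(0, blobpet:::crystal_flat_id(spec, 0L, 0L, 1L, 0L))
  y <- numeric(lut$n_lor)
  y[d_adj + 1] <- 5                       # impossible counts
  y[which(forward_project(rep(1, grid$n_blobs), srm, lut) > 0)[1:50]] <- 3
  expect_warning(up <- mlem_update(rep(1, grid$n_blobs), y, srm, lut, sens = sens),
                 "excluded")
  expect_equal(up$n_excluded, 1L)
  included <- sum(y) - 5
  expect_lt(abs(sum(sens * up$c) - included) / included, 1e-10)
})

test_that("run_mlem is deterministic, non-negative and support-preserving", {
  grid <- mini_grid(); lut <- mini_lut(); srm <- mini_srm()
  set.seed(15)
  c_true <- runif(grid$n_blobs, 0, 2)
  y <- simulate_counts(c_true, srm, lut, 5e4, seed = 3)
  f1 <- run_mlem(y, srm, lut, n_iter = 20, log_every = 5)
  f2 <- run_mlem(y, srm, lut, n_iter = 20, log_every = 5)
  expect_identical(f1$c, f2$c)             # bit-identical reruns
  expect_true(all(f1$c >= 0))
  # zeros in the initial image are fixed points of the multiplicative update
  init <- rep(1, grid$n_blobs); init[c(2, 30)] <- 0
  f3 <- run_mlem(y, srm, lut, n_iter = 10, init = init)
  expect_identical(f3$c[c(2, 30)], c(0, 0))
  # scatter-strategy reconstruction matches within summation tolerance
  f4 <- run_mlem(y, srm, lut, n_iter = 20, log_every = 5,
                 backprojection = "scatter")
  expect_rel_equal(f4$c, f1$c, 1e-8)
})

test_that("the Poisson log-likelihood is non-decreasing along the iterations", {
  grid <- mini_grid(); lut <- mini_lut(); srm <- mini_srm()
  set.seed(16)
  c_true <- runif(grid$n_blobs, 0, 2)
  y <- simulate_counts(c_true, srm, lut, 2e4, seed = 5)
  fit <- run_mlem(y, srm, lut, n_iter = 80, log_every = 1)
  ll <- fit$history$log_likelihood
  expect_true(all(diff(ll) >= -1e-9 * abs(ll[-length(ll)])))
})

test_that("point-source data reconstructs to the true blob", {
  grid <- mini_grid(); lut <- mini_lut(); srm <- mini_srm()
  b_true <- 15L
  c_true <- numeric(grid$n_blobs); c_true[b_true + 1] <- 1
  y <- simulate_counts(c_true, srm, lut, 2e5, seed = 6)
  fit <- run_mlem(y, srm, lut, n_iter = 50)
  expect_equal(which.max(fit$c) - 1L, b_true)
})

test_that("tidy and glance summarise a fit", {
  grid <- mini_grid(); lut <- mini_lut(); srm <- mini_srm()
  y <- simulate_counts(rep(1, grid$n_blobs), srm, lut, 1e4, seed = 8)
  fit <- run_mlem(y, srm, lut, n_iter = 6, log_every = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$iteration, c(2L, 4L, 6L))
  gl <- glance(fit)
  expect_equal(gl$n_iter, 6L)
  expect_lt(abs(gl$total_activity - sum(y$counts)) / sum(y$counts), 1e-10)
  expect_s3_class(autoplot(fit), "ggplot")
})
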