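#' LOR coincidence histogram
#'
#' Measured (or simulated) data: one non-negative integer count per LOR,
#' indexed by the dense LOR convention of [lor_index()].
#'
#' @param counts non-negative integer vector, length [lor_count()].
#' @param meta optional provenance list (duration, seed, phantom, ...).
#' @return an object of class `lor_histogram`.
#' @export
lor_histogram <- function(counts, meta = list()) {
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(list(counts = as.numeric(counts), meta = meta),
            class = "lor_histogram")
}

#' @export
print.lor_histogram <- function(x, ...) {
  cat(sprintf("<lor_histogram> %s LORs, %s counts total\n",
              format(length(x$counts), big.mark = ","),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

# Gather the coefficient sub-vector that transform t contributes to the
# wedge columns: u[w] = c[blob generated from wedge blob w by t], 0 if none.
wedge_gather <- function(lut, cvec, t) {
  b <- lut$blob_by_transform[, t + 1L]
  u <- numeric(length(b))
  ok <- !is.na(b)
  u[ok] <- cvec[b[ok] + 1L]
  u
}

#' Forward projection (gathering)
#'
#' Computes the expected LOR intensities \eqn{q_d = \sum_b p_{d,b} c_b}
#' with `b` running over ALL blobs of the grid: each LOR gathers the folded
#' wedge elements across every symmetry transform via the look-up table.
#'
#' @param c coefficient vector (length `n_blobs`) or a [blob_image()].
#' @param srm a wedge-folded [sparse_srm].
#' @param lut the matching [build_symmetry_lut()].
#' @return numeric vector of length [lor_count()].
#' @export
forward_project <- function(c, srm, lut) {
  if (inherits(c, "blob_image")) c <- c$c
  stopifnot(inherits(srm, "sparse_srm"), inherits(lut, "symmetry_lut"))
  if (length(c) != lut$n_blob)
    stop("coefficient length does not match the grid", call. = FALSE)
  if (srm$n_lor != lut$n_lor || srm$n_wedge != length(lut$wedge_ids))
    stop("SRM dimensions do not match the look-up table", call. = FALSE)
  M <- srm_as_matrix(srm)
  q <- numeric(lut$n_lor)
  for (t in 0:(lut$n_transforms - 1L)) {
    u <- wedge_gather(lut, c, t)
    if (all(u == 0)) next
    v <- as.numeric(M %*% u)
    ip <- lor_permutation(lut, invert_transform(lut$spec, t))
    q <- q + v[ip + 1L]
  }
  q
}

#' Backprojection (scattering)
#'
#' Computes \eqn{b_i = \sum_d p_{d,i} r_d} over all blobs. Two strategies
#' produce identical results up to floating-point summation order:
#' \describe{
#'   \item{`"transpose"`}{iterates the blob-ordered (transposed) SRM, so
#'     every output element is a private consecutive-memory reduction — no
#'     write hazards by construction.}
#'   \item{`"scatter"`}{iterates the LOR-ordered SRM in row chunks; each
#'     chunk accumulates into a private partial vector and the partials are
#'     merged by summation, the accumulation contract that guarantees no
#'     lost updates when chunks are processed independently. `chunk_order =
#'     "random"` processes chunks in a seeded random order (decorrelating
#'     spatially adjacent LORs); the result is order-invariant within
#'     summation tolerance.}
#' }
#'
#' @param r numeric vector over LORs.
#' @param srm a wedge-folded [sparse_srm].
#' @param lut the matching [build_symmetry_lut()].
#' @param strategy `"transpose"` or `"scatter"`.
#' @param chunk_size LOR rows per scatter chunk.
#' @param chunk_order `"sequential"` or `"random"` (scatter only).
#' @param seed RNG seed, mandatory when `chunk_order = "random"`.
#' @return numeric vector of length `n_blobs`.
#' @export
back_project <- function(r, srm, lut, strategy = c("transpose", "scatter"),
                         chunk_size = 4096L, chunk_order = c("sequential", "random"),
                         seed = NULL) {
  strategy <- match.arg(strategy)
  chunk_order <- match.arg(chunk_order)
  stopifnot(inherits(srm, "sparse_srm"), inherits(lut, "symmetry_lut"))
  if (length(r) != lut$n_lor)
    stop("`r` length does not match the LOR count", call. = FALSE)
  M <- srm_as_matrix(srm)
  out <- numeric(lut$n_blob)
  if (strategy == "scatter") {
    starts <- seq(1L, lut$n_lor, by = chunk_size)
    if (chunk_order == "random") {
      if (is.null(seed)) stop("`seed` is mandatory for random chunk ordering", call. = FALSE)
      starts <- with_local_seed(seed, sample(starts))
    }
  }
  for (t in 0:(lut$n_transforms - 1L)) {
    perm <- lor_permutation(lut, t)
    rT <- r[perm + 1L]
    w <- if (strategy == "transpose") {
      as.numeric(Matrix::t(M) %*% rT)
    } else {
      acc <- numeric(srm$n_wedge)
      for (s in starts) {
        e <- min(s + chunk_size - 1L, lut$n_lor)
        acc <- acc + as.numeric(Matrix::crossprod(M[s:e, , drop = FALSE], rT[s:e]))
      }
      acc
    }
    b <- lut$blob_by_transform[, t + 1L]
    ok <- !is.na(b)
    out[b[ok] + 1L] <- out[b[ok] + 1L] + w[ok]
  }
  out
}

#' Sensitivity image
#'
#' The ML-EM normaliser \eqn{s_b = \sum_d p_{d,b}}: the total detection
#' weight of each blob over all LORs, i.e. the backprojection of a
#' histogram of ones. Symmetry makes it constant on every orbit.
#'
#' @param srm a wedge-folded [sparse_srm].
#' @param lut the matching [build_symmetry_lut()].
#' @return numeric vector of length `n_blobs`.
#' @export
sensitivity <- function(srm, lut) {
  back_project(rep(1, lut$n_lor), srm, lut)
}

#' One ML-EM multiplicative update
#'
#' \deqn{c_b' = \frac{c_b}{s_b} \sum_d p_{d,b}\, y_d / q_d, \qquad
#'   q = P c,} the classic Poisson maximum-likelihood
#' expectation-maximisation step. Blobs with zero sensitivity stay 0.
#' LORs with measured counts but a vanishing projection (`q_d < q_floor`)
#' cannot be explained by the current support; they are excluded from the
#' update (not clamped) and counted in the returned report.
#'
#' @param c current coefficient vector (non-negative).
#' @param y a [lor_histogram()] or a plain count vector.
#' @param srm,lut as in [forward_project()].
#' @param sens sensitivity vector (computed once via [sensitivity()]).
#' @param q_floor threshold below which a projection is treated as zero.
#' @return a list: `c` (updated coefficients), `q` (the forward projection
#'   used), `n_excluded` (LORs with `y > 0` dropped for vanishing `q`).
#' @export
mlem_update <- function(c, y, srm, lut, sens = sensitivity(srm, lut),
                        q_floor = 1e-300) {
  if (inherits(y, "lor_histogram")) y <- y$counts
  if (any(c < 0)) stop("coefficients must be non-negative", call. = FALSE)
  q <- forward_project(c, srm, lut)
  bad <- y > 0 & q < q_floor
  if (any(bad))
    warning(sprintf("%d LORs with counts but zero projection were excluded", sum(bad)))
  ratio <- numeric(length(y))
  use <- q >= q_floor
  ratio[use] <- y[use] / q[use]
  bp <- back_project(ratio, srm, lut)
  cn <- numeric(length(c))
  pos <- sens > 0
  cn[pos] <- c[pos] / sens[pos] * bp[pos]
  list(c = cn, q = q, n_excluded = sum(bad))
}

#' Run ML-EM reconstruction
#'
#' Applies [mlem_update()] for `n_iter` iterations from a uniform positive
#' start, recording the Poisson log-likelihood
#' \eqn{\sum_d (y_d \ln q_d - q_d)} at every `log_every`-th iteration.
#' EM guarantees the likelihood is non-decreasing; the run is deterministic
#' given its inputs.
#'
#' @param y a [lor_histogram()] or count vector.
#' @param srm,lut as in [forward_project()].
#' @param n_iter number of iterations (>= 1).
#' @param init initial coefficient value (scalar > 0) or full vector.
#' @param log_every record the likelihood every this many iterations.
#' @param backprojection strategy passed to [back_project()] — kept fixed
#'   for the whole run.
#' @return an object of class `mlem_fit`: `c` (final coefficients, also as
#'   `image`, a [blob_image()]), `sens`, `history` (a tibble with
#'   `iteration`, `log_likelihood`, `n_excluded`), `n_iter`.
#' @export
run_mlem <- function(y, srm, lut, n_iter = 300L, init = 1.0, log_every = 1L,
                     backprojection = c("transpose", "scatter")) {
  backprojection <- match.arg(backprojection)
  n_iter <- assert_count(n_iter, "n_iter")
  log_every <- assert_count(log_every, "log_every")
  yv <- if (inherits(y, "lor_histogram")) y$counts else y
  sens <- sensitivity(srm, lut)
  c0 <- if (length(init) == 1L) {
    assert_positive(init, "init")
    rep(init, lut$n_blob)
  } else {
    if (length(init) != lut$n_blob) stop("`init` has the wrong length", call. = FALSE)
    as.numeric(init)
  }
  c0[sens == 0] <- 0
  hist_it <- integer(); hist_ll <- numeric(); hist_ex <- integer()
  cur <- c0
  for (it in seq_len(n_iter)) {
    q <- forward_project(cur, srm, lut)
    use <- q > 0
    ratio <- numeric(length(yv))
    ratio[use] <- yv[use] / q[use]
    bp <- back_project(ratio, srm, lut, strategy = backprojection)
    nxt <- numeric(length(cur))
    pos <- sens > 0
    nxt[pos] <- cur[pos] / sens[pos] * bp[pos]
    if (it %% log_every == 0L || it == n_iter) {
      ll_use <- use & yv > 0
      ll <- sum(yv[ll_use] * log(q[ll_use])) - sum(q)
      hist_it <- c(hist_it, it); hist_ll <- c(hist_ll, ll)
      hist_ex <- c(hist_ex, sum(yv > 0 & !use))
    }
    cur <- nxt
  }
  structure(list(c = cur, image = blob_image(cur, lut$grid), sens = sens,
                 history = tibble::tibble(iteration = hist_it,
                                          log_likelihood = hist_ll,
                                          n_excluded = hist_ex),
                 n_iter = n_iter, backprojection = backprojection),
            class = "mlem_fit")
}

#' @export
print.mlem_fit <- function(x, ...) {
  cat(sprintf("<mlem_fit> %d iterations (%s backprojection); final log-likelihood %.6g\n",
              x$n_iter, x$backprojection, utils::tail(x$history$log_likelihood, 1)))
  invisible(x)
}

#' Tidy the iteration history of an ML-EM fit
#'
#' @param x an `mlem_fit` from [run_mlem()].
#' @param ... unused.
#' @return a tibble with one row per logged iteration.
#' @method tidy mlem_fit
#' @export
tidy.mlem_fit <- function(x, ...) x$history

#' One-row summary of an ML-EM fit
#'
#' @param x an `mlem_fit` from [run_mlem()].
#' @param ... unused.
#' @return a tibble with `n_iter`, `log_likelihood` (final), `total_activity`
#'   (sensitivity-weighted coefficient sum) and `n_excluded`.
#' @method glance mlem_fit
#' @export
glance.mlem_fit <- function(x, ...) {
  tibble::tibble(n_iter = x$n_iter,
                 log_likelihood = utils::tail(x$history$log_likelihood, 1),
                 total_activity = sum(x$sens * x$c),
                 n_excluded = utils::tail(x$history$n_excluded, 1))
}

#' Plot the likelihood trace of an ML-EM fit
#'
#' @param object an `mlem_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mlem_fit
#' @export
autoplot.mlem_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$log_likelihood)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "iteration", y = "Poisson log-likelihood") +
    ggplot2::theme_minimal()
}
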