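`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats rpois runif integrate sd var
#' @importFrom utils head tail write.csv read.csv
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

assert_positive <- function(x, name, n = NULL) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  if (!is.null(n) && length(x) != n)
    stop(sprintf("`%s` must have length %d", name, n), call. = FALSE)
  x
}

# Stable content hash (md5 of the serialized object) for provenance fields.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 3L, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}
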