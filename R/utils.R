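# Internal helpers shared across modules. All coordinates are in nm.

res_key <- function(chain, resno) paste0(chain, ":", resno)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Squared distances between every row of A and every row of B (n x m matrix).
# A, B: numeric matrices with 3 columns.
cross_dist2 <- function(A, B) {
  a2 <- rowSums(A * A)
  b2 <- rowSums(B * B)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0 # guard tiny negative values from floating cancellation
  d2
}

# For each row of A, the minimum distance to any row of B. Chunked so the
# intermediate matrix stays modest for large water sets.
min_dist_to_set <- function(A, B, chunk = 4096L) {
  n <- nrow(A)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    out[i:j] <- sqrt(apply(cross_dist2(A[i:j, , drop = FALSE], B), 1L, min))
    i <- j + 1L
  }
  out
}

xyz_matrix <- function(structure, rows = NULL) {
  m <- cbind(structure$x, structure$y, structure$z)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  m
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}
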