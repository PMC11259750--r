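# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    })
    set.seed(seed)
  }
  force(expr)
}

vnorm <- function(x) sqrt(sum(x * x))

unit <- function(x) {
  n <- vnorm(x)
  if (n == 0) stop("cannot normalize a zero vector")
  x / n
}

row_norms <- function(m) sqrt(rowSums(m * m))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product for n x 3 matrices.
cross3_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Apply a 4x4 affine to 0-based voxel indices (n x 3) -> world mm (n x 3).
apply_affine <- function(affine, idx) {
  idx <- rbind_matrix(idx)
  sweep(idx %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], "+")
}

rbind_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be positive", name))
  invisible(x)
}
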