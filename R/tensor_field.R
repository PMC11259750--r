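#' Diffusion tensor field container
#'
#' Per-voxel symmetric 3x3 diffusion tensors stored as their six unique
#' components in lower-triangular order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), the
#' order used when the field is written to NIfTI as a 6-volume series.
#'
#' @param D 4D numeric array \code{[nx, ny, nz, 6]} in mm^2/s.
#' @param affine 4x4 voxel-to-world transform (0-based index to mm). Defaults
#'   to \code{diag(voxel_mm)}, zero origin.
#' @param voxel_mm isotropic voxel size used when \code{affine} is absent.
#' @return An object of class \code{tensor_field}.
#' @export
tensor_field <- function(D, affine = NULL, voxel_mm = 1) {
  if (length(dim(D)) != 4L || dim(D)[4] != 6L) {
    stop("'D' must be an [nx, ny, nz, 6] array")
  }
  if (is.null(affine)) affine <- diag(c(rep(voxel_mm, 3), 1))
  affine <- as.matrix(affine)
  structure(list(D = D, affine = affine, inv_affine = solve(affine)),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  d <- dim(x$D)
  cat(sprintf("tensor_field: %d x %d x %d voxels (6 components)\n",
              d[1], d[2], d[3]))
  invisible(x)
}

# 6-vector (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz) -> symmetric 3x3
tensor6_to_33 <- function(t6) {
  matrix(c(t6[1], t6[2], t6[4],
           t6[2], t6[3], t6[5],
           t6[4], t6[5], t6[6]), 3, 3)
}

tensor33_to_6 <- function(m) {
  c(m[1, 1], m[1, 2], m[2, 2], m[1, 3], m[2, 3], m[3, 3])
}

#' Fractional anisotropy of tensor eigenvalues
#'
#' The standard normalized-variance measure
#' \deqn{FA = \sqrt{3/2}\,\sqrt{\sum_i(\lambda_i-\bar\lambda)^2 / \sum_i \lambda_i^2}}
#' ranging from 0 (isotropic) to 1 (rank one).
#'
#' @param eigenvalues numeric vector of three eigenvalues (mm^2/s).
#' @return FA in [0, 1].
#' @export
fa <- function(eigenvalues) {
  if (length(eigenvalues) != 3L) stop("three eigenvalues required")
  ss <- sum(eigenvalues^2)
  if (ss == 0) stop("FA undefined for an all-zero tensor")
  lbar <- mean(eigenvalues)
  f <- sqrt(1.5 * sum((eigenvalues - lbar)^2) / ss)
  min(max(f, 0), 1)
}

# FA from the six tensor components without an eigendecomposition:
# FA^2 = 3/2 * (tr(D^2) - tr(D)^2/3) / tr(D^2).
fa_from_t6 <- function(t6) {
  tr <- t6[1] + t6[3] + t6[6]
  tr2 <- t6[1]^2 + t6[3]^2 + t6[6]^2 + 2 * (t6[2]^2 + t6[4]^2 + t6[5]^2)
  if (tr2 <= 0) return(NA_real_)
  f2 <- 1.5 * (tr2 - tr^2 / 3) / tr2
  sqrt(min(max(f2, 0), 1))
}

#' Principal diffusion direction
#'
#' Unit eigenvector of the largest eigenvalue of a symmetric diffusion
#' tensor. The sign of the returned vector is arbitrary; callers tracking a
#' streamline must align it with the current direction of travel. A leading
#' eigenvalue whose relative gap to the second is below \code{gap_tol} is
#' flagged degenerate (attribute \code{degenerate}); tracking treats such
#' voxels as stopping points.
#'
#' @param tensor a symmetric 3x3 matrix or a 6-vector in
#'   (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz) order.
#' @param gap_tol relative eigenvalue-gap tolerance.
#' @return unit 3-vector with attributes \code{eigenvalues} and
#'   \code{degenerate}.
#' @export
principal_direction <- function(tensor, gap_tol = 1e-9) {
  m <- if (is.matrix(tensor)) tensor else tensor6_to_33(tensor)
  e <- eigen(m, symmetric = TRUE)
  ev <- e$values
  scale <- max(abs(ev))
  degen <- scale == 0 || (ev[1] - ev[2]) / scale < gap_tol
  v <- e$vectors[, 1]
  structure(v / vnorm(v), eigenvalues = ev, degenerate = degen)
}

#' Trilinear tensor interpolation
#'
#' Component-wise trilinear interpolation of the six tensor components at a
#' world-coordinate point.
#'
#' @param field a \code{tensor_field}.
#' @param p 3-vector in mm.
#' @return 6-vector of interpolated components, or \code{NULL} if \code{p}
#'   falls outside the grid (the out-of-bounds tracking stop signal).
#' @export
interpolate_tensor <- function(field, p) {
  v <- field$inv_affine[1:3, 1:3] %*% p + field$inv_affine[1:3, 4]
  interp6_voxel(field$D, v[1], v[2], v[3])
}

# Trilinear interpolation at continuous 0-based voxel coords; NULL if outside.
interp6_voxel <- function(D, x, y, z) {
  d <- dim(D)
  if (x < 0 || y < 0 || z < 0 || x > d[1] - 1 || y > d[2] - 1 || z > d[3] - 1) {
    return(NULL)
  }
  i0 <- min(floor(x), d[1] - 2); j0 <- min(floor(y), d[2] - 2)
  k0 <- min(floor(z), d[3] - 2)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  w <- c((1 - fx) * (1 - fy) * (1 - fz), fx * (1 - fy) * (1 - fz),
         (1 - fx) * fy * (1 - fz), fx * fy * (1 - fz),
         (1 - fx) * (1 - fy) * fz, fx * (1 - fy) * fz,
         (1 - fx) * fy * fz, fx * fy * fz)
  nx <- d[1]; nxy <- d[1] * d[2]
  base <- (i0 + 1) + j0 * nx + k0 * nxy
  off <- c(0, 1, nx, nx + 1, nxy, nxy + 1, nxy + nx, nxy + nx + 1)
  idx <- base + off
  vol <- nxy * d[3]
  out <- numeric(6)
  for (cc in 1:6) {
    out[cc] <- sum(w * D[idx + (cc - 1) * vol])
  }
  out
}

# Scalar trilinear interpolation of a 3D array at continuous 0-based voxel
# coords; NA if outside the grid.
interp1_voxel <- function(A, x, y, z) {
  d <- dim(A)
  if (x < 0 || y < 0 || z < 0 || x > d[1] - 1 || y > d[2] - 1 || z > d[3] - 1) {
    return(NA_real_)
  }
  i0 <- min(floor(x), d[1] - 2); j0 <- min(floor(y), d[2] - 2)
  k0 <- min(floor(z), d[3] - 2)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  w <- c((1 - fx) * (1 - fy) * (1 - fz), fx * (1 - fy) * (1 - fz),
         (1 - fx) * fy * (1 - fz), fx * fy * (1 - fz),
         (1 - fx) * (1 - fy) * fz, fx * (1 - fy) * fz,
         (1 - fx) * fy * fz, fx * fy * fz)
  nx <- d[1]; nxy <- d[1] * d[2]
  base <- (i0 + 1) + j0 * nx + k0 * nxy
  off <- c(0, 1, nx, nx + 1, nxy, nxy + 1, nxy + nx, nxy + nx + 1)
  sum(w * A[base + off])
}
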