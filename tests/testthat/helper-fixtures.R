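# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Small zero-jitter unipennate phantom (alpha = 30 deg, slab 20 mm -> true
# fascicle length 40 mm) used across tractography/architecture tests.
small_phantom <- function() {
  memo("small_phantom", function() {
    build_unipennate(phantom_spec(shape_mm = c(70, 30, 40),
                                  slab_thickness_mm = 20, seed = 2))
  })
}

small_tracts <- function() {
  memo("small_tracts", function() {
    ph <- small_phantom()
    sample_tracts(ph$tensors, ph$label_map$voxels == 1, ph$aponeurosis,
                  ph$fibre_exit, track_params(n_tracts = 150), seed = 7)
  })
}

# Voxelized ball of radius r at voxel size h, centred in the grid.
ball_label_map <- function(r = 10, h = 1) {
  n <- ceiling(2 * (r + 3) / h)
  g <- (seq_len(n) - 1) * h
  cen <- (n - 1) / 2 * h
  vox <- array(0L, c(n, n, n))
  for (k in seq_len(n)) {
    vox[, , k] <- (outer((g - cen)^2, (g - cen)^2, "+") +
                     (g[k] - cen)^2 <= r^2) * 1L
  }
  label_map(vox, voxel_mm = h)
}

cube_label_map <- function(side = 20, h = 1, pad = 2) {
  n <- side / h + 2 * pad
  vox <- array(0L, c(n, n, n))
  idx <- (pad + 1):(pad + side / h)
  vox[idx, idx, idx] <- 1L
  label_map(vox, voxel_mm = h)
}

# Exact closed cube mesh with the given side length (12 triangles).
cube_mesh <- function(side = 20, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  v <- sweep(v, 2, origin, "+")
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  surface_mesh(v, f)
}

# Uniform-direction tensor field in a slab; direction in the x-z plane.
uniform_field <- function(dims = c(40, 11, 11), dir = c(1, 0, 0),
                          eigenvalues = c(1.7e-3, 1.2e-3, 1.2e-3)) {
  e1 <- dir / sqrt(sum(dir^2))
  ref <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e2 <- ref - sum(ref * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  B <- cbind(e1, e2, e3)
  Tm <- B %*% diag(eigenvalues) %*% t(B)
  t6 <- c(Tm[1, 1], Tm[1, 2], Tm[2, 2], Tm[1, 3], Tm[2, 3], Tm[3, 3])
  D <- array(0, c(dims, 6))
  for (cc in 1:6) D[, , , cc] <- t6[cc]
  tensor_field(D, voxel_mm = 1)
}

# Tangential (circular) tensor field in an annulus around `cen`; fibres run
# on circles in the x-y plane.
circular_field <- function(n = 61, nz = 11, r_in = 10, r_out = 30,
                           eigenvalues = c(1.7e-3, 1.2e-3, 1.2e-3)) {
  cen <- (n - 1) / 2
  D <- array(0, c(n, n, nz, 6))
  mask <- array(0, c(n, n, nz))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      x <- (i - 1) - cen
      y <- (j - 1) - cen
      r <- sqrt(x^2 + y^2)
      if (r >= r_in && r <= r_out) {
        e1 <- c(-y, x, 0) / r
        e2 <- c(0, 0, 1)
        e3 <- c(e1[2], -e1[1], 0)
        B <- cbind(e1, e2, e3)
        Tm <- B %*% diag(eigenvalues) %*% t(B)
        t6 <- c(Tm[1, 1], Tm[1, 2], Tm[2, 2], Tm[1, 3], Tm[2, 3], Tm[3, 3])
        for (k in seq_len(nz)) {
          D[i, j, k, ] <- t6
          mask[i, j, k] <- (x > 0 && y > 0) * 1
        }
      }
    }
  }
  list(field = tensor_field(D, voxel_mm = 1), mask = mask, centre = cen)
}

# Planar triangulated sheet z = z0 for pennation/termination tests.
plane_sheet <- function(x0 = -20, x1 = 40, y0 = -20, y1 = 40, z0 = 0,
                        step = 2) {
  xs <- seq(x0, x1, by = step)
  ys <- seq(y0, y1, by = step)
  nxg <- length(xs)
  nyg <- length(ys)
  verts <- cbind(rep(xs, times = nyg), rep(ys, each = nxg), z0)
  vid <- function(i, j) (j - 1L) * nxg + i
  i <- rep(seq_len(nxg - 1L), times = nyg - 1L)
  j <- rep(seq_len(nyg - 1L), each = nxg - 1L)
  surface_mesh(verts, rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
                            cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L))))
}

# A streamline object assembled by hand (for acceptance-rule tests).
fake_streamline <- function(points, status = "tracked") {
  structure(list(points = points, status = status,
                 stop_reasons = c("mask_exit", "mask_exit")),
            class = "streamline")
}

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3)
}
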