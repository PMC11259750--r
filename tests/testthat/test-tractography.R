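test_that("fractional anisotropy has the right limits and closed form", {
  expect_equal(fa(c(2e-3, 2e-3, 2e-3)), 0)
  expect_equal(fa(c(2e-3, 0, 0)), 1)
  # hand-evaluated closed form: sqrt(3/2 * (24/9) / 11) = sqrt(4/11)
  expect_equal(fa(c(3e-3, 1e-3, 1e-3)), sqrt(4 / 11), tolerance = 1e-12)
  expect_error(fa(c(0, 0, 0)), "all-zero")
  expect_true(abs(fa(c(1.7e-3, 1.2e-3, 1.2e-3)) - 0.2085) < 1e-3)
})

test_that("principal direction is the leading eigenvector, equivariant under
           rotation, and flags degeneracy", {
  d <- principal_direction(diag(c(2e-3, 1e-3, 1e-3)))
  expect_equal(abs(as.numeric(d)), c(1, 0, 0), tolerance = 1e-12)
  expect_false(attr(d, "degenerate"))

  set.seed(5)
  A <- matrix(rnorm(9), 3)
  spd <- crossprod(A) + diag(3) * 0.1
  v <- as.numeric(principal_direction(spd))
  # independent oracle: power iteration
  w <- c(1, 0.5, -0.2)
  for (i in 1:500) w <- spd %*% w / sqrt(sum((spd %*% w)^2))
  w <- as.numeric(w / sqrt(sum(w^2)))
  expect_equal(abs(sum(v * w)), 1, tolerance = 1e-9)

  R <- rot_z(0.9)
  vr <- as.numeric(principal_direction(R %*% spd %*% t(R)))
  expect_equal(abs(sum(vr * as.numeric(R %*% v))), 1, tolerance = 1e-9)

  iso <- principal_direction(diag(c(1e-3, 1e-3, 1e-3)))
  expect_true(attr(iso, "degenerate"))
})

test_that("tensor interpolation is exact at voxel centres, constant in
           uniform fields, and averages at midpoints", {
  fld <- uniform_field()
  t6 <- fld$D[1, 1, 1, ]
  expect_equal(interpolate_tensor(fld, c(3, 4, 5)), t6, tolerance = 1e-15)
  expect_equal(interpolate_tensor(fld, c(3.3, 4.7, 5.1)), t6,
               tolerance = 1e-15)
  # two different voxels, probe their midpoint
  fld2 <- fld
  fld2$D[2, 1, 1, ] <- 2 * t6
  expect_equal(interpolate_tensor(fld2, c(0.5, 0, 0)), 1.5 * t6,
               tolerance = 1e-12)
  expect_null(interpolate_tensor(fld, c(-5, 0, 0)))
})

test_that("a uniform field yields a straight streamline spanning the mask", {
  fld <- uniform_field(dims = c(40, 11, 11), dir = c(1, 0, 0))
  mask <- array(1, c(40, 11, 11))
  s <- propagate(c(20, 5, 5), fld, mask, track_params(min_len_mm = 5))
  expect_identical(s$status, "tracked")
  expect_identical(unname(s$stop_reasons), c("grid_exit", "grid_exit"))
  # straight: all points share y and z
  expect_lt(max(abs(s$points[, 2] - 5)), 1e-9)
  expect_lt(max(abs(s$points[, 3] - 5)), 1e-9)
  expect_equal(polyline_length(s), 39, tolerance = 1e-6)
})

test_that("low-FA fields reject the seed immediately", {
  fld <- uniform_field(eigenvalues = c(1.05e-3, 1e-3, 1e-3))  # FA ~ 0.03
  mask <- array(1, c(40, 11, 11))
  s <- propagate(c(20, 5, 5), fld, mask, track_params())
  expect_identical(s$status, "rejected_seed")
  expect_identical(nrow(s$points), 1L)
})

test_that("streamlines follow circular fibre fields with analytic arc length
           and curvature", {
  cf <- circular_field()
  R <- 20
  seed <- c(cf$centre + R / sqrt(2), cf$centre + R / sqrt(2), 5)
  s <- propagate(seed, cf$field, cf$mask,
                 track_params(step_mm = 0.2, max_len_mm = 60))
  # the quarter-annulus mask boundary sits half a voxel inside the axes
  analytic <- R * (pi / 2 - 2 * asin(0.5 / R))
  expect_equal(polyline_length(s), analytic, tolerance = 0.01)
  pts <- s$points[seq(1, nrow(s$points), by = 10), ]
  a <- pts[1:(nrow(pts) - 2), ]
  b <- pts[2:(nrow(pts) - 1), ]
  cc <- pts[3:nrow(pts), ]
  la <- sqrt(rowSums((b - cc)^2))
  lb <- sqrt(rowSums((a - cc)^2))
  lc <- sqrt(rowSums((a - b)^2))
  ar <- sqrt(rowSums(cuffarch:::cross3_rows(b - a, cc - a)^2)) / 2
  expect_equal(median(la * lb * lc / (4 * ar)), R, tolerance = 0.02)
})

test_that("endpoint acceptance classifies termination structures and length
           bounds", {
  apo <- plane_sheet(z0 = 0)
  exit <- plane_sheet(z0 = 30)
  p <- track_params()
  spanning <- fake_streamline(cbind(10, 10, seq(0, 30, by = 1)))
  expect_true(act_accept(spanning, apo, exit, 1, p)$accepted)

  # a 10 mm tract with valid endpoints on a thinner phantom is too short
  near_exit <- plane_sheet(z0 = 10)
  short <- fake_streamline(cbind(10, 10, seq(0, 10, by = 1)))
  res <- act_accept(short, apo, near_exit, 1, p)
  expect_false(res$accepted)
  expect_identical(res$reason, "too_short")

  both_apo <- fake_streamline(cbind(seq(5, 35), 10, 0.1))
  res2 <- act_accept(both_apo, apo, exit, 1, p)
  expect_identical(res2$reason, "both_ends_same_structure")

  floating <- fake_streamline(cbind(10, 10, seq(5, 25, by = 1)))
  expect_identical(act_accept(floating, apo, exit, 1, p)$reason,
                   "unterminated")
})

test_that("phantom tract sampling is deterministic in the seed and respects
           every tracking constraint", {
  ph <- small_phantom()
  ts <- small_tracts()
  expect_identical(ts$status, "complete")
  expect_length(ts$streamlines, 150)
  # determinism: same seed twice bit-identical, different seed differs
  ts2 <- sample_tracts(ph$tensors, ph$label_map$voxels == 1, ph$aponeurosis,
                       ph$fibre_exit, track_params(n_tracts = 10), seed = 7)
  ts3 <- sample_tracts(ph$tensors, ph$label_map$voxels == 1, ph$aponeurosis,
                       ph$fibre_exit, track_params(n_tracts = 10), seed = 8)
  expect_identical(ts2$streamlines[[1]]$points,
                   sample_tracts(ph$tensors, ph$label_map$voxels == 1,
                                 ph$aponeurosis, ph$fibre_exit,
                                 track_params(n_tracts = 10),
                                 seed = 7)$streamlines[[1]]$points)
  expect_false(isTRUE(all.equal(ts2$streamlines[[1]]$points,
                                ts3$streamlines[[1]]$points)))

  p <- ts$params
  cos_lim <- cos(p$max_turn_deg * pi / 180)
  for (s in ts$streamlines[1:40]) {
    segs <- diff(s$points)
    lens <- sqrt(rowSums(segs^2))
    expect_lte(max(lens), p$step_mm + 1e-9)
    u <- segs / lens
    dots <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
    expect_gte(min(dots), cos_lim - 1e-9)
    len <- sum(lens)
    expect_gte(len, p$min_len_mm)
    expect_lte(len, p$max_len_mm)
  }
  expect_true(all(ts$lengths >= p$min_len_mm & ts$lengths <= p$max_len_mm))
  expect_gte(ts$acceptance_rate, 0.9)
})

test_that("empty requests and FA-gate widening behave monotonically", {
  ph <- small_phantom()
  empty <- sample_tracts(ph$tensors, ph$label_map$voxels == 1,
                         ph$aponeurosis, ph$fibre_exit,
                         track_params(n_tracts = 0), seed = 1)
  expect_length(empty$streamlines, 0)
  expect_identical(empty$n_attempts, 0L)

  narrow <- sample_tracts(ph$tensors, ph$label_map$voxels == 1,
                          ph$aponeurosis, ph$fibre_exit,
                          track_params(n_tracts = 60), seed = 3)
  wide <- sample_tracts(ph$tensors, ph$label_map$voxels == 1,
                        ph$aponeurosis, ph$fibre_exit,
                        track_params(n_tracts = 60, fa_min = 0.05,
                                     fa_max = 0.9), seed = 3)
  expect_gte(wide$acceptance_rate, narrow$acceptance_rate - 1e-12)
})

test_that("tracking is equivariant under rigid transforms of field and seed", {
  ph <- small_phantom()
  mask <- ph$label_map$voxels == 1
  seed <- c(30, 15, 15)
  s1 <- propagate(seed, ph$tensors, mask, track_params())
  R <- rot_z(0.4)
  tr <- c(5, -3, 2)
  aff2 <- ph$tensors$affine
  aff2[1:3, 1:3] <- R %*% aff2[1:3, 1:3]
  aff2[1:3, 4] <- aff2[1:3, 4] + tr
  d <- dim(ph$tensors$D)
  Dm <- matrix(ph$tensors$D, prod(d[1:3]), 6)
  u6 <- unique(Dm)
  for (r in seq_len(nrow(u6))) {
    hit <- which(colSums(abs(t(Dm) - u6[r, ])) == 0)
    t33 <- R %*% cuffarch:::tensor6_to_33(u6[r, ]) %*% t(R)
    Dm[hit, ] <- matrix(cuffarch:::tensor33_to_6(t33), length(hit), 6,
                        byrow = TRUE)
  }
  fld2 <- tensor_field(array(Dm, d), affine = aff2)
  s2 <- propagate(as.numeric(R %*% seed + tr), fld2, mask, track_params())
  expect_equal(sweep(s1$points %*% t(R), 2, tr, "+"), s2$points,
               tolerance = 1e-6)
})
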