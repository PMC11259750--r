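test_that("phantom specs are validated against their invariants", {
  expect_error(phantom_spec(pennation_deg = 0), "pennation")
  expect_error(phantom_spec(pennation_deg = 95), "pennation")
  expect_error(phantom_spec(eigenvalues = c(1e-3, 2e-3, 1e-3)), "descending")
  expect_error(phantom_spec(eigenvalues = c(3e-3, 1e-3, 1e-3)), "FA")
  expect_error(phantom_spec(voxel_mm = 30), "unresolvable")
  expect_error(phantom_spec(length_jitter_sd = -1), "jitter")
})

test_that("closed-form fascicle length follows slab / sin(pennation)", {
  expect_equal(phantom_truth_len <- build_unipennate(
    phantom_spec(shape_mm = c(70, 24, 36), slab_thickness_mm = 25,
                 pennation_deg = 30))$truth$true_fascicle_length_mm, 50)
  ph90 <- build_unipennate(phantom_spec(shape_mm = c(40, 24, 44),
                                        slab_thickness_mm = 30,
                                        pennation_deg = 90))
  expect_equal(ph90$truth$true_fascicle_length_mm, 30)
  # fibres normal to the aponeurosis: principal axis along z
  mus <- which(ph90$label_map$voxels == 1, arr.ind = TRUE)[1, ]
  t6 <- ph90$tensors$D[mus[1], mus[2], mus[3], ]
  d <- as.numeric(principal_direction(t6))
  expect_equal(abs(d), c(0, 0, 1), tolerance = 1e-12)
})

test_that("every in-muscle tensor carries the spec's FA, inside the gate", {
  ph <- small_phantom()
  idx <- which(ph$label_map$voxels == 1)
  d <- dim(ph$tensors$D)
  Dm <- matrix(ph$tensors$D, prod(d[1:3]), 6)[idx, ]
  u6 <- unique(Dm)
  for (r in seq_len(nrow(u6))) {
    ev <- eigen(cuffarch:::tensor6_to_33(u6[r, ]), symmetric = TRUE,
                only.values = TRUE)$values
    f <- fa(ev)
    expect_equal(f, fa(ph$spec$eigenvalues), tolerance = 1e-12)
    expect_gte(f, 0.1)
    expect_lte(f, 0.5)
  }
})

test_that("ground-truth PCSA identity holds to machine precision", {
  for (ph in list(small_phantom(),
                  build_bipennate(phantom_spec(shape_mm = c(70, 24, 64),
                                               slab_thickness_mm = 20,
                                               arrangement = "bipennate")))) {
    tr <- ph$truth
    expect_equal(tr$true_pcsa_cm2 * tr$true_fascicle_length_mm / 10,
                 tr$true_volume_cm3, tolerance = 1e-12)
  }
})

test_that("phantom regeneration is seed-deterministic", {
  sp <- phantom_spec(shape_mm = c(70, 24, 44), slab_thickness_mm = 20,
                     length_jitter_sd = 5, seed = 9)
  a <- build_unipennate(sp)
  b <- build_unipennate(sp)
  expect_identical(a$label_map$voxels, b$label_map$voxels)
  expect_identical(a$tensors$D, b$tensors$D)
  sp2 <- sp
  sp2$seed <- 10L
  c3 <- build_unipennate(sp2)
  expect_false(identical(a$label_map$voxels, c3$label_map$voxels))
})

test_that("bipennate phantoms have symmetric populations and pooled truth", {
  sp <- phantom_spec(shape_mm = c(70, 24, 64), slab_thickness_mm = 20,
                     pennation_deg = 20, arrangement = "bipennate")
  bp <- build_bipennate(sp)
  expect_equal(bp$truth$true_pennation_deg, 20)
  expect_equal(bp$truth$per_population_pennation_deg, c(20, -20))
  # two opposed principal directions present in the muscle
  idx <- which(bp$label_map$voxels == 1)
  d <- dim(bp$tensors$D)
  u6 <- unique(matrix(bp$tensors$D, prod(d[1:3]), 6)[idx, ])
  expect_identical(nrow(u6), 2L)
  d1 <- as.numeric(principal_direction(u6[1, ]))
  d2 <- as.numeric(principal_direction(u6[2, ]))
  expect_equal(abs(d1[3]), abs(d2[3]), tolerance = 1e-12)
  expect_equal(abs(sum(d1 * d2)), abs(cos(2 * 20 * pi / 180)),
               tolerance = 1e-9)
})

test_that("measured pennation ordering follows the nominal angle", {
  angles <- c(20, 40)
  measured <- vapply(angles, function(a) {
    ph <- build_unipennate(phantom_spec(shape_mm = c(80, 24, 44),
                                        slab_thickness_mm = 20,
                                        pennation_deg = a, seed = 4))
    ts <- sample_tracts(ph$tensors, ph$label_map$voxels == 1,
                        ph$aponeurosis, ph$fibre_exit,
                        track_params(n_tracts = 40), seed = 5)
    rec <- fascicle_records(ts, ph$aponeurosis)
    mean(rec$pennation_deg, na.rm = TRUE)
  }, numeric(1))
  expect_lt(measured[1], measured[2])
  expect_equal(measured, angles, tolerance = 0.05)
})

test_that("articular cap samples sit exactly on the sphere without noise and
           average the radius with it", {
  art0 <- build_articular_surface(c(5, 6, 7), 24, 60, 50, 0, seed = 3)
  d <- sqrt(rowSums(sweep(art0$points, 2, c(5, 6, 7))^2))
  expect_equal(max(abs(d - 24)), 0, tolerance = 1e-12)

  art <- build_articular_surface(c(0, 0, 0), 24, 60, 500, 0.2, seed = 1)
  expect_equal(mean(sqrt(rowSums(art$points^2))), 24, tolerance = 0.002)
  expect_error(build_articular_surface(n_points = 3), "at least 4")
  expect_error(build_articular_surface(cap_half_angle_deg = 0), "cap_half")
})

test_that("tendon landmark construction hits the requested moment arm", {
  tl <- build_tendon_landmarks(c(3, -2, 10), 24.2, seed = 6)
  s <- seq(-1, 1, length.out = 1e5)
  brute <- min(sqrt(rowSums(sweep(tl$curve(s), 2, c(3, -2, 10))^2)))
  expect_equal(brute, 24.2, tolerance = 1e-6)
  # degenerate: a curve through the centre has zero arm
  tl0 <- build_tendon_landmarks(c(0, 0, 0), 0, seed = 2)
  brute0 <- min(sqrt(rowSums(tl0$curve(s)^2)))
  expect_lt(brute0, 1e-3)  # limited only by the sampling density
  expect_error(build_tendon_landmarks(n_landmarks = 3), ">= 4")
})

test_that("reliability cohorts encode the requested variance structure", {
  perfect <- build_reliability_cohort(10, 3, 0, 0, seed = 1)
  expect_equal(perfect$table$values[, 1], perfect$table$values[, 2],
               ignore_attr = TRUE)
  expect_equal(perfect$truth$true_icc, 1)
  rc <- build_reliability_cohort(10, 3, 0, 1, seed = 1)
  expect_equal(rc$truth$true_icc, 0.9)
  expect_error(build_reliability_cohort(10, 0, 0, 0), "ICC undefined")
  expect_error(build_reliability_cohort(2, 1, 0, 1), "at least 3")
})

test_that("architecture cohorts normalize relative volumes and carry the sex
           effect", {
  bc <- build_cohort(seed = 2)
  sums <- tapply(bc$cohort$relative_volume_pct, bc$cohort$subject, sum)
  expect_equal(as.numeric(sums), rep(100, 20), tolerance = 1e-9)
  expect_error(build_cohort(sex_volume_ratio = 0), "> 0")
  expect_error(build_cohort(n_subjects = 3), "per sex")
  # Monte-Carlo recovery of the injected male/female total-volume ratio
  ratios <- vapply(1:30, function(i) {
    b <- build_cohort(seed = 100 + i)
    tot <- tapply(b$cohort$volume_cm3, b$cohort$subject, sum)
    sex <- tapply(b$cohort$sex, b$cohort$subject, function(s) s[1])
    mean(tot[sex == "M"]) / mean(tot[sex == "F"])
  }, numeric(1))
  expect_equal(mean(ratios), 1.83, tolerance = 0.05)
})
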