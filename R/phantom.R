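#' Specification of a pennate muscle phantom
#'
#' Describes a synthetic multipennate muscle used to validate the whole
#' pipeline against closed-form ground truth: a planar internal aponeurosis
#' with one (unipennate) or two (bipennate) populations of straight fibres
#' at a fixed angle to it, filling a sheared prism so that every fibre spans
#' the full aponeurosis-to-surface distance.
#'
#' @param shape_mm box extents (mm), c(x, y, z).
#' @param voxel_mm isotropic voxel size (mm); must not exceed the slab
#'   thickness or the phantom is unresolvable.
#' @param pennation_deg nominal fibre angle to the aponeurosis plane, in
#'   (0, 90].
#' @param slab_thickness_mm perpendicular distance from aponeurosis to the
#'   fibre-exit surface (mm); true fascicle length is
#'   \code{slab_thickness_mm / sin(pennation)}.
#' @param eigenvalues three tensor eigenvalues (mm^2/s), strictly positive
#'   and descending, with fractional anisotropy inside [0.1, 0.5] so the
#'   phantom's own fibres pass the tracking gate.
#' @param arrangement \code{"unipennate"} or \code{"bipennate"}.
#' @param length_jitter_sd SD (mm) of smooth per-region fibre-length
#'   heterogeneity, implemented as a sinusoidal modulation of slab thickness
#'   across the fibre-transverse axis so tensors stay spatially coherent.
#' @param seed RNG seed recorded in the phantom metadata.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape_mm = c(90, 40, 48), voxel_mm = 1,
                         pennation_deg = 30, slab_thickness_mm = 25,
                         eigenvalues = c(1.7e-3, 1.2e-3, 1.2e-3),
                         arrangement = c("unipennate", "bipennate"),
                         length_jitter_sd = 0, seed = 1L) {
  arrangement <- match.arg(arrangement)
  if (!(pennation_deg > 0 && pennation_deg <= 90)) {
    stop("'pennation_deg' must be in (0, 90]")
  }
  if (length(eigenvalues) != 3 || any(eigenvalues <= 0) ||
      any(diff(eigenvalues) > 0)) {
    stop("'eigenvalues' must be three strictly positive descending values")
  }
  f <- fa(eigenvalues)
  if (f < 0.1 || f > 0.5) {
    stop(sprintf("FA of eigenvalues is %.3f; must lie in [0.1, 0.5]", f))
  }
  if (voxel_mm > slab_thickness_mm) {
    stop("voxel size exceeds slab thickness; phantom unresolvable")
  }
  if (length_jitter_sd < 0) stop("'length_jitter_sd' must be >= 0")
  structure(list(shape_mm = shape_mm, voxel_mm = voxel_mm,
                 pennation_deg = pennation_deg,
                 slab_thickness_mm = slab_thickness_mm,
                 eigenvalues = eigenvalues, arrangement = arrangement,
                 length_jitter_sd = length_jitter_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Constant tensor whose principal axis is `dir` (in the x-z plane) with the
# spec's eigenvalues, as a 6-vector (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz).
pennate_tensor6 <- function(dir, eigenvalues) {
  e1 <- unit(dir)
  e2 <- c(0, 1, 0)
  e3 <- cross3(e1, e2)
  B <- cbind(e1, e2, e3)
  tensor33_to_6(B %*% diag(eigenvalues) %*% t(B))
}

# Triangulated rectangle in a z = f(y) graph over [x0,x1] x [y0,y1].
sheet_mesh <- function(x0, x1, y0, y1, zfun, step = 2) {
  xs <- seq(x0, x1, by = step)
  if (xs[length(xs)] < x1) xs <- c(xs, x1)
  ys <- seq(y0, y1, by = step)
  if (ys[length(ys)] < y1) ys <- c(ys, y1)
  nxg <- length(xs); nyg <- length(ys)
  verts <- cbind(rep(xs, times = nyg), rep(ys, each = nxg), 0)
  verts[, 3] <- zfun(verts[, 2])
  vid <- function(i, j) (j - 1L) * nxg + i
  i <- rep(seq_len(nxg - 1L), times = nyg - 1L)
  j <- rep(seq_len(nyg - 1L), each = nxg - 1L)
  f1 <- cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L))
  f2 <- cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
  surface_mesh(verts, rbind(f1, f2))
}

build_pennate <- function(spec) {
  h <- spec$voxel_mm
  alpha <- deg2rad(spec$pennation_deg)
  sin_a <- sin(alpha)
  slab <- spec$slab_thickness_mm
  L0 <- slab / sin_a
  run <- slab / tan(alpha)  # horizontal excursion of one fibre
  bip <- spec$arrangement == "bipennate"
  apo_th <- 2  # aponeurosis sheet thickness (mm)
  margin <- 2 * h

  nx <- round(spec$shape_mm[1] / h)
  ny <- round(spec$shape_mm[2] / h)
  nz <- round(spec$shape_mm[3] / h)
  x <- (seq_len(nx) - 1) * h
  y <- (seq_len(ny) - 1) * h
  z <- (seq_len(nz) - 1) * h
  Ly <- ny * h

  Wx <- spec$shape_mm[1] - run - 2 * margin
  if (Wx < 5 * h) {
    stop("phantom box too small in x for this pennation/slab combination")
  }

  jitter_profile <- function(phase) {
    function(yy) {
      sqrt(2) * spec$length_jitter_sd *
        sin(2 * pi * yy / Ly + phase) * sin_a
    }
  }
  phases <- with_seed(spec$seed, stats::runif(2, 0, 2 * pi))
  t_top_fun <- function(yy) slab + jitter_profile(phases[1])(yy)
  t_bot_fun <- function(yy) slab + jitter_profile(phases[2])(yy)
  jit_max <- sqrt(2) * spec$length_jitter_sd * sin_a

  z0 <- if (bip) round(nz / 2) * h else 3 + apo_th
  if (z0 + slab + jit_max + 2 * h > max(z)) {
    stop("phantom box too short in z for slab thickness plus jitter")
  }
  if (bip && z0 - apo_th - slab - jit_max - 2 * h < 0) {
    stop("phantom box too short in z for the lower bipennate slab")
  }

  X <- array(rep(x, times = ny * nz), c(nx, ny, nz))
  Tt <- array(rep(rep(t_top_fun(y), each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(z, each = nx * ny), c(nx, ny, nz))
  zrel <- Z - z0
  x_lo <- margin + zrel / tan(alpha)
  upper <- zrel > 0 & zrel <= Tt & X >= x_lo & X <= x_lo + Wx

  vox <- array(0L, c(nx, ny, nz))
  vox[upper] <- 1L
  if (bip) {
    Tb <- array(rep(rep(t_bot_fun(y), each = nx), times = nz), c(nx, ny, nz))
    w <- -(zrel + apo_th)  # depth below the aponeurosis underside
    xb_lo <- margin + w / tan(alpha)
    lower <- w > 0 & w <= Tb & X >= xb_lo & X <= xb_lo + Wx
    vox[lower] <- 1L
  } else {
    lower <- NULL
  }
  vox[zrel >= -apo_th & zrel < 0 &
        X >= margin - 2 & X <= margin + Wx + run + 2] <- 2L

  map <- label_map(vox, voxel_mm = h)

  D <- array(0, c(nx, ny, nz, 6))
  t6_up <- pennate_tensor6(c(cos(alpha), 0, sin_a), spec$eigenvalues)
  mus_up <- which(upper)
  nvol <- nx * ny * nz
  for (cc in 1:6) D[mus_up + (cc - 1) * nvol] <- t6_up[cc]
  if (bip) {
    t6_dn <- pennate_tensor6(c(cos(alpha), 0, -sin_a), spec$eigenvalues)
    mus_dn <- which(lower)
    for (cc in 1:6) D[mus_dn + (cc - 1) * nvol] <- t6_dn[cc]
  }
  field <- tensor_field(D, voxel_mm = h)

  xmax_exit <- margin + Wx + run + 2
  apo_planes <- if (bip) c(z0, z0 - apo_th) else z0
  apo <- Reduce(merge_meshes, lapply(apo_planes, function(zp) {
    sheet_mesh(margin - 2, margin + Wx + run + 2, min(y), max(y),
               function(yy) rep(zp, length(yy)))
  }))
  exit_sheets <- list(sheet_mesh(margin, xmax_exit, min(y), max(y),
                                 function(yy) z0 + t_top_fun(yy)))
  if (bip) {
    exit_sheets[[2]] <- sheet_mesh(margin, xmax_exit, min(y), max(y),
                                   function(yy) z0 - apo_th - t_bot_fun(yy))
  }
  fibre_exit <- Reduce(merge_meshes, exit_sheets)

  muscle <- surface_from_labels(map, 1L)
  vol_cm3 <- enclosed_volume(muscle)
  n_pop <- if (bip) 2 else 1
  true_vol <- n_pop * Wx * Ly * slab / 1000  # mean thickness = slab
  truth <- list(
    true_fascicle_length_mm = L0,
    true_pennation_deg = spec$pennation_deg,
    true_volume_cm3 = true_vol,
    true_pcsa_cm2 = true_vol / (L0 / 10),
    true_length_cv_pct = if (L0 > 0) 100 * spec$length_jitter_sd / L0 else 0,
    per_population_pennation_deg = if (bip)
      c(spec$pennation_deg, -spec$pennation_deg) else spec$pennation_deg,
    seed = spec$seed
  )
  structure(list(label_map = map, tensors = field, aponeurosis = apo,
                 muscle = muscle, fibre_exit = fibre_exit,
                 measured_volume_cm3 = vol_cm3, truth = truth, spec = spec),
            class = "muscle_phantom")
}

#' Build a unipennate muscle phantom
#'
#' One population of straight fibres at the spec's pennation angle runs from
#' a planar internal aponeurosis to the opposite slab face. The muscle
#' occupies a sheared prism whose sides are parallel to the fibre direction,
#' so every fibre spans the full slab and has known length
#' \code{slab / sin(pennation)}. In-muscle voxels carry a constant tensor
#' whose principal eigenvector is the fibre direction.
#'
#' @param spec a \code{phantom_spec} (its \code{arrangement} is forced to
#'   unipennate).
#' @return An object of class \code{muscle_phantom}: \code{label_map},
#'   \code{tensors}, \code{aponeurosis} and closed \code{muscle} meshes, the
#'   open \code{fibre_exit} sheet (the slab face opposite the aponeurosis,
#'   used as the ACT termination surface), measured mesh volume, and
#'   closed-form ground \code{truth}.
#' @export
build_unipennate <- function(spec = phantom_spec()) {
  spec$arrangement <- "unipennate"
  build_pennate(spec)
}

#' Build a bipennate muscle phantom
#'
#' Two fibre populations at +pennation and -pennation on either side of a
#' central planar aponeurosis. The pooled pennation magnitude equals the
#' nominal angle; ground truth records per-population signs.
#'
#' @param spec a \code{phantom_spec} (its \code{arrangement} is forced to
#'   bipennate). The default box is taller to fit both slabs.
#' @return A \code{muscle_phantom}; see \code{\link{build_unipennate}}.
#' @export
build_bipennate <- function(spec = phantom_spec(shape_mm = c(90, 40, 72),
                                                arrangement = "bipennate")) {
  spec$arrangement <- "bipennate"
  build_pennate(spec)
}

#' @export
print.muscle_phantom <- function(x, ...) {
  cat(sprintf("muscle_phantom (%s): pennation %g deg, fascicle length %.1f mm, volume %.1f cm^3 (mesh %.1f)\n",
              x$spec$arrangement, x$spec$pennation_deg,
              x$truth$true_fascicle_length_mm, x$truth$true_volume_cm3,
              x$measured_volume_cm3))
  invisible(x)
}

#' Concatenate two meshes into one (disjoint components)
#' @param a,b \code{surface_mesh} objects.
#' @return combined \code{surface_mesh}.
#' @export
merge_meshes <- function(a, b) {
  surface_mesh(rbind(a$vertices, b$vertices),
               rbind(a$faces, b$faces + nrow(a$vertices)))
}

#' Sample a noisy spherical cap (synthetic articular surface)
#'
#' Points drawn uniformly on a spherical cap around +z with isotropic
#' Gaussian radial noise, emulating vertices picked on the humeral-head
#' articular surface.
#'
#' @param centre_mm sphere centre (mm).
#' @param radius_mm sphere radius (mm).
#' @param cap_half_angle_deg half-angle of the cap in (0, 90].
#' @param n_points number of points (>= 4).
#' @param noise_sd_mm SD of radial noise (mm).
#' @param seed RNG seed.
#' @return list with \code{points} (n x 3) and \code{truth}
#'   (\code{true_centre_mm}, \code{true_radius_mm}).
#' @export
build_articular_surface <- function(centre_mm = c(0, 0, 0), radius_mm = 24,
                                    cap_half_angle_deg = 60, n_points = 500,
                                    noise_sd_mm = 0.2, seed = 1L) {
  if (n_points < 4) stop("need at least 4 points to determine a sphere")
  if (!(cap_half_angle_deg > 0 && cap_half_angle_deg <= 90)) {
    stop("'cap_half_angle_deg' must be in (0, 90]")
  }
  pts <- with_seed(seed, {
    cosu <- stats::runif(n_points, cos(deg2rad(cap_half_angle_deg)), 1)
    phi <- stats::runif(n_points, 0, 2 * pi)
    sinu <- sqrt(pmax(1 - cosu^2, 0))
    dirs <- cbind(sinu * cos(phi), sinu * sin(phi), cosu)
    r <- radius_mm + stats::rnorm(n_points, 0, noise_sd_mm)
    sweep(dirs * r, 2, centre_mm, "+")
  })
  sv <- svd(sweep(pts, 2, colMeans(pts)))$d
  if (sv[3] < 1e-9 * max(sv[1], 1e-12)) {
    stop("degenerate (coplanar) articular sample; enlarge the cap or n")
  }
  list(points = pts,
       truth = list(true_centre_mm = centre_mm, true_radius_mm = radius_mm,
                    seed = seed))
}

#' Synthetic tendon landmark cluster with known moment arm
#'
#' Places landmarks exactly on a gently curved cubic space curve whose
#' minimum distance to the joint centre equals the requested moment arm (the
#' curve is tangent to the sphere of that radius at its midpoint, and its
#' distance to the centre increases away from the tangency point).
#'
#' @param centre_mm joint centre (mm).
#' @param true_moment_arm_mm desired minimum curve-to-centre distance (mm).
#' @param n_landmarks number of landmarks along the curve (>= 4).
#' @param seed RNG seed (random curve orientation).
#' @param half_span_mm landmark cluster half-extent along the tendon (mm).
#' @param bow_mm outward quadratic bow of the curve (mm).
#' @param twist_mm cubic out-of-plane component (mm).
#' @return list with \code{landmarks} (ordered, insertion first),
#'   \code{curve} (function of s in [-1, 1] returning points), and
#'   \code{truth}.
#' @export
build_tendon_landmarks <- function(centre_mm = c(0, 0, 0),
                                   true_moment_arm_mm = 24.2,
                                   n_landmarks = 4, seed = 1L,
                                   half_span_mm = 12, bow_mm = 1.5,
                                   twist_mm = 0.8) {
  if (n_landmarks < 4) stop("cubic line-of-action fit needs >= 4 landmarks")
  if (true_moment_arm_mm < 0) stop("'true_moment_arm_mm' must be >= 0")
  frame <- with_seed(seed, {
    u <- unit(stats::rnorm(3))
    v <- stats::rnorm(3)
    v <- unit(v - sum(v * u) * u)
    list(u = u, v = v, w = cross3(u, v))
  })
  curve <- function(s) {
    s <- as.numeric(s)
    radial <- true_moment_arm_mm + bow_mm * s^2
    t(vapply(seq_along(s), function(i) {
      centre_mm + radial[i] * frame$u + half_span_mm * s[i] * frame$v +
        twist_mm * s[i]^3 * frame$w
    }, numeric(3)))
  }
  s_land <- seq(-1, 1, length.out = n_landmarks)
  list(landmarks = curve(s_land), curve = curve, s_landmarks = s_land,
       truth = list(true_centre_mm = centre_mm,
                    true_moment_arm_mm = true_moment_arm_mm, seed = seed))
}

#' Two-session reliability cohort with known ICC
#'
#' Generates paired measurements under the two-way random-effects model
#' \eqn{y_{ij} = \mu + s_i + r_j + e_{ij}} (k = 2 sessions), whose
#' absolute-agreement single-measure ICC is
#' \eqn{\sigma_s^2 / (\sigma_s^2 + \sigma_r^2 + \sigma_e^2)}.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param sigma_subject,sigma_session,sigma_error SDs of the subject,
#'   session, and residual effects (all >= 0, not all zero).
#' @param mu grand mean of the measurement.
#' @param seed RNG seed.
#' @return list with \code{table} (a \code{paired_table}) and \code{truth}
#'   (\code{true_icc} and the variance components).
#' @export
build_reliability_cohort <- function(n_subjects = 10, sigma_subject = 3,
                                     sigma_session = 0, sigma_error = 1,
                                     mu = 50, seed = 1L) {
  if (n_subjects < 3) stop("need at least 3 subjects")
  if (any(c(sigma_subject, sigma_session, sigma_error) < 0)) {
    stop("variance components must be >= 0")
  }
  v <- c(sigma_subject, sigma_session, sigma_error)^2
  if (sum(v) == 0) stop("all variance components zero; ICC undefined")
  y <- with_seed(seed, {
    s <- stats::rnorm(n_subjects, 0, sigma_subject)
    r <- stats::rnorm(2, 0, sigma_session)
    e <- matrix(stats::rnorm(2 * n_subjects, 0, sigma_error), n_subjects, 2)
    mu + outer(s, rep(1, 2)) + outer(rep(1, n_subjects), r) + e
  })
  tab <- paired_table(seq_len(n_subjects), y[, 1], y[, 2])
  list(table = tab,
       truth = list(true_icc = v[1] / sum(v), sigma2 = v, seed = seed))
}

#' Paired two-session measurement table
#' @param subject subject identifiers.
#' @param measurement_1,measurement_2 paired values (same units), no missing.
#' @return An object of class \code{paired_table} with a \code{values}
#'   matrix.
#' @export
paired_table <- function(subject, measurement_1, measurement_2) {
  if (length(subject) != length(measurement_1) ||
      length(subject) != length(measurement_2)) {
    stop("subject and measurement vectors must have equal length")
  }
  if (length(subject) < 3) stop("need at least 3 subjects")
  if (anyNA(measurement_1) || anyNA(measurement_2)) {
    stop("missing pairs are not allowed")
  }
  structure(list(subject = subject,
                 values = cbind(m1 = measurement_1, m2 = measurement_2)),
            class = "paired_table")
}

#' Synthetic architecture cohort with a known sex effect
#'
#' Per-subject tables for the four rotator cuff muscles. Relative volumes
#' are drawn around the canonical 43/34/15/8 percent split (subscapularis,
#' infraspinatus, supraspinatus, teres minor) via a Dirichlet draw, so they
#' sum to 100 by construction. Male total volumes are scaled by
#' \code{sex_volume_ratio}; lengths, pennations, and moment arms are drawn
#' around published in vivo means with interindividual CVs in the reported
#' regime and no sex effect.
#'
#' @param n_subjects total subjects (default 20: 11 male, 9 female).
#' @param sex_volume_ratio male/female total-volume ratio (> 0).
#' @param n_males number of males (both sexes need >= 2).
#' @param seed RNG seed.
#' @return list with \code{cohort} (data.frame consumable by
#'   \code{\link{make_cohort_report}}) and \code{truth}.
#' @export
build_cohort <- function(n_subjects = 20, sex_volume_ratio = 1.83,
                         n_males = round(n_subjects * 11 / 20), seed = 1L) {
  if (sex_volume_ratio <= 0) stop("'sex_volume_ratio' must be > 0")
  n_females <- n_subjects - n_males
  if (n_males < 2 || n_females < 2) stop("need at least 2 subjects per sex")

  muscles <- c("supraspinatus", "subscapularis", "infraspinatus", "teres_minor")
  rel_means <- c(supraspinatus = 0.15, subscapularis = 0.43,
                 infraspinatus = 0.34, teres_minor = 0.08)
  len_means <- c(supraspinatus = 59.8, subscapularis = 61.8,
                 infraspinatus = 69.7, teres_minor = 41.9)
  penn_means <- c(supraspinatus = 17, subscapularis = 21,
                  infraspinatus = 20, teres_minor = 22)
  arm_means <- c(supraspinatus = 24.2, subscapularis = 23.3,
                 infraspinatus = 24.2, teres_minor = 22.9)
  female_total_mean <- 225  # cm^3
  total_cv <- 0.18
  concentration <- 360

  cohort <- with_seed(seed, {
    sex <- c(rep("M", n_males), rep("F", n_females))
    rows <- vector("list", n_subjects * 4)
    k <- 0L
    for (i in seq_len(n_subjects)) {
      tot_mean <- female_total_mean *
        if (sex[i] == "M") sex_volume_ratio else 1
      total <- stats::rnorm(1, tot_mean, total_cv * tot_mean)
      total <- max(total, 0.3 * tot_mean)
      g <- stats::rgamma(4, shape = rel_means * concentration, rate = 1)
      rel <- g / sum(g)
      for (m in seq_along(muscles)) {
        len <- max(stats::rnorm(1, len_means[m], 0.13 * len_means[m]), 10)
        penn <- max(stats::rnorm(1, penn_means[m], 0.10 * penn_means[m]), 1)
        arm <- max(stats::rnorm(1, arm_means[m], 0.07 * arm_means[m]), 5)
        vol <- total * rel[m]
        k <- k + 1L
        rows[[k]] <- data.frame(
          subject = sprintf("S%02d", i), sex = sex[i], muscle = muscles[m],
          volume_cm3 = vol, relative_volume_pct = 100 * rel[m],
          pcsa_cm2 = pcsa(vol, len), mean_fascicle_len_mm = len,
          mean_pennation_deg = penn, moment_arm_mm = arm)
      }
    }
    do.call(rbind, rows)
  })
  list(cohort = cohort,
       truth = list(sex_volume_ratio = sex_volume_ratio,
                    relative_volume_means_pct = 100 * rel_means,
                    female_total_mean_cm3 = female_total_mean, seed = seed))
}
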