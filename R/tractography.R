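#' Deterministic tracking parameters
#'
#' Defaults follow common practice for skeletal-muscle DTI fibre tracking:
#' 1.0 mm integration step, fractional anisotropy gate [0.1, 0.5], 15 degree
#' maximum turning angle between successive steps, accepted tract length
#' between 25 and 200 mm, and 3000 tracts per muscle.
#'
#' @param step_mm integration step size (mm).
#' @param fa_min,fa_max fractional anisotropy gate.
#' @param max_turn_deg maximum turning angle between successive steps.
#' @param min_len_mm,max_len_mm accepted tract length bounds (mm).
#' @param n_tracts number of accepted tracts to collect per muscle.
#' @return An object of class \code{track_params}.
#' @export
track_params <- function(step_mm = 1.0, fa_min = 0.1, fa_max = 0.5,
                         max_turn_deg = 15, min_len_mm = 25,
                         max_len_mm = 200, n_tracts = 3000) {
  stopifnot_scalar(step_mm, "step_mm", positive = TRUE)
  if (!(fa_min >= 0 && fa_min < fa_max && fa_max <= 1)) {
    stop("require 0 <= fa_min < fa_max <= 1")
  }
  if (!(min_len_mm < max_len_mm)) stop("require min_len_mm < max_len_mm")
  if (max_turn_deg <= 0 || max_turn_deg > 180) {
    stop("'max_turn_deg' must be in (0, 180]")
  }
  structure(list(step_mm = step_mm, fa_min = fa_min, fa_max = fa_max,
                 max_turn_deg = max_turn_deg, min_len_mm = min_len_mm,
                 max_len_mm = max_len_mm, n_tracts = n_tracts),
            class = "track_params")
}

# Resolve a muscle mask argument to a numeric 0/1 array on the field grid.
resolve_mask <- function(mask, field) {
  arr <- if (inherits(mask, "label_map")) mask$voxels else mask
  arr <- array(as.numeric(arr != 0), dim(arr))
  if (!all(dim(arr) == dim(field$D)[1:3])) {
    stop("mask grid does not match tensor field grid")
  }
  arr
}

#' Propagate one streamline through a tensor field
#'
#' Bidirectional fixed-step Euler integration from the seed, following the
#' interpolated principal eigenvector with sign continuity. Each half stops
#' when the fractional anisotropy leaves the gate, the turning angle exceeds
#' the limit, the streamline leaves the muscle mask or the grid, the local
#' tensor is degenerate, or the half reaches the maximum length. On a
#' mask/grid/FA exit the final point is refined by bisection onto the
#' constraint boundary so that endpoints land on the tissue interface.
#'
#' @param seed 3-vector in mm. Must lie in the mask with in-gate FA,
#'   otherwise a rejection record (\code{status = "rejected_seed"}) is
#'   returned rather than an error.
#' @param field a \code{tensor_field}.
#' @param muscle_mask a \code{label_map} or 3D array (non-zero = in mask) on
#'   the field grid.
#' @param params a \code{track_params}.
#' @return An object of class \code{streamline}: points (n x 3 mm), per-end
#'   \code{stop_reasons}, and \code{status} (\code{"tracked"} or
#'   \code{"rejected_seed"}).
#' @export
propagate <- function(seed, field, muscle_mask, params = track_params()) {
  mask <- resolve_mask(muscle_mask, field)
  D <- field$D
  inv3 <- field$inv_affine[1:3, 1:3]
  inv_o <- field$inv_affine[1:3, 4]
  step <- params$step_mm
  cos_max <- cos(deg2rad(params$max_turn_deg))

  to_vox <- function(p) inv3 %*% p + inv_o
  tensor_at <- function(p) {
    v <- to_vox(p)
    interp6_voxel(D, v[1], v[2], v[3])
  }
  valid_at <- function(p) {
    v <- to_vox(p)
    m <- interp1_voxel(mask, v[1], v[2], v[3])
    if (is.na(m)) return("grid_exit")
    if (m < 0.5) return("mask_exit")
    t6 <- interp6_voxel(D, v[1], v[2], v[3])
    f <- fa_from_t6(t6)
    if (is.na(f) || f < params$fa_min || f > params$fa_max) return("fa_out_of_range")
    "ok"
  }

  seed <- as.numeric(seed)
  seed_state <- valid_at(seed)
  if (seed_state != "ok") {
    return(structure(list(points = matrix(seed, 1, 3), status = "rejected_seed",
                          stop_reasons = c(seed_state, seed_state)),
                     class = "streamline"))
  }
  d0 <- principal_direction(tensor_at(seed))
  if (attr(d0, "degenerate")) {
    return(structure(list(points = matrix(seed, 1, 3), status = "rejected_seed",
                          stop_reasons = c("degenerate_tensor", "degenerate_tensor")),
                     class = "streamline"))
  }

  march <- function(dir0) {
    max_steps <- ceiling(params$max_len_mm / step) + 1L
    pts <- matrix(NA_real_, max_steps, 3)
    n <- 0L
    p <- seed
    d <- as.numeric(dir0)
    travelled <- 0
    reason <- "max_length"
    while (travelled < params$max_len_mm - 1e-9) {
      h <- min(step, params$max_len_mm - travelled)
      pn <- p + h * d
      st <- valid_at(pn)
      if (st != "ok") {
        # bisect onto the constraint boundary along the last step
        lo <- 0; hi <- h
        for (it in 1:40) {
          mid <- (lo + hi) / 2
          if (valid_at(p + mid * d) == "ok") lo <- mid else hi <- mid
        }
        if (lo > 1e-7) {
          n <- n + 1L
          pts[n, ] <- p + lo * d
        }
        reason <- st
        break
      }
      n <- n + 1L
      pts[n, ] <- pn
      travelled <- travelled + h
      dn <- principal_direction(tensor_at(pn))
      if (attr(dn, "degenerate")) {
        reason <- "degenerate_tensor"
        break
      }
      dn <- as.numeric(dn)
      dp <- sum(dn * d)
      if (dp < 0) {
        dn <- -dn
        dp <- -dp
      }
      if (dp < cos_max) {
        reason <- "max_turn"
        break
      }
      p <- pn
      d <- dn
    }
    list(points = pts[seq_len(n), , drop = FALSE], reason = reason)
  }

  plus <- march(d0)
  minus <- march(-as.numeric(d0))
  pts <- rbind(minus$points[rev(seq_len(nrow(minus$points))), , drop = FALSE],
               matrix(seed, 1, 3),
               plus$points)
  structure(list(points = pts, status = "tracked",
                 stop_reasons = c(minus$reason, plus$reason)),
            class = "streamline")
}

#' @export
print.streamline <- function(x, ...) {
  cat(sprintf("streamline: %d points, length %.1f mm, status %s (%s | %s)\n",
              nrow(x$points),
              if (nrow(x$points) > 1) polyline_length(x) else 0,
              x$status, x$stop_reasons[1], x$stop_reasons[2]))
  invisible(x)
}

#' Anatomical endpoint acceptance of a streamline
#'
#' A tract is accepted when one endpoint lies within \code{tol_mm} of the
#' aponeurosis mesh, the other within \code{tol_mm} of the muscle surface
#' mesh, and its arc length falls inside the accepted bounds. Endpoints near
#' the aponeurosis are classified as aponeurosis terminations even if they
#' are also near the muscle surface (the aponeurosis abuts the muscle
#' boundary, so aponeurosis proximity takes priority).
#'
#' @param s a \code{streamline}.
#' @param aponeurosis,muscle \code{surface_mesh} objects.
#' @param tol_mm endpoint-to-mesh tolerance (mm); a sensible default is half
#'   the voxel diagonal.
#' @param params a \code{track_params} providing length bounds.
#' @param apo_index,muscle_index optional precomputed proximity indexes.
#' @return list with \code{accepted} (logical), \code{reason} (\code{"accepted"},
#'   \code{"too_short"}, \code{"too_long"}, \code{"both_ends_same_structure"},
#'   \code{"unterminated"}), \code{end_structures}, and \code{length_mm}.
#' @export
act_accept <- function(s, aponeurosis, muscle, tol_mm,
                       params = track_params(),
                       apo_index = NULL, muscle_index = NULL) {
  if (s$status != "tracked" || nrow(s$points) < 2) {
    return(list(accepted = FALSE, reason = "unterminated",
                end_structures = c(NA, NA), length_mm = 0))
  }
  if (is.null(apo_index)) apo_index <- mesh_proximity_index(aponeurosis)
  if (is.null(muscle_index)) muscle_index <- mesh_proximity_index(muscle)
  ends <- s$points[c(1, nrow(s$points)), , drop = FALSE]
  classify <- function(p) {
    if (point_mesh_distance(aponeurosis, p, apo_index) <= tol_mm) {
      return("aponeurosis")
    }
    if (point_mesh_distance(muscle, p, muscle_index) <= tol_mm) {
      return("muscle_surface")
    }
    NA_character_
  }
  structs <- c(classify(ends[1, ]), classify(ends[2, ]))
  len <- polyline_length(s)
  if (any(is.na(structs))) {
    return(list(accepted = FALSE, reason = "unterminated",
                end_structures = structs, length_mm = len))
  }
  if (structs[1] == structs[2]) {
    return(list(accepted = FALSE, reason = "both_ends_same_structure",
                end_structures = structs, length_mm = len))
  }
  if (len < params$min_len_mm) {
    return(list(accepted = FALSE, reason = "too_short",
                end_structures = structs, length_mm = len))
  }
  if (len > params$max_len_mm) {
    return(list(accepted = FALSE, reason = "too_long",
                end_structures = structs, length_mm = len))
  }
  list(accepted = TRUE, reason = "accepted", end_structures = structs,
       length_mm = len)
}

#' Sample anatomically constrained tracts in a muscle
#'
#' Draws uniformly random seeds over in-mask voxel centres (jittered within
#' the voxel), propagates each deterministically, and keeps tracts passing
#' the anatomical endpoint constraint until \code{params$n_tracts} are
#' accepted or the attempt budget is exhausted.
#'
#' @param field a \code{tensor_field}.
#' @param muscle_mask a \code{label_map} or 3D array on the field grid.
#' @param aponeurosis,muscle termination \code{surface_mesh} objects (the
#'   muscle mesh is the fascicle-exit surface).
#' @param params a \code{track_params}.
#' @param seed RNG seed for seed-point placement.
#' @param tol_mm endpoint tolerance; default half the voxel diagonal.
#' @param max_attempts attempt budget (default 100 x n_tracts); if exhausted
#'   a partial set is returned with \code{status = "budget_exhausted"}.
#' @return An object of class \code{tract_set}: accepted \code{streamlines},
#'   their lengths and end structures, the acceptance rate, and a rejection
#'   tally by reason.
#' @export
sample_tracts <- function(field, muscle_mask, aponeurosis, muscle,
                          params = track_params(), seed = 1L,
                          tol_mm = NULL, max_attempts = NULL) {
  mask <- resolve_mask(muscle_mask, field)
  if (!any(mask > 0)) stop("muscle mask is empty")
  if (is.null(max_attempts)) max_attempts <- 100L * max(params$n_tracts, 1L)
  if (is.null(tol_mm)) {
    h <- field$affine[1:3, 1:3]
    tol_mm <- sqrt(sum((h %*% c(1, 1, 1))^2)) / 2
  }
  n_target <- params$n_tracts
  tally <- c(accepted = 0, rejected_seed = 0, too_short = 0, too_long = 0,
             both_ends_same_structure = 0, unterminated = 0)
  streamlines <- vector("list", n_target)
  lengths <- numeric(n_target)
  end_structs <- vector("list", n_target)
  if (n_target == 0L) {
    return(structure(list(streamlines = list(), lengths = numeric(0),
                          end_structures = list(), n_attempts = 0L,
                          acceptance_rate = NA_real_, tally = tally,
                          params = params, seed = seed, tol_mm = tol_mm,
                          status = "complete"),
                     class = "tract_set"))
  }
  apo_index <- mesh_proximity_index(aponeurosis)
  muscle_index <- mesh_proximity_index(muscle)
  in_idx <- which(mask > 0)
  d <- dim(mask)
  ijk <- cbind((in_idx - 1) %% d[1],
               ((in_idx - 1) %/% d[1]) %% d[2],
               (in_idx - 1) %/% (d[1] * d[2]))
  A3 <- field$affine[1:3, 1:3]
  origin <- field$affine[1:3, 4]

  n_acc <- 0L
  attempts <- 0L
  with_seed(seed, {
    while (n_acc < n_target && attempts < max_attempts) {
      attempts <- attempts + 1L
      row <- ijk[sample.int(nrow(ijk), 1L), ] + runif(3, -0.5, 0.5)
      p <- as.numeric(A3 %*% row + origin)
      s <- propagate(p, field, mask, params)
      if (s$status != "tracked") {
        tally["rejected_seed"] <- tally["rejected_seed"] + 1
        next
      }
      res <- act_accept(s, aponeurosis, muscle, tol_mm, params,
                        apo_index, muscle_index)
      if (res$accepted) {
        n_acc <- n_acc + 1L
        tally["accepted"] <- tally["accepted"] + 1
        s$end_structures <- res$end_structures
        streamlines[[n_acc]] <- s
        lengths[n_acc] <- res$length_mm
        end_structs[[n_acc]] <- res$end_structures
      } else {
        tally[res$reason] <- tally[res$reason] + 1
      }
    }
  })
  structure(list(streamlines = streamlines[seq_len(n_acc)],
                 lengths = lengths[seq_len(n_acc)],
                 end_structures = end_structs[seq_len(n_acc)],
                 n_attempts = attempts,
                 acceptance_rate = n_acc / attempts,
                 tally = tally, params = params, seed = seed, tol_mm = tol_mm,
                 status = if (n_acc == n_target) "complete" else "budget_exhausted"),
            class = "tract_set")
}

#' @export
print.tract_set <- function(x, ...) {
  cat(sprintf("tract_set: %d accepted tracts (%s), %d attempts, acceptance %.1f%%\n",
              length(x$streamlines), x$status, x$n_attempts,
              100 * x$acceptance_rate))
  if (length(x$lengths)) {
    cat(sprintf("  length %.1f +/- %.1f mm\n", mean(x$lengths),
                stats::sd(x$lengths)))
  }
  tl <- x$tally[x$tally > 0]
  if (length(tl)) {
    cat("  tally:", paste(names(tl), tl, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
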