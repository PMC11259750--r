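#' Arc length of a streamline polyline
#'
#' @param s a \code{streamline} or an n x 3 matrix of points (mm).
#' @return length in mm (sum of consecutive Euclidean segment lengths).
#' @export
polyline_length <- function(s) {
  pts <- if (inherits(s, "streamline")) s$points else as.matrix(s)
  if (nrow(pts) < 2) stop("polyline needs at least 2 points")
  sum(row_norms(diff(pts)))
}

#' Pennation angle of a fascicle against the aponeurosis mesh
#'
#' The fascicle direction is the unit chord over the last
#' \code{tangent_window_mm} of arc at the aponeurosis-terminating end. For
#' every aponeurosis face whose (exact point-to-triangle) distance from that
#' endpoint is at most \code{radius_mm}, the angle between the fascicle
#' direction and the face plane is computed as 90 degrees minus the angle to
#' the face normal, folded into [0, 90]; the mean over those faces is
#' returned.
#'
#' @param s a \code{streamline}; if it carries \code{end_structures} from
#'   acceptance, the aponeurosis-classified end is used, otherwise the end
#'   nearer the mesh (ties broken toward the first end).
#' @param aponeurosis the aponeurosis \code{surface_mesh}.
#' @param radius_mm face search radius around the endpoint (mm).
#' @param tangent_window_mm arc window for the endpoint chord direction; a
#'   single terminal segment is noise-sensitive, so a few integration steps
#'   are used.
#' @param index optional precomputed proximity index for the mesh.
#' @return angle in degrees, with attribute \code{n_faces}; \code{NA} (with a
#'   message) when no face lies within the radius.
#' @export
pennation_angle <- function(s, aponeurosis, radius_mm = 1.5,
                            tangent_window_mm = 3.0, index = NULL) {
  pts <- if (inherits(s, "streamline")) s$points else as.matrix(s)
  if (nrow(pts) < 2) stop("streamline needs at least 2 points")
  if (is.null(index)) index <- mesh_proximity_index(aponeurosis)

  which_end <- NA
  es <- if (inherits(s, "streamline")) s$end_structures else NULL
  if (!is.null(es) && sum(es == "aponeurosis", na.rm = TRUE) == 1) {
    which_end <- which(es == "aponeurosis")
  } else {
    d1 <- point_mesh_distance(aponeurosis, pts[1, ], index)
    d2 <- point_mesh_distance(aponeurosis, pts[nrow(pts), ], index)
    which_end <- if (d1 <= d2) 1L else 2L
  }
  if (which_end == 2L) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  endpoint <- pts[1, ]

  # chord over the last tangent_window_mm of arc at the terminating end
  acc <- 0
  inner <- nrow(pts)
  for (i in seq_len(nrow(pts) - 1)) {
    acc <- acc + vnorm(pts[i + 1, ] - pts[i, ])
    if (acc >= tangent_window_mm) {
      inner <- i + 1
      break
    }
  }
  dir <- unit(endpoint - pts[inner, ])

  faces <- faces_within(aponeurosis, endpoint, radius_mm, index)
  if (length(faces) == 0) {
    message("pennation_angle: no aponeurosis face within ", radius_mm,
            " mm of endpoint; returning NA")
    return(structure(NA_real_, n_faces = 0L))
  }
  a <- aponeurosis$vertices[aponeurosis$faces[faces, 1], , drop = FALSE]
  b <- aponeurosis$vertices[aponeurosis$faces[faces, 2], , drop = FALSE]
  c3 <- aponeurosis$vertices[aponeurosis$faces[faces, 3], , drop = FALSE]
  n <- cross3_rows(b - a, c3 - a)
  n <- n / row_norms(n)
  ang <- rad2deg(asin(pmin(abs(as.vector(n %*% dir)), 1)))
  structure(mean(ang), n_faces = length(faces))
}

#' Physiological cross-sectional area
#'
#' PCSA = muscle volume / mean fascicle length, the standard estimate of the
#' summed fibre cross-section (assumes the volume is all contractile tissue).
#'
#' @param volume_cm3 muscle volume in cm^3.
#' @param mean_fascicle_len_mm mean fascicle length in mm.
#' @return PCSA in cm^2.
#' @export
pcsa <- function(volume_cm3, mean_fascicle_len_mm) {
  stopifnot_scalar(volume_cm3, "volume_cm3", positive = TRUE)
  stopifnot_scalar(mean_fascicle_len_mm, "mean_fascicle_len_mm", positive = TRUE)
  volume_cm3 / (mean_fascicle_len_mm / 10)
}

#' Per-fascicle measurement records
#'
#' Computes length and pennation angle for every accepted tract.
#'
#' @param tracts a \code{tract_set}.
#' @param aponeurosis the aponeurosis \code{surface_mesh}.
#' @param radius_mm,tangent_window_mm passed to \code{\link{pennation_angle}}.
#' @return data.frame with columns \code{tract}, \code{length_mm},
#'   \code{pennation_deg}, \code{n_faces_used}.
#' @export
fascicle_records <- function(tracts, aponeurosis, radius_mm = 1.5,
                             tangent_window_mm = 3.0) {
  stopifnot(inherits(tracts, "tract_set"))
  index <- mesh_proximity_index(aponeurosis)
  n <- length(tracts$streamlines)
  penn <- numeric(n)
  nf <- integer(n)
  for (i in seq_len(n)) {
    p <- suppressMessages(
      pennation_angle(tracts$streamlines[[i]], aponeurosis, radius_mm,
                      tangent_window_mm, index))
    penn[i] <- as.numeric(p)
    nf[i] <- attr(p, "n_faces")
  }
  data.frame(tract = seq_len(n), length_mm = tracts$lengths,
             pennation_deg = penn, n_faces_used = nf)
}

#' Per-muscle architecture summary
#'
#' Mean, median, and sample SD (n - 1) of fascicle lengths and pennation
#' angles; intramuscular coefficients of variation (100 x SD / mean); PCSA
#' from volume and mean fascicle length; relative volume as a percentage of
#' the total rotator cuff volume. Fascicles with missing pennation (no
#' nearby aponeurosis faces) are excluded pairwise from the pennation
#' statistics and their count is recorded.
#'
#' @param records data.frame from \code{\link{fascicle_records}} (>= 2 rows).
#' @param volume_cm3 muscle volume in cm^3.
#' @param total_volume_cm3 optional total volume for relative volume.
#' @param muscle_name label carried into reports.
#' @return An object of class \code{architecture_summary}.
#' @export
summarize_muscle <- function(records, volume_cm3, total_volume_cm3 = NULL,
                             muscle_name = "muscle") {
  if (nrow(records) < 2) stop("need at least 2 fascicle records")
  stopifnot_scalar(volume_cm3, "volume_cm3", positive = TRUE)
  len <- records$length_mm
  penn <- records$pennation_deg[!is.na(records$pennation_deg)]
  mean_len <- mean(len)
  out <- list(
    muscle_name = muscle_name,
    volume_cm3 = volume_cm3,
    relative_volume_pct = if (is.null(total_volume_cm3)) NA_real_ else
      100 * volume_cm3 / total_volume_cm3,
    mean_fascicle_len_mm = mean_len,
    median_fascicle_len_mm = stats::median(len),
    sd_fascicle_len_mm = stats::sd(len),
    intramuscular_len_cv_pct = 100 * stats::sd(len) / mean_len,
    mean_pennation_deg = if (length(penn) >= 2) mean(penn) else NA_real_,
    sd_pennation_deg = if (length(penn) >= 2) stats::sd(penn) else NA_real_,
    intramuscular_penn_cv_pct = if (length(penn) >= 2)
      100 * stats::sd(penn) / mean(penn) else NA_real_,
    pcsa_cm2 = pcsa(volume_cm3, mean_len),
    n_tracts = nrow(records),
    n_pennation_missing = sum(is.na(records$pennation_deg))
  )
  structure(out, class = "architecture_summary")
}

#' @export
print.architecture_summary <- function(x, ...) {
  cat(sprintf("%s: volume %.1f cm^3", x$muscle_name, x$volume_cm3))
  if (!is.na(x$relative_volume_pct)) {
    cat(sprintf(" (%.0f%% of total)", x$relative_volume_pct))
  }
  cat("\n")
  cat(sprintf("  fascicle length %.1f (median %.1f, SD %.1f, CV %.0f%%) mm\n",
              x$mean_fascicle_len_mm, x$median_fascicle_len_mm,
              x$sd_fascicle_len_mm, x$intramuscular_len_cv_pct))
  cat(sprintf("  pennation %.0f (SD %.0f, CV %.0f%%) deg [%d missing]\n",
              x$mean_pennation_deg, x$sd_pennation_deg,
              x$intramuscular_penn_cv_pct, x$n_pennation_missing))
  cat(sprintf("  PCSA %.1f cm^2 over %d tracts\n", x$pcsa_cm2, x$n_tracts))
  invisible(x)
}

#' @export
as.data.frame.architecture_summary <- function(x, ...) {
  data.frame(muscle = x$muscle_name,
             volume_cm3 = x$volume_cm3,
             relative_volume_pct = x$relative_volume_pct,
             pcsa_cm2 = x$pcsa_cm2,
             mean_fascicle_len_mm = x$mean_fascicle_len_mm,
             median_fascicle_len_mm = x$median_fascicle_len_mm,
             sd_fascicle_len_mm = x$sd_fascicle_len_mm,
             intramuscular_len_cv_pct = x$intramuscular_len_cv_pct,
             mean_pennation_deg = x$mean_pennation_deg,
             sd_pennation_deg = x$sd_pennation_deg,
             intramuscular_penn_cv_pct = x$intramuscular_penn_cv_pct,
             n_tracts = x$n_tracts)
}
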