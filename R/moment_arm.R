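#' Least-squares sphere fit
#'
#' Estimates the glenohumeral centre of rotation by fitting a sphere to
#' points sampled on the humeral-head articular surface. An algebraic linear
#' solve provides the initial estimate; Gauss-Newton refinement then
#' minimizes the sum of squared geometric residuals
#' \eqn{\sum_i (\|p_i - c\| - r)^2}.
#'
#' @param points n x 3 matrix of surface points (mm), n >= 4, not coplanar.
#' @return An object of class \code{sphere_fit}: \code{centre_mm},
#'   \code{radius_mm}, \code{rms_residual_mm}, \code{n_points}.
#' @export
fit_sphere <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) < 4) stop("sphere fit needs at least 4 points")
  centred <- sweep(p, 2, colMeans(p))
  sv <- svd(centred)$d
  if (sv[3] < 1e-9 * max(sv[1], 1e-12)) {
    stop("points are coplanar (or otherwise degenerate); cannot fit a sphere")
  }
  # algebraic fit: |p|^2 = 2 p . c + (r^2 - |c|^2)
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  sol <- qr.solve(A, b)
  centre <- sol[1:3]
  r <- sqrt(sol[4] + sum(centre^2))

  # Gauss-Newton on (c, r)
  for (it in 1:50) {
    d <- sweep(p, 2, centre)
    dist <- row_norms(d)
    res <- dist - r
    J <- cbind(-d / dist, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 4))
    centre <- centre + step[1:3]
    r <- r + step[4]
    if (vnorm(step) < 1e-12 * max(r, 1)) break
  }
  d <- sweep(p, 2, centre)
  res <- row_norms(d) - r
  structure(list(centre_mm = as.numeric(centre), radius_mm = r,
                 rms_residual_mm = sqrt(mean(res^2)), n_points = nrow(p)),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("sphere_fit: centre (%.2f, %.2f, %.2f) mm, radius %.2f mm, RMS %.3g mm (n = %d)\n",
              x$centre_mm[1], x$centre_mm[2], x$centre_mm[3], x$radius_mm,
              x$rms_residual_mm, x$n_points))
  invisible(x)
}

#' Fit a cubic line of action through tendon landmarks
#'
#' Fits a third-order polynomial curve per axis through ordered landmarks
#' (insertion first), parameterized by normalized chord length t in [0, 1].
#' Four landmarks are interpolated exactly; more are fitted by least
#' squares.
#'
#' @param landmarks n x 3 matrix (mm), ordered along the tendon, n >= 4.
#' @return An object of class \code{line_of_action}: \code{coef} (4 x 3
#'   polynomial coefficients, constant term first), \code{t_domain},
#'   \code{landmarks}, \code{t_landmarks}.
#' @export
fit_line_of_action <- function(landmarks) {
  p <- as.matrix(landmarks)
  if (nrow(p) < 4) stop("line-of-action fit needs at least 4 landmarks")
  seg <- row_norms(diff(p))
  if (any(seg < 1e-9)) stop("coincident consecutive landmarks")
  t <- c(0, cumsum(seg)) / sum(seg)
  V <- cbind(1, t, t^2, t^3)
  coef <- qr.solve(V, p)  # exact when n = 4, least squares when n > 4
  structure(list(coef = coef, t_domain = c(0, 1), landmarks = p,
                 t_landmarks = t),
            class = "line_of_action")
}

#' Evaluate a line of action at parameter values
#' @param line a \code{line_of_action}.
#' @param t numeric vector of parameter values.
#' @return length(t) x 3 matrix of curve points (mm).
#' @export
line_point <- function(line, t) {
  cbind(1, t, t^2, t^3) %*% line$coef
}

#' @export
print.line_of_action <- function(x, ...) {
  cat(sprintf("line_of_action: cubic through %d landmarks, chord-length parameterized\n",
              nrow(x$landmarks)))
  invisible(x)
}

#' Moment arm as the minimum distance from a line of action to a centre
#'
#' The shortest perpendicular distance between the muscle line of action and
#' the joint centre of rotation, minimized over the landmark span t in
#' [0, 1] (dense sampling followed by local refinement). A minimum attained
#' at an endpoint of the span is flagged with attribute
#' \code{boundary_minimum}.
#'
#' @param line a \code{line_of_action}.
#' @param centre 3-vector, the centre of rotation (mm), or a
#'   \code{sphere_fit}.
#' @param n_samples dense-sampling resolution.
#' @return distance in mm with attributes \code{t_min} and
#'   \code{boundary_minimum}.
#' @export
moment_arm <- function(line, centre, n_samples = 1000L) {
  if (inherits(centre, "sphere_fit")) centre <- centre$centre_mm
  centre <- as.numeric(centre)
  f <- function(t) {
    pts <- line_point(line, t)
    rowSums(sweep(pts, 2, centre)^2)
  }
  ts <- seq(line$t_domain[1], line$t_domain[2], length.out = n_samples)
  d2 <- f(ts)
  i <- which.min(d2)
  lo <- ts[max(i - 1L, 1L)]
  hi <- ts[min(i + 1L, n_samples)]
  opt <- stats::optimize(function(t) f(t), interval = c(lo, hi),
                         tol = .Machine$double.eps^0.5)
  t_min <- opt$minimum
  d_min <- sqrt(opt$objective)
  # endpoints may beat the interior polish
  ends <- f(line$t_domain)
  if (min(ends) < d_min^2) {
    j <- which.min(ends)
    t_min <- line$t_domain[j]
    d_min <- sqrt(ends[j])
  }
  boundary <- min(abs(t_min - line$t_domain)) < 1e-6
  structure(d_min, t_min = t_min, boundary_minimum = boundary)
}
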