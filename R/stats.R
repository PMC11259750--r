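#' Coefficient of variation (percent)
#'
#' 100 x sample SD / mean: used intramuscularly (across fascicles of one
#' muscle) and interindividually (across subjects).
#'
#' @param values numeric vector, n >= 2, non-zero mean.
#' @return CV in percent.
#' @export
cv_pct <- function(values) {
  if (length(values) < 2) stop("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Absolute-agreement intraclass correlation, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC with its
#' F-based 95\% confidence interval. Mean squares are computed from
#' closed-form two-way ANOVA sums of squares (subjects x sessions, one
#' observation per cell):
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the subject, session, and
#' residual mean squares, n the number of subjects and k the number of
#' sessions.
#'
#' @param table data.frame or matrix: one row per subject, one column per
#'   session (k >= 2), no missing values; or a \code{paired_table}.
#' @param conf_level confidence level for the interval.
#' @return An object of class \code{reliability_result}: \code{icc},
#'   \code{ci_low}, \code{ci_high}, \code{mean_abs_diff_pct} (for k = 2),
#'   plus the mean squares.
#' @export
icc_2_1 <- function(table, conf_level = 0.95) {
  y <- as.matrix(if (inherits(table, "paired_table")) table$values else table)
  n <- nrow(y)
  k <- ncol(y)
  if (n < 3) stop("ICC needs at least 3 subjects")
  if (k < 2) stop("ICC needs at least 2 sessions")
  if (anyNA(y)) stop("missing pairs are not allowed")

  grand <- mean(y)
  row_m <- rowMeans(y)
  col_m <- colMeans(y)
  ss_total <- sum((y - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (ss_total <= 0) stop("zero total variance; ICC undefined")

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  # F-based confidence interval for the absolute-agreement single-measure ICC
  alpha <- 1 - conf_level
  if (msc <= 0 && mse <= 0) {
    # perfect agreement: no session or residual variance
    return(structure(list(icc = icc, ci_low = icc, ci_high = icc,
                          mean_abs_diff_pct = 0,
                          ms_rows = msr, ms_cols = msc, ms_error = mse,
                          n = n, k = k),
                     class = "reliability_result"))
  }
  # degrees-of-freedom approximation needs r in [0, 1)
  r <- min(max(icc, 0), 1 - 1e-9)
  a <- (k * r) / (n * (1 - r))
  b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  mad_pct <- if (k == 2) {
    pm <- rowMeans(y)
    if (any(pm == 0)) NA_real_ else mean(100 * abs(y[, 1] - y[, 2]) / pm)
  } else {
    NA_real_
  }
  structure(list(icc = icc, ci_low = min(ci_low, icc), ci_high = max(ci_high, icc),
                 mean_abs_diff_pct = mad_pct,
                 ms_rows = msr, ms_cols = msc, ms_error = mse,
                 n = n, k = k),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f (95%% CI %.3f to %.3f), n = %d, k = %d\n",
              x$icc, x$ci_low, x$ci_high, x$n, x$k))
  if (!is.na(x$mean_abs_diff_pct)) {
    cat(sprintf("  mean absolute difference %.1f%%\n", x$mean_abs_diff_pct))
  }
  invisible(x)
}

#' Mean absolute difference between paired measurements (percent)
#'
#' Mean over subjects of 100 x |m1 - m2| / denominator. The denominator is
#' the pair mean by default (symmetric in column order); the first
#' measurement can be used instead via \code{denominator}.
#'
#' @param m1,m2 numeric vectors of paired measurements, or \code{m1} may be
#'   a two-column table.
#' @param denominator \code{"pair_mean"} (default) or \code{"first"}.
#' @return percentage.
#' @export
mean_abs_diff_pct <- function(m1, m2 = NULL, denominator = c("pair_mean", "first")) {
  denominator <- match.arg(denominator)
  if (is.null(m2)) {
    y <- as.matrix(if (inherits(m1, "paired_table")) m1$values else m1)
    m2 <- y[, 2]
    m1 <- y[, 1]
  }
  if (length(m1) != length(m2)) stop("paired measurements must have equal length")
  den <- if (denominator == "pair_mean") (m1 + m2) / 2 else m1
  if (any(den == 0)) stop("zero denominator in mean absolute difference")
  mean(100 * abs(m1 - m2) / den)
}

#' Unpaired two-sample t-test
#'
#' Two-sided comparison of group means (e.g. male vs female architecture).
#' Welch's unequal-variance form is the default; the pooled-variance form is
#' available via \code{var_equal}. Degenerate input with zero variance in
#' both groups and equal means returns t = 0, p = 1 by convention.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param var_equal use the pooled-variance test.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
unpaired_t <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    return(list(t = if (mean(a) > mean(b)) Inf else -Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Cohort-level architecture report
#'
#' Aggregates per-subject, per-muscle architecture tables into a report of
#' across-subject means, SDs, and interindividual CVs for the six reported
#' parameters, together with in-table cross-checks: PCSA recomputed from the
#' across-subject mean volume and mean fascicle length (the ratio-of-means,
#' deliberately distinct from the reported mean-of-ratios PCSA), the sum of
#' per-subject relative volumes, the subscapularis vs infraspinatus + teres
#' minor PCSA comparison, and male/female comparisons per parameter.
#'
#' @param cohort data.frame with columns \code{subject}, \code{sex}
#'   (\code{"M"}/\code{"F"}), \code{muscle}, \code{volume_cm3},
#'   \code{relative_volume_pct}, \code{pcsa_cm2},
#'   \code{mean_fascicle_len_mm}, \code{mean_pennation_deg},
#'   \code{moment_arm_mm}.
#' @param var_equal passed to \code{\link{unpaired_t}} for sex comparisons.
#' @return An object of class \code{cohort_report}: \code{table} (per-muscle
#'   mean/SD/CV), \code{cross_checks}, \code{sex_comparison}.
#' @export
make_cohort_report <- function(cohort, var_equal = FALSE) {
  needed <- c("subject", "sex", "muscle", "volume_cm3", "relative_volume_pct",
              "pcsa_cm2", "mean_fascicle_len_mm", "mean_pennation_deg",
              "moment_arm_mm")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (length(unique(cohort$subject)) < 2) stop("need at least 2 subjects")
  sets <- tapply(cohort$muscle, cohort$subject,
                 function(m) paste(sort(unique(m)), collapse = "|"))
  if (length(unique(sets)) != 1) {
    offenders <- names(sets)[sets != names(sort(table(sets), decreasing = TRUE))[1]]
    stop("inconsistent muscle sets across subjects: ",
         paste(offenders, collapse = ", "))
  }

  params <- c("volume_cm3", "relative_volume_pct", "pcsa_cm2",
              "mean_fascicle_len_mm", "mean_pennation_deg", "moment_arm_mm")
  muscles <- unique(cohort$muscle)
  tab <- do.call(rbind, lapply(muscles, function(mu) {
    sub <- cohort[cohort$muscle == mu, ]
    row <- data.frame(muscle = mu, n = nrow(sub))
    for (pp in params) {
      row[[paste0(pp, "_mean")]] <- mean(sub[[pp]])
      row[[paste0(pp, "_sd")]] <- stats::sd(sub[[pp]])
      row[[paste0(pp, "_cv_pct")]] <- cv_pct(sub[[pp]])
    }
    row
  }))

  rel_sums <- tapply(cohort$relative_volume_pct, cohort$subject, sum)
  mean_vol <- tab$volume_cm3_mean
  mean_len <- tab$mean_fascicle_len_mm_mean
  pcsa_from_means <- mean_vol / (mean_len / 10)
  cross <- list(
    relative_volume_sums_pct = as.numeric(rel_sums),
    pcsa_from_means_cm2 = stats::setNames(pcsa_from_means, tab$muscle),
    pcsa_mean_of_ratios_cm2 = stats::setNames(tab$pcsa_cm2_mean, tab$muscle)
  )
  if (all(c("subscapularis", "infraspinatus", "teres_minor") %in% muscles)) {
    g <- function(mu) tab$pcsa_cm2_mean[tab$muscle == mu]
    cross$subscapularis_vs_infra_plus_teres_cm2 <-
      c(subscapularis = g("subscapularis"),
        infraspinatus_plus_teres_minor = g("infraspinatus") + g("teres_minor"))
  }

  sex_cmp <- NULL
  if (length(unique(cohort$sex)) == 2) {
    sex_cmp <- do.call(rbind, lapply(muscles, function(mu) {
      sub <- cohort[cohort$muscle == mu, ]
      do.call(rbind, lapply(params, function(pp) {
        tt <- unpaired_t(sub[[pp]][sub$sex == "M"], sub[[pp]][sub$sex == "F"],
                         var_equal = var_equal)
        data.frame(muscle = mu, parameter = pp,
                   male_mean = mean(sub[[pp]][sub$sex == "M"]),
                   female_mean = mean(sub[[pp]][sub$sex == "F"]),
                   t = tt$t, df = tt$df, p = tt$p)
      }))
    }))
  }
  structure(list(table = tab, cross_checks = cross, sex_comparison = sex_cmp),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort architecture report\n")
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    cat(sprintf("  %s (n = %d): volume %.0f +/- %.0f cm^3 (%.0f%%), PCSA %.0f cm^2, length %.1f mm, pennation %.0f deg, moment arm %.1f mm\n",
                r$muscle, r$n, r$volume_cm3_mean, r$volume_cm3_sd,
                r$volume_cm3_cv_pct, r$pcsa_cm2_mean,
                r$mean_fascicle_len_mm_mean, r$mean_pennation_deg_mean,
                r$moment_arm_mm_mean))
  }
  cat(sprintf("  relative volumes sum to %.2f%% (range %.2f-%.2f)\n",
              mean(x$cross_checks$relative_volume_sums_pct),
              min(x$cross_checks$relative_volume_sums_pct),
              max(x$cross_checks$relative_volume_sums_pct)))
  invisible(x)
}

#' Write a cohort report as CSV
#'
#' Table-style columns (volume, relative volume, PCSA, fascicle length,
#' pennation angle, moment arm) with report rounding: volumes and PCSAs to
#' integers, lengths to 0.1 mm, angles to integer degrees.
#'
#' @param report a \code{cohort_report}.
#' @param path output CSV path.
#' @return the formatted data.frame, invisibly.
#' @export
write_cohort_report <- function(report, path) {
  t0 <- report$table
  fmt <- data.frame(
    muscle = t0$muscle,
    n = t0$n,
    volume_cm3 = sprintf("%.0f +/- %.0f (%.0f)", t0$volume_cm3_mean,
                         t0$volume_cm3_sd, t0$volume_cm3_cv_pct),
    relative_volume_pct = sprintf("%.0f +/- %.0f (%.0f)",
                                  t0$relative_volume_pct_mean,
                                  t0$relative_volume_pct_sd,
                                  t0$relative_volume_pct_cv_pct),
    pcsa_cm2 = sprintf("%.0f +/- %.0f (%.0f)", t0$pcsa_cm2_mean,
                       t0$pcsa_cm2_sd, t0$pcsa_cm2_cv_pct),
    fascicle_length_mm = sprintf("%.1f +/- %.1f (%.0f)",
                                 t0$mean_fascicle_len_mm_mean,
                                 t0$mean_fascicle_len_mm_sd,
                                 t0$mean_fascicle_len_mm_cv_pct),
    pennation_deg = sprintf("%.0f +/- %.0f (%.0f)",
                            t0$mean_pennation_deg_mean,
                            t0$mean_pennation_deg_sd,
                            t0$mean_pennation_deg_cv_pct),
    moment_arm_mm = sprintf("%.1f +/- %.1f (%.0f)", t0$moment_arm_mm_mean,
                            t0$moment_arm_mm_sd, t0$moment_arm_mm_cv_pct))
  utils::write.csv(fmt, path, row.names = FALSE)
  invisible(fmt)
}
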