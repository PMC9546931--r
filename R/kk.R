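# (log k', log k) scatter geometry: confidence ellipse, flatness, taxonomy.
# Point coordinates are (log k', log k). Type labels follow the REFER-slope
# signature: V (vertically flattened in the original figures, which carry
# log k' on the vertical axis) means log k is roughly constant and log k'
# spread, driving the forward slope to 0 and the backward slope to -1;
# H is the mirror case (spread in log k; slopes 1 and 0).

as_kk_points <- function(points) {
  if (inherits(points, "residue_table") ||
      (is.data.frame(points) && all(c("k_forward", "k_backward") %in%
                                      names(points)))) {
    points <- cbind(log10(points$k_backward), log10(points$k_forward))
  }
  m <- as.matrix(points)
  if (ncol(m) != 2L || !is.numeric(m) || any(!is.finite(m))) {
    stop_domain("points must be a 2-column finite numeric matrix (log k', log k)")
  }
  colnames(m) <- c("logkb", "logk")
  m
}

#' Confidence ellipse of a bivariate point cloud
#'
#' Eigen-decomposition of the sample covariance matrix (n - 1
#' denominator): semi-axis lengths are `sqrt(lambda_i * q)` with `q` the
#' chi-square quantile with 2 degrees of freedom at the requested coverage
#' (q = 5.991 at 0.95). The chi-square (known-covariance-shape) scaling is
#' used rather than the small-sample F scaling; at typical residue counts
#' the difference is below 10%.
#'
#' @param points 2-column matrix or data.frame of coordinates, here
#'   (log k', log k); a `residue_table` is converted automatically. At
#'   least 3 points; exactly collinear input is allowed and yields `b = 0`.
#' @param level coverage probability, default 0.95.
#' @return object of class `confidence_ellipse`: list with `center`
#'   (length-2), `a` and `b` (long/short semi-axes, log10 units), `angle`
#'   (long-axis orientation vs horizontal, degrees in (-90, 90]), `level`,
#'   and `cov` (the sample covariance).
#' @export
confidence_ellipse <- function(points, level = 0.95) {
  m <- as_kk_points(points)
  if (nrow(m) < 3L) stop_domain("need at least 3 points for an ellipse")
  if (level <= 0 || level >= 1) stop_domain("level must be in (0, 1)")
  S <- stats::cov(m)
  if (sum(diag(S)) == 0) stop_domain("degenerate point cloud: zero variance")
  e <- eigen(S, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  q <- qchisq(level, df = 2)
  v <- e$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  out <- list(center = colMeans(m), a = sqrt(lambda[1] * q),
              b = sqrt(lambda[2] * q), angle = ang, level = level,
              cov = S, n = nrow(m))
  class(out) <- "confidence_ellipse"
  out
}

#' Flatness of a confidence ellipse
#'
#' `f = 1 - b/a` with `a` the long and `b` the short semi-axis. A value
#' near 1 (collinear cloud) indicates high linearity of the residue-based
#' free energy relationship; 0 is an isotropic cloud. Invariant under
#' translation, rotation and uniform scaling of the points.
#'
#' @param ellipse a `confidence_ellipse` object.
#' @return flatness in `[0, 1]`.
#' @export
flatness <- function(ellipse) {
  if (!inherits(ellipse, "confidence_ellipse")) {
    stop_domain("expected a confidence_ellipse object")
  }
  if (ellipse$a <= 0) stop_domain("degenerate ellipse: zero long axis")
  1 - ellipse$b / ellipse$a
}

#' Classify the (log k', log k) scatter of a dataset
#'
#' Taxonomy of scatter geometries:
#' \itemize{
#'   \item `N` -- significant negative correlation; the hallmark of a
#'     genuine residue-based LFER, forcing forward REFER slopes in (0, 1).
#'   \item `P` / `Pprime` -- significant positive correlation, with the
#'     spread of log k' respectively larger / smaller than that of log k;
#'     typically a sign of a violated two-state assumption or measurement
#'     bias, giving uninterpretable REFER slopes.
#'   \item `V` / `H` -- no significant correlation but a flattened cloud:
#'     `V` has log k roughly constant and log k' spread (forward/backward
#'     REFER slopes approach 0 and -1), `H` has log k' roughly constant
#'     and log k spread (slopes approach 1 and 0).
#'   \item `nr` -- no relation: neither correlated nor flattened; any
#'     apparent REFER linearity is then suspect.
#' }
#'
#' @inheritParams confidence_ellipse
#' @param alpha significance level for the Pearson test (default 0.05).
#' @param flatness_threshold minimum flatness for V/H (default 0.6).
#' @param angle_tolerance maximum deviation (degrees) of the long axis
#'   from vertical/horizontal for V/H (default 20).
#' @param level ellipse coverage (default 0.95).
#' @return object of class `kk_class`: list with `pearson_r`, `p_value`,
#'   `ellipse`, `flatness`, `kk_type`, `n`.
#' @export
classify_kk_type <- function(points, alpha = 0.05, flatness_threshold = 0.6,
                             angle_tolerance = 20, level = 0.95) {
  m <- as_kk_points(points)
  if (nrow(m) < 4L) stop_domain("need at least 4 points to classify")
  ell <- confidence_ellipse(m, level)
  f <- flatness(ell)
  ct <- suppressWarnings(cor.test(m[, 1], m[, 2], method = "pearson"))
  r <- unname(ct$estimate)
  p <- ct$p.value
  type <- if (!is.na(p) && p < alpha) {
    if (r < 0) "N" else if (var(m[, 1]) >= var(m[, 2])) "P" else "Pprime"
  } else if (f >= flatness_threshold && abs(ell$angle) <= angle_tolerance) {
    # long axis along log k' (first coordinate): log k roughly constant
    "V"
  } else if (f >= flatness_threshold &&
             90 - abs(ell$angle) <= angle_tolerance) {
    # long axis along log k: log k' roughly constant
    "H"
  } else {
    "nr"
  }
  out <- list(pearson_r = r, p_value = p, ellipse = ell, flatness = f,
              kk_type = type, points = m, n = nrow(m), alpha = alpha,
              flatness_threshold = flatness_threshold,
              angle_tolerance = angle_tolerance)
  class(out) <- "kk_class"
  out
}

#' @export
print.kk_class <- function(x, ...) {
  cat(sprintf(
    "log k vs log k' scatter: type %s (n = %d)\n  r = %.3f (p = %.3g), flatness = %.3f, long-axis angle = %.1f deg\n",
    x$kk_type, x$n, x$pearson_r, x$p_value, x$flatness, x$ellipse$angle))
  invisible(x)
}

#' @export
print.confidence_ellipse <- function(x, ...) {
  cat(sprintf(
    "%.0f%% confidence ellipse: a = %.3f, b = %.3f, angle = %.1f deg, center (%.3f, %.3f)\n",
    100 * x$level, x$a, x$b, x$angle, x$center[1], x$center[2]))
  invisible(x)
}
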