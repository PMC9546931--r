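#' Fit the forward and backward REFER lines
#'
#' Ordinary least squares of `log10 k_forward` (forward, slope
#' `rho_f`) and `log10 k_backward` (backward, slope `rho_b`) on
#' `log10 K` across residues. Because `log K = log k - log k'`, the two
#' slopes obey the algebraic identity `rho_f - rho_b = 1` whenever both
#' lines are fit on the same residues. Each direction is classified
#' independently by [classify_slope()]: a significant correlation with an
#' interpretable slope draws a solid line, a significant correlation with
#' an uninterpretable slope a dashed one, and an insignificant correlation
#' no line.
#'
#' @param records a `residue_table` (see [residue_table()]) or data.frame
#'   with columns `residue_id`, `K`, `k_forward`, `k_backward`.
#' @param min_n minimum number of residues (default 4; with fewer points a
#'   line is always drawn near-perfectly and classification is
#'   meaningless).
#' @param alpha two-sided significance level for the Pearson correlation
#'   test (default 0.05).
#' @param band_f interpretable forward-slope band (default `c(0, 1)`,
#'   transition state between the two ground states).
#' @param band_b interpretable backward-slope band (default `c(-1, 0)`).
#' @param weighted if `TRUE` and `err_logk`/`err_logkb` are available,
#'   weight the regressions by inverse squared log-scale errors; default
#'   `FALSE` (unweighted lines). Weighting breaks the exact slope
#'   identity.
#' @return an object of class `refer_fit`: list with `slope_f`,
#'   `intercept_f`, `r2_f`, `p_forward`, `line_class_f`, the backward
#'   counterparts, `n`, and `reason` (non-`NA` when no fit was possible,
#'   e.g. zero variance in `log K`).
#' @examples
#' rec <- residue_table(paste0("R", 1:6),
#'                      k_forward = 10^(0.5 * (1:6) / 3 + 1),
#'                      k_backward = 10^(0.5 * (1:6) / 3 + 1 - (1:6) / 3))
#' fit_refer(rec)
#' @export
fit_refer <- function(records, min_n = 4, alpha = 0.05,
                      band_f = c(0, 1), band_b = c(-1, 0),
                      weighted = FALSE) {
  lc <- log_columns(records)
  n <- nrow(lc)
  if (n < min_n) {
    stop_domain("need at least %d residues, got %d", min_n, n)
  }
  out <- list(slope_f = NA_real_, intercept_f = NA_real_, r2_f = NA_real_,
              p_forward = NA_real_, line_class_f = NA_character_,
              slope_b = NA_real_, intercept_b = NA_real_, r2_b = NA_real_,
              p_backward = NA_real_, line_class_b = NA_character_,
              n = n, alpha = alpha, reason = NA_character_,
              data = lc)
  class(out) <- "refer_fit"
  if (sd(lc$logK) < 1e-12 * max(1, abs(mean(lc$logK)))) {
    out$reason <- "degenerate abscissa: zero variance in log K"
    return(out)
  }
  w <- NULL
  if (weighted) {
    ek <- records$err_logk
    ekb <- records$err_logkb
    if (all(is.finite(ek)) && all(ek > 0) &&
        all(is.finite(ekb)) && all(ekb > 0)) {
      w <- list(f = 1 / ek^2, b = 1 / ekb^2)
    }
  }
  one_dir <- function(y, weights, band) {
    fit <- if (is.null(weights)) lm(y ~ lc$logK) else
      lm(y ~ lc$logK, weights = weights)
    ct <- cor.test(lc$logK, y, method = "pearson")
    slope <- unname(coef(fit)[2])
    # suppressed warning: summary.lm flags exactly collinear input, which
    # is a legitimate (noise-free) case here
    list(slope = slope, intercept = unname(coef(fit)[1]),
         r2 = suppressWarnings(summary(fit)$r.squared), p = ct$p.value,
         class = classify_slope(slope, ct$p.value, alpha, band))
  }
  f <- one_dir(lc$logk, w$f, band_f)
  b <- one_dir(lc$logkb, w$b, band_b)
  out$slope_f <- f$slope; out$intercept_f <- f$intercept
  out$r2_f <- f$r2; out$p_forward <- f$p; out$line_class_f <- f$class
  out$slope_b <- b$slope; out$intercept_b <- b$intercept
  out$r2_b <- b$r2; out$p_backward <- b$p; out$line_class_b <- b$class
  out
}

#' Classify a REFER line as solid, dashed, or not drawn
#'
#' A least-squares line is drawn solid when its correlation is significant
#' and the slope falls in the interpretable band (forward `[0, 1]`,
#' backward `[-1, 0]`: slope as transition-state similarity to a ground
#' state), dashed when significant but outside the band, and not at all
#' when the correlation is insignificant.
#'
#' @param slope fitted slope (dimensionless).
#' @param p_value two-sided correlation-test p-value.
#' @param alpha significance level (default 0.05).
#' @param band interpretable-slope interval, default `c(0, 1)`.
#' @return one of `"solid"`, `"dashed"`, `"none"`.
#' @export
classify_slope <- function(slope, p_value, alpha = 0.05, band = c(0, 1)) {
  if (is.na(p_value) || p_value >= alpha) return("none")
  if (slope >= band[1] && slope <= band[2]) "solid" else "dashed"
}

#' Tabulate a collection of REFER fits
#'
#' @param fits a named list of `refer_fit` objects (names become the
#'   `dataset` column).
#' @return data.frame with one row per fit: slopes, intercepts, R^2,
#'   p-values and line classes; slope cells of lines that are not drawn
#'   (`"none"`) carry `NA` in the `drawn_slope_*` columns.
#' @export
refer_summary <- function(fits) {
  if (length(fits) == 0L) stop_domain("no fits supplied")
  if (inherits(fits, "refer_fit")) fits <- list(fit = fits)
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("dataset", seq_along(fits))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(
      dataset = nm[i], n = f$n,
      slope_f = f$slope_f, intercept_f = f$intercept_f, r2_f = f$r2_f,
      p_forward = f$p_forward, line_class_f = f$line_class_f,
      slope_b = f$slope_b, intercept_b = f$intercept_b, r2_b = f$r2_b,
      p_backward = f$p_backward, line_class_b = f$line_class_b,
      drawn_slope_f = if (identical(f$line_class_f, "none")) NA_real_ else
        f$slope_f,
      drawn_slope_b = if (identical(f$line_class_b, "none")) NA_real_ else
        f$slope_b,
      reason = f$reason,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @export
print.refer_fit <- function(x, ...) {
  cat("REFER fit (n =", x$n, "residues)\n")
  if (!is.na(x$reason)) {
    cat("  no fit:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  forward : slope %.4f, intercept %.4f, R2 %.3f, p %.3g [%s]\n",
              x$slope_f, x$intercept_f, x$r2_f, x$p_forward,
              x$line_class_f))
  cat(sprintf("  backward: slope %.4f, intercept %.4f, R2 %.3f, p %.3g [%s]\n",
              x$slope_b, x$intercept_b, x$r2_b, x$p_backward,
              x$line_class_b))
  invisible(x)
}
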