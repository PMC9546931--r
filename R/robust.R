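#' Robust line fit by IRLS with Tukey bisquare weights
#'
#' Iteratively reweighted least squares for a straight line, following the
#' convention of MATLAB's `fitlm(..., 'RobustOpts')`: Tukey bisquare
#' weights with tuning constant 4.685, residual scale estimated each
#' iteration as `median(|r|)/0.6745`, and (optionally) residuals inflated
#' by the leverage factor `1/sqrt(1 - h_ii)` before weighting. The start
#' is ordinary least squares, so the procedure is deterministic. Points on
#' the line keep weight 1; gross outliers (beyond `tuning` scales) get
#' weight 0. Forcing all weights to 1 reproduces OLS exactly.
#'
#' @param x abscissa values (here `log10 K`).
#' @param y ordinate values (here `log10 k` or `log10 k'`).
#' @param ids optional point labels (residue ids); defaults to
#'   `names(y)` or an index.
#' @param tuning bisquare tuning constant (default 4.685, the conventional
#'   95%-Gaussian-efficiency value).
#' @param leverage adjust residuals for leverage as the reference
#'   implementation does (default `TRUE`).
#' @param max_iter,tol iteration cap (100) and coefficient-change
#'   convergence tolerance (1e-8).
#' @return object of class `robust_fit_result`: `slope`, `intercept`,
#'   `weights` (named, in `[0, 1]`), `scale` (robust residual scale, log10
#'   units), `n_iter`, `converged`, plus the data (`x`, `y`, `ids`) and
#'   final `residuals`.
#' @export
robust_fit <- function(x, y, ids = NULL, tuning = 4.685, leverage = TRUE,
                       max_iter = 100, tol = 1e-8) {
  n <- length(x)
  if (n != length(y)) stop_domain("x and y lengths differ")
  if (n < 5L) stop_domain("need at least 5 points for a robust fit")
  if (var(x) == 0) stop_domain("zero variance in abscissa")
  if (is.null(ids)) ids <- if (!is.null(names(y))) names(y) else
    as.character(seq_len(n))

  # leverage from the fixed design [1, x]
  h <- 1 / n + (x - mean(x))^2 / sum((x - mean(x))^2)
  adj <- if (leverage) 1 / sqrt(pmax(1 - h, .Machine$double.eps)) else
    rep(1, n)

  wls <- function(w) {
    sw <- sum(w)
    xb <- sum(w * x) / sw
    yb <- sum(w * y) / sw
    b <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
    c(intercept = yb - b * xb, slope = b)
  }

  w <- rep(1, n)
  beta <- wls(w)
  n_iter <- 0L
  converged <- FALSE
  s <- NA_real_
  for (it in seq_len(max_iter)) {
    n_iter <- it
    r <- y - (beta[1] + beta[2] * x)
    radj <- r * adj
    s <- median(abs(radj)) / 0.6745
    if (s <= .Machine$double.eps * max(abs(y), 1)) {
      # (near-)perfect fit: all points are inliers
      w <- rep(1, n)
      converged <- TRUE
      s <- 0
      break
    }
    u <- radj / (tuning * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 3L) break
    beta_new <- wls(w)
    if (max(abs(beta_new - beta)) < tol * max(1, max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  r <- y - (beta[1] + beta[2] * x)
  out <- list(slope = unname(beta[2]), intercept = unname(beta[1]),
              weights = setNames(w, ids), scale = s, n_iter = n_iter,
              converged = converged, residuals = setNames(r, ids),
              x = x, y = y, ids = ids, tuning = tuning,
              leverage = leverage)
  class(out) <- "robust_fit_result"
  out
}

#' @export
print.robust_fit_result <- function(x, ...) {
  cat(sprintf(
    "robust line: slope %.4f, intercept %.4f, scale %.4g (%d iter%s)\n",
    x$slope, x$intercept, x$scale, x$n_iter,
    if (x$converged) ", converged" else ", NOT converged"))
  low <- x$ids[x$weights < 0.5]
  if (length(low)) cat("  weights < 0.5:", paste(low, collapse = ", "), "\n")
  invisible(x)
}

#' Flag residues with small robust-regression weights
#'
#' A residue is flagged as an outlier when its bisquare weight falls below
#' `weight_threshold` in the forward (`log k` vs `log K`) fit OR in the
#' backward (`log k'` vs `log K`) fit.
#'
#' @param forward,backward `robust_fit_result` objects over the same
#'   residues.
#' @param weight_threshold flagging threshold (default 0.5, the midpoint
#'   of the weight range).
#' @return character vector of flagged residue ids (possibly empty).
#' @export
flag_outliers <- function(forward, backward, weight_threshold = 0.5) {
  if (!setequal(forward$ids, backward$ids)) {
    stop_domain("forward and backward fits cover different residue sets")
  }
  wf <- forward$weights[forward$ids]
  wb <- backward$weights[forward$ids]
  forward$ids[wf < weight_threshold | wb < weight_threshold]
}

#' Refit the REFER lines without the flagged outliers
#'
#' Redraws the ordinary least-squares lines on the retained residues and
#' quantifies how far the outliers sit from them: `offset_f`/`offset_b`
#' are the mean signed vertical displacements (log10 units) of the
#' outliers from the redrawn forward/backward lines, and
#' `rate_factor_f`/`rate_factor_b` the implied multiplicative rate changes
#' `10^offset`. A parallel second line (slope fixed to the redrawn line's)
#' is also fit through the outliers, operationalizing the observation that
#' collectively moving residues form second lines almost parallel to the
#' first.
#'
#' @param records a `residue_table`.
#' @param outlier_ids character vector of residue ids to set aside.
#' @param ... passed to [fit_refer()] for the refit.
#' @return object of class `outlier_report`: `outlier_ids`,
#'   `retained_ids`, `refit` (a `refer_fit`), `offset_f`, `offset_b`,
#'   `rate_factor_f`, `rate_factor_b`, `parallel_intercept_f`,
#'   `parallel_intercept_b`.
#' @export
refit_without_outliers <- function(records, outlier_ids, ...) {
  outlier_ids <- as.character(outlier_ids)
  unknown <- setdiff(outlier_ids, records$residue_id)
  if (length(unknown)) {
    stop_domain("unknown outlier residue(s): %s",
                paste(unknown, collapse = ", "))
  }
  keep <- !(records$residue_id %in% outlier_ids)
  if (sum(keep) < 4L) stop_domain("fewer than 4 retained residues")
  refit <- fit_refer(records[keep, , drop = FALSE], ...)
  out <- list(outlier_ids = outlier_ids,
              retained_ids = records$residue_id[keep],
              refit = refit,
              offset_f = NA_real_, offset_b = NA_real_,
              rate_factor_f = NA_real_, rate_factor_b = NA_real_,
              parallel_intercept_f = NA_real_,
              parallel_intercept_b = NA_real_)
  class(out) <- "outlier_report"
  if (length(outlier_ids)) {
    lo <- log_columns(records[!keep, , drop = FALSE])
    out$offset_f <- mean(lo$logk - (refit$intercept_f +
                                      refit$slope_f * lo$logK))
    out$offset_b <- mean(lo$logkb - (refit$intercept_b +
                                       refit$slope_b * lo$logK))
    out$rate_factor_f <- 10^out$offset_f
    out$rate_factor_b <- 10^out$offset_b
    # parallel second line: same slope, intercept through the outliers
    out$parallel_intercept_f <- refit$intercept_f + out$offset_f
    out$parallel_intercept_b <- refit$intercept_b + out$offset_b
  }
  out
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier report: %d flagged, %d retained\n",
              length(x$outlier_ids), length(x$retained_ids)))
  if (length(x$outlier_ids)) {
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
    cat(sprintf(
      "  offsets (log10): forward %+.3f (x%.2f), backward %+.3f (x%.2f)\n",
      x$offset_f, x$rate_factor_f, x$offset_b, x$rate_factor_b))
  }
  print(x$refit)
  invisible(x)
}

#' Full robust outlier pipeline on a residue table
#'
#' Runs [robust_fit()] in both REFER directions, flags residues by
#' [flag_outliers()], and refits without them via
#' [refit_without_outliers()].
#'
#' @param records a `residue_table`.
#' @param weight_threshold passed to [flag_outliers()].
#' @param tuning,leverage passed to [robust_fit()].
#' @param ... passed to [refit_without_outliers()].
#' @return list with `forward`, `backward` (the robust fits),
#'   `outlier_ids`, and `report` (an `outlier_report`).
#' @export
detect_outliers <- function(records, weight_threshold = 0.5,
                            tuning = 4.685, leverage = TRUE, ...) {
  lc <- log_columns(records)
  fwd <- robust_fit(lc$logK, lc$logk, ids = lc$residue_id,
                    tuning = tuning, leverage = leverage)
  bwd <- robust_fit(lc$logK, lc$logkb, ids = lc$residue_id,
                    tuning = tuning, leverage = leverage)
  ids <- flag_outliers(fwd, bwd, weight_threshold)
  report <- refit_without_outliers(records, ids, ...)
  list(forward = fwd, backward = bwd, outlier_ids = ids, report = report)
}
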