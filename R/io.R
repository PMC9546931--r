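#' Read a residue exchange table from CSV
#'
#' Canonical interchange format: UTF-8 CSV with header row and columns
#' `residue_id` plus `K` and/or both of `k_forward`, `k_backward`
#' (optional `err_logK`, `err_logk`, `err_logkb`, `source`). When only
#' rates are present, `K` is derived as `k/k'`; when all three are present
#' each row is checked against the triad identity (strict mode rejects
#' violations, lenient mode warns).
#'
#' @param path CSV file path.
#' @param strict triad-consistency handling (default `TRUE`).
#' @param tol triad tolerance in log10 units (default 0.05).
#' @param name dataset name (default the file name).
#' @return a `residue_table` with attributes `name` and `metadata`.
#' @export
read_residue_table <- function(path, strict = TRUE, tol = 0.05,
                               name = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"residue_id" %in% names(df)) {
    stop_domain("missing required column: residue_id")
  }
  has_rates <- all(c("k_forward", "k_backward") %in% names(df))
  has_K <- "K" %in% names(df)
  if (!has_rates && !has_K) {
    stop_domain("missing required columns: K and/or (k_forward, k_backward)")
  }
  if (!has_rates) {
    stop_domain("missing required columns: k_forward, k_backward")
  }
  for (col in intersect(c("K", "k_forward", "k_backward"), names(df))) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad)) {
      stop_domain("non-positive or missing %s at row(s) %s", col,
                  paste(bad, collapse = ", "))
    }
  }
  opt <- function(col) if (col %in% names(df)) df[[col]] else NA_real_
  tab <- residue_table(df$residue_id,
                       K = if (has_K) df$K else NULL,
                       k_forward = df$k_forward,
                       k_backward = df$k_backward,
                       err_logK = opt("err_logK"),
                       err_logk = opt("err_logk"),
                       err_logkb = opt("err_logkb"),
                       source = if ("source" %in% names(df)) df$source else
                         NA_character_,
                       tol = tol, strict = strict)
  attr(tab, "name") <- if (is.null(name)) basename(path) else name
  tab
}

#' Write a residue table (or any analysis report) to CSV
#'
#' Numeric columns are rounded to a repeatable number of significant
#' digits so that re-runs produce diff-stable files.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param digits significant digits for numeric columns (default 10).
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(x, path, digits = 10) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.numeric(x[[j]])) x[[j]] <- signif(x[[j]], digits)
  }
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read hydrogen-exchange observations from CSV
#'
#' Expects columns `residue_id`, `pH`, `pulse_duration_s`, `occupancy`
#' (optional `err_occupancy`).
#'
#' @param path CSV file path.
#' @return data.frame of observations, validated.
#' @export
read_hx_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("residue_id", "pH", "pulse_duration_s", "occupancy")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_domain("missing required column(s): %s", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(df$occupancy) | df$occupancy < 0 | df$occupancy > 1)) {
    stop_domain("occupancy must lie in [0, 1]")
  }
  check_positive(df$pulse_duration_s, "pulse_duration_s")
  df
}

#' Run the full REFER analysis on a residue table
#'
#' One-stop pipeline: REFER regression ([fit_refer()]), scatter
#' classification ([classify_kk_type()]), and robust outlier analysis
#' ([detect_outliers()]).
#'
#' @param records a `residue_table` (or path to one, read with
#'   [read_residue_table()]).
#' @param alpha significance level shared by the regression and the
#'   scatter classification.
#' @param weight_threshold robust-weight flagging threshold.
#' @param flatness_threshold,angle_tolerance scatter-classification
#'   thresholds.
#' @return list of class `refer_analysis` with elements `fit`
#'   (`refer_fit`), `kk` (`kk_class`), `outliers` (from
#'   [detect_outliers()]), and `summary` (one-row data.frame combining
#'   the headline numbers).
#' @export
analyze_residue_table <- function(records, alpha = 0.05,
                                  weight_threshold = 0.5,
                                  flatness_threshold = 0.6,
                                  angle_tolerance = 20) {
  if (is.character(records)) records <- read_residue_table(records)
  fit <- fit_refer(records, alpha = alpha)
  kk <- classify_kk_type(records, alpha = alpha,
                         flatness_threshold = flatness_threshold,
                         angle_tolerance = angle_tolerance)
  out_an <- detect_outliers(records, weight_threshold = weight_threshold)
  summ <- refer_summary(list(full = fit))
  summ$kk_type <- kk$kk_type
  summ$flatness <- kk$flatness
  summ$pearson_r_kk <- kk$pearson_r
  summ$n_outliers <- length(out_an$outlier_ids)
  summ$outlier_ids <- paste(out_an$outlier_ids, collapse = ";")
  res <- list(fit = fit, kk = kk, outliers = out_an, summary = summ)
  class(res) <- "refer_analysis"
  res
}

#' @export
print.refer_analysis <- function(x, ...) {
  print(x$fit)
  print(x$kk)
  cat(sprintf("outliers flagged: %d%s\n", length(x$outliers$outlier_ids),
              if (length(x$outliers$outlier_ids))
                paste0(" (", paste(x$outliers$outlier_ids, collapse = ", "),
                       ")") else ""))
  invisible(x)
}
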