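#' Equilibrium constant from forward and backward rates
#'
#' For a two-state exchange `closed <-> open` with forward rate `k_forward`
#' and backward rate `k_backward`, the equilibrium constant is
#' `K = k_forward / k_backward`, so that
#' `log10 K = log10 k_forward - log10 k_backward`.
#'
#' @param k_forward forward rate constant(s), s^-1, strictly positive.
#' @param k_backward backward rate constant(s), s^-1, strictly positive.
#' @return the equilibrium constant `k_forward / k_backward` (dimensionless).
#' @examples
#' equilibrium_from_rates(10, 2) # 5
#' @export
equilibrium_from_rates <- function(k_forward, k_backward) {
  check_positive(k_forward, "k_forward")
  check_positive(k_backward, "k_backward")
  k_forward / k_backward
}

#' Assemble and validate a residue exchange table
#'
#' The atomic datum of the analysis is one residue's triad
#' (K, k_forward, k_backward) with optional one-standard-error values on
#' the log10 scale. When all three constants are supplied, each row must
#' satisfy the triadic identity `K = k_forward / k_backward` to within
#' `tol` log10 units; when `K` is absent it is derived from the rates.
#'
#' @param residue_id character residue labels (e.g. `"A134"`), unique.
#' @param K equilibrium constants, dimensionless, > 0; may be `NULL` if
#'   both rates are given.
#' @param k_forward,k_backward forward/backward rate constants, s^-1, > 0.
#' @param err_logK,err_logk,err_logkb optional one-standard-error values on
#'   the log10 scale, >= 0.
#' @param source optional free-text provenance tag(s).
#' @param tol triad consistency tolerance in log10 units (default 0.05).
#' @param strict if `TRUE` (default) a triad violation is an error;
#'   otherwise a warning.
#' @return a `data.frame` of class `residue_table` with columns
#'   `residue_id`, `K`, `k_forward`, `k_backward`, `err_logK`, `err_logk`,
#'   `err_logkb`, `source`.
#' @export
residue_table <- function(residue_id, K = NULL, k_forward, k_backward,
                          err_logK = NA_real_, err_logk = NA_real_,
                          err_logkb = NA_real_, source = NA_character_,
                          tol = 0.05, strict = TRUE) {
  residue_id <- as.character(residue_id)
  n <- length(residue_id)
  if (n == 0L) stop_domain("empty residue table")
  if (anyDuplicated(residue_id)) {
    stop_domain("duplicate residue_id: %s",
                paste(unique(residue_id[duplicated(residue_id)]),
                      collapse = ", "))
  }
  check_positive(k_forward, "k_forward")
  check_positive(k_backward, "k_backward")
  if (is.null(K)) {
    K <- equilibrium_from_rates(k_forward, k_backward)
  } else {
    check_positive(K, "K")
    dev <- abs(log10(K) - (log10(k_forward) - log10(k_backward)))
    bad <- which(dev > tol)
    if (length(bad)) {
      msg <- sprintf(
        "triad K = k/k' violated beyond %.3g log10 units for residue(s): %s",
        tol, paste(residue_id[bad], collapse = ", "))
      if (strict) stop_domain("%s", msg) else warning(msg, call. = FALSE)
    }
  }
  for (e in list(err_logK, err_logk, err_logkb)) {
    if (any(!is.na(e) & e < 0)) stop_domain("log-scale errors must be >= 0")
  }
  out <- data.frame(
    residue_id = residue_id,
    K = rep_len(K, n),
    k_forward = rep_len(k_forward, n),
    k_backward = rep_len(k_backward, n),
    err_logK = rep_len(err_logK, n),
    err_logk = rep_len(err_logk, n),
    err_logkb = rep_len(err_logkb, n),
    source = rep_len(as.character(source), n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("residue_table", "data.frame")
  out
}

# log10-transformed columns used by every downstream fit
log_columns <- function(records) {
  data.frame(
    residue_id = records$residue_id,
    logK = log10(records$K),
    logk = log10(records$k_forward),
    logkb = log10(records$k_backward),
    stringsAsFactors = FALSE
  )
}
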