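#' Generate a synthetic residue ensemble obeying a linear free energy
#' relationship
#'
#' Inverse model of the residue-based LFER: residue-wise `log10 K` values
#' are drawn from a spread distribution, `log10 k = rho_true * log10 K +
#' intercept_true + noise` (plus an optional collective offset on an
#' outlier block, mimicking e.g. a transiently translocated helix), and
#' `log10 k' = log10 k - log10 K`, so every record satisfies the triad
#' `K = k/k'` exactly. Noise is applied to `log k` only and `k'` derived,
#' keeping the three quantities mutually constrained just as measured
#' triads are.
#'
#' @param n_residues number of residues (>= 4).
#' @param rho_true generating REFER slope.
#' @param intercept_true generating intercept, log10 units.
#' @param logK_center,logK_spread location and half-width (uniform) or
#'   standard deviation (normal) of the `log10 K` distribution; a spread
#'   of 1 gives the decade-wide dispersions typical of residue-resolved
#'   datasets.
#' @param noise_sigma standard deviation of additive Gaussian noise on
#'   `log10 k`, log10 units (default 0.05).
#' @param logK_dist `"uniform"` (default) or `"normal"`.
#' @param outlier_block optional integer vector of residue indices that
#'   receive a collective offset.
#' @param outlier_delta log10 offset added to `log10 k` of the outlier
#'   block (default 0).
#' @param seed integer seed; the generator is deterministic given the
#'   seed and never touches the caller's RNG state.
#' @return a `residue_table` with ids `"R001"`, `"R002"`, ...
#' @export
generate_lfer_ensemble <- function(n_residues = 40, rho_true = 0.5,
                                   intercept_true = 0, logK_center = 0,
                                   logK_spread = 1, noise_sigma = 0.05,
                                   logK_dist = c("uniform", "normal"),
                                   outlier_block = NULL, outlier_delta = 0,
                                   seed = NULL) {
  if (n_residues < 4L) stop_domain("'n_residues' must be >= 4")
  if (noise_sigma < 0) stop_domain("'noise_sigma' must be >= 0")
  if (logK_spread <= 0) stop_domain("'logK_spread' must be > 0")
  logK_dist <- match.arg(logK_dist)
  if (!is.null(outlier_block)) {
    outlier_block <- as.integer(outlier_block)
    if (any(outlier_block < 1L | outlier_block > n_residues)) {
      stop_domain("'outlier_block' must index residues 1..%d", n_residues)
    }
  }
  with_seed(seed, {
    logK <- switch(logK_dist,
      uniform = runif(n_residues, logK_center - logK_spread,
                      logK_center + logK_spread),
      normal = rnorm(n_residues, logK_center, logK_spread))
    logk <- rho_true * logK + intercept_true +
      rnorm(n_residues, 0, noise_sigma)
    if (length(outlier_block)) {
      logk[outlier_block] <- logk[outlier_block] + outlier_delta
    }
    logkb <- logk - logK
    residue_table(sprintf("R%03d", seq_len(n_residues)),
                  K = 10^logK, k_forward = 10^logk, k_backward = 10^logkb,
                  source = "synthetic-lfer")
  })
}

#' Simulate the fake-linearity construction
#'
#' Gedankenexperiment on the risk of artificial REFER linearity: for a
#' hypothetical protein all residues share single true k and k' values,
#' and the per-residue scatter is pure measurement error. Each replicate
#' draws `n_residues` forward rates uniformly from `k_range` and backward
#' rates from `kb_range` (defaults 3-7 and 8-12, ranges on the rates
#' themselves) and sets `K = k/k'`. Because `log K = log k - log k'`, the
#' REFER plot of such unrelated numbers shows deceptively good linearity
#' even though the (log k', log k) scatter is type nr; averaging over
#' replicates concentrates the points around the common mean while narrow
#' residual linearity remains.
#'
#' @param n_residues residues per replicate (default 15).
#' @param k_range,kb_range uniform ranges for k and k' (defaults
#'   `c(3, 7)` and `c(8, 12)`).
#' @param n_reps number of replicate draws per residue (default 30).
#' @param log_uniform draw log-uniformly instead (sensitivity option,
#'   default `FALSE`).
#' @param seed integer seed.
#' @return object of class `fake_linearity_sim`: `reps` (list of
#'   `residue_table`s), `fits` (per-rep [fit_refer()] results), `kk`
#'   (per-rep [classify_kk_type()] results), `aggregate` (per-residue
#'   mean, SD and standard error of the mean of k and k' across
#'   replicates), and `aggregate_records` (a `residue_table` built from
#'   the per-residue means).
#' @export
simulate_fake_linearity <- function(n_residues = 15, k_range = c(3, 7),
                                    kb_range = c(8, 12), n_reps = 30,
                                    log_uniform = FALSE, seed = NULL) {
  if (n_residues < 4L) stop_domain("'n_residues' must be >= 4")
  if (n_reps < 1L) stop_domain("'n_reps' must be >= 1")
  for (rg in list(k_range, kb_range)) {
    if (length(rg) != 2L || rg[2] < rg[1] || rg[1] <= 0) {
      stop_domain("ranges must be positive and ordered")
    }
  }
  if (diff(k_range) == 0 && diff(kb_range) == 0) {
    stop_domain("zero-width ranges make all points identical: degenerate regression")
  }
  draw <- function(n, rg) {
    if (log_uniform) 10^runif(n, log10(rg[1]), log10(rg[2])) else
      runif(n, rg[1], rg[2])
  }
  ids <- sprintf("R%02d", seq_len(n_residues))
  with_seed(seed, {
    reps <- lapply(seq_len(n_reps), function(i) {
      residue_table(ids, k_forward = draw(n_residues, k_range),
                    k_backward = draw(n_residues, kb_range),
                    source = sprintf("fake-rep%d", i))
    })
    fits <- lapply(reps, fit_refer)
    kk <- lapply(reps, classify_kk_type)
    kmat <- vapply(reps, function(r) r$k_forward, numeric(n_residues))
    kbmat <- vapply(reps, function(r) r$k_backward, numeric(n_residues))
    row_sd <- function(m) apply(m, 1, sd)
    agg <- data.frame(
      residue_id = ids,
      mean_k = rowMeans(kmat), sd_k = row_sd(kmat),
      se_k = row_sd(kmat) / sqrt(n_reps),
      mean_kb = rowMeans(kbmat), sd_kb = row_sd(kbmat),
      se_kb = row_sd(kbmat) / sqrt(n_reps),
      stringsAsFactors = FALSE
    )
    if (n_reps == 1L) agg$sd_k <- agg$se_k <- agg$sd_kb <- agg$se_kb <- NA_real_
    out <- list(reps = reps, fits = fits, kk = kk, aggregate = agg,
                aggregate_records = residue_table(
                  ids, k_forward = agg$mean_k, k_backward = agg$mean_kb,
                  source = "fake-aggregate"),
                n_reps = n_reps, k_range = k_range, kb_range = kb_range)
    class(out) <- "fake_linearity_sim"
    out
  })
}

#' @export
print.fake_linearity_sim <- function(x, ...) {
  r2 <- vapply(x$fits, function(f) f$r2_f, numeric(1))
  types <- vapply(x$kk, function(k) k$kk_type, character(1))
  cat(sprintf(
    "fake-linearity simulation: %d residues x %d replicates\n",
    nrow(x$aggregate), x$n_reps))
  cat(sprintf("  forward R2 per replicate: median %.3f (range %.3f-%.3f)\n",
              median(r2), min(r2), max(r2)))
  cat("  scatter types:", paste(sprintf("%s (%d)", names(table(types)),
                                        table(types)), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate hydrogen-exchange occupancies across a pH ladder
#'
#' Forward model of the two-process exchange scheme: for each residue with
#' true `(k_op, k_cl)` and each (pH, pulse) combination, the observed rate
#' is the steady-state rate of [hx_observed_rate()] with
#' `k_int = intrinsic_rate(pH, k_ref, pH_ref)` and the occupancy is
#' `exp(-k_obs * t)` plus Gaussian noise clipped to `[0, 1]`.
#'
#' @param truth data.frame with columns `residue_id`, `k_op`, `k_cl`.
#' @param pH numeric vector of labeling pH values (default 6:11).
#' @param pulse_s pulse durations in seconds (default `c(0.05, 0.2)`).
#' @param k_ref,pH_ref,kint_table intrinsic-rate model as in
#'   [fit_hx_rates()].
#' @param noise_sigma occupancy noise standard deviation (default 0).
#' @param seed integer seed.
#' @return data.frame with columns `residue_id`, `pH`, `pulse_duration_s`,
#'   `occupancy`, `err_occupancy`.
#' @export
generate_hx_dataset <- function(truth, pH = 6:11, pulse_s = c(0.05, 0.2),
                                k_ref = 1, pH_ref = 7, kint_table = NULL,
                                noise_sigma = 0, seed = NULL) {
  if (!all(c("residue_id", "k_op", "k_cl") %in% names(truth))) {
    stop_domain("truth needs columns residue_id, k_op, k_cl")
  }
  check_positive(truth$k_op, "k_op")
  check_positive(truth$k_cl, "k_cl")
  if (noise_sigma < 0) stop_domain("'noise_sigma' must be >= 0")
  grid <- expand.grid(i = seq_len(nrow(truth)), pH = pH,
                      pulse_duration_s = pulse_s,
                      KEEP.OUT.ATTRS = FALSE)
  with_seed(seed, {
    kref_i <- rep(k_ref, nrow(truth))
    if (!is.null(kint_table)) {
      m <- match(truth$residue_id, kint_table$residue_id)
      kref_i[!is.na(m)] <- kint_table$k_ref[m[!is.na(m)]]
    }
    kint <- intrinsic_rate(grid$pH, 1, pH_ref) * kref_i[grid$i]
    kobs <- hx_observed_rate(truth$k_op[grid$i], truth$k_cl[grid$i],
                             kint)$k_obs
    occ <- occupancy_after_pulse(kobs, grid$pulse_duration_s)
    if (noise_sigma > 0) {
      occ <- pmin(pmax(occ + rnorm(length(occ), 0, noise_sigma), 0), 1)
    }
    data.frame(residue_id = truth$residue_id[grid$i], pH = grid$pH,
               pulse_duration_s = grid$pulse_duration_s, occupancy = occ,
               err_occupancy = noise_sigma, stringsAsFactors = FALSE)
  })
}
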