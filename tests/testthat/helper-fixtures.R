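# Fixtures built in code. All logs base 10.

# residues exactly on log k = slope * log K + intercept, with log K spread
line_records <- function(n = 10, slope = 0.5, intercept = 1,
                         logK = seq(-1, 1, length.out = n)) {
  logk <- slope * logK + intercept
  residue_table(sprintf("R%02d", seq_len(n)),
                k_forward = 10^logk, k_backward = 10^(logk - logK))
}

# records from explicit log-scale coordinates (triad enforced)
records_from_logs <- function(logK, logk, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("R%02d", seq_along(logK))
  residue_table(ids, k_forward = 10^logk, k_backward = 10^(logk - logK))
}

# independent OLS slope, no lm(): direct moment formula
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
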