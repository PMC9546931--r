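test_that("a perfect line gets weight 1 everywhere and exact coefficients", {
  x <- seq(-1, 1, length.out = 20)
  y <- 0.4 * x + 2
  rf <- robust_fit(x, y)
  expect_equal(unname(rf$weights), rep(1, 20))
  expect_equal(rf$slope, 0.4, tolerance = 1e-12)
  expect_equal(rf$intercept, 2, tolerance = 1e-12)
  expect_true(rf$converged)
  expect_error(robust_fit(x[1:4], y[1:4]), "at least 5")
  expect_error(robust_fit(rep(1, 6), rnorm(6)), "zero variance")
})

test_that("on clean Gaussian data the robust slope tracks OLS", {
  # representative seeded dataset: slope within one OLS standard error,
  # no point substantially downweighted
  set.seed(14)
  x <- runif(20, -1, 1)
  y <- 0.5 * x + rnorm(20, sd = 0.1)
  rf <- robust_fit(x, y)
  b_ols <- ols_slope(x, y)
  se_ols <- sqrt(sum((y - mean(y) - b_ols * (x - mean(x)))^2) / 18 /
                   sum((x - mean(x))^2))
  expect_lt(abs(rf$slope - b_ols), se_ols)
  expect_gt(min(rf$weights), 0.5)
  # distributional behavior over replicates: the bulk of the weights stays
  # high and the slope never strays far from OLS (the MAD scale at n = 20
  # can downweight an extreme clean point, so the minimum is not bounded)
  for (i in 1:20) {
    x <- runif(20, -1, 1)
    y <- 0.5 * x + rnorm(20, sd = 0.1)
    rf <- robust_fit(x, y)
    b_ols <- ols_slope(x, y)
    se_ols <- sqrt(sum((y - mean(y) - b_ols * (x - mean(x)))^2) / 18 /
                     sum((x - mean(x))^2))
    expect_lt(abs(rf$slope - b_ols), 2 * se_ols)
    expect_gt(mean(rf$weights), 0.8)
  }
})

test_that("a single gross outlier is zero-weighted and does not move the line", {
  x <- seq(0, 1, length.out = 20)
  y <- 2 * x + 1
  set.seed(3)
  y <- y + rnorm(20, sd = 0.02)
  clean_slope <- ols_slope(x[-20], y[-20])
  y[20] <- y[20] + 10 * 0.02 / 0.6745 * 4.685 # ~10 robust scales past cutoff
  rf <- robust_fit(x, y)
  # bisquare weight vanishes beyond the tuning constant: u > 1 -> w = 0
  expect_lt(rf$weights[20], 0.05)
  expect_equal(rf$slope, clean_slope, tolerance = 0.01)
})

test_that("IRLS agrees with an independent M-estimator on contaminated data", {
  skip_if_not_installed("MASS")
  set.seed(19)
  x <- runif(40, -1, 1)
  y <- 0.5 * x + rnorm(40, sd = 0.05)
  y[1:5] <- y[1:5] + 1.5
  rf <- robust_fit(x, y, leverage = FALSE)
  mf <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
                  maxit = 100)
  expect_equal(rf$slope, unname(coef(mf)[2]), tolerance = 0.02)
  expect_equal(rf$intercept, unname(coef(mf)[1]), tolerance = 0.02)
})

test_that("outlier flagging applies the OR rule over both directions", {
  mk <- function(w) {
    structure(list(weights = setNames(w, c("A", "B", "C")),
                   ids = c("A", "B", "C")), class = "robust_fit_result")
  }
  f <- mk(c(1.0, 0.9, 0.05)); b <- mk(c(1.0, 0.9, 0.9))
  expect_equal(flag_outliers(f, b, 0.5), "C")
  expect_equal(flag_outliers(mk(c(1, 1, 1)), mk(c(0.9, 0.8, 0.7)), 0.5),
               character(0))
  # flagged in backward only
  expect_equal(flag_outliers(mk(c(1, 1, 1)), mk(c(1, 0.2, 1)), 0.5), "B")
  other <- structure(list(weights = setNames(rep(1, 3), c("A", "B", "X")),
                          ids = c("A", "B", "X")),
                     class = "robust_fit_result")
  expect_error(flag_outliers(f, other), "different residue sets")
})

test_that("flagging is monotone in the threshold", {
  ens <- generate_lfer_ensemble(n_residues = 30, noise_sigma = 0.15,
                                outlier_block = 1:4, outlier_delta = 0.8,
                                seed = 99)
  lc <- rblfer:::log_columns(ens)
  fwd <- robust_fit(lc$logK, lc$logk, ids = lc$residue_id)
  bwd <- robust_fit(lc$logK, lc$logkb, ids = lc$residue_id)
  prev <- character(0)
  for (thr in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    cur <- flag_outliers(fwd, bwd, thr)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("a collectively offset residue block is recovered and its offset measured", {
  ens <- generate_lfer_ensemble(n_residues = 40, rho_true = 0.4,
                                noise_sigma = 0.05, outlier_block = 10:16,
                                outlier_delta = 1.0, seed = 7)
  res <- detect_outliers(ens)
  expect_setequal(res$outlier_ids, sprintf("R%03d", 10:16))
  rep <- res$report
  expect_equal(rep$offset_f, 1.0, tolerance = 0.1)
  expect_equal(rep$rate_factor_f, 10, tolerance = 0.3)
  # second line parallel by construction: same slope, intercept raised
  expect_equal(rep$parallel_intercept_f - rep$refit$intercept_f,
               rep$offset_f)
  # refit line close to the generating slope
  expect_equal(rep$refit$slope_f, 0.4, tolerance = 0.1)
})

test_that("with no injected outliers nothing is flagged and the refit is the full fit", {
  ens <- generate_lfer_ensemble(n_residues = 30, noise_sigma = 0.05,
                                seed = 3)
  res <- detect_outliers(ens)
  expect_length(res$outlier_ids, 0)
  full <- fit_refer(ens)
  expect_equal(res$report$refit$slope_f, full$slope_f)
  expect_true(is.na(res$report$offset_f))
})

test_that("robust slope resists up to 20% gross contamination", {
  set.seed(101)
  for (i in 1:10) {
    ens <- generate_lfer_ensemble(n_residues = 40, rho_true = 0.5,
                                  noise_sigma = 0.05,
                                  outlier_block = 1:8, outlier_delta = 2,
                                  seed = 300 + i)
    clean <- ens[-(1:8), ]
    lc <- rblfer:::log_columns(ens)
    rf <- robust_fit(lc$logK, lc$logk)
    lcc <- rblfer:::log_columns(clean)
    b_clean <- ols_slope(lcc$logK, lcc$logk)
    expect_lt(abs(rf$slope - b_clean) / abs(b_clean), 0.05)
  }
})

test_that("offset sensitivity sweep reports recovery without asserting sub-threshold Deltas", {
  deltas <- c(0.3, 0.6, 1.0)
  rates <- vapply(deltas, function(d) {
    hits <- vapply(1:10, function(i) {
      ens <- generate_lfer_ensemble(n_residues = 40, rho_true = 0.4,
                                    noise_sigma = 0.05,
                                    outlier_block = 10:16,
                                    outlier_delta = d, seed = 5000 + i)
      res <- detect_outliers(ens)
      mean(sprintf("R%03d", 10:16) %in% res$outlier_ids)
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  # detection rate is monotone in the offset and saturates for large Delta
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[length(rates)], 1)
})
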