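test_that("confidence ellipse respects symmetry, collinearity and scaling", {
  # 4-point diamond: isotropic, flatness 0
  pts <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  e <- confidence_ellipse(pts)
  expect_equal(e$a, e$b)
  expect_equal(unname(e$center), c(0, 0))
  expect_equal(flatness(e), 0)
  # collinear cloud: rank-1 covariance, b = 0, flatness 1
  x <- seq(0, 1, length.out = 8)
  ec <- confidence_ellipse(cbind(x, 2 * x + 1))
  expect_equal(ec$b, 0, tolerance = 1e-6)
  expect_equal(flatness(ec), 1, tolerance = 1e-6)
  # semi-axes follow sqrt(lambda * chi2 quantile)
  set.seed(8)
  m <- cbind(rnorm(50, sd = 2), rnorm(50))
  e2 <- confidence_ellipse(m, level = 0.95)
  lam <- eigen(cov(m))$values
  expect_equal(e2$a, sqrt(lam[1] * qchisq(0.95, 2)))
  expect_equal(e2$b, sqrt(lam[2] * qchisq(0.95, 2)))
  expect_error(confidence_ellipse(pts[1:2, ]), "at least 3")
  expect_error(confidence_ellipse(matrix(1, 5, 2)), "degenerate")
})

test_that("flatness is invariant under translation, rotation and scaling", {
  set.seed(21)
  m <- cbind(rnorm(40, sd = 3), rnorm(40))
  f0 <- flatness(confidence_ellipse(m))
  for (i in 1:20) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    s <- 10^runif(1, -2, 2)
    shift <- runif(2, -5, 5)
    m2 <- sweep(s * (m %*% R), 2, shift, "+")
    e2 <- confidence_ellipse(m2)
    expect_equal(flatness(e2), f0, tolerance = 1e-8)
    # uniform scaling scales both axes equally
    e3 <- confidence_ellipse(s * m)
    expect_equal(e3$a / e3$b,
                 confidence_ellipse(m)$a / confidence_ellipse(m)$b,
                 tolerance = 1e-8)
  }
})

test_that("rotating the points rotates the ellipse long axis", {
  set.seed(33)
  m <- cbind(rnorm(60, sd = 3), rnorm(60, sd = 0.5))
  e0 <- confidence_ellipse(m)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) # R(theta)
  e1 <- confidence_ellipse(t(R %*% t(m)))
  d <- (e1$angle - e0$angle - 30) %% 180
  expect_lt(min(d, 180 - d), 1e-6)
})

test_that("scatter taxonomy identifies N, V, H, P, P' and nr", {
  set.seed(42)
  # constructed negative correlation -> N
  logkb <- rnorm(30, sd = 0.5)
  kN <- classify_kk_type(cbind(logkb, -logkb + rnorm(30, sd = 0.05)))
  expect_equal(kN$kk_type, "N")
  expect_lt(kN$pearson_r, 0)
  expect_lt(kN$p_value, 0.05)
  # log k nearly constant, log k' spread -> V (forward REFER slope -> 0)
  kV <- classify_kk_type(cbind(runif(30, -1, 1), rnorm(30, sd = 0.02)))
  expect_equal(kV$kk_type, "V")
  expect_gt(kV$flatness, 0.6)
  # log k' nearly constant, log k spread -> H
  kH <- classify_kk_type(cbind(rnorm(30, sd = 0.02), runif(30, -1, 1)))
  expect_equal(kH$kk_type, "H")
  # positive correlation, log k' spread dominant -> P
  z <- rnorm(40, sd = 1)
  kP <- classify_kk_type(cbind(2 * z + rnorm(40, sd = 0.1),
                               z + rnorm(40, sd = 0.1)))
  expect_equal(kP$kk_type, "P")
  # positive correlation, log k spread dominant -> P'
  kPp <- classify_kk_type(cbind(z + rnorm(40, sd = 0.1),
                                2 * z + rnorm(40, sd = 0.1)))
  expect_equal(kPp$kk_type, "Pprime")
  # isotropic independent cloud -> nr
  knr <- classify_kk_type(cbind(rnorm(30), rnorm(30)))
  expect_equal(knr$kk_type, "nr")
  expect_error(classify_kk_type(cbind(1:3, 1:3)), "at least 4")
})

test_that("classification is deterministic and type relations hold on REFER slopes", {
  pts <- cbind(runif(25, -1, 1), rnorm(25, sd = 0.02))
  expect_identical(classify_kk_type(pts)$kk_type,
                   classify_kk_type(pts)$kk_type)
  # V-type data: forward slope near 0, backward near -1
  set.seed(77)
  logkb <- runif(30, 0, 2)
  logk <- rnorm(30, 1, 0.02)
  recV <- records_from_logs(logK = logk - logkb, logk = logk)
  expect_equal(classify_kk_type(recV)$kk_type, "V")
  fitV <- fit_refer(recV)
  expect_lt(abs(fitV$slope_f - 0), 0.1)
  expect_lt(abs(fitV$slope_b - (-1)), 0.1)
  # H-type data: forward slope near 1, backward near 0
  logk2 <- runif(30, 0, 2)
  logkb2 <- rnorm(30, 1, 0.02)
  recH <- records_from_logs(logK = logk2 - logkb2, logk = logk2)
  expect_equal(classify_kk_type(recH)$kk_type, "H")
  fitH <- fit_refer(recH)
  expect_lt(abs(fitH$slope_f - 1), 0.1)
  expect_lt(abs(fitH$slope_b - 0), 0.1)
})

test_that("type N ensembles give interpretable REFER slopes (cross-module)", {
  set.seed(55)
  for (i in 1:50) {
    ens <- generate_lfer_ensemble(n_residues = 25,
                                  rho_true = runif(1, 0.2, 0.8),
                                  noise_sigma = 0.05, seed = 7000 + i)
    kk <- classify_kk_type(ens)
    expect_equal(kk$kk_type, "N")
    fit <- fit_refer(ens)
    expect_gt(fit$slope_f, 0); expect_lt(fit$slope_f, 1)
    expect_gt(fit$slope_b, -1); expect_lt(fit$slope_b, 0)
  }
})
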