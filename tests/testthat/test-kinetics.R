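test_that("forward model matches closed-form boxcar and impulse responses", {
  tt <- seq(0, 30, by = 0.5)
  # constant AIF c0 from t = 0: TAC -> A c0 (1 - exp(-lam t)) / lam
  aif <- aif_curve(tt, rep(2, length(tt)))
  for (lam in c(0.2, 0.5, 2)) {
    tac <- forward_model(aif, A = 0.1, lam = lam, times = tt)
    exact <- 0.1 * 2 * (1 - exp(-lam * tt)) / lam
    expect_lt(max(abs(tac[-1] - exact[-1]) / exact[-1]), 0.005)
  }
  # unit-area impulse -> A exp(-lam (t - t_spike))
  g <- seq(0, 10, by = 0.025)
  v <- numeric(length(g)); v[g == 0.5] <- 1 / 0.025
  imp <- aif_curve(g, v)
  out_t <- seq(1, 8, by = 0.5)
  tac <- forward_model(imp, A = 0.3, lam = 0.7, times = out_t)
  expect_equal(tac, 0.3 * exp(-0.7 * (out_t - 0.5)), tolerance = 1e-6)
})

test_that("forward model is linear in A and in AIF amplitude, zero at A = 0", {
  aif <- test_aif()
  tt <- test_times()
  expect_equal(forward_model(aif, 0, 0.5, tt), rep(0, length(tt)))
  m1 <- forward_model(aif, 0.1, 0.5, tt)
  expect_equal(forward_model(aif, 0.3, 0.5, tt), 3 * m1, tolerance = 1e-12)
  aif3 <- aif_curve(aif$times, 3 * aif$values)
  expect_equal(forward_model(aif3, 0.1, 0.5, tt), 3 * m1, tolerance = 1e-12)
  expect_error(forward_model(aif, 0.1, -1, tt), "lam")
  expect_error(forward_model(aif, 0.1, 0.5, c(1, 1, 2)), "increasing")
})

test_that("noiseless TAC fit recovers the generating parameters", {
  aif <- test_aif()
  tt <- test_times()
  tac <- forward_model(aif, A = 0.1, lam = 0.5, times = tt)
  f <- fit_voxel(tac, aif, tt)
  expect_true(f$converged)
  expect_equal(f$A, 0.1, tolerance = 1e-4)
  expect_equal(f$lam, 0.5, tolerance = 1e-4)
  expect_lt(f$residual_sd, 1e-6)
})

test_that("fit optimum agrees with an exhaustive grid search", {
  aif <- test_aif()
  tt <- test_times()
  set.seed(4)
  tac <- forward_model(aif, 0.1, 0.5, tt) + rnorm(length(tt), 0, 0.07)
  f <- fit_voxel(tac, aif, tt)
  # 200 x 200 brute-force sweep over the full bounds
  opts <- fit_options()
  A_grid <- seq(opts$lower[["A"]], opts$upper[["A"]], length.out = 200)
  l_grid <- seq(opts$lower[["lam"]], opts$upper[["lam"]], length.out = 200)
  sse <- matrix(NA_real_, 200, 200)
  for (j in seq_along(l_grid)) {
    m <- forward_model(aif, 1, l_grid[j], tt)
    sse[, j] <- vapply(A_grid, function(a) sum((tac - a * m)^2), 0)
  }
  best <- arrayInd(which.min(sse), dim(sse))
  expect_lte(abs(f$A - A_grid[best[1]]), diff(A_grid[1:2]))
  expect_lte(abs(f$lam - l_grid[best[2]]), diff(l_grid[1:2]))
  expect_lte(f$objective_value, min(sse) + 1e-10)
})

test_that("parameter errors follow the f_tol-scaled inverse Hessian", {
  # identity Hessian: f = 0.5 ||x - x*||^2
  f_id <- function(x) 0.5 * sum((x - c(1, 2))^2)
  expect_equal(as.numeric(fit_errors(f_id, c(1, 2), f_tol = 1)), c(1, 1),
               tolerance = 1e-6)
  # diagonal quadratic oracle: err_i = sqrt(f_tol / (2 a_i))
  a <- 3; b <- 0.25
  f_q <- function(x) a * (x[1] - 0.4)^2 + b * (x[2] - 1.1)^2
  e <- fit_errors(f_q, c(0.4, 1.1), f_tol = 1e-6)
  expect_equal(as.numeric(e), c(sqrt(1e-6 / (2 * a)), sqrt(1e-6 / (2 * b))),
               tolerance = 1e-4)
  # square-root law: scaling f_tol by 4 doubles both errors
  e4 <- fit_errors(f_q, c(0.4, 1.1), f_tol = 4e-6)
  expect_equal(as.numeric(e4), 2 * as.numeric(e), tolerance = 1e-10)
  # non-positive-definite Hessian -> NaN with warning
  expect_warning(bad <- fit_errors(function(x) -sum(x^2), c(0, 0)),
                 "positive definite")
  expect_true(all(is.nan(bad)))
  expect_false(attr(bad, "spd"))
  # optimum on a bound is flagged
  eb <- fit_errors(f_q, c(0.4, 1.1), lower = c(0.4, 0), upper = c(5, 5))
  expect_true(attr(eb, "boundary"))
})

test_that("TAC SNR estimates peak over noise and flags zero residuals", {
  aif <- test_aif()
  tt <- test_times()
  m <- forward_model(aif, 0.1, 0.5, tt)
  sigma <- max(m) / 20
  set.seed(11)
  snrs <- replicate(150, {
    f <- fit_voxel(m + rnorm(length(tt), 0, sigma), aif, tt)
    tac_snr(f)
  })
  expect_equal(median(snrs), max(m) / sigma, tolerance = 0.15)
  # halving the noise doubles the median SNR
  snrs2 <- replicate(150, {
    f <- fit_voxel(m + rnorm(length(tt), 0, sigma / 2), aif, tt)
    tac_snr(f)
  })
  expect_equal(median(snrs2) / median(snrs), 2, tolerance = 0.15)
  # exact fit: zero residual SD reported as flagged infinity
  perfect <- fit_voxel(m, aif, tt)
  perfect$residual_sd <- 0
  expect_warning(s <- tac_snr(structure(perfect, class = "compartment_fit")),
                 NA)
  expect_identical(as.numeric(s), Inf)
  expect_true(attr(s, "zero_residual"))
})

test_that("lambda recovery scatter at spectral noise matches the CRLB", {
  # Monte-Carlo calibration run in the highly-affected region:
  # empirical sd must match sigma^2 (J'J)^-1 from the model Jacobian, and
  # the within-5% coverage its normal-theory prediction
  aif <- test_aif()
  tt <- test_times()
  A <- 0.2 / 2.73; lam <- 1 / 2.73
  sigma <- 8 / 112.02
  m0 <- forward_model(aif, A, lam, tt)
  h <- 1e-6
  J <- cbind((forward_model(aif, A + h, lam, tt) - m0) / h,
             (forward_model(aif, A, lam + h, tt) - m0) / h)
  crlb_sd <- sqrt(diag(sigma^2 * solve(crossprod(J))))
  set.seed(31)
  lams <- replicate(400, fit_voxel(m0 + rnorm(length(tt), 0, sigma),
                                   aif, tt)$lam)
  expect_equal(mean(lams), lam, tolerance = 0.02)
  expect_equal(sd(lams), crlb_sd[2], tolerance = 0.15)
  coverage <- mean(abs(lams - lam) / lam < 0.05)
  predicted <- 2 * pnorm(0.05 * lam / crlb_sd[2]) - 1
  expect_equal(coverage, predicted, tolerance = 0.12)
})

test_that("flat TACs yield a converged low-signal fit at the lower bound", {
  aif <- test_aif()
  tt <- test_times()
  # the degenerate objective (flat in lambda at A = 0) also makes the error
  # Hessian singular, which is reported by a warning
  expect_warning(f <- fit_voxel(rep(0, length(tt)), aif, tt),
                 "positive definite")
  expect_true(f$converged)
  expect_equal(f$A, 0)
  expect_true("low-signal" %in% f$flags)
  expect_error(fit_voxel(c(1, NA, 3, 4), aif, tt))
  expect_error(fit_voxel(1:3, aif, c(0, 1, 2)), "4 time points")
})

test_that("volume fitting is mask-aware, deterministic and order-invariant", {
  cfg <- small_config(seed = 13)
  sim <- simulate_series(cfg, "spectral", seed = 13)
  aif <- measure_aif(sim$series, sim$labels)
  mask <- array(FALSE, dim = cfg$dims)
  idx <- which(unclass(sim$labels) == "highly")[1:2]
  mask[idx] <- TRUE
  fits <- fit_volume(sim$series, aif, mask = mask)
  expect_equal(fits$n_fitted, 2L)
  expect_equal(sum(is.finite(fits$A)), 2L)
  # identical TACs give identical fits: duplicate one voxel's TAC
  mat <- matrix(sim$series$data, nrow = cfg$n_timepoints)
  mat[, idx[2]] <- mat[, idx[1]]
  series2 <- time_series_volume(array(mat, dim = dim(sim$series$data)),
                                sim$series$timestamps, sim$series$modality)
  fits2 <- fit_volume(series2, aif, mask = mask)
  expect_identical(fits2$A[idx[1]], fits2$A[idx[2]])
  expect_identical(fits2$err_lam[idx[1]], fits2$err_lam[idx[2]])
  # rerunning the original fit reproduces it exactly
  fits3 <- fit_volume(sim$series, aif, mask = mask)
  expect_identical(fits$A, fits3$A)
  expect_warning(empty <- fit_volume(sim$series, aif,
                                     mask = array(FALSE, dim = cfg$dims)),
                 "empty mask")
  expect_equal(empty$n_fitted, 0L)
})

test_that("error estimates shrink with noise and favour the spectral modality", {
  aif <- test_aif()
  tt <- test_times()
  m0 <- forward_model(aif, 0.1, 0.5, tt)
  med_err <- sapply(c(0.2, 0.1, 0.05), function(sig) {
    set.seed(round(1000 * sig))
    errs <- replicate(60, {
      f <- fit_voxel(m0 + rnorm(length(tt), 0, sig), aif, tt)
      c(f$err_A, f$err_lam)
    })
    apply(errs, 1, median, na.rm = TRUE)
  })
  expect_true(all(diff(med_err[1, ]) < 0))   # err_A decreases with sigma
  expect_true(all(diff(med_err[2, ]) < 0))   # err_lam decreases with sigma
})

test_that("spectral fits carry smaller parameter errors than conventional", {
  cfg <- phantom_config(dims = c(1, 18, 18), seed = 17)
  meds <- lapply(c("spectral", "conventional"), function(mod) {
    sim <- simulate_series(cfg, mod, seed = 17)
    aif <- measure_aif(sim$series, sim$labels)
    fits <- suppressWarnings(
      fit_volume(sim$series, aif, mask = myocardium_mask(sim$labels)))
    c(A = median(fits$err_A, na.rm = TRUE),
      lam = median(fits$err_lam, na.rm = TRUE))
  })
  expect_lt(meds[[1]]["A"], meds[[2]]["A"])
  expect_lt(meds[[1]]["lam"], meds[[2]]["lam"])
})
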