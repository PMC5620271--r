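test_that("forward model limits and direct evaluation", {
  b <- c(0, 10, 50, 200, 1000)
  # mono-exponential limit at f = 0
  expect_equal(ivim_forward(b, 1e-3, 0, 0.1, 100), 100 * exp(-b * 1e-3))
  # normalization at b = 0
  expect_equal(ivim_forward(0, 2e-3, 0.3, 0.05, 123), 123)
  # direct scalar evaluation; perfusion term is ~1e-43 at b = 1000
  s <- ivim_forward(1000, 0.7e-3, 0.13, 98.7e-3, 1)
  expect_equal(s, 0.87 * exp(-0.7) + 0.13 * exp(-1000 * (0.7e-3 + 98.7e-3)))
  expect_equal(s, 0.87 * exp(-0.7), tolerance = 1e-12)
  expect_error(ivim_forward(-5, 1e-3, 0.1, 0.1), "non-negative")
})

test_that("forward signal is strictly decreasing in b for valid params", {
  set.seed(42)
  b <- c(0, 10, 20, 30, 40, 60, 100, 120, 160, 200, 300, 500, 1000)
  for (i in 1:50) {
    s <- ivim_forward(b, runif(1, 1e-4, 3e-3), runif(1, 0.01, 0.99),
                      runif(1, 0.01, 0.5), runif(1, 10, 1000))
    expect_true(all(diff(s) < 0))
  }
})

test_that("high-b log-linear stage recovers D", {
  b <- c(0, 10, 20, 30, 40, 60, 100, 120, 160, 200, 300, 500, 1000)
  # exact on pure mono-exponential data
  fit <- fit_high_b_mono(exp(-b * 1.0e-3), b)
  expect_equal(fit$D, 1.0e-3, tolerance = 1e-12)
  # constant signal has zero slope
  expect_equal(fit_high_b_mono(rep(3, 13), b)$D, 0)
  # bi-exponential with high-stage group means: perfusion term negligible
  # above b = 200, so D-hat lands within 0.5% of truth
  s <- ivim_forward(b, 0.700e-3, 0.130, 98.686e-3, 1000)
  expect_equal(fit_high_b_mono(s, b)$D, 0.700e-3, tolerance = 5e-3)
  # threshold is strict: b = 200 itself is excluded
  expect_error(fit_high_b_mono(s[b <= 300], b[b <= 300], 200),
               "at least 2")
  # non-positive signal at an included b invalidates the voxel
  s2 <- s; s2[13] <- 0
  expect_false(fit_high_b_mono(s2, b)$valid)
})

test_that("perfusion stage inverts noiseless signals to <= 0.1%", {
  b <- c(0, 10, 20, 30, 40, 60, 100, 120, 160, 200, 300, 500, 1000)
  s <- ivim_forward(b, 0.8e-3, 0.157, 109.9e-3, 1000)
  hb <- fit_high_b_mono(s, b)
  fit <- fit_perfusion(s, b, hb$D, hb$log_intercept)
  expect_true(fit$converged)
  expect_equal(fit$f, 0.157, tolerance = 1e-3)
  expect_equal(fit$Dstar, 109.9e-3, tolerance = 1e-3)
  # f = 0 reduces to mono-exponential; estimate pinned at the boundary
  s0 <- ivim_forward(b, 0.8e-3, 0, 0.1, 1000)
  fit0 <- fit_perfusion(s0, b, 0.8e-3)
  expect_lte(fit0$f, 1e-4)
})

test_that("perfusion fit matches a dense grid-search oracle", {
  b <- c(0, 10, 20, 30, 40, 60, 100, 120, 160, 200, 300, 500, 1000)
  set.seed(42)
  f_grid <- seq(0.005, 0.5, length.out = 200)
  ds_grid <- seq(0.005, 0.3, length.out = 200)
  for (i in 1:10) {
    truth <- c(D = runif(1, 0.5e-3, 1.2e-3), f = runif(1, 0.05, 0.35),
               Dstar = runif(1, 0.03, 0.25))
    s <- ivim_forward(b, truth["D"], truth["f"], truth["Dstar"], 1000)
    fit <- fit_perfusion(s, b, truth[["D"]])
    # brute force over (f, D*); S0 profiled out analytically per cell
    best <- c(NA, NA); best_rss <- Inf
    for (fv in f_grid) {
      m <- outer(ds_grid, b, function(d, bb)
        (1 - fv) * exp(-bb * truth["D"]) + fv * exp(-bb * (truth["D"] + d)))
      s0_hat <- (m %*% s) / rowSums(m^2)
      rss <- sum(s^2) - 2 * s0_hat * (m %*% s) + s0_hat^2 * rowSums(m^2)
      j <- which.min(rss)
      if (rss[j] < best_rss) { best_rss <- rss[j]; best <- c(fv, ds_grid[j]) }
    }
    expect_lt(abs(fit$f - best[1]), diff(f_grid[1:2]) * 1.5)
    expect_lt(abs(fit$Dstar - best[2]), diff(ds_grid[1:2]) * 1.5)
  }
})

test_that("SNR mask implements the threshold definition", {
  s0 <- array(c(3, 10, 4.9, 5), c(2, 2, 1))
  expect_equal(as.logical(snr_valid_mask(s0, 1, 5)), c(FALSE, TRUE, FALSE, TRUE))
  expect_true(all(snr_valid_mask(s0, 1, 0)))
  expect_error(snr_valid_mask(s0, 0), "noise_sigma")
})

test_that("background-only data is removed by the SNR filter", {
  # P(mean of 3 Rayleigh(sigma) draws >= 5 sigma) by Monte Carlo
  sigma <- 10
  set.seed(42)
  p_pass <- mean(replicate(10,
    mean(rowMeans(matrix(sqrt(rnorm(3e4, 0, sigma)^2 + rnorm(3e4, 0, sigma)^2),
                         ncol = 3)) >= 5 * sigma)))
  ph <- generate_phantom(shape = c(10, 10, 5), cv = 0, roi_frac = 2, seed = 1)
  ph$S0_map[] <- 1e-9
  dwi <- simulate_dwi(ph, noise_sigma = sigma, seed = 7)
  frac_valid <- mean(snr_valid_mask(dwi, sigma, 5))
  expect_lte(frac_valid, p_pass + 0.01)
})

test_that("voxel-wise map fitting: homogeneous noiseless phantom is exact", {
  ph <- generate_phantom(shape = c(5, 5, 2), cv = 0, roi_frac = 2, seed = 1)
  dwi <- simulate_dwi(ph, noise_sigma = 0)
  maps <- fit_ivim_map(dwi, ph$roi_mask)
  expect_true(all(maps$valid_mask[ph$roi_mask]))
  expect_equal(maps$D_map[ph$roi_mask],
               ph$D_map[ph$roi_mask], tolerance = 1e-6)
  expect_equal(maps$f_map[ph$roi_mask],
               ph$f_map[ph$roi_mask], tolerance = 1e-6)
  expect_equal(maps$Dstar_map[ph$roi_mask],
               ph$Dstar_map[ph$roi_mask], tolerance = 1e-6)
  expect_error(fit_ivim_map(dwi, array(FALSE, dim(ph$roi_mask))), "empty")
})

test_that("segmented fit equals the joint full-model fit when noiseless", {
  b <- dwi_scheme()$b_values
  s <- ivim_forward(b, 0.9e-3, 0.2, 0.08, 500)
  hb <- fit_high_b_mono(s, b)
  seg <- fit_perfusion(s, b, hb$D, hb$log_intercept)
  joint <- fit_perfusion(s, b, hb$D, hb$log_intercept, refine_D = TRUE)
  expect_equal(seg$f, joint$f, tolerance = 1e-4)
  expect_equal(seg$Dstar, joint$Dstar, tolerance = 1e-4)
  expect_equal(joint$D, 0.9e-3, tolerance = 1e-5)
})

test_that("D estimate is consistent as noise vanishes, and D* degrades faster", {
  ph <- generate_phantom(shape = c(8, 8, 4), cv = 0, roi_frac = 2, seed = 3)
  bias_D <- c(); rmse_D <- NA; rmse_Ds <- NA
  for (sigma in c(20, 5, 1)) {
    dwi <- simulate_dwi(ph, noise_sigma = sigma, seed = 11)
    maps <- fit_ivim_map(dwi, ph$roi_mask, noise_sigma = sigma)
    m <- maps$valid_mask
    rel_D <- (maps$D_map[m] - ph$D_map[m]) / ph$D_map[m]
    bias_D <- c(bias_D, abs(mean(rel_D)))
    if (sigma == 20) {
      rel_Ds <- (maps$Dstar_map[m] - ph$Dstar_map[m]) / ph$Dstar_map[m]
      rmse_D <- sqrt(mean(rel_D^2))
      rmse_Ds <- sqrt(mean(rel_Ds^2))
    }
  }
  expect_true(all(diff(bias_D) < 0))      # bias shrinks along the sigma ladder
  expect_gt(rmse_Ds, rmse_D)              # pseudodiffusion is the fragile one
})
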