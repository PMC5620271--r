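test_that("spoiled-gradient-echo signal equation", {
  # direct closed-form evaluation
  a <- 15 * pi / 180
  E1 <- exp(-4.8 / 1000)
  expect_equal(spgr_signal(1000, 1000, 4.8, 15),
               1000 * sin(a) * (1 - E1) / (1 - E1 * cos(a)))
  # saturation limit: T1 -> Inf kills the signal
  expect_lt(spgr_signal(1000, 1e9 * 4.8, 4.8, 15), 1e-3 * 1000)
  # full relaxation: TR >> T1 gives M0 sin(a)
  expect_equal(spgr_signal(1000, 10, 1e5, 15), 1000 * sin(a), tolerance = 1e-9)
  expect_error(spgr_signal(1000, -5, 4.8, 15), "T1")
})

test_that("two-point VFA inversion is exact on synthetic signals", {
  for (t1 in c(800, 1000, 1400)) {
    s5 <- spgr_signal(500, t1, 4.8, 5)
    s15 <- spgr_signal(500, t1, 4.8, 15)
    fit <- vfa_t1(s5, s15, 4.8, 5, 15)
    expect_true(fit$valid)
    expect_equal(fit$T10, t1, tolerance = 1e-6)
    expect_equal(fit$M0, 500, tolerance = 1e-6)
  }
  # a dynamic/pre-contrast signal ratio beyond sin(15)/sin(5) exceeds the
  # T1 -> 0 limit of the two-point equations: no physical T1 exists
  bad <- vfa_t1(40, 130, 4.8, 5, 15)
  expect_false(bad$valid)
  expect_true(is.na(bad$T10))
})

test_that("signal-to-concentration conversion", {
  sc <- dce_scheme()
  t1fit <- list(T10 = 1000, M0 = 800, valid = TRUE)
  base <- spgr_signal(800, 1000, sc$TR, sc$flip_dyn)
  # constant series at baseline maps to zero concentration
  conv0 <- signal_to_concentration(rep(base, 65), t1fit, sc$TR,
                                   sc$flip_dyn, sc$r1)
  expect_true(conv0$valid)
  expect_equal(conv0$ct, rep(0, 65), tolerance = 1e-10)
  # known concentration round trip
  ct_true <- c(rep(0, 7), seq(0, 1.2, length.out = 58))
  T1t <- 1000 / (1000 / 1000 + sc$r1 * ct_true)
  dyn <- spgr_signal(800, T1t, sc$TR, sc$flip_dyn)
  conv <- signal_to_concentration(dyn, t1fit, sc$TR, sc$flip_dyn, sc$r1)
  expect_equal(conv$ct, ct_true, tolerance = 5e-3)
  # doubling the relaxivity halves the recovered concentration
  conv2 <- signal_to_concentration(dyn, t1fit, sc$TR, sc$flip_dyn, 2 * sc$r1)
  expect_equal(conv2$ct, ct_true / 2, tolerance = 5e-3)
})

test_that("extended-Tofts forward model against closed forms", {
  times <- seq(0, 600, by = 5)
  # Ktrans = 0: pure plasma term
  cp <- pmax(sin(times / 60), 0)
  a0 <- aif(times, cp)
  expect_equal(extended_tofts_forward(0, 0.5, 0.07, a0), 0.07 * cp)
  # boxcar Cp of height 1 on [0, T]: Ct = (Ktrans/kep)(1 - exp(-kep t)), vp = 0
  cp_box <- as.numeric(times <= 300)
  ab <- aif(times, cp_box)
  Kt <- 0.6; ve <- 0.4; kep_s <- (Kt / ve) / 60
  ct <- extended_tofts_forward(Kt, ve, 0, ab)
  idx <- times <= 300 & times > 0
  closed <- (Kt / 60) / kep_s * (1 - exp(-kep_s * times[idx]))
  expect_equal(ct[idx], closed, tolerance = 1e-3)
  # mono-exponential AIF: Cp = exp(-a t) convolved with exp(-kep t)
  a_rate <- 1 / 120
  ae <- aif(times, exp(-a_rate * times))
  ct_e <- extended_tofts_forward(Kt, ve, 0, ae)
  closed_e <- (Kt / 60) / (a_rate - kep_s) *
    (exp(-kep_s * times) - exp(-a_rate * times))
  expect_equal(ct_e, closed_e, tolerance = 1e-3)
  # null model
  expect_equal(extended_tofts_forward(0, 0.5, 0, a0), rep(0, length(times)))
  # causality: Ct is zero while Cp has been zero
  sc <- dce_scheme()
  ap <- population_aif(sc)
  ct_p <- extended_tofts_forward(0.3, 0.3, 0.05, ap)
  expect_true(all(ct_p[seq_len(sc$injection_index - 1)] == 0))
  expect_error(aif(c(0, 10, 5), c(0, 1, 1)), "increasing")
})

test_that("noiseless Tofts inversion recovers the generative triple", {
  sc <- dce_scheme()
  ap <- population_aif(sc)
  # low-stage group means
  ct <- extended_tofts_forward(0.645, 0.555, 0.088, ap)
  fit <- fit_extended_tofts(ct, ap)
  expect_true(fit$converged)
  expect_equal(fit$Ktrans, 0.645, tolerance = 0.01)
  expect_equal(fit$ve, 0.555, tolerance = 0.01)
  expect_equal(fit$vp, 0.088, tolerance = 0.01)
  expect_equal(fit$kep * fit$ve, fit$Ktrans, tolerance = 1e-9)
  # an all-zero curve is excluded as unphysiological, not fitted
  z <- fit_extended_tofts(rep(0, 65), ap)
  expect_false(z$valid)
  expect_true(is.na(z$Ktrans))
})

test_that("Tofts fit matches a coarse grid-search oracle", {
  sc <- dce_scheme()
  ap <- population_aif(sc)
  grid <- ivimdce:::tofts_grid_(ap)
  kt_g <- seq(0.05, 1.5, length.out = 16)
  ve_g <- seq(0.1, 0.95, length.out = 16)
  vp_g <- seq(0, 0.2, length.out = 9)
  set.seed(42)
  for (i in 1:5) {
    truth <- c(runif(1, 0.2, 1.2), runif(1, 0.2, 0.9), runif(1, 0.01, 0.15))
    ct <- extended_tofts_forward(truth[1], truth[2], truth[3], ap)
    fit <- fit_extended_tofts(ct, ap)
    best <- NULL; best_rss <- Inf
    for (kt in kt_g) for (vv in ve_g) for (vp in vp_g) {
      rss <- sum((ct - extended_tofts_forward(kt, vv, vp, grid = grid))^2)
      if (rss < best_rss) { best_rss <- rss; best <- c(kt, vv, vp) }
    }
    expect_lt(abs(fit$Ktrans - best[1]), 1.5 * diff(kt_g[1:2]))
    expect_lt(abs(fit$ve - best[2]), 1.5 * diff(ve_g[1:2]))
    expect_lt(abs(fit$vp - best[3]), 1.5 * diff(vp_g[1:2]))
  }
})

test_that("concentration-scale invariance of the rate constants", {
  # scaling the AIF and tissue curve together leaves (Ktrans, ve, vp) fixed
  sc <- dce_scheme()
  ap <- population_aif(sc)
  ct <- extended_tofts_forward(0.5, 0.4, 0.06, ap)
  for (c_scale in c(0.5, 2)) {
    ap_s <- aif(ap$time, ap$cp * c_scale)
    fit <- fit_extended_tofts(ct * c_scale, ap_s)
    expect_equal(fit$Ktrans, 0.5, tolerance = 1e-3)
    expect_equal(fit$ve, 0.4, tolerance = 1e-3)
    expect_equal(fit$vp, 0.06, tolerance = 1e-3)
  }
})

test_that("full DCE map pipeline: homogeneous noiseless phantom is exact", {
  rp <- npc_tumor_params()
  ph <- generate_phantom(rp, shape = c(4, 4, 2), cv = 0, roi_frac = 2,
                         seed = 1)
  dce <- simulate_dce(ph, noise_sigma = 0)
  maps <- fit_dce_map(dce, ph$roi_mask)
  expect_true(all(maps$valid_mask))
  expect_equal(maps$Ktrans_map[1, 1, 1], rp$Ktrans, tolerance = 1e-4)
  expect_equal(maps$ve_map[1, 1, 1], rp$ve, tolerance = 1e-4)
  expect_equal(maps$vp_map[1, 1, 1], rp$vp, tolerance = 1e-4)
  # kep * ve = Ktrans on every fitted voxel
  m <- maps$valid_mask
  expect_equal(maps$kep_map[m] * maps$ve_map[m], maps$Ktrans_map[m],
               tolerance = 1e-6)
})

test_that("zero-enhancement voxels are excluded from the DCE maps", {
  rp <- npc_tumor_params()
  bg <- background_tissue_params()
  bg$Ktrans <- 0; bg$vp <- 0
  ph <- generate_phantom(rp, bg, shape = c(6, 6, 2), cv = 0, roi_frac = 0.5,
                         seed = 1)
  dce <- simulate_dce(ph, noise_sigma = 0)
  maps <- fit_dce_map(dce, array(TRUE, ph$shape))
  expect_true(all(maps$valid_mask[ph$roi_mask]))
  expect_false(any(maps$valid_mask[!ph$roi_mask]))
  expect_gt(maps$exclusions[["zero_enhancement"]], 0)
})
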