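test_that("stratification maps AJCC stages to the two groups", {
  rec <- data.frame(ajcc_stage = c("I", "II", "III", "IV"), x = 1:4)
  gr <- stratify(rec)
  expect_equal(gr$low$x, 1:2)
  expect_equal(gr$high$x, 3:4)
  expect_equal(unname(gr$counts), c(2L, 2L))
  expect_equal(unname(stratify(rec[0, ])$counts), c(0L, 0L))
  expect_error(stratify(data.frame(ajcc_stage = "V")), "unknown stage")
  # all-low input: downstream comparison refuses clearly
  tab <- data.frame(stage_group = rep("low", 5),
                    matrix(rnorm(35), 5, dimnames = list(NULL,
                      paste0("mean_", c("D","f","Dstar","Ktrans","kep","ve","vp")))))
  expect_error(analyze_cohort(tab), "at least 2")
})

test_that("Shapiro-Wilk wrapper behaves under both hypotheses", {
  set.seed(42)
  normal_p <- replicate(50, shapiro_wilk(rnorm(50))$p)
  lognorm_p <- replicate(50, shapiro_wilk(exp(rnorm(50, sd = 1.5)))$p)
  expect_gte(mean(normal_p > 0.05), 0.9)
  expect_gte(mean(lognorm_p < 0.05), 0.9)
  # affine invariance of W
  x <- rnorm(40)
  expect_equal(shapiro_wilk(x)$W, shapiro_wilk(5 - 3 * x)$W, tolerance = 1e-12)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
})

test_that("pooled t-test: identical groups, summary equivalence", {
  x <- c(1, 2, 3, 4)
  tt <- t_test_two_sample(x, x)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  # raw-data t equals summary-statistic t to machine precision
  set.seed(1)
  a <- rnorm(20, 1); b <- rnorm(30, 1.4)
  raw <- t_test_two_sample(a, b)
  summ <- t_test_from_summary(mean(a), sd(a), 20, mean(b), sd(b), 30)
  expect_equal(raw$t, summ$t, tolerance = 1e-12)
  expect_equal(raw$p, summ$p, tolerance = 1e-12)
  expect_error(t_test_two_sample(rep(2, 5), rep(2, 6)), "variance")
})

test_that("group-summary t for the reference D row gives t near 2.27", {
  # pooled closed form applied to the published low/high D summaries;
  # the resulting p (~0.026) documents that the table's printed p < 0.001
  # cannot come from this test on these summaries
  tt <- t_test_from_summary(0.803, 0.188, 29, 0.700, 0.193, 46)
  expect_equal(tt$t, 2.273, tolerance = 2e-3)
  expect_equal(tt$df, 73)
  expect_equal(tt$p, 0.026, tolerance = 0.02)
  expect_gt(tt$p, 0.001)
})

test_that("ROC analysis: separation, null band, and identities", {
  # perfectly separated groups
  r <- roc_analysis(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1), "higher")
  expect_equal(r$auc, 1)
  expect_equal(r$sens, 1)
  expect_equal(r$spec, 1)
  expect_true(r$optimal_cutoff > 3 && r$optimal_cutoff < 11)
  # labels independent of values
  set.seed(42)
  r0 <- roc_analysis(rnorm(500), rbinom(500, 1, 0.5), "higher")
  expect_gt(r0$auc, 0.45)
  expect_lt(r0$auc, 0.55)
  expect_error(roc_analysis(1:5, rep(1, 5)), "both classes")
})

test_that("AUC equals the Mann-Whitney identity and pROC agrees", {
  skip_if_not_installed("pROC")
  set.seed(42)
  for (i in 1:20) {
    n1 <- sample(10:40, 1); n0 <- sample(10:40, 1)
    v <- c(rnorm(n0), rnorm(n1, runif(1, 0, 2)))
    # ties with positive probability
    v <- round(v, sample(c(1, 2), 1))
    lab <- rep(c(0, 1), c(n0, n1))
    r <- roc_analysis(v, lab, "higher")
    u <- wilcox.test(v[lab == 1], v[lab == 0], exact = FALSE)$statistic
    expect_equal(r$auc, unname(u) / (n1 * n0), tolerance = 1e-12)
    pr <- pROC::roc(lab, v, direction = "<", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  }
})

test_that("optimal cut-off matches exhaustive threshold search", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    v <- round(rnorm(n, ifelse(rbinom(n, 1, 0.5), 0.8, 0)), 2)
    lab <- rbinom(n, 1, plogis(v))
    if (length(unique(lab)) < 2) next
    dir <- sample(c("lower", "higher"), 1)
    r <- roc_analysis(v, lab, dir)
    # brute force over every midpoint
    sv <- sort(unique(v))
    cand <- c(sv[1] - 1, (sv[-1] + head(sv, -1)) / 2, sv[length(sv)] + 1)
    best_j <- -Inf; best_spec <- -Inf; best_cut <- NA
    for (cc in cand) {
      pred <- if (dir == "lower") v <= cc else v >= cc
      se <- sum(pred & lab == 1) / sum(lab == 1)
      sp <- sum(!pred & lab == 0) / sum(lab == 0)
      j <- se + sp - 1
      if (j > best_j + 1e-12 ||
          (abs(j - best_j) <= 1e-12 && sp > best_spec)) {
        best_j <- j; best_spec <- sp; best_cut <- cc
      }
    }
    expect_equal(r$optimal_cutoff, best_cut)
    expect_equal(r$sens + r$spec - 1, best_j, tolerance = 1e-12)
  }
})

test_that("likelihood ratios at the cut-off obey their definitions", {
  set.seed(3)
  v <- c(rnorm(60), rnorm(60, 1))  # overlapping groups: interior cut-off
  lab <- rep(c(0, 1), each = 60)
  r <- roc_analysis(v, lab, "higher")
  expect_equal(r$lr_pos, r$sens / (1 - r$spec), tolerance = 1e-12)
  expect_equal(r$lr_neg, (1 - r$sens) / r$spec, tolerance = 1e-12)
  expect_true(r$lr_pos_ci[1] < r$lr_pos && r$lr_pos < r$lr_pos_ci[2])
  expect_true(r$sens_ci[1] <= r$sens && r$sens <= r$sens_ci[2])
})

test_that("DeLong comparison: self-test, power, rank invariance", {
  set.seed(42)
  lab <- rep(c(0, 1), each = 100)
  strong <- c(rnorm(100), rnorm(100, 2))
  noise <- rnorm(200)
  # marker against itself
  expect_equal(compare_auc(strong, strong, lab, "higher", "higher")$p, 1)
  # strong vs pure noise: significant in most seeded repeats
  hits <- 0
  for (i in 1:20) {
    set.seed(i)
    lb <- rep(c(0, 1), each = 100)
    st <- c(rnorm(100), rnorm(100, 2)); nz <- rnorm(200)
    if (compare_auc(st, nz, lb, "higher", "higher")$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 18)
  # invariance under monotone transform of either marker
  p1 <- compare_auc(strong, noise, lab, "higher", "higher")$p
  p2 <- compare_auc(exp(strong), noise, lab, "higher", "higher")$p
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_error(compare_auc(strong, noise[1:100], lab), "paired")
})

test_that("DeLong p agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  lab <- rep(c(0, 1), each = 60)
  a <- c(rnorm(60), rnorm(60, 1))
  b <- c(rnorm(60), rnorm(60, 0.5))
  mine <- compare_auc(a, b, lab, "higher", "higher")
  ra <- pROC::roc(lab, a, direction = "<", quiet = TRUE)
  rb <- pROC::roc(lab, b, direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
})

test_that("stepwise logistic selects planted signal and guards collinearity", {
  set.seed(42)
  n <- 300
  x <- data.frame(signal = rnorm(n), n1 = rnorm(n), n2 = rnorm(n))
  y <- rbinom(n, 1, plogis(1.2 * x$signal))
  fit <- stepwise_logistic(x, y)
  expect_true("signal" %in% fit$selected)
  # duplicated column enters only once
  x2 <- cbind(x, signal_copy = x$signal)
  fit2 <- stepwise_logistic(x2, y)
  expect_equal(fit2$dropped_duplicates, "signal_copy")
  expect_false("signal_copy" %in% fit2$selected)
  # pure-noise features give an empty model most of the time
  set.seed(1)
  empties <- sum(replicate(20, {
    xn <- data.frame(a = rnorm(100), b = rnorm(100))
    length(stepwise_logistic(xn, rbinom(100, 1, 0.5))$selected) == 0
  }))
  expect_gte(empties, 15)
})

test_that("stepwise logistic flags perfect separation and still reports", {
  x <- data.frame(sep = c(rnorm(20, -3), rnorm(20, 3)))
  y <- rep(c(0, 1), each = 20)
  expect_warning(fit <- stepwise_logistic(x, y), "separation")
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("Spearman with Bonferroni: monotone, multiplicity, constants", {
  d <- data.frame(x = rnorm(30))
  d$y <- exp(d$x)       # strictly monotone transform
  d$z <- rnorm(30)
  out <- spearman_with_bonferroni(d, list(c("x", "y"), c("x", "z")))
  expect_equal(out$rho[1], 1)
  expect_equal(out$m, c(2, 2))
  expect_equal(out$p_adjusted, pmin(1, 2 * out$p_raw))
  # multiplication rule at m = 8
  d8 <- data.frame(matrix(rnorm(30 * 9), 30))
  pairs8 <- lapply(2:9, function(i) c("X1", paste0("X", i)))
  out8 <- spearman_with_bonferroni(d8, pairs8)
  expect_equal(out8$p_adjusted, pmin(1, 8 * out8$p_raw))
  # constant member reported as undefined, not an error
  dc <- data.frame(x = rep(1, 10), y = rnorm(10))
  outc <- spearman_with_bonferroni(dc, list(c("x", "y")))
  expect_true(is.na(outc$rho))
  expect_match(outc$note, "constant")
})
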