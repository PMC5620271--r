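#' Stratify subject records into low and high stage groups
#'
#' AJCC stages I and II form the low-stage group, III and IV the high-
#' stage group.
#'
#' @param records Data.frame with an `ajcc_stage` column ("I".."IV") or a
#'   `stage_group` column ("low"/"high").
#' @return List: `low`, `high` (row subsets), `counts`.
#' @export
stratify <- function(records) {
  if (!is.data.frame(records)) stop("records must be a data.frame")
  if (nrow(records) == 0L)
    return(list(low = records, high = records, counts = c(low = 0L, high = 0L)))
  grp <- if ("ajcc_stage" %in% names(records)) {
    st <- as.character(records$ajcc_stage)
    bad <- !st %in% c("I", "II", "III", "IV")
    if (any(bad)) stop("unknown stage label: ", paste(unique(st[bad]), collapse = ", "))
    ifelse(st %in% c("I", "II"), "low", "high")
  } else if ("stage_group" %in% names(records)) {
    st <- as.character(records$stage_group)
    bad <- !st %in% c("low", "high")
    if (any(bad)) stop("unknown stage label: ", paste(unique(st[bad]), collapse = ", "))
    st
  } else stop("records need an ajcc_stage or stage_group column")
  list(low = records[grp == "low", , drop = FALSE],
       high = records[grp == "high", , drop = FALSE],
       counts = c(low = sum(grp == "low"), high = sum(grp == "high")))
}

#' Shapiro-Wilk normality test
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @return List: `W`, `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L || length(values) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("constant input: W undefined")
  st <- stats::shapiro.test(values)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Two-sample Student's t-test
#'
#' Pooled-variance Student form by default (Welch available by flag).
#'
#' @param x,y Numeric vectors, n >= 2 each.
#' @param var_equal Pooled-variance Student form when TRUE.
#' @return List: `t`, `df`, `p` (two-sided), `mean_x`, `mean_y`.
#' @export
t_test_two_sample <- function(x, y, var_equal = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per group")
  if (var_equal && stats::var(x) + stats::var(y) == 0)
    stop("zero pooled variance")
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Student's t-test from summary statistics
#'
#' Pooled closed form: sp^2 = ((n1-1)s1^2 + (n2-1)s2^2)/(n1+n2-2),
#' t = (m1 - m2) / (sp sqrt(1/n1 + 1/n2)), df = n1 + n2 - 2. Identical
#' to [t_test_two_sample()] applied to raw data with those summaries.
#'
#' @param m1,s1,n1 Mean, SD, size of group 1.
#' @param m2,s2,n2 Mean, SD, size of group 2.
#' @return List: `t`, `df`, `p` (two-sided).
#' @export
t_test_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Empirical ROC analysis with optimal cut-off and likelihood ratios
#'
#' Sweeps every midpoint between consecutive distinct values (plus open
#' extremes) as a candidate cut-off, computes sensitivity and specificity
#' at each, takes the AUC by the trapezoidal rule over the empirical
#' curve (which equals the Mann-Whitney statistic), and picks the cut-off
#' maximizing the chosen criterion (Youden's J by default, accuracy as
#' alternative), breaking ties toward higher specificity. Confidence
#' intervals: Clopper-Pearson (exact binomial) for sensitivity and
#' specificity, log method for the likelihood ratios.
#'
#' @param values Marker values.
#' @param labels Positive-class indicator (logical, 0/1, or factor whose
#'   second level is positive). Positive = the class being detected
#'   (e.g. high stage).
#' @param direction "lower" when low marker values predict the positive
#'   class, "higher" otherwise.
#' @param criterion "youden" or "accuracy".
#' @param conf_level Confidence level for the interval estimates.
#' @return Object of class `roc_result`: `curve` (data.frame threshold /
#'   sens / spec), `auc`, `optimal_cutoff`, `sens`, `spec`, `sens_ci`,
#'   `spec_ci`, `lr_pos`, `lr_neg`, `lr_pos_ci`, `lr_neg_ci`,
#'   `direction`, `criterion`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(values, labels, direction = c("lower", "higher"),
                         criterion = c("youden", "accuracy"),
                         conf_level = 0.95) {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  pos <- as_positive_(labels)
  keep <- is.finite(values) & !is.na(pos)
  values <- values[keep]; pos <- pos[keep]
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present")
  sv <- sort(unique(values))
  cuts <- c(sv[1] - 1, (sv[-1] + sv[-length(sv)]) / 2, sv[length(sv)] + 1)
  # positive call: value <= cut (direction "lower") or value >= cut ("higher")
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    call_pos <- if (direction == "lower") values <= cuts[i] else values >= cuts[i]
    sens[i] <- sum(call_pos & pos) / n_pos
    spec[i] <- sum(!call_pos & !pos) / n_neg
  }
  curve <- data.frame(threshold = cuts, sens = sens, spec = spec)
  # trapezoidal AUC over the empirical curve
  ord <- order(1 - spec, sens)
  fpr <- (1 - spec)[ord]; tpr <- sens[ord]
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  score <- switch(criterion,
                  youden = sens + spec - 1,
                  accuracy = (sens * n_pos + spec * n_neg) / (n_pos + n_neg))
  best <- which(score == max(score))
  best <- best[which.max(spec[best])]  # ties -> higher specificity
  se <- sens[best]; sp <- spec[best]
  ci_prop <- function(k, n)
    as.numeric(stats::binom.test(round(k), n, conf.level = conf_level)$conf.int)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lr_ci <- function(lr, p1, k1, n1, p0, k0, n0) {
    # log-method CI for a ratio of two proportions (Simel et al.)
    if (!is.finite(lr) || lr <= 0 || p1 %in% c(0, 1) || p0 %in% c(0, 1))
      return(c(NA_real_, NA_real_))
    se_log <- sqrt((1 - p1) / k1 + (1 - p0) / k0)
    exp(log(lr) + c(-1, 1) * z * se_log)
  }
  lr_pos <- if (sp < 1) se / (1 - sp) else Inf
  lr_neg <- if (sp > 0) (1 - se) / sp else Inf
  structure(list(
    curve = curve, auc = auc, optimal_cutoff = cuts[best],
    sens = se, spec = sp,
    sens_ci = ci_prop(se * n_pos, n_pos),
    spec_ci = ci_prop(sp * n_neg, n_neg),
    lr_pos = lr_pos, lr_neg = lr_neg,
    lr_pos_ci = lr_ci(lr_pos, se, se * n_pos, n_pos, 1 - sp,
                      (1 - sp) * n_neg, n_neg),
    lr_neg_ci = lr_ci(lr_neg, 1 - se, (1 - se) * n_pos, n_pos, sp,
                      sp * n_neg, n_neg),
    direction = direction, criterion = criterion,
    n_pos = n_pos, n_neg = n_neg), class = "roc_result")
}

# internal: coerce labels to a positive-class logical
as_positive_ <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("labels must have exactly 2 classes")
  f == levels(f)[2L]
}

#' DeLong paired test comparing two correlated ROC curves
#'
#' Nonparametric comparison of the AUCs of two markers measured on the
#' same subjects, using the DeLong placement-value covariance estimate.
#' Two-sided p. Identical markers give p = 1.
#'
#' @param values_a,values_b Paired marker values on the same subjects.
#' @param labels Positive-class indicator shared by both markers.
#' @param direction_a,direction_b Per-marker direction ("lower" = low
#'   values predict positive).
#' @return List: `auc_a`, `auc_b`, `z`, `p`.
#' @export
compare_auc <- function(values_a, values_b, labels,
                        direction_a = "lower", direction_b = "lower") {
  if (length(values_a) != length(values_b) ||
      length(values_a) != length(labels))
    stop("markers must be paired on the same subjects")
  pos <- as_positive_(labels)
  ok <- is.finite(values_a) & is.finite(values_b) & !is.na(pos)
  a <- values_a[ok]; b <- values_b[ok]; pos <- pos[ok]
  if (sum(pos) == 0L || sum(!pos) == 0L) stop("both classes must be present")
  score <- function(v, dir) if (dir == "lower") -v else v
  a <- score(a, match.arg(direction_a, c("lower", "higher")))
  b <- score(b, match.arg(direction_b, c("lower", "higher")))
  placements <- function(x) {
    xp <- x[pos]; xn <- x[!pos]
    m <- length(xp); n <- length(xn)
    psi <- outer(xp, xn, function(p, q) (p > q) + 0.5 * (p == q))
    list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
         m = m, n = n)
  }
  pa <- placements(a); pb <- placements(b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / pa$m + s01 / pa$n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else z <- d / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

# internal: Firth-penalized logistic regression (Jeffreys prior), used as
# fallback under separation; returns coefficients and Wald p-values
firth_logistic_ <- function(X, y, maxit = 50, tol = 1e-8) {
  X <- cbind(`(Intercept)` = 1, X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    XtW <- t(X * W)
    I <- XtW %*% X
    Iinv <- tryCatch(solve(I), error = function(e) NULL)
    if (is.null(Iinv)) break
    h <- rowSums((X %*% Iinv) * (X * W))
    U <- t(X) %*% (y - p + h * (0.5 - p))
    step <- Iinv %*% U
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(Iinv))
  zv <- beta / se
  list(coefficients = beta, se = se,
       wald_p = 2 * stats::pnorm(-abs(zv)))
}

#' Forward stepwise logistic regression with backward pruning
#'
#' Forward selection by likelihood-ratio test (enter at `p_enter`), with
#' backward removal of any included feature whose LR p rises above
#' `p_remove`; features are standardized internally; exact duplicate
#' columns are dropped before selection (collinearity guard). Perfect
#' separation in the final model is flagged and the coefficients refit
#' with a Firth-penalized likelihood.
#'
#' @param features Data.frame or matrix of candidate predictors.
#' @param labels Positive-class indicator.
#' @param p_enter LR p-value to enter (default 0.05).
#' @param p_remove LR p-value above which an included feature is removed
#'   (default 0.10).
#' @return List: `selected` (names in final model), `order` (entry
#'   order), `coefficients`, `wald_p`, `deviance`, `null_deviance`,
#'   `separation` (flag), `dropped_duplicates`.
#' @export
stepwise_logistic <- function(features, labels, p_enter = 0.05,
                              p_remove = 0.10) {
  X <- as.data.frame(features)
  y <- as.numeric(as_positive_(labels))
  if (nrow(X) != length(y)) stop("features and labels must align")
  if (nrow(X) <= ncol(X)) stop("need more subjects than candidate features")
  # standardize; constant columns cannot inform and are dropped
  keep <- vapply(X, function(col) stats::sd(col) > 0, logical(1))
  X <- X[keep]
  X[] <- lapply(X, function(col) (col - mean(col)) / stats::sd(col))
  dup <- duplicated(lapply(X, function(col) round(col, 10)))
  dropped_dup <- names(X)[dup]
  X <- X[!dup]
  vars <- names(X)
  dat <- cbind(X, .y = y)

  fit_model <- function(incl) {
    fml <- if (length(incl)) stats::reformulate(incl, ".y") else .y ~ 1
    suppressWarnings(stats::glm(fml, binomial(), dat))
  }
  lr_p <- function(small, big) {
    dd <- small$deviance - big$deviance
    dfd <- small$df.residual - big$df.residual
    if (dfd <= 0) return(1)
    stats::pchisq(max(dd, 0), dfd, lower.tail = FALSE)
  }
  included <- character(); order_in <- character()
  current <- fit_model(included)
  repeat {
    changed <- FALSE
    cand <- setdiff(vars, included)
    if (length(cand)) {
      ps <- vapply(cand, function(v)
        lr_p(current, fit_model(c(included, v))), numeric(1))
      if (min(ps) < p_enter) {
        add <- cand[which.min(ps)]
        included <- c(included, add); order_in <- c(order_in, add)
        current <- fit_model(included)
        changed <- TRUE
      }
    }
    # backward pruning
    repeat {
      if (length(included) == 0L) break
      ps <- vapply(included, function(v)
        lr_p(fit_model(setdiff(included, v)), current), numeric(1))
      if (max(ps) > p_remove) {
        included <- setdiff(included, included[which.max(ps)])
        current <- fit_model(included)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  sep <- length(included) > 0 &&
    (any(abs(stats::coef(current)[-1]) > 15, na.rm = TRUE) ||
       any(current$fitted.values < 1e-8 | current$fitted.values > 1 - 1e-8))
  if (sep) {
    warning("perfect or quasi-separation detected; reporting Firth-penalized fit")
    ff <- firth_logistic_(as.matrix(X[included]), y)
    coefs <- ff$coefficients; wald <- ff$wald_p
  } else {
    sm <- summary(current)$coefficients
    coefs <- sm[, "Estimate"]; wald <- sm[, "Pr(>|z|)"]
  }
  list(selected = included, order = order_in, coefficients = coefs,
       wald_p = wald, deviance = current$deviance,
       null_deviance = current$null.deviance, separation = sep,
       dropped_duplicates = dropped_dup)
}

#' Spearman rank correlations with Bonferroni correction
#'
#' Midrank-tie Spearman rho for each named pair, with
#' p_adjusted = min(1, m * p_raw) where m is the number of pairs tested.
#'
#' @param data Data.frame holding the variables.
#' @param pairs List of length-2 character vectors (x name, y name).
#' @param alpha Family-wise significance level.
#' @return Data.frame: x, y, n, rho, p_raw, p_adjusted, m, significant.
#'   Pairs with a constant member get NA rho and a note.
#' @export
spearman_with_bonferroni <- function(data, pairs, alpha = 0.05) {
  m <- length(pairs)
  if (m == 0L) stop("no pairs supplied")
  rows <- lapply(pairs, function(pr) {
    x <- data[[pr[1]]]; y <- data[[pr[2]]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 5L) stop("each pair needs n >= 5 complete observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(x = pr[1], y = pr[2], n = length(x),
                        rho = NA_real_, p_raw = NA_real_,
                        note = "constant vector: rho undefined"))
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    data.frame(x = pr[1], y = pr[2], n = length(x),
               rho = unname(ct$estimate), p_raw = ct$p.value, note = "")
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, m * out$p_raw)
  out$m <- m
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}

#' Full cohort-level staging analysis
#'
#' Runs the complete statistics layer on a cohort table: per-parameter
#' Shapiro-Wilk normality checks, pooled Student's t-tests between stage
#' groups, ROC analysis with Youden cut-offs (direction per parameter:
#' low values of D, f, D*, Ktrans, kep, vp predict high stage; high ve
#' does), paired DeLong comparisons of Ktrans against f and D*, forward
#' stepwise logistic regression over all parameters, and Spearman
#' correlations (with Bonferroni correction) between the IVIM
#' perfusion-related parameters (f, D*) and the DCE parameters.
#'
#' @param table Cohort table with `stage_group` and `mean_*` columns
#'   (as from [fit_cohort()], or `true_*` columns renamed).
#' @param criterion ROC cut-off criterion.
#' @param alpha Significance level.
#' @return List of class `cohort_report`: `counts`, `normality`,
#'   `t_tests`, `roc`, `auc_comparisons`, `stepwise`, `correlations`.
#' @export
analyze_cohort <- function(table, criterion = "youden", alpha = 0.05) {
  params <- c("D", "f", "Dstar", "Ktrans", "kep", "ve", "vp")
  cols <- paste0("mean_", params)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  groups <- stratify(table)
  if (groups$counts["low"] < 2L || groups$counts["high"] < 2L)
    stop("each stage group needs at least 2 subjects")
  high_flag <- table$stage_group == "high"  # positive class: high stage
  directions <- c(D = "lower", f = "lower", Dstar = "lower",
                  Ktrans = "lower", kep = "lower", ve = "higher",
                  vp = "lower")

  normality <- lapply(stats::setNames(cols, params), function(cl)
    tryCatch(shapiro_wilk(table[[cl]]), error = function(e) NULL))
  t_tests <- do.call(rbind, lapply(params, function(p) {
    tt <- t_test_two_sample(groups$low[[paste0("mean_", p)]],
                            groups$high[[paste0("mean_", p)]])
    data.frame(parameter = p, mean_low = tt$mean_x, mean_high = tt$mean_y,
               t = tt$t, df = tt$df, p = tt$p)
  }))
  roc <- lapply(stats::setNames(params, params), function(p)
    roc_analysis(table[[paste0("mean_", p)]], high_flag,
                 direction = directions[[p]], criterion = criterion))
  auc_comparisons <- do.call(rbind, lapply(c("f", "Dstar"), function(p) {
    cmp <- compare_auc(table$mean_Ktrans, table[[paste0("mean_", p)]],
                       high_flag, "lower", directions[[p]])
    data.frame(marker_a = "Ktrans", marker_b = p,
               auc_a = cmp$auc_a, auc_b = cmp$auc_b, p = cmp$p)
  }))
  stepwise <- if (nrow(table) > length(cols)) {
    stepwise_logistic(table[cols], high_flag)
  } else {
    list(selected = character(0), order = character(0),
         coefficients = numeric(0), wald_p = numeric(0),
         deviance = NA_real_, null_deviance = NA_real_,
         separation = FALSE, dropped_duplicates = character(0),
         note = "skipped: fewer subjects than candidate features")
  }
  pairs <- unlist(lapply(c("mean_f", "mean_Dstar"), function(iv)
    lapply(c("mean_Ktrans", "mean_kep", "mean_ve", "mean_vp"),
           function(dc) c(iv, dc))), recursive = FALSE)
  correlations <- spearman_with_bonferroni(table, pairs, alpha)
  structure(list(counts = groups$counts, normality = normality,
                 t_tests = t_tests, roc = roc,
                 auc_comparisons = auc_comparisons, stepwise = stepwise,
                 correlations = correlations, alpha = alpha),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort staging report: %d low / %d high subjects\n",
              x$counts["low"], x$counts["high"]))
  cat("\nGroup comparison (pooled Student's t):\n")
  print(transform(x$t_tests, p = signif(p, 3)), row.names = FALSE)
  cat("\nROC (AUC, optimal cut-off, sens, spec):\n")
  for (p in names(x$roc)) {
    r <- x$roc[[p]]
    cat(sprintf("  %-7s AUC=%.3f cut=%.4g sens=%.1f%% spec=%.1f%% LR+=%.2f LR-=%.2f\n",
                p, r$auc, r$optimal_cutoff, 100 * r$sens, 100 * r$spec,
                r$lr_pos, r$lr_neg))
  }
  cat("\nStepwise logistic selected:",
      if (length(x$stepwise$selected)) paste(x$stepwise$selected, collapse = ", ")
      else "(none)", "\n")
  cat("\nIVIM x DCE Spearman correlations (Bonferroni m =",
      x$correlations$m[1], "):\n")
  print(transform(x$correlations[, c("x", "y", "rho", "p_adjusted", "significant")],
                  rho = round(rho, 3), p_adjusted = signif(p_adjusted, 3)),
        row.names = FALSE)
  invisible(x)
}
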