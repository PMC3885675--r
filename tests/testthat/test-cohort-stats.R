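test_that("one nodule per patient is selected uniformly and reproducibly", {
  df <- data.frame(patient_id = c("a", "b", "b", "b", "c"),
                   nodule_id = paste0("n", 1:5))
  # singleton patients pass through unchanged
  solo <- df[c(1, 5), ]
  expect_equal(select_one_per_patient(solo, 1)$nodule_id, c("n1", "n5"))
  # one row per patient, deterministic per seed
  s1 <- select_one_per_patient(df, 7)
  expect_equal(nrow(s1), 3)
  expect_equal(sort(unique(s1$patient_id)), c("a", "b", "c"))
  expect_identical(select_one_per_patient(df, 7), s1)
  # uniform choice among patient b's three nodules
  picks <- vapply(1:4000, function(s) {
    sel <- select_one_per_patient(df, s)
    sel$nodule_id[sel$patient_id == "b"]
  }, character(1))
  freq <- table(picks) / length(picks)
  expect_equal(length(freq), 3L)
  expect_true(all(abs(freq - 1 / 3) < 0.03))
})

test_that("Welch t test matches its formula and is antisymmetric", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 3, 4, 5, 6)
  w <- welch_t(x, y)
  o <- oracle_welch(x, y)
  expect_equal(w$statistic, o$statistic, tolerance = 1e-10)
  expect_equal(w$df, o$df, tolerance = 1e-10)
  expect_equal(w$p_value, o$p_value, tolerance = 1e-8)
  rev <- welch_t(y, x)
  expect_equal(rev$statistic, -w$statistic)
  expect_equal(rev$p_value, w$p_value)
  expect_false(welch_t(rep(1, 3), rep(2, 4))$defined)
  expect_error(welch_t(1, c(1, 2)), class = "psn_validation_error")
})

test_that("2x2 tests match closed form and enumeration on published counts", {
  # sex distribution 22:9 vs 16:30 across the two groups
  sex <- matrix(c(22, 9, 16, 30), 2, byrow = FALSE)
  chi <- pearson_chi2(sex)
  expect_equal(chi$statistic,
               77 * (22 * 30 - 9 * 16)^2 / (31 * 46 * 38 * 39),
               tolerance = 1e-12)
  expect_equal(chi$statistic, 9.701, tolerance = 1e-3)
  expect_equal(chi$p_value, oracle_chi2(sex)$p_value, tolerance = 1e-10)

  # independence: ad = bc gives chi2 = 0 and Fisher p = 1
  ind <- matrix(c(10, 20, 5, 10), 2)
  expect_equal(pearson_chi2(ind)$statistic, 0)
  expect_equal(fisher_exact(ind)$p_value, 1)

  # eosinophilia 7:22 vs 1:45 - Fisher vs full enumeration, near 0.01
  eo <- matrix(c(7, 22, 1, 45), 2)
  fe <- fisher_exact(eo)
  expect_equal(fe$p_value, oracle_fisher(eo), tolerance = 1e-10)
  expect_lt(fe$p_value, 0.015)

  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2)),
               class = "psn_validation_error")
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)),
               class = "psn_validation_error")
})

test_that("univariate screening routes tests and respects alpha", {
  df <- make_stats_cohort(40, 40, seed = 3)
  df$mirror <- df$group == "transient" # predictor equal to the label
  df$flat <- 1
  # rare flag: expected cells below 5 must route to the Fisher exact test
  df$rare <- rep(FALSE, 80); df$rare[c(1, 2, 3, 41)] <- TRUE
  df$balanced <- rep(c(TRUE, FALSE), 40)
  expect_warning(
    scr <- univariate_screen(df, c("age", "male", "rare", "balanced",
                                   "mirror", "flat"), alpha = 0.05),
    "constant")
  expect_true("mirror" %in% scr$selected)
  expect_false("flat" %in% scr$table$predictor)
  expect_equal(scr$table$test[scr$table$predictor == "age"], "welch_t")
  expect_equal(scr$table$test[scr$table$predictor == "rare"], "fisher_exact")
  expect_equal(scr$table$test[scr$table$predictor == "balanced"],
               "pearson_chi2")
  expect_equal(length(univariate_screen(df, "age", alpha = 0)$selected), 0L)
})

test_that("screening holds its type-I rate on null predictors", {
  hits <- withr::with_seed(21, {
    vapply(1:1000, function(i) {
      df <- data.frame(group = rep(c("transient", "persistent"), c(30, 30)),
                       noise = rnorm(60))
      length(univariate_screen(df, "noise", alpha = 0.05)$selected) == 1L
    }, logical(1))
  })
  expect_lt(abs(mean(hits) - 0.05), 0.02)
})

test_that("logistic IRLS reproduces the saturated 2x2 odds ratio exactly", {
  x <- matrix(rep(c(1, 0), c(15, 15)), ncol = 1,
              dimnames = list(NULL, "exposed"))
  y <- c(rep(1, 10), rep(0, 5), rep(1, 4), rep(0, 11))
  fit <- logistic_fit(x, y)
  expect_true(fit$converged)
  expect_false(fit$separation)
  expect_equal(fit$coefficients$odds_ratio[2], 5.5, tolerance = 1e-6)
  expect_equal(fit$coefficients$estimate[2], log(5.5), tolerance = 1e-6)
  # odds-ratio / CI invariants
  expect_equal(fit$coefficients$ci_lower,
               exp(fit$coefficients$estimate - 1.96 * fit$coefficients$se))
  # cross-check coefficients and SEs against glm
  g <- glm(y ~ x, family = binomial())
  expect_equal(fit$coefficients$estimate, unname(coef(g)), tolerance = 1e-6)
  expect_equal(fit$coefficients$se,
               unname(summary(g)$coefficients[, 2]), tolerance = 1e-5)
})

test_that("logistic fit converges to zero score and respects nesting", {
  set.seed(33)
  X <- matrix(rnorm(300 * 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- runif(300) < plogis(0.3 + X %*% c(0.8, -0.5, 0))
  fit <- logistic_fit(X, y, tol = 1e-8)
  expect_true(fit$converged)
  # score (log-likelihood gradient) vanishes at the solution
  score <- crossprod(cbind(1, X), y - fit$fitted)
  expect_lt(max(abs(score)), 1e-6)
  # dropping a predictor never increases the log-likelihood
  for (drop in 1:3) {
    red <- logistic_fit(X[, -drop, drop = FALSE], y)
    expect_lte(red$loglik, fit$loglik + 1e-8)
  }
  # intercept-only truth p = 0.5: estimate within 3 SE of zero
  y0 <- withr::with_seed(8, runif(10000) < 0.5)
  f0 <- logistic_fit(matrix(rnorm(10000), ncol = 1,
                            dimnames = list(NULL, "z")), y0)
  expect_lt(abs(f0$coefficients$estimate[1]),
            3 * f0$coefficients$se[1] + 1e-8)
})

test_that("separation and collinearity are detected, not reported", {
  x <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1,
              dimnames = list(NULL, "sep"))
  y <- rep(c(0, 1), each = 10)
  fit <- logistic_fit(x, y)
  expect_true(fit$separation)
  expect_true(all(is.na(fit$coefficients$odds_ratio)))

  X <- cbind(a = rnorm(40), b = 0)
  expect_error(logistic_fit(X, rep(c(0, 1), 20)),
               class = "psn_validation_error")
  X2 <- cbind(a = rnorm(40))
  X2 <- cbind(X2, dup = X2[, 1])
  expect_error(logistic_fit(X2, rep(c(0, 1), 20)),
               class = "psn_validation_error")
  expect_warning(f2 <- logistic_fit(X2, rep(c(0, 1), 20),
                                    drop_aliased = TRUE), "collinear")
  expect_equal(length(f2$terms), 2L)
})

test_that("AUC matches exhaustive pair counting with tie credit", {
  a <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(a$auc, 0.75)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  set.seed(12)
  for (i in 1:30) {
    n <- sample(8:50, 1)
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    sc <- sample(round(rnorm(n), 1)) # rounded scores force ties
    r <- roc_auc(sc, pos)
    expect_equal(r$auc, oracle_auc(sc, pos), tolerance = 1e-12)
    # label flip mirrors the AUC
    expect_equal(roc_auc(sc, !pos)$auc, 1 - r$auc, tolerance = 1e-12)
    expect_gte(r$var, 0)
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), class = "psn_validation_error")
})

test_that("DeLong AUC variance and comparison agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(61)
  y <- rep(c(1, 0), c(30, 40))
  s1 <- y * 0.8 + rnorm(70)
  s2 <- y * 0.4 + rnorm(70)
  r <- roc_auc(s1, y == 1)
  pr <- pROC::roc(y, s1, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(r$var, pROC::var(pr, method = "delong"), tolerance = 1e-10)
  dc <- delong_compare(s1, s2, y == 1)
  pt <- pROC::roc.test(pr, pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(dc$p_value, pt$p.value, tolerance = 1e-10)
  expect_equal(dc$z, unname(pt$statistic), tolerance = 1e-10)
})

test_that("DeLong comparison handles self- and rank-identical scores", {
  y <- rep(c(TRUE, FALSE), c(20, 25))
  s <- c(rnorm(20, 1), rnorm(25))
  self <- delong_compare(s, s, y)
  expect_equal(self$z, 0)
  expect_equal(self$p_value, 1)
  expect_true(self$degenerate)
  # a monotone transform preserves ranks: AUC difference 0, p = 1
  mono <- delong_compare(s, plogis(3 * s - 1), y)
  expect_equal(mono$diff, 0)
  expect_equal(mono$p_value, 1)
})
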