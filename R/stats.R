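#' Select a single nodule per patient
#'
#' In consideration of within-patient correlation, one nodule is selected
#' uniformly at random per patient before any nodule-level statistics.
#' Deterministic given the seed; patients are processed in sorted
#' patient-id order.
#'
#' @param cohort `data.frame` with a `patient_id` column, one row per
#'   nodule.
#' @param seed integer seed.
#' @return the subset `data.frame`, one row per patient, original row
#'   order preserved.
#' @export
select_one_per_patient <- function(cohort, seed = 1) {
  if (!is.data.frame(cohort) || is.null(cohort$patient_id)) {
    validation_error("`cohort` must be a data.frame with a patient_id column")
  }
  idx <- withr::with_seed(derive_seed(seed, 17), {
    unlist(lapply(split(seq_len(nrow(cohort)), cohort$patient_id),
                  function(i) if (length(i) == 1L) i else i[sample.int(length(i), 1L)]),
           use.names = FALSE)
  })
  out <- cohort[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_group_comparison <- function(test, statistic, df, p_value,
                                 defined = TRUE) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, defined = defined),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = %s, p = %.4g%s\n", x$test,
              x$statistic, format(x$df), x$p_value,
              if (x$defined) "" else " (undefined)"))
  invisible(x)
}

#' Welch's independent-sample t test
#'
#' Two-sided unequal-variance t test with Satterthwaite degrees of
#' freedom. When both groups have zero variance the comparison is
#' undefined and flagged.
#'
#' @param x,y numeric vectors (each n >= 2, finite).
#' @return a `group_comparison` (test, statistic, df, p-value).
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L || any(!is.finite(c(x, y)))) {
    validation_error("`x` and `y` must be finite with n >= 2 each")
  }
  if (var(x) == 0 && var(y) == 0) {
    return(new_group_comparison("welch_t", NA_real_, NA_real_, NA_real_,
                                defined = FALSE))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  new_group_comparison("welch_t", unname(ht$statistic),
                       unname(ht$parameter), ht$p.value)
}

check_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L) || any(tab < 0) || any(tab != round(tab))) {
    validation_error("`tab` must be a 2x2 table of nonnegative integer counts")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    validation_error("all margins of the 2x2 table must be positive")
  }
  tab
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1.
#'
#' @param tab 2x2 matrix of counts with positive margins.
#' @return a `group_comparison`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- check_2x2(tab)
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  new_group_comparison("pearson_chi2", unname(ht$statistic), 1,
                       ht$p.value)
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' that are no more probable than the observed table.
#'
#' @param tab 2x2 matrix of counts with positive margins.
#' @return a `group_comparison`; the statistic slot carries the
#'   conditional-MLE odds ratio.
#' @export
fisher_exact <- function(tab) {
  tab <- check_2x2(tab)
  ht <- fisher.test(tab)
  new_group_comparison("fisher_exact", unname(ht$estimate), NA_real_,
                       ht$p.value)
}

#' Univariate screening of candidate predictors against the group label
#'
#' Continuous predictors are compared between groups with [welch_t()];
#' binary predictors with [pearson_chi2()], falling back to
#' [fisher_exact()] whenever any expected cell count is below 5.
#' Predictors with p below `alpha` are selected. Constant predictors are
#' skipped with a warning.
#'
#' @param cohort `data.frame` with a binary `group` column
#'   (`"transient"` / `"persistent"`) and the candidate columns.
#' @param predictors character vector of column names.
#' @param alpha selection threshold on the p-value.
#' @return list with `table` (predictor, type, test, statistic, p_value,
#'   selected) and `selected` (character vector).
#' @export
univariate_screen <- function(cohort, predictors, alpha = 0.05) {
  if (is.null(cohort$group)) validation_error("`cohort` needs a group column")
  y <- cohort$group == "transient"
  rows <- lapply(predictors, function(p) {
    if (is.null(cohort[[p]])) validation_error(sprintf("predictor `%s` not found", p))
    v <- cohort[[p]]
    if (is.character(v) || is.factor(v)) v <- as.integer(factor(v)) - 1L
    if (is.logical(v)) v <- as.integer(v)
    ok <- is.finite(v)
    if (sum(ok & y) < 2L || sum(ok & !y) < 2L) {
      warning(sprintf("predictor `%s` has too few complete values; skipped", p))
      return(NULL)
    }
    v <- v[ok]; y <- y[ok]
    if (length(unique(v)) < 2L) {
      warning(sprintf("predictor `%s` is constant; skipped", p))
      return(NULL)
    }
    if (length(unique(v)) == 2L) {
      tab <- table(factor(v, levels = sort(unique(v))),
                   factor(y, levels = c(FALSE, TRUE)))
      exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      gc <- if (any(exp_cells < 5)) fisher_exact(tab) else pearson_chi2(tab)
      type <- "binary"
    } else {
      gx <- v[y]; gy <- v[!y]
      if (var(gx) == 0 && var(gy) == 0) {
        warning(sprintf("predictor `%s` has no within-group variance; skipped", p))
        return(NULL)
      }
      gc <- welch_t(gx, gy)
      type <- "continuous"
    }
    data.frame(predictor = p, type = type, test = gc$test,
               statistic = gc$statistic, p_value = gc$p_value,
               # alpha = 1 disables the screen entirely (p-values of
               # exactly 1 still pass)
               selected = isTRUE(gc$p_value < alpha) || alpha >= 1,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(predictor = character(),
                                      type = character(), test = character(),
                                      statistic = numeric(),
                                      p_value = numeric(),
                                      selected = logical())
  rownames(tab) <- NULL
  list(table = tab, selected = tab$predictor[tab$selected])
}

#' Multivariate logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of a binary logistic model with an intercept
#' plus the supplied design columns (enter method: all columns entered
#' simultaneously). Predictors are standardized internally for numerical
#' conditioning and the fit transformed back to the original scale.
#' Convergence is declared when the maximum absolute score (gradient of
#' the log-likelihood) falls below `tol`. Wald standard errors come from
#' the inverse observed information; odds ratios are exp(coefficient) with
#' 95% CIs exp(coefficient +/- 1.96 SE). Quasi-complete separation
#' (coefficients diverging on the standardized scale) is detected and
#' flagged: raw coefficients are retained for prediction but odds ratios,
#' CIs and p-values are withheld.
#'
#' @param x numeric design matrix (no intercept column; column names
#'   required).
#' @param y binary outcome (logical or 0/1), length nrow(x).
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence threshold on the maximum absolute score.
#' @param drop_aliased drop rank-deficient columns (with a warning)
#'   instead of erroring.
#' @return an object of class `logistic_fit`: `coefficients` table (term,
#'   estimate, se, odds_ratio, ci_lower, ci_upper, p_value), `converged`,
#'   `separation`, `iterations`, `loglik`, `fitted`, `terms`.
#' @export
logistic_fit <- function(x, y, max_iter = 100, tol = 1e-8,
                         drop_aliased = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) validation_error("`y` must be binary (0/1 or logical)")
  if (nrow(x) != length(y)) validation_error("`x` and `y` sizes differ")
  if (any(!is.finite(x))) validation_error("`x` must be finite")
  const <- apply(x, 2, function(v) var(v) == 0)
  if (any(const)) {
    msg <- sprintf("constant non-intercept column(s): %s",
                   paste(colnames(x)[const], collapse = ", "))
    if (drop_aliased) {
      warning(paste(msg, "- dropped"))
      x <- x[, !const, drop = FALSE]
    } else {
      validation_error(msg)
    }
  }
  n <- nrow(x)
  if (n <= ncol(x) + 1L) validation_error("need more observations than model terms")

  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  X <- cbind(`(Intercept)` = 1, xs)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    msg <- sprintf("singular information: collinear column(s) %s",
                   paste(bad, collapse = ", "))
    if (!drop_aliased) validation_error(msg)
    warning(paste(msg, "- dropped"))
    keep <- setdiff(colnames(X), bad)
    X <- X[, keep, drop = FALSE]
    keep_x <- setdiff(keep, "(Intercept)")
    ctr <- ctr[keep_x]; scl <- scl[keep_x]
    x <- x[, keep_x, drop = FALSE]
  }
  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  repeat {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X)
    delta <- tryCatch(solve(H, score), error = function(e) {
      validation_error("singular information matrix during IRLS")
    })
    # step-halving for stability on steep likelihoods
    step <- 1
    ll0 <- sum(dbinom(y, 1, mu, log = TRUE))
    repeat {
      cand <- beta + step * delta
      mu_c <- plogis(drop(X %*% cand))
      ll_c <- sum(dbinom(y, 1, pmin(pmax(mu_c, 1e-12), 1 - 1e-12), log = TRUE))
      if (ll_c >= ll0 - 1e-12 || step < 1 / 64) break
      step <- step / 2
    }
    beta <- beta + step * delta
    iter <- iter + 1L
    if (max(abs(beta[-1])) > 15 || abs(beta[1]) > 30) {
      separation <- TRUE
      break
    }
  }
  mu <- plogis(drop(X %*% beta))
  loglik <- sum(dbinom(y, 1, pmin(pmax(mu, 1e-12), 1 - 1e-12), log = TRUE))
  # back-transform to the original predictor scale
  b_std <- beta[-1]
  b_orig <- b_std / scl
  a_orig <- beta[1] - sum(b_std * ctr / scl)
  est <- c(a_orig, b_orig)
  terms <- c("(Intercept)", colnames(x))
  Xo <- cbind(1, x)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(Xo * w, Xo)
  se <- rep(NA_real_, length(est))
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  report <- converged && !separation
  z <- est / se
  coefs <- data.frame(
    term = terms, estimate = est, se = se,
    odds_ratio = if (report) exp(est) else NA_real_,
    ci_lower = if (report) exp(est - 1.96 * se) else NA_real_,
    ci_upper = if (report) exp(est + 1.96 * se) else NA_real_,
    p_value = if (report) 2 * pnorm(-abs(z)) else NA_real_,
    stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs, converged = converged,
                 separation = separation, iterations = iter,
                 loglik = loglik, fitted = mu, terms = terms),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %d terms, loglik %.3f, %s%s\n",
              length(x$terms), x$loglik,
              if (x$converged) "converged" else "NOT converged",
              if (x$separation) " [quasi-complete separation]" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Predicted probabilities from a logistic fit
#'
#' @param object a `logistic_fit`.
#' @param newdata matrix or data.frame holding the fit's predictor
#'   columns.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  vars <- setdiff(object$terms, "(Intercept)")
  X <- cbind(1, as.matrix(as.data.frame(newdata)[, vars, drop = FALSE]))
  plogis(drop(X %*% object$coefficients$estimate))
}

delong_components <- function(scores, pos) {
  psi <- outer(scores[pos], scores[!pos],
               function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' C-statistic (AUC) with DeLong variance
#'
#' AUC by the Mann-Whitney estimator with ties counted one half; variance
#' from the DeLong structural components; 95% CI by normal approximation
#' truncated to \[0, 1\].
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (logical, 0/1, or two levels); the larger /
#'   `TRUE` level is the positive class.
#' @return an object of class `auc_result`: `auc`, `var`, `ci`, `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  if (length(scores) != length(pos) || any(!is.finite(scores))) {
    validation_error("`scores` must be finite and match `labels` in length")
  }
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L) validation_error("both classes must be present")
  dc <- delong_components(scores, pos)
  v <- if (m > 1L) var(dc$v10) / m else 0
  v <- v + if (n > 1L) var(dc$v01) / n else 0
  half <- 1.96 * sqrt(v)
  structure(list(auc = dc$auc, var = v,
                 ci = c(max(0, dc$auc - half), min(1, dc$auc + half)),
                 n_pos = m, n_neg = n),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> AUC %.3f (95%% CI %.3f, %.3f), n+ = %d, n- = %d\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  u <- sort(unique(labels))
  if (length(u) > 2L) validation_error("`labels` must have two levels")
  labels == u[length(u)]
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two score vectors computed on the same
#' cases: z = (AUC_A - AUC_B) / sqrt(var_A + var_B - 2 cov_AB), with
#' variances and covariance from the DeLong structural components, and a
#' two-sided normal p-value. A zero variance of the difference (e.g.
#' identical or rank-identical scores) yields p = 1 with a degeneracy
#' flag.
#'
#' @param scores_a,scores_b score vectors on the same cases.
#' @param labels binary labels (see [roc_auc()]).
#' @return list with `auc_a`, `auc_b`, `diff`, `var_diff`, `z`, `p_value`,
#'   `degenerate`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  pos <- as_binary_labels(labels)
  if (length(scores_a) != length(pos) || length(scores_b) != length(pos)) {
    validation_error("score vectors must match `labels` in length")
  }
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L) validation_error("both classes must be present")
  da <- delong_components(scores_a, pos)
  db <- delong_components(scores_b, pos)
  vd <- 0
  if (m > 1L) vd <- vd + var(da$v10 - db$v10) / m
  if (n > 1L) vd <- vd + var(da$v01 - db$v01) / n
  d <- da$auc - db$auc
  if (vd < 1e-14) {
    return(list(auc_a = da$auc, auc_b = db$auc, diff = d, var_diff = vd,
                z = 0, p_value = 1, degenerate = TRUE))
  }
  z <- d / sqrt(vd)
  list(auc_a = da$auc, auc_b = db$auc, diff = d, var_diff = vd,
       z = z, p_value = 2 * pnorm(-abs(z)), degenerate = FALSE)
}
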