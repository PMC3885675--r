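clinical_ct_candidates <- function(df) {
  intersect(c("age", "male", "smoker", "wbc", "eos", "eosinophilia", "crp",
              "lesion_size_mm", "solid_size_mm", "solid_prop_pct",
              "multiple"),
            names(df))
}

texture_candidates <- function(df) {
  cand <- intersect(c("whole_mean", "whole_sd", "whole_skewness",
                      "whole_kurtosis", "atten_ratio",
                      "whole_p5", "whole_p10", "whole_p25", "whole_p50",
                      "whole_p75", "whole_p95",
                      "solid_p75", "solid_p95", "sigmoid_slope"),
                    names(df))
  # candidates must be complete: features undefined for some nodules
  # (guarded attenuation ratio, skipped sigmoid slope) are excluded
  cand[vapply(cand, function(p) all(is.finite(as.numeric(df[[p]]))),
              logical(1))]
}

numeric_design <- function(df, vars) {
  X <- vapply(vars, function(p) {
    v <- df[[p]]
    if (is.logical(v)) as.numeric(v) else as.numeric(v)
  }, numeric(nrow(df)))
  X <- matrix(X, nrow = nrow(df), dimnames = list(NULL, vars))
  X
}

group_summary_row <- function(df, var, y) {
  v <- df[[var]]
  if (is.logical(v)) {
    tab <- table(factor(v, levels = c(FALSE, TRUE)),
                 factor(y, levels = c(TRUE, FALSE)))
    data.frame(variable = var,
               transient = sprintf("%d:%d", tab[1, 1], tab[2, 1]),
               persistent = sprintf("%d:%d", tab[1, 2], tab[2, 2]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(variable = var,
               transient = sprintf("%.1f +/- %.1f", mean(v[y]), sd(v[y])),
               persistent = sprintf("%.1f +/- %.1f", mean(v[!y]), sd(v[!y])),
               stringsAsFactors = FALSE)
  }
}

#' Run the full three-model discrimination comparison
#'
#' Reproduces the analysis pipeline end to end on a per-nodule cohort
#' table: one nodule is selected per patient; candidate clinical/CT and
#' texture predictors are screened univariately at `alpha`; one
#' enter-method multivariate logistic model is fit per predictor set
#' (clinical+CT, texture, combined = union of the two screened sets);
#' in-sample predicted probabilities give each model's C-statistic, and
#' the three AUCs are compared pairwise with the DeLong test. When both
#' the raw eosinophil count and the derived eosinophilia flag pass
#' screening, only the flag enters the models (the count and its
#' threshold flag carry the same information). On cohorts too small for
#' the screened set, each model keeps the predictors with the smallest
#' screening p-values, capped at two fewer terms than patients, so the
#' likelihood remains estimable. Optionally, a k-fold
#' cross-validated AUC is computed per model as an honest complement to
#' the in-sample C-statistic.
#'
#' @param cohort per-nodule `data.frame` with `patient_id`, `group`,
#'   clinical/CT columns and texture-feature columns (e.g. the merge of
#'   [generate_cohort()]'s table with [extract_cohort_features()]).
#' @param seed integer seed (nodule selection and CV folds).
#' @param alpha univariate screening threshold.
#' @param cv_folds number of cross-validation folds (0 = no CV).
#' @return an object of class `psn_model_comparison`: screening tables,
#'   the three `logistic_fit`s, `auc_result`s, pairwise DeLong
#'   comparisons, group-summary tables and bookkeeping.
#' @export
run_model_comparison <- function(cohort, seed = 1, alpha = 0.05,
                                 cv_folds = 0) {
  if (is.null(cohort$group) || is.null(cohort$patient_id)) {
    validation_error("`cohort` needs group and patient_id columns")
  }
  sel <- select_one_per_patient(cohort, seed)
  y <- sel$group == "transient"
  if (!any(y) || all(y)) validation_error("both groups must be present after selection")

  cand_cc <- clinical_ct_candidates(sel)
  cand_tx <- texture_candidates(sel)
  scr_cc <- withCallingHandlers(
    univariate_screen(sel, cand_cc, alpha),
    warning = function(w) invokeRestart("muffleWarning"))
  scr_tx <- withCallingHandlers(
    univariate_screen(sel, cand_tx, alpha),
    warning = function(w) invokeRestart("muffleWarning"))

  set_cc <- scr_cc$selected
  if (all(c("eos", "eosinophilia") %in% set_cc)) {
    set_cc <- setdiff(set_cc, "eos")
  }
  set_tx <- scr_tx$selected
  sets <- list(clinical_ct = set_cc, texture = set_tx,
               combined = union(set_cc, set_tx))

  # a logistic model needs fewer terms than observations; on small
  # cohorts keep the predictors with the smallest screening p-values
  scr_all <- rbind(scr_cc$table, scr_tx$table)
  p_of <- setNames(scr_all$p_value, scr_all$predictor)
  cap <- nrow(sel) - 2L
  sets <- lapply(sets, function(vars) {
    if (length(vars) > cap) vars <- vars[order(p_of[vars])][seq_len(cap)]
    vars
  })

  fit_one <- function(vars) {
    if (length(vars) == 0L) return(NULL) # intercept-only: AUC 0.5
    X <- numeric_design(sel, vars)
    withCallingHandlers(
      logistic_fit(X, y, drop_aliased = TRUE),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  fits <- lapply(sets, fit_one)
  scores <- lapply(seq_along(sets), function(i) {
    if (is.null(fits[[i]])) rep(0.5, nrow(sel)) else fits[[i]]$fitted
  })
  names(scores) <- names(sets)
  aucs <- lapply(scores, roc_auc, labels = y)

  pair_names <- list(c("combined", "clinical_ct"),
                     c("combined", "texture"),
                     c("texture", "clinical_ct"))
  delong <- do.call(rbind, lapply(pair_names, function(pr) {
    dc <- delong_compare(scores[[pr[1]]], scores[[pr[2]]], y)
    data.frame(model_a = pr[1], model_b = pr[2],
               auc_a = dc$auc_a, auc_b = dc$auc_b, diff = dc$diff,
               z = dc$z, p_value = dc$p_value,
               degenerate = dc$degenerate, stringsAsFactors = FALSE)
  }))

  cv_auc <- NULL
  if (cv_folds > 0) {
    cv_auc <- vapply(names(sets), function(sn) {
      vars <- sets[[sn]]
      if (length(vars) == 0L) return(0.5)
      cv_logistic_auc(sel, vars, y, cv_folds, seed)
    }, numeric(1))
  }

  summaries <- list(
    clinical_ct = do.call(rbind, lapply(cand_cc, group_summary_row,
                                        df = sel, y = y)),
    texture = do.call(rbind, lapply(cand_tx, group_summary_row,
                                    df = sel, y = y)))

  structure(list(screening = list(clinical_ct = scr_cc$table,
                                  texture = scr_tx$table),
                 predictor_sets = sets, models = fits, auc = aucs,
                 delong = delong, cv_auc = cv_auc, summaries = summaries,
                 n = nrow(sel), n_transient = sum(y),
                 n_persistent = sum(!y), seed = seed, alpha = alpha),
            class = "psn_model_comparison")
}

cv_logistic_auc <- function(sel, vars, y, folds, seed) {
  X <- numeric_design(sel, vars)
  fold_of <- withr::with_seed(derive_seed(seed, 31), {
    sample(rep_len(seq_len(folds), nrow(sel)))
  })
  pred <- rep(NA_real_, nrow(sel))
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    if (length(unique(y[tr])) < 2L) next
    ft <- tryCatch(
      withCallingHandlers(
        logistic_fit(X[tr, , drop = FALSE], y[tr], drop_aliased = TRUE),
        warning = function(w) invokeRestart("muffleWarning")),
      psn_error = function(e) NULL)
    if (is.null(ft)) next
    pred[!tr] <- predict(ft, as.data.frame(X[!tr, , drop = FALSE]))
  }
  ok <- !is.na(pred)
  if (sum(y[ok]) == 0L || sum(!y[ok]) == 0L) return(NA_real_)
  roc_auc(pred[ok], y[ok])$auc
}

#' @export
print.psn_model_comparison <- function(x, ...) {
  cat(sprintf("<psn_model_comparison> %d patients (%d transient / %d persistent), alpha = %g\n",
              x$n, x$n_transient, x$n_persistent, x$alpha))
  for (nm in names(x$auc)) {
    a <- x$auc[[nm]]
    cat(sprintf("  AUC %-12s %.3f (95%% CI %.3f, %.3f)  [%s]\n", nm, a$auc,
                a$ci[1], a$ci[2],
                paste(x$predictor_sets[[nm]], collapse = ", ")))
  }
  cat("  DeLong pairwise:\n")
  for (i in seq_len(nrow(x$delong))) {
    cat(sprintf("    %s vs %s: dAUC %+.3f, p = %.4g\n",
                x$delong$model_a[i], x$delong$model_b[i],
                x$delong$diff[i], x$delong$p_value[i]))
  }
  if (!is.null(x$cv_auc)) {
    cat("  cross-validated AUC:",
        paste(sprintf("%s %.3f", names(x$cv_auc), x$cv_auc),
              collapse = ", "), "\n")
  }
  invisible(x)
}
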