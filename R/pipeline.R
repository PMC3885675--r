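#' Build a validated pipeline run configuration
#'
#' A single configuration object drives the simulate / extract / analyze
#' stages. All randomness flows from one master seed via named substreams
#' per stage; there are no wall-clock defaults.
#'
#' @param out_dir output directory for all stages.
#' @param n_transient,n_persistent group sizes (nodules).
#' @param seed master integer seed.
#' @param alpha univariate screening threshold.
#' @param sigmoid compute the sigmoid fitting slope during extraction.
#' @param cv_folds cross-validation folds for the analysis stage (0 =
#'   in-sample only).
#' @param image_params,clinical_params optional per-group parameter lists
#'   (defaults: calibrated presets).
#' @return an object of class `psn_config`.
#' @export
psn_config <- function(out_dir, n_transient = 39, n_persistent = 47,
                       seed = 1, alpha = 0.05, sigmoid = FALSE,
                       cv_folds = 0, image_params = NULL,
                       clinical_params = NULL) {
  check_number(n_transient, "n_transient", lower = 1)
  check_number(n_persistent, "n_persistent", lower = 1)
  check_number(seed, "seed")
  check_prob(alpha, "alpha")
  check_number(cv_folds, "cv_folds", lower = 0)
  if (!is.character(out_dir) || length(out_dir) != 1L) {
    validation_error("`out_dir` must be a single path")
  }
  structure(list(out_dir = out_dir, n_transient = n_transient,
                 n_persistent = n_persistent, seed = seed, alpha = alpha,
                 sigmoid = isTRUE(sigmoid), cv_folds = cv_folds,
                 image_params = image_params,
                 clinical_params = clinical_params),
            class = "psn_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [psn_config()]; `out_dir` and `seed` are required.
#' @return a `psn_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) psn_error(sprintf("no such config file: %s", path),
                                    "psn_io_error")
  raw <- yaml::read_yaml(path)
  if (is.null(raw$out_dir) || is.null(raw$seed)) {
    validation_error("config must set `out_dir` and `seed` explicitly")
  }
  do.call(psn_config, raw[intersect(names(raw), names(formals(psn_config)))])
}

config_echo <- function(config) {
  config[c("n_transient", "n_persistent", "seed", "alpha", "sigmoid",
           "cv_folds")]
}

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    psn_error(sprintf("[%s] %s", stage, conditionMessage(e)),
              "psn_stage_error")
  })
}

#' Pipeline stage: simulate a cohort to disk
#'
#' @param config a [psn_config()].
#' @return path of the cohort directory, invisibly.
#' @export
psn_simulate <- function(config) {
  stopifnot(inherits(config, "psn_config"))
  stage_wrap("simulate", {
    dir <- file.path(config$out_dir, "cohort")
    generate_cohort(config$n_transient, config$n_persistent,
                    image_params = config$image_params,
                    clinical_params = config$clinical_params,
                    seed = derive_seed(config$seed, 101), dir = dir)
    invisible(dir)
  })
}

#' Pipeline stage: extract texture features from a cohort on disk
#'
#' Runs on any conformant image + annotation set, not only simulated
#' cohorts.
#'
#' @param config a [psn_config()]; reads `<out_dir>/cohort`, writes
#'   `<out_dir>/features/features.csv`.
#' @return path of the feature CSV, invisibly.
#' @export
psn_extract <- function(config) {
  stopifnot(inherits(config, "psn_config"))
  stage_wrap("extract", {
    cohort <- read_cohort(file.path(config$out_dir, "cohort"))
    feats <- extract_cohort_features(cohort, sigmoid = config$sigmoid)
    fdir <- file.path(config$out_dir, "features")
    dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
    out <- file.path(fdir, "features.csv")
    write.csv(feats, out, row.names = FALSE)
    write_manifest(fdir, "extract", config_echo(config))
    invisible(out)
  })
}

#' Pipeline stage: run the statistical analysis and write the report
#'
#' Joins the cohort table with the extracted features and runs
#' [run_model_comparison()]. The report directory holds screening and
#' coefficient CSVs, group-summary CSVs, an AUC/DeLong JSON, and a
#' deterministic run log.
#'
#' @param config a [psn_config()].
#' @return the `psn_model_comparison`, invisibly.
#' @export
psn_analyze <- function(config) {
  stopifnot(inherits(config, "psn_config"))
  stage_wrap("analyze", {
    tab <- read.csv(file.path(config$out_dir, "cohort", "nodules.csv"),
                    stringsAsFactors = FALSE)
    feats <- read.csv(file.path(config$out_dir, "features", "features.csv"),
                      stringsAsFactors = FALSE)
    merged <- merge(tab, feats[, setdiff(names(feats), "patient_id")],
                    by = "nodule_id", sort = TRUE)
    res <- run_model_comparison(merged, seed = derive_seed(config$seed, 202),
                                alpha = config$alpha,
                                cv_folds = config$cv_folds)
    rdir <- file.path(config$out_dir, "report")
    dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(res$screening$clinical_ct,
              file.path(rdir, "screening_clinical_ct.csv"), row.names = FALSE)
    write.csv(res$screening$texture,
              file.path(rdir, "screening_texture.csv"), row.names = FALSE)
    write.csv(res$summaries$clinical_ct,
              file.path(rdir, "summary_clinical_ct.csv"), row.names = FALSE)
    write.csv(res$summaries$texture,
              file.path(rdir, "summary_texture.csv"), row.names = FALSE)
    for (nm in names(res$models)) {
      if (!is.null(res$models[[nm]])) {
        write.csv(res$models[[nm]]$coefficients,
                  file.path(rdir, paste0("model_", nm, ".csv")),
                  row.names = FALSE)
      }
    }
    auc_obj <- lapply(res$auc, function(a) {
      list(auc = a$auc, var = a$var, ci = a$ci, n_pos = a$n_pos,
           n_neg = a$n_neg)
    })
    jsonlite::write_json(list(auc = auc_obj, delong = res$delong,
                              cv_auc = as.list(res$cv_auc)),
                         file.path(rdir, "auc.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    log_lines <- c(
      sprintf("psntexture %s", as.character(utils::packageVersion("psntexture"))),
      sprintf("seed: %s", format(config$seed)),
      sprintf("alpha: %g | sigmoid: %s | cv_folds: %g", config$alpha,
              config$sigmoid, config$cv_folds),
      sprintf("patients analyzed: %d (%d transient / %d persistent)",
              res$n, res$n_transient, res$n_persistent),
      vapply(names(res$auc), function(nm) {
        sprintf("auc %s: %.6f", nm, res$auc[[nm]]$auc)
      }, character(1)))
    writeLines(log_lines, file.path(rdir, "run.log"))
    write_manifest(rdir, "analyze", config_echo(config))
    invisible(res)
  })
}

#' Run the full pipeline: simulate, extract, analyze
#'
#' @param config a [psn_config()].
#' @return the `psn_model_comparison` from the analysis stage, invisibly.
#' @export
psn_run_all <- function(config) {
  psn_simulate(config)
  psn_extract(config)
  psn_analyze(config)
}
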