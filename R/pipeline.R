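#' Full-protocol configuration
#'
#' Everything needed to reproduce a run from the config and master seed
#' alone; serializable to YAML via [save_pipeline_config()].
#'
#' @param cohort Either a [measurement_table()], a CSV path readable by
#'   [read_cohort()], or `NULL` to generate a synthetic cohort from `spec`.
#' @param spec A [dimorphism_spec()] used when `cohort` is `NULL`.
#'   Default [femur_dimorphism_spec()].
#' @param n_per_sex Synthetic cohort size per sex (used when generating).
#'   Default 150.
#' @param train_fraction Training share of the initial split. Default 0.8.
#' @param cv A [cv_config()]. Default 50 iterations at 70/30.
#' @param classifiers List of [classifier_spec()]s. Default all four kinds.
#' @param top_k Number of top-ranked variables for the univariate models.
#'   Default 5.
#' @param target_level ABC target. Default 0.95.
#' @param run_sweep Also run the sample-size sweep. Default `FALSE`.
#' @param sweep_replicates Replicates per sweep cell. Default 5.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, spec = femur_dimorphism_spec(),
                            n_per_sex = 150L, train_fraction = 0.8,
                            cv = cv_config(), classifiers = default_classifiers(),
                            top_k = 5L, target_level = 0.95,
                            run_sweep = FALSE, sweep_replicates = 5L,
                            seed = 1L) {
  stopifnot(top_k >= 1, target_level > 0.5, target_level < 1)
  structure(list(cohort = cohort, spec = spec, n_per_sex = as.integer(n_per_sex),
                 train_fraction = train_fraction, cv = cv,
                 classifiers = classifiers, top_k = as.integer(top_k),
                 target_level = target_level, run_sweep = isTRUE(run_sweep),
                 sweep_replicates = as.integer(sweep_replicates),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Save a pipeline configuration as YAML
#'
#' Only scalar settings are serialized (a cohort given as an in-memory table
#' is written alongside as CSV and referenced by path).
#'
#' @param config A [pipeline_config()].
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
save_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort_path <- NULL
  if (inherits(config$cohort, "measurement_table")) {
    cohort_path <- sub("\\.ya?ml$", ".cohort.csv", path)
    write_cohort(config$cohort, cohort_path)
  } else if (is.character(config$cohort)) {
    cohort_path <- config$cohort
  }
  obj <- list(
    cohort = cohort_path,
    correlation = if (is.matrix(config$spec$correlation))
      config$spec$correlation[1, 2] else config$spec$correlation[1, 2],
    n_per_sex = config$n_per_sex,
    train_fraction = config$train_fraction,
    cv = list(n_iterations = config$cv$n_iterations,
              calibration_fraction = config$cv$calibration_fraction,
              seed = config$cv$seed),
    classifiers = vapply(config$classifiers, `[[`, character(1), "kind"),
    top_k = config$top_k,
    target_level = config$target_level,
    run_sweep = config$run_sweep,
    sweep_replicates = config$sweep_replicates,
    seed = config$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML path written by [save_pipeline_config()] (or hand
#'   written with the same fields).
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- if (is.null(obj$classifiers)) c("LR", "LDA", "GLMB", "SVM")
         else obj$classifiers
  pipeline_config(
    cohort = obj$cohort,
    spec = femur_dimorphism_spec(correlation = obj$correlation %||% 0.6),
    n_per_sex = obj$n_per_sex %||% 150L,
    train_fraction = obj$train_fraction %||% 0.8,
    cv = cv_config(obj$cv$n_iterations %||% 50L,
                   obj$cv$calibration_fraction %||% 0.7,
                   obj$cv$seed %||% 1L),
    classifiers = stats::setNames(lapply(cls, classifier_spec), cls),
    top_k = obj$top_k %||% 5L,
    target_level = obj$target_level %||% 0.95,
    run_sweep = obj$run_sweep %||% FALSE,
    sweep_replicates = obj$sweep_replicates %||% 5L,
    seed = obj$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end ABC protocol
#'
#' Executes: cohort acquisition (read or generate) -> stratified train/test
#' split -> sexual-dimorphism summary -> ROC ranking of all variables (top-k
#' retained for univariate models) -> per classifier: k univariate LGOCV
#' evaluations at threshold 0.5, an RFE-selected multivariate model, an ABC
#' threshold search on the pooled validation posteriors, and the application
#' of those thresholds to the held-out test set via a model refit on the
#' full training set -> optional sample-size sweep.
#'
#' @param config A [pipeline_config()].
#' @return List of class `protocol_bundle` with components `cohort`,
#'   `train`, `test`, `dimorphism`, `importance`, `models` (per classifier:
#'   univariate and multivariate results), `sweep` (or `NULL`), `config`,
#'   `log` (seeds consumed per stage).
#' @export
run_full_protocol <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list(master_seed = config$seed)
  cohort <- config$cohort
  if (is.null(cohort)) {
    log$cohort_seed <- derive_seed(config$seed, 11L)
    cohort <- generate_cohort(config$spec, config$n_per_sex,
                              seed = log$cohort_seed)
  } else if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
  }
  log$split_seed <- derive_seed(config$seed, 12L)
  parts <- stratified_split(cohort, config$train_fraction,
                            seed = log$split_seed)
  train <- parts$train
  test <- parts$test
  dimorphism <- dimorphism_table(train)
  importance <- roc_importance(train)
  top_vars <- utils::head(importance$variable[!is.na(importance$auc)],
                          config$top_k)
  models <- list()
  for (ci in seq_along(config$classifiers)) {
    spec <- config$classifiers[[ci]]
    stage <- function(...) derive_seed(config$seed, 20L + ci, ...)
    uni <- list()
    for (v in top_vars) {
      cvv <- cv_config(config$cv$n_iterations, config$cv$calibration_fraction,
                       stage(1L, match(v, top_vars)))
      ev <- lgocv_evaluate(spec, train, v, cv = cvv)
      abc_tr <- abc_search(ev$pp_pooled, config$target_level)
      model <- fit_classifier(spec, train, v, seed = stage(2L, match(v, top_vars)))
      abc_te <- abc_apply(abc_tr$thresholds, predict_pp(model, test))
      uni[[v]] <- list(variables = v, cv = ev, abc_train = abc_tr,
                       model = model, abc_test = abc_te)
    }
    rfe <- rfe_select(spec, train,
                      cv = cv_config(config$cv$n_iterations,
                                     config$cv$calibration_fraction,
                                     stage(3L)))
    cvm <- cv_config(config$cv$n_iterations, config$cv$calibration_fraction,
                     stage(4L))
    ev_m <- lgocv_evaluate(spec, train, rfe$variables, cv = cvm)
    abc_tr_m <- abc_search(ev_m$pp_pooled, config$target_level)
    model_m <- fit_classifier(spec, train, rfe$variables, seed = stage(5L))
    abc_te_m <- abc_apply(abc_tr_m$thresholds, predict_pp(model_m, test))
    models[[spec$kind]] <- list(
      univariate = uni,
      multivariate = list(variables = rfe$variables, rfe = rfe, cv = ev_m,
                          abc_train = abc_tr_m, model = model_m,
                          abc_test = abc_te_m))
    log[[paste0("classifier_", spec$kind)]] <- "stage seeds derived from master"
  }
  sweep <- NULL
  if (config$run_sweep) {
    log$sweep_seed <- derive_seed(config$seed, 40L)
    sweep <- run_sweep(train, test, config$classifiers, cv = config$cv,
                       target_level = config$target_level,
                       replicates = config$sweep_replicates,
                       seed = log$sweep_seed)
  }
  structure(list(cohort = cohort, train = train, test = test,
                 dimorphism = dimorphism, importance = importance,
                 top_variables = top_vars, models = models, sweep = sweep,
                 config = config, log = log),
            class = "protocol_bundle")
}

metrics_row <- function(label, report, cutoffs = NULL, c_index = NA_real_) {
  row <- data.frame(model = label, stringsAsFactors = FALSE)
  if (!is.null(cutoffs)) {
    row$cutoff_male <- cutoffs$cutoff_male
    row$cutoff_female <- cutoffs$cutoff_female
    row$pct_classified_male <- fmt_pct(report$pct_classified_male)
    row$pct_classified_female <- fmt_pct(report$pct_classified_female)
    row$pct_classified_overall <- fmt_pct(report$pct_classified_overall)
  }
  row$accuracy <- fmt_pct(report$accuracy)
  row$sensitivity <- fmt_pct(report$sensitivity)
  row$specificity <- fmt_pct(report$specificity)
  row$ppv <- fmt_pct(report$ppv)
  row$npv <- fmt_pct(report$npv)
  row$c_index <- if (is.na(c_index)) "/" else formatC(c_index, format = "f",
                                                      digits = 3)
  row
}

#' Render the protocol bundle as CSV reports
#'
#' Writes four reports into `dir`: the dimorphism summary
#' (`dimorphism.csv`), the unadjusted cross-validated metrics at threshold
#' 0.5 (`cv_metrics.csv`), the ABC-adjusted cross-validation results with
#' per-sex cutoffs and classified percentages (`abc_train.csv`), and the
#' ABC results on the held-out test set (`abc_test.csv`). Undefined metrics
#' are rendered `"/"`; percentages carry two decimals. If the bundle holds a
#' sweep, its long-format endpoints go to `sweep.csv`.
#'
#' @param bundle A [run_full_protocol()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
render_tables <- function(bundle, dir) {
  stopifnot(inherits(bundle, "protocol_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  dim_out <- bundle$dimorphism
  for (col in setdiff(names(dim_out), "variable")) {
    dim_out[[col]] <- round(dim_out[[col]], 4)
  }
  f <- file.path(dir, "dimorphism.csv")
  utils::write.csv(dim_out, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  cv_rows <- list()
  tr_rows <- list()
  te_rows <- list()
  for (kind in names(bundle$models)) {
    mk <- bundle$models[[kind]]
    all_fits <- c(mk$univariate, list(multivariate = mk$multivariate))
    for (lbl in names(all_fits)) {
      fit <- all_fits[[lbl]]
      label <- paste(kind, if (lbl == "multivariate")
        paste0("multivariate[", paste(fit$variables, collapse = "+"), "]")
        else lbl, sep = ":")
      rep_cv <- fit$cv$report
      cv_rows[[label]] <- metrics_row(label, rep_cv,
                                      c_index = rep_cv$c_index)
      tr_rows[[label]] <- metrics_row(label, fit$abc_train$report,
                                      cutoffs = fit$abc_train$thresholds,
                                      c_index = rep_cv$c_index)
      te <- fit$abc_test
      te_pp <- tryCatch(c_index(predict_pp(fit$model, bundle$test)),
                        error = function(e) NA_real_)
      te_rows[[label]] <- metrics_row(label, te$report,
                                      cutoffs = te$thresholds,
                                      c_index = te_pp)
    }
  }
  for (pair in list(list("cv_metrics.csv", cv_rows),
                    list("abc_train.csv", tr_rows),
                    list("abc_test.csv", te_rows))) {
    f <- file.path(dir, pair[[1]])
    utils::write.csv(do.call(rbind, pair[[2]]), f, row.names = FALSE,
                     quote = FALSE)
    files <- c(files, f)
  }
  if (!is.null(bundle$sweep)) {
    f <- file.path(dir, "sweep.csv")
    utils::write.csv(bundle$sweep$endpoints, f, row.names = FALSE,
                     quote = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
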