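#' Training-sample-size sweep grid
#'
#' Fractions 0.10 to 1.00 in steps of 0.05 of the training size, each
#' rounded to the nearest even count (keeping the sexes balanced) and capped
#' at the training size. A 240-specimen training set yields 19 sizes from
#' 24 to 240.
#'
#' @param train_n Training-set size (>= 20).
#' @return Data frame of class `sweep_grid` with `fraction` and `size`.
#' @export
build_grid <- function(train_n) {
  if (train_n < 20) stop("training set too small for a size sweep")
  fractions <- seq(0.10, 1.00, by = 0.05)
  sizes <- pmin(2 * round(fractions * train_n / 2), train_n)
  structure(data.frame(fraction = fractions, size = as.integer(sizes)),
            class = c("sweep_grid", "data.frame"))
}

sweep_cell <- function(train, test, spec, cv, target_level, size, seed) {
  sub <- stratified_subsample(train, size, seed = derive_seed(seed, 1L))
  rfe <- rfe_select(spec, sub, cv = cv_config(cv$n_iterations,
                                              cv$calibration_fraction,
                                              derive_seed(seed, 2L)))
  ev <- lgocv_evaluate(spec, sub, rfe$variables,
                       cv = cv_config(cv$n_iterations,
                                      cv$calibration_fraction,
                                      derive_seed(seed, 3L)))
  abc_train <- abc_search(ev$pp_pooled, target_level)
  model <- fit_classifier(spec, sub, rfe$variables,
                          seed = derive_seed(seed, 4L))
  abc_test <- abc_apply(abc_train$thresholds, predict_pp(model, test))
  list(variables = rfe$variables, thresholds = abc_train$thresholds,
       train_abc = abc_train, test_abc = abc_test)
}

#' Run the training-sample-size robustness sweep
#'
#' For every grid size, classifier and replicate: draw a balanced stratified
#' subsample of the training set, select variables by RFE, evaluate by
#' Monte-Carlo cross-validation, search ABC thresholds on the pooled
#' validation posteriors, then refit on the full subsample and apply the
#' thresholds to the fixed test set. All cell seeds derive deterministically
#' from the master seed; failed cells (degenerate small-sample fits) are
#' recorded with their error message rather than aborting the sweep.
#'
#' @param train,test Disjoint [measurement_table()]s; the test set is
#'   identical across all cells.
#' @param classifiers List of [classifier_spec()]s (default: all four kinds).
#' @param cv A [cv_config()] for the per-cell resampling.
#' @param target_level ABC target. Default 0.95.
#' @param replicates Independent subsample draws per cell. Default 5;
#'   replicate 1 mirrors a single-draw protocol.
#' @param seed Master seed.
#' @param sizes Optional subset of grid sizes to run (default: full grid).
#' @return List of class `sweep_result`: `grid`, `endpoints` (long data
#'   frame: size, classifier, replicate, endpoint, value), `cells`,
#'   `failures`.
#' @export
run_sweep <- function(train, test, classifiers = default_classifiers(),
                      cv = cv_config(25L), target_level = 0.95,
                      replicates = 5L, seed = 1L, sizes = NULL) {
  stopifnot(length(intersect(train$ids, test$ids)) == 0)
  grid <- build_grid(n_specimens(train))
  run_sizes <- if (is.null(sizes)) grid$size else as.integer(sizes)
  stopifnot(all(run_sizes %in% grid$size))
  cells <- list()
  failures <- list()
  rows <- list()
  for (si in seq_along(run_sizes)) {
    size <- run_sizes[si]
    for (ci in seq_along(classifiers)) {
      spec <- classifiers[[ci]]
      for (rep in seq_len(replicates)) {
        key <- paste(size, spec$kind, rep, sep = ".")
        cell_seed <- derive_seed(seed, match(size, grid$size), ci, rep)
        cell <- tryCatch(
          sweep_cell(train, test, spec, cv, target_level, size, cell_seed),
          error = function(e) e)
        if (inherits(cell, "error")) {
          failures[[key]] <- conditionMessage(cell)
          next
        }
        cells[[key]] <- cell
        r_tr <- cell$train_abc$report
        r_te <- cell$test_abc$report
        vals <- c(cutoff_male = cell$thresholds$cutoff_male,
                  cutoff_female = cell$thresholds$cutoff_female,
                  pct_classified_male = r_tr$pct_classified_male,
                  pct_classified_female = r_tr$pct_classified_female,
                  pct_classified_overall = r_tr$pct_classified_overall,
                  test_pct_classified_male = r_te$pct_classified_male,
                  test_pct_classified_female = r_te$pct_classified_female,
                  test_pct_classified_overall = r_te$pct_classified_overall,
                  test_accuracy = r_te$accuracy)
        rows[[key]] <- data.frame(size = size, classifier = spec$kind,
                                  replicate = rep,
                                  endpoint = names(vals),
                                  value = unname(vals),
                                  stringsAsFactors = FALSE)
      }
    }
  }
  endpoints <- if (length(rows)) do.call(rbind, rows) else
    data.frame(size = integer(0), classifier = character(0),
               replicate = integer(0), endpoint = character(0),
               value = numeric(0))
  rownames(endpoints) <- NULL
  structure(list(grid = grid, endpoints = endpoints, cells = cells,
                 failures = failures, replicates = replicates, seed = seed),
            class = "sweep_result")
}

#' The four default classifier specifications
#'
#' @return Named list of [classifier_spec()]s for LR, LDA, GLMB and SVM.
#' @export
default_classifiers <- function() {
  kinds <- c("LR", "LDA", "GLMB", "SVM")
  stats::setNames(lapply(kinds, classifier_spec), kinds)
}

#' Correlate sweep endpoints with training size
#'
#' Pearson correlation (and its two-sided p-value) between training-set size
#' and each recorded endpoint, per classifier, with a significance flag at
#' p < 0.05. Replicates are averaged per size before correlating. A constant
#' endpoint has an undefined correlation, reported as `NA`.
#'
#' @param sweep A [run_sweep()] result with >= 3 grid points.
#' @return Data frame: `classifier`, `endpoint`, `r`, `p`, `significant`.
#' @export
endpoint_correlations <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  ep <- sweep$endpoints
  out <- list()
  for (cls in unique(ep$classifier)) {
    for (e in unique(ep$endpoint)) {
      d <- ep[ep$classifier == cls & ep$endpoint == e & !is.na(ep$value), ]
      if (nrow(d) == 0) next
      m <- stats::aggregate(value ~ size, data = d, FUN = mean)
      if (nrow(m) < 3) next
      if (stats::sd(m$value) == 0 || stats::sd(m$size) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(m$size, m$value, method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[paste(cls, e)]] <- data.frame(
        classifier = cls, endpoint = e, r = r, p = p,
        significant = !is.na(p) && p < 0.05, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
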