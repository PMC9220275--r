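#' Monte-Carlo (leave-group-out) cross-validation configuration
#'
#' @param n_iterations Number of random calibration/validation splits.
#'   Default 50.
#' @param calibration_fraction Proportion of the training sample used for
#'   calibration at each iteration (stratified by sex). Default 0.7.
#' @param seed Integer seed; iteration k uses a seed derived from it.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_iterations = 50L, calibration_fraction = 0.7,
                      seed = 1L) {
  stopifnot(n_iterations >= 1,
            calibration_fraction > 0, calibration_fraction < 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 calibration_fraction = calibration_fraction,
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Confusion counts (male = positive)
#'
#' @param pred_labels Predicted labels (`"female"`/`"male"`).
#' @param true_sex True labels, same length.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion <- function(pred_labels, true_sex) {
  pred <- factor(as.character(pred_labels), levels = .SEX_LEVELS)
  truth <- factor(as.character(true_sex), levels = .SEX_LEVELS)
  if (length(pred) != length(truth)) stop("length mismatch")
  if (anyNA(pred) || anyNA(truth)) stop("labels must be 'female' or 'male'")
  c(TP = sum(pred == "male" & truth == "male"),
    FP = sum(pred == "male" & truth == "female"),
    TN = sum(pred == "female" & truth == "female"),
    FN = sum(pred == "female" & truth == "male"))
}

#' Confusion-derived performance metrics
#'
#' Accuracy, sensitivity, specificity, PPV and NPV on the 0-100 scale.
#' A metric whose denominator is zero is undefined and reported as `NA`
#' (rendered `"/"` in reports).
#'
#' @param counts Named vector from [confusion()].
#' @return List with `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`
#'   (percentages or `NA`).
#' @export
metrics_from_confusion <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  n <- tp + fp + tn + fn
  if (n < 1) stop("empty confusion")
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(accuracy = rate(tp + tn, n),
       sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp),
       ppv = rate(tp, tp + fp),
       npv = rate(tn, tn + fn))
}

#' Concordance index of a posterior set
#'
#' Probability that a randomly chosen male-female pair is ordered correctly
#' by `pp_male`, counting ties as 1/2 — the Mann-Whitney AUC. Computed via
#' midranks, which is exactly the pair-counting definition.
#'
#' @param pp A [posterior_set()] containing both sexes.
#' @return Concordance in `[0, 1]`.
#' @export
c_index <- function(pp) {
  stopifnot(inherits(pp, "posterior_set"))
  male <- pp$true_sex == "male"
  n1 <- sum(male)
  n0 <- sum(!male)
  if (n1 == 0 || n0 == 0) stop("c-index needs both sexes")
  r <- rank(pp$pp_male)  # midranks handle ties as 0.5 per pair
  (sum(r[male]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Trapezoidal area under the ROC curve of a raw score. Ties grouped, so the
# trapezoid over a tied block contributes exactly 0.5 per tied pair.
trapezoid_auc <- function(score, male) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  y <- male[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(male))
  fpr <- c(0, fp[last] / sum(!male))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Univariate ROC-based variable importance
#'
#' For each measurement, the area under the ROC curve obtained by using the
#' raw value as a classification score across all cutoffs (trapezoidal
#' rule), folded to `max(auc, 1 - auc)` so importance ignores direction.
#' Variables are returned in descending folded-AUC order; a constant
#' variable has undefined AUC (`NA`) and ranks last.
#'
#' @param train A [measurement_table()] with both sexes.
#' @param top_k Optionally return only the best `top_k` variables.
#' @return Data frame with `variable`, `auc` (folded), `auc_raw`.
#' @export
roc_importance <- function(train, top_k = NULL) {
  stopifnot(inherits(train, "measurement_table"))
  male <- train$sex == "male"
  if (sum(male) < 2 || sum(!male) < 2) stop("need >= 2 specimens per sex")
  auc_raw <- vapply(train$names, function(nm) {
    v <- train$values[, nm]
    if (stats::sd(v) == 0) return(NA_real_)
    trapezoid_auc(v, male)
  }, numeric(1))
  folded <- ifelse(is.na(auc_raw), NA_real_, pmax(auc_raw, 1 - auc_raw))
  out <- data.frame(variable = train$names, auc = folded, auc_raw = auc_raw,
                    stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$auc), -1, out$auc)), ]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}

# Metric averaging across iterations: undefined (NA) values are excluded,
# with the exclusion count reported alongside.
average_metrics <- function(per_iter) {
  avg <- lapply(per_iter, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  excl <- vapply(per_iter, function(v) sum(is.na(v)), integer(1))
  list(mean = avg, n_excluded = excl)
}

#' Monte-Carlo cross-validated evaluation of a classifier
#'
#' At each iteration the training cohort is split (stratified by sex) into
#' calibration and validation subsets; the model is fit on calibration and
#' scored on validation at a fixed posterior threshold. Metrics are averaged
#' arithmetically across iterations (undefined per-iteration metrics are
#' excluded and counted); all validation-fold posteriors are pooled —
#' specimen-level posteriors are what the ABC threshold search consumes.
#'
#' @param spec A [classifier_spec()].
#' @param train A [measurement_table()].
#' @param variables Measurement names to use; default all.
#' @param cv A [cv_config()].
#' @param threshold Fixed classification threshold. Default 0.5.
#' @return List of class `lgocv_result`: `report` (averaged metrics incl.
#'   mean `c_index` and the pooled-posterior overlap percentage),
#'   `pp_pooled` (a [posterior_set()] with iteration-tagged ids),
#'   `n_excluded`, `per_iteration` (data frame), `cv`, `variables`.
#' @export
lgocv_evaluate <- function(spec, train, variables = NULL, cv = cv_config(),
                           threshold = 0.5) {
  stopifnot(inherits(cv, "cv_config"))
  if (is.null(variables)) variables <- train$names
  metrics_names <- c("accuracy", "sensitivity", "specificity", "ppv", "npv",
                     "c_index")
  per_iter <- matrix(NA_real_, cv$n_iterations, length(metrics_names),
                     dimnames = list(NULL, metrics_names))
  ids_all <- character(0)
  sex_all <- character(0)
  pp_all <- numeric(0)
  for (it in seq_len(cv$n_iterations)) {
    cal_idx <- split_indices_by_sex(train$sex, cv$calibration_fraction,
                                    derive_seed(cv$seed, 101L, it))
    val_idx <- setdiff(seq_along(train$ids), cal_idx)
    model <- fit_classifier(spec, subset_rows(train, cal_idx), variables,
                            seed = derive_seed(cv$seed, 103L, it))
    pp <- predict_pp(model, subset_rows(train, val_idx))
    m <- metrics_from_confusion(confusion(classify_at(pp, threshold),
                                          pp$true_sex))
    per_iter[it, ] <- c(unlist(m), c_index(pp))
    ids_all <- c(ids_all, paste0(pp$ids, ".it", it))
    sex_all <- c(sex_all, as.character(pp$true_sex))
    pp_all <- c(pp_all, pp$pp_male)
  }
  pooled <- posterior_set(ids_all, sex_all, pp_all)
  avg <- average_metrics(as.data.frame(per_iter))
  ppo <- tryCatch(
    overlap_index(pp_all[sex_all == "male"],
                  pp_all[sex_all == "female"])$overlap_pct,
    error = function(e) NA_real_)
  report <- c(avg$mean, list(pp_overlap_pct = ppo))
  structure(list(report = report, pp_pooled = pooled,
                 n_excluded = avg$n_excluded,
                 per_iteration = as.data.frame(per_iter),
                 cv = cv, variables = variables),
            class = "lgocv_result")
}

#' Recursive feature elimination by cross-validated accuracy
#'
#' Backward elimination: starting from all variables, each step drops the
#' variable whose removal least degrades the Monte-Carlo cross-validated
#' accuracy (threshold 0.5), evaluating every candidate removal with the
#' same set of resampling splits. All subset sizes down to 1 are profiled
#' and the subset with the highest cross-validated accuracy is returned,
#' ties broken toward fewer variables.
#'
#' @param spec A [classifier_spec()].
#' @param train A [measurement_table()] with >= 2 variables.
#' @param cv A [cv_config()] governing the inner resampling.
#' @return List of class `rfe_result`: `variables` (selected set, in the
#'   original column order), `profile` (data frame of size vs accuracy),
#'   `best_accuracy`.
#' @export
rfe_select <- function(spec, train, cv = cv_config(25L)) {
  stopifnot(inherits(train, "measurement_table"))
  p <- length(train$names)
  if (p < 2) stop("RFE needs at least 2 variables")
  splits <- lapply(seq_len(cv$n_iterations), function(it) {
    cal <- split_indices_by_sex(train$sex, cv$calibration_fraction,
                                derive_seed(cv$seed, 101L, it))
    list(cal = cal, val = setdiff(seq_along(train$ids), cal))
  })
  eval_subset <- function(vars) {
    accs <- vapply(seq_along(splits), function(it) {
      sp <- splits[[it]]
      model <- fit_classifier(spec, subset_rows(train, sp$cal), vars,
                              seed = derive_seed(cv$seed, 103L, it))
      pp <- predict_pp(model, subset_rows(train, sp$val))
      mean(classify_at(pp, 0.5) == pp$true_sex)
    }, numeric(1))
    mean(accs)
  }
  current <- train$names
  profile <- data.frame(size = integer(0), accuracy = numeric(0),
                        variables = character(0), stringsAsFactors = FALSE)
  best_sets <- list()
  acc_full <- eval_subset(current)
  profile[1, ] <- list(p, acc_full, paste(current, collapse = "+"))
  best_sets[[p]] <- current
  while (length(current) > 1) {
    cand_acc <- vapply(current, function(v) {
      eval_subset(setdiff(current, v))
    }, numeric(1))
    drop_var <- current[which.max(cand_acc)]
    current <- setdiff(current, drop_var)
    k <- length(current)
    profile[nrow(profile) + 1, ] <- list(k, max(cand_acc),
                                         paste(current, collapse = "+"))
    best_sets[[k]] <- current
  }
  # highest accuracy wins; ties toward fewer variables
  best <- profile[order(profile$accuracy, -profile$size,
                        decreasing = TRUE), ][1, ]
  structure(list(variables = best_sets[[best$size]],
                 profile = profile[order(profile$size), ],
                 best_accuracy = best$accuracy),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat("rfe_result:", length(x$variables), "variable(s) selected:",
      paste(x$variables, collapse = " + "), "\n")
  cat(sprintf("  cross-validated accuracy %.2f%%\n", 100 * x$best_accuracy))
  invisible(x)
}
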