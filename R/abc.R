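#' ABC per-sex posterior-probability thresholds
#'
#' The pair of reject-option cutoffs produced by [abc_search()]: a specimen
#' is called male if `pp_male >= cutoff_male`, female if
#' `1 - pp_male >= cutoff_female`, and left indeterminate otherwise. Both
#' cutoffs exceed 0.5 (except in the degenerate last-resort case), so the two
#' classification regions never overlap.
#'
#' @param cutoff_male,cutoff_female Posterior cutoffs on the male and female
#'   probability scales.
#' @param target_level Required accuracy/PPV/NPV level in (0.5, 1).
#' @param feasible Whether a cutoff pair meeting all three constraints was
#'   found; infeasible searches carry both cutoffs at 1.
#' @return An object of class `abc_thresholds`.
#' @export
abc_thresholds <- function(cutoff_male, cutoff_female, target_level = 0.95,
                           feasible = TRUE) {
  stopifnot(cutoff_male >= 0.5, cutoff_male <= 1,
            cutoff_female >= 0.5, cutoff_female <= 1,
            target_level > 0.5, target_level < 1)
  structure(list(cutoff_male = cutoff_male, cutoff_female = cutoff_female,
                 target_level = target_level, feasible = isTRUE(feasible)),
            class = "abc_thresholds")
}

#' @export
print.abc_thresholds <- function(x, ...) {
  cat(sprintf(
    "abc_thresholds: male >= %.3f, female >= %.3f (target %.0f%%, %s)\n",
    x$cutoff_male, x$cutoff_female, 100 * x$target_level,
    if (x$feasible) "feasible" else "infeasible"))
  invisible(x)
}

# Classified-subset bookkeeping for a cutoff pair.
abc_partition <- function(pp, cutoff_male, cutoff_female) {
  as_male <- pp$pp_male >= cutoff_male
  as_female <- (1 - pp$pp_male) >= cutoff_female & !as_male
  list(as_male = as_male, as_female = as_female,
       classified = as_male | as_female)
}

abc_metrics <- function(pp, part) {
  truth_male <- pp$true_sex == "male"
  tp <- sum(part$as_male & truth_male)
  fp <- sum(part$as_male & !truth_male)
  tn <- sum(part$as_female & !truth_male)
  fn <- sum(part$as_female & truth_male)
  n_cls <- tp + fp + tn + fn
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  n_m <- sum(truth_male)
  n_f <- sum(!truth_male)
  list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       accuracy = rate(tp + tn, n_cls),
       sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp),
       ppv = rate(tp, tp + fp),
       npv = rate(tn, tn + fn),
       pct_classified_male = rate(sum(part$classified & truth_male), n_m),
       pct_classified_female = rate(sum(part$classified & !truth_male), n_f),
       pct_classified_overall = rate(n_cls, n_m + n_f))
}

# Does the pair satisfy PPV, NPV and accuracy >= target on the classified
# subset? Undefined metrics (empty side) fail the constraint.
abc_ok <- function(m, target) {
  vals <- c(m$ppv, m$npv, m$accuracy)
  !anyNA(vals) && all(vals >= 100 * target - 1e-9)
}

#' ABC threshold search
#'
#' Finds per-sex posterior-probability cutoffs such that accuracy, PPV and
#' NPV on the classified subset all reach `target_level`, leaving the rest
#' indeterminate. Candidate cutoffs are the observed posterior values above
#' 0.5 on each side (so a reported cutoff is always attained by at least one
#' specimen), scanned in ascending order to classify as many specimens as
#' possible: the smallest male cutoff achieving the PPV constraint and the
#' smallest female cutoff achieving the NPV constraint are chosen, then
#' overall accuracy on the union is verified; on violation the side with
#' the lower predictive value advances to its next satisfying candidate and
#' the check repeats. If no pair satisfies all three constraints the result
#' is flagged infeasible with both cutoffs at 1.
#'
#' @param pp A [posterior_set()] containing both sexes (typically the pooled
#'   validation posteriors of [lgocv_evaluate()]).
#' @param target_level Required accuracy/PPV/NPV, in (0.5, 1). Default 0.95.
#' @return List of class `abc_result`: `thresholds` ([abc_thresholds()]),
#'   `report` (metrics on the classified subset, percentages or `NA`, plus
#'   per-sex and overall classified percentages), `classified_ids`,
#'   `indeterminate_ids`, `target_attained`.
#' @export
abc_search <- function(pp, target_level = 0.95) {
  stopifnot(inherits(pp, "posterior_set"))
  if (target_level <= 0.5 || target_level >= 1) {
    stop("target_level must lie in (0.5, 1)")
  }
  if (length(unique(pp$true_sex)) < 2) stop("both sexes required")

  # ascending candidate grids of observed values; 0.5 is a last resort only
  cand_m <- c(sort(unique(pp$pp_male[pp$pp_male > 0.5])), 0.5)
  pf <- 1 - pp$pp_male
  cand_f <- c(sort(unique(pf[pf > 0.5])), 0.5)

  eval_pair <- function(cm, cf) abc_metrics(pp, abc_partition(pp, cm, cf))
  side_ok_m <- function(cm) {
    m <- abc_metrics(pp, abc_partition(pp, cm, 2))  # cf = 2: nobody female
    !is.na(m$ppv) && m$ppv >= 100 * target_level - 1e-9
  }
  side_ok_f <- function(cf) {
    m <- abc_metrics(pp, abc_partition(pp, 2, cf))
    !is.na(m$npv) && m$npv >= 100 * target_level - 1e-9
  }
  ok_m <- which(vapply(cand_m, side_ok_m, logical(1)))
  ok_f <- which(vapply(cand_f, side_ok_f, logical(1)))
  if (length(ok_m) == 0 || length(ok_f) == 0) {
    return(abc_build_result(pp, abc_thresholds(1, 1, target_level, FALSE)))
  }
  i_m <- 1L
  i_f <- 1L
  repeat {
    cm <- cand_m[ok_m[i_m]]
    cf <- cand_f[ok_f[i_f]]
    m <- eval_pair(cm, cf)
    if (abc_ok(m, target_level)) {
      th <- abc_thresholds(cm, cf, target_level, TRUE)
      return(abc_build_result(pp, th))
    }
    # repair: advance the side with the lower predictive value first
    adv_male <- if (is.na(m$ppv)) FALSE
                else if (is.na(m$npv)) TRUE
                else m$ppv <= m$npv
    if (adv_male && i_m < length(ok_m)) {
      i_m <- i_m + 1L
    } else if (i_f < length(ok_f)) {
      i_f <- i_f + 1L
    } else if (i_m < length(ok_m)) {
      i_m <- i_m + 1L
    } else {
      return(abc_build_result(pp, abc_thresholds(1, 1, target_level, FALSE)))
    }
  }
}

abc_build_result <- function(pp, thresholds, check_attained = FALSE) {
  if (thresholds$feasible || check_attained) {
    part <- abc_partition(pp, thresholds$cutoff_male, thresholds$cutoff_female)
  } else {
    part <- abc_partition(pp, 2, 2)  # nothing classified
  }
  m <- abc_metrics(pp, part)
  attained <- abc_ok(m, thresholds$target_level)
  structure(list(thresholds = thresholds,
                 report = m[setdiff(names(m), "counts")],
                 counts = m$counts,
                 classified_ids = pp$ids[part$classified],
                 indeterminate_ids = pp$ids[!part$classified],
                 target_attained = attained),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  print(x$thresholds)
  r <- x$report
  cat(sprintf("  classified: %s%% (male %s%%, female %s%%)\n",
              fmt_pct(r$pct_classified_overall),
              fmt_pct(r$pct_classified_male),
              fmt_pct(r$pct_classified_female)))
  cat(sprintf("  accuracy %s  PPV %s  NPV %s  (target %s)\n",
              fmt_pct(r$accuracy), fmt_pct(r$ppv), fmt_pct(r$npv),
              if (x$target_attained) "attained" else "not attained"))
  invisible(x)
}

#' Apply fixed ABC thresholds to new posteriors
#'
#' Classifies male where `pp_male >= cutoff_male`, female where
#' `1 - pp_male >= cutoff_female`, indeterminate otherwise, and reports the
#' metrics on the classified subset. There is no guarantee the target level
#' is met on new data; attainment is recorded as a flag, never an error.
#'
#' @param thresholds An [abc_thresholds()].
#' @param pp A [posterior_set()].
#' @return An `abc_result` (see [abc_search()]).
#' @export
abc_apply <- function(thresholds, pp) {
  stopifnot(inherits(thresholds, "abc_thresholds"),
            inherits(pp, "posterior_set"))
  abc_build_result(pp, thresholds, check_attained = TRUE)
}

#' Save ABC thresholds as JSON
#' @param thresholds An [abc_thresholds()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "abc_thresholds"))
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load ABC thresholds from JSON
#' @param path Path written by [save_thresholds()].
#' @return An `abc_thresholds`.
#' @export
load_thresholds <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  abc_thresholds(obj$cutoff_male, obj$cutoff_female, obj$target_level,
                 obj$feasible)
}
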