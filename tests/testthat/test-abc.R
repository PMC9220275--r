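worked_example_pp <- function() {
  posterior_set(
    ids = sprintf("s%02d", 1:9),
    true_sex = rep(c("male", "female"), c(5, 4)),
    pp_male = c(0.99, 0.95, 0.90, 0.70, 0.55, 0.01, 0.05, 0.45, 0.60))
}

test_that("threshold search solves the worked reject-option example", {
  res <- abc_search(worked_example_pp(), target_level = 0.95)
  expect_true(res$thresholds$feasible)
  expect_equal(res$thresholds$cutoff_male, 0.70)
  expect_equal(res$thresholds$cutoff_female, 0.55)
  expect_length(res$classified_ids, 7L)
  expect_equal(res$report$ppv, 100)
  expect_equal(res$report$npv, 100)
  expect_equal(res$report$accuracy, 100)
  # the exhaustive pair oracle confirms 7 is the optimum
  pp <- worked_example_pp()
  expect_equal(oracle_abc_max_classified(pp$true_sex == "male",
                                         pp$pp_male, 0.95), 7L)
})

test_that("perfect separation classifies everyone at the smallest candidates", {
  pp <- posterior_set(sprintf("s%02d", 1:10),
                      rep(c("male", "female"), each = 5),
                      c(0.95, 0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1, 0.05))
  res <- abc_search(pp, 0.95)
  expect_true(res$thresholds$feasible)
  expect_equal(res$thresholds$cutoff_male, 0.6)
  expect_equal(res$thresholds$cutoff_female, 0.6)
  expect_equal(res$report$pct_classified_overall, 100)
  expect_equal(res$report$accuracy, 100)
})

test_that("uninformative posteriors are infeasible with nothing classified", {
  pp <- posterior_set(sprintf("s%02d", 1:10),
                      rep(c("male", "female"), each = 5), rep(0.5, 10))
  res <- abc_search(pp, 0.95)
  expect_false(res$thresholds$feasible)
  expect_equal(res$thresholds$cutoff_male, 1)
  expect_length(res$classified_ids, 0L)
  expect_error(abc_search(pp, 0.4), "target_level")
  one <- posterior_set("a", "male", 0.9)
  expect_error(abc_search(one, 0.95), "both sexes")
})

test_that("the ABC contract holds on every feasible random instance", {
  violations <- 0
  for (s in 1:200) {
    pp <- random_posterior_set(5000 + s)
    res <- abc_search(pp, 0.95)
    if (res$thresholds$feasible) {
      r <- res$report
      if (anyNA(c(r$accuracy, r$ppv, r$npv)) ||
          r$accuracy < 95 - 1e-9 || r$ppv < 95 - 1e-9 || r$npv < 95 - 1e-9) {
        violations <- violations + 1
      }
    }
  }
  expect_equal(violations, 0)
})

test_that("sequential search matches the exhaustive oracle on small instances", {
  agree <- 0
  total <- 0
  for (s in 1:80) {
    set.seed(9000 + s)
    n <- sample(8:20, 1)
    n_m <- sample(2:(n - 2), 1)
    truth <- rep(c(TRUE, FALSE), c(n_m, n - n_m))
    pp_vals <- round(plogis(rnorm(n, ifelse(truth, 1, -1), 1.5)), 2)
    pp <- posterior_set(sprintf("s%02d", 1:n),
                        ifelse(truth, "male", "female"), pp_vals)
    res <- abc_search(pp, 0.95)
    got <- length(res$classified_ids)
    opt <- oracle_abc_max_classified(truth, pp_vals, 0.95)
    total <- total + 1
    if (got == opt) agree <- agree + 1
    # never claims feasibility when the oracle finds nothing admissible
    if (opt == 0) expect_false(res$thresholds$feasible)
  }
  expect_gte(agree / total, 0.95)
})

test_that("raising the target never increases the classified count", {
  for (s in 1:40) {
    pp <- random_posterior_set(7000 + s)
    n80 <- length(abc_search(pp, 0.80)$classified_ids)
    n90 <- length(abc_search(pp, 0.90)$classified_ids)
    n97 <- length(abc_search(pp, 0.97)$classified_ids)
    expect_true(n80 >= n90 && n90 >= n97)
  }
})

test_that("raising a cutoff never classifies more specimens of that sex", {
  pp <- random_posterior_set(123)
  male_count <- function(cm) {
    r <- abc_apply(abc_thresholds(cm, 0.8), pp)
    sum(pp$pp_male[pp$ids %in% r$classified_ids] >= cm)
  }
  counts <- vapply(c(0.55, 0.7, 0.85, 0.95), male_count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("abc_apply is idempotent on the search set and handles extremes", {
  pp <- worked_example_pp()
  res <- abc_search(pp, 0.95)
  re <- abc_apply(res$thresholds, pp)
  expect_identical(re$classified_ids, res$classified_ids)
  expect_equal(re$report, res$report)
  expect_true(re$target_attained)

  nothing <- abc_apply(abc_thresholds(1, 1), pp)
  expect_length(nothing$classified_ids, 0L)
  expect_true(is.na(nothing$report$accuracy))

  # everyone called male -> NPV undefined, reported as NA (rendered "/")
  all_male <- abc_apply(abc_thresholds(0.5, 1), posterior_set(
    c("a", "b"), c("male", "female"), c(0.9, 0.8)))
  expect_true(is.na(all_male$report$npv))
  expect_false(all_male$target_attained)
})

test_that("thresholds survive a JSON round trip", {
  th <- abc_thresholds(0.734, 0.778, 0.95, TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  save_thresholds(th, path)
  back <- load_thresholds(path)
  expect_equal(back$cutoff_male, 0.734)
  expect_equal(back$cutoff_female, 0.778)
  expect_true(back$feasible)
})
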