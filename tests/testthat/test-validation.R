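test_that("confusion counts partition the sample", {
  cc <- confusion(c("male", "male", "female", "female"),
                  c("male", "female", "female", "male"))
  expect_equal(cc, c(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  all_right <- confusion(c("male", "female"), c("male", "female"))
  expect_equal(all_right[["FP"]] + all_right[["FN"]], 0L)
  set.seed(3)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    pred <- sample(c("male", "female"), n, TRUE)
    truth <- sample(c("male", "female"), n, TRUE)
    expect_equal(sum(confusion(pred, truth)), n)
  }
  expect_error(confusion("male", c("male", "female")), "mismatch")
})

test_that("metrics match hand formulas, mark undefined cells, and are scale-free", {
  m <- metrics_from_confusion(c(TP = 1, FP = 1, TN = 1, FN = 1))
  expect_equal(unlist(m), c(accuracy = 50, sensitivity = 50,
                            specificity = 50, ppv = 50, npv = 50))
  # nobody classified male -> PPV undefined
  m0 <- metrics_from_confusion(c(TP = 0, FP = 0, TN = 5, FN = 3))
  expect_true(is.na(m0$ppv))
  expect_false(is.na(m0$npv))
  set.seed(4)
  for (i in 1:10) {
    cts <- c(TP = sample(0:20, 1), FP = sample(0:20, 1),
             TN = sample(0:20, 1), FN = sample(0:20, 1))
    if (sum(cts) == 0) next
    got <- metrics_from_confusion(cts)
    n <- sum(cts)
    expect_equal(got$accuracy, 100 * (cts[["TP"]] + cts[["TN"]]) / n)
    scaled <- metrics_from_confusion(cts * 3L)
    expect_equal(unlist(got), unlist(scaled))
  }
})

test_that("c-index equals exhaustive pair enumeration", {
  perfect <- posterior_set(letters[1:4], c("male", "male", "female", "female"),
                           c(0.9, 0.8, 0.3, 0.2))
  expect_equal(c_index(perfect), 1)
  flat <- posterior_set(letters[1:4], c("male", "male", "female", "female"),
                        rep(0.5, 4))
  expect_equal(c_index(flat), 0.5)
  mixed <- posterior_set(letters[1:4], c("male", "male", "female", "female"),
                         c(0.9, 0.4, 0.6, 0.1))
  expect_equal(c_index(mixed), 0.75)
  set.seed(5)
  for (i in 1:50) {
    n_m <- sample(2:12, 1); n_f <- sample(2:12, 1)
    pp_m <- round(runif(n_m), 2)  # rounding forces ties
    pp_f <- round(runif(n_f), 2)
    ps <- posterior_set(sprintf("s%02d", seq_len(n_m + n_f)),
                        rep(c("male", "female"), c(n_m, n_f)),
                        c(pp_m, pp_f))
    expect_equal(c_index(ps), oracle_c_index(pp_m, pp_f), tolerance = 1e-12)
  }
  single <- posterior_set("a", "male", 0.7)
  expect_error(c_index(single), "both sexes")
})

test_that("trapezoidal ROC importance equals the concordance of the raw score", {
  set.seed(6)
  for (i in 1:30) {
    n_m <- sample(3:15, 1); n_f <- sample(3:15, 1)
    vals <- round(c(rnorm(n_m, 12), rnorm(n_f, 10)), 1) + 100
    tab <- measurement_table(sprintf("s%02d", seq_len(n_m + n_f)),
                             rep(c("male", "female"), c(n_m, n_f)),
                             cbind(V = vals))
    ps <- posterior_set(tab$ids, tab$sex, (vals - min(vals)) /
                          diff(range(vals)))
    auc_raw <- roc_importance(tab)$auc_raw
    expect_equal(auc_raw, c_index(ps), tolerance = 1e-12)
  }
})

test_that("ROC importance agrees with an independent AUC implementation", {
  coh <- generate_cohort(femur_dimorphism_spec(), 100, seed = 13)
  imp <- roc_importance(coh)
  for (nm in c("FEB", "MTD")) {
    ref <- suppressMessages(pROC::auc(
      response = coh$sex, predictor = coh$values[, nm],
      levels = c("female", "male"), direction = "<"))
    expect_equal(imp$auc_raw[imp$variable == nm], as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("ROC importance: perfect, noise and constant variables", {
  set.seed(14)
  n <- 2000
  sex <- rep(c("male", "female"), each = n / 2)
  ind <- ifelse(sex == "male", 2, 1)  # identical to the label indicator
  noise <- runif(n) + 1
  tab <- measurement_table(sprintf("s%04d", 1:n), sex,
                           cbind(IND = ind + 0.001 * seq_len(n) / n,
                                 NOISE = noise))
  imp <- roc_importance(tab)
  expect_equal(imp$auc[imp$variable == "IND"], 1, tolerance = 1e-6)
  expect_lt(abs(imp$auc_raw[imp$variable == "NOISE"] - 0.5), 0.03)
  # constant column is flagged NA and ranked last
  tab2 <- measurement_table(tab$ids, tab$sex,
                            cbind(tab$values, K = rep(7, n)))
  imp2 <- roc_importance(tab2)
  expect_true(is.na(imp2$auc[imp2$variable == "K"]))
  expect_equal(imp2$variable[nrow(imp2)], "K")
  # the epiphyseal set dominates the shaft widths on reference cohorts
  coh <- generate_cohort(femur_dimorphism_spec(), 1000, seed = 15)
  top5 <- roc_importance(coh, top_k = 5)$variable
  expect_true(all(top5 %in% c("FEB", "VHD", "FVDN", "FNAL", "FBP", "FBCB")))
  expect_false(any(c("MTD", "MLD") %in% top5))
})

test_that("LGOCV split sizes, averaging and determinism", {
  coh <- generate_cohort(femur_dimorphism_spec(), 120, seed = 16)
  cv <- cv_config(5L, 0.7, seed = 9)
  ev <- lgocv_evaluate(classifier_spec("LDA"), coh, c("FEB", "FVDN"), cv)
  # 240 at 70/30 -> 168 calibration / 72 validation, so 5 x 72 pooled pps
  expect_length(ev$pp_pooled$pp_male, 5L * 72L)
  ev2 <- lgocv_evaluate(classifier_spec("LDA"), coh, c("FEB", "FVDN"), cv)
  expect_identical(ev$report, ev2$report)
  expect_identical(ev$pp_pooled$pp_male, ev2$pp_pooled$pp_male)
  expect_true(ev$report$accuracy > 50 && ev$report$accuracy <= 100)
})

test_that("LGOCV is perfect on separable data and chance-level on null data", {
  sep <- separable_fixture(30, 20, seed = 17)
  ev <- lgocv_evaluate(classifier_spec("LDA"), sep, cv = cv_config(5L, seed = 2))
  expect_equal(ev$report$accuracy, 100)
  expect_equal(ev$report$c_index, 1)
  flat <- separable_fixture(60, 0, seed = 18)
  ev0 <- lgocv_evaluate(classifier_spec("LDA"), flat,
                        cv = cv_config(20L, seed = 3))
  expect_lt(abs(ev0$report$accuracy - 50), 10)
})

test_that("RFE finds the informative variable and respects the tie rule", {
  # 1 informative variable (5 SD gap) + 4 pure-noise variables
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 30
    sex <- rep(c("male", "female"), each = n)
    X <- cbind(SIG = rnorm(2 * n, ifelse(sex == "male", 105, 100), 1),
               N1 = rnorm(2 * n, 50, 5), N2 = rnorm(2 * n, 50, 5),
               N3 = rnorm(2 * n, 50, 5), N4 = rnorm(2 * n, 50, 5))
    tab <- measurement_table(sprintf("s%03d", seq_len(2 * n)), sex, X)
    sel <- rfe_select(classifier_spec("LDA"), tab,
                      cv = cv_config(10L, seed = s))
    if ("SIG" %in% sel$variables) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # identical copies: accuracy cannot improve with size, so ties -> 1 variable
  set.seed(200)
  base <- rnorm(40, ifelse(rep(c(TRUE, FALSE), each = 20), 104, 100), 1.5)
  tabc <- measurement_table(sprintf("c%02d", 1:40),
                            rep(c("male", "female"), each = 20),
                            cbind(A = base, B = base, C = base))
  # componentwise boosting tolerates the exact collinearity
  selc <- rfe_select(classifier_spec("GLMB", glmb_mstop_grid = 50L), tabc,
                     cv = cv_config(8L, seed = 5))
  expect_length(selc$variables, 1L)
  expect_true(all(selc$profile$size == sort(selc$profile$size)))
})
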