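make_univariate <- function(n_per_sex, mu_m, mu_f, sigma, seed) {
  params <- data.frame(name = "X", male_mean = mu_m, male_sd = sigma,
                       female_mean = mu_f, female_sd = sigma)
  generate_cohort(dimorphism_spec(params, 0), n_per_sex, seed = seed)
}

test_that("LDA posteriors equal the closed-form Gaussian Bayes posterior", {
  coh <- make_univariate(60, 52, 48, 2, seed = 21)
  m <- fit_classifier(classifier_spec("LDA"), coh)
  pp <- predict_pp(m, coh)
  x <- coh$values[, 1]
  male <- coh$sex == "male"
  # plug the sample moments into the closed-form posterior
  mu_m <- mean(x[male]); mu_f <- mean(x[!male])
  s2 <- ((sum(male) - 1) * var(x[male]) + (sum(!male) - 1) * var(x[!male])) /
    (length(x) - 2)
  expect_equal(pp$pp_male, oracle_lda_pp(x, mu_m, mu_f, sqrt(s2)),
               tolerance = 1e-10)
  # midpoint of the class means scores exactly 0.5
  mid <- measurement_table("q", "male", cbind(X = (mu_m + mu_f) / 2))
  expect_equal(predict_pp(m, mid)$pp_male, 0.5, tolerance = 1e-12)
})

test_that("multivariate LDA posteriors agree with an independent implementation", {
  coh <- generate_cohort(femur_dimorphism_spec(), 60, seed = 22)
  vars <- c("FEB", "VHD", "FVDN")
  m <- fit_classifier(classifier_spec("LDA"), coh, vars)
  ref <- MASS::lda(coh$values[, vars], grouping = coh$sex,
                   prior = c(0.5, 0.5))
  ref_pp <- predict(ref, coh$values[, vars])$posterior[, "male"]
  expect_equal(predict_pp(m, coh)$pp_male, unname(ref_pp), tolerance = 1e-8)
})

test_that("GLMB converges to the logistic MLE with one predictor and shrinks early", {
  coh <- make_univariate(80, 51, 49, 2, seed = 31)  # overlapping, no separation
  lr <- fit_classifier(classifier_spec("LR"), coh)
  expect_false(lr$separated)
  glmb <- fit_classifier(classifier_spec("GLMB", glmb_mstop_grid = 5000L),
                         coh)
  expect_lt(abs(glmb$beta - lr$beta), 1e-3)
  expect_lt(abs(glmb$alpha - lr$alpha), 1e-3 * abs(lr$alpha) + 1e-3)
  # early stopping shrinks standardized coefficients toward zero
  coh13 <- generate_cohort(femur_dimorphism_spec(), 60, seed = 32)
  lr13 <- fit_classifier(classifier_spec("LR"), coh13)
  g50 <- fit_classifier(classifier_spec("GLMB", glmb_mstop_grid = 50L), coh13)
  sds <- apply(coh13$values, 2, sd)
  expect_true(all(abs(g50$beta * sds) <= abs(lr13$beta * sds) + 1e-8))
})

test_that("LR flags separation, caps coefficients and keeps valid posteriors", {
  sep <- separable_fixture(25, gap_sds = 20, seed = 41)
  m <- fit_classifier(classifier_spec("LR"), sep)
  expect_true(m$separated)
  expect_lte(abs(m$beta * sd(sep$values[, 1])), 15 + 1e-8)
  pp <- predict_pp(m, sep)
  expect_true(all(pp$pp_male > 0 & pp$pp_male < 1))
  expect_equal(as.character(classify_at(pp)), as.character(sep$sex))
})

test_that("SVM posterior is a monotone function of the decision value", {
  coh <- make_univariate(60, 52, 48, 2, seed = 51)
  m <- fit_classifier(classifier_spec("SVM"), coh)
  grid <- measurement_table(sprintf("g%02d", 1:50), rep("male", 50),
                            cbind(X = seq(40, 60, length.out = 50)))
  pp <- predict_pp(m, grid)$pp_male
  expect_true(all(diff(pp) > 0))  # larger measurement -> higher male pp
  expect_true(!is.null(m$platt_A) && !is.null(m$platt_B))
})

test_that("all four classifiers are perfect on an ample separable fixture", {
  sep <- separable_fixture(40, gap_sds = 20, seed = 61)
  for (kind in c("LR", "LDA", "GLMB", "SVM")) {
    m <- fit_classifier(classifier_spec(kind), sep)
    pp <- predict_pp(m, sep)
    expect_equal(as.character(classify_at(pp, 0.5)), as.character(sep$sex),
                 info = kind)
    expect_true(all(pp$pp_male > 0 & pp$pp_male < 1), info = kind)
  }
})

test_that("the four classifiers are comparable on a univariate dimorphic cohort", {
  # one overlapping variable: every linear classifier approximates the same
  # Bayes rule, so cross-validated accuracies agree closely
  coh <- make_univariate(120, 52, 48, 2, seed = 65)
  accs <- vapply(c("LR", "LDA", "GLMB", "SVM"), function(kind) {
    lgocv_evaluate(classifier_spec(kind), coh,
                   cv = cv_config(10L, seed = 9))$report$accuracy
  }, numeric(1))
  expect_lt(max(accs) - min(accs), 2)
})

test_that("classification threshold semantics: ties to male, monotone", {
  pp <- posterior_set(c("a", "b", "c"), c("male", "female", "male"),
                      c(0.9, 0.2, 0.5))
  lab <- classify_at(pp, 0.5)
  expect_equal(as.character(lab), c("male", "female", "male"))  # tie -> male
  set.seed(8)
  for (i in 1:20) {
    pps <- runif(30)
    ps <- posterior_set(sprintf("s%02d", 1:30),
                        sample(c("male", "female"), 30, TRUE), pps)
    hi <- classify_at(ps, 0.8)
    lo <- classify_at(ps, 0.3)
    # lowering the threshold never flips male -> female
    expect_true(all(!(hi == "male" & lo == "female")))
  }
})

test_that("posterior sets enforce closure and bounds", {
  expect_error(posterior_set("a", "male", 1.2), "\\[0, 1\\]")
  pp <- posterior_set(c("a", "b"), c("male", "female"), c(0.7, 0.3))
  expect_equal(pp$pp_male + (1 - pp$pp_male), c(1, 1))  # two-class closure
  expect_error(posterior_set(c("a", "b"), c("male", "x"), c(0.5, 0.5)),
               "female")
})

test_that("fitted models survive a JSON round trip", {
  coh <- generate_cohort(femur_dimorphism_spec(), 40, seed = 71)
  m <- fit_classifier(classifier_spec("GLMB"), coh,
                      variables = c("FEB", "FVDN", "FNAL"))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$kind, "GLMB")
  expect_equal(back$variables, c("FEB", "FVDN", "FNAL"))
  pp1 <- predict_pp(m, coh)
  pp2 <- predict_pp(back, coh)
  expect_equal(pp1$pp_male, pp2$pp_male, tolerance = 1e-12)
})

test_that("degenerate training inputs are rejected", {
  coh <- toy_cohort()
  const <- measurement_table(coh$ids, coh$sex,
                             cbind(coh$values, K = rep(5, 4)))
  expect_error(fit_classifier(classifier_spec("LR"), const), "constant")
  one_sex <- measurement_table(c("a", "b", "c"), rep("male", 3),
                               cbind(X = c(1, 2, 3)))
  expect_error(fit_classifier(classifier_spec("LDA"), one_sex), "per sex")
  m <- fit_classifier(classifier_spec("LDA"), coh)
  missing_var <- measurement_table("z", "male", cbind(Q = 5))
  expect_error(predict_pp(m, missing_var), "not in table")
})
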