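#' Classifier specification
#'
#' Configuration for the four interchangeable linear classifiers. All emit a
#' posterior probability of the male (positive) class through a linear logit,
#' so fitted models are portable (alpha, beta) artifacts whatever the kind.
#'
#' @param kind One of `"LR"` (binomial GLM), `"LDA"` (two-class linear
#'   discriminant, pooled covariance, equal priors), `"GLMB"` (componentwise
#'   gradient-boosted linear logit) or `"SVM"` (linear soft-margin SVM with
#'   sigmoid-calibrated posteriors).
#' @param glmb_mstop_grid Candidate boosting iteration counts; a single value
#'   skips internal selection. Default `c(50, 100, 150)`.
#' @param glmb_step Boosting step length nu in (0, 1]. Default 0.1.
#' @param glmb_inner_iters Monte-Carlo iterations of the internal 70/30
#'   resampling used to pick mstop from the grid. Default 25.
#' @param svm_C Soft-margin misclassification cost, held constant. Default 1.
#' @param standardize Standardize predictors internally for the
#'   scale-sensitive kinds (GLMB, SVM). Default `TRUE`. LR and LDA are fit on
#'   the raw scale so their intercept/coefficients stay interpretable.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("LR", "LDA", "GLMB", "SVM"),
                            glmb_mstop_grid = c(50L, 100L, 150L),
                            glmb_step = 0.1,
                            glmb_inner_iters = 25L,
                            svm_C = 1,
                            standardize = TRUE) {
  kind <- match.arg(kind)
  glmb_mstop_grid <- sort(unique(as.integer(glmb_mstop_grid)))
  stopifnot(all(glmb_mstop_grid > 0), glmb_step > 0, glmb_step <= 1,
            svm_C > 0, glmb_inner_iters >= 1)
  structure(list(kind = kind, glmb_mstop_grid = glmb_mstop_grid,
                 glmb_step = glmb_step,
                 glmb_inner_iters = as.integer(glmb_inner_iters),
                 svm_C = svm_C, standardize = isTRUE(standardize)),
            class = "classifier_spec")
}

# |standardized coefficient| cap flagging/repairing logistic separation:
# keeps posteriors finite-precision-safe while preserving near-0/1 values.
.LR_SEPARATION_CAP <- 15

#' Fit a classifier on a training cohort
#'
#' All four kinds reduce to a calibrated linear logit for the male class:
#' `pp_male(x) = plogis(alpha + beta' x)` on the raw measurement scale.
#'
#' * `LR` — binomial GLM by IRLS. Detected separation (non-convergence,
#'   fitted probabilities of 0/1, or a standardized coefficient beyond the
#'   cap) flags the model `separated`; offending standardized coefficients
#'   are capped at the cap and the intercept refit, so posteriors remain
#'   valid probabilities.
#' * `LDA` — pooled-covariance discriminant with equal priors; the Bayes
#'   posterior of a two-class Gaussian model is exactly a linear logit.
#' * `GLMB` — componentwise gradient boosting of a linear logit: each
#'   iteration fits every single predictor (plus intercept) to the negative
#'   binomial-log-likelihood gradient and updates only the best-fitting
#'   component by `glmb_step` times its fit; `mstop` is chosen from the grid
#'   by internal 70/30 Monte-Carlo validation accuracy (ties to the smaller
#'   value). Early stopping shrinks coefficients toward zero.
#' * `SVM` — linear soft-margin SVM (kernlab, C fixed); posteriors from a
#'   two-parameter sigmoid fit by regularized maximum likelihood on 3-fold
#'   cross-fitted decision values (Platt-style, with smoothed targets).
#'
#' @param spec A [classifier_spec()].
#' @param train A [measurement_table()] with >= 2 specimens per sex.
#' @param variables Measurement names to use; default all columns.
#' @param seed Integer seed driving the internal resampling (GLMB mstop
#'   selection, SVM calibration folds).
#' @return An object of class `fitted_model`.
#' @export
fit_classifier <- function(spec, train, variables = NULL, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(train, "measurement_table"))
  if (is.null(variables)) variables <- train$names
  train <- subset_variables(train, variables)
  X <- train$values
  y <- as.integer(train$sex == "male")
  if (sum(y) < 2 || sum(1 - y) < 2) stop("need >= 2 specimens per sex")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(variables[sds == 0], collapse = ", "))
  }
  fit <- switch(spec$kind,
                LR = fit_lr(X, y),
                LDA = fit_lda(X, y),
                GLMB = fit_glmb(X, y, spec, train$sex, seed),
                SVM = fit_svm(X, y, spec, train$sex, seed))
  structure(c(list(kind = spec$kind, variables = variables,
                   standardize = spec$standardize), fit),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("fitted_model [", x$kind, "] on ",
      paste(x$variables, collapse = " + "), "\n", sep = "")
  cat("  alpha =", signif(x$alpha, 6), "\n")
  cat("  beta  =", paste(signif(x$beta, 6), collapse = ", "), "\n")
  if (isTRUE(x$separated)) cat("  (separation detected; coefficients capped)\n")
  if (!is.null(x$mstop)) cat("  mstop =", x$mstop, "\n")
  invisible(x)
}

fit_lr <- function(X, y) {
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(y ~ ., family = stats::binomial(), data = df))
  beta <- stats::coef(fit)[-1]
  alpha <- stats::coef(fit)[1]
  sds <- apply(X, 2, stats::sd)
  beta_std <- beta * sds
  separated <- !fit$converged || anyNA(beta) ||
    any(abs(beta_std) > .LR_SEPARATION_CAP)
  if (anyNA(beta)) beta_std[is.na(beta_std)] <- 0  # aliased columns drop out
  if (separated) {
    beta_std <- pmin(pmax(beta_std, -.LR_SEPARATION_CAP), .LR_SEPARATION_CAP)
    beta <- beta_std / sds
    off <- as.vector(X %*% beta)
    refit <- suppressWarnings(
      stats::glm(y ~ 1, family = stats::binomial(), offset = off))
    alpha <- stats::coef(refit)[1]
  }
  list(alpha = unname(alpha), beta = unname(beta), separated = separated)
}

fit_lda <- function(X, y) {
  Xm <- X[y == 1, , drop = FALSE]
  Xf <- X[y == 0, , drop = FALSE]
  mu_m <- colMeans(Xm)
  mu_f <- colMeans(Xf)
  n_m <- nrow(Xm)
  n_f <- nrow(Xf)
  S <- ((n_m - 1) * stats::cov(Xm) + (n_f - 1) * stats::cov(Xf)) /
    (n_m + n_f - 2)
  beta <- tryCatch(solve(S, mu_m - mu_f),
                   error = function(e) stop("singular pooled covariance: ",
                                            conditionMessage(e)))
  # equal priors: the prior log-odds term is zero
  alpha <- -0.5 * sum((mu_m + mu_f) * beta)
  list(alpha = unname(alpha), beta = unname(beta), separated = FALSE)
}

# Componentwise boosting of the binomial negative log-likelihood in the
# AdaBoost half-log-odds parameterization standard for boosted binomial
# GLMs: loss log(1 + exp(-2*y*f)) with y in {-1, 1}, so f converges to half
# the logit and the negative gradient is 2*(y01 - plogis(2f)). Base learners
# are simple linear fits (intercept + one predictor) to the current
# gradient; only the best-fitting component is updated, by nu times its fit.
# Runs on centered/scaled predictors; returns coefficient snapshots at the
# requested checkpoints, already mapped back to the full-logit scale
# (standardized predictors).
glmb_path <- function(Xs, y, mstop_max, nu, checkpoints) {
  n <- nrow(Xs)
  xtx <- colSums(Xs^2)
  alpha <- stats::qlogis(mean(y)) / 2
  beta <- rep(0, ncol(Xs))
  f <- rep(alpha, n)
  snaps <- vector("list", length(checkpoints))
  names(snaps) <- as.character(checkpoints)
  for (m in seq_len(mstop_max)) {
    u <- 2 * (y - stats::plogis(2 * f))
    g <- crossprod(Xs, u)[, 1]
    slopes <- g / xtx
    j <- which.max(slopes * g)  # largest RSS reduction among components
    a_j <- mean(u)
    alpha <- alpha + nu * a_j
    beta[j] <- beta[j] + nu * slopes[j]
    f <- f + nu * (a_j + slopes[j] * Xs[, j])
    pos <- match(m, checkpoints)
    if (!is.na(pos)) {
      snaps[[pos]] <- list(alpha = 2 * alpha, beta = 2 * beta)
    }
  }
  snaps
}

fit_glmb <- function(X, y, spec, sex, seed) {
  ctr <- if (spec$standardize) colMeans(X) else rep(0, ncol(X))
  scl <- if (spec$standardize) apply(X, 2, stats::sd) else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  grid <- spec$glmb_mstop_grid
  if (length(grid) > 1) {
    acc <- matrix(NA_real_, spec$glmb_inner_iters, length(grid))
    for (it in seq_len(spec$glmb_inner_iters)) {
      cal <- split_indices_by_sex(sex, 0.7, derive_seed(seed, 811L, it))
      val <- setdiff(seq_along(y), cal)
      snaps <- glmb_path(Xs[cal, , drop = FALSE], y[cal],
                         max(grid), spec$glmb_step, grid)
      for (k in seq_along(grid)) {
        s <- snaps[[k]]
        pp <- stats::plogis(s$alpha +
                              Xs[val, , drop = FALSE] %*% s$beta)
        acc[it, k] <- mean((pp >= 0.5) == (y[val] == 1))
      }
    }
    mstop <- grid[which.max(colMeans(acc))]  # which.max ties -> smaller mstop
  } else {
    mstop <- grid
  }
  fin <- glmb_path(Xs, y, mstop, spec$glmb_step, mstop)[[1]]
  beta <- fin$beta / scl
  alpha <- fin$alpha - sum(fin$beta * ctr / scl)
  list(alpha = unname(alpha), beta = unname(beta), separated = FALSE,
       mstop = mstop)
}

svm_weights <- function(m) {
  sv <- kernlab::xmatrix(m)[[1]]
  co <- kernlab::coef(m)[[1]]
  w <- as.vector(t(sv) %*% co)
  list(w = w, b = kernlab::b(m))
}

# Two-parameter sigmoid pp = plogis(a0 + a1 * d) fit to decision values by
# regularized maximum likelihood with Platt's smoothed targets.
platt_fit <- function(d, y) {
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  t_i <- ifelse(y == 1, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  nll <- function(par) {
    eta <- par[1] + par[2] * d
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - t_i * eta) +
      1e-6 * sum(par^2)
  }
  stats::optim(c(0, 1), nll, method = "BFGS")$par
}

fit_svm <- function(X, y, spec, sex, seed) {
  ctr <- if (spec$standardize) colMeans(X) else rep(0, ncol(X))
  scl <- if (spec$standardize) apply(X, 2, stats::sd) else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  yf <- factor(ifelse(y == 1, "male", "female"), levels = .SEX_LEVELS)
  ksvm_fit <- function(Xsub, ysub) {
    kernlab::ksvm(Xsub, ysub, type = "C-svc",
                  kernel = "vanilladot", kpar = list(),
                  C = spec$svm_C, scaled = FALSE)
  }
  # 3-fold stratified cross-fitted decision values for the sigmoid
  folds <- with_seed(derive_seed(seed, 271L), {
    f <- integer(length(y))
    for (lev in .SEX_LEVELS) {
      idx <- sample(which(sex == lev))
      f[idx] <- rep_len(1:3, length(idx))
    }
    f
  })
  d_cv <- numeric(length(y))
  for (k in 1:3) {
    hold <- folds == k
    mk <- ksvm_fit(Xs[!hold, , drop = FALSE], yf[!hold])
    wk <- svm_weights(mk)
    d_cv[hold] <- Xs[hold, , drop = FALSE] %*% wk$w - wk$b
  }
  ab <- platt_fit(d_cv, y)
  m <- ksvm_fit(Xs, yf)
  wb <- svm_weights(m)
  # fold sigmoid o decision o standardization into one raw-scale linear logit
  beta_std <- ab[2] * wb$w
  alpha_std <- ab[1] - ab[2] * wb$b
  beta <- beta_std / scl
  alpha <- alpha_std - sum(beta_std * ctr / scl)
  list(alpha = unname(alpha), beta = unname(beta), separated = FALSE,
       platt_A = ab[2], platt_B = ab[1], svm_w = wb$w, svm_b = wb$b)
}

#' Posterior-probability set
#'
#' Per-specimen posterior probability of the male (positive) class with the
#' true labels; the interface between classifiers, metrics and the ABC
#' threshold search. The female posterior is `1 - pp_male` (two-class
#' closure).
#'
#' @param ids Specimen identifiers.
#' @param true_sex Factor/character vector of `"female"`/`"male"`.
#' @param pp_male Numeric vector in `[0, 1]`.
#' @return An object of class `posterior_set`.
#' @export
posterior_set <- function(ids, true_sex, pp_male) {
  ids <- as.character(ids)
  true_sex <- factor(as.character(true_sex), levels = .SEX_LEVELS)
  if (anyNA(true_sex)) stop("true_sex labels must be 'female' or 'male'")
  pp_male <- as.numeric(pp_male)
  if (length(ids) != length(true_sex) || length(ids) != length(pp_male)) {
    stop("ids, true_sex and pp_male must have equal length")
  }
  if (any(!is.finite(pp_male)) || any(pp_male < 0) || any(pp_male > 1)) {
    stop("pp_male must lie in [0, 1]")
  }
  structure(list(ids = ids, true_sex = true_sex, pp_male = pp_male),
            class = "posterior_set")
}

#' @export
print.posterior_set <- function(x, ...) {
  cat("posterior_set:", length(x$ids), "specimens,",
      sum(x$true_sex == "male"), "male /",
      sum(x$true_sex == "female"), "female\n")
  invisible(x)
}

#' Predict male posterior probabilities
#'
#' @param model A [fit_classifier()] result.
#' @param data A [measurement_table()] containing the model's variables.
#' @return A [posterior_set()] with `pp_male` strictly inside (0, 1).
#' @export
predict_pp <- function(model, data) {
  stopifnot(inherits(model, "fitted_model"),
            inherits(data, "measurement_table"))
  X <- subset_variables(data, model$variables)$values
  pp <- stats::plogis(model$alpha + as.vector(X %*% model$beta))
  pp <- pmin(pmax(pp, 1e-12), 1 - 1e-12)
  posterior_set(data$ids, data$sex, pp)
}

#' Classify at a fixed posterior threshold
#'
#' Assigns male if and only if `pp_male >= threshold` (a tie at the
#' threshold goes to male — the recorded convention).
#'
#' @param pp A [posterior_set()].
#' @param threshold Probability cutoff in (0, 1). Default 0.5, the
#'   traditional sectioning point.
#' @return Factor of `"female"`/`"male"` labels.
#' @export
classify_at <- function(pp, threshold = 0.5) {
  stopifnot(inherits(pp, "posterior_set"), threshold > 0, threshold < 1)
  factor(ifelse(pp$pp_male >= threshold, "male", "female"),
         levels = .SEX_LEVELS)
}

#' Save a fitted model as JSON
#'
#' @param model A [fit_classifier()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fitted_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a fitted model from JSON
#'
#' @param path Path written by [save_model()].
#' @return A `fitted_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$beta <- as.numeric(obj$beta)
  structure(obj, class = "fitted_model")
}
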