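# Independent oracles used across test files. These re-derive expected
# values from first principles and must stay independent of the package's
# own code paths.

# Closed-form Bayes posterior for univariate equal-variance Gaussian classes
# with equal priors.
oracle_lda_pp <- function(x, mu_m, mu_f, sigma) {
  stats::plogis(((mu_m - mu_f) / sigma^2) * (x - (mu_m + mu_f) / 2))
}

# Concordance by exhaustive male-female pair enumeration.
oracle_c_index <- function(pp_male_m, pp_male_f) {
  conc <- 0
  for (a in pp_male_m) {
    for (b in pp_male_f) {
      conc <- conc + (a > b) + 0.5 * (a == b)
    }
  }
  conc / (length(pp_male_m) * length(pp_male_f))
}

# Closed-form overlap of two equal-SD normal densities with means delta
# apart: 2 * Phi(-delta / (2 * sigma)).
oracle_normal_overlap_pct <- function(delta, sigma) {
  200 * stats::pnorm(-abs(delta) / (2 * sigma))
}

# Pooled two-sample t from first principles (textbook formula).
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# Exhaustive ABC oracle: scan every candidate cutoff pair (observed values
# > 0.5 on each scale, plus the 0.5 boundary) and return the maximal
# classified count subject to PPV, NPV and accuracy >= target on the
# classified subset. Returns 0 when no pair is admissible.
oracle_abc_max_classified <- function(truth_male, pp_male, target) {
  cand_m <- c(sort(unique(pp_male[pp_male > 0.5])), 0.5)
  pf <- 1 - pp_male
  cand_f <- c(sort(unique(pf[pf > 0.5])), 0.5)
  best <- 0L
  for (cm in cand_m) {
    for (cf in cand_f) {
      as_m <- pp_male >= cm
      as_f <- (1 - pp_male) >= cf & !as_m
      tp <- sum(as_m & truth_male); fp <- sum(as_m & !truth_male)
      tn <- sum(as_f & !truth_male); fn <- sum(as_f & truth_male)
      n_cls <- tp + fp + tn + fn
      if (tp + fp == 0 || tn + fn == 0) next
      ppv <- tp / (tp + fp); npv <- tn / (tn + fn)
      acc <- (tp + tn) / n_cls
      if (ppv >= target - 1e-12 && npv >= target - 1e-12 &&
          acc >= target - 1e-12) {
        best <- max(best, n_cls)
      }
    }
  }
  best
}

# Random posterior sets of mixed separability for ABC property tests.
random_posterior_set <- function(seed) {
  set.seed(seed)
  n <- sample(10:200, 1)
  n_m <- sample(2:(n - 2), 1)
  sep <- stats::runif(1, 0, 3)  # separation of the latent logit means
  pp_m <- stats::plogis(stats::rnorm(n_m, sep, 1.5))
  pp_f <- stats::plogis(stats::rnorm(n - n_m, -sep, 1.5))
  posterior_set(sprintf("S%03d", seq_len(n)),
                rep(c("male", "female"), c(n_m, n - n_m)),
                c(pp_m, pp_f))
}

# Small two-variable toy cohort written/read in several IO tests.
toy_cohort <- function() {
  measurement_table(
    ids = c("a", "b", "c", "d"),
    sex = c("male", "male", "female", "female"),
    values = cbind(FML = c(450, 445, 410, 405),
                   FEB = c(86, 84, 77, 76)))
}
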