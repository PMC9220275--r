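.SEX_LEVELS <- c("female", "male")
.MODULUS <- 2147483647L

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic seed derivation: fold indices into the master seed so every
# sub-computation (CV iteration, sweep cell, replicate) gets its own stream.
# Kept below 2^31 - 1.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master %% .MODULUS)
  for (k in idx) {
    s <- (s * 31 + as.double(k) + 1) %% .MODULUS
  }
  as.integer(s)
}

# Stratified index split by sex: round-half-to-even per-sex training counts.
split_indices_by_sex <- function(sex, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  with_seed(seed, {
    train_idx <- integer(0)
    for (lev in levels(sex)) {
      idx <- which(sex == lev)
      n_train <- round(fraction * length(idx))
      if (n_train < 1 || n_train >= length(idx)) {
        stop("train fraction ", fraction, " leaves an empty partition for sex '",
             lev, "' (n = ", length(idx), ")")
      }
      train_idx <- c(train_idx, sample(idx, n_train))
    }
    sort(train_idx)
  })
}

fmt_pct <- function(x) ifelse(is.na(x), "/", formatC(x, format = "f", digits = 2))
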