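#' The canonical femoral measurement names
#'
#' The 13 linear femoral measurements (in mm) used throughout the package:
#' maximum length (FML), bicondylar length (FBL), trochanteric length (FTL),
#' transverse midshaft diameter (MTD), vertical head diameter (VHD), vertical
#' neck diameter (FVDN), neck axis length (FNAL), proximal breadth (FBP),
#' transverse subtrochanteric diameter (MLD), bicondylar breadth (FBCB),
#' epicondylar breadth (FEB), and the antero-posterior diameters of the
#' lateral (APDLC) and medial (APDMC) condyles.
#'
#' @return Character vector of the 13 measurement names.
#' @export
femur_measurement_names <- function() {
  c("FML", "FBL", "FTL", "MTD", "VHD", "FVDN", "FNAL",
    "FBP", "MLD", "FBCB", "FEB", "APDLC", "APDMC")
}

#' Construct a measurement table
#'
#' The universal cohort container: specimen ids, a binary sex label
#' (male = positive class, female = negative class), and a matrix of
#' continuous measurements in mm.
#'
#' @param ids Character vector of unique specimen identifiers.
#' @param sex Factor or character vector with exactly the levels
#'   `"female"` and `"male"` (male is the positive class everywhere).
#' @param values Numeric matrix, one row per specimen, one named column per
#'   measurement. All values must be finite and strictly positive.
#' @return An object of class `measurement_table`.
#' @export
measurement_table <- function(ids, sex, values) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate specimen id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sex <- factor(as.character(sex), levels = .SEX_LEVELS)
  if (anyNA(sex)) stop("sex labels must be 'female' or 'male'")
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("measurement columns must have unique names")
  }
  if (ncol(values) < 1) stop("at least one measurement column is required")
  if (nrow(values) != length(ids) || length(sex) != length(ids)) {
    stop("ids, sex and measurement rows must have equal length")
  }
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-finite or non-positive measurement at row '", ids[bad[1, 1]],
         "', column '", colnames(values)[bad[1, 2]], "'")
  }
  rownames(values) <- NULL
  structure(list(ids = ids, sex = sex, values = values,
                 names = colnames(values)),
            class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat("measurement_table: ", length(x$ids), " specimens (",
      sum(x$sex == "male"), " male / ", sum(x$sex == "female"), " female), ",
      length(x$names), " measurement(s): ",
      paste(x$names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of specimens in a measurement table
#' @param table A `measurement_table`.
#' @return Integer count.
#' @export
n_specimens <- function(table) length(table$ids)

# Row subset preserving the class.
subset_rows <- function(table, idx) {
  measurement_table(table$ids[idx], table$sex[idx],
                    table$values[idx, , drop = FALSE])
}

# Column (variable) subset preserving the class.
subset_variables <- function(table, variables) {
  missing_vars <- setdiff(variables, table$names)
  if (length(missing_vars) > 0) {
    stop("variable(s) not in table: ", paste(missing_vars, collapse = ", "))
  }
  measurement_table(table$ids, table$sex,
                    table$values[, variables, drop = FALSE])
}

#' Read a cohort from CSV
#'
#' Expects a header row with an id column, a sex column holding exactly two
#' label values, and numeric measurement columns. Any missing or non-numeric
#' cell is rejected with an error naming the offending row and column.
#'
#' @param path Path to a CSV file (comma separator, `.` decimal, UTF-8).
#' @param sex_column Name of the sex column. Default `"sex"`.
#' @param positive_label The label value mapped to male (the positive class).
#'   Default `"male"`; the other observed label is mapped to female.
#' @param id_column Name of the id column. Default `"id"`.
#' @return A [measurement_table()].
#' @export
read_cohort <- function(path, sex_column = "sex", positive_label = "male",
                        id_column = "id") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(id_column, sex_column)) {
    if (!col %in% names(df)) stop("missing column '", col, "' in ", path)
  }
  ids <- as.character(df[[id_column]])
  raw_sex <- as.character(df[[sex_column]])
  labs <- unique(raw_sex)
  if (length(labs) != 2) {
    stop("sex column must contain exactly two label values, found: ",
         paste(labs, collapse = ", "))
  }
  if (!positive_label %in% labs) {
    stop("positive label '", positive_label, "' absent from sex column")
  }
  sex <- ifelse(raw_sex == positive_label, "male", "female")
  meas_cols <- setdiff(names(df), c(id_column, sex_column))
  if (length(meas_cols) == 0) stop("no measurement columns in ", path)
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(meas_cols),
                 dimnames = list(NULL, meas_cols))
  for (col in meas_cols) {
    v <- df[[col]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0) {
        stop("non-numeric value '", v[bad[1]], "' at row '", ids[bad[1]],
             "', column '", col, "'")
      }
      v <- vn
    }
    nas <- which(is.na(v))
    if (length(nas) > 0) {
      stop("missing value at row '", ids[nas[1]], "', column '", col, "'")
    }
    vals[, col] <- as.numeric(v)
  }
  measurement_table(ids, sex, vals)
}

#' Write a cohort to CSV
#'
#' Writes a header `id,sex,<measurements...>` followed by one row per
#' specimen at full double precision, so that [read_cohort()] round-trips
#' losslessly.
#'
#' @param table A [measurement_table()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "measurement_table"))
  if (length(table$names) == 0) stop("table has no measurement columns")
  df <- data.frame(id = table$ids, sex = as.character(table$sex),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in table$names) {
    df[[nm]] <- format(table$values[, nm], digits = 17, trim = TRUE,
                       scientific = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits a cohort into training and testing partitions with the per-sex
#' training count equal to `round(train_fraction * n_sex)` (round half to
#' even). Deterministic under a fixed seed; partitions are disjoint and
#' jointly exhaustive.
#'
#' @param table A [measurement_table()].
#' @param train_fraction Proportion assigned to training, in (0, 1).
#' @param seed Integer RNG seed.
#' @return List with elements `train` and `test`, both measurement tables.
#' @export
stratified_split <- function(table, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(table, "measurement_table"))
  for (lev in .SEX_LEVELS) {
    if (sum(table$sex == lev) < 2) {
      stop("need at least 2 specimens of each sex to split")
    }
  }
  train_idx <- split_indices_by_sex(table$sex, train_fraction, seed)
  list(train = subset_rows(table, train_idx),
       test = subset_rows(table, setdiff(seq_along(table$ids), train_idx)))
}

#' Balanced stratified subsample
#'
#' Draws `n_total / 2` specimens of each sex without replacement,
#' deterministically under the seed. Used by the training-sample-size sweep.
#'
#' @param table A [measurement_table()].
#' @param n_total Even total size of the subsample.
#' @param seed Integer RNG seed.
#' @return A [measurement_table()] with `n_total` rows.
#' @export
stratified_subsample <- function(table, n_total, seed = 1L) {
  stopifnot(inherits(table, "measurement_table"))
  if (n_total %% 2 != 0) stop("n_total must be even (equal sexes)")
  n_half <- n_total / 2
  with_seed(seed, {
    idx <- integer(0)
    for (lev in .SEX_LEVELS) {
      avail <- which(table$sex == lev)
      if (n_half > length(avail)) {
        stop("requested ", n_half, " ", lev, " specimens but only ",
             length(avail), " available")
      }
      idx <- c(idx, sample(avail, n_half))
    }
    subset_rows(table, sort(idx))
  })
}
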