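#' Encode a categorical column as 0/1
#'
#' Replaces a two-level categorical column (e.g. `Gender` with levels
#' `"M"`/`"F"`) by numeric 0/1 codes so it can enter the Euclidean distance of
#' the affinity graph alongside continuous attributes. All other columns are
#' left untouched and row order is preserved.
#'
#' @param data A data frame.
#' @param column Name of the column to encode (string).
#' @param mapping Named numeric vector mapping each category to 0 or 1,
#'   e.g. `c(M = 0, F = 1)`.
#' @return A tibble with `column` replaced by its numeric codes.
#' @examples
#' df <- tibble::tibble(Gender = c("M", "F", "F"), Age = c(70, 81, 75))
#' encode_categorical(df, "Gender", c(M = 0, F = 1))
#' @export
encode_categorical <- function(data, column, mapping) {
  stopifnot(is.data.frame(data))
  if (!column %in% names(data)) {
    abort(paste0("Column '", column, "' not found."))
  }
  x <- data[[column]]
  obs <- !is.na(x)
  unknown <- setdiff(unique(as.character(x[obs])), names(mapping))
  if (length(unknown) > 0) {
    abort(paste0(
      "Value(s) not in mapping for '", column, "': ",
      paste(unknown, collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(data)
  coded <- rep(NA_real_, length(x))
  coded[obs] <- unname(mapping[as.character(x[obs])])
  out[[column]] <- coded
  out
}

#' Fit per-column min-max normalization state
#'
#' Records, for each named column, the observed minimum and maximum of THIS
#' table only (missing entries ignored), so that [transform_minmax()] can
#' rescale values into \eqn{(x - x_{min}) / (x_{max} - x_{min})}. Fitting on a
#' training fold and applying to a test fold keeps test information out of the
#' normalization (values outside the fitted range transform linearly beyond
#' \[0, 1\] without clamping).
#'
#' @param data A data frame.
#' @param columns Character vector of columns to fit; default all numeric
#'   columns.
#' @return An object of class `minmax_fit`: a tibble with `column`, `min`,
#'   `max`, and a `degenerate` flag for constant columns.
#' @seealso [transform_minmax()], [inverse_minmax()]
#' @export
fit_minmax <- function(data, columns = NULL) {
  stopifnot(is.data.frame(data))
  columns <- columns %||% names(data)[vapply(data, is.numeric, logical(1))]
  missing_cols <- setdiff(columns, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Column(s) not found: ", paste(missing_cols, collapse = ", ")))
  }
  rows <- purrr::map(columns, function(col) {
    v <- data[[col]]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      abort(paste0("Column '", col, "' is all-missing; cannot fit min-max."))
    }
    tibble::tibble(
      column = col, min = min(v), max = max(v),
      degenerate = isTRUE(min(v) == max(v))
    )
  })
  structure(dplyr::bind_rows(rows), class = c("minmax_fit", class(tibble::tibble())))
}

#' Apply fitted min-max normalization
#'
#' Each non-missing value `v` of a fitted column becomes
#' `(v - min) / (max - min)`. Degenerate (constant) columns map to 0.0 so that
#' small folds keep flowing through the pipeline; missing entries stay missing;
#' out-of-range values are transformed linearly without clamping.
#'
#' @param data A data frame.
#' @param fitted A `minmax_fit` from [fit_minmax()].
#' @return A tibble with fitted columns rescaled.
#' @export
transform_minmax <- function(data, fitted) {
  stopifnot(is.data.frame(data), inherits(fitted, "minmax_fit"))
  out <- tibble::as_tibble(data)
  for (i in seq_len(nrow(fitted))) {
    col <- fitted$column[i]
    if (!col %in% names(out)) {
      abort(paste0("Fitted column '", col, "' not present in data."))
    }
    v <- out[[col]]
    if (fitted$degenerate[i]) {
      v[!is.na(v)] <- 0
    } else {
      v <- (v - fitted$min[i]) / (fitted$max[i] - fitted$min[i])
    }
    out[[col]] <- v
  }
  out
}

#' Invert a min-max transform
#'
#' Maps normalized values back to the original scale,
#' `v * (max - min) + min`. Degenerate columns recover the stored constant.
#'
#' @inheritParams transform_minmax
#' @return A tibble on the original scale.
#' @export
inverse_minmax <- function(data, fitted) {
  stopifnot(is.data.frame(data), inherits(fitted, "minmax_fit"))
  out <- tibble::as_tibble(data)
  for (i in seq_len(nrow(fitted))) {
    col <- fitted$column[i]
    v <- out[[col]]
    if (fitted$degenerate[i]) {
      v[!is.na(v)] <- fitted$min[i]
    } else {
      v <- v * (fitted$max[i] - fitted$min[i]) + fitted$min[i]
    }
    out[[col]] <- v
  }
  out
}

#' Fit per-column means for imputation
#'
#' Stores the mean of the non-missing entries of each named column (on the raw
#' scale — imputation precedes normalization, so stored means are directly
#' comparable with published summary statistics).
#'
#' @param data A data frame.
#' @param columns Columns to fit; default: numeric columns containing any `NA`.
#' @return An object of class `impute_fit`: tibble with `column` and `mean`.
#' @export
fit_mean_impute <- function(data, columns = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(columns)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    columns <- num[vapply(num, function(col) anyNA(data[[col]]), logical(1))]
  }
  rows <- purrr::map(columns, function(col) {
    if (!col %in% names(data)) abort(paste0("Column '", col, "' not found."))
    v <- data[[col]]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      abort(paste0("Column '", col, "' is all-missing; cannot fit a mean."))
    }
    tibble::tibble(column = col, mean = mean(v))
  })
  structure(dplyr::bind_rows(rows), class = c("impute_fit", class(tibble::tibble())))
}

#' Fill missing entries with fitted means
#'
#' Replaces `NA` entries of each fitted column with the stored mean; observed
#' values are never touched.
#'
#' @param data A data frame.
#' @param fitted An `impute_fit` from [fit_mean_impute()].
#' @return A tibble with no missing values in the fitted columns.
#' @export
transform_impute <- function(data, fitted) {
  stopifnot(is.data.frame(data))
  if (!inherits(fitted, "impute_fit")) {
    abort("`fitted` must come from fit_mean_impute(); fit before transforming.")
  }
  out <- tibble::as_tibble(data)
  for (i in seq_len(nrow(fitted))) {
    col <- fitted$column[i]
    if (!col %in% names(out)) {
      abort(paste0("Fitted column '", col, "' not present in data."))
    }
    v <- out[[col]]
    v[is.na(v)] <- fitted$mean[i]
    out[[col]] <- v
  }
  out
}

#' Pairwise Pearson correlation matrix
#'
#' Symmetric matrix of Pearson correlations between all numeric columns, used
#' to spot redundant attribute pairs (e.g. an intracranial-volume measure that
#' is a deterministic function of the atlas scaling factor). Zero-variance
#' columns yield `NA` against every other column rather than an error.
#'
#' @param data A data frame with no missing values in its numeric columns
#'   (impute first).
#' @return An n-by-n named correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(data) {
  stopifnot(is.data.frame(data))
  num <- data[vapply(data, is.numeric, logical(1))]
  if (ncol(num) < 1) abort("No numeric columns.")
  if (nrow(num) < 2) abort("Need at least 2 rows.")
  if (anyNA(num)) abort("Missing values present; impute before correlating.")
  X <- as.matrix(num)
  sds <- apply(X, 2, stats::sd)
  R <- suppressWarnings(stats::cor(X))
  # zero-variance columns: undefined against others, 1 on the diagonal
  zero <- which(sds == 0)
  if (length(zero) > 0) {
    R[zero, ] <- NA_real_
    R[, zero] <- NA_real_
  }
  diag(R) <- 1
  R
}

#' Report highly correlated attribute pairs
#'
#' Lists pairs with `|r| >= threshold` so the analyst can decide which
#' redundant attribute to drop; dropping is a deliberate manual step, not
#' automatic.
#'
#' @param data A data frame (no missing numeric values).
#' @param threshold Absolute-correlation threshold, default 0.95.
#' @return A tibble with `var1`, `var2`, `r`, ordered by decreasing `|r|`.
#' @export
correlation_screen <- function(data, threshold = 0.95) {
  R <- pearson_matrix(data)
  nm <- colnames(R)
  idx <- which(upper.tri(R) & !is.na(R) & abs(R) >= threshold, arr.ind = TRUE)
  tibble::tibble(
    var1 = nm[idx[, 1]],
    var2 = nm[idx[, 2]],
    r = R[idx]
  ) |>
    dplyr::arrange(dplyr::desc(abs(.data$r)))
}

#' Fit the full preprocessing pipeline
#'
#' Convenience wrapper fitting, in order: categorical encoding, mean
#' imputation (raw scale), then min-max normalization — the preparation used
#' before graph construction. The label column, if named, is carried through
#' untouched.
#'
#' @param data Training data frame.
#' @param label Optional label column name, excluded from preprocessing.
#' @param encode Named list: column -> named 0/1 mapping, e.g.
#'   `list(Gender = c(M = 0, F = 1))`.
#' @param impute_cols Columns to mean-impute; default auto-detects numeric
#'   columns with missing values (after encoding).
#' @param drop_cols Columns to drop entirely (e.g. a redundant attribute
#'   flagged by [correlation_screen()]).
#' @return A `feature_prep` object with the fitted state.
#' @export
preprocess_fit <- function(data, label = NULL, encode = list(),
                           impute_cols = NULL, drop_cols = NULL) {
  stopifnot(is.data.frame(data))
  work <- tibble::as_tibble(data)
  if (!is.null(drop_cols)) work <- work[setdiff(names(work), drop_cols)]
  for (col in names(encode)) {
    work <- encode_categorical(work, col, encode[[col]])
  }
  feat_cols <- setdiff(
    names(work)[vapply(work, is.numeric, logical(1))], label
  )
  feats <- work[feat_cols]
  imp <- fit_mean_impute(feats, columns = impute_cols)
  feats <- transform_impute(feats, imp)
  mm <- fit_minmax(feats, columns = feat_cols)
  structure(
    list(
      label = label, encode = encode, drop_cols = drop_cols,
      impute = imp, minmax = mm, feature_names = feat_cols
    ),
    class = "feature_prep"
  )
}

#' Apply a fitted preprocessing pipeline
#'
#' @param prep A `feature_prep` from [preprocess_fit()].
#' @param data New data frame with the same columns as the training data.
#' @return A tibble of normalized features (plus the label column if present).
#' @export
preprocess_apply <- function(prep, data) {
  stopifnot(inherits(prep, "feature_prep"), is.data.frame(data))
  work <- tibble::as_tibble(data)
  if (!is.null(prep$drop_cols)) work <- work[setdiff(names(work), prep$drop_cols)]
  for (col in names(prep$encode)) {
    work <- encode_categorical(work, col, prep$encode[[col]])
  }
  feats <- work[prep$feature_names]
  feats <- transform_impute(feats, prep$impute)
  feats <- transform_minmax(feats, prep$minmax)
  if (!is.null(prep$label) && prep$label %in% names(work)) {
    feats[[prep$label]] <- work[[prep$label]]
  }
  feats
}

#' @export
print.feature_prep <- function(x, ...) {
  cat("<feature_prep> ", length(x$feature_names), " features\n", sep = "")
  cat("  imputed: ", paste(x$impute$column, collapse = ", "), "\n", sep = "")
  cat("  normalized: min-max to [0,1] on training ranges\n")
  invisible(x)
}

#' Serialize fitted preprocessing state to JSON
#'
#' @param prep A `feature_prep`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_prep_json <- function(prep, path) {
  stopifnot(inherits(prep, "feature_prep"))
  obj <- list(
    label = prep$label,
    encode = purrr::map(prep$encode, as.list),
    drop_cols = prep$drop_cols,
    impute = as.list(tibble::as_tibble(prep$impute)),
    minmax = as.list(tibble::as_tibble(prep$minmax)),
    feature_names = prep$feature_names
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Read fitted preprocessing state from JSON
#'
#' @param path File written by [write_prep_json()].
#' @return A `feature_prep` object.
#' @export
read_prep_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      label = obj$label,
      encode = purrr::map(obj$encode, unlist),
      drop_cols = obj$drop_cols,
      impute = structure(tibble::as_tibble(obj$impute),
        class = c("impute_fit", class(tibble::tibble()))
      ),
      minmax = structure(tibble::as_tibble(obj$minmax),
        class = c("minmax_fit", class(tibble::tibble()))
      ),
      feature_names = obj$feature_names
    ),
    class = "feature_prep"
  )
}

#' Read a subject-by-attribute CSV
#'
#' Header row expected; empty fields and "NA" are read as missing.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_feature_csv <- function(path) {
  readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE)
}
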