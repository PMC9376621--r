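#' Fit the full dominant-set ANFIS classifier
#'
#' End-to-end training on a subject-by-attribute data frame: preprocess
#' (encode, mean-impute, min-max normalize on this data's ranges), build the
#' Gaussian-affinity graph, peel off dominant sets, convert clusters to
#' Gaussian fuzzy rules, and (optionally) refine the rule base with hybrid
#' ANFIS learning. The number of rules is discovered by the peeling, never
#' pre-specified.
#'
#' @param data Data frame with numeric features and one binary 0/1 label
#'   column.
#' @param label Name of the label column.
#' @param encode Named list of categorical 0/1 encodings passed to
#'   [preprocess_fit()].
#' @param drop_cols Columns to exclude (e.g. redundant attributes flagged by
#'   [correlation_screen()]).
#' @param sigma2 Kernel bandwidth rule or value, see [gaussian_affinity()].
#' @param min_remaining,support_eps,max_iter,min_increment Peeling controls,
#'   see [peel_off()].
#' @param include_residual Convert the residual clutter group into a rule
#'   (default TRUE).
#' @param sigma_floor Minimum Gaussian membership width.
#' @param optimize Run hybrid ANFIS learning after initialization (default
#'   TRUE); `FALSE` keeps the cluster-initialized rules (the unsupervised
#'   ablation).
#' @param epochs,learning_rate,mf_convention ANFIS training controls, see
#'   [anfis_model()].
#' @return A `ds_anfis` fit: list with `prep` (fitted preprocessing), `graph`
#'   parameters, `partition`, `model` (the `anfis_model`), and `label`.
#' @examples
#' spec <- blob_spec(
#'   centers = list(c(0.2, 0.2), c(0.8, 0.8)),
#'   spreads = 0.05, sizes = 15, labels = c(0, 1), seed = 1
#' )
#' blobs <- make_blobs(spec)
#' fit <- ds_anfis(blobs$data, label = "label", epochs = 10)
#' predict(fit, blobs$data)
#' @export
ds_anfis <- function(data, label,
                     encode = list(), drop_cols = NULL,
                     sigma2 = "auto_dist_var",
                     min_remaining = 2, support_eps = 1e-5,
                     max_iter = 1000, min_increment = 1e-8,
                     include_residual = TRUE, sigma_floor = 0.01,
                     optimize = TRUE, epochs = 50, learning_rate = 0.01,
                     mf_convention = "half") {
  stopifnot(is.data.frame(data), label %in% names(data))
  prep <- preprocess_fit(data,
    label = label, encode = encode,
    drop_cols = drop_cols
  )
  prepped <- preprocess_apply(prep, data)
  y <- prepped[[label]]
  if (!all(y %in% c(0, 1))) abort("Label column must be binary 0/1.")
  X <- as.matrix(prepped[setdiff(names(prepped), label)])
  graph <- gaussian_affinity(X, sigma2 = sigma2)
  partition <- peel_off(graph,
    min_remaining = min_remaining,
    support_eps = support_eps, max_iter = max_iter,
    min_increment = min_increment
  )
  rb <- build_rule_base(X, y, partition,
    include_residual = include_residual, sigma_floor = sigma_floor
  )
  model <- anfis_model(rb,
    learning_rate = learning_rate, epochs = epochs,
    sigma_floor = sigma_floor, mf_convention = mf_convention
  )
  if (optimize) model <- anfis_fit(model, X, y)
  structure(
    list(
      prep = prep, sigma2 = graph$sigma2, partition = partition,
      model = model, label = label
    ),
    class = "ds_anfis"
  )
}

#' Predict from a fitted dominant-set ANFIS classifier
#'
#' Applies the training-fitted preprocessing to the new data, then runs ANFIS
#' inference and thresholds at 0.5.
#'
#' @param object A `ds_anfis` fit.
#' @param new_data Data frame with the training columns (label optional).
#' @param ... Unused.
#' @return A tibble with `raw`, `class`, `confidence`, one row per input row.
#' @export
predict.ds_anfis <- function(object, new_data, ...) {
  prepped <- preprocess_apply(object$prep, new_data)
  X <- as.matrix(prepped[object$model$feature_names])
  predict_class(object$model, X)
}

#' @export
print.ds_anfis <- function(x, ...) {
  cat("<ds_anfis> ", nrow(x$model$centers), " rules, ",
    length(x$model$feature_names), " features, kernel sigma2 = ",
    format(x$sigma2, digits = 4), "\n",
    sep = ""
  )
  print(x$model)
  invisible(x)
}

#' @export
tidy.ds_anfis <- function(x, ...) {
  tidy(x$model)
}

#' @export
glance.ds_anfis <- function(x, ...) {
  dplyr::mutate(glance(x$model),
    n_clusters = length(x$partition$clusters),
    n_residual = length(x$partition$residual),
    sigma2 = x$sigma2
  )
}
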