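#' Stratified k-fold assignment
#'
#' Splits row indices into `k` disjoint folds preserving class proportions:
#' within each class the (shuffled) members are dealt so per-fold class counts
#' differ from exact proportionality by at most one, and the classes' surplus
#' members are rotated across folds so total fold sizes also differ by at most
#' the number of classes. Deterministic given `seed`.
#'
#' @param labels Vector of class labels (any type).
#' @param k Number of folds (2 <= k <= length(labels)).
#' @param seed Integer seed controlling the shuffle.
#' @return A list of `k` integer index vectors.
#' @export
stratified_folds <- function(labels, k, seed) {
  M <- length(labels)
  if (k > M) abort("k cannot exceed the number of rows.")
  if (k < 2) abort("k must be at least 2.")
  classes <- unique(labels)
  small <- classes[vapply(
    classes, function(cl) sum(labels == cl) < k, logical(1)
  )]
  if (length(small) > 0) {
    warn(paste0(
      "Class(es) with fewer members than folds: ",
      paste(small, collapse = ", "), "; some folds will lack them."
    ))
  }
  folds <- vector("list", k)
  offset <- 0L
  withr::with_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      n_c <- length(idx)
      base <- n_c %/% k
      extras <- n_c %% k
      counts <- rep(base, k)
      if (extras > 0) {
        bump <- ((offset + seq_len(extras) - 1L) %% k) + 1L
        counts[bump] <- counts[bump] + 1L
        offset <- (offset + extras) %% k
      }
      pos <- 0L
      for (f in seq_len(k)) {
        if (counts[f] > 0) {
          folds[[f]] <- c(folds[[f]], idx[pos + seq_len(counts[f])])
          pos <- pos + counts[f]
        }
      }
    }
  })
  purrr::map(folds, sort)
}

#' Confusion-matrix counts
#'
#' Class 1 (demented) is the positive class by default.
#'
#' @param truth Vector of true 0/1 labels.
#' @param estimate Vector of predicted 0/1 labels, same length.
#' @param positive The positive class value (default 1).
#' @return A `confusion_summary`: tibble with one row, columns `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion <- function(truth, estimate, positive = 1) {
  if (length(truth) != length(estimate)) {
    abort("truth and estimate must have equal length.")
  }
  pos_t <- truth == positive
  pos_e <- estimate == positive
  out <- tibble::tibble(
    tp = sum(pos_t & pos_e),
    tn = sum(!pos_t & !pos_e),
    fp = sum(!pos_t & pos_e),
    fn = sum(pos_t & !pos_e)
  )
  structure(out, class = c("confusion_summary", class(out)))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall (sensitivity), and specificity, each as a
#' percentage. A metric whose denominator is zero is returned as `NA` rather
#' than raising an error.
#'
#' @param cs A `confusion_summary` from [confusion()], or any one-row data
#'   frame / named list with `tp`, `tn`, `fp`, `fn`.
#' @return A tibble with `accuracy`, `precision`, `recall`, `specificity`
#'   (percentages in \[0, 100\]).
#' @examples
#' classification_metrics(list(tp = 1249, tn = 1798, fp = 262, fn = 421))
#' @export
classification_metrics <- function(cs) {
  tp <- cs$tp
  tn <- cs$tn
  fp <- cs$fp
  fn <- cs$fn
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble::tibble(
    accuracy = rate(tp + tn, tp + tn + fp + fn),
    precision = rate(tp, tp + fp),
    recall = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp)
  )
}

#' Stratified repeated cross-validation of the DS-ANFIS pipeline
#'
#' For each repeat: derive a run seed, split stratified folds, and for each
#' fold fit the full pipeline on the training rows (preprocessing statistics
#' are fitted inside the training fold — no leakage) and score the held-out
#' fold. Reports per-fold accuracies, per-run means with their across-fold
#' SDs, the across-run mean and SD, pooled confusion counts over all scored
#' instances, and the mean rule count. Fully deterministic given `base_seed`.
#'
#' @param data Data frame with features and a binary label column.
#' @param label Label column name.
#' @param k Number of folds (default 10).
#' @param repeats Number of repeated CVs (default 10).
#' @param base_seed Integer; run `r` uses seed `base_seed + r - 1`.
#' @param optimize `TRUE` (default) for the full hybrid-trained system;
#'   `FALSE` for the ablation using cluster-initialized rules only.
#' @param ... Further arguments passed to [ds_anfis()] (e.g. `epochs`,
#'   `encode`, `drop_cols`).
#' @return A `ds_cv` object: list with `folds` (tibble: run, fold, n_test,
#'   accuracy, n_rules), `runs` (tibble: run, mean accuracy, sd over folds),
#'   `pooled` (a `confusion_summary` over all runs x instances),
#'   `mean_rules`, `errors` (tibble of any failed folds; empty when clean).
#' @export
repeated_cv <- function(data, label, k = 10, repeats = 10, base_seed = 1,
                        optimize = TRUE, ...) {
  stopifnot(is.data.frame(data), label %in% names(data))
  y_all <- data[[label]]
  fold_rows <- list()
  err_rows <- list()
  pooled <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (r in seq_len(repeats)) {
    run_seed <- base_seed + r - 1L
    folds <- stratified_folds(y_all, k = k, seed = run_seed)
    for (f in seq_along(folds)) {
      test_idx <- folds[[f]]
      train <- data[-test_idx, , drop = FALSE]
      test <- data[test_idx, , drop = FALSE]
      res <- tryCatch(
        {
          fit <- ds_anfis(train, label = label, optimize = optimize, ...)
          pred <- predict(fit, test)
          cs <- confusion(test[[label]], pred$class)
          list(
            acc = 100 * (cs$tp + cs$tn) / nrow(test),
            cs = cs, n_rules = nrow(fit$model$centers)
          )
        },
        error = function(e) e
      )
      if (inherits(res, "error")) {
        err_rows <- c(err_rows, list(tibble::tibble(
          run = r, fold = f, message = conditionMessage(res)
        )))
        next
      }
      pooled <- pooled + c(
        tp = res$cs$tp, tn = res$cs$tn, fp = res$cs$fp, fn = res$cs$fn
      )
      fold_rows <- c(fold_rows, list(tibble::tibble(
        run = r, fold = f, n_test = nrow(test),
        accuracy = res$acc, n_rules = res$n_rules
      )))
    }
  }
  fold_tbl <- dplyr::bind_rows(fold_rows)
  runs <- fold_tbl |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      accuracy = mean(.data$accuracy),
      sd_folds = stats::sd(.data$accuracy),
      mean_rules = mean(.data$n_rules),
      .groups = "drop"
    )
  pooled_cs <- confusion(
    truth = c(rep(1, pooled["tp"] + pooled["fn"]), rep(0, pooled["tn"] + pooled["fp"])),
    estimate = c(
      rep(1, pooled["tp"]), rep(0, pooled["fn"]),
      rep(0, pooled["tn"]), rep(1, pooled["fp"])
    )
  )
  structure(
    list(
      folds = fold_tbl,
      runs = runs,
      pooled = pooled_cs,
      mean_accuracy = mean(runs$accuracy),
      sd_runs = stats::sd(runs$accuracy),
      mean_rules = mean(fold_tbl$n_rules),
      errors = if (length(err_rows)) {
        dplyr::bind_rows(err_rows)
      } else {
        tibble::tibble(run = integer(), fold = integer(), message = character())
      },
      k = k, repeats = repeats, base_seed = base_seed
    ),
    class = "ds_cv"
  )
}

#' @export
print.ds_cv <- function(x, ...) {
  cat("<ds_cv> ", x$repeats, " x ", x$k, "-fold stratified CV\n", sep = "")
  cat(sprintf(
    "  accuracy: %.3f%% (SD over runs %.3f), mean rules %.2f\n",
    x$mean_accuracy, x$sd_runs, x$mean_rules
  ))
  if (nrow(x$errors) > 0) {
    cat("  !! ", nrow(x$errors), " fold(s) failed\n", sep = "")
  }
  invisible(x)
}

#' Tidy cross-validation results
#'
#' @param x A `ds_cv`.
#' @param ... Unused.
#' @return The per-fold tibble (`run`, `fold`, `n_test`, `accuracy`,
#'   `n_rules`).
#' @export
tidy.ds_cv <- function(x, ...) {
  x$folds
}

#' @export
glance.ds_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      mean_accuracy = x$mean_accuracy,
      sd_runs = x$sd_runs,
      mean_rules = x$mean_rules,
      k = x$k, repeats = x$repeats,
      failed_folds = nrow(x$errors)
    ),
    classification_metrics(x$pooled) |>
      dplyr::rename_with(~ paste0("pooled_", .x))
  )
}

#' Plot cross-validation accuracies
#'
#' Box plot of fold accuracies per repeat, with the across-run mean overlaid.
#'
#' @param object A `ds_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ds_cv <- function(object, ...) {
  ggplot2::ggplot(
    object$folds,
    ggplot2::aes(x = factor(.data$run), y = .data$accuracy)
  ) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::geom_hline(
      yintercept = object$mean_accuracy,
      linetype = "dashed", color = "steelblue"
    ) +
    ggplot2::labs(
      x = "run", y = "fold accuracy (%)",
      title = "Stratified repeated cross-validation"
    ) +
    ggplot2::theme_minimal()
}

#' Write a cross-validation report
#'
#' Per-fold CSV plus a JSON summary (run means, pooled confusion counts and
#' metrics, mean rule count).
#'
#' @param cv A `ds_cv`.
#' @param csv_path Path for the per-fold CSV.
#' @param json_path Path for the JSON summary.
#' @return Invisibly, a list with both paths.
#' @export
write_cv_report <- function(cv, csv_path, json_path) {
  stopifnot(inherits(cv, "ds_cv"))
  readr::write_csv(cv$folds, csv_path)
  summary <- list(
    k = cv$k, repeats = cv$repeats, base_seed = cv$base_seed,
    mean_accuracy = cv$mean_accuracy, sd_runs = cv$sd_runs,
    mean_rules = cv$mean_rules,
    runs = as.list(cv$runs),
    pooled = as.list(tibble::as_tibble(cv$pooled)),
    pooled_metrics = as.list(classification_metrics(cv$pooled)),
    failed_folds = nrow(cv$errors)
  )
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = I(17))
  invisible(list(csv = csv_path, json = json_path))
}
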