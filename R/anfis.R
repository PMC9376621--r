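#' Initialize an ANFIS model from a rule base
#'
#' Wraps a rule base with the training configuration for the zero-order TSK
#' engine. Premise parameters (Gaussian centers and widths) and consequents
#' are copied into dense matrices; the rule count and feature set are fixed
#' for the model's lifetime — hybrid learning tunes parameters only, never
#' structure.
#'
#' @param rule_base A `rule_base` from [build_rule_base()].
#' @param learning_rate Gradient-descent step size for premise parameters
#'   (default 0.01).
#' @param epochs Default number of hybrid-learning epochs (default 50).
#' @param sigma_floor Minimum membership width enforced after every update.
#' @param mf_convention `"half"` (default): \eqn{\mu = \exp(-(x-c)^2/(2\sigma^2))},
#'   the standard Gaussian membership; `"plain"`:
#'   \eqn{\mu = \exp(-((x-c)/\sigma)^2)}.
#' @return An `anfis_model`.
#' @export
anfis_model <- function(rule_base, learning_rate = 0.01, epochs = 50,
                        sigma_floor = 0.01,
                        mf_convention = c("half", "plain")) {
  stopifnot(inherits(rule_base, "rule_base"))
  mf_convention <- match.arg(mf_convention)
  centers <- rb_centers(rule_base)
  sigmas <- rb_sigmas(rule_base)
  structure(
    list(
      centers = centers,
      sigmas = pmax(sigmas, sigma_floor),
      consequents = rb_consequents(rule_base),
      feature_names = rule_base$feature_names,
      support_sizes = vapply(rule_base$rules, `[[`, numeric(1), "support_size"),
      config = list(
        learning_rate = learning_rate, epochs = epochs,
        sigma_floor = sigma_floor, mf_convention = mf_convention
      ),
      history = tibble::tibble(
        epoch = integer(), mse_before = numeric(),
        mse_after_lse = numeric(), mse_after_grad = numeric()
      ),
      trained = FALSE
    ),
    class = "anfis_model"
  )
}

#' Recover the rule base of an ANFIS model
#'
#' @param model An `anfis_model`.
#' @return A `rule_base` with the model's current (possibly trained)
#'   parameters; consequents are real-valued after training.
#' @export
as_rule_base <- function(model) {
  stopifnot(inherits(model, "anfis_model"))
  D <- nrow(model$centers)
  rules <- purrr::map(seq_len(D), function(d) {
    ctr <- model$centers[d, ]
    sg <- model$sigmas[d, ]
    names(ctr) <- model$feature_names
    names(sg) <- model$feature_names
    structure(
      list(
        centers = ctr, sigmas = sg,
        consequent = model$consequents[d],
        support_size = model$support_sizes[d]
      ),
      class = "fuzzy_rule"
    )
  })
  structure(
    list(
      rules = rules, feature_names = model$feature_names,
      class_labels = c(negative = 0, positive = 1)
    ),
    class = "rule_base"
  )
}

#' Gaussian membership degree
#'
#' Default ("half") convention \eqn{\mu(x) = \exp(-(x-c)^2 / (2\sigma^2))};
#' the "plain" convention omits the 1/2. Vectorized over `x`; always in
#' (0, 1\].
#'
#' @param mf A `gaussian_mf` (or any list with `center` and `sigma`).
#' @param x Numeric vector of input values.
#' @param convention `"half"` or `"plain"`.
#' @return Membership degrees in (0, 1\].
#' @export
membership_degree <- function(mf, x, convention = c("half", "plain")) {
  convention <- match.arg(convention)
  stopifnot(mf$sigma > 0)
  q <- ((x - mf$center) / mf$sigma)^2
  if (convention == "half") exp(-q / 2) else exp(-q)
}

# M x D matrix of log firing strengths
log_firing_matrix <- function(model, X) {
  X <- as.matrix(X)
  D <- nrow(model$centers)
  n <- ncol(model$centers)
  if (ncol(X) != n) abort("Feature count does not match the rule base.")
  if (anyNA(X)) abort("Missing feature values; impute upstream.")
  half <- model$config$mf_convention == "half"
  out <- matrix(0, nrow(X), D)
  for (d in seq_len(D)) {
    Q <- sweep(X, 2, model$centers[d, ], "-")
    Q <- sweep(Q^2, 2, model$sigmas[d, ]^2, "/")
    out[, d] <- if (half) -rowSums(Q) / 2 else -rowSums(Q)
  }
  out
}

# M x D normalized firing strengths, numerically stable (softmax in log space;
# each row has a unit maximum before normalization, so the sum never underflows)
normalized_firing_matrix <- function(model, X) {
  lw <- log_firing_matrix(model, X)
  lw <- lw - apply(lw, 1, max)
  w <- exp(lw)
  w / rowSums(w)
}

#' Rule firing strengths for one input
#'
#' \eqn{w_d = \prod_k \mu_{A^d_k}(x_k)}: the product T-norm across the rule's
#' per-feature membership degrees.
#'
#' @param model An `anfis_model`.
#' @param x Numeric feature vector (fully observed).
#' @return A length-D positive vector (may underflow to 0 for inputs far from
#'   every rule; see [normalize_firing()]).
#' @export
firing_strengths <- function(model, x) {
  stopifnot(inherits(model, "anfis_model"))
  as.numeric(exp(log_firing_matrix(model, matrix(x, nrow = 1))))
}

#' Normalize firing strengths
#'
#' \eqn{\bar w_d = w_d / \sum_d w_d}, the rule's relative contribution. If the
#' total underflows to zero (an input astronomically far from every rule), the
#' contribution falls back to uniform 1/D with a warning.
#'
#' @param w Nonnegative vector of firing strengths.
#' @return A vector summing to 1.
#' @export
normalize_firing <- function(w) {
  stopifnot(all(w >= 0))
  s <- sum(w)
  if (s == 0) {
    warn("All firing strengths underflowed; falling back to uniform weights.",
      class = "dsanfis_firing_underflow"
    )
    return(rep(1 / length(w), length(w)))
  }
  w / s
}

#' ANFIS inference
#'
#' Overall output \eqn{z = \sum_d \bar w_d z_d} — a convex combination of the
#' rule consequents, weighted by normalized firing strengths.
#'
#' @param model An `anfis_model`.
#' @param X Numeric feature vector, matrix, or data frame (rows = subjects).
#' @return Numeric vector of raw outputs, one per input row.
#' @export
anfis_infer <- function(model, X) {
  stopifnot(inherits(model, "anfis_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  wbar <- normalized_firing_matrix(model, X)
  as.numeric(wbar %*% model$consequents)
}

#' Classify with confidence
#'
#' Thresholds the raw output at 0.5 (ties to positive): class 1 when
#' \eqn{z \ge 0.5}, with confidence `z` for positive calls and `1 - z` for
#' negative ones, clamped into \[0.5, 1\] (trained consequents are unbounded,
#' so the raw output can leave the unit interval).
#'
#' @param model An `anfis_model`.
#' @param X Feature vector, matrix, or data frame.
#' @return A tibble with `raw`, `class` (integer 0/1), `confidence`.
#' @export
predict_class <- function(model, X) {
  z <- anfis_infer(model, X)
  cls <- as.integer(z >= 0.5)
  zc <- pmin(pmax(z, 0), 1)
  conf <- ifelse(cls == 1L, zc, 1 - zc)
  tibble::tibble(raw = z, class = cls, confidence = conf)
}

model_mse <- function(model, X, y) {
  mean((anfis_infer(model, X) - y)^2)
}

#' Least-squares estimation of rule consequents (forward pass)
#'
#' With premises fixed, the output is linear in the consequents with design
#' matrix \eqn{\bar W} (rows = normalized firing vectors); the step sets the
#' consequents to the least-squares solution, using the minimum-norm solution
#' via SVD when \eqn{\bar W} is rank-deficient (e.g. two rules firing
#' identically on all data). Training SSE never increases.
#'
#' @param model An `anfis_model`.
#' @param X Feature matrix or data frame.
#' @param y Numeric target vector (0/1 class labels for classification).
#' @return The model with updated consequents.
#' @export
lse_consequents <- function(model, X, y) {
  stopifnot(inherits(model, "anfis_model"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  Wbar <- normalized_firing_matrix(model, X)
  sv <- svd(Wbar)
  tol <- max(dim(Wbar)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  z <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  model$consequents <- as.numeric(z)
  model
}

# analytic gradient of mean squared error wrt centers and sigmas, both D x n
premise_gradients <- function(model, X, y) {
  X <- as.matrix(X)
  M <- nrow(X)
  Wbar <- normalized_firing_matrix(model, X)
  yhat <- as.numeric(Wbar %*% model$consequents)
  r <- yhat - y
  # G[i, d] = r_i * (z_d - yhat_i) * wbar_id ; then
  # dE/dc_dk  = (2/M) * fac * sum_i G_id (x_ik - c_dk) / sigma_dk^2
  # dE/ds_dk  = (2/M) * fac * sum_i G_id (x_ik - c_dk)^2 / sigma_dk^3
  # fac = 1 for the "half" convention, 2 for "plain"
  G <- (outer(r, model$consequents) - r * yhat) * Wbar
  S0 <- colSums(G) # length D
  S1 <- crossprod(G, X) # D x n
  S2 <- crossprod(G, X^2) # D x n
  C <- model$centers
  S <- model$sigmas
  fac <- if (model$config$mf_convention == "half") 1 else 2
  grad_c <- (2 / M) * fac * (S1 - C * S0) / S^2
  grad_s <- (2 / M) * fac * (S2 - 2 * C * S1 + C^2 * S0) / S^3
  list(centers = grad_c, sigmas = grad_s)
}

#' One gradient-descent step on premise parameters (backward pass)
#'
#' Batch gradient descent on the mean squared error of the inference output,
#' with analytic gradients propagated through the membership, firing,
#' normalization, and output layers. Widths are re-floored after the update
#' so memberships stay proper. Consequents are held fixed.
#'
#' @param model An `anfis_model`.
#' @param X Feature matrix or data frame.
#' @param y Numeric target vector.
#' @param learning_rate Step size; default the model's configured rate.
#' @return The model with updated centers and sigmas.
#' @export
gradient_premise_step <- function(model, X, y,
                                  learning_rate = model$config$learning_rate) {
  stopifnot(inherits(model, "anfis_model"))
  g <- premise_gradients(model, X, y)
  model$centers <- model$centers - learning_rate * g$centers
  model$sigmas <- pmax(
    model$sigmas - learning_rate * g$sigmas,
    model$config$sigma_floor
  )
  model
}

#' Hybrid ANFIS training
#'
#' Each epoch runs the forward least-squares pass on the consequents, then one
#' backward gradient-descent step on the Gaussian premise parameters. The rule
#' count and feature set never change; only parameters adapt. Per-epoch MSE is
#' recorded in the model history.
#'
#' @param model An `anfis_model` (freshly initialized or partially trained).
#' @param X Feature matrix or data frame.
#' @param y Numeric target vector (0/1 labels).
#' @param epochs Number of epochs; default the model's configured count.
#'   `epochs = 0` returns the model unchanged.
#' @param learning_rate Premise step size; default the configured rate.
#' @return The trained `anfis_model` with an appended `history` tibble
#'   (`epoch`, `mse_before`, `mse_after_lse`, `mse_after_grad`).
#' @export
anfis_fit <- function(model, X, y, epochs = model$config$epochs,
                      learning_rate = model$config$learning_rate) {
  stopifnot(inherits(model, "anfis_model"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (epochs == 0) {
    return(model)
  }
  hist_rows <- vector("list", epochs)
  offset <- nrow(model$history)
  for (e in seq_len(epochs)) {
    mse0 <- model_mse(model, X, y)
    model <- lse_consequents(model, X, y)
    mse1 <- model_mse(model, X, y)
    model <- gradient_premise_step(model, X, y, learning_rate = learning_rate)
    mse2 <- model_mse(model, X, y)
    hist_rows[[e]] <- tibble::tibble(
      epoch = offset + e, mse_before = mse0,
      mse_after_lse = mse1, mse_after_grad = mse2
    )
  }
  model$history <- dplyr::bind_rows(model$history, hist_rows)
  model$trained <- TRUE
  model
}

#' @export
print.anfis_model <- function(x, ...) {
  cat("<anfis_model> ", nrow(x$centers), " rules x ", ncol(x$centers),
    " features (", if (x$trained) "trained" else "initialized", ")\n",
    sep = ""
  )
  if (nrow(x$history) > 0) {
    cat("  final training MSE: ",
      format(x$history$mse_after_grad[nrow(x$history)], digits = 5), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @export
tidy.anfis_model <- function(x, ...) {
  tidy(as_rule_base(x))
}

#' @export
glance.anfis_model <- function(x, ...) {
  tibble::tibble(
    n_rules = nrow(x$centers),
    n_features = ncol(x$centers),
    trained = x$trained,
    epochs = nrow(x$history),
    final_mse = if (nrow(x$history) > 0) {
      x$history$mse_after_grad[nrow(x$history)]
    } else {
      NA_real_
    }
  )
}

#' Plot the training history of an ANFIS model
#'
#' Mean squared error across epochs, after each least-squares and gradient
#' sub-step.
#'
#' @param object A trained `anfis_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.anfis_model <- function(object, ...) {
  if (nrow(object$history) == 0) abort("Model has no training history yet.")
  df <- tidyr::pivot_longer(object$history,
    cols = c("mse_after_lse", "mse_after_grad"),
    names_to = "stage", values_to = "mse"
  ) |>
    dplyr::mutate(stage = dplyr::recode(.data$stage,
      mse_after_lse = "after LSE pass",
      mse_after_grad = "after gradient pass"
    ))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$epoch, y = .data$mse,
    color = .data$stage
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "epoch", y = "training MSE",
      title = "Hybrid ANFIS learning curve", color = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Save an ANFIS model to JSON
#'
#' Stores the rule base, configuration, and training history.
#'
#' @param model An `anfis_model`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_anfis_json <- function(model, path) {
  stopifnot(inherits(model, "anfis_model"))
  obj <- list(
    features = model$feature_names,
    centers = apply(model$centers, 1, identity, simplify = FALSE),
    sigmas = apply(model$sigmas, 1, identity, simplify = FALSE),
    consequents = model$consequents,
    support_sizes = model$support_sizes,
    config = model$config,
    history = as.list(model$history),
    trained = model$trained
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load an ANFIS model from JSON
#'
#' @param path File written by [write_anfis_json()].
#' @return An `anfis_model`.
#' @export
read_anfis_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- as.character(unlist(obj$features))
  centers <- do.call(rbind, purrr::map(obj$centers, ~ as.numeric(unlist(.x))))
  sigmas <- do.call(rbind, purrr::map(obj$sigmas, ~ as.numeric(unlist(.x))))
  colnames(centers) <- feats
  colnames(sigmas) <- feats
  history <- purrr::map(obj$history, ~ as.numeric(unlist(.x)))
  history$epoch <- as.integer(history$epoch)
  structure(
    list(
      centers = centers, sigmas = sigmas,
      consequents = as.numeric(unlist(obj$consequents)),
      feature_names = feats,
      support_sizes = as.numeric(unlist(obj$support_sizes)),
      config = list(
        learning_rate = as.numeric(obj$config$learning_rate),
        epochs = as.numeric(obj$config$epochs),
        sigma_floor = as.numeric(obj$config$sigma_floor),
        mf_convention = obj$config$mf_convention
      ),
      history = tibble::as_tibble(history),
      trained = isTRUE(obj$trained)
    ),
    class = "anfis_model"
  )
}
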