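#' Pairwise squared Euclidean distances
#'
#' Entry (i, j) is \eqn{\sum_k (x_{ik} - x_{jk})^2}; symmetric, nonnegative,
#' zero diagonal. Computed via the Gram-matrix identity with a clamp at zero
#' to absorb floating-point cancellation.
#'
#' @param X Numeric matrix or data frame, rows = subjects.
#' @return An M-by-M matrix of squared distances.
#' @export
pairwise_sq_distances <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) abort("Missing values present; impute before computing distances.")
  storage.mode(X) <- "double"
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  D2 <- (D2 + t(D2)) / 2
  diag(D2) <- 0
  D2
}

#' Gaussian-kernel affinity graph
#'
#' Builds the edge-weighted undirected graph over subjects: affinity
#' \eqn{a_{ij} = \exp(-d_{ij}^2 / \sigma^2)} for \eqn{i \ne j} with a zero
#' diagonal (no self-loops). Features should already be normalized to
#' comparable scales (e.g. min-max to \[0, 1\]).
#'
#' The automatic bandwidth follows the convention that \eqn{\sigma^2} is the
#' variance of the pairwise distances: `"auto_dist_var"` (default) uses the
#' variance of the unsquared upper-triangle Euclidean distances;
#' `"auto_sqdist_var"` uses the variance of the squared distances; a positive
#' number fixes \eqn{\sigma^2} directly.
#'
#' @param X Numeric matrix or data frame of normalized features (M >= 2 rows).
#' @param sigma2 `"auto_dist_var"`, `"auto_sqdist_var"`, or a positive number.
#' @return An `affinity_graph`: list with `A` (M-by-M affinity matrix),
#'   `sigma2`, and `node_ids` (row indices into the source table).
#' @examples
#' X <- rbind(c(0, 0), c(1, 0), c(0, 2))
#' g <- gaussian_affinity(X, sigma2 = 1)
#' g$A[1, 2] # exp(-1)
#' @export
gaussian_affinity <- function(X, sigma2 = "auto_dist_var") {
  X <- as.matrix(X)
  if (nrow(X) < 2) abort("Need at least 2 subjects to build a graph.")
  D2 <- pairwise_sq_distances(X)
  if (is.character(sigma2)) {
    d2_upper <- D2[upper.tri(D2)]
    s2 <- switch(sigma2,
      auto_dist_var = stats::var(sqrt(d2_upper)),
      auto_sqdist_var = stats::var(d2_upper),
      abort(paste0("Unknown bandwidth rule '", sigma2, "'."))
    )
    if (!is.finite(s2) || s2 <= 0) {
      abort(paste0(
        "Automatic bandwidth failed (zero variance of pairwise distances); ",
        "supply an explicit positive sigma2."
      ))
    }
    sigma2 <- s2
  }
  if (!is.numeric(sigma2) || length(sigma2) != 1 || sigma2 <= 0) {
    abort("sigma2 must be a single positive number.")
  }
  A <- exp(-D2 / sigma2)
  diag(A) <- 0
  structure(
    list(A = A, sigma2 = sigma2, node_ids = seq_len(nrow(X))),
    class = "affinity_graph"
  )
}

#' @export
print.affinity_graph <- function(x, ...) {
  cat("<affinity_graph> ", nrow(x$A), " nodes, sigma2 = ",
    format(x$sigma2, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Export an affinity matrix as dense CSV
#'
#' @param graph An `affinity_graph`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_affinity_csv <- function(graph, path) {
  stopifnot(inherits(graph, "affinity_graph"))
  utils::write.table(graph$A, path,
    sep = ",", row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

as_affinity_matrix <- function(A) {
  if (inherits(A, "affinity_graph")) A <- A$A
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A))
  A
}
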