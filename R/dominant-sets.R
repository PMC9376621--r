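#' Relative similarity of an outside node to a set member
#'
#' \eqn{\phi_S(i, j) = a_{ij} - \frac{1}{|S|}\sum_{k \in S} a_{jk}}: how
#' similar node `i` is to the in-set node `j`, relative to `j`'s average
#' affinity to its neighbours in `S` (the zero diagonal contributes the
#' \eqn{a_{jj} = 0} term to the mean). May be negative.
#'
#' @param A Affinity matrix or `affinity_graph`.
#' @param S Integer vector of node indices (nonempty).
#' @param i Node index (conceptually outside `S`).
#' @param j Node index, must be a member of `S`.
#' @return A single number.
#' @export
relative_similarity <- function(A, S, i, j) {
  A <- as_affinity_matrix(A)
  if (length(S) == 0) abort("S must be nonempty.")
  if (!(j %in% S)) abort("j must belong to S.")
  A[i, j] - mean(A[j, S])
}

# Memoized dominant-set weights for one affinity matrix. Exponential in |S|;
# intended for diagnostics and small-graph oracles, never the pipeline path.
weight_cache <- function(A) {
  A <- as_affinity_matrix(A)
  memo <- new.env(parent = emptyenv())
  get_weight <- function(S, i) {
    S <- sort(as.integer(S))
    if (!(i %in% S)) abort("i must belong to S.")
    key <- paste0(paste(S, collapse = "."), "|", i)
    hit <- memo[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    val <- if (length(S) == 1) {
      1
    } else {
      R <- setdiff(S, i)
      mean_aff <- colMeans(A[R, R, drop = FALSE]) # mean_k A[j, k] over k in R
      sum(vapply(
        seq_along(R),
        function(idx) {
          j <- R[idx]
          (A[i, j] - mean_aff[idx]) * get_weight(R, j)
        },
        numeric(1)
      ))
    }
    memo[[key]] <- val
    val
  }
  get_weight
}

#' Dominant-set node weight
#'
#' \eqn{W_S(i)}: 1 for singletons, otherwise the recursive sum
#' \eqn{\sum_{j \in S \setminus \{i\}} \phi_{S\setminus\{i\}}(i, j)\,
#' W_{S\setminus\{i\}}(j)}. A positive weight means adding `i` raises the
#' internal coherence of `S`. Memoized over subsets, but still exponential in
#' `|S|` — use for diagnostics and oracles only.
#'
#' @inheritParams relative_similarity
#' @param i Node index, must belong to `S`.
#' @return A single number.
#' @export
node_weight <- function(A, S, i) {
  weight_cache(A)(S, i)
}

#' Total weight of a node set
#'
#' \eqn{W(S) = \sum_{i \in S} W_S(i)}.
#'
#' @inheritParams relative_similarity
#' @return A single number.
#' @export
set_weight <- function(A, S) {
  w <- weight_cache(A)
  sum(vapply(S, function(i) w(S, i), numeric(1)))
}

#' Test the dominant-set conditions
#'
#' `S` is dominant iff every nonempty subset has positive total weight, every
#' internal node weight \eqn{W_S(i)} is positive, and no external node has a
#' positive extension weight \eqn{W_{S \cup \{i\}}(i)} (internal homogeneity
#' plus maximality). A zero extension weight counts as non-extending: on
#' unweighted graphs ties at exactly zero arise generically (e.g. a path
#' graph's edges) and the maximal-clique correspondence requires treating
#' them as maximal. Exhaustive over subsets of `S`; keep `|S|` small.
#'
#' @inheritParams relative_similarity
#' @return A list: `dominant` (logical) and `diagnostics` listing violating
#'   internal nodes, external nodes, and subsets.
#' @export
is_dominant_set <- function(A, S) {
  A <- as_affinity_matrix(A)
  if (length(S) == 0) abort("S must be nonempty.")
  S <- sort(as.integer(S))
  w <- weight_cache(A)
  internal_bad <- S[vapply(S, function(i) w(S, i) <= 0, logical(1))]
  outside <- setdiff(seq_len(nrow(A)), S)
  external_bad <- outside[vapply(
    outside,
    function(i) w(sort(c(S, i)), i) > 0, logical(1)
  )]
  subset_bad <- list()
  if (length(S) > 1) {
    for (m in seq_len(length(S) - 1)) {
      subs <- utils::combn(S, m, simplify = FALSE)
      for (Tset in subs) {
        wt <- sum(vapply(Tset, function(i) w(Tset, i), numeric(1)))
        if (wt <= 0) subset_bad <- c(subset_bad, list(Tset))
      }
    }
  }
  list(
    dominant = length(internal_bad) == 0 && length(external_bad) == 0 &&
      length(subset_bad) == 0,
    diagnostics = list(
      internal_violations = internal_bad,
      external_violations = external_bad,
      subset_violations = subset_bad
    )
  )
}

#' Replicator dynamics on the standard simplex
#'
#' Multiplicative update \eqn{z_i \leftarrow z_i (Az)_i / (z^\top A z)}
#' maximizing \eqn{f(z) = z^\top A z} over the simplex
#' \eqn{\Delta = \{z : \sum z_i = 1,\ z \ge 0\}}. Trajectories stay in
#' \eqn{\Delta} and `f` is non-decreasing; the positive support of a strict
#' local maximizer is a dominant set.
#'
#' @param A Affinity matrix or `affinity_graph`.
#' @param z0 Start point in the simplex, or `"barycenter"` (uniform 1/M,
#'   deterministic default).
#' @param max_iter Iteration cap (default 1000).
#' @param min_increment Stop once the objective gain per step falls below this
#'   (default 1e-8).
#' @return A list of class `replicator_run`: `z` (final simplex vector),
#'   `objective` (`f(z)`), `iterations`, `converged`, `degenerate` (true when
#'   \eqn{z^\top A z = 0} was hit, e.g. on an edgeless support).
#' @export
replicator_dynamics <- function(A, z0 = "barycenter", max_iter = 1000,
                                min_increment = 1e-8) {
  A <- as_affinity_matrix(A)
  M <- nrow(A)
  if (identical(z0, "barycenter")) {
    z <- rep(1 / M, M)
  } else {
    z <- as.numeric(z0)
    stopifnot(length(z) == M, all(z >= 0))
    if (abs(sum(z) - 1) > 1e-9) abort("z0 must lie on the simplex (sum to 1).")
  }
  f_prev <- as.numeric(crossprod(z, A %*% z))
  iterations <- 0L
  converged <- FALSE
  degenerate <- FALSE
  for (t in seq_len(max_iter)) {
    Az <- as.numeric(A %*% z)
    denom <- sum(z * Az)
    if (denom <= 0) {
      degenerate <- TRUE
      break
    }
    z <- z * Az / denom
    z <- z / sum(z) # guard accumulated round-off; a no-op analytically
    iterations <- t
    f <- as.numeric(crossprod(z, A %*% z))
    if (f - f_prev < min_increment) {
      f_prev <- f
      converged <- TRUE
      break
    }
    f_prev <- f
  }
  structure(
    list(
      z = z, objective = f_prev, iterations = iterations,
      converged = converged, degenerate = degenerate
    ),
    class = "replicator_run"
  )
}

#' Extract one dominant set
#'
#' Runs replicator dynamics from the barycenter and returns the support
#' \eqn{\{i : z_i > \epsilon\}}. The theoretical membership criterion
#' \eqn{z_i > 0} is realized with a small numeric threshold. Degenerate
#' dynamics (zero objective, e.g. an edgeless graph) fall back to a flagged
#' singleton at the maximum-degree node.
#'
#' @inheritParams replicator_dynamics
#' @param support_eps Support threshold on `z` (default 1e-5, small against
#'   the 1/M barycenter scale).
#' @return List: `support` (integer node indices), `z`, `objective`,
#'   `iterations`, `degenerate`.
#' @export
extract_dominant_set <- function(A, support_eps = 1e-5, max_iter = 1000,
                                 min_increment = 1e-8) {
  A <- as_affinity_matrix(A)
  if (nrow(A) < 2) abort("Need at least 2 nodes.")
  run <- replicator_dynamics(A,
    z0 = "barycenter",
    max_iter = max_iter, min_increment = min_increment
  )
  if (run$degenerate) {
    deg <- rowSums(A)
    i <- which.max(deg)
    return(list(
      support = i, z = run$z, objective = run$objective,
      iterations = run$iterations, degenerate = TRUE
    ))
  }
  support <- which(run$z > support_eps)
  list(
    support = support, z = run$z, objective = run$objective,
    iterations = run$iterations, degenerate = FALSE
  )
}

#' Peeling-off dominant-set clustering
#'
#' Iteratively extracts a dominant set from the subgraph on the remaining
#' nodes and removes it (`V <- V \\ S`), so the number of clusters is
#' discovered rather than pre-specified. Peeling stops when fewer than
#' `min_remaining` nodes remain or an extraction degenerates; leftover nodes
#' form a residual "clutter" group, which downstream rule induction may keep
#' as its own rule. The affinity submatrix is peeled directly — the kernel is
#' never recomputed.
#'
#' @inheritParams extract_dominant_set
#' @param min_remaining Stop peeling when fewer nodes than this remain
#'   (default 2).
#' @return A `ds_partition`: list with `clusters` (list of integer index
#'   vectors, in extraction order), `weights` (support weights of each
#'   cluster's characteristic vector), `residual` (integer vector, possibly
#'   empty), and `extraction_log` (tibble: cluster, size, iterations,
#'   objective).
#' @export
peel_off <- function(A, min_remaining = 2, support_eps = 1e-5,
                     max_iter = 1000, min_increment = 1e-8) {
  A <- as_affinity_matrix(A)
  M <- nrow(A)
  remaining <- seq_len(M)
  clusters <- list()
  weights <- list()
  log_rows <- list()
  while (length(remaining) >= min_remaining) {
    sub <- A[remaining, remaining, drop = FALSE]
    ex <- extract_dominant_set(sub,
      support_eps = support_eps,
      max_iter = max_iter, min_increment = min_increment
    )
    if (ex$degenerate) break
    members <- remaining[ex$support]
    clusters <- c(clusters, list(members))
    weights <- c(weights, list(ex$z[ex$support]))
    log_rows <- c(log_rows, list(tibble::tibble(
      cluster = length(clusters), size = length(members),
      iterations = ex$iterations, objective = ex$objective
    )))
    remaining <- setdiff(remaining, members)
  }
  structure(
    list(
      clusters = clusters,
      weights = weights,
      residual = remaining,
      extraction_log = if (length(log_rows)) {
        dplyr::bind_rows(log_rows)
      } else {
        tibble::tibble(
          cluster = integer(), size = integer(),
          iterations = integer(), objective = numeric()
        )
      },
      n_nodes = M
    ),
    class = "ds_partition"
  )
}

#' @export
print.ds_partition <- function(x, ...) {
  cat("<ds_partition> ", length(x$clusters), " dominant sets over ",
    x$n_nodes, " nodes",
    sep = ""
  )
  if (length(x$residual) > 0) {
    cat(" (+", length(x$residual), " residual)", sep = "")
  }
  cat("\n  sizes: ", paste(lengths(x$clusters), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a dominant-set partition
#'
#' One row per node: cluster id (extraction order; the residual, if any, gets
#' the last id), characteristic-vector support weight (`NA` for residual
#' nodes), and a residual flag.
#'
#' @param x A `ds_partition`.
#' @param ... Unused.
#' @return A tibble with `node`, `cluster`, `weight`, `residual`.
#' @export
tidy.ds_partition <- function(x, ...) {
  rows <- purrr::imap(x$clusters, function(members, d) {
    tibble::tibble(
      node = members, cluster = d, weight = x$weights[[d]], residual = FALSE
    )
  })
  if (length(x$residual) > 0) {
    rows <- c(rows, list(tibble::tibble(
      node = x$residual, cluster = length(x$clusters) + 1L,
      weight = NA_real_, residual = TRUE
    )))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$node)
}

#' Enumerate all dominant sets of a small graph
#'
#' Brute-force oracle: checks every nonempty node subset against
#' [is_dominant_set()]. Exponential — capped at 12 nodes.
#'
#' @param A Affinity matrix or `affinity_graph` with at most 12 nodes.
#' @return A list of integer vectors, each a dominant set.
#' @export
brute_force_dominant_sets <- function(A) {
  A <- as_affinity_matrix(A)
  M <- nrow(A)
  if (M > 12) abort("Brute-force enumeration capped at 12 nodes.")
  w <- weight_cache(A)
  all_nodes <- seq_len(M)
  # precompute all subset total weights once via the shared cache
  subset_weight <- function(S) sum(vapply(S, function(i) w(S, i), numeric(1)))
  out <- list()
  for (m in seq_len(M)) {
    for (S in utils::combn(all_nodes, m, simplify = FALSE)) {
      ok_internal <- all(vapply(S, function(i) w(S, i) > 0, logical(1)))
      if (!ok_internal) next
      outside <- setdiff(all_nodes, S)
      ok_external <- all(vapply(
        outside,
        function(i) w(sort(c(S, i)), i) <= 0, logical(1)
      ))
      if (!ok_external) next
      ok_subsets <- TRUE
      if (m > 1) {
        for (mm in seq_len(m - 1)) {
          for (Tset in utils::combn(S, mm, simplify = FALSE)) {
            if (subset_weight(Tset) <= 0) {
              ok_subsets <- FALSE
              break
            }
          }
          if (!ok_subsets) break
        }
      }
      if (ok_subsets) out <- c(out, list(S))
    }
  }
  out
}
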