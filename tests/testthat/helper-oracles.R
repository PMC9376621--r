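# Shared oracles and fixture builders. Everything here is deliberately naive
# (double loops, exhaustive enumeration) and independent of the package's
# vectorized implementations.

# random symmetric affinity matrix with zero diagonal, weights in (0, 1)
rand_affinity <- function(n, seed) {
  withr::with_seed(seed, {
    A <- matrix(runif(n * n), n, n)
  })
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# random 0/1 adjacency with edge probability p
rand_adjacency <- function(n, p, seed) {
  withr::with_seed(seed, {
    A <- matrix(as.numeric(runif(n * n) < p), n, n)
  })
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0
  A
}

# brute-force squared distances by double loop
sq_dist_loop <- function(X) {
  M <- nrow(X)
  D2 <- matrix(0, M, M)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      D2[i, j] <- sum((X[i, ] - X[j, ])^2)
    }
  }
  D2
}

# memo-free exponential evaluation of the dominant-set weight recursion
node_weight_naive <- function(A, S, i) {
  S <- sort(S)
  if (length(S) == 1) {
    return(1)
  }
  R <- setdiff(S, i)
  total <- 0
  for (j in R) {
    phi <- A[i, j] - mean(A[j, R])
    total <- total + phi * node_weight_naive(A, R, j)
  }
  total
}

# exact maximum clique size by subset enumeration (small n only)
max_clique_naive <- function(adj) {
  n <- nrow(adj)
  best <- 1
  for (m in 2:n) {
    for (S in utils::combn(n, m, simplify = FALSE)) {
      sub <- adj[S, S, drop = FALSE]
      if (all(sub[upper.tri(sub)] == 1)) best <- max(best, m)
    }
  }
  best
}

# central finite-difference gradient of a scalar function
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    xp <- x
    xm <- x
    xp[k] <- xp[k] + h
    xm[k] <- xm[k] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# canonical well-separated 3-blob fixture (package defaults)
demo_blobs <- function(seed = 42) {
  make_blobs(blob_spec(seed = seed))
}

# hand-assembled ANFIS model from parameter matrices (D x n)
toy_model <- function(centers, sigmas, consequents, mf_convention = "half",
                      feature_names = paste0("x", seq_len(ncol(centers)))) {
  rules <- lapply(seq_len(nrow(centers)), function(d) {
    ctr <- centers[d, ]
    sg <- sigmas[d, ]
    names(ctr) <- feature_names
    names(sg) <- feature_names
    structure(
      list(centers = ctr, sigmas = sg, consequent = consequents[d], support_size = 1L),
      class = "fuzzy_rule"
    )
  })
  rb <- structure(
    list(
      rules = rules, feature_names = feature_names,
      class_labels = c(negative = 0, positive = 1)
    ),
    class = "rule_base"
  )
  anfis_model(rb, mf_convention = mf_convention)
}
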