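test_that("relative similarity matches hand arithmetic and direct summation", {
  A <- rand_affinity(6, seed = 1)
  # singleton set: the mean collapses to the zero self-affinity
  expect_equal(relative_similarity(A, S = 2, i = 5, j = 2), A[5, 2])

  # all-equal affinities w: phi = w - w(m-1)/m = w/m (the a_jj = 0 term counts)
  w <- 0.6
  Aeq <- matrix(w, 5, 5)
  diag(Aeq) <- 0
  S <- c(1, 2, 3)
  expect_equal(relative_similarity(Aeq, S, i = 4, j = 2), w / 3, tolerance = 1e-12)

  # direct summation oracle on a random graph
  S2 <- c(2, 4, 5)
  phi <- A[6, 4] - sum(A[4, S2]) / length(S2)
  expect_equal(relative_similarity(A, S2, i = 6, j = 4), phi, tolerance = 1e-12)

  expect_error(relative_similarity(A, S = c(1, 2), i = 3, j = 5), "belong")
})

test_that("node weights satisfy the recursion base cases and match the naive oracle", {
  A <- rand_affinity(5, seed = 2)
  expect_equal(node_weight(A, S = 3, i = 3), 1) # singleton
  expect_equal(node_weight(A, S = c(1, 4), i = 1), A[4, 1]) # one unroll

  # memoized vs memo-free exponential evaluation on 5-node sets
  for (seed in 1:5) {
    B <- rand_affinity(5, seed = seed + 10)
    S <- 1:5
    for (i in S) {
      expect_equal(node_weight(B, S, i), node_weight_naive(B, S, i),
        tolerance = 1e-10
      )
    }
    expect_equal(
      set_weight(B, S),
      sum(vapply(S, function(i) node_weight_naive(B, S, i), numeric(1))),
      tolerance = 1e-10
    )
  }
  expect_error(node_weight(A, S = c(1, 2), i = 3), "belong")
})

test_that("dominant-set conditions recover maximal cliques on unweighted graphs", {
  # path 1-2-3: the two edges are the dominant sets
  P <- matrix(0, 3, 3)
  P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- 1
  expect_true(is_dominant_set(P, c(1, 2))$dominant)
  expect_true(is_dominant_set(P, c(2, 3))$dominant)
  expect_false(is_dominant_set(P, c(1, 3))$dominant)
  expect_false(is_dominant_set(P, 1:3)$dominant)
  expect_equal(brute_force_dominant_sets(P), list(c(1, 2), c(2, 3)))

  # complete K4: only the full vertex set; an inner triangle fails maximality
  K4 <- matrix(1, 4, 4)
  diag(K4) <- 0
  res <- is_dominant_set(K4, 1:3)
  expect_false(res$dominant)
  expect_equal(res$diagnostics$external_violations, 4)
  expect_equal(brute_force_dominant_sets(K4), list(1:4))

  # all equal positive affinities: the full set is dominant
  Aeq <- matrix(0.3, 5, 5)
  diag(Aeq) <- 0
  expect_true(is_dominant_set(Aeq, 1:5)$dominant)

  # edgeless graph: each singleton, nothing larger
  E <- matrix(0, 3, 3)
  expect_equal(brute_force_dominant_sets(E), list(1, 2, 3))

  expect_error(brute_force_dominant_sets(matrix(0, 13, 13)), "12")
})

test_that("replicator dynamics converges to known fixed points", {
  # symmetric 2-node graph: barycenter is the fixed point, f = w/2
  w <- 0.8
  A2 <- matrix(c(0, w, w, 0), 2)
  run <- replicator_dynamics(A2)
  expect_equal(run$z, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(run$objective, w / 2, tolerance = 1e-9)

  # triangle plus pendant: Motzkin-Straus maximum 1 - 1/3 on the triangle
  A4 <- matrix(0, 4, 4)
  A4[1, 2] <- A4[2, 1] <- A4[1, 3] <- A4[3, 1] <- A4[2, 3] <- A4[3, 2] <- 1
  A4[3, 4] <- A4[4, 3] <- 1
  run4 <- replicator_dynamics(A4, max_iter = 20000, min_increment = 0)
  expect_equal(run4$objective, 2 / 3, tolerance = 1e-6)
  expect_setequal(which(run4$z > 1e-5), 1:3)

  # degenerate graph: flagged, not an error
  rundeg <- replicator_dynamics(matrix(0, 3, 3))
  expect_true(rundeg$degenerate)
})

test_that("replicator trajectories stay on the simplex with non-decreasing objective", {
  for (seed in 1:20) {
    A <- rand_affinity(sample(4:12, 1), seed = seed)
    z <- rep(1 / nrow(A), nrow(A))
    f_prev <- drop(z %*% A %*% z)
    for (t in 1:50) {
      Az <- drop(A %*% z)
      z <- z * Az / sum(z * Az)
      expect_true(all(z >= 0))
      expect_equal(sum(z), 1, tolerance = 1e-9)
      f <- drop(z %*% A %*% z)
      expect_gte(f, f_prev - 1e-12)
      f_prev <- f
    }
    # package run agrees with the hand loop's invariants
    run <- replicator_dynamics(A)
    expect_equal(sum(run$z), 1, tolerance = 1e-9)
    expect_true(all(run$z >= 0))
  }
})

test_that("extracted support is a dominant set on small graphs", {
  for (seed in 1:20) {
    A <- rand_affinity(6, seed = seed + 100)
    ex <- extract_dominant_set(A, max_iter = 1e5, min_increment = 0)
    if (ex$degenerate) next
    expect_true(is_dominant_set(A, ex$support)$dominant,
      label = paste("seed", seed, "support", paste(ex$support, collapse = ","))
    )
  }
})

test_that("extraction isolates one blob when blobs are far separated", {
  withr::with_seed(21, {
    X <- rbind(
      matrix(rnorm(10, mean = 0, sd = 0.02), 5, 2),
      matrix(rnorm(10, mean = 5, sd = 0.02), 5, 2)
    )
  })
  g <- gaussian_affinity(X, sigma2 = 0.5) # between-blob affinity ~ exp(-100)
  expect_lt(max(g$A[1:5, 6:10]), 1e-6)
  ex <- extract_dominant_set(g)
  expect_true(all(ex$support %in% 1:5) || all(ex$support %in% 6:10))
  expect_equal(length(ex$support), 5)

  # three mutually identical nodes: uniform support over all of them
  A3 <- matrix(0.4, 3, 3)
  diag(A3) <- 0
  ex3 <- extract_dominant_set(A3)
  expect_equal(ex3$support, 1:3)
  expect_equal(ex3$z, rep(1 / 3, 3), tolerance = 1e-9)
})

test_that("peeling off recovers separated blobs and keeps the partition contract", {
  blobs <- demo_blobs(seed = 42)
  g <- gaussian_affinity(as.matrix(blobs$data[, 1:2]))
  p <- peel_off(g)
  nodes <- tidy(p)
  # disjoint cover of all nodes
  expect_equal(sort(nodes$node), 1:75)
  expect_equal(anyDuplicated(nodes$node), 0)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(nodes$cluster, blobs$membership), 1)

  # single homogeneous blob with a bandwidth well above its internal spread:
  # near-uniform affinities, one cluster holding (nearly) all nodes
  one <- make_blobs(blob_spec(
    centers = list(c(0.5, 0.5)), spreads = 0.05,
    sizes = 30, labels = 1, seed = 3
  ))
  g1 <- gaussian_affinity(as.matrix(one$data[, 1:2]), sigma2 = 1)
  p1 <- peel_off(g1)
  expect_gte(length(p1$clusters[[1]]), 27)
})

test_that("peeling is deterministic for identical inputs", {
  blobs <- demo_blobs(seed = 7)
  g <- gaussian_affinity(as.matrix(blobs$data[, 1:2]))
  p1 <- peel_off(g)
  p2 <- peel_off(g)
  expect_identical(tidy(p1), tidy(p2))
})
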