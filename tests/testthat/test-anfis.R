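test_that("gaussian membership matches hand arithmetic under both conventions", {
  mf <- structure(list(center = 0.96, sigma = 0.04), class = "gaussian_mf")
  expect_equal(membership_degree(mf, 0.96), 1)
  expect_equal(membership_degree(mf, 0.88), exp(-2), tolerance = 1e-12)
  expect_equal(membership_degree(mf, 0.88, convention = "plain"), exp(-4),
    tolerance = 1e-12
  )
  # even function around the center
  expect_equal(
    membership_degree(mf, 0.96 + 0.03),
    membership_degree(mf, 0.96 - 0.03)
  )
})

test_that("firing strengths are the product T-norm across features", {
  ctr <- rbind(c(0.2, 0.8), c(0.7, 0.3))
  sg <- matrix(0.1, 2, 2)
  m <- toy_model(ctr, sg, c(0, 1))

  # input at a rule's center fires that rule fully
  expect_equal(firing_strengths(m, c(0.2, 0.8))[1], 1)

  # product of known membership degrees
  mu1 <- exp(-0.5 * ((0.3 - 0.2) / 0.1)^2)
  mu2 <- exp(-0.5 * ((0.6 - 0.8) / 0.1)^2)
  expect_equal(firing_strengths(m, c(0.3, 0.6))[1], mu1 * mu2, tolerance = 1e-12)

  # naive loop oracle on a random model
  withr::with_seed(6, {
    C <- matrix(runif(12), 4, 3)
    S <- matrix(runif(12, 0.05, 0.3), 4, 3)
    x <- runif(3)
  })
  mr <- toy_model(C, S, rep(0, 4))
  w <- firing_strengths(mr, x)
  for (d in 1:4) {
    prod_mu <- 1
    for (k in 1:3) {
      prod_mu <- prod_mu * exp(-(x[k] - C[d, k])^2 / (2 * S[d, k]^2))
    }
    expect_equal(w[d], prod_mu, tolerance = 1e-12)
  }
  expect_error(firing_strengths(mr, c(0.1, NA, 0.3)), "impute")
})

test_that("firing normalization sums to one with a flagged underflow fallback", {
  expect_equal(normalize_firing(0.37), 1)
  expect_equal(normalize_firing(c(0.3, 0.1)), c(0.75, 0.25))
  withr::with_seed(13, {
    w <- runif(7)
  })
  expect_equal(sum(normalize_firing(w)), 1)
  expect_warning(out <- normalize_firing(c(0, 0, 0)), class = "dsanfis_firing_underflow")
  expect_equal(out, rep(1 / 3, 3))
})

test_that("inference is a convex combination of consequents", {
  ctr <- rbind(c(0.2, 0.2), c(0.8, 0.8))
  sg <- matrix(0.15, 2, 2)

  # all consequents equal: output constant regardless of input
  m_const <- toy_model(ctr, sg, c(0.4, 0.4))
  withr::with_seed(14, {
    X <- matrix(runif(20), 10, 2)
  })
  expect_equal(anfis_infer(m_const, X), rep(0.4, 10), tolerance = 1e-12)

  # bounded by the consequent range everywhere
  m <- toy_model(ctr, sg, c(-0.2, 1.3))
  z <- anfis_infer(m, X)
  expect_true(all(z >= -0.2 - 1e-12 & z <= 1.3 + 1e-12))

  # two-rule hand example
  x <- c(0.5, 0.4)
  w1 <- exp(-0.5 * sum((x - c(0.2, 0.2))^2) / 0.15^2)
  w2 <- exp(-0.5 * sum((x - c(0.8, 0.8))^2) / 0.15^2)
  expect_equal(
    anfis_infer(m, x),
    (w1 * (-0.2) + w2 * 1.3) / (w1 + w2),
    tolerance = 1e-12
  )
})

test_that("class prediction thresholds at 0.5 with complement confidence", {
  one_rule <- function(z) toy_model(matrix(0.5, 1, 1), matrix(0.1, 1, 1), z)
  p <- predict_class(one_rule(0.776), 0.3)
  expect_equal(p$class, 1L)
  expect_equal(p$confidence, 0.776)

  expect_equal(predict_class(one_rule(0.5), 0.1)$class, 1L) # tie to positive
  expect_equal(predict_class(one_rule(0.5), 0.1)$confidence, 0.5)

  p0 <- predict_class(one_rule(0.2), 0.9)
  expect_equal(p0$class, 0L)
  expect_equal(p0$confidence, 0.8)

  # out-of-unit trained consequent: confidence clamped into [0.5, 1]
  p2 <- predict_class(one_rule(1.4), 0)
  expect_equal(p2$class, 1L)
  expect_equal(p2$confidence, 1)
})

test_that("LSE consequents match the normal-equations oracle and never raise SSE", {
  # single rule: normalized firing is identically 1, so consequent = mean(y)
  m1 <- toy_model(matrix(0.5, 1, 2), matrix(0.2, 1, 2), 0)
  withr::with_seed(15, {
    X <- matrix(runif(12), 6, 2)
    y <- runif(6)
  })
  expect_equal(lse_consequents(m1, X, y)$consequents, mean(y), tolerance = 1e-10)

  # two rules, four samples vs explicit (W'W)^-1 W'y
  m2 <- toy_model(rbind(c(0.2, 0.3), c(0.7, 0.8)), matrix(0.2, 2, 2), c(0, 1))
  X4 <- rbind(c(0.1, 0.2), c(0.3, 0.4), c(0.6, 0.9), c(0.8, 0.7))
  y4 <- c(0, 0, 1, 1)
  W <- t(apply(X4, 1, function(x) normalize_firing(firing_strengths(m2, x))))
  z_oracle <- solve(crossprod(W), crossprod(W, y4))
  m2b <- lse_consequents(m2, X4, y4)
  expect_equal(m2b$consequents, drop(z_oracle), tolerance = 1e-8)

  # SSE after the step never exceeds SSE before
  sse <- function(m) sum((anfis_infer(m, X4) - y4)^2)
  expect_lte(sse(m2b), sse(m2) + 1e-12)

  # rank-deficient design (duplicate rules): minimum-norm solution, finite
  m_dup <- toy_model(
    rbind(c(0.5, 0.5), c(0.5, 0.5)), matrix(0.2, 2, 2), c(0, 1)
  )
  m_dup2 <- lse_consequents(m_dup, X4, y4)
  expect_true(all(is.finite(m_dup2$consequents)))
  expect_equal(m_dup2$consequents[1], m_dup2$consequents[2], tolerance = 1e-8)
})

test_that("analytic premise gradients agree with central finite differences", {
  for (conv in c("half", "plain")) {
    withr::with_seed(16, {
      C <- matrix(runif(4, 0.2, 0.8), 2, 2)
      S <- matrix(runif(4, 0.1, 0.3), 2, 2)
      X <- matrix(runif(16), 8, 2)
      y <- runif(8)
    })
    zc <- c(0.1, 0.9)
    mse_at <- function(theta) {
      Ct <- matrix(theta[1:4], 2, 2)
      St <- matrix(theta[5:8], 2, 2)
      m <- toy_model(Ct, St, zc, mf_convention = conv)
      mean((anfis_infer(m, X) - y)^2)
    }
    m0 <- toy_model(C, S, zc, mf_convention = conv)
    g <- dsanfis:::premise_gradients(m0, X, y)
    g_fd <- fd_grad(mse_at, c(as.vector(C), as.vector(S)))
    expect_lt(max(abs(c(as.vector(g$centers), as.vector(g$sigmas)) - g_fd)), 1e-5)
  }
})

test_that("a gradient step is stationary at zero error and respects the width floor", {
  # targets generated by the model itself: residuals are zero, so no movement
  m <- toy_model(rbind(c(0.3, 0.3), c(0.7, 0.7)), matrix(0.2, 2, 2), c(0.2, 0.9))
  withr::with_seed(17, {
    X <- matrix(runif(10), 5, 2)
  })
  y_exact <- anfis_infer(m, X)
  m_step <- gradient_premise_step(m, X, y_exact)
  expect_equal(m_step$centers, m$centers, tolerance = 1e-12)
  expect_equal(m_step$sigmas, m$sigmas, tolerance = 1e-12)

  # widths never fall below the floor even under a huge step
  m_big <- gradient_premise_step(m, X, 1 - y_exact, learning_rate = 100)
  expect_true(all(m_big$sigmas >= m_big$config$sigma_floor))
})

test_that("hybrid training reduces error, preserves structure, and logs history", {
  blobs <- make_blobs(blob_spec(
    centers = list(c(0.25, 0.25), c(0.75, 0.75)),
    spreads = 0.06, sizes = 20, labels = c(0, 1), seed = 18
  ))
  X <- as.matrix(blobs$data[, 1:2])
  y <- blobs$data$label
  rb <- build_rule_base(X, y, peel_off(gaussian_affinity(X)))
  m0 <- anfis_model(rb, epochs = 25)

  # epochs = 0 is the identity
  expect_identical(anfis_fit(m0, X, y, epochs = 0), m0)

  m1 <- anfis_fit(m0, X, y)
  # structure frozen: rule count and feature count unchanged
  expect_equal(dim(m1$centers), dim(m0$centers))
  expect_equal(nrow(m1$history), 25)
  # each LSE sub-step never raises the MSE
  expect_true(all(m1$history$mse_after_lse <= m1$history$mse_before + 1e-12))
  # training accuracy at least as good as the untrained initialization
  acc <- function(m) mean(predict_class(m, X)$class == y)
  expect_gte(acc(m1), acc(m0))
  expect_true(all(m1$sigmas >= m1$config$sigma_floor))
})

test_that("training recovers the generating centers of a two-rule system", {
  true_centers <- rbind(c(0.2, 0.25), c(0.8, 0.7))
  blobs <- make_blobs(blob_spec(
    centers = list(true_centers[1, ], true_centers[2, ]),
    spreads = 0.05, sizes = 30, labels = c(0, 1), seed = 19
  ))
  X <- as.matrix(blobs$data[, 1:2])
  y <- blobs$data$label
  rb <- build_rule_base(X, y, peel_off(gaussian_affinity(X)))
  m <- anfis_fit(anfis_model(rb), X, y)
  # nearest-assignment matching of learned to true centers
  for (t in 1:2) {
    dists <- apply(m$centers, 1, function(c0) sqrt(sum((c0 - true_centers[t, ])^2)))
    expect_lt(min(dists), 0.1)
  }
})

test_that("anfis model JSON round-trips parameters, config, and history", {
  blobs <- demo_blobs(seed = 20)
  X <- as.matrix(blobs$data[, 1:2])
  y <- blobs$data$label
  rb <- build_rule_base(X, y, peel_off(gaussian_affinity(X)))
  m <- anfis_fit(anfis_model(rb, epochs = 5), X, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_anfis_json(m, path)
  m2 <- read_anfis_json(path)
  expect_equal(m2$centers, m$centers, tolerance = 0)
  expect_equal(m2$sigmas, m$sigmas, tolerance = 0)
  expect_equal(m2$consequents, m$consequents, tolerance = 0)
  expect_equal(anfis_infer(m2, X), anfis_infer(m, X), tolerance = 0)
})
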