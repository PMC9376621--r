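#' Specify a Gaussian blob mixture with clutter
#'
#' Describes the synthetic clustering fixture: a few well-separated isotropic
#' Gaussian blobs on the unit cube, each carrying a class label, plus an
#' optional uniform clutter group emulating the unstructured leftovers that
#' peeling-off clustering is designed to tolerate.
#'
#' The defaults define the canonical clustering fixture: three 25-point blobs
#' on the unit square with spread 0.02 and pairwise center separations of
#' 0.65-0.78 (over 30 spreads — comfortably past the several-spread
#' separation at which dominant sets align with blobs), one negative and two
#' positive.
#'
#' @param centers List of numeric center vectors, all the same length n.
#' @param spreads Per-blob isotropic SD (recycled if scalar); all > 0.
#' @param sizes Per-blob point counts (recycled if scalar); all >= 1.
#' @param labels Per-blob class label in \{0, 1\} (recycled if scalar).
#' @param clutter Number of uniform-noise points on \[0, 1\]^n (default 0).
#' @param clutter_label Class label assigned to clutter points (default 1).
#' @param seed Integer seed; the generator is fully determined by it.
#' @return A `blob_spec` list.
#' @export
blob_spec <- function(centers = list(
                        c(0.15, 0.15), c(0.5, 0.85), c(0.85, 0.25)
                      ),
                      spreads = 0.02, sizes = 25, labels = c(0, 1, 1),
                      clutter = 0, clutter_label = 1, seed = 1) {
  stopifnot(is.list(centers), length(centers) >= 1)
  B <- length(centers)
  n <- length(centers[[1]])
  stopifnot(all(lengths(centers) == n))
  spreads <- rep_len(spreads, B)
  sizes <- rep_len(as.integer(sizes), B)
  labels <- rep_len(labels, B)
  stopifnot(all(spreads > 0), all(sizes >= 1), all(labels %in% c(0, 1)))
  structure(
    list(
      centers = centers, spreads = spreads, sizes = sizes,
      labels = labels, clutter = as.integer(clutter),
      clutter_label = clutter_label, seed = as.integer(seed)
    ),
    class = "blob_spec"
  )
}

#' Generate labeled Gaussian blobs with clutter
#'
#' Draws each blob from an isotropic Gaussian around its center, appends
#' uniform clutter on the unit cube, and clips all features to \[0, 1\].
#' Ground-truth blob memberships are returned alongside (clutter gets id 0).
#' Identical seeds give identical tables; the global random state is left
#' untouched.
#'
#' @param spec A [blob_spec()].
#' @return A list: `data` (tibble with features `x1..xn` and `label`) and
#'   `membership` (integer ground-truth blob ids, 0 for clutter).
#' @export
make_blobs <- function(spec) {
  stopifnot(inherits(spec, "blob_spec"))
  n <- length(spec$centers[[1]])
  withr::with_seed(spec$seed, {
    parts <- purrr::imap(spec$centers, function(ctr, b) {
      m <- spec$sizes[b]
      pts <- matrix(rnorm(m * n, mean = rep(ctr, each = m), sd = spec$spreads[b]),
        nrow = m
      )
      list(pts = pts, id = rep(b, m), label = rep(spec$labels[b], m))
    })
    X <- do.call(rbind, purrr::map(parts, "pts"))
    membership <- unlist(purrr::map(parts, "id"))
    label <- unlist(purrr::map(parts, "label"))
    if (spec$clutter > 0) {
      X <- rbind(X, matrix(runif(spec$clutter * n), nrow = spec$clutter))
      membership <- c(membership, rep(0L, spec$clutter))
      label <- c(label, rep(spec$clutter_label, spec$clutter))
    }
  })
  X <- pmin(pmax(X, 0), 1)
  colnames(X) <- paste0("x", seq_len(n))
  data <- tibble::as_tibble(X)
  data$label <- label
  list(data = data, membership = as.integer(membership))
}

# draw from a normal truncated to [lo, hi] by rejection (vectorized resampling)
rnorm_trunc <- function(m, mean, sd, lo, hi) {
  x <- rnorm(m, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a dementia-study-like tabular dataset
#'
#' Emulates the marginal structure of a longitudinal MRI tabular cohort:
#' seven predictors (Age, Gender, EDUC, SES, MMSE, nWBV, ASF) plus an eTIV
#' column constructed as a noisy reciprocal of ASF (so correlation screening
#' has a near-collinear pair to flag), missing values injected into SES and
#' MMSE, and a binary diagnosis driven by MMSE and nWBV — the two attributes
#' most correlated with the outcome in such cohorts. Continuous marginals
#' (means, SDs, ranges) follow the published cohort summary: Age
#' 77.0 +/- 7.6 on \[60, 98\], EDUC 14.6 +/- 2.9 on \[6, 23\], SES integers
#' 1-5 around 2.5, MMSE left-skewed with median 29 on \[4, 30\], nWBV
#' 0.730 +/- 0.037, ASF 1.195 +/- 0.138, eTIV about 1778 / ASF.
#'
#' The diagnosis is Bernoulli with logit
#' \eqn{3 \cdot s(-MMSE) + 2 \cdot s(-nWBV) - 0.25} (s = standardize), giving
#' roughly 45% prevalence and a recoverable supervised signal; it makes no
#' claim to the real cohort's joint distribution.
#'
#' @param M Number of rows (>= 10).
#' @param missing_rate Length-2 numeric: fraction of missing entries in SES
#'   and MMSE. Default `c(19, 2) / 373`, the published missingness.
#' @param seed Integer seed.
#' @return A tibble with columns Age, Gender (character "M"/"F"), EDUC, SES,
#'   MMSE, eTIV, nWBV, ASF, Diagnosis (0/1).
#' @export
make_oasis_like <- function(M, missing_rate = c(19, 2) / 373, seed = 1) {
  stopifnot(M >= 10)
  missing_rate <- rep_len(missing_rate, 2)
  withr::with_seed(seed, {
    age <- rnorm_trunc(M, 77.013, 7.641, 60, 98)
    gender <- ifelse(runif(M) < 0.57, "F", "M")
    educ <- round(rnorm_trunc(M, 14.598, 2.876, 6, 23))
    # SES: integers 1..5 from a discretized normal around the published mean
    ses_probs <- stats::dnorm(1:5, mean = 2.46, sd = 1.134)
    ses <- sample(1:5, M, replace = TRUE, prob = ses_probs / sum(ses_probs))
    # MMSE: left-skewed ceiling effect; 30 minus a gamma tail, capped to [4, 30]
    mmse_gap <- rgamma(M, shape = 0.52, rate = 0.196)
    mmse <- round(pmax(30 - mmse_gap, 4), 0)
    nwbv <- rnorm_trunc(M, 0.730, 0.037, 0.644, 0.837)
    asf <- rnorm_trunc(M, 1.195, 0.138, 0.876, 1.587)
    etiv <- pmin(pmax(1778 / asf + rnorm(M, 0, 15), 1106), 2004)
    z1 <- -(mmse - mean(mmse)) / sd(mmse)
    z2 <- -(nwbv - mean(nwbv)) / sd(nwbv)
    diagnosis <- rbinom(M, 1, plogis(3 * z1 + 2 * z2 - 0.25))
    ses[runif(M) < missing_rate[1]] <- NA
    mmse[runif(M) < missing_rate[2]] <- NA
  })
  tibble::tibble(
    Age = age, Gender = gender, EDUC = educ, SES = as.numeric(ses),
    MMSE = as.numeric(mmse), eTIV = etiv, nWBV = nwbv, ASF = asf,
    Diagnosis = diagnosis
  )
}
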