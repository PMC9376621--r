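#' Gaussian membership parameters from projected cluster points
#'
#' Projects cluster members onto one attribute and takes the center as their
#' mean and the width as their POPULATION standard deviation (denominator
#' `|S_d|`). Degenerate spreads (singleton or identical points) are floored at
#' `sigma_floor` so the membership function stays proper.
#'
#' @param points Numeric vector of projected values (length >= 1).
#' @param sigma_floor Minimum width, default 0.01 on \[0, 1\]-normalized
#'   features.
#' @return A `gaussian_mf`: list with `center` and `sigma`.
#' @export
init_membership <- function(points, sigma_floor = 0.01) {
  points <- as.numeric(points)
  if (length(points) == 0) abort("Cannot fit a membership function to an empty cluster.")
  ctr <- mean(points)
  sg <- sqrt(mean((points - ctr)^2)) # population SD
  structure(
    list(center = ctr, sigma = max(sg, sigma_floor)),
    class = "gaussian_mf"
  )
}

#' Convert one cluster into a zero-order TSK fuzzy rule
#'
#' One Gaussian membership per feature from the cluster's projected moments;
#' the consequent is the majority class among cluster members, with ties
#' broken toward the class more frequent in the full training labels
#' (deterministic, maximizes prior accuracy).
#'
#' @param X Numeric feature matrix or data frame (all training rows).
#' @param labels Binary 0/1 labels for all rows of `X`.
#' @param cluster Integer row indices forming the cluster.
#' @param sigma_floor Minimum membership width.
#' @return A `fuzzy_rule`: list with `centers`, `sigmas` (named per feature),
#'   `consequent` (0 or 1), `support_size`.
#' @export
cluster_to_rule <- function(X, labels, cluster, sigma_floor = 0.01) {
  X <- as.matrix(X)
  if (length(cluster) == 0) abort("Cluster is empty.")
  mfs <- apply(X[cluster, , drop = FALSE], 2, init_membership,
    sigma_floor = sigma_floor, simplify = FALSE
  )
  cl_labels <- labels[cluster]
  n1 <- sum(cl_labels == 1)
  n0 <- sum(cl_labels == 0)
  consequent <- if (n1 > n0) {
    1
  } else if (n0 > n1) {
    0
  } else {
    # tie: fall back on the globally dominant class
    if (sum(labels == 1) >= sum(labels == 0)) 1 else 0
  }
  structure(
    list(
      centers = vapply(mfs, `[[`, numeric(1), "center"),
      sigmas = vapply(mfs, `[[`, numeric(1), "sigma"),
      consequent = consequent,
      support_size = length(cluster)
    ),
    class = "fuzzy_rule"
  )
}

#' Build a fuzzy rule base from a dominant-set partition
#'
#' One rule per extracted cluster, in extraction order. The residual clutter
#' group becomes a final rule by default — clutter carries diagnostic signal
#' too — and can be excluded.
#'
#' @param X Numeric feature matrix or data frame (training rows).
#' @param labels Binary 0/1 labels.
#' @param partition A `ds_partition` from [peel_off()].
#' @param include_residual Keep the residual group as a rule (default TRUE;
#'   ignored when the residual is empty).
#' @param sigma_floor Minimum membership width.
#' @return A `rule_base`: list with `rules` (list of `fuzzy_rule`),
#'   `feature_names`, `class_labels`.
#' @export
build_rule_base <- function(X, labels, partition, include_residual = TRUE,
                            sigma_floor = 0.01) {
  stopifnot(inherits(partition, "ds_partition"))
  X <- as.matrix(X)
  groups <- partition$clusters
  if (include_residual && length(partition$residual) > 0) {
    groups <- c(groups, list(partition$residual))
  }
  if (length(groups) == 0) abort("Partition has no clusters to convert.")
  rules <- purrr::map(groups, function(members) {
    cluster_to_rule(X, labels, members, sigma_floor = sigma_floor)
  })
  structure(
    list(
      rules = rules,
      feature_names = colnames(X) %||% paste0("x", seq_len(ncol(X))),
      class_labels = c(negative = 0, positive = 1)
    ),
    class = "rule_base"
  )
}

n_rules <- function(rb) length(rb$rules)

# stacked parameter matrices (D x n), the compute layout used by the engine
rb_centers <- function(rb) {
  do.call(rbind, purrr::map(rb$rules, "centers"))
}
rb_sigmas <- function(rb) {
  do.call(rbind, purrr::map(rb$rules, "sigmas"))
}
rb_consequents <- function(rb) {
  vapply(rb$rules, `[[`, numeric(1), "consequent")
}

#' Render a rule base as a plain-text report
#'
#' Each Gaussian antecedent reads as a fuzzy number: "`<feature>` is Around
#' `<center>` (+/- `<sigma>`)", joined by "and", followed by the consequent as
#' a diagnosis with its confidence value — the linguistic form meant for
#' communication with clinicians.
#'
#' @param rb A `rule_base`.
#' @param digits Significant digits for centers/widths.
#' @return A character scalar (multi-line).
#' @export
render_rule_base <- function(rb, digits = 3) {
  stopifnot(inherits(rb, "rule_base"))
  if (length(rb$feature_names) == 0) abort("Rule base has no feature names.")
  blocks <- purrr::imap_chr(rb$rules, function(rule, d) {
    ants <- paste(
      sprintf(
        "%s is Around %s (±%s)",
        rb$feature_names,
        signif(rule$centers, digits),
        signif(rule$sigmas, digits)
      ),
      collapse = " and "
    )
    cls <- if (rule$consequent >= 0.5) "positive" else "negative"
    sprintf(
      "Rule %d: If %s, Then %s (confidence %s) [support %d]",
      d, ants, cls, signif(rule$consequent, digits), rule$support_size
    )
  })
  paste(blocks, collapse = "\n")
}

#' @export
print.rule_base <- function(x, ...) {
  cat("<rule_base> ", n_rules(x), " rules over ",
    length(x$feature_names), " features\n",
    sep = ""
  )
  cat(render_rule_base(x), "\n")
  invisible(x)
}

#' Tidy a rule base
#'
#' Long format: one row per rule-feature pair with the Gaussian center and
#' width, plus the rule's consequent and support size repeated.
#'
#' @param x A `rule_base`.
#' @param ... Unused.
#' @return A tibble with `rule`, `feature`, `center`, `sigma`, `consequent`,
#'   `support`.
#' @export
tidy.rule_base <- function(x, ...) {
  purrr::imap(x$rules, function(r, d) {
    ctr <- unname(r$centers)
    sg <- unname(r$sigmas)
    tibble::tibble(
      rule = d,
      feature = x$feature_names,
      center = ctr,
      sigma = sg,
      consequent = r$consequent,
      support = r$support_size
    )
  }) |>
    dplyr::bind_rows()
}

#' @export
glance.rule_base <- function(x, ...) {
  tibble::tibble(
    n_rules = n_rules(x),
    n_features = length(x$feature_names),
    n_positive_rules = sum(rb_consequents(x) >= 0.5)
  )
}

#' Plot the Gaussian membership functions of a rule base
#'
#' One panel per rule-feature pair, membership degree over the normalized
#' \[0, 1\] domain.
#'
#' @param object A `rule_base`.
#' @param convention Membership convention, `"half"` or `"plain"` (see
#'   [membership_degree()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rule_base <- function(object, convention = "half", ...) {
  grid <- seq(0, 1, length.out = 201)
  df <- tidy(object) |>
    dplyr::mutate(curve = purrr::map2(.data$center, .data$sigma, function(c0, s0) {
      tibble::tibble(
        x = grid,
        mu = membership_degree(
          structure(list(center = c0, sigma = s0), class = "gaussian_mf"),
          grid,
          convention = convention
        )
      )
    })) |>
    tidyr::unnest("curve")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$mu)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$rule),
      cols = ggplot2::vars(.data$feature)
    ) +
    ggplot2::labs(
      x = "normalized feature value", y = "membership degree",
      title = "Gaussian membership functions by rule"
    ) +
    ggplot2::theme_minimal()
}

#' Serialize a rule base to JSON
#'
#' Round-trips exactly through [read_rule_base()] (full double precision).
#'
#' @param rb A `rule_base`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_rule_base <- function(rb, path) {
  stopifnot(inherits(rb, "rule_base"))
  obj <- list(
    features = rb$feature_names,
    rules = purrr::map(rb$rules, function(r) {
      list(
        centers = unname(r$centers), sigmas = unname(r$sigmas),
        consequent = r$consequent, support = r$support_size
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a rule base from JSON
#'
#' @param path File written by [write_rule_base()].
#' @return A `rule_base`.
#' @export
read_rule_base <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- as.character(unlist(obj$features))
  rules <- purrr::map(obj$rules, function(r) {
    centers <- as.numeric(unlist(r$centers))
    sigmas <- as.numeric(unlist(r$sigmas))
    names(centers) <- feats
    names(sigmas) <- feats
    structure(
      list(
        centers = centers, sigmas = sigmas,
        consequent = as.numeric(r$consequent),
        support_size = as.numeric(r$support)
      ),
      class = "fuzzy_rule"
    )
  })
  structure(
    list(
      rules = rules, feature_names = feats,
      class_labels = c(negative = 0, positive = 1)
    ),
    class = "rule_base"
  )
}
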