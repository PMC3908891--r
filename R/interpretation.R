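#' Binarize one membership column by two-cluster scalar k-means
#'
#' Membership weights of a well-separated component pile up at zero for
#' non-members and spread over a positive bulk for members. A two-cluster
#' k-means on the scalar weights splits the two populations; nodes in the
#' cluster with the higher center are members. The clustering is fully
#' deterministic: centers are initialized at the minimum and maximum
#' weight, Lloyd iterations are capped at 100, and a point equidistant
#' from both centers joins the lower cluster. Columns whose maximum
#' weight is at most `eps` yield no members. The result is invariant
#' under positive rescaling of the column.
#'
#' @param weights Non-negative numeric vector (one factor column).
#' @param eps Degeneracy guard: a column with `max(weights) <= eps` has
#'   no members (default 1e-9).
#' @return A logical vector: `TRUE` for members.
#' @export
binarize_membership <- function(weights, eps = 1e-9) {
  stopifnot(is.numeric(weights), all(weights >= 0))
  n <- length(weights)
  if (n == 0L || max(weights) <= eps) return(rep(FALSE, n))
  lo <- min(weights); hi <- max(weights)
  if (hi - lo <= eps) return(rep(TRUE, n))  # one indivisible positive bulk
  centers <- c(lo, hi)
  assign_hi <- NULL
  for (it in seq_len(100L)) {
    # tie (equidistant point) goes to the lower cluster: strict inequality
    new_assign <- abs(weights - centers[2L]) < abs(weights - centers[1L])
    if (identical(new_assign, assign_hi)) break
    assign_hi <- new_assign
    if (!any(assign_hi) || all(assign_hi)) break
    centers <- c(mean(weights[!assign_hi]), mean(weights[assign_hi]))
  }
  assign_hi
}

#' Binary node-component membership matrix
#'
#' Applies [binarize_membership()] to every column of the node factor,
#' yielding the `N x R` binary matrix `M` with `M[i, k] = 1` when node
#' `i` is a member of component `k`. Nodes may belong to several
#' components (overlap) or to none; rows are not constrained to sum
#' to 1.
#'
#' @param model A `cp_model`.
#' @param factor Which node mode to binarize: `"A"` (default; for
#'   undirected networks the two node modes agree up to noise), `"B"`,
#'   or `"average"` (mean of the column-normalized `A` and `B`).
#' @param eps Passed to [binarize_membership()].
#' @return A `membership_matrix`: binary `N x R` matrix with node ids as
#'   row names.
#' @export
membership_matrix <- function(model, factor = c("A", "B", "average"),
                              eps = 1e-9) {
  factor <- match.arg(factor)
  stopifnot(inherits(model, "cp_model"))
  w <- switch(factor,
    A = model$A,
    B = model$B,
    average = {
      nm <- normalize_cp(model)
      (nm$A + nm$B) / 2
    })
  m <- apply(w, 2L, function(col) as.integer(binarize_membership(col, eps)))
  m <- matrix(m, nrow = nrow(w),
              dimnames = list(rownames(w), NULL))
  structure(m, class = c("membership_matrix", "matrix", "array"))
}

#' Member node ids of one component
#' @param m A `membership_matrix`.
#' @param component Component index.
#' @return Character vector of member node ids (or integer positions if
#'   the matrix has no row names).
#' @export
component_members <- function(m, component) {
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  ids[m[, component] == 1L]
}

#' Tidy node memberships
#'
#' Long-format view of a model's membership weights and binarized
#' assignments.
#'
#' @param model A `cp_model`.
#' @param ... Passed to [membership_matrix()].
#' @return A tibble with columns `node_id`, `component`, `weight`,
#'   `member`.
#' @export
memberships <- function(model, ...) {
  m <- membership_matrix(model, ...)
  w <- model$A
  ids <- rownames(w) %||% as.character(seq_len(nrow(w)))
  tibble::tibble(
    node_id = rep(ids, times = ncol(w)),
    component = rep(seq_len(ncol(w)), each = nrow(w)),
    weight = as.vector(w),
    member = as.vector(m) == 1L
  )
}

#' Per-component activity strength over time
#'
#' The strength of component `k` at interval `t` combines the component's
#' temporal activity (factor `C`) with the total membership weight of its
#' nodes (factor `A`): `s_k(t) = C[t, k] * sum_i A[i, k]`. With
#' `normalized = TRUE` the same quantity is computed from the normalized
#' model ([normalize_cp()]), i.e. the column scales are first absorbed
#' into `C`; the two variants agree up to a per-component constant.
#'
#' @param model A `cp_model`.
#' @param normalized Use unit-norm node columns with scales absorbed into
#'   `C` (default FALSE).
#' @return An `activity_profile`: `S x R` non-negative matrix.
#' @export
activity_strength <- function(model, normalized = FALSE) {
  stopifnot(inherits(model, "cp_model"))
  if (normalized) model <- normalize_cp(model)
  s <- sweep(model$C, 2L, colSums(model$A), "*")
  structure(s, class = c("activity_profile", "matrix", "array"))
}

#' Tidy an activity profile
#'
#' @param x An `activity_profile`.
#' @param interval_length,t0 Optional timeline metadata; when given, an
#'   `interval_start` column (seconds) is included.
#' @param ... Unused.
#' @return A tibble with columns `interval`, `component`, `strength`
#'   (and `interval_start` when the timeline is known).
#' @export
tidy.activity_profile <- function(x, interval_length = NULL, t0 = 0, ...) {
  s <- unclass(x)
  out <- tibble::tibble(
    interval = rep(seq_len(nrow(s)), times = ncol(s)),
    component = rep(seq_len(ncol(s)), each = nrow(s)),
    strength = as.vector(s)
  )
  if (!is.null(interval_length)) {
    out <- dplyr::mutate(out,
      interval_start = t0 + (.data$interval - 1L) * interval_length,
      .after = "interval")
  }
  out
}

#' Plot per-component activity timelines
#'
#' One panel per component, strength against interval index.
#'
#' @param object An `activity_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.activity_profile <- function(object, ...) {
  ggplot2::ggplot(tidy.activity_profile(object),
                  ggplot2::aes(x = .data$interval, y = .data$strength)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ component, scales = "free_y") +
    ggplot2::labs(x = "interval", y = "activity strength") +
    ggplot2::theme_minimal()
}

#' Plot a binary membership matrix
#'
#' Node-by-component tile plot of the binarized memberships.
#'
#' @param object A `membership_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.membership_matrix <- function(object, ...) {
  ids <- rownames(object) %||% as.character(seq_len(nrow(object)))
  df <- tibble::tibble(
    node_id = factor(rep(ids, times = ncol(object)), levels = rev(ids)),
    component = rep(seq_len(ncol(object)), each = nrow(object)),
    member = as.vector(object) == 1L
  )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$component),
                                   y = .data$node_id,
                                   fill = .data$member)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "component", y = "node", fill = "member") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Summarize components: size, relevance, activity peak
#'
#' @param model A `cp_model`.
#' @param m Optional `membership_matrix` (recomputed from `model` when
#'   missing).
#' @return A tibble ordered by relevance (descending) with columns
#'   `component`, `size`, `relevance`, `peak_interval` (interval of
#'   maximum activity strength; `NA` for all-zero activity).
#' @export
summarize_components <- function(model, m = NULL) {
  stopifnot(inherits(model, "cp_model"))
  if (is.null(m)) m <- membership_matrix(model)
  s <- activity_strength(model)
  peaks <- apply(unclass(s), 2L, function(col) {
    if (max(col) <= 0) NA_integer_ else which.max(col)
  })
  dplyr::arrange(
    tibble::tibble(
      component = seq_len(model$R),
      size = as.integer(colSums(m)),
      relevance = component_relevance(model),
      peak_interval = as.integer(peaks)
    ),
    dplyr::desc(.data$relevance)
  )
}

#' Broom-style one-row model summary
#'
#' @param x A `cp_model`.
#' @param ... Unused.
#' @return A one-row tibble: `r`, `fit`, `objective`, `n_iter`,
#'   `converged`, `asymmetry`, `seed`.
#' @export
glance.cp_model <- function(x, ...) {
  tibble::tibble(r = x$R, fit = x$fit, objective = x$objective,
                 n_iter = x$n_iter, converged = x$converged,
                 asymmetry = x$asymmetry, seed = x$seed)
}

#' Tidy a CP model's factors
#'
#' @param x A `cp_model`.
#' @param matrix Which factor to tidy: `"A"`, `"B"` or `"C"`.
#' @param ... Unused.
#' @return A long tibble: `row` (node id or interval index),
#'   `component`, `value`.
#' @export
tidy.cp_model <- function(x, matrix = c("A", "B", "C"), ...) {
  matrix <- match.arg(matrix)
  m <- x[[matrix]]
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  tibble::tibble(
    row = rep(ids, times = ncol(m)),
    component = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}
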