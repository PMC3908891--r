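#' Jaccard overlap of two sets
#'
#' `|A intersect B| / |A union B|`; 0 by convention when both sets are
#' empty. Symmetric, 1 for identical non-empty sets.
#'
#' @param a,b Finite sets (vectors; duplicates ignored).
#' @return A scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Match components to ground-truth classes by strict Jaccard criterion
#'
#' For every component, computes the Jaccard overlap between its member
#' set and each known class. A component matches a class if and only if
#' exactly one class has overlap greater than zero — a deliberately
#' strict criterion: a component that touches two classes, however
#' slightly, is unmatched ("mixed"). Teachers are excluded from the
#' overlap computation by default because their class association is
#' ambiguous; set `students_only = FALSE` to include them.
#'
#' @param m A `membership_matrix`.
#' @param truth A [ground_truth()].
#' @param students_only Restrict both component members and class members
#'   to students (default TRUE).
#' @return A tibble with one row per component: `component`, `size`
#'   (members considered, after any student restriction), `matched_class`
#'   (`NA` when unmatched), `jaccard` (overlap with the matched class,
#'   `NA` when unmatched), `n_overlapping_classes`.
#' @export
match_components <- function(m, truth, students_only = TRUE) {
  stopifnot(inherits(truth, "ground_truth"))
  students <- truth$labels$node_id[truth$labels$role == "student"]
  class_sets <- purrr::map(
    rlang::set_names(truth$classes),
    ~ class_members(truth, .x, students_only = students_only)
  )
  purrr::map_dfr(seq_len(ncol(m)), function(k) {
    members <- component_members(m, k)
    if (students_only) members <- intersect(members, students)
    overlaps <- purrr::map_dbl(class_sets, ~ jaccard(members, .x))
    nz <- which(overlaps > 0)
    matched <- length(nz) == 1L
    tibble::tibble(
      component = k,
      size = length(members),
      matched_class = if (matched) names(class_sets)[nz] else NA_character_,
      jaccard = if (matched) unname(overlaps[nz]) else NA_real_,
      n_overlapping_classes = length(nz)
    )
  })
}

#' Recall of the known class structure
#'
#' Given the component-class matches, counts how many nodes of the
#' matched classes were recovered inside their matching components:
#' `class_nodes` is the total number of students the matched classes are
#' known to comprise, `covered_nodes` the number of those students found
#' in the matching components (union over components when several match
#' the same class), and `recall = covered_nodes / class_nodes`. With no
#' matched class, recall is undefined and reported as `NA`.
#'
#' @param matches A tibble from [match_components()].
#' @param m The `membership_matrix` the matches were computed from.
#' @param truth A [ground_truth()].
#' @return A one-row tibble: `n_matched_classes`, `class_nodes`,
#'   `covered_nodes`, `recall`.
#' @export
recall_and_coverage <- function(matches, m, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  matched <- matches[!is.na(matches$matched_class), , drop = FALSE]
  classes <- unique(matched$matched_class)
  if (length(classes) == 0L) {
    return(tibble::tibble(n_matched_classes = 0L, class_nodes = 0L,
                          covered_nodes = 0L, recall = NA_real_))
  }
  students <- truth$labels$node_id[truth$labels$role == "student"]
  class_nodes <- 0L
  covered <- 0L
  for (cl in classes) {
    cls <- class_members(truth, cl, students_only = TRUE)
    comps <- matched$component[matched$matched_class == cl]
    found <- unique(unlist(purrr::map(comps, function(k) {
      intersect(intersect(component_members(m, k), students), cls)
    })))
    class_nodes <- class_nodes + length(cls)
    covered <- covered + length(found)
  }
  tibble::tibble(n_matched_classes = length(classes),
                 class_nodes = class_nodes,
                 covered_nodes = covered,
                 recall = covered / class_nodes)
}

#' Score matrix of a node-community assignment against known classes
#'
#' Entry `(c, k)` is the number of students of class `c` assigned to
#' component (community) `k` — the cross-tabulation `P^T Q` of the class
#' indicator matrix `P` with the binary node-community matrix `Q`. When
#' `Q` encodes the true classes, the score matrix is diagonal with the
#' class sizes on the diagonal (see [reference_score_matrix()]). Works
#' for any binary node-community matrix, including tables produced by
#' external community-detection algorithms.
#'
#' @param m A binary node-by-community matrix with node ids as row names
#'   (e.g. a `membership_matrix`).
#' @param truth A [ground_truth()].
#' @return An integer `n_classes x R` matrix, classes as row names.
#' @export
score_matrix <- function(m, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- matrix(0L, length(truth$classes), ncol(m),
                dimnames = list(truth$classes, NULL))
  for (ci in seq_along(truth$classes)) {
    cls <- class_members(truth, truth$classes[ci], students_only = TRUE)
    for (k in seq_len(ncol(m))) {
      out[ci, k] <- length(intersect(component_members(m, k), cls))
    }
  }
  out
}

#' Reference score matrix (true classes against themselves)
#'
#' The diagonal matrix whose diagonal holds the number of students in
#' each class — the score matrix an exact community recovery would
#' reproduce up to column permutation.
#'
#' @param truth A [ground_truth()].
#' @return An integer diagonal `n_classes x n_classes` matrix.
#' @export
reference_score_matrix <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  sizes <- vapply(truth$classes,
                  function(cl) length(class_members(truth, cl, TRUE)), 1L)
  out <- diag(sizes, nrow = length(sizes))
  dimnames(out) <- list(truth$classes, truth$classes)
  storage.mode(out) <- "integer"
  out
}

#' Co-location series of a component
#'
#' Element-wise product, over all member nodes, of their location
#' fingerprints: `v[b, t] = prod_i f_i[b, t]`. The product is nonzero at
#' receiver `b` and interval `t` if and only if every member emitted
#' packets there — i.e. all members were simultaneously near the same
#' receiver. Members without fingerprint rows contribute all-zero
#' fingerprints (with a warning), zeroing the series. For large
#' components raw products overflow; `log_domain = TRUE` instead returns
#' the binarized AND in log form: `sum_i log1p(f_i[b, t])` where all
#' members are present, 0 elsewhere.
#'
#' @param members Character vector of member node ids.
#' @param fingerprints A [location_fingerprints()].
#' @param rescale Rescale each receiver's series to maximum 1 (for
#'   plotting/reporting; default FALSE).
#' @param log_domain Use the log-domain AND variant (default FALSE).
#' @return A `colocation_series`: `n_receivers x S` non-negative matrix,
#'   receivers as row names.
#' @export
colocation <- function(members, fingerprints, rescale = FALSE,
                       log_domain = FALSE) {
  stopifnot(inherits(fingerprints, "location_fingerprints"))
  if (length(members) == 0L) {
    stop("co-location needs at least one member", call. = FALSE)
  }
  f <- fingerprints$counts
  missing <- setdiff(members, fingerprints$nodes)
  if (length(missing) > 0L) {
    warning("member(s) without fingerprints treated as all-zero: ",
            paste(missing, collapse = ", "), call. = FALSE)
    v <- matrix(0, dim(f)[2L], dim(f)[3L],
                dimnames = list(fingerprints$receivers, NULL))
    return(structure(v, class = c("colocation_series", "matrix", "array")))
  }
  sub <- f[members, , , drop = FALSE]
  v <- if (log_domain) {
    present <- apply(sub > 0, c(2L, 3L), all)
    apply(log1p(sub), c(2L, 3L), sum) * present
  } else {
    apply(sub, c(2L, 3L), prod)
  }
  if (rescale) {
    mx <- apply(v, 1L, max)
    v <- sweep(v, 1L, ifelse(mx > 0, mx, 1), "/")
  }
  structure(v, class = c("colocation_series", "matrix", "array"))
}

#' Tidy a co-location series
#'
#' @param x A `colocation_series`.
#' @param ... Unused.
#' @return A tibble with columns `receiver`, `interval`, `value`.
#' @export
tidy.colocation_series <- function(x, ...) {
  v <- unclass(x)
  recv <- rownames(v) %||% as.character(seq_len(nrow(v)))
  tibble::tibble(
    receiver = rep(recv, times = ncol(v)),
    interval = rep(seq_len(ncol(v)), each = nrow(v)),
    value = as.vector(v)
  )
}

#' Plot a co-location series
#'
#' One line per receiver over intervals.
#'
#' @param object A `colocation_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.colocation_series <- function(object, ...) {
  ggplot2::ggplot(tidy.colocation_series(object),
                  ggplot2::aes(x = .data$interval, y = .data$value,
                               colour = .data$receiver)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "interval", y = "co-location", colour = "receiver") +
    ggplot2::theme_minimal()
}

#' Full structural-validation report for one fitted model
#'
#' Convenience wrapper chaining [membership_matrix()],
#' [match_components()], [recall_and_coverage()] and [score_matrix()].
#'
#' @param model A `cp_model`.
#' @param truth A [ground_truth()].
#' @param students_only Passed to [match_components()].
#' @return A `validation_report` list: `matches` (tibble), `summary`
#'   (one-row tibble incl. recall), `score_matrix`,
#'   `reference_score_matrix`, `membership`.
#' @export
validate_model <- function(model, truth, students_only = TRUE) {
  m <- membership_matrix(model)
  matches <- match_components(m, truth, students_only = students_only)
  structure(
    list(matches = matches,
         summary = recall_and_coverage(matches, m, truth),
         score_matrix = score_matrix(m, truth),
         reference_score_matrix = reference_score_matrix(truth),
         membership = m),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  s <- x$summary
  cat("<validation_report> ", s$n_matched_classes, " matched class(es); ",
      s$covered_nodes, "/", s$class_nodes, " class nodes covered",
      if (!is.na(s$recall)) paste0(" (recall ",
                                   formatC(s$recall, digits = 5,
                                           format = "f"), ")"),
      "\n", sep = "")
  invisible(x)
}
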