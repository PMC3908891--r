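#' Construct a ground-truth labelling of nodes
#'
#' Associates every labelled node with exactly one class and a role
#' (`student` or `teacher`). Class-based validation (Jaccard matching,
#' recall, score matrices) is usually restricted to students, since
#' teachers have no unambiguous class association.
#'
#' @param labels Data frame with columns `node_id`, `class` and
#'   optionally `role` (default `"student"`).
#' @return A `ground_truth` object: tibble `labels` plus the sorted
#'   `classes` vector.
#' @export
ground_truth <- function(labels) {
  stopifnot(is.data.frame(labels))
  if (!all(c("node_id", "class") %in% names(labels))) {
    stop("`labels` needs columns node_id and class", call. = FALSE)
  }
  if (!"role" %in% names(labels)) labels$role <- "student"
  lab <- tibble::tibble(
    node_id = as.character(labels$node_id),
    class = as.character(labels$class),
    role = as.character(labels$role)
  )
  if (anyDuplicated(lab$node_id)) {
    stop("each node must carry exactly one class label; duplicated: ",
         paste(unique(lab$node_id[duplicated(lab$node_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(lab$role), c("student", "teacher"))
  if (length(bad_role) > 0L) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  structure(list(labels = lab, classes = sort(unique(lab$class))),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nrow(x$labels), " nodes (",
      sum(x$labels$role == "student"), " students, ",
      sum(x$labels$role == "teacher"), " teachers) in ",
      length(x$classes), " classes\n", sep = "")
  invisible(x)
}

#' Nodes of one class
#' @param truth A `ground_truth`.
#' @param class A class label.
#' @param students_only Restrict to students (default TRUE).
#' @return Character vector of node ids.
#' @export
class_members <- function(truth, class, students_only = TRUE) {
  stopifnot(inherits(truth, "ground_truth"))
  lab <- truth$labels
  if (students_only) lab <- lab[lab$role == "student", , drop = FALSE]
  lab$node_id[lab$class == class]
}

#' Read node metadata (class labels and roles)
#'
#' Tab-separated file `node_id<TAB>class<TAB>role`, no header; `role` is
#' `student` or `teacher`. When `nodes` is given, metadata node ids absent
#' from it are an error (the metadata must describe the network at hand).
#'
#' @param path Path to the metadata TSV.
#' @param nodes Optional character vector (or [temporal_network()]) whose
#'   registry the metadata must be a subset of.
#' @return A [ground_truth()].
#' @export
read_metadata <- function(path, nodes = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("node_id", "class", "role"),
                           colClasses = "character")
  if (inherits(nodes, "temporal_network")) nodes <- nodes$nodes
  if (!is.null(nodes)) {
    unknown <- setdiff(tab$node_id, nodes)
    if (length(unknown) > 0L) {
      stop("metadata refers to node(s) absent from the network: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  ground_truth(tab)
}

#' Construct location fingerprints
#'
#' Per-node, per-receiver, per-interval radio packet counts: a proxy for
#' room-level position. Stored densely as a `node x receiver x interval`
#' integer array.
#'
#' @param counts A non-negative integer array with dimnames
#'   `(node, receiver, NULL)`.
#' @return A `location_fingerprints` object.
#' @export
location_fingerprints <- function(counts) {
  stopifnot(is.array(counts), length(dim(counts)) == 3L)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("fingerprint counts must be non-negative integers", call. = FALSE)
  }
  structure(list(counts = counts,
                 nodes = dimnames(counts)[[1L]],
                 receivers = dimnames(counts)[[2L]]),
            class = "location_fingerprints")
}

#' @export
print.location_fingerprints <- function(x, ...) {
  d <- dim(x$counts)
  cat("<location_fingerprints> ", d[1L], " nodes x ", d[2L],
      " receivers x ", d[3L], " intervals\n", sep = "")
  invisible(x)
}

#' Read raw location fingerprints and bin them into intervals
#'
#' Tab-separated file `t<TAB>node_id<TAB>receiver_id<TAB>count`, no
#' header. Rows are binned with the same half-open rule as
#' [build_tensor()] (`[t0 + m*delta, t0 + (m+1)*delta)`), summing counts
#' within each (node, receiver, interval) cell.
#'
#' @param path Path to the fingerprint TSV.
#' @param interval_length Interval width in seconds.
#' @param t0 Timeline origin (default 0).
#' @param n_intervals Optional fixed interval count (to align with a
#'   tensor built from the same timeline); inferred from the data when
#'   missing.
#' @return A [location_fingerprints()].
#' @export
read_fingerprints <- function(path, interval_length, t0 = 0,
                              n_intervals = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("t", "node_id", "receiver_id", "count"),
                           colClasses = c("numeric", "character", "character",
                                          "integer"))
  if (nrow(tab) == 0L) stop("empty fingerprint file", call. = FALSE)
  if (min(tab$t) < t0) stop("fingerprint rows before t0", call. = FALSE)
  slot <- floor((tab$t - t0) / interval_length) + 1L
  s <- if (is.null(n_intervals)) max(slot) else n_intervals
  if (any(slot > s)) stop("fingerprint rows beyond interval ", s, call. = FALSE)
  nodes <- sort(unique(tab$node_id))
  receivers <- sort(unique(tab$receiver_id))
  counts <- array(0L, dim = c(length(nodes), length(receivers), s),
                  dimnames = list(nodes, receivers, NULL))
  idx <- cbind(match(tab$node_id, nodes), match(tab$receiver_id, receivers), slot)
  for (row in seq_len(nrow(tab))) {
    counts[idx[row, , drop = FALSE]] <- counts[idx[row, , drop = FALSE]] +
      tab$count[row]
  }
  location_fingerprints(counts)
}

# full-precision numeric formatting so write -> read round-trips exactly
fmt_real <- function(x) sprintf("%.17g", x)

#' Write and read CP factor matrices
#'
#' Factors are written as one TSV per matrix (`<stem>_A.tsv`, `_B.tsv`,
#' `_C.tsv`) with row identifiers in the first column and one column per
#' component, at full double precision so that write-then-read reproduces
#' the values exactly.
#'
#' @param model A `cp_model` (see [factorize()]).
#' @param stem Path stem for the three files.
#' @return `write_factors()` returns the written paths invisibly;
#'   `read_factors()` returns a list of matrices `A`, `B`, `C`.
#' @export
write_factors <- function(model, stem) {
  stopifnot(inherits(model, "cp_model"))
  paths <- paste0(stem, "_", c("A", "B", "C"), ".tsv")
  mats <- list(model$A, model$B, model$C)
  for (m in 1:3) {
    mat <- mats[[m]]
    df <- data.frame(id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
                     apply(mat, 2L, fmt_real))
    names(df) <- c("id", paste0("comp", seq_len(ncol(mat))))
    utils::write.table(df, paths[m], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' @rdname write_factors
#' @export
read_factors <- function(stem) {
  out <- lapply(c("A", "B", "C"), function(which) {
    tab <- utils::read.table(paste0(stem, "_", which, ".tsv"),
                             sep = "\t", header = TRUE,
                             colClasses = "character")
    mat <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- tab[[1L]]
    colnames(mat) <- NULL
    mat
  })
  names(out) <- c("A", "B", "C")
  out
}

#' Write node memberships to TSV
#'
#' Columns: `node_id`, `component`, `weight`, `member` (0/1).
#'
#' @param memberships A tibble as returned by [memberships()].
#' @param path Output path.
#' @export
write_memberships <- function(memberships, path) {
  df <- as.data.frame(memberships)
  df$weight <- fmt_real(df$weight)
  df$member <- as.integer(df$member)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write component activity strengths to CSV
#'
#' Columns: `interval_start` (seconds), `component`, `strength`.
#'
#' @param activities A tibble as returned by [activity_strength()] in
#'   tidy form (see [tidy.activity_profile()]).
#' @param path Output path.
#' @export
write_activities <- function(activities, path) {
  df <- as.data.frame(activities)
  df$strength <- fmt_real(df$strength)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read a snapshot tensor in sparse COO exchange format
#'
#' `<stem>.tsv` holds the nonzero entries `i<TAB>j<TAB>m<TAB>value`
#' (1-based axis positions); `<stem>.json` holds the header (N, S, delta,
#' t0, node order).
#'
#' @param tensor A `snapshot_tensor`.
#' @param stem Path stem.
#' @return `write_tensor()` the paths, invisibly; `read_tensor()` the
#'   reconstructed `snapshot_tensor`.
#' @export
write_tensor <- function(tensor, stem) {
  stopifnot(inherits(tensor, "snapshot_tensor"))
  nz <- which(tensor$values != 0, arr.ind = TRUE)
  df <- data.frame(i = nz[, 1L], j = nz[, 2L], m = nz[, 3L],
                   value = fmt_real(tensor$values[nz]))
  df <- df[order(df$m, df$j, df$i), , drop = FALSE]
  utils::write.table(df, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  header <- list(N = dim(tensor$values)[1L], S = dim(tensor$values)[3L],
                 interval_length = tensor$interval_length, t0 = tensor$t0,
                 nodes = tensor$nodes)
  jsonlite::write_json(header, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(stem, c(".tsv", ".json")))
}

#' @rdname write_tensor
#' @export
read_tensor <- function(stem) {
  header <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  tab <- utils::read.table(paste0(stem, ".tsv"), sep = "\t", header = TRUE,
                           colClasses = c("integer", "integer", "integer",
                                          "character"))
  vals <- array(0, dim = c(header$N, header$N, header$S),
                dimnames = list(header$nodes, header$nodes, NULL))
  vals[cbind(tab$i, tab$j, tab$m)] <- as.numeric(tab$value)
  new_snapshot_tensor(vals, header$nodes, as.numeric(header$interval_length),
                      as.numeric(header$t0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
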