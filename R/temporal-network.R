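#' Construct a temporal network from a table of contact events
#'
#' A temporal network is a stream of timestamped undirected contact events
#' `(time, i, j)` plus a frozen, lexicographically sorted node registry.
#' Self-loop events (`i == j`) and exact duplicate events are dropped with
#' a message; events are sorted by time.
#'
#' @param events A data frame with columns `time` (non-negative numeric
#'   seconds), `i` and `j` (node ids, coerced to character).
#' @param nodes Optional character vector of node ids to register in
#'   addition to those appearing in `events` (isolated nodes).
#' @return A `temporal_network` object: a list with `events` (tibble,
#'   sorted by time), `nodes` (sorted character vector) and
#'   `n_dropped_self_loops` / `n_dropped_duplicates` counts.
#' @export
#' @examples
#' net <- temporal_network(data.frame(time = c(10, 30), i = "A", j = c("B", "C")))
#' net$nodes
temporal_network <- function(events, nodes = NULL) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0L) {
    events <- tibble::tibble(time = numeric(), i = character(), j = character())
  }
  if (!all(c("time", "i", "j") %in% names(events))) {
    stop("`events` needs columns time, i, j", call. = FALSE)
  }
  ev <- tibble::tibble(
    time = as.numeric(events$time),
    i = as.character(events$i),
    j = as.character(events$j)
  )
  if (anyNA(ev)) stop("events contain missing values", call. = FALSE)
  if (any(ev$time < 0)) stop("event times must be non-negative", call. = FALSE)
  loops <- ev$i == ev$j
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop event(s)")
    ev <- ev[!loops, , drop = FALSE]
  }
  # canonical endpoint order so duplicates are direction-independent
  swap <- ev$i > ev$j
  tmp <- ev$i[swap]; ev$i[swap] <- ev$j[swap]; ev$j[swap] <- tmp
  dup <- duplicated(ev)
  if (any(dup)) {
    message("dropped ", sum(dup), " duplicate event(s)")
    ev <- ev[!dup, , drop = FALSE]
  }
  ev <- dplyr::arrange(ev, .data$time, .data$i, .data$j)
  registry <- sort(unique(c(ev$i, ev$j, as.character(nodes))))
  structure(
    list(events = ev, nodes = registry, undirected = TRUE,
         n_dropped_self_loops = sum(loops), n_dropped_duplicates = sum(dup)),
    class = "temporal_network"
  )
}

#' @export
print.temporal_network <- function(x, ...) {
  cat("<temporal_network> ", length(x$nodes), " nodes, ",
      nrow(x$events), " events", sep = "")
  if (nrow(x$events) > 0L) {
    cat(", time span [", min(x$events$time), ", ", max(x$events$time), "] s",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Read a SocioPatterns-style contact edge list
#'
#' Each data line is whitespace- or tab-separated `t i j [extra ...]`:
#' integer seconds, then two node ids; trailing columns are ignored.
#' Blank lines and lines starting with `#` are skipped. Self-loop lines
#' are dropped (with a reported count, see [temporal_network()]).
#'
#' @param path Path to the edge-list file.
#' @param dialect `"whitespace"` (any run of blanks/tabs, default) or
#'   `"tsv"` (single tab separator).
#' @return A [temporal_network()].
#' @export
read_edge_list <- function(path, dialect = c("whitespace", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(temporal_network(data.frame(time = numeric(),
                                       i = character(), j = character())))
  }
  split_pat <- if (dialect == "tsv") "\t" else "[ \t]+"
  parts <- strsplit(trimws(lines[idx]), split_pat)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad) > 0L) {
    stop("malformed edge-list line ", idx[bad[1L]], ": ",
         dQuote(lines[idx[bad[1L]]]), call. = FALSE)
  }
  t <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  if (anyNA(t)) {
    first <- which(is.na(t))[1L]
    stop("malformed edge-list line ", idx[first],
         ": non-numeric timestamp", call. = FALSE)
  }
  temporal_network(data.frame(
    time = t,
    i = vapply(parts, `[[`, "", 2L),
    j = vapply(parts, `[[`, "", 3L)
  ))
}

#' Bin a temporal network into a snapshot adjacency tensor
#'
#' Divides the timeline into consecutive half-open intervals
#' `[t0 + m*delta, t0 + (m+1)*delta)` and builds one adjacency slice per
#' interval: entry `(i, j, m)` is 1 when nodes `i` and `j` had at least
#' one contact during interval `m` (binary default), or the contact count
#' with `weighted = TRUE`. The network is undirected, so both `(i, j, m)`
#' and `(j, i, m)` are set and every slice is symmetric with zero
#' diagonal. The number of slices is `S = ceiling((t_max - t0 + 1)/delta)`
#' and empty intervals (e.g. overnight gaps) are kept, so the time axis is
#' uniform.
#'
#' @param net A [temporal_network()], non-empty.
#' @param interval_length Interval width `delta` in seconds (default 780,
#'   a 13-minute aggregation typical for school-day contact data).
#' @param t0 Timeline origin in seconds; must not exceed the first event
#'   time. Default 0.
#' @param weighted If `TRUE`, entries hold contact counts per interval
#'   instead of presence indicators.
#' @return A `snapshot_tensor`: list with `values` (`N x N x S` array,
#'   dimnames = node ids), `nodes`, `interval_length`, `t0`.
#' @export
build_tensor <- function(net, interval_length = 780, t0 = 0,
                         weighted = FALSE) {
  stopifnot(inherits(net, "temporal_network"))
  if (nrow(net$events) == 0L) stop("cannot bin an empty network", call. = FALSE)
  if (interval_length <= 0) stop("`interval_length` must be positive", call. = FALSE)
  if (min(net$events$time) < t0) {
    stop("events before t0 = ", t0, "; set t0 at or before the first event",
         call. = FALSE)
  }
  nodes <- net$nodes
  n <- length(nodes)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  s <- ceiling((max(net$events$time) - t0 + 1) / interval_length)
  slot <- floor((net$events$time - t0) / interval_length) + 1L
  ii <- match(net$events$i, nodes)
  jj <- match(net$events$j, nodes)
  vals <- array(0, dim = c(n, n, s), dimnames = list(nodes, nodes, NULL))
  idx <- cbind(c(ii, jj), c(jj, ii), c(slot, slot))
  if (weighted) {
    for (row in seq_len(nrow(idx))) {
      vals[idx[row, , drop = FALSE]] <- vals[idx[row, , drop = FALSE]] + 1
    }
  } else {
    vals[idx] <- 1
  }
  new_snapshot_tensor(vals, nodes, interval_length, t0)
}

new_snapshot_tensor <- function(values, nodes, interval_length, t0) {
  structure(
    list(values = values, nodes = nodes,
         interval_length = interval_length, t0 = t0),
    class = "snapshot_tensor"
  )
}

#' @export
print.snapshot_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("<snapshot_tensor> ", d[1L], " nodes x ", d[3L], " intervals (delta = ",
      x$interval_length, " s, t0 = ", x$t0, "), ",
      sum(x$values != 0), " nonzero entries\n", sep = "")
  invisible(x)
}

#' Aggregate a snapshot tensor over time
#'
#' Collapses a binary snapshot tensor into the weighted time-aggregated
#' network: the weight of link `i`-`j` is the number of intervals during
#' which that link was active.
#'
#' @param tensor A binary `snapshot_tensor`.
#' @return An `aggregated_network`: list with `weights` (symmetric
#'   `N x N` integer matrix, zero diagonal) and `nodes`.
#' @export
aggregate_time <- function(tensor) {
  stopifnot(inherits(tensor, "snapshot_tensor"))
  v <- tensor$values
  if (!all(v %in% c(0, 1))) {
    stop("aggregate_time() expects a binary tensor", call. = FALSE)
  }
  w <- apply(v, c(1L, 2L), sum)
  storage.mode(w) <- "integer"
  structure(list(weights = w, nodes = tensor$nodes),
            class = "aggregated_network")
}

#' @export
print.aggregated_network <- function(x, ...) {
  cat("<aggregated_network> ", length(x$nodes), " nodes, ",
      sum(x$weights[upper.tri(x$weights)] > 0), " weighted links\n", sep = "")
  invisible(x)
}

#' Tidy the events of a temporal network
#'
#' @param x A `temporal_network`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `i`, `j`.
#' @export
tidy.temporal_network <- function(x, ...) x$events
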