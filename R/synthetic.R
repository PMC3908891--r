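#' Specification of a planted community-activity benchmark
#'
#' Describes a population partitioned into disjoint groups, each with a
#' per-interval activity schedule, plus optional cross-group "social
#' event" intervals (a lunch-time gathering at a named location) and
#' background noise — the ingredients of a school-like contact network.
#' During an interval a group is active with its scheduled probability;
#' within an active group every node pair makes contact independently
#' with probability `p_in`. Every node pair additionally makes a noise
#' contact with probability `p_noise` per interval. During an event
#' interval, every pair of nodes drawn from the event's groups makes
#' contact with probability `p_event`, and participants emit location
#' fingerprints at the event receiver.
#'
#' @param groups Named list of disjoint character vectors: the member
#'   node ids of each group (names are the class labels).
#' @param schedule Numeric matrix, groups x intervals, activity
#'   probabilities in `[0, 1]` (row names must match group names).
#' @param p_in Within-group contact probability per pair per active
#'   interval.
#' @param p_noise Background contact probability per pair per interval
#'   (default 0).
#' @param events List of events, each a list with `intervals` (integer
#'   vector), `groups` (character vector of group names), `p_event`
#'   (probability) and `location` (receiver name).
#' @param teachers Optional named character vector: teacher node ids,
#'   named by the group they teach; a teacher behaves as a group member
#'   but carries the `teacher` role in the ground truth.
#' @param fingerprint_rate Poisson mean of packet counts emitted at the
#'   home (or event) receiver while active (default 5).
#' @param seed RNG seed; regeneration with the same spec is
#'   bit-identical.
#' @return A `planted_spec` list.
#' @export
planted_spec <- function(groups, schedule, p_in, p_noise = 0,
                         events = list(), teachers = character(),
                         fingerprint_rate = 5, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1L,
            !is.null(names(groups)), all(nzchar(names(groups))))
  all_members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop("groups must be disjoint; duplicated member(s): ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "),
         call. = FALSE)
  }
  schedule <- as.matrix(schedule)
  if (nrow(schedule) != length(groups)) {
    stop("schedule needs one row per group", call. = FALSE)
  }
  if (is.null(rownames(schedule))) rownames(schedule) <- names(groups)
  probs <- c(schedule, p_in, p_noise,
             vapply(events, function(e) e$p_event, 1.0))
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  s <- ncol(schedule)
  for (e in events) {
    stopifnot(all(e$intervals >= 1L), all(e$intervals <= s),
              all(e$groups %in% names(groups)))
  }
  if (length(teachers) > 0L) {
    stopifnot(!is.null(names(teachers)),
              all(names(teachers) %in% names(groups)))
    if (any(teachers %in% all_members)) {
      stop("teacher ids must not overlap group members", call. = FALSE)
    }
  }
  structure(
    list(groups = groups, schedule = schedule, p_in = p_in,
         p_noise = p_noise, events = events, teachers = teachers,
         fingerprint_rate = fingerprint_rate, seed = as.integer(seed)),
    class = "planted_spec"
  )
}

#' The ground truth implied by a planted spec
#' @param spec A [planted_spec()].
#' @return A [ground_truth()] covering group members and teachers.
#' @export
planted_truth <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  lab <- purrr::imap_dfr(spec$groups, function(members, g) {
    tibble::tibble(node_id = members, class = g, role = "student")
  })
  if (length(spec$teachers) > 0L) {
    lab <- dplyr::bind_rows(lab, tibble::tibble(
      node_id = unname(spec$teachers),
      class = names(spec$teachers),
      role = "teacher"
    ))
  }
  ground_truth(lab)
}

#' Generate a planted temporal network with ground truth and fingerprints
#'
#' Draws one realization of the benchmark described by a
#' [planted_spec()]: the snapshot tensor (or, with
#' `output = "network"`, a timestamped event stream placing one contact
#' event at the midpoint of each active pair-interval), the matching
#' ground truth, and location fingerprints. Fingerprints place members of
#' an active group at their home receiver (named after the group) with
#' Poisson-distributed packet counts, and event participants at the
#' event's receiver during event intervals. All randomness derives from
#' `spec$seed`.
#'
#' @param spec A [planted_spec()].
#' @param interval_length Interval width in seconds used for the
#'   synthetic timeline (default 780).
#' @param output `"tensor"` (default) or `"network"`.
#' @return A list with elements `tensor` (or `network`), `truth`
#'   (a [ground_truth()]) and `fingerprints`
#'   (a [location_fingerprints()]).
#' @export
generate_planted <- function(spec, interval_length = 780,
                             output = c("tensor", "network")) {
  output <- match.arg(output)
  stopifnot(inherits(spec, "planted_spec"))
  set.seed(spec$seed)
  s <- ncol(spec$schedule)
  # teachers join their group's roster for contact purposes
  rosters <- spec$groups
  for (g in names(spec$teachers)) {
    rosters[[g]] <- c(rosters[[g]], unname(spec$teachers[names(spec$teachers) == g]))
  }
  nodes <- sort(unique(c(unlist(rosters, use.names = FALSE))))
  n <- length(nodes)
  vals <- array(0, dim = c(n, n, s), dimnames = list(nodes, nodes, NULL))
  receivers <- sort(unique(c(names(spec$groups),
                             vapply(spec$events, function(e) e$location, ""))))
  fp <- array(0L, dim = c(n, length(receivers), s),
              dimnames = list(nodes, receivers, NULL))
  pair_idx <- function(members) {
    idx <- match(members, nodes)
    if (length(idx) < 2L) return(NULL)
    t(utils::combn(sort(idx), 2L))
  }
  add_links <- function(pairs, m, p) {
    if (is.null(pairs) || p <= 0) return(invisible())
    on <- stats::runif(nrow(pairs)) < p
    if (!any(on)) return(invisible())
    pr <- pairs[on, , drop = FALSE]
    vals[cbind(pr[, 1L], pr[, 2L], m)] <<- 1
    vals[cbind(pr[, 2L], pr[, 1L], m)] <<- 1
    invisible()
  }
  group_pairs <- purrr::map(rosters, pair_idx)
  all_pairs <- pair_idx(nodes)
  event_pairs <- purrr::map(spec$events, function(e) {
    pair_idx(unlist(rosters[e$groups], use.names = FALSE))
  })
  for (m in seq_len(s)) {
    for (gi in seq_along(rosters)) {
      g <- names(rosters)[gi]
      if (stats::runif(1L) < spec$schedule[g, m]) {
        add_links(group_pairs[[gi]], m, spec$p_in)
        # active members emit packets at their home receiver
        midx <- match(rosters[[gi]], nodes)
        ridx <- match(g, receivers)
        fp[cbind(midx, ridx, m)] <- fp[cbind(midx, ridx, m)] +
          stats::rpois(length(midx), spec$fingerprint_rate)
      }
    }
    add_links(all_pairs, m, spec$p_noise)
    for (ei in seq_along(spec$events)) {
      e <- spec$events[[ei]]
      if (m %in% e$intervals) {
        add_links(event_pairs[[ei]], m, e$p_event)
        participants <- match(unlist(rosters[e$groups], use.names = FALSE),
                              nodes)
        ridx <- match(e$location, receivers)
        fp[cbind(participants, ridx, m)] <- fp[cbind(participants, ridx, m)] +
          stats::rpois(length(participants), spec$fingerprint_rate)
      }
    }
  }
  truth <- planted_truth(spec)
  fingerprints <- location_fingerprints(fp)
  if (output == "tensor") {
    list(tensor = new_snapshot_tensor(vals, nodes, interval_length, 0),
         truth = truth, fingerprints = fingerprints)
  } else {
    nz <- which(vals != 0, arr.ind = TRUE)
    nz <- nz[nz[, 1L] < nz[, 2L], , drop = FALSE]
    events <- tibble::tibble(
      time = (nz[, 3L] - 1) * interval_length + interval_length / 2,
      i = nodes[nz[, 1L]],
      j = nodes[nz[, 2L]]
    )
    list(network = temporal_network(events, nodes = nodes),
         truth = truth, fingerprints = fingerprints)
  }
}

#' School-like benchmark specification
#'
#' The canonical planted fixture: `n_groups` classes of `group_size`
#' students over `n_intervals` intervals. Classes follow a shared school
#' schedule (high activity during class time, a dip during the lunch
#' block), and one lunch-time gathering mixes the first `event_groups`
#' classes at the cafeteria.
#'
#' @param n_groups Number of classes (default 10).
#' @param group_size Students per class (default 6).
#' @param n_intervals Number of intervals (default 40).
#' @param lunch_intervals Intervals of the lunch block; by default a
#'   block of about a tenth of the timeline starting at 45% of it
#'   (18:21 for the default 40 intervals).
#' @param event_groups How many classes join the cafeteria gathering
#'   (default 4, capped at `n_groups`).
#' @param p_in Within-class contact probability (default 0.6).
#' @param p_event Cross-class contact probability during the gathering
#'   (default 0.5).
#' @param p_noise Background contact probability (default 0.001).
#' @param class_activity Activity probability during class time
#'   (default 0.8).
#' @param lunch_activity Class activity during the lunch block
#'   (default 0.15).
#' @param teachers Add one teacher per class (default FALSE).
#' @param seed RNG seed (default 11).
#' @return A [planted_spec()].
#' @export
school_spec <- function(n_groups = 10L, group_size = 6L, n_intervals = 40L,
                        lunch_intervals = NULL, event_groups = 4L,
                        p_in = 0.6, p_event = 0.5, p_noise = 0.001,
                        class_activity = 0.8, lunch_activity = 0.15,
                        teachers = FALSE, seed = 11L) {
  if (is.null(lunch_intervals)) {
    lunch_intervals <- seq(max(1L, floor(0.45 * n_intervals)),
                           length.out = max(2L, round(0.1 * n_intervals)))
  }
  stopifnot(all(lunch_intervals >= 1L), all(lunch_intervals <= n_intervals))
  event_groups <- min(event_groups, n_groups)
  labels <- sprintf("class%02d", seq_len(n_groups))
  groups <- rlang::set_names(purrr::map(seq_len(n_groups), function(g) {
    sprintf("n%02d_%02d", g, seq_len(group_size))
  }), labels)
  schedule <- matrix(class_activity, n_groups, n_intervals,
                     dimnames = list(labels, NULL))
  schedule[, lunch_intervals] <- lunch_activity
  events <- list(list(intervals = lunch_intervals,
                      groups = labels[seq_len(event_groups)],
                      p_event = p_event, location = "cafeteria"))
  tch <- if (teachers) {
    rlang::set_names(sprintf("t%02d", seq_len(n_groups)), labels)
  } else character()
  planted_spec(groups = groups, schedule = schedule, p_in = p_in,
               p_noise = p_noise, events = events, teachers = tch,
               seed = seed)
}

#' Exact low-rank non-negative tensor with known factors
#'
#' Draws sparse non-negative factor matrices with full column rank and
#' returns their CP reconstruction together with the factors — the
#' standard fixture for core-consistency and recovery properties (an
#' exact rank-`R` tensor fitted with its true factors has core
#' consistency 100).
#'
#' @param r Number of components.
#' @param shape Length-3 integer vector `(I, J, K)`; every mode must be
#'   at least `r` so the factors can have full column rank.
#' @param seed RNG seed.
#' @param sparsity Fraction of entries zeroed in each factor
#'   (default 0.4).
#' @return A list with `tensor` (the `I x J x K` array) and `factors`
#'   (list of `A`, `B`, `C`).
#' @export
exact_lowrank <- function(r, shape, seed = 1L, sparsity = 0.4) {
  stopifnot(length(shape) == 3L, r >= 1L)
  if (any(shape < r)) {
    stop("every mode must be at least r = ", r,
         " for full-column-rank factors", call. = FALSE)
  }
  set.seed(seed)
  draw <- function(nr) {
    for (attempt in 1:50) {
      m <- matrix(stats::runif(nr * r), nr, r)
      m[matrix(stats::runif(nr * r) < sparsity, nr, r)] <- 0
      # keep at least one positive entry per column and full column rank
      if (all(colSums(m) > 0) && qr(m)$rank == r) return(m)
    }
    stop("failed to draw a full-column-rank factor", call. = FALSE)
  }
  a <- draw(shape[1L]); b <- draw(shape[2L]); cc <- draw(shape[3L])
  list(tensor = cp_reconstruct(a, b, cc), factors = list(A = a, B = b, C = cc))
}
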