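# ground truth and membership builders used across blocks
truth_from_sizes <- function(sizes) {
  labels <- purrr::imap_dfr(sizes, function(n, cl) {
    tibble::tibble(node_id = sprintf("%s_s%02d", cl, seq_len(n)),
                   class = cl, role = "student")
  })
  ground_truth(labels)
}

encode_truth <- function(truth) {
  nodes <- truth$labels$node_id
  m <- matrix(0L, length(nodes), length(truth$classes),
              dimnames = list(nodes, NULL))
  for (k in seq_along(truth$classes)) {
    m[class_members(truth, truth$classes[k]), k] <- 1L
  }
  structure(m, class = c("membership_matrix", "matrix", "array"))
}

test_that("jaccard overlap has its defining values", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(1:3, 2:4), 0.5)
  expect_equal(jaccard(1:2, 3:4), 0)
  expect_equal(jaccard(character(), character()), 0)
  expect_equal(jaccard(c(1, 1, 2), c(2, 2, 1)), 1)  # duplicates ignored
  expect_equal(jaccard(1:3, 2:4), jaccard(2:4, 1:3))
})

test_that("the strict single-overlap criterion matches and rejects correctly", {
  truth <- truth_from_sizes(c(A = 4, B = 4))
  m <- encode_truth(truth)
  matches <- match_components(m, truth)
  expect_equal(matches$matched_class, c("A", "B"))
  expect_equal(matches$jaccard, c(1, 1))
  # a component spanning both classes is mixed, hence unmatched
  mixed <- m
  mixed[, 1] <- 1L
  matches2 <- match_components(mixed, truth)
  expect_true(is.na(matches2$matched_class[1]))
  expect_equal(matches2$n_overlapping_classes[1], 2L)
  # even one stray node from another class voids the match
  stray <- encode_truth(truth)
  stray["B_s01", 1] <- 1L
  expect_true(is.na(match_components(stray, truth)$matched_class[1]))
})

test_that("teachers are excluded from matching when students_only", {
  truth <- ground_truth(tibble::tibble(
    node_id = c(sprintf("s%d", 1:4), "t1"),
    class = c("A", "A", "B", "B", "A"),
    role = c(rep("student", 4), "teacher")))
  m <- matrix(0L, 5, 1, dimnames = list(c(sprintf("s%d", 1:4), "t1"), NULL))
  m[c("s1", "s2", "t1"), 1] <- 1L
  m <- structure(m, class = c("membership_matrix", "matrix", "array"))
  matches <- match_components(m, truth, students_only = TRUE)
  expect_equal(matches$matched_class, "A")
  expect_equal(matches$jaccard, 1)  # the teacher does not dilute it
  expect_equal(matches$size, 2L)    # students only
})

test_that("recall counts covered class nodes, full and partial", {
  truth <- truth_from_sizes(c(A = 25))
  m <- encode_truth(truth)
  rc <- recall_and_coverage(match_components(m, truth), m, truth)
  expect_equal(rc$class_nodes, 25L)
  expect_equal(rc$covered_nodes, 25L)
  expect_equal(rc$recall, 1)
  # one member deleted: recall (n-1)/n, still matched
  m2 <- encode_truth(truth)
  m2[1, 1] <- 0L
  rc2 <- recall_and_coverage(match_components(m2, truth), m2, truth)
  expect_equal(rc2$recall, 24 / 25)
  # no matches at all: recall undefined
  m3 <- encode_truth(truth_from_sizes(c(A = 3, B = 3)))
  m3[, 1] <- 1L; m3[, 2] <- 1L
  truth2 <- truth_from_sizes(c(A = 3, B = 3))
  rc3 <- recall_and_coverage(match_components(m3, truth2), m3, truth2)
  expect_equal(rc3$n_matched_classes, 0L)
  expect_true(is.na(rc3$recall))
})

test_that("recall is monotone when a matched component gains a correct member", {
  truth <- truth_from_sizes(c(A = 6, B = 6))
  m <- encode_truth(truth)
  m[2, 1] <- 0L; m[3, 1] <- 0L
  base <- recall_and_coverage(match_components(m, truth), m, truth)$recall
  m[2, 1] <- 1L
  gained <- recall_and_coverage(match_components(m, truth), m, truth)$recall
  expect_gt(gained, base)
  expect_true(base >= 0 && gained <= 1)
})

test_that("score matrices cross-tabulate classes against communities", {
  truth <- truth_from_sizes(c(A = 5, B = 3, C = 4))
  m <- encode_truth(truth)
  sm <- score_matrix(m, truth)
  expect_equal(sm, reference_score_matrix(truth),
               ignore_attr = "dimnames")
  expect_equal(unname(diag(reference_score_matrix(truth))), c(5L, 3L, 4L))
  # empty assignment -> zero matrix
  expect_true(all(score_matrix(m * 0L, truth) == 0L))
  # random assignment against a double-loop counting oracle
  set.seed(70)
  q <- matrix(rbinom(12 * 3, 1, 0.4), 12, 3,
              dimnames = list(truth$labels$node_id, NULL))
  sm2 <- score_matrix(q, truth)
  for (ci in seq_along(truth$classes)) {
    cls <- class_members(truth, truth$classes[ci])
    for (k in 1:3) {
      expect_equal(unname(sm2[ci, k]), sum(q[cls, k]))
    }
  }
  # column sums equal student-restricted component sizes
  expect_equal(unname(colSums(sm2)), unname(colSums(q)))
})

test_that("co-location is the member-wise fingerprint product", {
  counts <- array(0L, c(2, 2, 3),
                  dimnames = list(c("a", "b"), c("r1", "r2"), NULL))
  counts["a", "r1", 1] <- 2L; counts["b", "r1", 1] <- 2L
  counts["a", "r2", 2] <- 3L  # b absent at r2 interval 2
  fp <- location_fingerprints(counts)
  v <- colocation(c("a", "b"), fp)
  expect_equal(unname(v["r1", 1]), 4)
  expect_equal(unname(v["r2", 2]), 0)
  # log-domain AND variant is nonzero exactly where the product is
  vl <- colocation(c("a", "b"), fp, log_domain = TRUE)
  expect_equal(unclass(vl) > 0, unclass(v) > 0)
  # rescaling caps each receiver series at 1
  expect_equal(max(colocation(c("a", "b"), fp, rescale = TRUE)), 1)
  expect_warning(v0 <- colocation(c("a", "zz"), fp), "all-zero")
  expect_true(all(v0 == 0))
})

test_that("the planted gathering is found at the event receiver and time", {
  sim <- tiny_school()
  spec_events <- tiny_school_spec()$events[[1]]
  participants <- unlist(sim$truth$labels$node_id[
    sim$truth$labels$class %in% spec_events$groups])
  v <- colocation(participants, sim$fingerprints)
  peak <- which.max(v["cafeteria", ])
  expect_true(peak %in% spec_events$intervals)
  # off-event intervals have zero cafeteria co-location
  expect_true(all(v["cafeteria", setdiff(1:24, spec_events$intervals)] == 0))
})

test_that("validate_model assembles a coherent report on a planted fixture", {
  sim <- tiny_school()
  fit <- ntf(sim$tensor, r = 4, n_runs = 5, seed = 9, max_iter = 300)
  rep <- validate_model(fit$model, sim$truth)
  expect_equal(rep$summary$n_matched_classes, 3L)
  expect_equal(rep$summary$recall, 1)
  matched <- rep$matches[!is.na(rep$matches$matched_class), ]
  expect_equal(matched$jaccard, rep(1, 3))
  # exactly one mixed component, overlapping the two event groups
  unmatched <- rep$matches[is.na(rep$matches$matched_class), ]
  expect_equal(nrow(unmatched), 1L)
  expect_equal(unmatched$n_overlapping_classes, 2L)
  # score matrix: diagonal block for matched classes
  for (i in seq_len(nrow(matched))) {
    ci <- match(matched$matched_class[i], sim$truth$classes)
    expect_equal(unname(rep$score_matrix[ci, matched$component[i]]),
                 unname(diag(rep$reference_score_matrix))[ci])
  }
})
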