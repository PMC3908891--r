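edge_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".dat",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("edge lists parse, with a frozen sorted node registry", {
  net <- read_edge_list(edge_file(c("10 A B", "30 B C", "30 A B")))
  expect_s3_class(net, "temporal_network")
  expect_equal(nrow(net$events), 3L)
  expect_equal(net$nodes, c("A", "B", "C"))
  expect_false(is.unsorted(net$events$time))
  # trailing columns ignored; tabs allowed in whitespace dialect
  net2 <- read_edge_list(edge_file(c("10\tA\tB\textra stuff", "30 B C",
                                     "30 A B")))
  expect_equal(net2$events, net$events)
})

test_that("empty input yields an empty network without error", {
  net <- read_edge_list(edge_file(character()))
  expect_equal(nrow(net$events), 0L)
  expect_equal(length(net$nodes), 0L)
})

test_that("self-loops are dropped with a reported count", {
  path <- edge_file(c("10 A B", "20 C C", "30 B C"))
  expect_message(net <- read_edge_list(path), "1 self-loop")
  expect_equal(nrow(net$events), 2L)
  expect_equal(net$n_dropped_self_loops, 1L)
})

test_that("malformed lines fail with their line number", {
  expect_error(read_edge_list(edge_file(c("10 A B", "garbage"))), "line 2")
  expect_error(read_edge_list(edge_file(c("# comment", "x A B"))),
               "non-numeric timestamp")
  expect_error(read_edge_list("/nonexistent/file.dat"), "no such file")
})

test_that("tensor binning is binary, symmetric and half-open", {
  net <- temporal_network(data.frame(time = 5, i = "a", j = "b"))
  tz <- build_tensor(net, interval_length = 10, t0 = 0)
  expect_equal(dim(tz$values), c(2L, 2L, 1L))
  expect_equal(sum(tz$values != 0), 2)  # (a,b) and (b,a)
  # repeated contacts in one interval still give a presence indicator of 1
  net2 <- temporal_network(data.frame(time = c(2, 7), i = "a", j = "b"))
  t2 <- build_tensor(net2, interval_length = 10)
  expect_equal(max(t2$values), 1)
  expect_equal(build_tensor(net2, interval_length = 10,
                            weighted = TRUE)$values["a", "b", 1], 2)
  # boundary event at t = 10 with delta = 10 falls in the second interval
  net3 <- temporal_network(data.frame(time = c(5, 10), i = "a", j = "b"))
  t3 <- build_tensor(net3, interval_length = 10)
  expect_equal(dim(t3$values)[3], 2L)
  expect_equal(t3$values["a", "b", ], c(1, 1))
  expect_error(build_tensor(net3, interval_length = 10, t0 = 6), "before t0")
})

test_that("every slice of an undirected tensor is symmetric with zero diagonal", {
  set.seed(21)
  ev <- data.frame(time = sample(0:500, 40, replace = TRUE),
                   i = sample(letters[1:6], 40, replace = TRUE),
                   j = sample(letters[1:6], 40, replace = TRUE))
  ev <- ev[ev$i != ev$j, ]
  tz <- build_tensor(temporal_network(ev), interval_length = 60)
  for (m in seq_len(dim(tz$values)[3])) {
    slice <- tz$values[, , m]
    expect_equal(slice, t(slice))
    expect_true(all(diag(slice) == 0))
  }
})

test_that("time aggregation equals a direct event-scan oracle", {
  set.seed(22)
  for (rep in 1:5) {
    ev <- data.frame(time = sample(0:300, 30, replace = TRUE),
                     i = sample(letters[1:4], 30, replace = TRUE),
                     j = sample(letters[1:4], 30, replace = TRUE))
    ev <- ev[ev$i != ev$j, ]
    if (nrow(ev) == 0) next
    net <- temporal_network(ev)
    tz <- build_tensor(net, interval_length = 50)
    agg <- aggregate_time(tz)
    expect_equal(agg$weights, t(agg$weights))
    # oracle: distinct intervals containing an (i,j) event
    for (a in net$nodes) for (b in net$nodes) {
      if (a >= b) next
      hit <- net$events$time[(net$events$i == a & net$events$j == b) |
                             (net$events$i == b & net$events$j == a)]
      expect_equal(agg$weights[a, b], length(unique(hit %/% 50)))
    }
    expect_true(all(agg$weights <= dim(tz$values)[3]))
  }
  # weighted tensors are refused
  net <- temporal_network(data.frame(time = c(1, 2), i = "a", j = "b"))
  wt <- build_tensor(net, interval_length = 10, weighted = TRUE)
  expect_error(aggregate_time(wt), "binary")
})

test_that("metadata reading validates node ids and roles", {
  meta <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\t1A\tstudent", "b\t1A\tteacher", "c\t2B\tstudent"), meta)
  truth <- read_metadata(meta, nodes = c("a", "b", "c", "d"))
  expect_s3_class(truth, "ground_truth")
  expect_equal(truth$classes, c("1A", "2B"))
  expect_equal(class_members(truth, "1A"), "a")
  expect_equal(class_members(truth, "1A", students_only = FALSE), c("a", "b"))
  expect_error(read_metadata(meta, nodes = c("a", "b")), "absent.*c")
  writeLines(c("a\t1A\tjanitor"), meta)
  expect_error(read_metadata(meta), "unknown role")
  expect_error(ground_truth(data.frame(node_id = c("a", "a"),
                                       class = c("1A", "2B"))),
               "exactly one class")
})

test_that("factor matrices round-trip exactly through TSV", {
  fx <- exact_lowrank(2, c(5, 5, 4), seed = 30)
  model <- tempocomm:::new_cp_model(fx$factors$A, fx$factors$B,
                                    fx$factors$C)
  stem <- file.path(withr::local_tempdir(), "f")
  write_factors(model, stem)
  back <- read_factors(stem)
  expect_identical(unname(back$A), unname(fx$factors$A))
  expect_identical(unname(back$B), unname(fx$factors$B))
  expect_identical(unname(back$C), unname(fx$factors$C))
})

test_that("snapshot tensors round-trip through sparse COO exchange files", {
  sim <- tiny_school()
  stem <- file.path(withr::local_tempdir(), "t")
  write_tensor(sim$tensor, stem)
  back <- read_tensor(stem)
  expect_identical(back$values, sim$tensor$values)
  expect_identical(back$nodes, sim$tensor$nodes)
  expect_identical(back$interval_length, sim$tensor$interval_length)
})

test_that("fingerprint binning matches a brute-force binning oracle", {
  set.seed(31)
  tab <- data.frame(t = sample(0:199, 50, replace = TRUE),
                    node = sample(c("a", "b", "c"), 50, replace = TRUE),
                    recv = sample(c("r1", "r2"), 50, replace = TRUE),
                    count = sample(1:5, 50, replace = TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fp <- read_fingerprints(path, interval_length = 60)
  for (nd in c("a", "b", "c")) for (rv in c("r1", "r2")) {
    for (m in seq_len(dim(fp$counts)[3])) {
      sel <- tab$node == nd & tab$recv == rv &
        tab$t >= (m - 1) * 60 & tab$t < m * 60
      expect_equal(fp$counts[nd, rv, m], sum(tab$count[sel]))
    }
  }
})
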