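# independent CORCONDIA oracle: least-squares core via the explicit
# Kronecker system, then the similarity formula
corcondia_oracle <- function(x, a, b, cc) {
  k <- kronecker(cc, kronecker(b, a))
  g <- array(qr.solve(crossprod(k), crossprod(k, as.vector(x))),
             dim = rep(ncol(a), 3))
  100 * (1 - sum((g - superdiagonal(ncol(a)))^2) / ncol(a))
}

test_that("core consistency is 100 for exact models with true factors", {
  for (r in 1:4) {
    fx <- exact_lowrank(r, c(8, 9, 7), seed = 50 + r)
    model <- tempocomm:::new_cp_model(fx$factors$A, fx$factors$B,
                                      fx$factors$C)
    expect_equal(as.numeric(core_consistency(fx$tensor, model)), 100,
                 tolerance = 1e-6)
  }
})

test_that("single-component core consistency reduces to its closed form", {
  set.seed(51)
  x <- array(runif(4 * 3 * 5), c(4, 3, 5))
  a <- matrix(runif(4), 4, 1); b <- matrix(runif(3), 3, 1)
  cc <- matrix(runif(5), 5, 1)
  g <- as.numeric(tucker_core_fit(x, a, b, cc))
  model <- tempocomm:::new_cp_model(a, b, cc)
  expect_equal(as.numeric(core_consistency(x, model)),
               100 * (1 - (g - 1)^2))
})

test_that("a duplicated component degrades core consistency as the oracle predicts", {
  fx <- exact_lowrank(2, c(7, 7, 6), seed = 52)
  # same column twice at halved weight: identical reconstruction, but a
  # redundant 3-component model
  a3 <- cbind(fx$factors$A[, 1] / 2, fx$factors$A[, 1] / 2, fx$factors$A[, 2])
  b3 <- cbind(fx$factors$B[, 1], fx$factors$B[, 1], fx$factors$B[, 2])
  c3 <- cbind(fx$factors$C[, 1], fx$factors$C[, 1], fx$factors$C[, 2])
  model <- tempocomm:::new_cp_model(a3, b3, c3)
  cc_val <- core_consistency(fx$tensor, model)
  expect_true(attr(cc_val, "rank_deficient"))
  # independent pinv-based oracle (minimum-norm core through MASS::ginv)
  vg <- kronecker(MASS::ginv(c3), kronecker(MASS::ginv(b3),
                                            MASS::ginv(a3))) %*%
    as.vector(fx$tensor)
  oracle <- 100 * (1 - sum((array(vg, c(3, 3, 3)) - superdiagonal(3))^2) / 3)
  expect_equal(as.numeric(cc_val), oracle, tolerance = 1e-6)
  expect_lt(as.numeric(cc_val), 51)  # far from the exact-model value of 100
})

test_that("core consistency never exceeds 100 on random fitted models", {
  set.seed(53)
  for (rep in 1:10) {
    x <- array(runif(5 * 5 * 4), c(5, 5, 4))
    runs <- factorize(x, solver_config(r = 2, n_runs = 1, seed = rep,
                                       max_iter = 40))
    cc_val <- as.numeric(core_consistency(x, runs[[1]]))
    expect_lte(cc_val, 100 + 1e-9)
    expect_equal(cc_val, corcondia_oracle(x, runs[[1]]$A, runs[[1]]$B,
                                          runs[[1]]$C),
                 tolerance = 1e-6)
  }
})

test_that("relevance is the product of column norms and scale-invariant", {
  # unit-norm columns in all three factors give relevance 1
  u <- matrix(c(1, 0, 0, 1), 2)
  model <- tempocomm:::new_cp_model(u, u, u)
  expect_equal(component_relevance(model), c(1, 1))
  set.seed(54)
  a <- matrix(runif(8), 4, 2); b <- matrix(runif(6), 3, 2)
  cc <- matrix(runif(10), 5, 2)
  m1 <- tempocomm:::new_cp_model(a, b, cc)
  oracle <- vapply(1:2, function(k) {
    sqrt(sum(a[, k]^2)) * sqrt(sum(b[, k]^2)) * sqrt(sum(cc[, k]^2))
  }, 1.0)
  expect_equal(component_relevance(m1), oracle)
  alpha <- c(3, 0.5); beta <- c(0.2, 7)
  m2 <- tempocomm:::new_cp_model(sweep(a, 2, alpha, "*"),
                                 sweep(b, 2, beta, "*"),
                                 sweep(cc, 2, alpha * beta, "/"))
  expect_equal(component_relevance(m2), component_relevance(m1),
               tolerance = 1e-12)
  expect_equal(decomposition_score(m2, "sum"),
               decomposition_score(m1, "sum"), tolerance = 1e-12)
  expect_equal(decomposition_score(m2, "product"),
               decomposition_score(m1, "product"), tolerance = 1e-12)
})

test_that("run selection ranks by core consistency then by score", {
  diag3 <- tibble::tibble(run = 1:3, seed = 1:3,
                          core_consistency = c(90, 99, 95),
                          score = c(1, 1, 1))
  kept <- select_best(diag3, keep_cc = 2, keep_score = 2)
  expect_setequal(kept$core_consistency, c(99, 95))
  diag_tie <- tibble::tibble(run = 1:2, seed = 1:2,
                             core_consistency = c(80, 80),
                             score = c(3, 5))
  expect_equal(select_best(diag_tie, 2, 2)$score[1], 5)
  # 20 simulated runs against a sort oracle
  set.seed(55)
  sim <- tibble::tibble(run = 1:20, seed = sample(1000, 20),
                        core_consistency = round(runif(20, 50, 100), 1),
                        score = round(runif(20, 1, 10), 2))
  kept <- select_best(sim, keep_cc = 10, keep_score = 5)
  oracle <- sim[order(-sim$core_consistency, sim$seed), ][1:10, ]
  oracle <- oracle[order(-oracle$score, oracle$seed), ][1:5, ]
  expect_equal(kept$run, oracle$run)
})

test_that("the consistency sweep exposes the planted-rank crossover", {
  fx <- exact_lowrank(3, c(9, 9, 8), seed = 56, sparsity = 0.3)
  report <- consistency_sweep(fx$tensor, ranks = 2:6, n_runs = 4,
                              max_iter = 150, seed = 3, keep_cc = 3,
                              keep_score = 2)
  best_cc <- tapply(report$core_consistency, report$r, max)
  expect_gte(best_cc[["2"]], 95)
  expect_gte(best_cc[["3"]], 95)
  expect_lt(best_cc[["5"]], 90)
  expect_lt(best_cc[["6"]], 90)
  # deterministic under the master seed
  report2 <- consistency_sweep(fx$tensor, ranks = 2:6, n_runs = 4,
                               max_iter = 150, seed = 3, keep_cc = 3,
                               keep_score = 2)
  expect_equal(as.data.frame(report), as.data.frame(report2))
  single <- consistency_sweep(fx$tensor, ranks = 3, n_runs = 2,
                              max_iter = 60, seed = 3, keep_cc = 1,
                              keep_score = 1)
  expect_equal(nrow(single), 1L)
  expect_s3_class(autoplot(single), "ggplot")
})
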