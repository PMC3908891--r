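# shared fixtures and independent oracles

random_tensor <- function(dims, seed) {
  set.seed(seed)
  array(runif(prod(dims)), dim = dims)
}

# triple-loop CP reconstruction, independent of the unfolded-form path
cp_triple_sum <- function(a, b, c) {
  out <- array(0, dim = c(nrow(a), nrow(b), nrow(c)))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    for (k in seq_len(nrow(c))) {
      out[i, j, k] <- sum(a[i, ] * b[j, ] * c[k, ])
    }
  out
}

# column-wise Kronecker oracle
kr_oracle <- function(a, b) {
  out <- matrix(0, nrow(a) * nrow(b), ncol(a))
  for (r in seq_len(ncol(a))) out[, r] <- kronecker(a[, r], b[, r])
  out
}

# exhaustive NNLS by enumerating all passive-set sign patterns (<= 3 vars):
# for every subset P, solve the unconstrained LS on P, keep feasible
# candidates, return the best
nnls_enumerate <- function(k, x) {
  r <- ncol(k)
  best <- NULL; best_obj <- Inf
  for (mask in 0:(2^r - 1)) {
    p <- as.logical(bitwAnd(mask, 2^(seq_len(r) - 1L)))
    f <- numeric(r)
    if (any(p)) {
      kp <- k[, p, drop = FALSE]
      sol <- tryCatch(qr.solve(kp, x), error = function(e) NULL)
      if (is.null(sol)) next
      f[p] <- sol
    }
    if (any(f < -1e-12)) next
    obj <- sum((x - as.vector(k %*% f))^2)
    if (obj < best_obj - 1e-12) { best_obj <- obj; best <- pmax(f, 0) }
  }
  best
}

# KKT residual of an NNLS solution: stationarity on the support,
# non-negative gradient off it
nnls_kkt_residual <- function(k, x, f) {
  grad <- as.vector(crossprod(k, k %*% f - x))
  max(abs(grad[f > 1e-10]), -min(grad, 0), 0)
}

# small planted fixture shared across interpretation/validation tests;
# contacts dense enough that the planted structure is reliably recoverable
tiny_school_spec <- function(seed = 11, ...) {
  school_spec(n_groups = 3L, group_size = 5L, n_intervals = 24L,
              lunch_intervals = 11:14, event_groups = 2L,
              p_in = 0.8, p_event = 0.7, seed = seed, ...)
}

tiny_school <- function(seed = 11, ...) {
  generate_planted(tiny_school_spec(seed = seed, ...))
}
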