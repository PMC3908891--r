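#' Construct a CP model object
#'
#' Bundles the three non-negative factor matrices of a CP (PARAFAC)
#' decomposition with its fit metadata. `A` and `B` carry node membership
#' weights (first and second node mode), `C` the per-interval activity of
#' each component.
#'
#' @param a,b,c Non-negative factor matrices with a common column count.
#' @param objective Final residual `||T - That||_F`.
#' @param fit Relative fit `1 - objective / ||T||_F`.
#' @param n_iter Number of alternating sweeps performed.
#' @param seed RNG seed of the run.
#' @param converged Logical: did the relative objective change fall below
#'   tolerance before the iteration cap?
#' @param collapsed Integer vector of component indices whose columns
#'   collapsed to zero and stayed there.
#' @param asymmetry `||A_n - B_n||_F / ||A_n||_F` on column-normalized
#'   factors; near zero for well-converged undirected fits, where the two
#'   node modes agree.
#' @return A `cp_model` object.
#' @keywords internal
new_cp_model <- function(a, b, c, objective = NA_real_, fit = NA_real_,
                         n_iter = 0L, seed = NA_integer_, converged = FALSE,
                         collapsed = integer(), asymmetry = NA_real_) {
  stopifnot(ncol(a) == ncol(b), ncol(b) == ncol(c))
  if (min(a, b, c) < 0) stop("CP factors must be non-negative", call. = FALSE)
  structure(
    list(A = a, B = b, C = c, R = ncol(a), objective = objective, fit = fit,
         n_iter = n_iter, seed = seed, converged = converged,
         collapsed = collapsed, asymmetry = asymmetry),
    class = "cp_model"
  )
}

#' @export
print.cp_model <- function(x, ...) {
  cat("<cp_model> R = ", x$R, ", ", nrow(x$A), " nodes x ", nrow(x$C),
      " intervals\n  fit = ", formatC(x$fit, digits = 5, format = "f"),
      ", objective = ", formatC(x$objective, digits = 4, format = "g"),
      ", ", x$n_iter, " sweeps",
      if (isTRUE(x$converged)) " (converged)" else " (iteration cap)",
      "\n", sep = "")
  if (length(x$collapsed) > 0L) {
    cat("  collapsed component(s): ", paste(x$collapsed, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Reconstruct the tensor approximated by a CP model
#' @param model A `cp_model`.
#' @return A three-way array.
#' @export
cp_tensor <- function(model) {
  stopifnot(inherits(model, "cp_model"))
  cp_reconstruct(model$A, model$B, model$C)
}

#' Normalize a CP model's node factors
#'
#' Rescales every column of `A` and `B` to unit L2 norm and absorbs the
#' scale into the matching column of `C`, leaving the reconstruction
#' unchanged (the CP scaling indeterminacy). All-zero columns are left
#' untouched.
#'
#' @param model A `cp_model`.
#' @return A `cp_model` with unit-norm `A`, `B` columns.
#' @export
normalize_cp <- function(model) {
  stopifnot(inherits(model, "cp_model"))
  na <- sqrt(colSums(model$A^2)); nb <- sqrt(colSums(model$B^2))
  sa <- ifelse(na > 0, na, 1); sb <- ifelse(nb > 0, nb, 1)
  out <- model
  out$A <- sweep(model$A, 2L, sa, "/")
  out$B <- sweep(model$B, 2L, sb, "/")
  out$C <- sweep(model$C, 2L, sa * sb, "*")
  out
}

factor_asymmetry <- function(a, b) {
  if (nrow(a) != nrow(b)) return(NA_real_)  # node modes differ in size
  na <- sqrt(colSums(a^2)); nb <- sqrt(colSums(b^2))
  an <- sweep(a, 2L, ifelse(na > 0, na, 1), "/")
  bn <- sweep(b, 2L, ifelse(nb > 0, nb, 1), "/")
  denom <- frobenius(an)
  if (denom == 0) return(NA_real_)
  frobenius(an - bn) / denom
}

#' Solver configuration for non-negative CP factorization
#'
#' @param r Number of components (rank of the approximation), >= 1.
#' @param n_runs Number of independent multi-start runs (default 20).
#' @param max_iter Sweep cap per run (default 500).
#' @param tol Convergence threshold on the relative objective change per
#'   sweep (default 1e-7).
#' @param seed Master seed; run `k` uses a seed derived from
#'   `(seed, k)`, so runs are individually reproducible.
#' @param nnls_method Per-block NNLS algorithm, `"block-pivot"` or
#'   `"active-set"` (see [nnls_block()]).
#' @return A `solver_config` list.
#' @export
solver_config <- function(r, n_runs = 20L, max_iter = 500L, tol = 1e-7,
                          seed = 1L, nnls_method = c("block-pivot",
                                                     "active-set")) {
  nnls_method <- match.arg(nnls_method)
  stopifnot(r >= 1L, n_runs >= 1L, max_iter >= 1L, tol > 0)
  structure(list(r = as.integer(r), n_runs = as.integer(n_runs),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), nnls_method = nnls_method),
            class = "solver_config")
}

# deterministic per-run seed below 2^31
run_seed <- function(seed, run) {
  as.integer((as.double(seed) * 48271 + run * 7919) %% 2147483647)
}

tensor_values <- function(x) {
  if (inherits(x, "snapshot_tensor")) x$values else x
}

#' One alternating-least-squares sweep over the three factor blocks
#'
#' Updates `A` from the mode-1 unfolding against `C kr B`, then `B` from
#' mode 2 against `C kr A`, then `C` from mode 3 against `B kr A`, each
#' by an exact non-negative least-squares block solve ([nnls_block()]).
#' Because every block solve is exact, the objective is monotone
#' non-increasing; a numerical increase beyond tolerance raises an error
#' (it would indicate a solver defect).
#'
#' @param x A three-way non-negative array or `snapshot_tensor`.
#' @param model A `cp_model` holding the current factors.
#' @param nnls_method Passed to [nnls_block()].
#' @return The updated `cp_model` (with refreshed objective and fit).
#' @export
als_sweep <- function(x, model, nnls_method = "block-pivot") {
  v <- tensor_values(x)
  stopifnot(inherits(model, "cp_model"), length(dim(v)) == 3L)
  a <- model$A; b <- model$B; cc <- model$C
  obj_before <- model$objective
  if (is.na(obj_before)) {
    obj_before <- frobenius(v - cp_reconstruct(a, b, cc))
  }
  a <- nnls_block(unfold(v, 1L), khatri_rao(cc, b), method = nnls_method,
                  warn_zero = FALSE, f_init = unname(a))
  b <- nnls_block(unfold(v, 2L), khatri_rao(cc, a), method = nnls_method,
                  warn_zero = FALSE, f_init = unname(b))
  cc <- nnls_block(unfold(v, 3L), khatri_rao(b, a), method = nnls_method,
                   warn_zero = FALSE, f_init = unname(cc))
  obj <- frobenius(v - cp_reconstruct(a, b, cc))
  if (obj > obj_before * (1 + 1e-10) + 1e-10) {
    if (obj - obj_before < 1e-8 * (1 + frobenius(v))) {
      # floating-point jitter at an essentially exact fit: keep the
      # previous iterate so the reported objective stays monotone
      out <- model
      out$objective <- obj_before
      nv <- frobenius(v)
      out$fit <- if (nv > 0) 1 - obj_before / nv else NA_real_
      return(out)
    }
    stop("ALS objective increased within one sweep (",
         obj_before, " -> ", obj, "); solver defect", call. = FALSE)
  }
  rownames(a) <- rownames(model$A); rownames(b) <- rownames(model$B)
  out <- model
  out$A <- a; out$B <- b; out$C <- cc
  out$objective <- obj
  nv <- frobenius(v)
  out$fit <- if (nv > 0) 1 - obj / nv else NA_real_
  out
}

init_cp_run <- function(v, r, seed) {
  set.seed(seed)
  scale <- max(mean(v), .Machine$double.eps)^(1 / 3)
  d <- dim(v)
  a <- matrix(stats::runif(d[1L] * r), d[1L], r) * scale
  b <- matrix(stats::runif(d[2L] * r), d[2L], r) * scale
  cc <- matrix(stats::runif(d[3L] * r), d[3L], r) * scale
  list(a = a, b = b, c = cc)
}

# reseed all-zero columns once from uniform noise; report repeat offenders
handle_collapse <- function(model, reseeded) {
  zero_cols <- which(colSums(model$A) + colSums(model$B) + colSums(model$C) == 0)
  collapsed <- intersect(zero_cols, reseeded)
  fresh <- setdiff(zero_cols, reseeded)
  for (k in fresh) {
    model$A[, k] <- stats::runif(nrow(model$A)) * 1e-2
    model$B[, k] <- stats::runif(nrow(model$B)) * 1e-2
    model$C[, k] <- stats::runif(nrow(model$C)) * 1e-2
    model$objective <- NA_real_   # reconstruction changed; re-baseline
  }
  list(model = model, reseeded = union(reseeded, fresh), collapsed = collapsed)
}

#' Multi-start non-negative CP (PARAFAC) factorization
#'
#' Approximates a non-negative three-way tensor as a sum of `R`
#' non-negative rank-1 components by minimizing `||T - That||_F` with
#' alternating non-negative least squares. Each of the `n_runs` runs
#' starts from independent uniform(0, 1) factors scaled to the tensor
#' magnitude and sweeps ([als_sweep()]) until the relative objective
#' change drops below `tol` or `max_iter` is reached. Runs are
#' individually seeded from the master seed, so the full list is
#' reproducible. Because the objective is non-convex, runs end in
#' different local minima; rank them with [diagnose_runs()] and
#' [select_best()].
#'
#' @param x A non-negative three-way array or `snapshot_tensor`.
#' @param config A [solver_config()].
#' @return A list of `cp_model` objects, one per run.
#' @export
#' @examples
#' fx <- exact_lowrank(2, c(6, 6, 5), seed = 1)
#' runs <- factorize(fx$tensor, solver_config(r = 2, n_runs = 2, seed = 1))
#' runs[[1]]
factorize <- function(x, config) {
  v <- tensor_values(x)
  stopifnot(inherits(config, "solver_config"), length(dim(v)) == 3L)
  if (min(v) < 0) stop("tensor must be non-negative", call. = FALSE)
  d <- dim(v)
  if (config$r > d[1L] * d[2L] || config$r > max(d)) {
    warning("R = ", config$r, " is large for a ",
            paste(d, collapse = "x"), " tensor", call. = FALSE)
  }
  nodes <- if (inherits(x, "snapshot_tensor")) x$nodes else dimnames(v)[[1L]]
  nv <- frobenius(v)
  purrr::map(seq_len(config$n_runs), function(run) {
    rs <- run_seed(config$seed, run)
    ini <- init_cp_run(v, config$r, rs)
    model <- new_cp_model(ini$a, ini$b, ini$c, seed = rs)
    if (!is.null(nodes)) {
      rownames(model$A) <- nodes
      rownames(model$B) <- nodes
    }
    reseeded <- integer()
    obj_prev <- Inf
    converged <- FALSE
    iter <- 0L
    while (iter < config$max_iter) {
      iter <- iter + 1L
      model <- als_sweep(v, model, nnls_method = config$nnls_method)
      hc <- handle_collapse(model, reseeded)
      model <- hc$model; reseeded <- hc$reseeded
      if (is.finite(obj_prev) && !is.na(model$objective)) {
        rel <- abs(obj_prev - model$objective) /
          max(obj_prev, .Machine$double.eps)
        if (rel < config$tol) { converged <- TRUE; break }
      }
      if (!is.na(model$objective)) obj_prev <- model$objective
    }
    model$n_iter <- iter
    model$converged <- converged
    model$collapsed <- which(
      colSums(model$A) + colSums(model$B) + colSums(model$C) == 0)
    model$asymmetry <- factor_asymmetry(model$A, model$B)
    model
  })
}
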