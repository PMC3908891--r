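#' Non-negative least squares for a block of right-hand sides
#'
#' Solves `min_{F >= 0} || X - F K^T ||_F` row by row: each row `f` of `F`
#' is the exact solution of the non-negative least-squares problem
#' `min_{f >= 0} || x - K f ||_2` for the matching row `x` of `X`. The
#' primary algorithm is block principal pivoting on the normal equations
#' (fast for the many-small-problems shape of alternating least squares);
#' when the pivoting safeguard detects cycling it falls back to single
#' exchanges (Murty's rule, lowest infeasible index first), which is
#' finitely terminating. `method = "active-set"` instead solves every row
#' with the Lawson-Hanson active-set algorithm.
#'
#' Columns of `K` that are identically zero carry no information: the
#' corresponding coefficients are fixed at zero and a warning is issued.
#'
#' @param x Numeric matrix of right-hand sides, one problem per row
#'   (`n x m`).
#' @param k Numeric design matrix (`m x R`), no missing values.
#' @param method `"block-pivot"` (default) or `"active-set"`.
#' @param warn_zero Warn about zero design columns (default TRUE; the
#'   ALS solver silences this because it tracks collapsed components
#'   itself).
#' @param f_init Optional feasible (non-negative) starting matrix of the
#'   same shape as the result. When supplied, a row update is only
#'   accepted if it does not increase that row's objective — with nearly
#'   collinear design columns the normal-equation solves lose precision,
#'   and this safeguard keeps alternating sweeps monotone.
#' @return A non-negative `n x R` matrix `F`. Each row satisfies the KKT
#'   conditions of its NNLS problem to tight tolerance.
#' @export
nnls_block <- function(x, k, method = c("block-pivot", "active-set"),
                       warn_zero = TRUE, f_init = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), is.matrix(k))
  if (anyNA(k) || anyNA(x)) stop("NNLS inputs must not contain NA", call. = FALSE)
  if (ncol(x) != nrow(k)) {
    stop("ncol(x) must equal nrow(k): got ", ncol(x), " and ", nrow(k),
         call. = FALSE)
  }
  r <- ncol(k)
  live <- colSums(k^2) > 0
  if (!all(live) && warn_zero) {
    warning(sum(!live), " zero column(s) in the design matrix; ",
            "their coefficients are fixed at 0", call. = FALSE)
  }
  out <- matrix(0, nrow(x), r)
  if (!any(live)) return(out)
  kl <- k[, live, drop = FALSE]
  g <- crossprod(kl)            # R x R Gram, shared by all rows
  h <- x %*% kl                 # n x R
  # quadratic form of row i's problem (up to the constant ||x_i||^2 / 2)
  qval <- function(f, i) 0.5 * sum(f * (g %*% f)) - sum(h[i, ] * f)
  for (i in seq_len(nrow(x))) {
    f <- if (method == "active-set") {
      pracma::lsqnonneg(kl, x[i, ])$x
    } else {
      nnls_bpp_one(g, h[i, ]) %||%
        pracma::lsqnonneg(kl, x[i, ])$x  # cycling cap hit: Lawson-Hanson
    }
    if (!is.null(f_init)) {
      f0 <- f_init[i, live]
      if (qval(f, i) > qval(f0, i)) f <- f0
    }
    out[i, live] <- f
  }
  out
}

# Block principal pivoting for min_{f>=0} f'Gf/2 - h'f (normal-equation
# form of NNLS). Kim & Park style safeguard: full exchanges while the
# infeasible count keeps dropping, then single lowest-index exchanges.
nnls_bpp_one <- function(g, h, tol = 1e-12) {
  r <- length(h)
  passive <- rep(FALSE, r)
  f <- numeric(r)
  y <- -h                       # dual residual y = G f - h
  max_backup <- 3L
  alpha <- max_backup
  beta <- r + 1L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 20L * r + 100L) return(NULL)
    infeas <- (passive & (f < -tol)) | (!passive & (y < -tol))
    n_inf <- sum(infeas)
    if (n_inf == 0L) break
    if (n_inf < beta) {         # progress: allow full exchanges again
      beta <- n_inf
      alpha <- max_backup
      flip <- infeas
    } else if (alpha >= 1L) {   # tolerate a bounded number of non-improving
      alpha <- alpha - 1L       # full exchanges
      flip <- infeas
    } else {                    # cycling guard: single exchange, lowest index
      flip <- rep(FALSE, r)
      flip[which(infeas)[1L]] <- TRUE
    }
    passive <- xor(passive, flip)
    f <- numeric(r)
    if (any(passive)) {
      gp <- g[passive, passive, drop = FALSE]
      sol <- tryCatch(solve(gp, h[passive]),
                      error = function(e) {
                        as.vector(pinv_tol(gp) %*% h[passive])
                      })
      f[passive] <- sol
    }
    y <- as.vector(g %*% f) - h
    y[passive] <- 0
  }
  f[f < 0] <- 0                 # clip tolerance-level negatives
  f
}
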