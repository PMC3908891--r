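#' Unfold (matricize) a three-way tensor along one mode
#'
#' Rearranges a three-way array into a matrix whose rows index the chosen
#' mode and whose columns linearize the remaining two modes in increasing
#' mode order (the layout standard in the tensor-decomposition literature).
#' For a tensor of shape `I x J x K`:
#' * mode 1 gives an `I x (J*K)` matrix, column index `j + J*k` (0-based);
#' * mode 2 gives a `J x (I*K)` matrix, column index `i + I*k`;
#' * mode 3 gives a `K x (I*J)` matrix, column index `i + I*j`.
#'
#' Under this layout the CP identity `unfold(X, 1) = A (C kr B)^T` holds,
#' with `kr` the Khatri-Rao product (see [khatri_rao()]).
#'
#' @param x A numeric three-way array.
#' @param mode Integer 1, 2 or 3.
#' @return A numeric matrix containing every tensor entry exactly once.
#' @seealso [fold()], [khatri_rao()], [cp_reconstruct()]
#' @export
#' @examples
#' x <- array(1:8, dim = c(2, 2, 2))
#' unfold(x, 1)
unfold <- function(x, mode) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  mode <- check_mode(mode)
  d <- dim(x)
  switch(mode,
    matrix(x, nrow = d[1L]),
    matrix(aperm(x, c(2L, 1L, 3L)), nrow = d[2L]),
    matrix(aperm(x, c(3L, 1L, 2L)), nrow = d[3L])
  )
}

#' Fold a matricized tensor back into a three-way array
#'
#' Inverse of [unfold()]: `fold(unfold(x, m), m, dim(x))` recovers `x` for
#' every mode.
#'
#' @param m A matrix produced by (or conformable with) [unfold()].
#' @param mode Integer 1, 2 or 3: the mode `m` was unfolded along.
#' @param dims Length-3 integer vector, the shape of the target tensor.
#' @return A numeric array with dimensions `dims`.
#' @export
fold <- function(m, mode, dims) {
  stopifnot(is.matrix(m), length(dims) == 3L)
  mode <- check_mode(mode)
  dims <- as.integer(dims)
  if (nrow(m) != dims[mode] || length(m) != prod(dims)) {
    stop("matrix shape ", nrow(m), "x", ncol(m),
         " is not a mode-", mode, " unfolding of a ",
         paste(dims, collapse = "x"), " tensor", call. = FALSE)
  }
  switch(mode,
    array(m, dim = dims),
    aperm(array(m, dim = dims[c(2L, 1L, 3L)]), c(2L, 1L, 3L)),
    aperm(array(m, dim = dims[c(3L, 1L, 2L)]), c(2L, 3L, 1L))
  )
}

check_mode <- function(mode) {
  if (!is.numeric(mode) || length(mode) != 1L || !(mode %in% 1:3)) {
    stop("`mode` must be 1, 2 or 3", call. = FALSE)
  }
  as.integer(mode)
}

#' Khatri-Rao (column-wise Kronecker) product
#'
#' For `A` (`I x R`) and `B` (`J x R`), returns the `IJ x R` matrix whose
#' column `r` is the Kronecker product of column `r` of `A` with column `r`
#' of `B` (the `B` index varies fastest, consistent with [unfold()]).
#'
#' @param a,b Numeric matrices with equal column counts.
#' @return A numeric matrix of dimension `nrow(a)*nrow(b) x ncol(a)`.
#' @export
#' @examples
#' khatri_rao(diag(2), matrix(1:4, 2))
khatri_rao <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b))
  if (ncol(a) != ncol(b)) {
    stop("Khatri-Rao product needs equal column counts (got ",
         ncol(a), " and ", ncol(b), ")", call. = FALSE)
  }
  # col r = kron(a[, r], b[, r]); vectorized over columns
  out <- matrix(0, nrow(a) * nrow(b), ncol(a))
  for (r in seq_len(ncol(a))) {
    out[, r] <- tcrossprod(b[, r], a[, r])  # b fastest
  }
  out
}

#' Reconstruct a tensor from CP (Kruskal) factors
#'
#' Computes the rank-`R` tensor `sum_r a_r o b_r o c_r` (`o` the outer
#' product): entry `(i, j, k)` equals `sum_r A[i,r] B[j,r] C[k,r]`.
#' Internally uses the unfolded form `A (C kr B)^T` folded back.
#'
#' @param a,b,c Numeric factor matrices with a common column count `R`;
#'   `a` is `I x R`, `b` is `J x R`, `c` is `K x R`.
#' @return A numeric `I x J x K` array.
#' @export
cp_reconstruct <- function(a, b, c) {
  stopifnot(is.matrix(a), is.matrix(b), is.matrix(c))
  if (length(unique(c(ncol(a), ncol(b), ncol(c)))) != 1L) {
    stop("CP factors must share a column count", call. = FALSE)
  }
  fold(a %*% t(khatri_rao(c, b)), 1L, c(nrow(a), nrow(b), nrow(c)))
}

#' Frobenius norm of a tensor or matrix
#'
#' @param x A numeric array or matrix.
#' @return The square root of the sum of squared entries.
#' @export
frobenius <- function(x) sqrt(sum(x^2))

#' Relative fit of an approximation to a tensor
#'
#' `1 - ||x - xhat||_F / ||x||_F`: 1 for a perfect reconstruction, 0 for
#' the zero approximation, negative when the approximation is worse than
#' reporting all zeros.
#'
#' @param x Reference tensor (non-zero).
#' @param xhat Approximation, same shape.
#' @return A scalar.
#' @export
relative_fit <- function(x, xhat) {
  nx <- frobenius(x)
  if (nx == 0) stop("relative fit is undefined for a zero reference tensor",
                    call. = FALSE)
  stopifnot(identical(dim(x), dim(xhat)))
  1 - frobenius(x - xhat) / nx
}

#' Moore-Penrose pseudoinverse with a tolerance rank cutoff
#'
#' SVD-based pseudoinverse; singular values below
#' `max(dim(m)) * .Machine$double.eps * max(sv)` are treated as zero.
#' The returned matrix carries an attribute `rank` with the numerical rank.
#'
#' @param m A numeric matrix.
#' @return The pseudoinverse of `m` (`ncol(m) x nrow(m)`).
#' @keywords internal
pinv_tol <- function(m) {
  s <- svd(m)
  tol <- max(dim(m)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  r <- sum(keep)
  out <- if (r == 0L) {
    matrix(0, ncol(m), nrow(m))
  } else {
    s$v[, keep, drop = FALSE] %*%
      (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  }
  attr(out, "rank") <- r
  out
}

#' Multiply a tensor by a matrix along one mode
#'
#' @param x A three-way array.
#' @param m A matrix with `ncol(m) == dim(x)[mode]`.
#' @param mode Mode along which to multiply.
#' @return The mode product, a three-way array.
#' @keywords internal
mode_multiply <- function(x, m, mode) {
  mode <- check_mode(mode)
  dims <- dim(x)
  dims[mode] <- nrow(m)
  fold(m %*% unfold(x, mode), mode, dims)
}

#' Least-squares Tucker core for fixed factor matrices
#'
#' With the CP factors `A`, `B`, `C` held fixed, finds the `R x R x R` core
#' `G` minimizing `||x - G x1 A x2 B x3 C||_F` (the `xn` are mode
#' products). Computed as `x x1 pinv(A) x2 pinv(B) x3 pinv(C)` with
#' SVD-based tolerance-rank pseudoinverses, which yields the minimum-norm
#' least-squares core even for rank-deficient factors. For a perfectly
#' fitted CP model with full-column-rank factors the core is the unit
#' superdiagonal cube — the fact the core-consistency diagnostic rests on.
#'
#' @param x A three-way array (`I x J x K`).
#' @param a,b,c Factor matrices (`I x R`, `J x R`, `K x R`).
#' @return An `R x R x R` array with attribute `rank_deficient` (logical:
#'   TRUE when any factor had numerical column rank below `R`).
#' @seealso [core_consistency()]
#' @export
tucker_core_fit <- function(x, a, b, c) {
  stopifnot(length(dim(x)) == 3L)
  r <- ncol(a)
  if (ncol(b) != r || ncol(c) != r) {
    stop("factors must share a column count", call. = FALSE)
  }
  d <- dim(x)
  if (nrow(a) != d[1L] || nrow(b) != d[2L] || nrow(c) != d[3L]) {
    stop("factor row counts must match the tensor shape", call. = FALSE)
  }
  if (r > max(d)) {
    warning("component count R = ", r,
            " exceeds every tensor mode; core fit is rank deficient",
            call. = FALSE)
  }
  pa <- pinv_tol(a); pb <- pinv_tol(b); pc <- pinv_tol(c)
  deficient <- min(attr(pa, "rank"), attr(pb, "rank"), attr(pc, "rank")) < r
  g <- mode_multiply(mode_multiply(mode_multiply(x, pa, 1L), pb, 2L), pc, 3L)
  attr(g, "rank_deficient") <- deficient
  g
}

#' Unit superdiagonal cube
#'
#' The `r x r x r` tensor with ones on the superdiagonal and zeros
#' elsewhere — the Tucker core of an exact CP decomposition.
#'
#' @param r Side length.
#' @return An `r x r x r` array.
#' @export
superdiagonal <- function(r) {
  g <- array(0, dim = c(r, r, r))
  g[cbind(seq_len(r), seq_len(r), seq_len(r))] <- 1
  g
}
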