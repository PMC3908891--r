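#' Core consistency (CORCONDIA) of a CP model
#'
#' Fits the least-squares Tucker core `G` for the model's factors held
#' fixed ([tucker_core_fit()]) and compares it with the unit
#' superdiagonal cube `I` that an exact CP decomposition would produce:
#'
#' `CC = 100 * (1 - sum((G - I)^2) / R)`
#'
#' The value is 100 exactly when `G = I`; it degrades — and can go
#' negative — when the `R`-component CP structure stops describing the
#' tensor (overfitting, redundant components). Negative values are
#' reported as-is, matching the diagnostic's standard definition.
#'
#' @param x The tensor the model was fitted to (three-way array or
#'   `snapshot_tensor`).
#' @param model A `cp_model`.
#' @return A scalar `<= 100`, with attribute `rank_deficient` (logical)
#'   when the core had to be fitted through rank-deficient factors.
#' @export
core_consistency <- function(x, model) {
  v <- tensor_values(x)
  stopifnot(inherits(model, "cp_model"))
  g <- tucker_core_fit(v, model$A, model$B, model$C)
  r <- model$R
  cc <- 100 * (1 - sum((g - superdiagonal(r))^2) / r)
  attr(cc, "rank_deficient") <- attr(g, "rank_deficient")
  cc
}

#' Component relevance
#'
#' The relevance of component `k` is the product of the L2 norms of its
#' three factor columns, `r_k = ||a_k|| * ||b_k|| * ||c_k||`, computed on
#' the raw (unnormalized) factors. It ranks components by the weight they
#' contribute to the decomposition and is invariant under the CP scaling
#' indeterminacy.
#'
#' @param model A `cp_model`.
#' @return A numeric vector of length `R`, all entries `>= 0`.
#' @export
component_relevance <- function(model) {
  stopifnot(inherits(model, "cp_model"))
  sqrt(colSums(model$A^2)) * sqrt(colSums(model$B^2)) *
    sqrt(colSums(model$C^2))
}

#' Score of a whole decomposition
#'
#' Aggregates the per-component relevances into one number, by sum
#' (default) or product.
#'
#' @param model A `cp_model`.
#' @param score_mode `"sum"` or `"product"`.
#' @return A scalar.
#' @export
decomposition_score <- function(model, score_mode = c("sum", "product")) {
  score_mode <- match.arg(score_mode)
  r <- component_relevance(model)
  if (score_mode == "sum") sum(r) else prod(r)
}

#' Diagnose a list of factorization runs
#'
#' Computes, for every run, the core consistency, the per-run
#' decomposition score, the relative fit and convergence metadata.
#'
#' @param x The tensor the runs were fitted to.
#' @param runs A list of `cp_model` objects (from [factorize()]).
#' @param score_mode Passed to [decomposition_score()].
#' @return A tibble with one row per run: `run`, `seed`, `r`,
#'   `core_consistency`, `score`, `fit`, `n_iter`, `converged`,
#'   `rank_deficient`.
#' @export
diagnose_runs <- function(x, runs, score_mode = c("sum", "product")) {
  score_mode <- match.arg(score_mode)
  stopifnot(length(runs) >= 1L)
  purrr::imap_dfr(runs, function(model, run) {
    cc <- core_consistency(x, model)
    tibble::tibble(
      run = run,
      seed = model$seed,
      r = model$R,
      core_consistency = as.numeric(cc),
      score = decomposition_score(model, score_mode),
      fit = model$fit,
      n_iter = model$n_iter,
      converged = model$converged,
      rank_deficient = isTRUE(attr(cc, "rank_deficient"))
    )
  })
}

#' Rank multi-start runs by core consistency, then by score
#'
#' The two-stage selection protocol: sort runs by core consistency
#' (descending), keep the top `keep_cc`; re-rank those by decomposition
#' score (descending), keep the top `keep_score`. Ties are broken
#' deterministically by run seed (ascending).
#'
#' @param diagnostics A tibble from [diagnose_runs()] (or any table with
#'   columns `run`, `seed`, `core_consistency`, `score`).
#' @param keep_cc Runs kept after the core-consistency stage
#'   (default 10).
#' @param keep_score Runs kept after the score stage (default 5).
#' @return The selected rows, ranked best-first, with a `rank` column.
#'   The best run overall is row 1.
#' @export
select_best <- function(diagnostics, keep_cc = 10L, keep_score = 5L) {
  stopifnot(nrow(diagnostics) >= 1L)
  stage1 <- dplyr::slice_head(
    dplyr::arrange(diagnostics, dplyr::desc(.data$core_consistency),
                   .data$seed),
    n = keep_cc
  )
  stage2 <- dplyr::slice_head(
    dplyr::arrange(stage1, dplyr::desc(.data$score), .data$seed),
    n = keep_score
  )
  dplyr::mutate(stage2, rank = dplyr::row_number())
}

#' Core-consistency sweep over a range of component counts
#'
#' For each `R` in `ranks`, runs the full multi-start factorization and
#' the two-stage selection, and tabulates the surviving runs' core
#' consistencies. Plotting core consistency against `R` typically shows a
#' crossover from high values at low `R` to degraded values once the
#' model overfits; the crossover locates the useful range of `R`. No
#' automatic choice of `R` is made — the diagnostic informs the user.
#'
#' @param x A non-negative three-way array or `snapshot_tensor`.
#' @param ranks Increasing integer vector of component counts to try.
#' @param n_runs,max_iter,tol,seed,nnls_method Per-`R` solver settings
#'   (see [solver_config()]); the master `seed` derives one sub-seed per
#'   `R`, so the whole sweep is reproducible.
#' @param keep_cc,keep_score Selection protocol (see [select_best()]).
#' @param score_mode Passed to [diagnose_runs()].
#' @return A `sweep_report`: tibble with one row per surviving run and
#'   columns `r`, `run`, `seed`, `core_consistency`, `score`, `fit`,
#'   `stage` (`"cc"` rows survived the core-consistency stage,
#'   `"score"` rows also survived the score stage), plus attribute
#'   `models` (the selected best `cp_model` per `R`, a named list).
#' @export
consistency_sweep <- function(x, ranks, n_runs = 20L, max_iter = 500L,
                              tol = 1e-7, seed = 1L, keep_cc = 10L,
                              keep_score = 5L,
                              score_mode = c("sum", "product"),
                              nnls_method = "block-pivot") {
  score_mode <- match.arg(score_mode)
  stopifnot(length(ranks) >= 1L, !is.unsorted(ranks, strictly = TRUE))
  best_models <- list()
  rows <- purrr::map_dfr(seq_along(ranks), function(ri) {
    r <- ranks[ri]
    cfg <- solver_config(r = r, n_runs = n_runs, max_iter = max_iter,
                         tol = tol, seed = run_seed(seed, ri),
                         nnls_method = nnls_method)
    runs <- factorize(x, cfg)
    diag <- diagnose_runs(x, runs, score_mode)
    stage1 <- select_best(diag, keep_cc = keep_cc, keep_score = nrow(diag))
    stage2 <- select_best(diag, keep_cc = keep_cc, keep_score = keep_score)
    best_models[[as.character(r)]] <<- runs[[stage2$run[1L]]]
    dplyr::mutate(
      dplyr::select(stage1, -"rank"),
      r = r,
      stage = ifelse(.data$run %in% stage2$run, "score", "cc"),
      .before = 1L
    )
  })
  structure(rows, class = c("sweep_report", class(rows)),
            models = best_models)
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("<sweep_report> component counts:",
      paste(sort(unique(x$r)), collapse = ", "), "\n")
  NextMethod()
}

#' Write a sweep report to TSV and JSON
#'
#' @param report A `sweep_report`.
#' @param stem Path stem; writes `<stem>.tsv` and `<stem>.json`.
#' @export
write_sweep_report <- function(report, stem) {
  df <- as.data.frame(report)[, c("r", "run", "seed", "core_consistency",
                                  "score", "stage")]
  utils::write.table(df, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(df, paste0(stem, ".json"), digits = NA)
  invisible(paste0(stem, c(".tsv", ".json")))
}

#' Plot a core-consistency sweep
#'
#' Core consistency against the number of components, one point per
#' surviving run, with the conventional acceptability reference line at
#' 90 (configurable). The crossover where values fall away marks the
#' onset of overfitting.
#'
#' @param object A `sweep_report`.
#' @param reference Reference line level (default 90); `NULL` to omit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_report <- function(object, reference = 90, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$r, y = .data$core_consistency,
                                    shape = .data$stage)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_continuous(breaks = sort(unique(object$r))) +
    ggplot2::labs(x = "number of components (R)",
                  y = "core consistency", shape = "selection stage") +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_hline(yintercept = reference, linetype = "dashed")
  }
  p
}
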