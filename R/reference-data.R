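#' Published class-recovery reference tables
#'
#' Two small reference tables bundled with the package, summarizing the
#' class-structure recovery reported for the SocioPatterns primary-school
#' contact network (the standard empirical benchmark for this method):
#'
#' * `reference_recovery_table()` — one row per component count `R`
#'   (2–20): core consistency of the selected decomposition, number of
#'   matched classes, total students in those classes (`class_nodes`),
#'   students recovered inside the matching components
#'   (`covered_nodes`), and the printed `recall`.
#' * `reference_components_table()` — the per-component breakdown at the
#'   13-component decomposition: binarized component size, matched class,
#'   class size (students only), teachers found, and missing students.
#'
#' These support arithmetic consistency checks (`recall =
#' covered_nodes / class_nodes`; `component_size = class_size +
#' teacher_found - missing_nodes`). Note the rows for 6 and 7 components
#' print a recall inconsistent with their own counts (91/94); treat those
#' two rows as printed values only.
#'
#' @return A tibble.
#' @export
reference_recovery_table <- function() {
  path <- system.file("extdata", "school_recovery_by_rank.tsv",
                      package = "tempocomm", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname reference_recovery_table
#' @export
reference_components_table <- function() {
  path <- system.file("extdata", "school_components_r13.tsv",
                      package = "tempocomm", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
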