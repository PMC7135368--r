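#' Construct and validate a virtual-screen score table
#'
#' A screen table holds the per-compound records of one retrospective docking
#' screen: known ligands and property-matched decoys docked against a single
#' binding-site model, ranked by predicted binding energy (lower = better).
#'
#' @param compound_id Character vector of compound identifiers, unique within
#'   each model's screen.
#' @param is_ligand Logical; `TRUE` for known ligands, `FALSE` for decoys.
#' @param score Numeric docking score (predicted binding energy, kcal/mol by
#'   convention; lower is better). Must be finite for docked compounds; may be
#'   `NA` for compounds that failed to dock.
#' @param model_id Character model identifier (recycled if length 1).
#' @param docked Logical; whether the compound docked successfully. Defaults
#'   to `!is.na(score)`.
#'
#' @return A tibble with columns `compound_id`, `is_ligand`, `model_id`,
#'   `score`, `docked`.
#' @examples
#' screen_table(c("L1", "D1"), c(TRUE, FALSE), c(-10, -5))
#' @export
screen_table <- function(compound_id, is_ligand, score,
                         model_id = "model", docked = !is.na(score)) {
  tbl <- tibble::tibble(
    compound_id = as.character(compound_id),
    is_ligand = as.logical(is_ligand),
    model_id = as.character(model_id),
    score = as.numeric(score),
    docked = as.logical(docked)
  )
  validate_screen_table(tbl)
}

#' Validate a screen table
#'
#' Checks the invariants every enrichment computation relies on: at least one
#' ligand and one decoy, unique compound ids within each model, and finite
#' scores for all docked compounds.
#'
#' @param tbl A data frame with columns `compound_id`, `is_ligand`, `score`
#'   and optionally `model_id`, `docked`.
#' @return The validated table as a tibble (invisibly usable in pipes).
#' @export
validate_screen_table <- function(tbl) {
  required <- c("compound_id", "is_ligand", "score")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("screen table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tbl <- tibble::as_tibble(tbl)
  if (!"model_id" %in% names(tbl)) tbl$model_id <- "model"
  if (!"docked" %in% names(tbl)) tbl$docked <- !is.na(tbl$score)
  if (any(is.na(tbl$is_ligand))) {
    stop("is_ligand must be TRUE/FALSE with no missing values", call. = FALSE)
  }
  per_model <- dplyr::count(tbl, .data$model_id, .data$is_ligand)
  counts <- tidyr::pivot_wider(per_model, names_from = "is_ligand",
                               values_from = "n", values_fill = 0L)
  if (!"TRUE" %in% names(counts) || any(counts[["TRUE"]] == 0L)) {
    stop("invalid screen table: every screen needs at least one ligand",
         call. = FALSE)
  }
  if (!"FALSE" %in% names(counts) || any(counts[["FALSE"]] == 0L)) {
    stop("invalid screen table: every screen needs at least one decoy",
         call. = FALSE)
  }
  dup <- tbl |>
    dplyr::count(.data$model_id, .data$compound_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    stop("duplicated compound_id within a screen: ",
         paste(utils::head(dup$compound_id, 5), collapse = ", "),
         call. = FALSE)
  }
  bad <- tbl$docked & !is.finite(tbl$score)
  if (any(bad)) {
    stop("non-finite score on docked record(s): ",
         paste(utils::head(tbl$compound_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  tbl
}

#' Read / write screen tables as delimited text
#'
#' Screen tables are exchanged as CSV (or TSV) with header columns
#' `compound_id`, `is_ligand`, `model_id`, `score`, `docked`.
#'
#' @param path File path.
#' @param delim Field delimiter, `","` by default.
#' @return `read_screen_table()` returns a validated screen-table tibble.
#' @export
read_screen_table <- function(path, delim = ",") {
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_screen_table(tbl)
}

#' @rdname read_screen_table
#' @param tbl A screen table.
#' @return `write_screen_table()` returns `path` invisibly.
#' @export
write_screen_table <- function(tbl, path, delim = ",") {
  tbl <- validate_screen_table(tbl)
  readr::write_delim(tbl, path, delim = delim, progress = FALSE)
  invisible(path)
}
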