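#' Merge screens of the same library by best score
#'
#' Ensemble docking evaluation assigns each compound its most favorable
#' (lowest) docking energy over a set of binding-site models, yielding a
#' single merged screen and hence a single aLogAUC for the whole ensemble.
#' A compound counts as docked if it docked in any member; compounds that
#' failed to dock everywhere stay undocked in the merged table.
#'
#' @param screens A list of screen tables sharing one compound universe, or a
#'   single table holding several screens distinguished by `model_id`.
#' @param model_id Model id given to the merged screen.
#' @return A screen table with one record per compound.
#' @examples
#' ens <- gen_ensemble(n_models = 3, n_ligands = 10, n_decoys = 50, seed = 1)
#' merge_best_score(ens)
#' @export
merge_best_score <- function(screens, model_id = "ensemble") {
  tbl <- bind_screens(screens)
  universes <- tbl |>
    dplyr::group_by(.data$model_id) |>
    dplyr::summarise(ids = list(sort(.data$compound_id)), .groups = "drop")
  ref <- universes$ids[[1]]
  same <- vapply(universes$ids, identical, logical(1), y = ref)
  if (!all(same)) {
    offenders <- purrr::map(universes$ids[!same], ~ c(setdiff(.x, ref), setdiff(ref, .x)))
    stop("screens do not share one compound universe; mismatched ids: ",
         paste(utils::head(unique(unlist(offenders)), 10), collapse = ", "),
         call. = FALSE)
  }
  merged <- tbl |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(
      is_ligand = .data$is_ligand[1],
      score = if (any(.data$docked)) min(.data$score[.data$docked]) else NA_real_,
      docked = any(.data$docked),
      .groups = "drop"
    ) |>
    dplyr::mutate(model_id = model_id) |>
    dplyr::select("compound_id", "is_ligand", "model_id", "score", "docked")
  validate_screen_table(merged)
}

bind_screens <- function(screens) {
  if (is.data.frame(screens)) screens <- list(screens)
  if (length(screens) < 1) stop("need at least one screen", call. = FALSE)
  screens <- purrr::imap(screens, function(s, i) {
    s <- validate_screen_table(s)
    # disambiguate duplicated model ids coming from separate list elements
    s$model_id <- paste0(s$model_id, "#", i)
    s
  })
  dplyr::bind_rows(screens)
}

#' Ensemble enrichment over multiple binding-site models
#'
#' Equivalent to [screen_enrichment()] of [merge_best_score()]: the aLogAUC
#' of the screen in which every compound keeps its best docking score over
#' the member models.
#'
#' @inheritParams merge_best_score
#' @inheritParams log_auc
#' @return A one-row tibble as returned by [screen_enrichment()], with
#'   `n_members` prepended.
#' @export
ensemble_enrichment <- function(screens, lambda = 0.001) {
  n_members <- if (is.data.frame(screens)) {
    dplyr::n_distinct(screens$model_id)
  } else {
    length(screens)
  }
  merged <- merge_best_score(screens)
  res <- screen_enrichment(merged, lambda = lambda)
  dplyr::bind_cols(tibble::tibble(n_members = n_members), res)
}

#' Enrichment of a chemotype subset of the ligands
#'
#' Recomputes enrichment counting only the named subset of ligands (e.g. the
#' eticlopride-like or doxepin-like chemotype) as actives. All decoys are
#' retained; ligands outside the subset are removed from both numerator and
#' denominator rather than recast as decoys, since they are known actives and
#' would contaminate the negative set.
#'
#' @param tbl A screen table for a single model.
#' @param ligand_ids Character vector of compound ids defining the chemotype
#'   subset; must intersect the screen's ligands.
#' @param name Label for the subset in the output.
#' @inheritParams log_auc
#' @return A one-row tibble: `set_name`, `n_subset`, plus the
#'   [screen_enrichment()] columns.
#' @export
subset_enrichment <- function(tbl, ligand_ids, name = "subset", lambda = 0.001) {
  tbl <- validate_screen_table(tbl)
  ligand_ids <- as.character(ligand_ids)
  in_subset <- tbl$is_ligand & tbl$compound_id %in% ligand_ids
  if (!any(in_subset)) {
    stop("invalid subset: no ligand of the screen belongs to `ligand_ids`",
         call. = FALSE)
  }
  sub <- tbl[!tbl$is_ligand | in_subset, , drop = FALSE]
  res <- screen_enrichment(sub, lambda = lambda)
  dplyr::bind_cols(
    tibble::tibble(set_name = name, n_subset = sum(in_subset)),
    res
  )
}

#' Boxplot of per-template enrichment with ensemble overlay
#'
#' Mirrors the standard way template quality is visualized: one box per
#' template over its models' aLogAUC values, with the ensemble enrichment of
#' each template overlaid as a filled point.
#'
#' @param model_results Tibble with columns `template_id` and `alogauc`, one
#'   row per model.
#' @param ensemble_results Optional tibble with `template_id` and `alogauc`
#'   for ensembles.
#' @return A ggplot.
#' @export
plot_enrichment_distribution <- function(model_results, ensemble_results = NULL) {
  p <- ggplot2::ggplot(model_results,
                       ggplot2::aes(x = .data$template_id, y = .data$alogauc)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "Template", y = "aLogAUC") +
    ggplot2::theme_classic()
  if (!is.null(ensemble_results)) {
    p <- p + ggplot2::geom_point(data = ensemble_results, colour = "red",
                                 size = 2.5)
  }
  p
}
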