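#' Build a ROC curve from a screen table
#'
#' Compounds are retrieved in order of ascending docking score (lower
#' predicted binding energy = earlier retrieval). Compounds sharing a score
#' form a single tied block that advances the decoy fraction (FPR) and ligand
#' fraction (TPR) simultaneously, which makes the curve independent of record
#' order. Compounds that failed to dock are appended as one final tied block,
#' so docking failures of ligands are penalized rather than silently dropped.
#'
#' @param tbl A screen table (see [screen_table()]) for a single model.
#' @return A tibble of class `roc_curve` with columns `fpr` (fraction of
#'   decoys retrieved) and `tpr` (fraction of ligands retrieved), starting at
#'   (0, 0) and ending at (1, 1). Ligand/decoy counts are kept as attributes.
#' @examples
#' roc_curve(screen_table(c("L", "D"), c(TRUE, FALSE), c(-10, -5)))
#' @export
roc_curve <- function(tbl) {
  tbl <- validate_screen_table(tbl)
  if (dplyr::n_distinct(tbl$model_id) > 1L) {
    stop("roc_curve() expects a single screen; got multiple model_id values",
         call. = FALSE)
  }
  n_lig <- sum(tbl$is_ligand)
  n_dec <- sum(!tbl$is_ligand)

  docked <- tbl[tbl$docked, , drop = FALSE]
  blocks <- docked |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(lig = sum(.data$is_ligand),
                     dec = sum(!.data$is_ligand), .groups = "drop") |>
    dplyr::arrange(.data$score)

  lig_steps <- blocks$lig
  dec_steps <- blocks$dec
  n_undocked <- sum(!tbl$docked)
  if (n_undocked > 0) {
    lig_steps <- c(lig_steps, sum(tbl$is_ligand & !tbl$docked))
    dec_steps <- c(dec_steps, sum(!tbl$is_ligand & !tbl$docked))
  }

  curve <- tibble::tibble(
    fpr = c(0, cumsum(dec_steps) / n_dec),
    tpr = c(0, cumsum(lig_steps) / n_lig)
  )
  structure(curve,
            class = c("roc_curve", class(curve)),
            n_ligands = n_lig, n_decoys = n_dec,
            model_id = tbl$model_id[1])
}

check_roc <- function(curve) {
  if (!all(c("fpr", "tpr") %in% names(curve))) {
    stop("a ROC curve needs `fpr` and `tpr` columns", call. = FALSE)
  }
  if (nrow(curve) < 2 ||
      abs(curve$fpr[1]) > 1e-12 || abs(curve$tpr[1]) > 1e-12 ||
      abs(curve$fpr[nrow(curve)] - 1) > 1e-12 ||
      abs(curve$tpr[nrow(curve)] - 1) > 1e-12 ||
      is.unsorted(curve$fpr) || is.unsorted(curve$tpr)) {
    stop("invalid ROC curve: points must run monotonically from (0,0) to (1,1)",
         call. = FALSE)
  }
  curve
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda <= 0 || lambda >= 1) {
    stop("lambda must be a single number in (0, 1)", call. = FALSE)
  }
  lambda
}

#' Semi-log area under the ROC curve (logAUC)
#'
#' The ROC curve is transformed to a log10 decoy-fraction axis and integrated
#' from `lambda` to 1, then normalized by `log10(1/lambda)` and expressed as
#' a percentage, so a perfect screen scores 100. The metric up-weights early
#' enrichment: the first fractions of a ranked database dominate the log axis
#' and they are what matters in a prospective virtual screen.
#'
#' The TPR is linearly interpolated between curve points on the linear FPR
#' axis and each linear piece is integrated against `d log10(x)` in closed
#' form, so the value is exact for the interpolated curve (no quadrature
#' grid). The curve is clamped at `fpr = lambda` on the left.
#'
#' @param curve A `roc_curve` (or any data frame with `fpr`, `tpr` columns
#'   satisfying the ROC invariants).
#' @param lambda Lower bound of the log axis, a fraction in (0, 1).
#'   Default 0.001, the established convention for this metric family.
#' @return logAUC in percent, in \[0, 100\].
#' @seealso [adjusted_log_auc()], [random_log_auc()]
#' @export
log_auc <- function(curve, lambda = 0.001) {
  curve <- check_roc(curve)
  check_lambda(lambda)
  x <- curve$fpr
  y <- curve$tpr

  x0 <- x[-length(x)]; x1 <- x[-1]
  y0 <- y[-length(y)]; y1 <- y[-1]
  # drop segments entirely left of lambda and vertical segments
  keep <- x1 > lambda & x1 > x0
  x0 <- x0[keep]; x1 <- x1[keep]; y0 <- y0[keep]; y1 <- y1[keep]
  # clamp the segment straddling lambda
  clip <- x0 < lambda
  if (any(clip)) {
    b <- (y1[clip] - y0[clip]) / (x1[clip] - x0[clip])
    y0[clip] <- y0[clip] + b * (lambda - x0[clip])
    x0[clip] <- lambda
  }
  # integral of (a + b x) d log10(x) over [x0, x1]
  b <- (y1 - y0) / (x1 - x0)
  a <- y0 - b * x0
  area <- sum(a * log(x1 / x0) + b * (x1 - x0)) / log(10)
  100 * area / log10(1 / lambda)
}

#' logAUC of random selection
#'
#' Closed form of the semi-log AUC of the random diagonal `TPR(x) = x`:
#' `100 * (1 - lambda) / ln(1/lambda)`. This is the zero point that the
#' adjusted logAUC subtracts; at the default `lambda = 0.001` it equals
#' about 14.47.
#'
#' @inheritParams log_auc
#' @return Percent in (0, 100).
#' @export
random_log_auc <- function(lambda = 0.001) {
  check_lambda(lambda)
  100 * (1 - lambda) / log(1 / lambda)
}

#' Adjusted logAUC (aLogAUC)
#'
#' The logAUC of the screen minus the logAUC of random selection, in
#' percentage points. Positive values mean the scoring function retrieves
#' ligands better than random; an aLogAUC of 10 corresponds to retrieving
#' more than twice the ligands expected by chance over the log axis.
#'
#' @inheritParams log_auc
#' @return aLogAUC in percentage points (may be negative).
#' @export
adjusted_log_auc <- function(curve, lambda = 0.001) {
  log_auc(curve, lambda) - random_log_auc(lambda)
}

enrichment_bands <- c("poor", "fair", "good", "very good", "excellent")

#' Qualitative enrichment category for an aLogAUC value
#'
#' Maps aLogAUC values to the qualitative bands used to judge binding-site
#' models: `< 10` poor, `10-15` fair, `>15-20` good, `>20-25` very good and
#' `> 25` excellent. Each band's upper edge is inclusive, and 10 falls in
#' "fair".
#'
#' @param alogauc Numeric vector of aLogAUC values (percentage points).
#' @return An ordered factor with levels poor < fair < good < very good <
#'   excellent.
#' @examples
#' classify_enrichment(c(9, 10, 18.1, 26.6))
#' @export
classify_enrichment <- function(alogauc) {
  if (!is.numeric(alogauc) || any(!is.finite(alogauc))) {
    stop("alogauc must be finite numeric", call. = FALSE)
  }
  out <- dplyr::case_when(
    alogauc < 10 ~ "poor",
    alogauc <= 15 ~ "fair",
    alogauc <= 20 ~ "good",
    alogauc <= 25 ~ "very good",
    TRUE ~ "excellent"
  )
  factor(out, levels = enrichment_bands, ordered = TRUE)
}

#' Enrichment statistics for one or more screens
#'
#' The front door of the enrichment module: takes a score table (possibly
#' holding several screens distinguished by `model_id`), builds each screen's
#' ROC curve, and returns the semi-log enrichment statistics one row per
#' model.
#'
#' @param tbl A screen table; may contain multiple `model_id` values.
#' @inheritParams log_auc
#' @return A tibble with columns `model_id`, `n_ligands`, `n_decoys`,
#'   `logauc`, `alogauc`, `category`, `lambda`.
#' @examples
#' gen_screen(n_ligands = 20, n_decoys = 400, seed = 1) |> screen_enrichment()
#' @export
screen_enrichment <- function(tbl, lambda = 0.001) {
  tbl <- validate_screen_table(tbl)
  check_lambda(lambda)
  tbl |>
    dplyr::group_by(.data$model_id) |>
    dplyr::group_modify(function(d, key) {
      curve <- roc_curve(dplyr::mutate(d, model_id = key$model_id))
      la <- log_auc(curve, lambda)
      aa <- la - random_log_auc(lambda)
      tibble::tibble(
        n_ligands = sum(d$is_ligand),
        n_decoys = sum(!d$is_ligand),
        logauc = la,
        alogauc = aa,
        category = classify_enrichment(aa),
        lambda = lambda
      )
    }) |>
    dplyr::ungroup()
}

#' Plot a semi-log ROC curve
#'
#' @param object A `roc_curve`.
#' @param lambda Lower bound of the log axis used for display and for the
#'   random reference line.
#' @param ... Ignored.
#' @return A ggplot: ligand fraction against decoy fraction on a log10 axis,
#'   with the random-selection diagonal dashed.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_curve <- function(object, lambda = 0.001, ...) {
  check_lambda(lambda)
  df <- tibble::as_tibble(object)
  df$fpr <- pmax(df$fpr, lambda)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_step(direction = "vh", colour = "#2166ac") +
    ggplot2::scale_x_log10(limits = c(lambda, 1)) +
    ggplot2::labs(x = "Fraction of decoys retrieved (log scale)",
                  y = "Fraction of ligands retrieved") +
    ggplot2::theme_classic()
}
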