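#' Order-statistics summary of per-model enrichment for a template
#'
#' The per-template view of model quality: minimum, lower quartile, median,
#' upper quartile and maximum of the aLogAUC values of a template's models
#' (quantiles by linear interpolation between order statistics, matching the
#' usual boxplot semantics). The median measures the template's typical
#' quality; the maximum identifies its best binding-site model.
#'
#' @param values Numeric vector of aLogAUC values (one per model), finite,
#'   length >= 1.
#' @param template_id Label for the output row.
#' @param ensemble_alogauc Optional ensemble enrichment to carry along.
#' @return A one-row tibble: `template_id`, `n_models`, `min`, `q25`,
#'   `median`, `q75`, `max`, `ensemble_alogauc`.
#' @examples
#' summarize_template(c(12, 15, 9, 20), "D3R")
#' @export
summarize_template <- function(values, template_id = "template",
                               ensemble_alogauc = NA_real_) {
  if (length(values) < 1 || !is.numeric(values) || any(!is.finite(values))) {
    stop("values must be a non-empty finite numeric vector", call. = FALSE)
  }
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                       names = FALSE)
  tibble::tibble(
    template_id = template_id,
    n_models = length(values),
    min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5],
    ensemble_alogauc = ensemble_alogauc
  )
}

#' @rdname summarize_template
#' @param data A data frame with one row per model.
#' @param value Column of `data` holding the aLogAUC values (tidy-eval).
#' @param template Column of `data` identifying the template.
#' @return `template_summary()` returns one row per template.
#' @export
template_summary <- function(data, value = "alogauc", template = "template_id") {
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(template))) |>
    dplyr::group_modify(function(d, key) {
      summarize_template(d[[value]])[-1]
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(template_id = dplyr::all_of(template))
}

#' Linear regression with Pearson correlation
#'
#' Ordinary least squares of `y` on `x` with the product-moment correlation
#' coefficient, the statistic used to relate enrichment to sequence identity
#' or structural accuracy. No p-value is attached; the correlation itself is
#' the reported quantity.
#'
#' @param data Data frame.
#' @param x,y Column names (strings) of predictor and response.
#' @return An object of class `screen_lm` wrapping the `lm` fit; see
#'   [glance.screen_lm()] for the one-row summary.
#' @examples
#' d <- data.frame(identity = c(20, 40, 60, 80), alogauc = c(2, 9, 14, 22))
#' glance(regress(d, "identity", "alogauc"))
#' @export
regress <- function(data, x, y) {
  xv <- data[[x]]
  yv <- data[[y]]
  if (is.null(xv) || is.null(yv)) {
    stop("columns not found: ", x, ", ", y, call. = FALSE)
  }
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 2) stop("need at least 2 complete observations", call. = FALSE)
  if (stats::sd(xv) == 0) {
    stop("degenerate input: zero variance in ", x, call. = FALSE)
  }
  fit <- stats::lm(yv ~ xv)
  structure(list(fit = fit, x = x, y = y,
                 pearson_r = stats::cor(xv, yv), n = length(xv),
                 data = tibble::tibble(x = xv, y = yv)),
            class = "screen_lm")
}

#' Tidy / summarize a `screen_lm`
#'
#' Broom-style accessors: `tidy()` returns per-term coefficients, `glance()`
#' the one-row model summary (`slope`, `intercept`, `pearson_r`, `n`).
#'
#' @param x A `screen_lm` from [regress()].
#' @param ... Ignored.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.screen_lm <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", x$x),
    estimate = unname(co[, 1]),
    std_error = unname(co[, 2])
  )
}

#' @rdname tidy.screen_lm
#' @exportS3Method generics::glance
glance.screen_lm <- function(x, ...) {
  co <- stats::coef(x$fit)
  tibble::tibble(
    slope = unname(co[2]),
    intercept = unname(co[1]),
    pearson_r = x$pearson_r,
    n = x$n
  )
}

#' @export
print.screen_lm <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Linear fit %s ~ %s: slope %.4g, intercept %.4g, R = %.3f (n = %d)\n",
              x$y, x$x, g$slope, g$intercept, g$pearson_r, g$n))
  invisible(x)
}

#' @param object A `screen_lm`.
#' @rdname tidy.screen_lm
#' @exportS3Method ggplot2::autoplot
autoplot.screen_lm <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.5) +
    ggplot2::labs(x = object$x, y = object$y,
                  title = sprintf("R = %.2f", object$pearson_r)) +
    ggplot2::theme_classic()
}

#' Assemble benchmark report tables
#'
#' Joins per-template enrichment summaries with structural-accuracy reports
#' into one wide table per template/model, and carries regression summaries
#' as a separate block. Output is deterministic: the same inputs give
#' byte-identical CSVs.
#'
#' @param summaries Tibble from [template_summary()] (requires
#'   `template_id`).
#' @param regressions Optional named list of `screen_lm` objects; omitted
#'   from the report when `NULL` or empty.
#' @param rmsd_reports Optional tibble of [rmsd_report()] rows with a
#'   `template_id` column to join on.
#' @param out_dir Optional directory; when given, each block is written as
#'   `<name>.csv` inside it.
#' @return A named list of tibbles: `templates` (always), `regressions`
#'   (when supplied).
#' @export
build_report <- function(summaries, regressions = NULL, rmsd_reports = NULL,
                         out_dir = NULL) {
  stopifnot("template_id" %in% names(summaries))
  templates <- tibble::as_tibble(summaries)
  if (!is.null(rmsd_reports)) {
    if (!"template_id" %in% names(rmsd_reports)) {
      stop("rmsd_reports needs a template_id column to join on", call. = FALSE)
    }
    only_rmsd <- setdiff(rmsd_reports$template_id, templates$template_id)
    if (length(only_rmsd) > 0) {
      stop("join error: rmsd_reports has template_id values absent from the ",
           "summaries: ", paste(only_rmsd, collapse = ", "), call. = FALSE)
    }
    templates <- dplyr::left_join(templates, rmsd_reports, by = "template_id")
  }
  report <- list(templates = dplyr::arrange(templates, .data$template_id))
  if (!is.null(regressions) && length(regressions) > 0) {
    report$regressions <- purrr::imap_dfr(regressions, function(r, nm) {
      dplyr::bind_cols(tibble::tibble(name = nm), glance(r))
    })
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    purrr::iwalk(report, function(tbl, nm) {
      readr::write_csv(tbl, file.path(out_dir, paste0(nm, ".csv")),
                       progress = FALSE)
    })
  }
  report
}
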