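#' Tidy a matching result
#'
#' @param x A `match_result`.
#' @param ... Unused.
#' @return Tibble with one row per class: tp, fp, fn and the derived
#'   precision/recall/F1.
#' @export
tidy.match_result <- function(x, ...) precision_recall(x)

#' @rdname tidy.match_result
#' @export
glance.match_result <- function(x, ...) {
  pc <- precision_recall(x)
  support <- pc$tp + pc$fn
  tibble(tp = sum(pc$tp), fp = sum(pc$fp), fn = sum(pc$fn),
         precision = weighted_average(pc$precision, support),
         recall = weighted_average(pc$recall, support),
         f1 = weighted_average(pc$f1, support))
}

#' Tidy a score report
#'
#' @param x A `score_report`.
#' @param ... Unused.
#' @return `tidy()`: the per-class metric tibble. `glance()`: a one-row
#'   tibble with the weighted averages and clinical scores.
#' @export
tidy.score_report <- function(x, ...) x$per_class

#' @rdname tidy.score_report
#' @export
glance.score_report <- function(x, ...) {
  tibble(precision = x$weighted$precision, recall = x$weighted$recall,
         f1 = x$weighted$f1, ki67_index = x$ki67_index,
         til_score = x$til_score,
         ki67_category = as.character(x$ki67_category),
         til_category = as.character(x$til_category))
}

#' Tidy an evaluation report
#'
#' @param x A `cell_eval_report`.
#' @param ... Unused.
#' @return `tidy()`: per-class detection metrics. `glance()`: one row with
#'   the weighted averages, per-image RMSEs and cut-off accuracies.
#' @export
tidy.cell_eval_report <- function(x, ...) x$per_class

#' @rdname tidy.cell_eval_report
#' @export
glance.cell_eval_report <- function(x, ...) {
  tibble(n_images = nrow(x$images),
         precision = x$weighted$precision, recall = x$weighted$recall,
         f1 = x$weighted$f1,
         rmse_ki67 = x$rmse_image$ki67, rmse_til = x$rmse_image$til,
         cutoff_acc_ki67 = if (is.null(x$cutoff_accuracy)) NA_real_
                           else x$cutoff_accuracy$ki67,
         cutoff_acc_til = if (is.null(x$cutoff_accuracy)) NA_real_
                          else x$cutoff_accuracy$til)
}
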