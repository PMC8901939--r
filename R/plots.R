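#' Box plot of one feature across groups
#'
#' The pre/post-harmonization box-plot panel: one box per batch (or
#' acquisition-parameter level) for a single feature.
#'
#' @param table Feature table containing the grouping column.
#' @param feature Feature column name.
#' @param grouping Grouping column name (e.g. `"batch_id"` after
#'   [with_batches()]).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_feature_boxplot <- function(table, feature, grouping, title = NULL) {
  dat <- export_boxplot_data(table, feature, grouping)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$group), y = .data$value)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6,
                          outlier.size = 0.8) +
    ggplot2::labs(x = grouping, y = feature,
                  title = title %||% paste(feature, "by", grouping)) +
    ggplot2::theme_minimal()
}

#' Plot an assessment
#'
#' Bar chart of per-feature Kruskal-Wallis p-values (log10 scale) with the
#' significance threshold marked.
#'
#' @param object A `radh_assessment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radh_assessment <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$feature <- factor(dat$feature, levels = dat$feature[order(dat$p_value)])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$feature, y = .data$p_value,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "alpha"),
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = NULL, y = "Kruskal-Wallis p-value",
                  title = paste0("Batch dependence by ",
                                 attr(object, "grouping"),
                                 if (nzchar(attr(object, "stage")))
                                   paste0(" (", attr(object, "stage"), ")"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pre/post comparison
#'
#' Side-by-side significant-feature counts per grouping variable.
#'
#' @param object Result of [compare_pre_post()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_comparison <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$summary,
                             c("n_significant_pre", "n_significant_post"),
                             names_to = "stage", values_to = "n_significant")
  dat$stage <- factor(sub("n_significant_", "", dat$stage),
                      levels = c("pre", "post"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$grouping,
                                    y = .data$n_significant,
                                    fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "significant features",
                  title = "Batch dependence before vs after harmonization") +
    ggplot2::theme_minimal()
}
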