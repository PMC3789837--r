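# ggplot2 displays for the main result types.

#' @method autoplot ortho_classification
#' @export
autoplot.ortho_classification <- function(object, ...) {
  df <- tidy(object)
  df$focal <- ifelse(df$focal_present, "focal present", "focal absent")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, fill = .data$focal)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "ortholog groups", fill = NULL,
                  title = "Classification of ortholog groups") +
    ggplot2::theme_minimal()
}

#' @method autoplot enrichment_table
#' @export
autoplot.enrichment_table <- function(object, ...) {
  df <- tidy(object)
  df$category <- factor(df$category, levels = rev(df$category))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$q), y = .data$category,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(
      xintercept = -log10(attr(object, "alpha") %||% 0.05),
      linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10](q)), y = NULL, fill = NULL,
                  title = "Category enrichment") +
    ggplot2::theme_minimal()
}

#' @method autoplot coverage_report
#' @export
autoplot.coverage_report <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[order(df$coverage), ]
  df$code <- factor(df$code, levels = df$code)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coverage, y = .data$code,
                                   fill = .data$is_metazoan)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "core-gene coverage", y = NULL, fill = "metazoan",
                  title = "Genome-completeness approximation") +
    ggplot2::theme_minimal()
}

#' Grouped bar chart of two sets' proportions
#'
#' Displays the per-measure proportions of a two-set comparison (RNAi
#' phenotype classes or expression panels) side by side, with the Fisher
#' p-value annotated.
#'
#' @param comparison Output of [compare_sets_fisher()].
#' @param labels Length-2 names for the sets (defaults to the attribute
#'   stored by the comparison).
#' @return A ggplot object.
#' @export
plot_set_comparison <- function(comparison,
                                labels = attr(comparison, "labels")) {
  labels <- labels %||% c("A", "B")
  long <- bind_rows(
    tibble(measure = comparison$measure, set = labels[1],
           prop = comparison$prop_a),
    tibble(measure = comparison$measure, set = labels[2],
           prop = comparison$prop_b)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$measure, y = .data$prop,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "proportion of genes", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
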