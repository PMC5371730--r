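# ggplot2 views of the result types.

#' Plot an enrichment result
#'
#' Dot plot of the top terms: query fraction against term, sized by the
#' annotated query count and coloured by `-log10` adjusted p-value.
#'
#' @param object A `ppi_enrichment` tibble.
#' @param top_n Number of top terms (by adjusted p) to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppi_enrichment <- function(object, top_n = 20, ...) {
  df <- head(tidy(object), top_n)
  df$term <- factor(df$term_name, levels = rev(df$term_name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$term)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$k,
                                     colour = -log10(.data$p_adj))) +
    ggplot2::scale_colour_viridis_c(name = expression(-log[10] ~ italic(P)[adj])) +
    ggplot2::scale_size_continuous(name = "proteins") +
    ggplot2::labs(x = "fraction of query", y = NULL,
                  title = sprintf("Term enrichment (%s)",
                                  attr(object, "namespace") %||% "")) +
    ggplot2::theme_minimal()
}

#' Plot domain-set pair enrichment
#'
#' Horizontal bars of `-log10` adjusted p-value for the top bait-set /
#' prey-set pairs.
#'
#' @param object A `ppi_domain_pairs` tibble.
#' @param top_n Number of top pairs to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppi_domain_pairs <- function(object, top_n = 15, ...) {
  df <- head(tidy(object), top_n)
  df$pair <- paste(df$bait_set_members, df$prey_set_members, sep = " ~ ")
  df$pair <- factor(df$pair, levels = rev(unique(df$pair)))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_adj), y = .data$pair)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(-log[10] ~ italic(P)[adj]),
                  y = "bait domain set ~ prey domain set",
                  title = "Domain-set pair enrichment") +
    ggplot2::theme_minimal()
}

#' Plot validation rates
#'
#' Bar chart of per-scope validation success rates with tested counts.
#'
#' @param object A `ppi_validation_summary` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppi_validation_summary <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$rate), , drop = FALSE]
  df$scope <- factor(df$scope, levels = df$scope)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scope, y = .data$rate)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d", .data$n_validated,
                                                    .data$n_tested)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "validation rate (%)",
                  title = "Orthogonal validation") +
    ggplot2::ylim(0, 105) +
    ggplot2::theme_minimal()
}
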