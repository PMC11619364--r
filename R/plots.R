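#' Plot a per-rank concordance table
#'
#' Bar chart of the cumulative percentage of plasmids whose reported host is
#' captured at or below each taxonomic rank, among matched plasmids and
#' (dotted reference) among all plasmids.
#'
#' @param object A [concordance_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot concordance_table
#' @export
autoplot.concordance_table <- function(object, ...) {
  df <- object %>%
    filter(.data$rank != "none") %>%
    mutate(rank = factor(.data$rank, levels = rank_ladder())) %>%
    tidyr::pivot_longer(c("pct_matched", "pct_total"),
                        names_to = "denominator", values_to = "pct") %>%
    mutate(denominator = dplyr::recode(.data$denominator,
                                       pct_matched = "matched plasmids",
                                       pct_total = "all plasmids"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$pct,
                                   fill = .data$denominator)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("matched plasmids" = "grey25",
                                          "all plasmids" = "grey70")) +
    ggplot2::labs(x = "taxonomic rank", y = "concordant plasmids (%)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a host-range grade distribution
#'
#' Stacked percentage bars of grades I-VI per group (all / MOB+ / MOB-).
#'
#' @param object A [grade_distribution()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grade_distribution
#' @export
autoplot.grade_distribution <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$group, y = .data$pct,
                               fill = .data$grade)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(x = NULL, y = "plasmids (%)", fill = "grade") +
    ggplot2::theme_minimal()
}

#' Plot a target category summary
#'
#' Known-function breakdown of targeted features (the four categories other
#' than unknown function).
#'
#' @param object A [category_summary()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot category_summary
#' @export
autoplot.category_summary <- function(object, ...) {
  df <- as_tibble(object) %>% filter(!is.na(.data$pct_known))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$category,
                                                      -.data$pct_known),
                                   y = .data$pct_known)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "known-function targets (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
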