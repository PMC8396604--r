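# ggplot2 displays for the package's result types.

#' Plot enrichment results as a -log10(p) bar chart
#'
#' @param object An `enrich_result` from [hypergeom_enrich()].
#' @param n_terms Show at most this many top terms (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrich_result
#' @export
autoplot.enrich_result <- function(object, n_terms = 20, ...) {
  df <- head(as_tibble(object), n_terms)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$neg_log10_p,
    y = stats::reorder(.data$term_id, .data$neg_log10_p)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(-log[10](italic(p))), y = NULL,
                  title = "Term enrichment") +
    ggplot2::theme_minimal()
}

#' Plot switch calls as usage difference vs. significance
#'
#' @param object A `switch_calls` tibble from [detect_switches()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot switch_calls
#' @export
autoplot.switch_calls <- function(object, ...) {
  df <- as_tibble(object) %>% mutate(nlp = -log10(pmax(.data$p_bh, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(.data$dif, .data$nlp,
                                   colour = .data$is_switch)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "dIF (knockdown - control)",
                  y = expression(-log[10](adj.~italic(p))),
                  colour = "switch") +
    ggplot2::theme_minimal()
}

#' Plot per-group fold changes from a ddCt fit
#'
#' Bar chart of group mean fold with SEM error bars, the standard display
#' for relative qPCR quantification.
#'
#' @param object A `ddct_fit` from [ddct_fold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddct_fit
#' @export
autoplot.ddct_fit <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(.data$group, .data$mean_fold)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_fold - .data$sem_fold,
      ymax = .data$mean_fold + .data$sem_fold
    ), width = 0.2) +
    ggplot2::geom_point(data = object$samples,
                        ggplot2::aes(.data$group, .data$fold), alpha = 0.6) +
    ggplot2::labs(y = sprintf("%s / %s fold (2^-ddCt)", object$target_gene,
                              object$reference_gene),
                  x = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked isoform-usage bars per condition
#'
#' Displays each isoform's share of its gene's expression ("% of total
#' isoforms") side by side for the two conditions.
#'
#' @param table Transcript-level counts (see [isoform_fractions()]).
#' @param genes Optional gene subset to display.
#' @return A ggplot object.
#' @export
plot_isoform_usage <- function(table, genes = NULL) {
  fr <- isoform_fractions(table)
  if (!is.null(genes)) fr <- filter(fr, .data$gene_id %in% genes)
  ggplot2::ggplot(fr, ggplot2::aes(.data$condition, 100 * .data$frac,
                                   fill = .data$isoform_id)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~gene_id) +
    ggplot2::labs(x = NULL, y = "Isoform usage (% of total isoforms)",
                  fill = "isoform") +
    ggplot2::theme_minimal()
}

#' Partner-category counts per structure and replicate
#'
#' @param sets Output of [partner_sets()].
#' @return A ggplot object.
#' @export
plot_partner_categories <- function(sets) {
  check_columns(sets, c("structure", "replicate", "n_unique", "n_selected",
                        "n_unique_small"), "`sets`")
  long <- sets %>%
    select("structure", "replicate", "n_unique", "n_selected",
           "n_unique_small") %>%
    tidyr::pivot_longer(cols = c("n_unique", "n_selected", "n_unique_small"),
                        names_to = "category", values_to = "count") %>%
    mutate(category = sub("^n_", "", .data$category))
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$replicate), .data$count,
                                     fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~structure) +
    ggplot2::labs(x = "replicate", y = "proteins", fill = NULL) +
    ggplot2::theme_minimal()
}
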