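# broom-style tidy()/glance() methods for the package's result objects.

#' @describeIn consensus_genes tidy(): one row per consensus or discordant
#'   gene with its `status`.
#' @param x A `consensus_genes` object.
#' @param ... Unused.
#' @method tidy consensus_genes
#' @export
tidy.consensus_genes <- function(x, ...) {
  x$membership %>%
    filter(.data$status %in% c("up", "down", "discordant")) %>%
    arrange(.data$status, .data$gene_id) %>%
    as_tibble()
}

#' @describeIn consensus_genes glance(): one row with list sizes.
#' @method glance consensus_genes
#' @export
glance.consensus_genes <- function(x, ...) {
  tibble(
    n_up = length(x$up),
    n_down = length(x$down),
    n_discordant = length(x$discordant),
    n_comparisons = length(x$require)
  )
}

#' @describeIn cross_structure glance(): counts of proteins shared across the
#'   required structures and of those also found in each further structure.
#' @param x A `cross_structure` tibble.
#' @param ... Unused.
#' @method glance cross_structure
#' @export
glance.cross_structure <- function(x, ...) {
  out <- tibble(
    n_proteins = nrow(x),
    n_shared_required = sum(x$in_all_required)
  )
  for (s in attr(x, "also")) {
    out[[paste0("n_also_", s)]] <- sum(x[[paste0("also_in_", s)]])
  }
  out
}

#' @describeIn hypergeom_enrich glance(): term counts and the number
#'   significant at BH 0.05.
#' @param x An `enrich_result` tibble.
#' @param ... Unused.
#' @method glance enrich_result
#' @export
glance.enrich_result <- function(x, ...) {
  tibble(
    n_terms = nrow(x),
    n_sig_bh_05 = sum(x$p_bh < 0.05),
    n_query = if (nrow(x) > 0) x$n[1] else 0L,
    n_background = if (nrow(x) > 0) x$N[1] else 0L
  )
}

#' @describeIn detect_switches glance(): number of isoforms tested, switches
#'   called, and genes with at least one switch.
#' @param x A `switch_calls` tibble.
#' @param ... Unused.
#' @method glance switch_calls
#' @export
glance.switch_calls <- function(x, ...) {
  tibble(
    n_isoforms_tested = nrow(x),
    n_switch_isoforms = sum(x$is_switch),
    n_switch_genes = n_distinct(x$gene_id[x$is_switch])
  )
}

#' @describeIn ddct_fold tidy(): the per-sample fold table.
#' @param x A `ddct_fit` object.
#' @param ... Unused.
#' @method tidy ddct_fit
#' @export
tidy.ddct_fit <- function(x, ...) {
  x$samples
}

#' @describeIn ddct_fold glance(): one row with per-group mean folds (columns
#'   `mean_fold_<group>`), their SEMs, and the group t-test p-value when
#'   available.
#' @method glance ddct_fit
#' @export
glance.ddct_fit <- function(x, ...) {
  wide <- x$summary %>%
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("mean_fold", "sem_fold", "n"))
  wide$p_value <- if (is.null(x$ttest)) NA_real_ else x$ttest$p.value
  wide
}
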