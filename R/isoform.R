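#' Isoform usage fractions per condition
#'
#' Converts transcript-level counts into each isoform's share of its gene's
#' expression ("% of total isoforms") per condition. Replicates are pooled by
#' default: the fraction is the summed isoform count over the summed gene
#' count. The per-replicate mode instead averages replicate-level fractions
#' (replicates where the gene has zero total are dropped). A gene with zero
#' total in a condition is excluded for that condition.
#'
#' @param table Data frame with columns `gene_id`, `isoform_id`, `condition`
#'   (`"control"` / `"knockdown"`), `replicate`, `count` (non-negative).
#' @param pool_replicates Pool counts across replicates before forming
#'   fractions (default `TRUE`)?
#'
#' @return Tibble `gene_id`, `isoform_id`, `condition`, `count` (pooled),
#'   `frac` (isoform fraction, summing to 1 within gene and condition).
#'
#' @examples
#' tbl <- tibble::tibble(
#'   gene_id = "g1", isoform_id = c("i1", "i2"), condition = "control",
#'   replicate = 1L, count = c(30, 70)
#' )
#' isoform_fractions(tbl)
#' @export
isoform_fractions <- function(table, pool_replicates = TRUE) {
  check_columns(table, c("gene_id", "isoform_id", "condition", "replicate",
                         "count"), "`table`")
  check_nonneg(table$count, "count")
  check_condition_levels(table$condition)
  multi_gene <- table %>%
    distinct(.data$gene_id, .data$isoform_id) %>%
    count(.data$isoform_id) %>%
    filter(.data$n > 1)
  if (nrow(multi_gene) > 0) {
    abort(sprintf("Isoform %s is assigned to more than one gene.",
                  multi_gene$isoform_id[1]))
  }

  if (pool_replicates) {
    as_tibble(table) %>%
      group_by(.data$gene_id, .data$isoform_id, .data$condition) %>%
      summarise(count = sum(.data$count), .groups = "drop") %>%
      group_by(.data$gene_id, .data$condition) %>%
      filter(sum(.data$count) > 0) %>%
      mutate(frac = .data$count / sum(.data$count)) %>%
      ungroup()
  } else {
    as_tibble(table) %>%
      group_by(.data$gene_id, .data$condition, .data$replicate) %>%
      filter(sum(.data$count) > 0) %>%
      mutate(rep_frac = .data$count / sum(.data$count)) %>%
      group_by(.data$gene_id, .data$isoform_id, .data$condition) %>%
      summarise(count = sum(.data$count),
                frac = mean(.data$rep_frac), .groups = "drop")
  }
}

check_condition_levels <- function(condition) {
  bad <- setdiff(unique(as.character(condition)), c("control", "knockdown"))
  if (length(bad) > 0) {
    abort(sprintf("`condition` must be 'control' or 'knockdown' (found '%s').",
                  bad[1]))
  }
}

#' Detect isoform switches between conditions
#'
#' For every isoform of genes quantified in both conditions with at least two
#' isoforms, computes the usage difference `dIF = IF_knockdown - IF_control`
#' (replicate-pooled fractions) and a p-value from a two-proportion test of
#' the isoform's pooled count against its gene's pooled total across the two
#' conditions (z-test without continuity correction; exact conditional test
#' when any 2x2 expected count is below 5). P-values are Benjamini-Hochberg
#' adjusted over all tested isoforms. An isoform is called a switch when
#' `|dIF| >= dif_cutoff` and the adjusted p-value is below `alpha`.
#'
#' @param table Transcript-level counts as in [isoform_fractions()]. Counts
#'   are rounded to integers for the test.
#' @param dif_cutoff Minimum absolute usage difference (default 0.15,
#'   inclusive).
#' @param alpha Threshold on the adjusted p-value (default 0.05, strict `<`).
#'
#' @return Tibble of class `switch_calls`: `gene_id`, `isoform_id`,
#'   `if_control`, `if_kd`, `dif`, `p`, `p_bh`, `is_switch`, sorted by
#'   ascending `p_bh` then descending `|dif|`.
#'
#' @export
detect_switches <- function(table, dif_cutoff = 0.15, alpha = 0.05) {
  check_fraction(dif_cutoff, "dif_cutoff")
  fr <- isoform_fractions(table, pool_replicates = TRUE)

  conds <- fr %>%
    distinct(.data$gene_id, .data$condition) %>%
    count(.data$gene_id)
  dropped <- conds$gene_id[conds$n < 2]
  if (length(dropped) > 0) {
    warn(sprintf("%d gene%s absent from one condition excluded: %s.",
                 length(dropped), if (length(dropped) > 1) "s" else "",
                 paste(head(dropped, 5), collapse = ", ")))
  }
  n_iso <- fr %>%
    distinct(.data$gene_id, .data$isoform_id) %>%
    count(.data$gene_id)
  testable <- setdiff(n_iso$gene_id[n_iso$n >= 2], dropped)

  wide <- fr %>%
    filter(.data$gene_id %in% testable) %>%
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("count", "frac"),
                       values_fill = list(count = 0, frac = 0)) %>%
    group_by(.data$gene_id) %>%
    mutate(total_control = sum(.data$count_control),
           total_knockdown = sum(.data$count_knockdown)) %>%
    ungroup()

  res <- wide %>%
    mutate(
      if_control = .data$frac_control,
      if_kd = .data$frac_knockdown,
      dif = .data$if_kd - .data$if_control,
      p = purrr::pmap_dbl(
        list(.data$count_control, .data$total_control,
             .data$count_knockdown, .data$total_knockdown),
        two_proportion_p
      )
    ) %>%
    mutate(p_bh = bh_adjust(.data$p),
           is_switch = abs(.data$dif) >= dif_cutoff & .data$p_bh < alpha) %>%
    arrange(.data$p_bh, desc(abs(.data$dif)), .data$gene_id, .data$isoform_id) %>%
    select("gene_id", "isoform_id", "if_control", "if_kd", "dif",
           "p", "p_bh", "is_switch")
  new_result(res, "switch_calls")
}

# p-value for isoform count x of gene total n in each condition: large-sample
# two-proportion z-test, exact fallback when the chi-square expecteds are small
two_proportion_p <- function(x1, n1, x2, n2) {
  x1 <- round(x1); n1 <- round(n1); x2 <- round(x2); n2 <- round(n2)
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  if (any(n1 == 0, n2 == 0)) return(NA_real_)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    fisher.test(tab)$p.value
  } else if (x1 / n1 == x2 / n2) {
    1
  } else {
    suppressWarnings(
      prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$p.value
    )
  }
}
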