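#' Signed fold change between condition means
#'
#' Expresses the change from control to knockdown as a signed ratio whose
#' magnitude is always >= 1: upregulation as `+ mean_kd / mean_control`,
#' downregulation under the negative-reciprocal convention as
#' `- mean_control / mean_kd`. A gene silent in the control but expressed in
#' the knockdown returns `+Inf` ("infinite" induction); the reverse returns
#' `-Inf`; two zeros are undefined (`NA`). Equal positive means give `+1`.
#'
#' @param mean_control,mean_kd Non-negative mean read counts per condition.
#'   Vectorised.
#'
#' @return Numeric vector of signed folds (may contain `Inf`, `-Inf`, `NA`).
#'
#' @examples
#' signed_fold(10, 66)   #  6.6
#' signed_fold(444, 83)  # -5.35, prints as -5.3 at two significant figures
#' signed_fold(0, 28.6)  #  Inf
#' @export
signed_fold <- function(mean_control, mean_kd) {
  check_nonneg(mean_control, "mean_control", allow_na = TRUE)
  check_nonneg(mean_kd, "mean_kd", allow_na = TRUE)
  n <- max(length(mean_control), length(mean_kd))
  c0 <- rep_len(as.numeric(mean_control), n)
  k0 <- rep_len(as.numeric(mean_kd), n)
  case_when(
    is.na(c0) | is.na(k0) ~ NA_real_,
    c0 == 0 & k0 == 0 ~ NA_real_,
    c0 == 0 ~ Inf,
    k0 == 0 ~ -Inf,
    k0 >= c0 ~ k0 / c0,
    TRUE ~ -c0 / k0
  )
}

#' Round a fold change for reporting
#'
#' Published fold-change tables print two significant figures; this keeps
#' signs and infinities intact.
#'
#' @param fold Numeric vector of signed folds.
#' @param digits Significant figures (default 2).
#' @return Numeric vector.
#' @export
round_fold <- function(fold, digits = 2) {
  out <- fold
  fin <- is.finite(fold)
  out[fin] <- signif(fold[fin], digits)
  out
}

#' Percent knockdown from condition means
#'
#' `100 * (1 - mean_kd / mean_control)`, the percentage decrease in the
#' knockdown relative to the control. Undefined (`NA`) when the control mean
#' is zero. Set `round = TRUE` to round to the nearest integer percentage as
#' reported in text.
#'
#' @param mean_control,mean_kd Non-negative condition means; vectorised.
#' @param round Round to whole percent? Default `TRUE`.
#' @return Numeric vector of percentages (negative when expression rises).
#' @examples
#' percent_knockdown(7924, 4143) # 48
#' percent_knockdown(6399, 3957) # 38
#' @export
percent_knockdown <- function(mean_control, mean_kd, round = TRUE) {
  check_nonneg(mean_control, "mean_control", allow_na = TRUE)
  check_nonneg(mean_kd, "mean_kd", allow_na = TRUE)
  pct <- ifelse(!is.na(mean_control) & mean_control > 0,
                100 * (1 - mean_kd / mean_control), NA_real_)
  if (round) round(pct) else pct
}

#' Significant differentially expressed genes per comparison
#'
#' Filters a differential-expression table to genes with adjusted p-value
#' strictly below `alpha`, and assigns a direction from the signed fold:
#' `up` for fold > 1, `down` for fold < 1 (including infinite folds). Genes
#' with missing `p_adj`, or with no change (fold exactly +1 or undefined),
#' are excluded.
#'
#' @param de Data frame with columns `gene_id`, `comparison`, `mean_control`,
#'   `mean_kd`, `p_adj`.
#' @param alpha Significance threshold on the adjusted p-value (default 0.05,
#'   strict `<`).
#'
#' @return Tibble `gene_id`, `comparison`, `direction` (`"up"`/`"down"`),
#'   `fold`, `p_adj`.
#'
#' @export
significant_genes <- function(de, alpha = 0.05) {
  check_columns(de, c("gene_id", "comparison", "mean_control", "mean_kd", "p_adj"),
                "`de`")
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single value in (0, 1).")
  }
  as_tibble(de) %>%
    mutate(fold = signed_fold(.data$mean_control, .data$mean_kd)) %>%
    filter(!is.na(.data$p_adj), .data$p_adj < alpha,
           !is.na(.data$fold), .data$fold != 1) %>%
    mutate(direction = ifelse(.data$fold > 1, "up", "down")) %>%
    select("gene_id", "comparison", "direction", "fold", "p_adj")
}

#' Consensus gene list across knockdown comparisons
#'
#' A gene is in the consensus `up` (`down`) list when it is significant with
#' direction up (down) in every required comparison. Genes significant in all
#' required comparisons but with conflicting directions are reported as
#' `discordant` and belong to neither list.
#'
#' @param de Differential-expression table as in [significant_genes()], or an
#'   already-filtered output of [significant_genes()] (detected by the
#'   presence of a `direction` column).
#' @param require Character vector of comparisons a gene must be significant
#'   in (default: all comparisons present, which must be at least two).
#' @param alpha Passed to [significant_genes()] when `de` is unfiltered.
#'
#' @return An object of class `consensus_genes`: a list with character
#'   vectors `up`, `down`, `discordant`, the `require`d comparisons, and a
#'   `membership` tibble (`gene_id`, one direction column per comparison,
#'   `status`). [tidy()] returns one row per consensus gene; [glance()] the
#'   list sizes.
#'
#' @export
consensus_genes <- function(de, require = NULL, alpha = 0.05) {
  sig <- if ("direction" %in% names(de)) {
    check_columns(de, c("gene_id", "comparison", "direction"), "`de`")
    as_tibble(de)
  } else {
    significant_genes(de, alpha = alpha)
  }
  if (is.null(require)) require <- unique(as.character(sig$comparison))
  if (length(require) < 2) {
    abort("Consensus needs at least two comparisons (`require`).")
  }
  missing_cmp <- setdiff(require, unique(as.character(sig$comparison)))
  if (length(missing_cmp) > 0 && nrow(sig) > 0) {
    warn(sprintf("No significant genes in comparison%s %s; consensus is empty.",
                 if (length(missing_cmp) > 1) "s" else "",
                 paste(missing_cmp, collapse = ", ")))
  }

  membership <- sig %>%
    filter(.data$comparison %in% require) %>%
    distinct(.data$gene_id, .data$comparison, .data$direction) %>%
    tidyr::pivot_wider(names_from = "comparison", values_from = "direction")
  for (cmp in setdiff(require, names(membership))) {
    membership[[cmp]] <- NA_character_
  }
  dirs <- as.matrix(membership[, require, drop = FALSE])
  in_all <- rowSums(!is.na(dirs)) == length(require)
  all_up <- in_all & rowSums(dirs == "up") == length(require)
  all_down <- in_all & rowSums(dirs == "down") == length(require)
  membership$status <- case_when(
    all_up ~ "up",
    all_down ~ "down",
    in_all ~ "discordant",
    TRUE ~ "partial"
  )
  structure(
    list(
      up = sort(membership$gene_id[membership$status == "up"]),
      down = sort(membership$gene_id[membership$status == "down"]),
      discordant = sort(membership$gene_id[membership$status == "discordant"]),
      require = require,
      membership = membership
    ),
    class = "consensus_genes"
  )
}

#' @export
print.consensus_genes <- function(x, ...) {
  cat(sprintf(
    "Consensus across %s:\n  %d up, %d down, %d direction-discordant\n",
    paste(x$require, collapse = ", "),
    length(x$up), length(x$down), length(x$discordant)
  ))
  invisible(x)
}

#' Venn region counts for two or three gene sets
#'
#' Counts every exclusive intersection region of 2 or 3 named sets; region
#' counts sum to the size of the union.
#'
#' @param sets Named list of 2 or 3 character vectors (duplicates within a
#'   set are ignored).
#'
#' @return Tibble with `region` (set names joined by `&`), `degree` (number
#'   of sets in the region), `count`, and a `members` list-column.
#'
#' @examples
#' venn_counts(list(LV = c("A", "B"), FourV = c("B", "C")))
#' @export
venn_counts <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3) {
    abort("`sets` must be a named list of 2 or 3 gene sets.")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be named.")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets))
  pattern <- if (length(universe) == 0) {
    matrix(logical(0), nrow = 0, ncol = length(sets))
  } else {
    matrix(vapply(sets, function(s) universe %in% s, logical(length(universe))),
           nrow = length(universe))
  }
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))[-2^length(sets), , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    mask <- as.logical(combos[i, ])
    in_region <- rowSums(pattern[, mask, drop = FALSE] == TRUE) == sum(mask) &
      rowSums(pattern[, !mask, drop = FALSE] == TRUE) == 0
    tibble(
      region = paste(names(sets)[mask], collapse = " & "),
      degree = sum(mask),
      count = sum(in_region),
      members = list(sort(universe[in_region]))
    )
  }) %>%
    arrange(desc(.data$degree), .data$region)
}

#' Overlap of a gene list with an external list
#'
#' @param genes Character vector (the list under study).
#' @param external Non-empty character vector (the published or reference
#'   list the overlap fraction is expressed against).
#'
#' @return One-row tibble: `n_overlap`, `n_external`, `fraction`
#'   (`n_overlap / n_external`), and a `members` list-column.
#'
#' @examples
#' overlap_with_external(c("A", "B", "C"), c("B", "C", "D", "E"))
#' @export
overlap_with_external <- function(genes, external) {
  external <- unique(as.character(external))
  if (length(external) == 0) abort("`external` must be non-empty.")
  genes <- unique(as.character(genes))
  ov <- intersect(genes, external)
  tibble(
    n_overlap = length(ov),
    n_external = length(external),
    fraction = length(ov) / length(external),
    members = list(sort(ov))
  )
}

#' Expressed-gene background for enrichment
#'
#' Genes whose mean reads exceed `min_reads` in at least one condition of at
#' least one comparison — the standard expression floor applied before
#' ontology analysis.
#'
#' @param de Differential-expression table (`gene_id`, `mean_control`,
#'   `mean_kd`).
#' @param min_reads Floor on the mean reads (strict `>`, default 10).
#' @return Character vector of gene IDs.
#' @export
expression_floor <- function(de, min_reads = 10) {
  check_columns(de, c("gene_id", "mean_control", "mean_kd"), "`de`")
  de %>%
    filter(.data$mean_control > min_reads | .data$mean_kd > min_reads) %>%
    pull("gene_id") %>%
    unique() %>%
    sort()
}

#' Fold-change report for a differential-expression table
#'
#' Adds signed and plain-ratio fold changes (rounded for reporting) to a
#' table of condition means — the layout used when tabulating candidate
#' genes such as secreted factors.
#'
#' @param de Table with `gene_id`, `comparison`, `mean_control`, `mean_kd`,
#'   and optionally `p_adj`.
#' @param digits Significant figures for the reported folds (default 2).
#' @return Tibble with `fold` (signed) and `ratio` (`mean_kd/mean_control`)
#'   columns, both rounded.
#' @export
de_report <- function(de, digits = 2) {
  check_columns(de, c("gene_id", "comparison", "mean_control", "mean_kd"), "`de`")
  as_tibble(de) %>%
    mutate(
      fold = round_fold(signed_fold(.data$mean_control, .data$mean_kd), digits),
      ratio = ifelse(!is.na(.data$mean_control) & .data$mean_control > 0,
                     signif(.data$mean_kd / .data$mean_control, digits),
                     ifelse(!is.na(.data$mean_kd) & .data$mean_kd > 0,
                            Inf, NA_real_))
    )
}
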