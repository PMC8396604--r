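#' Relative quantification by the 2^-ddCt method
#'
#' Computes per-sample relative expression of a target gene against a
#' reference gene, normalised to a calibrator group. Technical replicates
#' (repeated Ct rows for the same sample and gene) are averaged on the Ct
#' scale, then per sample `dCt = Ct_target - Ct_reference`,
#' `ddCt = dCt - mean(dCt in calibrator group)`, and `fold = 2^-ddCt`. By
#' construction the calibrator group's mean log2 fold is zero, i.e. its
#' geometric mean fold is 1. Samples missing a target or reference Ct are
#' excluded with a warning.
#'
#' @param ct_data Data frame with columns `sample_id`, `group`, `gene_id`,
#'   `ct` (cycle thresholds, typically 10-40; repeated rows are technical
#'   replicates).
#' @param target_gene,reference_gene Gene IDs of the gene of interest and the
#'   housekeeping reference (e.g. `Hprt`, `Gapdh`).
#' @param calibrator_group Group whose mean expression defines fold = 1
#'   (default `"control"`).
#'
#' @return An object of class `ddct_fit`: list with `samples` (per-sample
#'   tibble: `sample_id`, `group`, `ct_target`, `ct_reference`, `delta_ct`,
#'   `ddct`, `fold`), `summary` (per-group mean fold, SEM, n), `ttest`
#'   (two-sample t-test on fold values when two groups each have >= 2
#'   samples, else `NULL`), and the gene/group settings. [tidy()] returns the
#'   per-sample folds, [glance()] a one-row group comparison.
#'
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = rep(paste0("m", 1:4), each = 2),
#'   group = rep(c("control", "treated"), each = 4),
#'   gene_id = rep(c("Gpx3", "Hprt"), 4),
#'   ct = c(25, 20, 25.2, 20.1, 23, 20, 22.8, 19.9)
#' )
#' ddct_fold(ct, "Gpx3", "Hprt")
#' @export
ddct_fold <- function(ct_data, target_gene, reference_gene,
                      calibrator_group = "control") {
  check_columns(ct_data, c("sample_id", "group", "gene_id", "ct"), "`ct_data`")
  if (any(!is.finite(ct_data$ct))) abort("`ct` values must be finite.")
  if (identical(target_gene, reference_gene)) {
    abort("`target_gene` and `reference_gene` must differ.")
  }

  # technical replicates averaged on the Ct scale
  cts <- as_tibble(ct_data) %>%
    filter(.data$gene_id %in% c(target_gene, reference_gene)) %>%
    group_by(.data$sample_id, .data$group, .data$gene_id) %>%
    summarise(ct = mean(.data$ct), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "gene_id", values_from = "ct")
  for (g in c(target_gene, reference_gene)) {
    if (!g %in% names(cts)) cts[[g]] <- NA_real_
  }
  incomplete <- is.na(cts[[target_gene]]) | is.na(cts[[reference_gene]])
  if (any(incomplete)) {
    warn(sprintf("%d sample%s missing a target or reference Ct excluded: %s.",
                 sum(incomplete), if (sum(incomplete) > 1) "s" else "",
                 paste(head(cts$sample_id[incomplete], 5), collapse = ", ")))
    cts <- cts[!incomplete, , drop = FALSE]
  }
  if (!calibrator_group %in% cts$group) {
    abort(sprintf("No complete samples in calibrator group '%s'.",
                  calibrator_group))
  }

  samples <- cts %>%
    mutate(
      ct_target = .data[[target_gene]],
      ct_reference = .data[[reference_gene]],
      delta_ct = .data$ct_target - .data$ct_reference
    ) %>%
    select("sample_id", "group", "ct_target", "ct_reference", "delta_ct")
  calibrator_mean <- mean(samples$delta_ct[samples$group == calibrator_group])
  samples <- samples %>%
    mutate(ddct = .data$delta_ct - calibrator_mean,
           fold = 2^(-.data$ddct))

  summary <- samples %>%
    group_by(.data$group) %>%
    summarise(
      n = n(),
      mean_fold = mean(.data$fold),
      sem_fold = sd(.data$fold) / sqrt(n()),
      .groups = "drop"
    )
  groups <- unique(samples$group)
  ttest <- NULL
  if (length(groups) == 2 && all(table(samples$group) >= 2)) {
    ttest <- t.test(fold ~ group, data = samples)
  }
  structure(
    list(samples = samples, summary = summary, ttest = ttest,
         target_gene = target_gene, reference_gene = reference_gene,
         calibrator_group = calibrator_group),
    class = "ddct_fit"
  )
}

#' @export
print.ddct_fit <- function(x, ...) {
  cat(sprintf("2^-ddCt quantification of %s (reference %s, calibrator '%s')\n",
              x$target_gene, x$reference_gene, x$calibrator_group))
  print(x$summary)
  if (!is.null(x$ttest)) {
    cat(sprintf("t-test across groups: p = %.4g\n", x$ttest$p.value))
  }
  invisible(x)
}
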