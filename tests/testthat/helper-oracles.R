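suppressPackageStartupMessages(library(dplyr))

# Independent oracles kept deliberately separate from the package internals.

# Literal per-protein transcription of the three partner rules, evaluated
# with scalar if-logic (no vectorisation shared with the implementation).
triage_oracle <- function(bait, control, mw = NA, min_pep = 3, mw_max = 25) {
  flags <- character(0)
  if (control == 0 && bait >= min_pep) flags <- c(flags, "unique")
  if (bait >= min_pep && control >= 1) {
    rd <- (bait - control) / bait
    if (rd > 0.5) flags <- c(flags, "selected")
  }
  if (control == 0 && bait >= 1 && !is.na(mw) && mw <= mw_max) {
    flags <- c(flags, "unique_small")
  }
  flags
}

# Upper-tail hypergeometric p by exhaustive enumeration of all query draws
# of size n from a universe of size N containing a term of size K.
hyper_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K) # term = elements 1..K
  mean(hits >= k)
}

# Small co-IP table builder for hand-specified counts.
coip_table <- function(bait, control, ids = NULL, structure = "ChP",
                       replicate = 1L) {
  if (is.null(ids)) ids <- sprintf("prot%02d", seq_along(bait))
  tibble::tibble(
    protein_id = ids, structure = structure, replicate = replicate,
    bait_peptides = bait, control_peptides = control
  )
}

# One-comparison DE table builder.
de_table <- function(gene_id, mean_control, mean_kd, p_adj,
                     comparison = "LV_cond") {
  tibble::tibble(gene_id = gene_id, comparison = comparison,
                 mean_control = mean_control, mean_kd = mean_kd, p_adj = p_adj)
}

# Fraction of simulations in which the planted switch gene is flagged.
switch_gene_hits <- function(calls) {
  unique(calls$gene_id[calls$is_switch])
}
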