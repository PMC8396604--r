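# Readers for the tab-separated dialects the pipeline consumes. All readers
# return plain tibbles in the column layout the analysis functions expect.

#' Path to a bundled example dataset
#'
#' The package ships small published-style example tables: a peptide-count
#' table for 14 candidate OTX2 partner proteins across four brain structures
#' (`otx2_coip_peptides.tsv`), the top differentially expressed choroid
#' plexus genes of the conditional knockdown (`otx2_de_top10.tsv`), and the
#' secreted-factor expression table across all three knockdown comparisons
#' (`otx2_de_secreted.tsv`).
#'
#' @param file File name; with no argument, lists the available files.
#' @return Full path to the file.
#' @examples
#' otx_example()
#' otx_example("otx2_coip_peptides.tsv")
#' @export
otx_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "otxtools"))
  } else {
    path <- system.file("extdata", file, package = "otxtools")
    if (path == "") abort(sprintf("No example file '%s'.", file))
    path
  }
}

#' Read a bait-vs-control peptide-count table
#'
#' Tab-separated with header columns `protein_id`, `structure`, `replicate`,
#' and either `bait_peptides`/`control_peptides` or the assay-specific names
#' `otx2_peptides`/`igg_peptides` (renamed on read).
#'
#' @param path File path.
#' @return Tibble in the [classify_partners()] input layout.
#' @export
read_peptide_counts <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if ("otx2_peptides" %in% names(df)) df <- rename(df, bait_peptides = "otx2_peptides")
  if ("igg_peptides" %in% names(df)) df <- rename(df, control_peptides = "igg_peptides")
  check_columns(df, c("protein_id", "structure", "replicate",
                      "bait_peptides", "control_peptides"), path)
  df
}

#' Read protein annotations (mass table or FASTA)
#'
#' A `.tsv` file must carry `protein_id` and `mw_kda` (and optionally
#' `sequence`). A FASTA file of amino-acid sequences is converted with
#' [mw_from_sequence()], using the first word of each header as the protein
#' ID (requires the Biostrings package).
#'
#' @param path File path; format chosen by extension (`.fa`, `.fasta` for
#'   FASTA, anything else read as TSV).
#' @return Tibble `protein_id`, `mw_kda` (and `sequence` for FASTA input).
#' @export
read_protein_annotations <- function(path) {
  if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("Reading FASTA annotations requires the Biostrings package.")
    }
    seqs <- Biostrings::readAAStringSet(path)
    tibble(
      protein_id = sub("\\s.*$", "", names(seqs)),
      sequence = as.character(seqs)
    ) %>%
      mutate(mw_kda = mw_from_sequence(.data$sequence))
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    check_columns(df, "protein_id", path)
    if (!any(c("mw_kda", "sequence") %in% names(df))) {
      abort(sprintf("%s must carry `mw_kda` and/or `sequence`.", path))
    }
    df
  }
}

#' Read a differential-expression table
#'
#' Tab-separated with header `gene_id`, `comparison`, `mean_control`,
#' `mean_kd`, `p_adj`.
#'
#' @param path File path.
#' @return Tibble in the [significant_genes()] input layout.
#' @export
read_de_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("gene_id", "comparison", "mean_control", "mean_kd",
                      "p_adj"), path)
  df
}

#' Read a transcript-level count table
#'
#' Tab-separated with header `gene_id`, `isoform_id`, `condition`,
#' `replicate`, `count`.
#'
#' @param path File path.
#' @return Tibble in the [isoform_fractions()] input layout.
#' @export
read_isoform_counts <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("gene_id", "isoform_id", "condition", "replicate",
                      "count"), path)
  df
}

#' Read a qPCR cycle-threshold table
#'
#' Tab-separated with header `sample_id`, `group`, `gene_id`, `ct`.
#'
#' @param path File path.
#' @return Tibble in the [ddct_fold()] input layout.
#' @export
read_ct_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("sample_id", "group", "gene_id", "ct"), path)
  df
}

#' Read gene-to-term annotations
#'
#' Accepts either a two-column tab-separated file (`term_id`, `gene_id`) or
#' GMT format (term, description, then member genes, tab-separated, one term
#' per line).
#'
#' @param path File path; `.gmt` extension selects the GMT parser.
#' @return Long tibble `term_id`, `gene_id`, ready for [annotation_map()].
#' @export
read_term_annotations <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readr::read_lines(path)
    purrr::map_dfr(lines[nzchar(lines)], function(line) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3) {
        abort("GMT lines need a term, a description, and at least one gene.")
      }
      tibble(term_id = parts[1], gene_id = parts[-(1:2)])
    })
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    check_columns(df, c("term_id", "gene_id"), path)
    df
  }
}

#' Read a one-ID-per-line gene list
#'
#' @param path File path; blank lines are skipped.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readr::read_lines(path))
  x[nzchar(x)]
}
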