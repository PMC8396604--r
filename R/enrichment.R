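#' Build a term-annotation map
#'
#' Normalises gene-to-term annotations into the structure used by
#' [hypergeom_enrich()]: a list of term gene sets plus a background universe.
#' Annotated genes outside a user-supplied background are dropped, terms left
#' empty are removed, and no term may exceed the background.
#'
#' @param annotations Either a data frame with columns `term_id` and
#'   `gene_id` (long format, one gene per row), or a named list of character
#'   vectors.
#' @param background Optional character vector of background gene IDs; by
#'   default the union of all annotated genes.
#'
#' @return An object of class `annotation_map`: list with `terms` (named list
#'   of gene vectors) and `background` (character vector).
#'
#' @export
annotation_map <- function(annotations, background = NULL) {
  terms <- if (is.data.frame(annotations)) {
    check_columns(annotations, c("term_id", "gene_id"), "`annotations`")
    split(as.character(annotations$gene_id), as.character(annotations$term_id))
  } else if (is.list(annotations)) {
    if (is.null(names(annotations))) abort("Annotation list must be named by term.")
    lapply(annotations, as.character)
  } else {
    abort("`annotations` must be a data frame or a named list.")
  }
  terms <- lapply(terms, unique)
  if (is.null(background)) {
    background <- unique(unlist(terms, use.names = FALSE))
  } else {
    background <- unique(as.character(background))
    if (length(background) == 0) abort("`background` must be non-empty.")
    terms <- lapply(terms, intersect, background)
  }
  terms <- terms[lengths(terms) > 0]
  structure(list(terms = terms, background = background),
            class = "annotation_map")
}

#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for over-representation in a query set against
#' a background universe, with the upper-tail hypergeometric probability
#' `P[X >= k]` (one-sided Fisher test) and Benjamini-Hochberg correction
#' across all tested terms. This is a generic over-representation statistic;
#' it makes no attempt to replicate any specific web tool's modified score.
#'
#' @param query Character vector of gene IDs. Genes outside the background
#'   are dropped with a warning.
#' @param annotations An [annotation_map()], or anything it accepts.
#' @param background Optional background passed through to [annotation_map()]
#'   when `annotations` is not already a map (e.g. [expression_floor()]
#'   output).
#' @param min_term_size Smallest in-background term size tested (default 2).
#'
#' @return Tibble of class `enrich_result`, sorted by ascending p:
#'   `term_id`, `k` (query hits in term), `K` (term size), `n` (query size),
#'   `N` (background size), `p`, `p_bh`, `neg_log10_p`.
#'
#' @examples
#' amap <- annotation_map(list(term = letters[1:5]), background = letters[1:10])
#' hypergeom_enrich(letters[1:5], amap)
#' @export
hypergeom_enrich <- function(query, annotations, background = NULL,
                             min_term_size = 2) {
  if (!inherits(annotations, "annotation_map")) {
    annotations <- annotation_map(annotations, background = background)
  }
  bg <- annotations$background
  if (length(bg) == 0) abort("Empty background.")
  query <- unique(as.character(query))
  outside <- setdiff(query, bg)
  if (length(outside) > 0) {
    warn(sprintf("%d query gene%s outside the background dropped.",
                 length(outside), if (length(outside) > 1) "s" else ""))
    query <- intersect(query, bg)
  }
  terms <- annotations$terms[lengths(annotations$terms) >= min_term_size]
  n <- length(query)
  N <- length(bg)
  res <- purrr::imap_dfr(terms, function(members, term) {
    K <- length(members)
    k <- length(intersect(query, members))
    tibble(
      term_id = term, k = k, K = K, n = n, N = N,
      # upper tail P[X >= k]
      p = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    )
  })
  if (nrow(res) == 0) {
    res <- tibble(term_id = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p = numeric())
  }
  res <- res %>%
    mutate(p_bh = bh_adjust(.data$p), neg_log10_p = -log10(.data$p)) %>%
    arrange(.data$p, .data$term_id)
  new_result(res, "enrich_result")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (wraps
#' [stats::p.adjust()] after range validation); invariant under permutation
#' of the input order and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("`p` must contain p-values in [0, 1].")
  }
  p.adjust(p, method = "BH")
}
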