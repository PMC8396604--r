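#' Relative peptide difference between bait and control co-IPs
#'
#' Scores how strongly a protein's peptide evidence favours the bait
#' co-immunoprecipitation over the IgG control. With bait count \eqn{O} and
#' control count \eqn{I}, the default score is \eqn{(O - I)/O}, clamped to
#' \[0, 1\]; a protein detected exclusively in the bait (\eqn{I = 0},
#' \eqn{O > 0}) scores 1, and a protein absent from the bait (\eqn{O = 0})
#' is undefined (`NA`). The `"control"` mode uses \eqn{(O - I)/I} instead,
#' also clamped to \[0, 1\]; both modes agree with the published peptide-count
#' tables at the conventional > 0.5 partner threshold.
#'
#' @param bait_peptides,control_peptides Non-negative integer peptide counts
#'   (distinct peptide sequences) in the bait and control co-IPs. Vectorised.
#' @param mode `"bait"` (default) divides the difference by the bait count;
#'   `"control"` divides by the control count.
#'
#' @return Numeric vector of fractions in \[0, 1\], `NA` where undefined.
#'
#' @examples
#' rel_delta(11, 5) # 0.545..., passes the > 0.5 threshold
#' rel_delta(20, 0) # exclusive detection -> 1
#' rel_delta(0, 4)  # undefined -> NA
#' @export
rel_delta <- function(bait_peptides, control_peptides, mode = c("bait", "control")) {
  mode <- arg_match(mode)
  check_nonneg(bait_peptides, "bait_peptides")
  check_nonneg(control_peptides, "control_peptides")
  n <- max(length(bait_peptides), length(control_peptides))
  o <- rep_len(as.numeric(bait_peptides), n)
  i <- rep_len(as.numeric(control_peptides), n)
  out <- rep(NA_real_, length(o))
  if (mode == "bait") {
    ok <- o > 0
    out[ok] <- (o[ok] - i[ok]) / o[ok]
  } else {
    excl <- i == 0 & o > 0
    out[excl] <- 1
    ok <- i > 0 & o > 0
    out[ok] <- (o[ok] - i[ok]) / i[ok]
    out[i > 0 & o == 0] <- 0
  }
  pmin(pmax(out, 0), 1)
}

#' Classify proteins as putative bait partners
#'
#' Applies the three-way partner triage to a bait-vs-IgG peptide-count table:
#' \describe{
#'   \item{unique}{>= 3 peptides, detected exclusively in the bait co-IP.}
#'   \item{selected}{>= 3 bait peptides, detected in the control too
#'     (`control_peptides >= 1`), and relative peptide difference > 0.5.}
#'   \item{unique_small}{small protein (<= 25 kDa) detected exclusively in
#'     the bait, regardless of peptide number.}
#' }
#' `unique` and `selected` are mutually exclusive by construction; `unique`
#' and `unique_small` can co-occur. A protein is called a partner when it
#' carries at least one flag.
#'
#' @param counts Data frame with columns `protein_id`, `structure`,
#'   `replicate`, `bait_peptides`, `control_peptides` (one row per protein per
#'   structure per replicate; a protein seen in only one co-IP carries count 0
#'   in the other).
#' @param annotations Optional data frame with `protein_id` and either
#'   `mw_kda` (kilodaltons) or `sequence` (amino acids, used via
#'   [mw_from_sequence()] when `mw_kda` is absent or missing). Without a known
#'   mass the `unique_small` flag can never fire.
#' @param rel_delta_mode Passed to [rel_delta()].
#' @param min_peptides Peptide threshold for the `unique`/`selected`
#'   criteria (default 3).
#' @param small_mw_kda Inclusive mass ceiling for `unique_small` (default 25).
#'
#' @return A tibble of class `triage_calls`: the input columns plus `mw_kda`,
#'   `rel_delta`, logical `unique`, `selected`, `unique_small`, a
#'   comma-separated `flags` string, and `is_partner`.
#'
#' @examples
#' counts <- tibble::tibble(
#'   protein_id = c("ACIN1", "EIF4A3", "RPL22"),
#'   structure = "SVZ", replicate = 1L,
#'   bait_peptides = c(3, 11, 2), control_peptides = c(0, 5, 0)
#' )
#' anno <- tibble::tibble(protein_id = "RPL22", mw_kda = 14.8)
#' classify_partners(counts, anno)
#' @export
classify_partners <- function(counts, annotations = NULL,
                              rel_delta_mode = c("bait", "control"),
                              min_peptides = 3, small_mw_kda = 25) {
  rel_delta_mode <- arg_match(rel_delta_mode)
  check_columns(counts, c("protein_id", "structure", "replicate",
                          "bait_peptides", "control_peptides"), "`counts`")
  check_nonneg(counts$bait_peptides, "bait_peptides")
  check_nonneg(counts$control_peptides, "control_peptides")

  calls <- as_tibble(counts) %>%
    mutate(mw_kda = resolve_mw(.data$protein_id, annotations)) %>%
    mutate(
      rel_delta = rel_delta(.data$bait_peptides, .data$control_peptides,
                            mode = rel_delta_mode),
      unique = .data$control_peptides == 0 & .data$bait_peptides >= min_peptides,
      selected = .data$bait_peptides >= min_peptides &
        .data$control_peptides >= 1 & .data$rel_delta > 0.5,
      unique_small = .data$control_peptides == 0 & .data$bait_peptides >= 1 &
        !is.na(.data$mw_kda) & .data$mw_kda <= small_mw_kda,
      flags = flag_string(.data$unique, .data$selected, .data$unique_small),
      is_partner = .data$unique | .data$selected | .data$unique_small
    )
  new_result(calls, "triage_calls")
}

resolve_mw <- function(protein_id, annotations) {
  if (is.null(annotations)) return(rep(NA_real_, length(protein_id)))
  check_columns(annotations, "protein_id", "`annotations`")
  anno <- as_tibble(annotations)
  if (!"mw_kda" %in% names(anno)) anno$mw_kda <- NA_real_
  if ("sequence" %in% names(anno)) {
    # mw_kda takes precedence over the sequence when both are present
    fill <- is.na(anno$mw_kda) & !is.na(anno$sequence)
    anno$mw_kda[fill] <- mw_from_sequence(anno$sequence[fill])
  }
  if (any(!is.na(anno$mw_kda) & anno$mw_kda <= 0)) {
    abort("`mw_kda` must be positive.")
  }
  anno$mw_kda[match(protein_id, anno$protein_id)]
}

flag_string <- function(unique, selected, unique_small) {
  purrr::pmap_chr(
    list(unique, selected, unique_small),
    function(u, s, us) paste(c("unique", "selected", "unique_small")[c(u, s, us)],
                             collapse = ",")
  )
}

#' Summarise partner sets per structure and replicate
#'
#' Collapses triage calls into one row per structure and replicate, with the
#' partner membership and per-category counts. The total is the size of the
#' union of the three categories; because `unique` and `unique_small` can
#' overlap, `total = n_unique + n_selected + n_unique_small - n_overlap`.
#'
#' @param calls A `triage_calls` tibble from [classify_partners()].
#'
#' @return Tibble with columns `structure`, `replicate`, `n_unique`,
#'   `n_selected`, `n_unique_small`, `n_overlap` (unique and unique_small),
#'   `total`, and a `members` list-column of partner IDs ordered by
#'   descending bait peptide count then ID.
#'
#' @export
partner_sets <- function(calls) {
  check_columns(calls, c("protein_id", "structure", "replicate", "bait_peptides",
                         "unique", "selected", "unique_small", "is_partner"),
                "`calls`")
  dup <- calls %>%
    count(.data$structure, .data$replicate, .data$protein_id) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "Duplicate protein_id within a structure/replicate (e.g. %s in %s replicate %s).",
      dup$protein_id[1], dup$structure[1], dup$replicate[1]
    ))
  }
  as_tibble(calls) %>%
    group_by(.data$structure, .data$replicate) %>%
    arrange(desc(.data$bait_peptides), .data$protein_id, .by_group = TRUE) %>%
    summarise(
      n_unique = sum(.data$unique),
      n_selected = sum(.data$selected),
      n_unique_small = sum(.data$unique_small),
      n_overlap = sum(.data$unique & .data$unique_small),
      total = sum(.data$is_partner),
      members = list(.data$protein_id[.data$is_partner]),
      .groups = "drop"
    )
}

#' Consensus partners across replicates
#'
#' Intersects the partner sets of all replicates within each structure: a
#' protein is a consensus partner only if it is called a partner in every
#' replicate of that structure.
#'
#' @param sets Output of [partner_sets()] (or any tibble with `structure`,
#'   `replicate`, and a `members` list-column).
#'
#' @return Tibble with one row per structure: `structure`,
#'   `replicate = "consensus"`, `n_replicates`, `total`, and a `members`
#'   list-column (sorted IDs).
#'
#' @export
consensus_partners <- function(sets) {
  check_columns(sets, c("structure", "replicate", "members"), "`sets`")
  if (nrow(sets) == 0) abort("`sets` must contain at least one partner set.")
  as_tibble(sets) %>%
    group_by(.data$structure) %>%
    summarise(
      replicate = "consensus",
      n_replicates = n(),
      members = list(sort(Reduce(intersect, .data$members))),
      .groups = "drop"
    ) %>%
    mutate(total = lengths(.data$members)) %>%
    select("structure", "replicate", "n_replicates", "total", "members")
}

#' Cross-structure comparison of high-confidence partners
#'
#' Applies the high-confidence filter (>= `min_peptides` bait peptides and
#' relative peptide difference > `rel_delta_cutoff`, with bait-exclusive
#' detection counting as a difference of 1) per structure, then reports which
#' proteins pass in every structure of a required subset and which of those
#' also pass in further structures. With several replicates per structure a
#' protein must pass in all of them; a protein with no record in a structure
#' is treated as 0 peptides there and fails.
#'
#' @param calls A `triage_calls` tibble from [classify_partners()] covering
#'   two or more structures.
#' @param require Character vector of structure names whose intersection is
#'   reported (e.g. `c("SVZ", "RMS", "VCx")`).
#' @param also Optional further structure names; for each, the report states
#'   which intersection members also pass there.
#' @param min_peptides,rel_delta_cutoff High-confidence filter parameters
#'   (defaults 3 and 0.5).
#'
#' @return A tibble of class `cross_structure`: `protein_id`, one logical
#'   `pass_<structure>` column per structure involved, `in_all_required`, and
#'   one `also_in_<structure>` column per `also` entry (`in_all_required` AND
#'   passing there). Rows are ordered by total bait evidence.
#'
#' @export
cross_structure <- function(calls, require, also = NULL,
                            min_peptides = 3, rel_delta_cutoff = 0.5) {
  check_columns(calls, c("protein_id", "structure", "replicate",
                         "bait_peptides", "control_peptides"), "`calls`")
  structures <- unique(as.character(calls$structure))
  asked <- c(require, also)
  unknown <- setdiff(asked, structures)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown structure name%s: %s.",
                  if (length(unknown) > 1) "s" else "",
                  paste(unknown, collapse = ", ")))
  }
  if (length(require) < 1) abort("`require` must name at least one structure.")
  if (length(unique(asked)) < 2) abort("Need at least two structures to compare.")

  df <- as_tibble(calls) %>%
    mutate(
      rd = rel_delta(.data$bait_peptides, .data$control_peptides),
      pass = .data$bait_peptides >= min_peptides &
        !is.na(.data$rd) & .data$rd > rel_delta_cutoff
    )
  # a protein absent from a structure (or a replicate of it) counts as 0/0
  grid <- tidyr::expand_grid(
    protein_id = unique(df$protein_id),
    structure = asked
  )
  per_structure <- df %>%
    filter(.data$structure %in% asked) %>%
    group_by(.data$protein_id, .data$structure) %>%
    summarise(pass = all(.data$pass),
              evidence = sum(.data$bait_peptides), .groups = "drop")
  wide <- grid %>%
    left_join(per_structure, by = c("protein_id", "structure")) %>%
    mutate(pass = !is.na(.data$pass) & .data$pass,
           evidence = ifelse(is.na(.data$evidence), 0, .data$evidence))
  evidence <- wide %>%
    group_by(.data$protein_id) %>%
    summarise(evidence = sum(.data$evidence), .groups = "drop")
  wide <- wide %>%
    select(-"evidence") %>%
    tidyr::pivot_wider(names_from = "structure", values_from = "pass",
                       names_prefix = "pass_")
  wide$in_all_required <- Reduce(
    `&`, lapply(paste0("pass_", require), function(cn) wide[[cn]])
  )
  for (s in also) {
    wide[[paste0("also_in_", s)]] <- wide$in_all_required & wide[[paste0("pass_", s)]]
  }
  out <- wide %>%
    left_join(evidence, by = "protein_id") %>%
    arrange(desc(.data$in_all_required), desc(.data$evidence), .data$protein_id) %>%
    select(-"evidence")
  attr(out, "require") <- require
  attr(out, "also") <- also
  new_result(out, "cross_structure")
}
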