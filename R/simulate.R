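# Seeded generators with planted ground truth for every pipeline input.
# All generators are pure functions of (spec, seed): the same seed reproduces
# the same tables, and truth tables cross-reference the data by ID.

#' Specification for a simulated co-IP peptide-count experiment
#'
#' Defines the planted composition of a bait-vs-IgG co-IP screen: true
#' partners exclusive to the bait, symmetric background contaminants detected
#' in both co-IPs, and small bait-exclusive proteins below the 25 kDa
#' criterion. Peptide counts are Poisson around the stated class means;
#' molecular weights are log-normal with the small class forced below
#' `small_mw_kda`. Defaults mirror a choroid-plexus screen with three
#' replicate experiments and a consensus of 60 partners.
#'
#' @param n_true_partners,n_contaminants,n_small_exclusive Class sizes.
#' @param bait_mean_partner Mean bait peptide count for true partners
#'   (must give >= 3 peptides in expectation; default 8).
#' @param contaminant_mean Mean peptide count in *both* co-IPs for
#'   contaminants (symmetric background, relative difference ~ 0).
#' @param bait_mean_small Mean bait count for small exclusive proteins
#'   (default 2, below the 3-peptide rule so only the mass criterion fires).
#' @param small_mw_kda Mass ceiling for the small class (default 25).
#' @param mw_meanlog,mw_sdlog Log-normal molecular-weight parameters for the
#'   non-small classes (default median ~ 50 kDa).
#' @param n_replicates Number of replicate experiments (default 3).
#' @param structure Structure label stamped on the output (default "ChP").
#'
#' @return Object of class `triage_sim_spec`.
#' @export
triage_sim_spec <- function(n_true_partners = 60, n_contaminants = 300,
                            n_small_exclusive = 30, bait_mean_partner = 8,
                            contaminant_mean = 10, bait_mean_small = 2,
                            small_mw_kda = 25, mw_meanlog = log(50),
                            mw_sdlog = 0.5, n_replicates = 3,
                            structure = "ChP") {
  spec <- list(
    n_true_partners = check_count_scalar(n_true_partners, "n_true_partners"),
    n_contaminants = check_count_scalar(n_contaminants, "n_contaminants"),
    n_small_exclusive = check_count_scalar(n_small_exclusive, "n_small_exclusive"),
    bait_mean_partner = bait_mean_partner,
    contaminant_mean = contaminant_mean,
    bait_mean_small = bait_mean_small,
    small_mw_kda = small_mw_kda,
    mw_meanlog = mw_meanlog, mw_sdlog = mw_sdlog,
    n_replicates = check_count_scalar(n_replicates, "n_replicates", min = 1),
    structure = structure
  )
  if (bait_mean_partner < 3) abort("`bait_mean_partner` must be >= 3.")
  if (bait_mean_small < 1) abort("`bait_mean_small` must be >= 1.")
  structure(spec, class = "triage_sim_spec")
}

#' Simulate a bait-vs-IgG co-IP peptide-count table
#'
#' Draws peptide counts for the classes planted in a [triage_sim_spec()]:
#' true partners (bait-only Poisson counts truncated to >= 1), contaminants
#' (independent Poisson counts with the same mean in both co-IPs), and small
#' exclusive proteins. In `noise_free` mode every count is fixed at its class
#' mean, so the triage recovers the planted classes exactly.
#'
#' @param spec A [triage_sim_spec()].
#' @param seed Integer seed; the output is a pure function of (spec, seed).
#' @param noise_free Use deterministic class-mean counts (default `FALSE`)?
#'
#' @return List with `counts` (tibble `protein_id`, `structure`, `replicate`,
#'   `bait_peptides`, `control_peptides`), `annotations` (`protein_id`,
#'   `mw_kda`), and `truth` (`protein_id`, `class`, `is_partner`).
#'
#' @export
simulate_coip <- function(spec, seed, noise_free = FALSE) {
  stopifnot(inherits(spec, "triage_sim_spec"))
  withr::with_seed(as.integer(seed), {
    classes <- rep(c("true_partner", "contaminant", "small_exclusive"),
                   c(spec$n_true_partners, spec$n_contaminants,
                     spec$n_small_exclusive))
    n <- length(classes)
    ids <- sprintf("P%04d", seq_len(n))
    mw <- rlnorm(n, spec$mw_meanlog, spec$mw_sdlog)
    small <- classes == "small_exclusive"
    # small class forced under the mass ceiling; others forced above it so the
    # planted classes stay disjoint
    mw[small] <- runif(sum(small), 5, spec$small_mw_kda)
    mw[!small] <- pmax(mw[!small], spec$small_mw_kda + 5)

    bait_mean <- c(true_partner = spec$bait_mean_partner,
                   contaminant = spec$contaminant_mean,
                   small_exclusive = spec$bait_mean_small)[classes]
    ctrl_mean <- ifelse(classes == "contaminant", spec$contaminant_mean, 0)

    counts <- purrr::map_dfr(seq_len(spec$n_replicates), function(rep) {
      if (noise_free) {
        bait <- round(bait_mean)
        ctrl <- round(ctrl_mean)
      } else {
        bait <- pmax(rpois(n, bait_mean), 1) # planted proteins were detected
        ctrl <- rpois(n, ctrl_mean)
      }
      tibble(protein_id = ids, structure = spec$structure, replicate = rep,
             bait_peptides = bait, control_peptides = ctrl)
    })
    list(
      counts = counts,
      annotations = tibble(protein_id = ids, mw_kda = mw),
      truth = tibble(protein_id = ids, class = classes,
                     is_partner = classes != "contaminant")
    )
  })
}

#' Specification for simulated differential-expression tables
#'
#' Plants a consensus of direction-consistent significant genes across three
#' knockdown comparisons, plus comparison-specific significant genes, on a
#' log-normal baseline of mean reads. Adjusted p-values are generated
#' directly (significant genes uniform below `alpha`, null genes at or above
#' it), since the tables consumed by the pipeline carry facility-computed
#' p-values. Defaults mirror the study conditions: comparisons `LV_cond`,
#' `FourV_cond`, `FourV_GFP` with 375, 808, and 528 significant genes
#' respectively, of which 42 up + 34 down are consensus.
#'
#' @param n_genes Total genes (default 15000).
#' @param n_consensus_up,n_consensus_down Consensus list sizes (defaults 42
#'   and 34).
#' @param comparisons Comparison labels (3 by default).
#' @param n_sig_per_comparison Total significant genes per comparison
#'   (consensus included); defaults `c(375, 808, 528)`.
#' @param n_discordant Genes significant in all comparisons with conflicting
#'   directions (default 0).
#' @param baseline_meanlog,baseline_sdlog Log-normal mean-read parameters
#'   (default median ~ 300 reads).
#' @param fold_meanlog,fold_sdlog Log-normal fold-effect magnitude for
#'   significant genes, floored at 1.2 (default median ~ 3).
#' @param alpha Significance boundary used to assign p-values (default 0.05).
#'
#' @return Object of class `de_sim_spec`.
#' @export
de_sim_spec <- function(n_genes = 15000, n_consensus_up = 42,
                        n_consensus_down = 34,
                        comparisons = c("LV_cond", "FourV_cond", "FourV_GFP"),
                        n_sig_per_comparison = c(375, 808, 528),
                        n_discordant = 0,
                        baseline_meanlog = log(300), baseline_sdlog = 1.5,
                        fold_meanlog = log(3), fold_sdlog = 0.5,
                        alpha = 0.05) {
  if (length(comparisons) < 2) abort("Need at least two comparisons.")
  if (length(n_sig_per_comparison) != length(comparisons)) {
    abort("`n_sig_per_comparison` must match `comparisons` in length.")
  }
  n_consensus <- n_consensus_up + n_consensus_down + n_discordant
  if (any(n_sig_per_comparison < n_consensus)) {
    abort("Each comparison must allow at least the consensus genes.")
  }
  if (n_genes < n_consensus + sum(n_sig_per_comparison - n_consensus)) {
    abort("`n_genes` too small for the planted gene classes.")
  }
  structure(
    list(n_genes = check_count_scalar(n_genes, "n_genes"),
         n_consensus_up = check_count_scalar(n_consensus_up, "n_consensus_up"),
         n_consensus_down = check_count_scalar(n_consensus_down, "n_consensus_down"),
         comparisons = comparisons,
         n_sig_per_comparison = setNames(n_sig_per_comparison, comparisons),
         n_discordant = check_count_scalar(n_discordant, "n_discordant"),
         baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
         fold_meanlog = fold_meanlog, fold_sdlog = fold_sdlog,
         alpha = alpha),
    class = "de_sim_spec"
  )
}

#' Simulate differential-expression result tables
#'
#' Generates one table per comparison in the [de_sim_spec()] layout:
#' consensus genes receive a consistent direction and a significant adjusted
#' p-value in every comparison; comparison-specific genes are significant in
#' exactly one comparison; discordant genes (if any) are significant
#' everywhere with the direction flipped in the last comparison; all other
#' genes stay null (fold near 1, p_adj >= alpha).
#'
#' @param spec A [de_sim_spec()].
#' @param seed Integer seed.
#'
#' @return List with `de` (tibble `gene_id`, `comparison`, `mean_control`,
#'   `mean_kd`, `p_adj`) and `truth` (`gene_id`, `role`, `direction`).
#'
#' @export
simulate_de <- function(spec, seed) {
  stopifnot(inherits(spec, "de_sim_spec"))
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("g%05d", seq_len(spec$n_genes))
    n_cons <- spec$n_consensus_up + spec$n_consensus_down + spec$n_discordant
    role <- rep("null", spec$n_genes)
    direction <- rep(NA_character_, spec$n_genes)
    i <- 0
    take <- function(k) {
      out <- seq_len(k) + i
      i <<- i + k
      out
    }
    up_idx <- take(spec$n_consensus_up)
    down_idx <- take(spec$n_consensus_down)
    disc_idx <- take(spec$n_discordant)
    role[up_idx] <- "consensus_up"; direction[up_idx] <- "up"
    role[down_idx] <- "consensus_down"; direction[down_idx] <- "down"
    role[disc_idx] <- "discordant"
    extra_idx <- lapply(spec$comparisons, function(cmp) {
      k <- spec$n_sig_per_comparison[[cmp]] - n_cons
      idx <- take(k)
      role[idx] <<- paste0("extra_", cmp)
      idx
    })
    names(extra_idx) <- spec$comparisons

    baseline <- rlnorm(spec$n_genes, spec$baseline_meanlog, spec$baseline_sdlog)
    de <- purrr::imap_dfr(setNames(nm = spec$comparisons), function(cmp, nm) {
      last <- cmp == spec$comparisons[length(spec$comparisons)]
      sig <- rep(FALSE, spec$n_genes)
      sig[c(up_idx, down_idx, disc_idx, extra_idx[[cmp]])] <- TRUE
      dir <- direction
      dir[disc_idx] <- if (last) "down" else "up"
      dir[extra_idx[[cmp]]] <- sample(c("up", "down"),
                                      length(extra_idx[[cmp]]), replace = TRUE)
      effect <- pmax(rlnorm(spec$n_genes, spec$fold_meanlog, spec$fold_sdlog), 1.2)
      # null genes wobble within +/- 10%, never crossing the fold = 1 line
      # in a way that matters because their p_adj is never significant
      wobble <- runif(spec$n_genes, 0.9, 1.1)
      mean_kd <- ifelse(!sig, baseline * wobble,
                        ifelse(dir == "up", baseline * effect, baseline / effect))
      p_adj <- ifelse(sig, runif(spec$n_genes, 0, spec$alpha * 0.98),
                      runif(spec$n_genes, spec$alpha, 1))
      tibble(gene_id = ids, comparison = cmp,
             mean_control = baseline, mean_kd = mean_kd, p_adj = p_adj)
    })
    list(de = de, truth = tibble(gene_id = ids, role = role,
                                 direction = direction))
  })
}

#' Specification for simulated transcript-level counts
#'
#' Plants isoform switches of a chosen usage difference (dIF) among genes
#' with multinomial transcript counts. For a switch gene two focal isoforms
#' exchange exactly `target_dif` of usage between conditions; remaining
#' isoforms keep a fixed residual share. Defaults mirror a two-replicate
#' RNA-seq design with 1000 reads per gene and condition and a planted dIF
#' of 0.30.
#'
#' @param n_genes Genes simulated (default 50).
#' @param n_switch_genes Genes with a planted switch (default 4).
#' @param isoforms_per_gene Isoforms per gene (>= 2, default 3).
#' @param target_dif Planted usage difference on the focal isoform pair
#'   (default 0.30; must leave valid fractions given `focal_share`).
#' @param focal_share Combined usage of the two focal isoforms in switch
#'   genes (default 0.9; the rest is split evenly among other isoforms).
#' @param reads_per_gene Sequencing depth per gene per condition per
#'   replicate (default 1000).
#' @param n_replicates Replicates per condition (default 2).
#' @param dirichlet_precision Overdispersion control: finite values draw each
#'   replicate's isoform proportions from a Dirichlet with this precision
#'   around the planted fractions; `Inf` (default) uses pure multinomial
#'   sampling.
#'
#' @return Object of class `isoform_sim_spec`.
#' @export
isoform_sim_spec <- function(n_genes = 50, n_switch_genes = 4,
                             isoforms_per_gene = 3, target_dif = 0.30,
                             focal_share = 0.9, reads_per_gene = 1000,
                             n_replicates = 2, dirichlet_precision = Inf) {
  if (isoforms_per_gene < 2) abort("`isoforms_per_gene` must be >= 2.")
  if (n_switch_genes > n_genes) abort("`n_switch_genes` exceeds `n_genes`.")
  if (isoforms_per_gene == 2) focal_share <- 1
  if (target_dif >= focal_share || target_dif < 0) {
    abort("`target_dif` must lie in [0, focal_share).")
  }
  structure(
    list(n_genes = check_count_scalar(n_genes, "n_genes", min = 1),
         n_switch_genes = check_count_scalar(n_switch_genes, "n_switch_genes"),
         isoforms_per_gene = check_count_scalar(isoforms_per_gene,
                                                "isoforms_per_gene", min = 2),
         target_dif = target_dif, focal_share = focal_share,
         reads_per_gene = check_count_scalar(reads_per_gene, "reads_per_gene",
                                             min = 1),
         n_replicates = check_count_scalar(n_replicates, "n_replicates", min = 1),
         dirichlet_precision = dirichlet_precision),
    class = "isoform_sim_spec"
  )
}

#' Simulate transcript-level counts with planted isoform switches
#'
#' Draws multinomial (optionally Dirichlet-multinomial) transcript counts
#' around planted per-condition isoform fractions. In `deterministic` mode
#' counts equal their expectations (`reads * fraction`, real-valued), so
#' [isoform_fractions()] returns exactly the planted fractions.
#'
#' @param spec An [isoform_sim_spec()].
#' @param seed Integer seed.
#' @param deterministic Use expected counts instead of sampling (default
#'   `FALSE`)?
#'
#' @return List with `counts` (tibble `gene_id`, `isoform_id`, `condition`,
#'   `replicate`, `count`) and `truth` (per gene and isoform: planted
#'   `if_control`, `if_kd`, `dif`, `is_switch`).
#'
#' @export
simulate_isoforms <- function(spec, seed, deterministic = FALSE) {
  stopifnot(inherits(spec, "isoform_sim_spec"))
  withr::with_seed(as.integer(seed), {
    k <- spec$isoforms_per_gene
    genes <- sprintf("g%03d", seq_len(spec$n_genes))
    is_switch_gene <- seq_len(spec$n_genes) <= spec$n_switch_genes

    plan <- purrr::map_dfr(seq_len(spec$n_genes), function(gi) {
      if (is_switch_gene[gi]) {
        s <- spec$focal_share
        d <- spec$target_dif
        rest <- if (k > 2) rep((1 - s) / (k - 2), k - 2) else numeric(0)
        if_control <- c((s - d) / 2, (s + d) / 2, rest)
        if_kd <- c((s + d) / 2, (s - d) / 2, rest)
      } else {
        # random but condition-identical usage (Dirichlet(2,...,2))
        g <- rgamma(k, shape = 2)
        if_control <- if_kd <- g / sum(g)
      }
      tibble(gene_id = genes[gi], isoform_id = paste0(genes[gi], "_i", seq_len(k)),
             if_control = if_control, if_kd = if_kd,
             dif = if_kd - if_control,
             is_switch = is_switch_gene[gi] & abs(if_kd - if_control) > 0)
    })

    draw <- function(prob, reads) {
      if (deterministic) return(reads * prob)
      if (is.finite(spec$dirichlet_precision)) {
        g <- rgamma(length(prob), shape = spec$dirichlet_precision * prob)
        prob <- if (sum(g) > 0) g / sum(g) else prob
      }
      as.numeric(rmultinom(1, size = reads, prob = prob))
    }
    counts <- purrr::map_dfr(c("control", "knockdown"), function(cond) {
      purrr::map_dfr(seq_len(spec$n_replicates), function(rep) {
        plan %>%
          group_by(.data$gene_id) %>%
          mutate(
            condition = cond, replicate = rep,
            count = draw(if (cond == "control") .data$if_control else .data$if_kd,
                         spec$reads_per_gene)
          ) %>%
          ungroup() %>%
          select("gene_id", "isoform_id", "condition", "replicate", "count")
      })
    })
    list(counts = counts, truth = plan)
  })
}
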