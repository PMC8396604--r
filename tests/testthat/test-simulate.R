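test_that("generators are pure functions of spec and seed", {
  tsp <- triage_sim_spec(n_true_partners = 10, n_contaminants = 30,
                         n_small_exclusive = 5, n_replicates = 2)
  expect_identical(simulate_coip(tsp, seed = 1), simulate_coip(tsp, seed = 1))
  expect_false(identical(simulate_coip(tsp, seed = 1)$counts,
                         simulate_coip(tsp, seed = 2)$counts))

  dsp <- de_sim_spec(n_genes = 100, n_consensus_up = 3, n_consensus_down = 2,
                     n_sig_per_comparison = c(8, 9, 10))
  expect_identical(simulate_de(dsp, seed = 4), simulate_de(dsp, seed = 4))
  expect_false(identical(simulate_de(dsp, seed = 4)$de,
                         simulate_de(dsp, seed = 5)$de))

  isp <- isoform_sim_spec(n_genes = 6, n_switch_genes = 2)
  expect_identical(simulate_isoforms(isp, seed = 6),
                   simulate_isoforms(isp, seed = 6))
  expect_false(identical(simulate_isoforms(isp, seed = 6)$counts,
                         simulate_isoforms(isp, seed = 7)$counts))
})

test_that("truth tables cross-reference the data with no orphans", {
  co <- simulate_coip(triage_sim_spec(n_true_partners = 8, n_contaminants = 20,
                                      n_small_exclusive = 4), seed = 9)
  expect_setequal(unique(co$counts$protein_id), co$truth$protein_id)
  expect_setequal(co$annotations$protein_id, co$truth$protein_id)

  de <- simulate_de(de_sim_spec(n_genes = 120, n_consensus_up = 4,
                                n_consensus_down = 4,
                                n_sig_per_comparison = c(10, 10, 10)), seed = 9)
  expect_setequal(unique(de$de$gene_id), de$truth$gene_id)

  iso <- simulate_isoforms(isoform_sim_spec(n_genes = 5, n_switch_genes = 1),
                           seed = 9)
  expect_setequal(unique(iso$counts$isoform_id), iso$truth$isoform_id)
})

test_that("noise-free co-IP simulations are recovered exactly by the triage", {
  spec <- triage_sim_spec(n_true_partners = 25, n_contaminants = 60,
                          n_small_exclusive = 10, n_replicates = 3)
  sim <- simulate_coip(spec, seed = 10, noise_free = TRUE)
  calls <- classify_partners(sim$counts, sim$annotations)
  cons <- consensus_partners(partner_sets(calls))
  planted <- sim$truth$protein_id[sim$truth$is_partner]
  expect_setequal(cons$members[[1]], planted)
})

test_that("an empty partner class yields an empty consensus", {
  spec <- triage_sim_spec(n_true_partners = 0, n_contaminants = 40,
                          n_small_exclusive = 0, n_replicates = 2)
  sim <- simulate_coip(spec, seed = 12, noise_free = TRUE)
  cons <- consensus_partners(partner_sets(classify_partners(sim$counts,
                                                            sim$annotations)))
  expect_equal(cons$total, 0)
})

test_that("contaminants stay near symmetric and partners bait-heavy", {
  sim <- simulate_coip(triage_sim_spec(n_true_partners = 50,
                                       n_contaminants = 200,
                                       n_small_exclusive = 0,
                                       n_replicates = 1), seed = 13)
  joined <- dplyr::inner_join(sim$counts, sim$truth, by = "protein_id")
  cont <- joined[joined$class == "contaminant", ]
  expect_equal(mean(cont$bait_peptides), mean(cont$control_peptides),
               tolerance = 0.15)
  part <- joined[joined$class == "true_partner", ]
  expect_true(all(part$control_peptides == 0))
  expect_gt(mean(part$bait_peptides), 3)
})

test_that("planted DE consensus and discordant genes behave as constructed", {
  spec <- de_sim_spec(n_genes = 400, n_consensus_up = 7, n_consensus_down = 5,
                      n_sig_per_comparison = c(40, 50, 30), n_discordant = 3)
  sim <- simulate_de(spec, seed = 15)
  cg <- consensus_genes(sim$de)
  expect_setequal(cg$up, sim$truth$gene_id[sim$truth$role == "consensus_up"])
  expect_setequal(cg$down, sim$truth$gene_id[sim$truth$role == "consensus_down"])
  expect_setequal(cg$discordant,
                  sim$truth$gene_id[sim$truth$role == "discordant"])
})

test_that("all-null DE simulations give an empty consensus", {
  spec <- de_sim_spec(n_genes = 150, n_consensus_up = 0, n_consensus_down = 0,
                      n_sig_per_comparison = c(0, 0, 0))
  sim <- simulate_de(spec, seed = 16)
  expect_equal(nrow(significant_genes(sim$de)), 0)
  cg <- suppressWarnings(consensus_genes(sim$de,
                                         require = unique(sim$de$comparison)))
  expect_equal(length(cg$up) + length(cg$down), 0)
})

test_that("deterministic isoform counts reproduce the planted fractions", {
  spec <- isoform_sim_spec(n_genes = 6, n_switch_genes = 2, target_dif = 0.25)
  sim <- simulate_isoforms(spec, seed = 18, deterministic = TRUE)
  fr <- isoform_fractions(sim$counts)
  joined <- dplyr::inner_join(fr, sim$truth, by = c("gene_id", "isoform_id"))
  ctrl <- joined[joined$condition == "control", ]
  kd <- joined[joined$condition == "knockdown", ]
  expect_equal(ctrl$frac, ctrl$if_control, tolerance = 1e-12)
  expect_equal(kd$frac, kd$if_kd, tolerance = 1e-12)
  # planted dIF achieved exactly on the focal pair
  expect_setequal(round(sim$truth$dif[sim$truth$is_switch], 10), c(0.25, -0.25))
})

test_that("overdispersed isoform draws still centre on the planted fractions", {
  spec <- isoform_sim_spec(n_genes = 1, n_switch_genes = 0,
                           reads_per_gene = 2000, n_replicates = 50,
                           dirichlet_precision = 50)
  sim <- simulate_isoforms(spec, seed = 20)
  fr <- isoform_fractions(sim$counts)
  joined <- dplyr::inner_join(fr, sim$truth, by = c("gene_id", "isoform_id"))
  expect_equal(joined$frac, joined$if_control, tolerance = 0.08)
})

test_that("spec constructors validate their planted composition", {
  expect_error(triage_sim_spec(bait_mean_partner = 2), ">= 3")
  expect_error(de_sim_spec(n_genes = 10, n_consensus_up = 8,
                           n_consensus_down = 8,
                           n_sig_per_comparison = c(20, 20, 20)),
               "too small")
  expect_error(de_sim_spec(n_sig_per_comparison = c(10, 10, 10)),
               "at least the consensus")
  expect_error(isoform_sim_spec(target_dif = 0.95), "focal_share")
  expect_error(isoform_sim_spec(isoforms_per_gene = 1), ">= 2")
})
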