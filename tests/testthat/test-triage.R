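test_that("rel_delta matches hand-computed fractions and handles exclusivity", {
  expect_equal(rel_delta(11, 5), (11 - 5) / 11, tolerance = 1e-12)
  expect_gt(rel_delta(11, 5), 0.5)
  expect_equal(rel_delta(13, 6), (13 - 6) / 13, tolerance = 1e-12)
  expect_equal(rel_delta(c(1, 5, 20), 0), c(1, 1, 1))
  expect_true(is.na(rel_delta(0, 4)))
  expect_true(is.na(rel_delta(0, 0)))
  expect_equal(rel_delta(3, 7), 0) # negative difference clamps to zero
  expect_error(rel_delta(-1, 0), "non-negative")
})

test_that("rel_delta control-denominator mode agrees at the 0.5 threshold", {
  expect_equal(rel_delta(4, 3, mode = "control"), 1 / 3, tolerance = 1e-12)
  expect_equal(rel_delta(11, 5, mode = "control"), 1) # (O-I)/I capped at 1
  expect_equal(rel_delta(7, 0, mode = "control"), 1)
  expect_equal(rel_delta(0, 3, mode = "control"), 0)
  # both modes agree on >0.5 for every printed-style count pair
  for (o in 0:15) for (i in 0:15) {
    b <- rel_delta(o, i)
    cmode <- rel_delta(o, i, mode = "control")
    if (!is.na(b) && o > 2 * i) {
      expect_true(b > 0.5 && cmode > 0.5)
    }
  }
})

test_that("classify_partners applies the three partner criteria", {
  counts <- coip_table(
    bait = c(3, 11, 2, 4, 2, 3),
    control = c(0, 5, 0, 2, 1, 0),
    ids = c("ACIN1", "EIF4A3", "SMALL", "BOUND", "LOWEV", "SMALLBIG")
  )
  anno <- tibble::tibble(
    protein_id = c("ACIN1", "SMALL", "BOUND", "SMALLBIG"),
    mw_kda = c(151.8, 18, 100, 20)
  )
  calls <- classify_partners(counts, anno)
  get <- function(id) calls[calls$protein_id == id, ]
  expect_equal(get("ACIN1")$flags, "unique")
  expect_equal(get("EIF4A3")$flags, "selected")
  expect_equal(get("SMALL")$flags, "unique_small")
  expect_equal(get("BOUND")$flags, "") # rel_delta exactly 0.5, strict >
  expect_false(get("BOUND")$is_partner)
  expect_equal(get("LOWEV")$flags, "") # 2 peptides, detected in control
  # >= 3 peptides, exclusive, and small: unique and unique_small co-occur
  expect_equal(get("SMALLBIG")$flags, "unique,unique_small")
  expect_error(classify_partners(dplyr::mutate(counts, bait_peptides = -1)),
               "non-negative")
})

test_that("mass boundary is inclusive and unknown mass disables unique_small", {
  counts <- coip_table(c(1, 1, 1), 0, ids = c("at25", "above", "nomw"))
  anno <- tibble::tibble(protein_id = c("at25", "above"), mw_kda = c(25, 25.01))
  calls <- classify_partners(counts, anno)
  expect_true(calls$unique_small[calls$protein_id == "at25"])
  expect_false(calls$unique_small[calls$protein_id == "above"])
  expect_false(calls$unique_small[calls$protein_id == "nomw"])
})

test_that("annotation mw_kda takes precedence over sequence", {
  counts <- coip_table(1, 0, ids = "p1")
  anno <- tibble::tibble(protein_id = "p1", mw_kda = 60,
                         sequence = "GG") # sequence would say tiny
  calls <- classify_partners(counts, anno)
  expect_equal(calls$mw_kda, 60)
  anno2 <- tibble::tibble(protein_id = "p1", mw_kda = NA_real_, sequence = "GG")
  calls2 <- classify_partners(counts, anno2)
  expect_equal(calls2$mw_kda, mw_from_sequence("GG"))
})

test_that("partner_sets counts categories and their union", {
  counts <- coip_table(c(3, 4, 1), c(0, 2, 0), ids = c("a", "b", "c"))
  anno <- tibble::tibble(protein_id = c("a", "b", "c"), mw_kda = c(100, 100, 20))
  sets <- partner_sets(classify_partners(counts, anno))
  expect_equal(sets$total, 2)
  expect_equal(sets$n_unique, 1)
  expect_equal(sets$n_selected, 0)
  expect_equal(sets$n_unique_small, 1)
  expect_setequal(sets$members[[1]], c("a", "c"))
})

test_that("partner_sets rejects duplicates and handles empty input", {
  counts <- coip_table(c(3, 4), c(0, 0), ids = c("a", "a"))
  expect_error(partner_sets(classify_partners(counts)), "Duplicate")
  empty <- classify_partners(coip_table(numeric(0), numeric(0), ids = character(0)))
  expect_equal(nrow(partner_sets(empty)), 0)
})

test_that("total equals the category inclusion-exclusion identity", {
  # mirrors the published bookkeeping, e.g. 17 + 6 + 31 with overlap 2 -> 52
  sim <- simulate_coip(triage_sim_spec(n_true_partners = 40, n_contaminants = 100,
                                       n_small_exclusive = 25, n_replicates = 2),
                       seed = 11)
  sets <- partner_sets(classify_partners(sim$counts, sim$annotations))
  expect_true(all(sets$total ==
    sets$n_unique + sets$n_selected + sets$n_unique_small - sets$n_overlap))
})

test_that("consensus is the strict replicate intersection", {
  sets <- tibble::tibble(
    structure = "ChP", replicate = 1:3,
    members = list(c("A", "B", "C"), c("B", "C"), c("C", "B", "D"))
  )
  cons <- consensus_partners(sets)
  expect_equal(cons$members[[1]], c("B", "C"))
  expect_equal(cons$replicate, "consensus")
  # identity on a single set
  single <- consensus_partners(sets[1, ])
  expect_setequal(single$members[[1]], c("A", "B", "C"))
  # disjoint sets
  disj <- consensus_partners(tibble::tibble(
    structure = "ChP", replicate = 1:2, members = list("A", "B")
  ))
  expect_equal(disj$total, 0)
})

test_that("consensus is a subset of every input and idempotent", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      sets <- tibble::tibble(
        structure = "SVZ", replicate = 1:3,
        members = lapply(1:3, function(i) sample(letters, sample(5:20, 1)))
      )
      cons <- consensus_partners(sets)
      for (m in sets$members) {
        expect_true(all(cons$members[[1]] %in% m))
      }
      again <- consensus_partners(dplyr::mutate(cons, replicate = 1L))
      expect_equal(again$members, cons$members)
    }
  })
})

test_that("increasing bait evidence never demotes a partner", {
  for (i in c(0, 1, 4)) {
    for (mw in c(NA, 15, 80)) {
      partner_seen <- FALSE
      for (o in 0:25) {
        counts <- coip_table(o, i, ids = "p")
        anno <- if (is.na(mw)) NULL else tibble::tibble(protein_id = "p", mw_kda = mw)
        now <- classify_partners(counts, anno)$is_partner
        expect_false(partner_seen && !now,
                     label = sprintf("monotonicity at O=%d I=%d mw=%s", o, i, mw))
        partner_seen <- partner_seen || now
      }
    }
  }
})

test_that("partner calls agree with the exhaustive rule oracle", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      n <- sample(1:20, 1)
      bait <- rpois(n, 4)
      control <- rpois(n, 2)
      mw <- ifelse(runif(n) < 0.3, runif(n, 5, 25), runif(n, 26, 200))
      mw[runif(n) < 0.2] <- NA
      counts <- coip_table(bait, control)
      anno <- tibble::tibble(protein_id = counts$protein_id, mw_kda = mw)
      calls <- classify_partners(counts, anno)
      for (j in seq_len(n)) {
        expected <- triage_oracle(bait[j], control[j], mw[j])
        got <- setdiff(strsplit(calls$flags[j], ",")[[1]], "")
        expect_setequal(got, expected)
      }
    }
  })
})

test_that("cross_structure validates structure names and input size", {
  counts <- coip_table(c(5, 5), 0, ids = c("a", "b"), structure = "SVZ")
  calls <- classify_partners(counts)
  expect_error(cross_structure(calls, require = c("SVZ", "XXX")), "Unknown structure")
  expect_error(cross_structure(calls, require = "SVZ"), "at least two")
})

test_that("cross_structure reports shared and exclusive proteins", {
  counts <- dplyr::bind_rows(
    coip_table(c(5, 5), 0, ids = c("a", "b"), structure = "SVZ"),
    coip_table(c(5, 2), 0, ids = c("a", "b"), structure = "RMS")
  )
  cs <- cross_structure(classify_partners(counts), require = c("SVZ", "RMS"))
  expect_equal(cs$protein_id[cs$in_all_required], "a")
  # b passes only in SVZ: reported, not shared
  expect_true(cs$pass_SVZ[cs$protein_id == "b"])
  expect_false(cs$pass_RMS[cs$protein_id == "b"])
  # identical sets: intersection is the whole set
  counts2 <- dplyr::bind_rows(
    coip_table(c(5, 6), 0, ids = c("a", "b"), structure = "SVZ"),
    coip_table(c(5, 6), 0, ids = c("a", "b"), structure = "RMS")
  )
  cs2 <- cross_structure(classify_partners(counts2), require = c("SVZ", "RMS"))
  expect_true(all(cs2$in_all_required))
})

test_that("exclusivity counts as full relative difference in the filter", {
  # a bait-exclusive protein passes the high-confidence filter like a 100%
  # relative-difference protein would
  counts <- dplyr::bind_rows(
    coip_table(20, 0, ids = "excl", structure = "SVZ"),
    coip_table(20, 0, ids = "excl", structure = "RMS")
  )
  cs <- cross_structure(classify_partners(counts), require = c("SVZ", "RMS"))
  expect_true(cs$in_all_required)
})
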