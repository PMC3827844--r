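test_that("high-PCS selection flags the ceil-rounded top fraction per platform", {
  recs <- tibble::tibble(
    probe_id = sprintf("p%03d", 1:100),
    gene_symbol = sprintf("G%03d", 1:100),
    platform_id = "AFFY",
    pcs = seq(100, 1),
    direction = 1,
    mean_intensity = 1000,
    n_comparisons = 3L,
    passed_intensity_filter = TRUE
  )
  out <- select_high_pcs(recs, 0.10)
  expect_equal(sum(out$high_pcs), 10L)
  expect_setequal(out$probe_id[out$high_pcs], sprintf("p%03d", 1:10))

  all_flagged <- select_high_pcs(recs, 1.0)
  expect_true(all(all_flagged$high_pcs))

  ties <- recs
  ties$pcs <- 5
  out_tie <- select_high_pcs(ties, 0.10)
  expect_setequal(out_tie$probe_id[out_tie$high_pcs], sprintf("p%03d", 1:10))

  # probes outside the intensity filter are never flagged
  recs$passed_intensity_filter[1:50] <- FALSE
  out2 <- select_high_pcs(recs, 0.10)
  expect_equal(sum(out2$high_pcs), 5L)
  expect_false(any(out2$high_pcs[1:50]))
  expect_error(select_high_pcs(recs[0, ]), "empty")
})

test_that("the six constructed probe configurations yield the stated tiers", {
  recs <- tier_records(
    # 1. two same-platform probes, both down -> Tier 2 via T2a
    list(probe_id = "a1", gene = "G1", platform = "AFFY", direction = -1),
    list(probe_id = "a2", gene = "G1", platform = "AFFY", direction = -1),
    # 2. one Illumina + two Affymetrix probes, all up -> Tier 1 via T1a
    list(probe_id = "a3", gene = "G2", platform = "AFFY", direction = 1),
    list(probe_id = "a4", gene = "G2", platform = "AFFY", direction = 1),
    list(probe_id = "i1", gene = "G2", platform = "ILMN", direction = 1),
    # 3. two same-platform probes, opposite directions -> not Tier 2
    list(probe_id = "a5", gene = "G3", platform = "AFFY", direction = 1),
    list(probe_id = "a6", gene = "G3", platform = "AFFY", direction = -1),
    # 4. three same-platform probes, concordant -> Tier 1 via T1c
    list(probe_id = "a7", gene = "G4", platform = "AFFY", direction = -1),
    list(probe_id = "a8", gene = "G4", platform = "AFFY", direction = -1),
    list(probe_id = "a9", gene = "G4", platform = "AFFY", direction = -1),
    # 5. one probe on each platform, concordant -> Tier 2 via T2b
    list(probe_id = "a10", gene = "G5", platform = "AFFY", direction = 1),
    list(probe_id = "i2", gene = "G5", platform = "ILMN", direction = 1),
    # 6. Tier 2 pair that also shares a pathway with another high-PCS gene
    #    -> Tier 1 via T1b
    list(probe_id = "a11", gene = "G6", platform = "AFFY", direction = -1),
    list(probe_id = "a12", gene = "G6", platform = "AFFY", direction = -1)
  )
  sets <- structure(
    tibble::tibble(
      term_id = "PW:1", term_name = "shared pathway",
      members = list(c("G6", "G1", "OTHER"))
    ),
    class = c("cdm_gene_sets", class(tibble::tibble()))
  )
  tiers <- assign_tiers(recs, gene_sets = sets, multiprobe_platform = "AFFY")
  got <- setNames(tiers$tier, tiers$gene_symbol)
  rules <- setNames(tiers$rule_fired, tiers$gene_symbol)
  expect_equal(got[["G1"]], "1") # T2a plus shared pathway promotes via T1b
  expect_equal(rules[["G1"]], "T1b")
  expect_equal(got[["G2"]], "1")
  expect_equal(rules[["G2"]], "T1a")
  expect_equal(got[["G3"]], "high_pcs_unconfirmed")
  expect_equal(got[["G4"]], "1")
  expect_equal(rules[["G4"]], "T1c")
  expect_equal(got[["G5"]], "2")
  expect_equal(rules[["G5"]], "T2b")
  expect_equal(got[["G6"]], "1")
  expect_equal(rules[["G6"]], "T1b")

  # without gene sets, G1 stays Tier 2 and G6's pathway promotion vanishes
  tiers_nogs <- assign_tiers(recs, multiprobe_platform = "AFFY")
  got2 <- setNames(tiers_nogs$tier, tiers_nogs$gene_symbol)
  expect_equal(got2[["G1"]], "2")
  expect_equal(got2[["G6"]], "2")
  expect_equal(setNames(tiers_nogs$rule_fired, tiers_nogs$gene_symbol)[["G1"]], "T2a")
})

test_that("discordant consensus disqualifies Tier 1/2 but majority sign wins", {
  recs <- tier_records(
    list(probe_id = "a1", gene = "G1", platform = "AFFY", direction = 1),
    list(probe_id = "a2", gene = "G1", platform = "AFFY", direction = -1),
    list(probe_id = "i1", gene = "G1", platform = "ILMN", direction = 1),
    list(probe_id = "x1", gene = "G9", platform = "ILMN", direction = -1)
  )
  tiers <- assign_tiers(recs, multiprobe_platform = "AFFY")
  g1 <- tiers[tiers$gene_symbol == "G1", ]
  expect_equal(g1$tier, "high_pcs_unconfirmed")
  expect_equal(g1$consensus_direction, 1) # 2 up vs 1 down
})

test_that("Tier 0 is the intersection with the auxiliary high-PCS genes", {
  recs <- tier_records(
    list(probe_id = "a1", gene = "A", platform = "AFFY", direction = -1),
    list(probe_id = "a2", gene = "A", platform = "AFFY", direction = -1),
    list(probe_id = "a3", gene = "B", platform = "AFFY", direction = 1),
    list(probe_id = "i1", gene = "B", platform = "ILMN", direction = 1),
    list(probe_id = "a4", gene = "C", platform = "AFFY", direction = -1),
    list(probe_id = "a5", gene = "C", platform = "AFFY", direction = -1)
  )
  tiers <- assign_tiers(recs, multiprobe_platform = "AFFY")
  expect_setequal(tiers$gene_symbol[tiers$tier %in% c("1", "2")], c("A", "B", "C"))

  aux <- tier_records(
    list(probe_id = "x1", gene = "B", platform = "AUX", direction = -1),
    list(probe_id = "x2", gene = "C", platform = "AUX", direction = -1),
    list(probe_id = "x3", gene = "D", platform = "AUX", direction = -1)
  )
  with0 <- add_tier0(tiers, aux, top_fraction = 1.0)
  expect_setequal(tier_sets(with0)$tier0, c("B", "C"))
  # Tier 0 genes keep their underlying tier membership
  expect_true(all(tier_sets(with0)$tier0 %in%
    c(tier_sets(with0)$tier1, tier_sets(with0)$tier2)))

  aux_disjoint <- tier_records(
    list(probe_id = "y1", gene = "Z1", platform = "AUX", direction = 1),
    list(probe_id = "y2", gene = "Z2", platform = "AUX", direction = 1)
  )
  expect_length(tier_sets(add_tier0(tiers, aux_disjoint, 1.0))$tier0, 0)
  expect_error(add_tier0(tiers, aux[0, ]), "empty")

  # auxiliary top fraction 1.0 with all tier-1/2 genes present: Tier 0 = Tier 1+2
  aux_all <- tier_records(
    list(probe_id = "z1", gene = "A", platform = "AUX", direction = 1),
    list(probe_id = "z2", gene = "B", platform = "AUX", direction = 1),
    list(probe_id = "z3", gene = "C", platform = "AUX", direction = 1)
  )
  expect_setequal(tier_sets(add_tier0(tiers, aux_all, 1.0))$tier0, c("A", "B", "C"))
})

test_that("venn differences subtract consecutive tier lists", {
  sets <- list(
    tier0 = c("A"), tier1 = c("A", "B"), tier2 = c("C", "D"), tier3 = c("C", "E")
  )
  v <- venn_difference(sets)
  expect_equal(v$tier1_minus_0, "B")
  expect_equal(v$tier2_minus_1, c("C", "D"))
  expect_equal(v$tier3_minus_2, "E")
  expect_length(intersect(v$tier1_minus_0, sets$tier0), 0)

  nested <- list(tier0 = "A", tier1 = c("A", "B"), tier2 = c("A", "B"), tier3 = c("A", "B", "C"))
  v2 <- venn_difference(nested)
  expect_length(v2$tier2_minus_1, 0)
  expect_equal(v2$tier3_minus_2, "C")
})

test_that("relaxing the high-PCS fraction never demotes a gene", {
  sim <- small_sim(seed = 5)
  recs <- dplyr::bind_rows(purrr::map(
    sim$datasets[c("AFFY", "ILMN")],
    function(d) {
      score_consistency(d, sim$annotation[sim$annotation$platform_id == d$platform_id, ])
    }
  ))
  rank_of <- c("1" = 1, "2" = 2, "3" = 3, "high_pcs_unconfirmed" = 4)
  tiers_strict <- assign_tiers(recs, top_fraction = 0.1)
  tiers_loose <- assign_tiers(recs, top_fraction = 0.25)
  strict <- setNames(rank_of[tiers_strict$tier], tiers_strict$gene_symbol)
  loose <- setNames(rank_of[tiers_loose$tier], tiers_loose$gene_symbol)
  common <- names(strict)
  expect_true(all(common %in% names(loose)))
  expect_true(all(loose[common] <= strict[common]))
})
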