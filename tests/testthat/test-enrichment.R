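test_that("expression-matched background is the shortest sufficient prefix", {
  total <- tibble::tibble(
    gene_symbol = c("g1", "g2", "g3", "g4"),
    intensity = c(100, 50, 10, 1)
  )
  # changed mean 50: prefix means 100, 75, 53.3, 40.25 -> size 3
  bg <- match_background_by_expression(total, "g2")
  expect_setequal(bg, c("g1", "g2", "g3"))

  # changed mean equal to the global mean: full total retained
  uniform <- tibble::tibble(gene_symbol = c("a", "b", "c"), intensity = 5)
  expect_setequal(match_background_by_expression(uniform, "b"), c("a", "b", "c"))

  # low-intensity changed list: full total, changed genes always included
  bg_low <- match_background_by_expression(total, "g4")
  expect_setequal(bg_low, total$gene_symbol)

  # monotone: lowering the changed mean never shrinks the background
  bg_hi <- match_background_by_expression(total, "g1")
  expect_true(all(bg_hi %in% bg_low))

  expect_error(match_background_by_expression(total, "nope"), "nope")
})

test_that("the enrichment coefficient follows its definition", {
  expect_equal(enrichment_coefficient(4, 100, 8, 3000), 15.0)
  expect_equal(enrichment_coefficient(0, 50, 10, 1000), 0)
  expect_error(enrichment_coefficient(4, 100, 0, 3000), "TG")

  # within one tier (fixed L, T) the ratio of two coefficients is the ratio
  # of CG/TG: kinesin-binding (TG 8, CG 4) vs neurotransmitter secretion
  # (TG 38, CG 7) must reproduce the reported 15 / 5.7 within rounding
  r_counts <- (4 / 8) / (7 / 38)
  r_reported <- 15 / 5.7
  expect_lt(abs(r_counts / r_reported - 1), 0.05)
})

test_that("one-sided Fisher p matches the exhaustive enumeration oracle", {
  expect_equal(fisher_one_sided(0, 5, 3, 10), 1)
  expect_equal(fisher_one_sided(5, 5, 5, 10), 1 / choose(10, 5))
  expect_error(fisher_one_sided(6, 10, 5, 20), "CG > TG")

  withr::with_seed(21, {
    for (i in 1:40) {
      T_total <- sample(4:12, 1)
      TG <- sample(1:T_total, 1)
      L <- sample(1:T_total, 1)
      CG <- sample(0:min(TG, L), 1)
      expect_equal(
        fisher_one_sided(CG, L, TG, T_total),
        enum_hyper_tail(CG, L, TG, T_total),
        tolerance = 1e-12,
        info = sprintf("T=%d TG=%d L=%d CG=%d", T_total, TG, L, CG)
      )
    }
  })

  # tail monotonicity in CG at fixed margins
  p <- fisher_one_sided(0:5, 10, 5, 30)
  expect_true(all(diff(p) <= 0))

  # cross-check against stats::fisher.test one-sided
  expect_equal(
    fisher_one_sided(4, 10, 7, 40),
    stats::fisher.test(
      matrix(c(4, 6, 3, 27), 2),
      alternative = "greater"
    )$p.value,
    tolerance = 1e-10
  )
})

test_that("permutation FDR is deterministic, clipped, and flags planted terms", {
  withr::with_seed(31, {
    genes <- sprintf("g%03d", 1:300)
    changed <- genes[1:30]
  })
  sets <- simulate_gene_sets(genes, changed,
    n_terms = 40, n_planted_terms = 1,
    planted_size = 15, planted_member_fraction = 1, seed = 32
  )
  obs <- compactdm:::compute_term_stats(changed, genes, sets)
  f1 <- permutation_fdr(obs, genes, sets, cycles = 100, seed = 33)
  f2 <- permutation_fdr(obs, genes, sets, cycles = 100, seed = 33)
  expect_identical(f1$fdr, f2$fdr)
  expect_true(all(f1$fdr >= 0 & f1$fdr <= 1))
  expect_lt(f1$fdr[f1$term_id == "PLANTED:0001"], 0.05)

  # stability: 100 vs 1000 cycles moves the estimates by < 0.05 on average,
  # and the planted term's estimate by < 0.05
  f3 <- permutation_fdr(obs, genes, sets, cycles = 1000, seed = 34)
  expect_lt(mean(abs(f1$fdr - f3$fdr)), 0.05)
  expect_lt(abs(f1$fdr - f3$fdr)[f1$term_id == "PLANTED:0001"], 0.05)

  # a term whose observed p is at least every random p has FDR clipped at 1
  boundary <- obs
  boundary$p_value[1] <- 1
  fb <- permutation_fdr(boundary, genes, sets, cycles = 100, seed = 33)
  expect_equal(fb$fdr[1], 1)
  expect_error(permutation_fdr(obs, genes, sets, cycles = 0, seed = 1), "cycles")
})

test_that("report filtering drops small categories and sorts FDR then ENR", {
  res <- tibble::tibble(
    term_id = c("t1", "t2", "t3", "t4"),
    TG = c(4, 10, 12, 9),
    ENR = c(50, 5.7, 15, 3),
    fdr = c(0.001, 0.05, 0.05, 0.5)
  )
  out <- filter_and_sort(res)
  expect_false("t1" %in% out$term_id) # TG < 5 excluded regardless of FDR
  expect_false("t4" %in% out$term_id) # FDR >= 0.2
  expect_equal(out$term_id, c("t3", "t2")) # equal FDR: larger ENR first

  all_bad <- res
  all_bad$fdr <- 0.9
  expect_equal(nrow(filter_and_sort(all_bad)), 0)
})

test_that("a uniformly drawn list is unenriched on average (ENR expectation 1)", {
  withr::with_seed(41, {
    genes <- sprintf("g%03d", 1:200)
    sets <- simulate_gene_sets(genes,
      n_terms = 20, n_planted_terms = 0,
      size_range = c(10, 40), seed = 42
    )
    enr <- replicate(60, {
      changed <- sample(genes, 25)
      mean(compactdm:::compute_term_stats(changed, genes, sets)$ENR)
    })
    expect_lt(abs(mean(enr) - 1), 0.1)
  })
})

test_that("the full enrichment step recovers a planted term end to end", {
  sim <- small_sim(seed = 6)
  recs <- dplyr::bind_rows(purrr::map(
    sim$datasets[c("AFFY", "ILMN")],
    function(d) {
      score_consistency(d, sim$annotation[sim$annotation$platform_id == d$platform_id, ])
    }
  ))
  total <- expression_background(recs)
  changed <- sim$truth$planted_genes
  sets <- simulate_gene_sets(total$gene_symbol, changed, n_terms = 50, seed = 7)
  rep <- enrich_ontology(changed, total, sets, cycles = 100, seed = 8)
  expect_s3_class(rep, "cdm_enrichment")
  expect_true(any(grepl("^PLANTED", rep$term_id)))
  expect_true(all(rep$TG >= 5) && all(rep$fdr < 0.2))
  expect_true(all(diff(rep$fdr) >= 0))
  expect_true(all(rep$CG <= pmin(rep$TG, rep$list_size_L)))
})
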