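test_that("study generation is deterministic and structurally faithful", {
  a <- simulate_study(n_genes = 120, n_per_group = 4, seed = 71)
  b <- simulate_study(n_genes = 120, n_per_group = 4, seed = 71)
  expect_identical(a$datasets$AFFY$intensities, b$datasets$AFFY$intensities)
  expect_identical(a$truth$planted_genes, b$truth$planted_genes)
  c_ <- simulate_study(n_genes = 120, n_per_group = 4, seed = 72)
  expect_false(identical(a$datasets$AFFY$intensities, c_$datasets$AFFY$intensities))

  # split-design platform is condition-pure per subset; tissue design mixed
  ilmn <- a$datasets$ILMN$samples
  expect_true(all(table(ilmn$subset, ilmn$condition) %in% c(0, 4)))
  affy <- a$datasets$AFFY$samples
  expect_true(all(table(affy$subset, affy$condition) == 4))

  expect_setequal(unname(a$roles), c("primary", "primary", "auxiliary"))
  expect_true(all(a$truth$aux_shared_genes %in% a$truth$planted_genes))
  expect_error(simulate_study(n_genes = 50, planted_fraction = 1, seed = 1), "planted_fraction")
})

test_that("the down-regulation bias matches the requested fraction", {
  sim <- simulate_study(n_genes = 2000, n_per_group = 4, seed = 73)
  frac_down <- mean(sim$truth$direction == -1)
  expect_equal(frac_down, 0.8, tolerance = 0.08)
})

test_that("a zero effect size leaves planted and null PCS indistinguishable", {
  pcs_planted <- c()
  pcs_null <- c()
  for (seed in 1:20) {
    sim <- simulate_study(
      n_genes = 120, planted_fraction = 0.1, effect_size = 0,
      n_per_group = 5, seed = seed,
      platforms = default_platforms()[c("AFFY", "ILMN")]
    )
    ann <- sim$annotation[sim$annotation$platform_id == "AFFY", ]
    rec <- score_consistency(sim$datasets$AFFY, ann, intensity_fraction = 1)
    planted <- rec$gene_symbol %in% sim$truth$planted_genes
    pcs_planted <- c(pcs_planted, rec$pcs[planted])
    pcs_null <- c(pcs_null, rec$pcs[!planted])
  }
  ks <- suppressWarnings(stats::ks.test(pcs_planted, pcs_null))
  expect_gt(ks$p.value, 0.01)
})

test_that("gene-set generation respects sizes and plants covered terms", {
  genes <- sprintf("g%03d", 1:500)
  planted_genes <- genes[1:40]
  sets <- simulate_gene_sets(genes, planted_genes,
    n_terms = 30, size_range = c(5, 25),
    n_planted_terms = 2, planted_size = 10,
    planted_member_fraction = 0.8, seed = 74
  )
  expect_equal(nrow(sets), 30L)
  truth <- attr(sets, "truth")
  expect_length(truth$planted_terms, 2)
  null_sizes <- lengths(sets$members[!sets$term_id %in% truth$planted_terms])
  expect_true(all(null_sizes >= 5 & null_sizes <= 25))
  # planted term of size 10 with 8 disease genes: CG >= 8 when the changed
  # list recovers all planted genes
  planted_members <- sets$members[[match(truth$planted_terms[1], sets$term_id)]]
  expect_equal(length(planted_members), 10L)
  expect_gte(length(intersect(planted_members, planted_genes)), 8L)

  expect_identical(
    sets$members,
    simulate_gene_sets(genes, planted_genes, 30, c(5, 25), 2, 10, 0.8, seed = 74)$members
  )
})

test_that("with no planted terms the FDR stays quiet", {
  hits <- vapply(1:10, function(seed) {
    genes <- sprintf("g%03d", 1:200)
    sets <- simulate_gene_sets(genes,
      n_terms = 25, n_planted_terms = 0,
      size_range = c(5, 30), seed = seed
    )
    changed <- withr::with_seed(seed + 500, sample(genes, 25))
    obs <- compactdm:::compute_term_stats(changed, genes, sets)
    fdr <- permutation_fdr(obs, genes, sets, cycles = 100, seed = seed + 1000)
    any(fdr$fdr < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.1)
})

test_that("corpus generation is deterministic with identifiable folds", {
  genes <- sprintf("g%03d", 1:300)
  disease <- genes[1:30]
  corp <- simulate_corpus(genes,
    n_documents = 1500,
    associations = list(list(genes = disease, tag = "neurodegeneration", fold = 10)),
    seed = 75
  )
  corp2 <- simulate_corpus(genes,
    n_documents = 1500,
    associations = list(list(genes = disease, tag = "neurodegeneration", fold = 10)),
    seed = 75
  )
  expect_identical(corp$tags, corp2$tags)
  expect_equal(nrow(corp), 1500L)

  # fold 1 everywhere: disease list behaves like any list
  flat <- simulate_corpus(genes, n_documents = 1500, seed = 76)
  prof <- semantic_profile(flat, list(d = disease), c(t = "neurodegeneration"))
  expect_lt(abs(prof$ratio - 0.05), 0.03)
})

test_that("network generation plants cliques and matches the degree exponent", {
  genes <- sprintf("G%04d", 1:300)
  module <- genes[1:12]
  net <- simulate_network(genes, planted_module = module, planted_density = 1, seed = 77)
  sub <- igraph::induced_subgraph(net, module)
  expect_equal(igraph::ecount(sub), choose(12, 2))
  net2 <- simulate_network(genes, planted_module = module, planted_density = 1, seed = 77)
  expect_identical(igraph::as_edgelist(net), igraph::as_edgelist(net2))

  # tail-exponent recovery needs enough tail mass for a stable MLE fit
  big <- simulate_network(sprintf("g%05d", 1:20000),
    avg_degree = 10,
    degree_exponent = 2.5, seed = 78
  )
  deg <- igraph::degree(big)
  fit <- igraph::fit_power_law(deg[deg > 0])
  expect_lt(abs(fit$alpha - 2.5), 0.3)
})
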