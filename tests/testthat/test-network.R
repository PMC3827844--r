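path_graph <- function(edges) {
  igraph::graph_from_data_frame(
    data.frame(from = edges[c(TRUE, FALSE)], to = edges[c(FALSE, TRUE)]),
    directed = FALSE
  )
}

test_that("induced networks add first-order neighbors around the seeds", {
  g <- path_graph(c("A", "C", "C", "B"))
  net <- build_induced_network(c("A", "B"), g, include_neighbors = TRUE)
  expect_setequal(igraph::V(net)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(net), 2L)
  expect_setequal(igraph::V(net)$name[igraph::V(net)$is_focus], c("A", "B"))

  bare <- build_induced_network(c("A", "B"), g, include_neighbors = FALSE)
  expect_setequal(igraph::V(bare)$name, c("A", "B"))
  expect_equal(igraph::ecount(bare), 0L)

  everything <- build_induced_network(c("A", "B", "C"), g, include_neighbors = TRUE)
  expect_equal(igraph::ecount(everything), igraph::ecount(g))

  expect_error(build_induced_network(c("X", "Y"), g), "no seed gene")
})

test_that("partitioning separates obvious communities", {
  two_tri <- path_graph(c("A", "B", "B", "C", "C", "A", "X", "Y", "Y", "Z", "Z", "X"))
  part <- partition_subnetworks(two_tri)
  expect_equal(length(unique(part$subnetwork_id)), 2L)
  expect_equal(
    length(unique(part$subnetwork_id[part$gene %in% c("A", "B", "C")])), 1L
  )

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- LETTERS[1:5]
  expect_equal(length(unique(partition_subnetworks(k5)$subnetwork_id)), 1L)
})

test_that("the barbell graph splits at the bridge, matching exhaustive modularity", {
  left <- c("A1", "A2", "A3", "A4")
  right <- c("B1", "B2", "B3", "B4")
  edges <- rbind(
    t(utils::combn(left, 2)), t(utils::combn(right, 2)), c("A1", "B1")
  )
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE)
  part <- partition_subnetworks(g)
  expect_equal(length(unique(part$subnetwork_id)), 2L)
  expect_equal(length(unique(part$subnetwork_id[part$gene %in% left])), 1L)
  expect_equal(length(unique(part$subnetwork_id[part$gene %in% right])), 1L)

  # oracle: the best of all 2^8 membership vectors is the bridge split
  nodes <- igraph::V(g)$name
  best_q <- -Inf
  best_mem <- NULL
  for (mask in 0:(2^8 - 1)) {
    mem <- bitwAnd(bitwShiftR(mask, 0:7), 1) + 1
    q <- igraph::modularity(g, mem)
    if (q > best_q) {
      best_q <- q
      best_mem <- mem
    }
  }
  oracle_split <- split(nodes, best_mem)
  expect_setequal(oracle_split[[1]], if ("A1" %in% oracle_split[[1]]) left else right)
  achieved_q <- igraph::modularity(g, as.integer(factor(part$subnetwork_id[match(nodes, part$gene)])))
  expect_equal(achieved_q, best_q, tolerance = 1e-12)
})

test_that("single-node refinement never decreases modularity", {
  withr::with_seed(61, {
    for (i in 1:5) {
      g <- igraph::sample_gnp(30, 0.12)
      igraph::V(g)$name <- sprintf("n%02d", 1:30)
      g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
      if (igraph::ecount(g) == 0) next
      cl <- igraph::membership(igraph::cluster_fast_greedy(g))
      q0 <- igraph::modularity(g, cl)
      refined <- compactdm:::refine_partition(g, as.integer(cl))
      expect_gte(igraph::modularity(g, refined), q0)
    }
  })
})

test_that("oversized components are split below max_size", {
  g <- igraph::sample_gnp(60, 0.3)
  igraph::V(g)$name <- sprintf("n%02d", 1:60)
  withr::with_seed(62, g <- igraph::rewire(g, igraph::keeping_degseq(niter = 100)))
  part <- partition_subnetworks(g, max_size = 20)
  expect_true(all(table(part$subnetwork_id) <= 20))
})

test_that("sub-network scores match the hypergeometric enumeration oracle", {
  none <- score_subnetwork(letters[1:4], c("X", "Y"), background_size = 20)
  expect_equal(none$p_value, 1)
  expect_equal(none$score, 0)

  all_focus <- score_subnetwork(letters[1:5], letters[1:5],
    n_focus_total = 5, background_size = 20
  )
  expect_equal(all_focus$p_value, 1 / choose(20, 5))
  expect_equal(all_focus$score, 4.19, tolerance = 1e-2)

  withr::with_seed(63, {
    for (i in 1:30) {
      B <- sample(5:12, 1)
      nf <- sample(1:B, 1)
      nn <- sample(1:B, 1)
      fm <- sample(0:min(nf, nn), 1)
      nodes <- sprintf("v%02d", seq_len(nn))
      focus <- sprintf("v%02d", seq_len(fm))
      sc <- score_subnetwork(nodes, focus, n_focus_total = nf, background_size = B)
      expect_equal(sc$p_value, enum_hyper_tail(fm, nn, nf, B), tolerance = 1e-12)
    }
  })

  # score is non-decreasing in the number of focus molecules
  scores <- vapply(0:4, function(fm) {
    score_subnetwork(letters[1:6], letters[seq_len(fm)],
      n_focus_total = 5, background_size = 30
    )$score
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
  expect_error(
    score_subnetwork(letters[1:5], letters[1:5], n_focus_total = 2, background_size = 3),
    "impossible"
  )
})

test_that("hub statistics compare against size-matched random draws", {
  conn <- setNames(c(rep(10, 10), rep(1, 90)), sprintf("g%03d", 1:100))
  hubs <- names(conn)[1:10]
  hs <- hub_stats(hubs, conn, threshold = 5, n_resamples = 200, seed = 64)
  expect_equal(hs$n_hubs, 10)
  expect_gt(hs$enrichment_ratio, 5)

  all_counted <- hub_stats(hubs, conn, threshold = 0, n_resamples = 10, seed = 65)
  expect_equal(all_counted$n_hubs, 10)
  expect_equal(all_counted$enrichment_ratio, 1)

  uniform <- setNames(rep(7, 100), sprintf("g%03d", 1:100))
  hu <- hub_stats(sprintf("g%03d", 1:20), uniform, threshold = 5, n_resamples = 50, seed = 66)
  expect_equal(hu$enrichment_ratio, 1)
  expect_error(hub_stats(hubs, conn, threshold = -1, 10, seed = 1), "threshold")
})
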