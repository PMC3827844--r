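#' Induce a network around a seed gene list
#'
#' Subgraph of the global interaction network on the seed genes plus,
#' optionally, all their first-order interaction partners (the imputed
#' neighbors that re-expand a distilled list into its mechanistic context).
#' Seed genes present in the global network but with no retained edges stay
#' as singletons.
#'
#' @param seed_genes Character vector of seed gene symbols.
#' @param global_network Undirected igraph object (e.g. from
#'   [read_edge_list()]).
#' @param include_neighbors Include first-order neighbors (default `TRUE`).
#' @return An igraph object whose vertices carry an `is_focus` attribute
#'   (`TRUE` for seed genes).
#' @export
build_induced_network <- function(seed_genes, global_network, include_neighbors = TRUE) {
  seed_genes <- unique(normalize_gene_symbols(seed_genes))
  present <- intersect(seed_genes, igraph::V(global_network)$name)
  if (length(present) == 0) abort_validation("no seed gene is present in the global network")
  nodes <- present
  if (include_neighbors) {
    nb <- unlist(igraph::adjacent_vertices(global_network, present))
    nodes <- union(present, igraph::V(global_network)$name[nb])
  }
  g <- igraph::induced_subgraph(global_network, nodes)
  if (!include_neighbors) {
    # only seed-seed edges are meaningful without imputed partners
    g <- igraph::induced_subgraph(g, intersect(igraph::V(g)$name, present))
  }
  igraph::V(g)$is_focus <- igraph::V(g)$name %in% seed_genes
  g
}

# Single-node shift refinement: move a node to a neighboring community when
# that increases modularity; accepted moves never decrease it. Deterministic
# (nodes visited in name order).
refine_partition <- function(graph, membership, max_passes = 10) {
  q <- igraph::modularity(graph, membership)
  nodes <- order(igraph::V(graph)$name)
  for (pass in seq_len(max_passes)) {
    moved <- FALSE
    for (v in nodes) {
      nb <- as.integer(igraph::neighbors(graph, v))
      cand <- setdiff(unique(membership[nb]), membership[v])
      for (comm in sort(cand)) {
        trial <- membership
        trial[v] <- comm
        q_trial <- igraph::modularity(graph, trial)
        if (q_trial > q + 1e-12) {
          stopifnot(q_trial >= q) # accepted shifts never decrease modularity
          membership <- trial
          q <- q_trial
          moved <- TRUE
          break
        }
      }
    }
    if (!moved) break
  }
  membership
}

#' Partition a network into sub-networks
#'
#' Greedy modularity maximization (connected components first, then
#' fast-greedy agglomeration within each) followed by single-node shift
#' refinement: a gene is moved between sub-networks whenever the move
#' increases modularity. Sub-networks larger than `max_size` are split
#' recursively by re-clustering. Deterministic for a given graph.
#'
#' @param graph Undirected igraph object.
#' @param max_size Largest allowed sub-network; default 35.
#' @return Tibble with columns `gene`, `subnetwork_id` (integers numbered by
#'   decreasing sub-network size).
#' @export
partition_subnetworks <- function(graph, max_size = 35) {
  if (igraph::vcount(graph) == 0) abort_validation("empty network")
  comp <- igraph::components(graph)
  membership <- integer(igraph::vcount(graph))
  next_id <- 0L

  cluster_component <- function(sub_ids) {
    sub <- igraph::induced_subgraph(graph, sub_ids)
    if (igraph::vcount(sub) <= 2 || igraph::ecount(sub) == 0) {
      return(rep(1L, igraph::vcount(sub)))
    }
    cl <- igraph::membership(igraph::cluster_fast_greedy(sub))
    as.integer(refine_partition(sub, as.integer(cl)))
  }

  split_oversized <- function(sub_ids, mem) {
    out <- integer(length(sub_ids))
    nid <- 0L
    for (comm in sort(unique(mem))) {
      idx <- which(mem == comm)
      if (length(idx) > max_size) {
        subsub <- igraph::induced_subgraph(graph, sub_ids[idx])
        cl2 <- igraph::membership(igraph::cluster_fast_greedy(subsub))
        if (length(unique(cl2)) > 1) {
          inner <- split_oversized(sub_ids[idx], as.integer(cl2))
          out[idx] <- nid + inner
          nid <- nid + max(inner)
          next
        }
        warn(sprintf("sub-network of size %d cannot be split below max_size", length(idx)))
      }
      nid <- nid + 1L
      out[idx] <- nid
    }
    out
  }

  for (ci in seq_len(comp$no)) {
    sub_ids <- which(comp$membership == ci)
    mem <- cluster_component(sub_ids)
    mem <- split_oversized(sub_ids, mem)
    membership[sub_ids] <- next_id + mem
    next_id <- next_id + max(mem)
  }
  out <- tibble::tibble(gene = igraph::V(graph)$name, subnetwork_id = membership)
  sizes <- sort(table(out$subnetwork_id), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  out$subnetwork_id <- as.integer(relabel[as.character(out$subnetwork_id)])
  out[order(out$subnetwork_id, out$gene), ]
}

#' Score one sub-network's non-randomness
#'
#' The probability that a node set of this size, drawn uniformly from a
#' background of `background_size` genes containing `n_focus_total` focus
#' genes, captures at least the observed number of focus molecules — an
#' upper-tail hypergeometric p-value. The score is `-log10(p)`.
#'
#' @param nodes Character vector, the sub-network's genes.
#' @param focus_genes Character vector, the input (tier) gene list.
#' @param n_focus_total Focus genes available in the background; defaults to
#'   `length(unique(focus_genes))`.
#' @param background_size Size of the gene background the network was drawn
#'   from (at least `length(nodes)`).
#' @return Tibble row: `n_nodes`, `focus_molecules`, `p_value`, `score`.
#' @export
score_subnetwork <- function(nodes, focus_genes, n_focus_total = NULL, background_size) {
  nodes <- unique(normalize_gene_symbols(nodes))
  focus_genes <- unique(normalize_gene_symbols(focus_genes))
  fm <- length(intersect(nodes, focus_genes))
  if (is.null(n_focus_total)) n_focus_total <- length(focus_genes)
  if (background_size < length(nodes) || n_focus_total > background_size || fm > n_focus_total) {
    abort_validation("impossible margins for sub-network score")
  }
  p <- phyper(fm - 1, n_focus_total, background_size - n_focus_total,
    length(nodes),
    lower.tail = FALSE
  )
  tibble::tibble(
    n_nodes = length(nodes), focus_molecules = fm,
    p_value = p, score = -log10(p)
  )
}

#' Score all sub-networks of a partition
#'
#' @param partition Tibble from [partition_subnetworks()].
#' @param focus_genes The input (tier) gene list.
#' @param background_size Gene background size; defaults to the global
#'   network order when given via `global_order`.
#' @param global_order Optional number of genes in the global network used
#'   as the default background.
#' @return Tibble of class `cdm_subnetworks`: `subnetwork_id`, `n_nodes`,
#'   `focus_molecules`, `internal_edges` (NA unless `graph` given),
#'   `p_value`, `score`, plus list-column `nodes`; sorted by decreasing
#'   score.
#' @param graph Optional igraph used to count internal edges.
#' @export
score_subnetworks <- function(partition, focus_genes, background_size = NULL,
                              global_order = NULL, graph = NULL) {
  if (is.null(background_size)) background_size <- global_order
  if (is.null(background_size)) abort_validation("`background_size` is required")
  n_focus_total <- length(unique(normalize_gene_symbols(focus_genes)))
  groups <- split(partition$gene, partition$subnetwork_id)
  rows <- purrr::imap(groups, function(nodes, id) {
    sc <- score_subnetwork(nodes, focus_genes, n_focus_total, background_size)
    sc$subnetwork_id <- as.integer(id)
    sc$nodes <- list(sort(nodes))
    sc$internal_edges <- if (!is.null(graph)) {
      igraph::ecount(igraph::induced_subgraph(graph, nodes))
    } else {
      NA_integer_
    }
    sc
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$score, out$subnetwork_id), c(
    "subnetwork_id", "n_nodes", "focus_molecules", "internal_edges",
    "p_value", "score", "nodes"
  )]
  structure(out, class = c("cdm_subnetworks", class(tibble::tibble())))
}

#' Hub statistics of a gene set
#'
#' Counts genes whose connectivity proxy (network degree, or a literature
#' hit count) exceeds a threshold, and compares against size-matched random
#' draws from all genes with a known proxy.
#'
#' @param genes Character vector of gene symbols.
#' @param connectivity Named non-negative numeric vector, the proxy for all
#'   background genes.
#' @param threshold Hub threshold (proxy strictly greater); must be >= 0.
#' @param n_resamples Random draws; default 100.
#' @param seed Mandatory integer seed.
#' @return List: `n_hubs`, `n_genes`, `expected_random` (mean hub count over
#'   draws), `enrichment_ratio`, `ratio_interval` (2.5%/97.5% resampling
#'   quantiles of the ratio).
#' @export
hub_stats <- function(genes, connectivity, threshold, n_resamples = 100, seed) {
  if (threshold < 0) abort_validation("`threshold` must be >= 0")
  genes <- unique(normalize_gene_symbols(genes))
  names(connectivity) <- normalize_gene_symbols(names(connectivity))
  pool <- names(connectivity)
  known <- intersect(genes, pool)
  n_hubs <- sum(connectivity[known] > threshold)
  draws <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      sum(connectivity[sample(pool, length(known))] > threshold)
    }, numeric(1))
  })
  expected <- mean(draws)
  ratio <- if (expected > 0) n_hubs / expected else NA_real_
  interval <- if (all(draws > 0)) {
    unname(quantile(n_hubs / draws, c(0.025, 0.975)))
  } else {
    c(NA_real_, NA_real_)
  }
  list(
    n_hubs = n_hubs, n_genes = length(known),
    expected_random = expected, enrichment_ratio = ratio,
    ratio_interval = interval
  )
}
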