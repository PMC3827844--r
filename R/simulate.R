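#' Default platform layout for synthetic studies
#'
#' Mirrors the structure of the real inputs the pipeline is designed for:
#' a multi-probe oligonucleotide platform with several tissue subsets each
#' containing both conditions, a single-probe bead platform whose cohort is
#' split into condition-pure halves (tested as the full control-split by
#' disease-split cross product), and a single-probe auxiliary platform
#' standing in for a multi-disease panel.
#'
#' @return Named list of platform descriptors.
#' @export
default_platforms <- function() {
  list(
    AFFY = list(
      platform_id = "AFFY", probes_per_gene = c(`2` = 0.4, `3` = 0.4, `4` = 0.2),
      design = "tissue", n_subsets = 3, role = "primary"
    ),
    ILMN = list(
      platform_id = "ILMN", probes_per_gene = c(`1` = 1),
      design = "split", n_subsets = 2, role = "primary"
    ),
    ILMN_AUX = list(
      platform_id = "ILMN_AUX", probes_per_gene = c(`1` = 1),
      design = "tissue", n_subsets = 2, role = "auxiliary"
    )
  )
}

#' Simulate a multi-platform case/control expression study
#'
#' Generates probe-by-sample intensity matrices for each platform, a probe
#' annotation, and the ground truth needed to evaluate recovery. The
#' intensity model is log-normal: each gene draws a baseline log2 level
#' (shared across platforms, so the intensity filter acts consistently and
#' low-expressed planted genes are genuinely harder to detect), probes add a
#' small offset, and measurements add Gaussian log-scale noise. A planted
#' fraction of genes is shifted in disease samples by `effect_size` noise
#' standard deviations, with a configurable down-regulation bias, on every
#' primary platform and every subset. Two nuisance processes make the
#' benchmark realistic: per-gene, per-subset disease heterogeneity
#' (`subset_sd`) emulating region- or cohort-specific responses that a
#' single pooled test mistakes for signal, and platform-specific artifact
#' probes (`artifact_fraction`) carrying a spurious but within-platform
#' consistent differential shift, which single-platform rankings cannot
#' reject. The auxiliary platform shows the effect only for a
#' `aux_shared_fraction` subset of planted genes (diseases sharing part of
#' the mechanism).
#'
#' @param n_genes Number of genes; default 5000.
#' @param planted_fraction Fraction of genes carrying a true effect;
#'   default 0.02 (must be < 1).
#' @param effect_size Disease shift in units of `noise_sd`; default 1.5.
#' @param downregulated_fraction Fraction of planted genes shifted down;
#'   default 0.8.
#' @param noise_sd Measurement noise sd on the log2 scale; default 0.5.
#' @param subset_sd Disease heterogeneity sd, in units of `noise_sd`;
#'   default 0.5.
#' @param artifact_fraction Fraction of probes per platform carrying a
#'   platform-specific artifact shift; default 0.015.
#' @param artifact_sd Artifact shift sd, in units of `noise_sd`; default 1.
#' @param baseline_log2_mean,baseline_log2_sd Gene baseline distribution on
#'   the log2 scale; defaults 9 and 2.
#' @param probe_sd Probe offset sd (log2); default 0.25.
#' @param n_per_group Samples per condition per subset; default 10.
#' @param platforms Platform descriptors; default [default_platforms()].
#' @param aux_shared_fraction Fraction of planted genes also perturbed on
#'   auxiliary platforms; default 0.5.
#' @param seed Mandatory integer seed; identical seeds give identical
#'   output.
#' @return List with `datasets` (named list of [cdm_dataset()]), `roles`
#'   (named character vector, `"primary"`/`"auxiliary"`), `annotation`
#'   (probe to gene tibble) and `truth` (planted genes, directions,
#'   auxiliary-shared genes, artifact probes, parameters).
#' @export
simulate_study <- function(n_genes = 5000, planted_fraction = 0.02, effect_size = 1.5,
                           downregulated_fraction = 0.8, noise_sd = 0.5,
                           subset_sd = 0.5, artifact_fraction = 0.015, artifact_sd = 1,
                           baseline_log2_mean = 9, baseline_log2_sd = 2,
                           probe_sd = 0.25, n_per_group = 10,
                           platforms = default_platforms(),
                           aux_shared_fraction = 0.5, seed) {
  if (planted_fraction >= 1) abort_validation("`planted_fraction` must be < 1")
  if (length(platforms) < 2) abort_validation("need >= 2 platforms")
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    baseline <- rnorm(n_genes, baseline_log2_mean, baseline_log2_sd)
    names(baseline) <- genes
    n_planted <- round(planted_fraction * n_genes)
    planted <- sort(sample(genes, n_planted))
    direction <- setNames(
      ifelse(runif(n_planted) < downregulated_fraction, -1, 1),
      planted
    )
    aux_shared <- sort(sample(planted, round(aux_shared_fraction * n_planted)))

    datasets <- list()
    roles <- character()
    annotation <- list()
    artifacts <- list()

    for (pl in platforms) {
      pid <- pl$platform_id
      counts <- sample(
        as.integer(names(pl$probes_per_gene)), n_genes,
        replace = TRUE, prob = pl$probes_per_gene
      )
      probe_gene <- rep(genes, counts)
      probe_id <- sprintf("%s_%s_%02d", pid, probe_gene, sequence(counts))
      n_probes <- length(probe_id)
      probe_base <- baseline[probe_gene] + rnorm(n_probes, 0, probe_sd)

      if (pl$design == "split") {
        subsets <- c(
          rep(sprintf("C%d", seq_len(pl$n_subsets)), each = n_per_group),
          rep(sprintf("D%d", seq_len(pl$n_subsets)), each = n_per_group)
        )
        condition <- rep(c("control", "disease"), each = pl$n_subsets * n_per_group)
      } else {
        subsets <- rep(sprintf("S%d", seq_len(pl$n_subsets)), each = 2 * n_per_group)
        condition <- rep(rep(c("control", "disease"), each = n_per_group), pl$n_subsets)
      }
      sample_id <- sprintf("%s_%03d", pid, seq_along(subsets))
      n_samples <- length(sample_id)

      log2x <- matrix(rnorm(n_probes * n_samples, 0, noise_sd), n_probes, n_samples)
      log2x <- log2x + probe_base

      is_disease <- condition == "disease"
      eff_genes <- if (identical(pl$role, "auxiliary")) aux_shared else planted
      eff <- setNames(numeric(n_genes), genes)
      eff[eff_genes] <- direction[eff_genes] * effect_size * noise_sd
      log2x[, is_disease] <- log2x[, is_disease] + eff[probe_gene]

      # region/cohort-specific disease heterogeneity, gene-level, per subset
      disease_subsets <- unique(subsets[is_disease])
      for (s in disease_subsets) {
        delta <- rnorm(n_genes, 0, subset_sd * noise_sd)
        names(delta) <- genes
        cols <- is_disease & subsets == s
        log2x[, cols] <- log2x[, cols] + delta[probe_gene]
      }

      # platform-specific artifact probes: consistent spurious shift
      n_art <- floor(artifact_fraction * n_probes)
      art_idx <- sort(sample.int(n_probes, n_art))
      art_shift <- rnorm(n_art, 0, artifact_sd * noise_sd)
      log2x[art_idx, is_disease] <- log2x[art_idx, is_disease] + art_shift
      artifacts[[pid]] <- probe_id[art_idx]

      mat <- 2^log2x
      dimnames(mat) <- list(probe_id, sample_id)
      datasets[[pid]] <- cdm_dataset(
        mat,
        tibble::tibble(sample_id = sample_id, condition = condition, subset = subsets),
        pid
      )
      roles[pid] <- pl$role %||% "primary"
      annotation[[pid]] <- tibble::tibble(
        probe_id = probe_id, gene_symbol = probe_gene, platform_id = pid
      )
    }

    list(
      datasets = datasets,
      roles = roles,
      annotation = dplyr::bind_rows(annotation),
      truth = list(
        planted_genes = planted,
        direction = direction,
        downregulated_fraction = downregulated_fraction,
        effect_size = effect_size,
        aux_shared_genes = aux_shared,
        artifact_probes = artifacts,
        genes = genes,
        seed = seed
      )
    )
  })
}

#' Simulate a gene-set collection with planted enriched terms
#'
#' Null terms draw members uniformly from the gene universe; planted terms
#' draw `planted_member_fraction` of their members from the planted disease
#' genes, so a changed list recovering those genes is strongly enriched.
#'
#' @param genes Gene universe (character).
#' @param planted_genes Genes the planted terms concentrate on.
#' @param n_terms Total number of terms; default 100.
#' @param size_range Null-term size range (inclusive); default `c(5, 50)`.
#' @param n_planted_terms Number of planted terms; default 2 (0 allowed).
#' @param planted_size Planted term size; default 20.
#' @param planted_member_fraction Fraction of planted-term members drawn
#'   from `planted_genes`; default 0.8.
#' @param seed Mandatory integer seed.
#' @return A `cdm_gene_sets` tibble with a `truth` attribute naming the
#'   planted term ids.
#' @export
simulate_gene_sets <- function(genes, planted_genes = character(), n_terms = 100,
                               size_range = c(5, 50), n_planted_terms = 2,
                               planted_size = 20, planted_member_fraction = 0.8,
                               seed) {
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_planted_terms)) {
      n_in <- min(round(planted_member_fraction * planted_size), length(planted_genes))
      members <- c(
        sample(planted_genes, n_in),
        sample(setdiff(genes, planted_genes), planted_size - n_in)
      )
      rows[[i]] <- tibble::tibble(
        term_id = sprintf("PLANTED:%04d", i),
        term_name = sprintf("planted_term_%d", i),
        members = list(sort(members))
      )
    }
    for (i in seq_len(n_terms - n_planted_terms)) {
      size <- sample(size_range[1]:size_range[2], 1)
      rows[[n_planted_terms + i]] <- tibble::tibble(
        term_id = sprintf("NULL:%04d", i),
        term_name = sprintf("null_term_%d", i),
        members = list(sort(sample(genes, size)))
      )
    }
    sets <- dplyr::bind_rows(rows)
    structure(sets,
      class = c("cdm_gene_sets", class(tibble::tibble())),
      truth = list(planted_terms = sets$term_id[seq_len(n_planted_terms)], seed = seed)
    )
  })
}

#' Simulate an offline literature corpus with planted tag associations
#'
#' Each document carries one primary gene mention (drawn uniformly from the
#' universe) and Bernoulli topic tags. A tag's probability is its base rate,
#' multiplied by the association fold (capped at 1) when the document's gene
#' belongs to an associated gene group — e.g. a 10-fold
#' disease-tag association for the planted disease genes. One mention per
#' document keeps the fold identifiable from hit ratios; co-mention
#' confounding is a property of real corpora this generator deliberately
#' omits.
#'
#' @param genes Gene universe.
#' @param n_documents Number of documents; default 2000.
#' @param tag_probs Named base tag probabilities; default covers `disease`,
#'   `cancer`, `stress`, `neurodegeneration`, `oncogene`,
#'   `tumor_suppressor`.
#' @param associations List of `list(genes=, tag=, fold=)` planted
#'   associations.
#' @param seed Mandatory integer seed.
#' @return A `cdm_corpus` tibble with a `truth` attribute.
#' @export
simulate_corpus <- function(genes, n_documents = 2000,
                            tag_probs = c(
                              disease = 0.2, cancer = 0.1, stress = 0.1,
                              neurodegeneration = 0.05, oncogene = 0.05,
                              tumor_suppressor = 0.05
                            ),
                            associations = list(), seed) {
  with_seed(seed, {
    mention <- sample(genes, n_documents, replace = TRUE)
    vocab <- names(tag_probs)
    tag_matrix <- matrix(FALSE, n_documents, length(vocab), dimnames = list(NULL, vocab))
    for (tg in vocab) {
      p <- rep(tag_probs[[tg]], n_documents)
      for (assoc in associations) {
        if (assoc$tag == tg) {
          hit <- mention %in% assoc$genes
          p[hit] <- pmin(1, tag_probs[[tg]] * assoc$fold)
        }
      }
      tag_matrix[, tg] <- runif(n_documents) < p
    }
    docs <- tibble::tibble(
      document_id = sprintf("DOC%06d", seq_len(n_documents)),
      genes = as.list(mention),
      tags = purrr::map(seq_len(n_documents), function(i) vocab[tag_matrix[i, ]])
    )
    out <- as_cdm_corpus(docs)
    attr(out, "vocabulary") <- vocab
    attr(out, "truth") <- list(associations = associations, tag_probs = tag_probs, seed = seed)
    out
  })
}

#' Simulate a scale-free interaction network with a planted module
#'
#' A static fitness power-law graph (degree distribution with the requested
#' tail exponent) over the gene universe, plus a planted densely
#' interconnected module: each pair of module genes is connected with
#' probability `planted_density` (a clique at density 1).
#'
#' @param genes Gene universe used as vertex names.
#' @param avg_degree Average degree of the background graph; default 4.
#' @param degree_exponent Power-law tail exponent; default 2.5.
#' @param planted_module Genes of the planted module (default none).
#' @param planted_density Edge probability within the module; default 0.3.
#' @param seed Mandatory integer seed.
#' @return An undirected igraph with a `truth` attribute listing the module.
#' @export
simulate_network <- function(genes, avg_degree = 4, degree_exponent = 2.5,
                             planted_module = character(), planted_density = 0.3,
                             seed) {
  genes <- normalize_gene_symbols(genes)
  planted_module <- normalize_gene_symbols(planted_module)
  n <- length(genes)
  with_seed(seed, {
    g <- igraph::sample_fitness_pl(n, round(avg_degree * n / 2), degree_exponent)
    igraph::V(g)$name <- sample(genes) # decouple fitness rank from gene order
    if (length(planted_module) >= 2) {
      pairs <- utils::combn(planted_module, 2)
      keep <- if (planted_density >= 1) {
        rep(TRUE, ncol(pairs))
      } else {
        runif(ncol(pairs)) < planted_density
      }
      if (any(keep)) {
        g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
      }
    }
    g <- igraph::simplify(g)
    attr(g, "truth") <- list(
      planted_module = sort(planted_module),
      degree_exponent = degree_exponent, seed = seed
    )
    g
  })
}
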