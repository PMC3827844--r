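run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "compactdm_stage_error"
    )
  })
}

#' Per-tier intensity summary with rank-matched random control
#'
#' Mean and variance of gene-level expression intensity within each tier
#' list, compared against a deterministic intensity-rank-matched control:
#' for every tier gene the nearest background gene by intensity rank that is
#' not itself in a tier is taken. Tiers with fewer than two genes have an
#' undefined variance and are flagged.
#'
#' @param records Row-bound `cdm_consistency` records (primary platforms).
#' @param tiers A `cdm_tiers` tibble.
#' @return Tibble: `tier`, `n_genes`, `mean_intensity`, `var_intensity`,
#'   `control_mean`, `control_var`, `variance_undefined`.
#' @export
report_intensity_summary <- function(records, tiers) {
  bg <- expression_background(records)
  bg <- bg[order(-bg$intensity, bg$gene_symbol), ]
  sets <- tier_sets(tiers)
  sets$tier1_plus_2 <- sort(union(sets$tier1, sets$tier2))
  tiered <- unique(unlist(sets))
  free_rank <- which(!bg$gene_symbol %in% tiered)
  rows <- purrr::imap(sets, function(genes, label) {
    ranks <- match(genes, bg$gene_symbol)
    ranks <- ranks[!is.na(ranks)]
    ctrl_idx <- vapply(ranks, function(r) {
      free_rank[which.min(abs(free_rank - r))]
    }, numeric(1))
    x <- bg$intensity[ranks]
    ctrl <- bg$intensity[ctrl_idx]
    tibble::tibble(
      tier = label,
      n_genes = length(x),
      mean_intensity = if (length(x) > 0) mean(x) else NA_real_,
      var_intensity = if (length(x) > 1) var(x) else NA_real_,
      control_mean = if (length(ctrl) > 0) mean(ctrl) else NA_real_,
      control_var = if (length(ctrl) > 1) var(ctrl) else NA_real_,
      variance_undefined = length(x) < 2
    )
  })
  dplyr::bind_rows(rows)
}

default_delimiters <- function(vocabulary) {
  cand <- c(
    disease = "disease",
    cancer = "cancer",
    disease_stress = "disease AND stress",
    disease_specific = "disease AND neurodegeneration"
  )
  tags_of <- function(expr) {
    tk <- stringr::str_match_all(expr, "[A-Za-z0-9_]+")[[1]][, 1]
    setdiff(tolower(tk), c("and", "or", "not"))
  }
  cand[vapply(cand, function(e) all(tags_of(e) %in% tolower(vocabulary)), logical(1))]
}

#' Run the full Compact Disease Model pipeline
#'
#' Orchestrates the stages in order: per-platform consistency scoring, tier
#' assignment (with Tier 0 promotion when an auxiliary multi-disease dataset
#' is given), expression-matched ontology enrichment per tier list,
#' semantic-tag enrichment against the literature corpus, and sub-network
#' scoring of the induced interaction network around the Tier 1 list. A
#' stage whose required input is missing is skipped with a message; a stage
#' that errors aborts the run naming the stage. With an `out_dir`, all stage
#' outputs are written as TSV/GraphML/JSON and a manifest of files,
#' checksums and parameters is produced; identical inputs, parameters and
#' seed give identical checksums.
#'
#' @param primary Named list of [cdm_dataset()] objects (>= 2 platforms).
#' @param annotation Probe annotation tibble (`probe_id`, `gene_symbol`,
#'   optionally `platform_id`).
#' @param auxiliary Optional auxiliary [cdm_dataset()] for Tier 0.
#' @param gene_sets Optional `cdm_gene_sets` (enables Tier 3 and the
#'   enrichment stage).
#' @param corpus Optional `cdm_corpus` (enables the semantic stage).
#' @param network Optional global igraph (enables the network stage).
#' @param intensity_fraction Top-intensity fraction; default 0.40.
#' @param top_fraction High-PCS fraction, primary platforms; default 0.10.
#' @param top_fraction_auxiliary High-PCS fraction, auxiliary; default 0.10.
#' @param tier3_max_set_size Largest pathway for the Tier 3 rule;
#'   default 500.
#' @param cycles Enrichment randomization cycles; default 100.
#' @param fdr_cutoff,min_category_size Enrichment report filters.
#' @param delimiters Named delimiter expressions for the semantic stage;
#'   default built from the corpus vocabulary.
#' @param n_control_resamples Random-control resamples, semantic stage;
#'   default 50.
#' @param include_neighbors,max_subnetwork_size Network stage parameters.
#' @param seed Mandatory integer seed governing every stochastic stage.
#' @param out_dir Optional output directory.
#' @return List of class `cdm_result`: `consistency` (per platform),
#'   `records`, `tiers`, `tier_sets`, `venn`, `enrichment` (per list),
#'   `semantic`, `subnetworks`, `partition`, `intensity_summary`,
#'   `parameters`, and `manifest` when `out_dir` is set.
#' @export
run_cdm <- function(primary, annotation, auxiliary = NULL, gene_sets = NULL,
                    corpus = NULL, network = NULL,
                    intensity_fraction = 0.4, top_fraction = 0.1,
                    top_fraction_auxiliary = 0.1, tier3_max_set_size = 500,
                    cycles = 100, fdr_cutoff = 0.2, min_category_size = 5,
                    delimiters = NULL, n_control_resamples = 50,
                    include_neighbors = TRUE, max_subnetwork_size = 35,
                    seed, out_dir = NULL) {
  if (length(primary) < 2) abort_validation("need >= 2 primary datasets")
  params <- list(
    intensity_fraction = intensity_fraction, top_fraction = top_fraction,
    top_fraction_auxiliary = top_fraction_auxiliary,
    tier3_max_set_size = tier3_max_set_size, cycles = cycles,
    fdr_cutoff = fdr_cutoff, min_category_size = min_category_size,
    n_control_resamples = n_control_resamples,
    include_neighbors = include_neighbors,
    max_subnetwork_size = max_subnetwork_size, seed = seed
  )

  ann_for <- function(pid) {
    if ("platform_id" %in% names(annotation)) {
      sub <- annotation[is.na(annotation$platform_id) | annotation$platform_id == pid, ]
    } else {
      sub <- annotation
    }
    sub
  }

  consistency <- run_stage("consistency", {
    purrr::imap(primary, function(ds, pid) {
      score_consistency(ds, ann_for(ds$platform_id),
        intensity_fraction = intensity_fraction
      )
    })
  })
  records <- dplyr::bind_rows(consistency)

  tiers <- run_stage("tiers", {
    assign_tiers(records,
      gene_sets = gene_sets, top_fraction = top_fraction,
      tier3_max_set_size = tier3_max_set_size
    )
  })

  aux_records <- NULL
  if (!is.null(auxiliary)) {
    aux_records <- run_stage("tier0", {
      score_consistency(auxiliary, ann_for(auxiliary$platform_id),
        intensity_fraction = intensity_fraction
      )
    })
    tiers <- run_stage("tier0", add_tier0(tiers, aux_records, top_fraction_auxiliary))
  } else {
    warn("no auxiliary dataset: Tier 0 stage skipped")
  }
  sets <- tier_sets(tiers)
  venn <- venn_difference(sets)

  enrichment <- NULL
  if (!is.null(gene_sets)) {
    enrichment <- run_stage("enrichment", {
      total <- expression_background(records)
      lists <- list(
        tier0 = sets$tier0,
        tier1 = sets$tier1,
        tier1_plus_2 = union(sets$tier1, sets$tier2),
        tier1_plus_2_plus_3 = Reduce(union, sets[c("tier1", "tier2", "tier3")])
      )
      lists <- lists[lengths(lists) > 0]
      purrr::imap(lists, function(genes, label) {
        enrich_ontology(genes, total, gene_sets,
          cycles = cycles, seed = seed + match(label, names(lists)),
          fdr_cutoff = fdr_cutoff, min_category_size = min_category_size
        )
      })
    })
  }

  semantic <- NULL
  if (!is.null(corpus)) {
    semantic <- run_stage("semantic", {
      vocab <- attr(corpus, "vocabulary")
      delims <- delimiters %||% default_delimiters(vocab)
      background <- expression_background(records)$gene_symbol
      lists <- c(
        list(tier0 = sets$tier0),
        venn["tier1_minus_0"], venn["tier2_minus_1"], venn["tier3_minus_2"]
      )
      lists <- lists[lengths(lists) > 0]
      rows <- purrr::imap(lists, function(genes, label) {
        prof <- semantic_profile(corpus, setNames(list(genes), label), delims)
        ctrl <- random_control_profile(
          corpus, background, length(genes), delims,
          n_resamples = n_control_resamples,
          seed = seed + 100 + match(label, names(lists)), exclude = genes
        )
        relative_enrichment(prof, ctrl)
      })
      out <- dplyr::bind_rows(rows)
      structure(out, class = c("cdm_semantic", class(tibble::tibble())))
    })
  }

  subnetworks <- NULL
  partition <- NULL
  induced <- NULL
  if (!is.null(network) && length(sets$tier1) > 0) {
    net <- run_stage("network", {
      induced <- build_induced_network(sets$tier1, network, include_neighbors)
      partition <- partition_subnetworks(induced, max_size = max_subnetwork_size)
      scores <- score_subnetworks(partition, sets$tier1,
        background_size = igraph::vcount(network), graph = induced
      )
      list(induced = induced, partition = partition, scores = scores)
    })
    induced <- net$induced
    partition <- net$partition
    subnetworks <- net$scores
  }

  intensity_summary <- run_stage(
    "report",
    report_intensity_summary(records, tiers)
  )

  result <- structure(
    list(
      consistency = consistency, records = records,
      auxiliary_records = aux_records,
      tiers = tiers, tier_sets = sets, venn = venn,
      enrichment = enrichment, semantic = semantic,
      subnetworks = subnetworks, partition = partition,
      induced_network = induced,
      intensity_summary = intensity_summary,
      parameters = params
    ),
    class = "cdm_result"
  )
  if (!is.null(out_dir)) {
    result$manifest <- write_cdm_outputs(result, out_dir)
  }
  result
}

write_cdm_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files[[name]] <<- path
    invisible(path)
  }
  for (pid in names(result$consistency)) {
    local({
      tab <- result$consistency[[pid]]
      put(sprintf("consistency_%s.tsv", pid), function(p) readr::write_tsv(tab, p, progress = FALSE))
    })
  }
  put("tiers.tsv", function(p) readr::write_tsv(tidy(result$tiers), p, progress = FALSE))
  put("intensity_summary.tsv", function(p) {
    readr::write_tsv(result$intensity_summary, p, progress = FALSE)
  })
  if (!is.null(result$enrichment)) {
    for (label in names(result$enrichment)) {
      local({
        tab <- tibble::as_tibble(result$enrichment[[label]])
        put(sprintf("enrichment_%s.tsv", label), function(p) {
          readr::write_tsv(tab, p, progress = FALSE)
        })
      })
    }
  }
  if (!is.null(result$semantic)) {
    put("semantic.tsv", function(p) {
      readr::write_tsv(tibble::as_tibble(result$semantic), p, progress = FALSE)
    })
  }
  if (!is.null(result$subnetworks)) {
    put("subnetworks.tsv", function(p) {
      readr::write_tsv(tidy(result$subnetworks), p, progress = FALSE)
    })
    put("partition.tsv", function(p) readr::write_tsv(result$partition, p, progress = FALSE))
    put("induced_network.graphml", function(p) {
      igraph::write_graph(result$induced_network, p, format = "graphml")
    })
  }
  checksums <- tools::md5sum(unlist(files))
  manifest <- list(
    files = as.list(setNames(unname(checksums), names(files))),
    parameters = result$parameters
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  manifest
}

#' @export
print.cdm_result <- function(x, ...) {
  s <- x$tier_sets
  cat("<cdm_result>\n")
  cat(sprintf(
    "  tiers: %d tier0 / %d tier1 / %d tier2 / %d tier3 / %d unconfirmed genes\n",
    length(s$tier0), length(s$tier1), length(s$tier2), length(s$tier3),
    length(s$high_pcs_unconfirmed)
  ))
  if (!is.null(x$enrichment)) {
    cat(sprintf(
      "  enrichment: %s\n",
      paste(sprintf("%s (%d terms)", names(x$enrichment),
        vapply(x$enrichment, nrow, integer(1))), collapse = ", ")
    ))
  }
  if (!is.null(x$subnetworks)) {
    cat(sprintf(
      "  sub-networks: %d, top score %.1f\n",
      nrow(x$subnetworks), max(x$subnetworks$score)
    ))
  }
  invisible(x)
}

#' Run the pipeline from a configuration file
#'
#' The configuration (YAML or JSON, or an equivalent R list) names the input
#' files and parameters: `datasets:` a list of entries with `matrix`,
#' `metadata`, `role` (`primary`/`auxiliary`) and optional `platform`;
#' `annotation`, `gene_sets`, `corpus`, `network` file paths;
#' `parameters:` any [run_cdm()] parameter; `seed`; `out_dir`. Every
#' referenced path must exist at validation time.
#'
#' @param config Path to a YAML/JSON config file, or a list.
#' @return A `cdm_result`.
#' @export
run_cdm_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (is.null(config$seed)) abort_validation("config must set a seed")
  paths <- c(
    unlist(purrr::map(config$datasets, function(d) c(d$matrix, d$metadata))),
    config$annotation, config$gene_sets, config$corpus, config$network
  )
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort_validation(sprintf("config path(s) not found: %s", paste(missing, collapse = ", ")))
  }
  primary <- list()
  auxiliary <- NULL
  for (d in config$datasets) {
    ds <- read_expression_matrix(d$matrix, d$metadata, platform_id = d$platform)
    if (identical(d$role, "auxiliary")) {
      auxiliary <- ds
    } else {
      primary[[ds$platform_id]] <- ds
    }
  }
  args <- c(
    list(
      primary = primary,
      annotation = read_probe_annotation(config$annotation),
      auxiliary = auxiliary,
      gene_sets = if (!is.null(config$gene_sets)) read_gene_sets(config$gene_sets),
      corpus = if (!is.null(config$corpus)) read_corpus(config$corpus),
      network = if (!is.null(config$network)) read_edge_list(config$network),
      seed = config$seed,
      out_dir = config$out_dir
    ),
    config$parameters
  )
  do.call(run_cdm, args)
}
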