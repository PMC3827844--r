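#' Flag high-PCS probes
#'
#' Within each platform, probes that passed the intensity filter are ranked
#' by Primary Consistency Score and the top `top_fraction` flagged
#' (`ceiling(top_fraction * n)` probes; ties broken by lexicographically
#' smaller probe id).
#'
#' @param records A `cdm_consistency` tibble, or several row-bound together.
#' @param top_fraction Fraction flagged per platform; default 0.10.
#' @return `records` with a logical `high_pcs` column added.
#' @export
select_high_pcs <- function(records, top_fraction = 0.1) {
  if (nrow(records) == 0) abort_validation("empty record list")
  if (top_fraction <= 0 || top_fraction > 1) abort_validation("`top_fraction` must be in (0, 1]")
  flagged <- dplyr::group_modify(
    dplyr::group_by(records, .data$platform_id),
    function(df, key) {
      eligible <- df$passed_intensity_filter & !is.na(df$pcs)
      pool <- df[eligible, ]
      k <- top_n_count(top_fraction, nrow(pool))
      top <- top_k_ids(pool$probe_id, pool$pcs, k)
      df$high_pcs <- eligible & df$probe_id %in% top
      df
    }
  )
  out <- dplyr::ungroup(flagged)
  out <- out[, union(names(records), "high_pcs")]
  structure(out, class = unique(c("cdm_consistency", class(tibble::tibble()))))
}

rule_order <- c("T1a", "T1b", "T1c", "T2a", "T2b", "T3", "T0")

tier_of_rules <- function(rules) {
  if (any(rules %in% c("T1a", "T1b", "T1c"))) return("1")
  if (any(rules %in% c("T2a", "T2b"))) return("2")
  if ("T3" %in% rules) return("3")
  "high_pcs_unconfirmed"
}

#' Assign consistency tiers to genes
#'
#' Converts high-PCS probes from two or more primary platforms into
#' gene-level evidence tiers. With `d` the set of directions of a gene's
#' high-PCS probes ("concordant" meaning all equal and non-zero):
#'
#' * **T2a** — at least two high-PCS probes on one platform, that platform's
#'   probes concordant;
#' * **T2b** — high-PCS probes on at least two platforms, all concordant;
#' * **T1a** — T2b and at least two high-PCS probes on the multi-probe
#'   platform, all concordant;
#' * **T1c** — at least three high-PCS probes on one platform, concordant;
#' * **T3** — the gene shares a gene set (of size at most
#'   `tier3_max_set_size`, so that vacuously large categories do not count
#'   as pathways) with at least one other high-PCS gene;
#' * **T1b** — qualifies for Tier 3 and Tier 2 simultaneously.
#'
#' A gene receives the best (lowest-numbered) tier it qualifies for;
#' remaining high-PCS genes are `high_pcs_unconfirmed`. Direction
#' discordance (including an exact tie of the majority sign) disqualifies
#' the Tier 1/2 rules.
#'
#' @param records Row-bound `cdm_consistency` tibbles from the primary
#'   platforms (gene symbols attached). If no `high_pcs` column is present,
#'   [select_high_pcs()] is applied with `top_fraction`.
#' @param gene_sets Optional `cdm_gene_sets` used for the Tier 3 pathway
#'   co-membership rule; when `NULL`, T3/T1b are not evaluated.
#' @param top_fraction High-PCS fraction per platform; default 0.10.
#' @param tier3_max_set_size Largest gene set accepted as a "pathway" for
#'   Tier 3; default 500.
#' @param multiprobe_platform Platform id treated as the multi-probe design
#'   for rule T1a; defaults to the platform with the highest mean number of
#'   probes per gene.
#' @return Tibble of class `cdm_tiers`: `gene_symbol`, `tier`, `tier0`
#'   (logical, set later by [add_tier0()]), `rule_fired`, `rules_satisfied`,
#'   `consensus_direction`, `n_probes`, `n_platforms`, and list-column
#'   `supporting_probes`.
#' @export
assign_tiers <- function(records, gene_sets = NULL, top_fraction = 0.1,
                         tier3_max_set_size = 500, multiprobe_platform = NULL) {
  if (length(unique(records$platform_id)) < 2) {
    abort_validation("tier assignment needs records from >= 2 primary platforms")
  }
  if (!"high_pcs" %in% names(records)) {
    records <- select_high_pcs(records, top_fraction)
  }
  if (is.null(multiprobe_platform)) {
    ppg <- dplyr::summarise(
      dplyr::group_by(records[!is.na(records$gene_symbol), ], .data$platform_id),
      ppg = dplyr::n() / dplyr::n_distinct(.data$gene_symbol),
      .groups = "drop"
    )
    multiprobe_platform <- ppg$platform_id[order(-ppg$ppg, ppg$platform_id)][1]
  }
  hp <- records[records$high_pcs %in% TRUE, ]
  unmapped <- is.na(hp$gene_symbol) | hp$gene_symbol == ""
  if (any(unmapped)) {
    warn(sprintf("dropping %d high-PCS probe(s) with no gene symbol", sum(unmapped)))
    hp <- hp[!unmapped, ]
  }
  if (nrow(hp) == 0) abort_validation("no high-PCS probe maps to a gene")

  support <- split(
    tibble::as_tibble(hp)[, c("probe_id", "platform_id", "direction", "pcs")],
    hp$gene_symbol
  )
  base <- dplyr::summarise(
    dplyr::group_by(hp, .data$gene_symbol),
    n_probes = dplyr::n(),
    n_platforms = dplyr::n_distinct(.data$platform_id),
    .groups = "drop"
  )
  base$supporting_probes <- unname(support[base$gene_symbol])

  # Tier 3: genes sharing a sufficiently small set with another high-PCS gene
  hp_genes <- unique(hp$gene_symbol)
  t3_genes <- character()
  if (!is.null(gene_sets) && nrow(gene_sets) > 0) {
    small <- gene_sets[lengths(gene_sets$members) <= tier3_max_set_size, ]
    t3_genes <- unique(unlist(purrr::map(small$members, function(m) {
      inside <- intersect(m, hp_genes)
      if (length(inside) >= 2) inside else character()
    })))
  }

  evaluate_gene <- function(probes, gene) {
    dirs <- probes$direction
    concordant <- function(d) length(d) > 0 && !anyNA(d) && all(d != 0) && length(unique(d)) == 1
    all_conc <- concordant(dirs)
    by_platform <- split(probes, probes$platform_id)
    n_by_platform <- vapply(by_platform, nrow, integer(1))
    plat_conc <- vapply(by_platform, function(p) concordant(p$direction), logical(1))
    rules <- character()
    t2a <- any(n_by_platform >= 2 & plat_conc)
    t2b <- length(by_platform) >= 2 && all_conc
    if (t2b && multiprobe_platform %in% names(n_by_platform) &&
      n_by_platform[[multiprobe_platform]] >= 2 && all_conc) {
      rules <- c(rules, "T1a")
    }
    t3 <- gene %in% t3_genes
    if (t3 && (t2a || t2b)) rules <- c(rules, "T1b")
    if (any(n_by_platform >= 3 & plat_conc)) rules <- c(rules, "T1c")
    if (t2a) rules <- c(rules, "T2a")
    if (t2b) rules <- c(rules, "T2b")
    if (t3) rules <- c(rules, "T3")
    # consensus direction: majority sign; an exact tie is discordant (0)
    s <- sign(sum(sign(dirs), na.rm = TRUE))
    list(rules = list(rules[order(match(rules, rule_order))]), consensus_direction = s)
  }

  ev <- purrr::map2(base$supporting_probes, base$gene_symbol, evaluate_gene)
  base$rules_satisfied <- purrr::map(ev, function(e) e$rules[[1]])
  base$consensus_direction <- purrr::map_dbl(ev, "consensus_direction")
  base$rule_fired <- purrr::map_chr(base$rules_satisfied, function(r) {
    if (length(r) == 0) "none" else r[1]
  })
  base$tier <- purrr::map_chr(base$rules_satisfied, tier_of_rules)
  base$tier0 <- FALSE
  out <- base[, c(
    "gene_symbol", "tier", "tier0", "rule_fired", "rules_satisfied",
    "consensus_direction", "n_probes", "n_platforms", "supporting_probes"
  )]
  out <- out[order(match(out$tier, c("1", "2", "3", "high_pcs_unconfirmed")), out$gene_symbol), ]
  structure(out,
    class = c("cdm_tiers", class(tibble::tibble())),
    multiprobe_platform = multiprobe_platform,
    top_fraction = top_fraction
  )
}

#' Promote genes to Tier 0 using an auxiliary multi-disease study
#'
#' Tier 0 is the intersection of the Tier 1 and Tier 2 genes with the
#' highest-PCS genes of an auxiliary dataset covering several related
#' diseases — the genes participating in the pathology class broadly, not
#' only in the study disease. Promoted genes keep their underlying Tier 1/2
#' assignment (`tier` column) and gain `tier0 = TRUE`.
#'
#' @param tiers A `cdm_tiers` tibble.
#' @param auxiliary_records `cdm_consistency` records of the auxiliary
#'   dataset (gene symbols attached).
#' @param top_fraction High-PCS fraction applied to the auxiliary dataset;
#'   default 0.10, mirroring the primary selection.
#' @return The updated `cdm_tiers` tibble.
#' @export
add_tier0 <- function(tiers, auxiliary_records, top_fraction = 0.1) {
  if (is.null(auxiliary_records) || nrow(auxiliary_records) == 0) {
    abort_validation("empty auxiliary record list")
  }
  aux <- select_high_pcs(auxiliary_records, top_fraction)
  aux_genes <- unique(aux$gene_symbol[aux$high_pcs %in% TRUE & !is.na(aux$gene_symbol)])
  tier12 <- tiers$gene_symbol[tiers$tier %in% c("1", "2")]
  tiers$tier0 <- tiers$gene_symbol %in% intersect(tier12, aux_genes)
  tiers$rules_satisfied <- purrr::map2(
    tiers$rules_satisfied, tiers$tier0,
    function(r, is0) if (is0) unique(c(r, "T0")) else setdiff(r, "T0")
  )
  tiers
}

#' Gene sets of each consistency tier
#'
#' @param tiers A `cdm_tiers` tibble.
#' @return Named list of character vectors: `tier0`, `tier1`, `tier2`,
#'   `tier3`, `high_pcs_unconfirmed`. Tier 0 genes also appear in their
#'   underlying Tier 1 or 2 list.
#' @export
tier_sets <- function(tiers) {
  list(
    tier0 = sort(tiers$gene_symbol[tiers$tier0]),
    tier1 = sort(tiers$gene_symbol[tiers$tier == "1"]),
    tier2 = sort(tiers$gene_symbol[tiers$tier == "2"]),
    tier3 = sort(tiers$gene_symbol[tiers$tier == "3"]),
    high_pcs_unconfirmed = sort(tiers$gene_symbol[tiers$tier == "high_pcs_unconfirmed"])
  )
}

#' Venn-differenced tier lists
#'
#' Set differences between consecutive tier lists, isolating the evidence
#' unique to each level: Tier 1 minus 0, Tier 2 minus 1, Tier 3 minus 2.
#'
#' @param sets Named list as returned by [tier_sets()] (needs `tier0` ..
#'   `tier3`).
#' @return Named list `tier1_minus_0`, `tier2_minus_1`, `tier3_minus_2`.
#' @export
venn_difference <- function(sets) {
  list(
    tier1_minus_0 = sort(setdiff(sets$tier1, sets$tier0)),
    tier2_minus_1 = sort(setdiff(sets$tier2, sets$tier1)),
    tier3_minus_2 = sort(setdiff(sets$tier3, sets$tier2))
  )
}
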