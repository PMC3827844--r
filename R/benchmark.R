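#' Score probes by a single case/control comparison
#'
#' The traditional single-experiment benchmark: one Welch test per probe,
#' using only the first subset comparison the dataset supports, with no
#' consistency averaging.
#'
#' @param dataset A [cdm_dataset()].
#' @param intensity_fraction Top-intensity fraction tested; default 0.40.
#' @return Tibble with `probe_id`, `neg_log10_p`.
#' @export
single_comparison_scores <- function(dataset, intensity_fraction = 0.4) {
  kept <- filter_top_intensity(dataset, intensity_fraction)
  st <- subset_tests(dataset, kept)
  first <- st[st$subset_id == st$subset_id[1], ]
  tibble::tibble(probe_id = first$probe_id, neg_log10_p = first$neg_log10_p)
}

#' Planted-gene recovery of tiering versus simpler rankings
#'
#' Runs consistency scoring and tier assignment on a simulated study and
#' compares the precision (planted genes recovered per gene reported) of
#' three size-matched gene lists: the Tier 1 list, the top genes by Primary
#' Consistency Score alone, and the top genes by a single-comparison Welch
#' test (the traditional analysis). Gene-level scores aggregate probes and
#' platforms by their maximum.
#'
#' @param sim A study from [simulate_study()] (needs >= 2 primary
#'   platforms).
#' @param intensity_fraction,top_fraction Passed to the scoring steps.
#' @return One-row tibble: `k` (list size, = Tier 1 size),
#'   `precision_tier1`, `precision_top_pcs`, `precision_single_test`.
#' @export
evaluate_recovery <- function(sim, intensity_fraction = 0.4, top_fraction = 0.1) {
  primary <- sim$datasets[names(sim$roles)[sim$roles == "primary"]]
  records <- dplyr::bind_rows(purrr::map(primary, function(d) {
    ann <- sim$annotation[sim$annotation$platform_id == d$platform_id, ]
    score_consistency(d, ann, intensity_fraction = intensity_fraction)
  }))
  tiers <- assign_tiers(records, top_fraction = top_fraction)
  tier1 <- tier_sets(tiers)$tier1
  k <- length(tier1)
  truth <- sim$truth$planted_genes

  best_genes <- function(tab, score_col) {
    by_gene <- dplyr::summarise(
      dplyr::group_by(tab[!is.na(tab$gene_symbol), ], .data$gene_symbol),
      s = max(.data[[score_col]]), .groups = "drop"
    )
    top_k_ids(by_gene$gene_symbol, by_gene$s, k)
  }

  scored <- records[records$passed_intensity_filter & !is.na(records$pcs), ]
  top_pcs <- best_genes(scored, "pcs")

  single <- dplyr::bind_rows(purrr::map(primary, function(d) {
    sc <- single_comparison_scores(d, intensity_fraction)
    dplyr::left_join(sc, sim$annotation[, c("probe_id", "gene_symbol")], by = "probe_id")
  }))
  top_single <- best_genes(single, "neg_log10_p")

  tibble::tibble(
    k = k,
    precision_tier1 = mean(tier1 %in% truth),
    precision_top_pcs = mean(top_pcs %in% truth),
    precision_single_test = mean(top_single %in% truth)
  )
}
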