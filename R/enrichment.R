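#' Gene-level expression background from consistency records
#'
#' Collapses probe-level records to one intensity per gene (the maximum of
#' its probes' mean intensities) over all supplied platforms. This is the
#' "total file" against which enrichment is computed; genes absent from the
#' ontology stay in it and dilute the per-term background fraction.
#'
#' @param records Row-bound `cdm_consistency` tibbles.
#' @return Tibble with columns `gene_symbol`, `intensity`.
#' @export
expression_background <- function(records) {
  recs <- records[!is.na(records$gene_symbol) & records$gene_symbol != "", ]
  dplyr::summarise(
    dplyr::group_by(recs, .data$gene_symbol),
    intensity = max(.data$mean_intensity, na.rm = TRUE),
    .groups = "drop"
  )
}

#' Expression-matched background ("expression-adjusted total file")
#'
#' Highly expressed genes give more consistent differential-expression
#' signals, so an enrichment of a high-consistency list against the full
#' gene universe is confounded by intensity. The background is therefore
#' trimmed: the total list is ranked by intensity (descending) and the
#' largest prefix whose mean intensity is at least the mean intensity of the
#' changed list is retained, always including every changed gene. When the
#' changed list's mean does not exceed the global mean, the full total list
#' is returned.
#'
#' @param total Tibble with columns `gene_symbol`, `intensity` (the total
#'   gene list, e.g. [expression_background()]).
#' @param changed_genes Character vector of changed genes; all must be
#'   present in `total`.
#' @return Character vector of background gene symbols.
#' @export
match_background_by_expression <- function(total, changed_genes) {
  changed_genes <- unique(changed_genes)
  missing <- setdiff(changed_genes, total$gene_symbol)
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "changed gene(s) absent from total list: %s",
      paste(missing, collapse = ", ")
    ))
  }
  ord <- order(-total$intensity, total$gene_symbol, method = "radix")
  genes <- total$gene_symbol[ord]
  intens <- total$intensity[ord]
  target <- mean(intens[genes %in% changed_genes])
  prefix_mean <- cumsum(intens) / seq_along(intens)
  ok <- which(prefix_mean >= target)
  k <- if (length(ok) == 0) length(genes) else max(ok)
  union(genes[seq_len(k)], changed_genes)
}

#' Enrichment coefficient
#'
#' `ENR = (CG / L) / (TG / T)`: the fraction of the changed list falling in
#' a functional category over the fraction of the background in that
#' category.
#'
#' @param CG Changed genes in the category.
#' @param L Size of the changed list.
#' @param TG Background genes in the category (>= 1).
#' @param T_total Background size.
#' @return The enrichment coefficient (vectorized).
#' @export
#' @examples
#' enrichment_coefficient(4, 100, 8, 3000)
enrichment_coefficient <- function(CG, L, TG, T_total) {
  if (any(TG < 1) || any(L < 1)) abort_validation("TG and L must be >= 1")
  if (any(CG > L) || any(TG > T_total)) abort_validation("need CG <= L and TG <= T")
  (CG / L) / (TG / T_total)
}

#' One-sided Fisher p-value for category enrichment
#'
#' Upper-tail hypergeometric probability `P(X >= CG)` with
#' `X ~ Hypergeom(T, TG, L)`: the chance that a uniformly drawn changed list
#' of size `L` captures at least `CG` of the `TG` category members.
#'
#' @inheritParams enrichment_coefficient
#' @return One-sided p-value (vectorized).
#' @export
#' @examples
#' fisher_one_sided(5, 5, 5, 10) # 1 / choose(10, 5)
fisher_one_sided <- function(CG, L, TG, T_total) {
  if (any(CG > TG)) abort_validation("impossible margins: CG > TG")
  if (any(CG > L) || any(TG > T_total) || any(L > T_total)) {
    abort_validation("impossible margins")
  }
  phyper(CG - 1, TG, T_total - TG, L, lower.tail = FALSE)
}

# Per-term counts, ENR and p for one changed list against one background.
compute_term_stats <- function(changed, background, gene_sets) {
  background <- unique(background)
  changed <- intersect(unique(changed), background)
  L <- length(changed)
  T_total <- length(background)
  if (L == 0) abort_validation("changed list is empty (after background restriction)")
  TG <- vapply(gene_sets$members, function(m) length(intersect(m, background)), integer(1))
  keep <- TG >= 1
  sets <- gene_sets[keep, ]
  TG <- TG[keep]
  CG <- vapply(sets$members, function(m) length(intersect(m, changed)), integer(1))
  tibble::tibble(
    term_id = sets$term_id,
    term_name = sets$term_name,
    TG = TG,
    CG = CG,
    ENR = enrichment_coefficient(CG, L, TG, T_total),
    p_value = fisher_one_sided(CG, L, TG, T_total),
    list_size_L = L,
    background_size_T = T_total
  )
}

#' Permutation (randomization-cycle) false discovery rate
#'
#' For each cycle a random gene list of the observed size is drawn uniformly
#' without replacement from the background and all term p-values recomputed.
#' The FDR of a term is the average number of random terms at or below its
#' p-value, divided by the number of observed terms at or below it, clipped
#' to `[0, 1]`.
#'
#' @param observed Tibble from [compute_term_stats()] / [enrich_ontology()]
#'   (columns `term_id`, `p_value`, `list_size_L`).
#' @param background Character vector, the background gene universe.
#' @param gene_sets `cdm_gene_sets` collection.
#' @param cycles Number of randomization cycles; default 100.
#' @param seed Mandatory integer seed.
#' @return `observed` with an `fdr` column added.
#' @export
permutation_fdr <- function(observed, background, gene_sets, cycles = 100, seed) {
  if (cycles < 1) abort_validation("`cycles` must be >= 1")
  background <- unique(background)
  L <- observed$list_size_L[1]
  sets <- gene_sets[gene_sets$term_id %in% observed$term_id, ]
  # terms x background incidence matrix for fast per-cycle counting
  M <- vapply(sets$members, function(m) background %in% m, logical(length(background)))
  TG <- colSums(M)
  T_total <- length(background)
  rand_p <- with_seed(seed, {
    unlist(lapply(seq_len(cycles), function(i) {
      idx <- sample.int(T_total, L)
      CG <- colSums(M[idx, , drop = FALSE])
      phyper(CG - 1, TG, T_total - TG, L, lower.tail = FALSE)
    }))
  })
  rand_sorted <- sort(rand_p)
  obs_sorted <- sort(observed$p_value)
  n_rand <- findInterval(observed$p_value, rand_sorted) / cycles
  n_obs <- findInterval(observed$p_value, obs_sorted)
  observed$fdr <- pmin(pmax(n_rand / n_obs, 0), 1)
  observed
}

#' Filter and sort an enrichment report
#'
#' Drops categories smaller than `min_category_size` in the background,
#' keeps terms below the FDR cutoff, and sorts by FDR ascending, then
#' enrichment coefficient descending, then term id.
#'
#' @param results Enrichment tibble with columns `TG`, `ENR`, `fdr`.
#' @param fdr_cutoff Keep terms with `fdr` strictly below this; default 0.2.
#' @param min_category_size Smallest accepted category size; default 5.
#' @return The filtered, sorted tibble.
#' @export
filter_and_sort <- function(results, fdr_cutoff = 0.2, min_category_size = 5) {
  out <- results[results$TG >= min_category_size & results$fdr < fdr_cutoff, ]
  out[order(out$fdr, -out$ENR, out$term_id), ]
}

#' Expression-matched functional enrichment with permutation FDR
#'
#' The full ontological-enrichment step for one changed gene list: build the
#' expression-adjusted background (optional), count category membership,
#' compute enrichment coefficients and one-sided Fisher p-values, estimate
#' the FDR by randomization cycles, then filter and sort the report.
#'
#' @param changed_genes Character vector, the changed ("L") list.
#' @param total Tibble with `gene_symbol`, `intensity`
#'   (e.g. [expression_background()]).
#' @param gene_sets `cdm_gene_sets` collection.
#' @param match_expression Trim the background to match the changed list's
#'   mean intensity (default `TRUE`).
#' @param cycles Randomization cycles for the FDR; default 100.
#' @param seed Mandatory integer seed for the randomization.
#' @param fdr_cutoff,min_category_size Report filters; defaults 0.2 and 5.
#' @param filter Apply [filter_and_sort()] (default `TRUE`); when `FALSE`
#'   the unfiltered per-term table is returned.
#' @return Tibble of class `cdm_enrichment` with columns `term_id`,
#'   `term_name`, `TG`, `CG`, `ENR`, `p_value`, `fdr`, `list_size_L`,
#'   `background_size_T`.
#' @export
enrich_ontology <- function(changed_genes, total, gene_sets, match_expression = TRUE,
                            cycles = 100, seed, fdr_cutoff = 0.2,
                            min_category_size = 5, filter = TRUE) {
  background <- if (match_expression) {
    match_background_by_expression(total, changed_genes)
  } else {
    unique(total$gene_symbol)
  }
  res <- compute_term_stats(changed_genes, background, gene_sets)
  res <- permutation_fdr(res, background, gene_sets, cycles = cycles, seed = seed)
  if (filter) res <- filter_and_sort(res, fdr_cutoff, min_category_size)
  structure(res,
    class = c("cdm_enrichment", class(tibble::tibble())),
    matched_background = match_expression, cycles = cycles
  )
}
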