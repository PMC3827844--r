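#' Tidy a tier assignment
#'
#' One row per gene with the list-columns flattened: supporting probes as a
#' `;`-joined string and all satisfied rules collapsed.
#'
#' @param x A `cdm_tiers` tibble.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.cdm_tiers <- function(x, ...) {
  tibble::tibble(
    gene_symbol = x$gene_symbol,
    tier = x$tier,
    tier0 = x$tier0,
    rule_fired = x$rule_fired,
    rules_satisfied = purrr::map_chr(x$rules_satisfied, paste, collapse = ";"),
    consensus_direction = x$consensus_direction,
    n_probes = x$n_probes,
    n_platforms = x$n_platforms,
    supporting_probes = purrr::map_chr(
      x$supporting_probes,
      function(p) paste(p$probe_id, collapse = ";")
    )
  )
}

#' Summarize a tier assignment
#'
#' @param x A `cdm_tiers` tibble.
#' @param ... Unused.
#' @return One-row tibble with tier cardinalities and the down-regulated
#'   fraction of the Tier 1+2 genes.
#' @export
glance.cdm_tiers <- function(x, ...) {
  t12 <- x[x$tier %in% c("1", "2"), ]
  tibble::tibble(
    n_genes = nrow(x),
    n_tier0 = sum(x$tier0),
    n_tier1 = sum(x$tier == "1"),
    n_tier2 = sum(x$tier == "2"),
    n_tier3 = sum(x$tier == "3"),
    n_unconfirmed = sum(x$tier == "high_pcs_unconfirmed"),
    frac_down_tier12 = if (nrow(t12) > 0) mean(t12$consensus_direction < 0) else NA_real_
  )
}

#' @export
tidy.cdm_consistency <- function(x, ...) tibble::as_tibble(x)

#' Summarize a consistency table
#'
#' @param x A `cdm_consistency` tibble.
#' @param ... Unused.
#' @return One-row tibble: probe counts, median PCS and down-regulated
#'   fraction among intensity-filtered probes.
#' @export
glance.cdm_consistency <- function(x, ...) {
  tested <- x[x$passed_intensity_filter & !is.na(x$pcs), ]
  tibble::tibble(
    n_probes = nrow(x),
    n_tested = nrow(tested),
    median_pcs = stats::median(tested$pcs),
    frac_down = mean(tested$direction < 0)
  )
}

#' @export
tidy.cdm_enrichment <- function(x, ...) tibble::as_tibble(x)

#' Summarize an enrichment report
#'
#' @param x A `cdm_enrichment` tibble.
#' @param ... Unused.
#' @return One-row tibble: term count, best FDR, largest enrichment
#'   coefficient, list and background sizes.
#' @export
glance.cdm_enrichment <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x),
    min_fdr = if (nrow(x) > 0) min(x$fdr) else NA_real_,
    max_enr = if (nrow(x) > 0) max(x$ENR) else NA_real_,
    list_size_L = if (nrow(x) > 0) x$list_size_L[1] else NA_integer_,
    background_size_T = if (nrow(x) > 0) x$background_size_T[1] else NA_integer_
  )
}

#' Tidy sub-network scores
#'
#' @param x A `cdm_subnetworks` tibble.
#' @param ... Unused.
#' @return Tibble with node sets flattened to `;`-joined strings.
#' @export
tidy.cdm_subnetworks <- function(x, ...) {
  out <- tibble::as_tibble(x[, setdiff(names(x), "nodes")])
  out$molecules <- purrr::map_chr(x$nodes, paste, collapse = ";")
  out
}

#' Summarize sub-network scores
#'
#' @param x A `cdm_subnetworks` tibble.
#' @param ... Unused.
#' @return One-row tibble: sub-network count, top score, focus molecules in
#'   the top sub-network.
#' @export
glance.cdm_subnetworks <- function(x, ...) {
  tibble::tibble(
    n_subnetworks = nrow(x),
    top_score = if (nrow(x) > 0) max(x$score) else NA_real_,
    top_focus_molecules = if (nrow(x) > 0) x$focus_molecules[which.max(x$score)] else NA_integer_,
    total_focus_molecules = sum(x$focus_molecules)
  )
}

#' @export
tidy.cdm_semantic <- function(x, ...) tibble::as_tibble(x)
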