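# Fixture builders and independent oracles shared across the suite.

# A deterministic toy dataset: `n_probes` probes whose intensities are simple
# arithmetic patterns, one mixed subset unless `samples` is supplied.
toy_dataset <- function(n_probes = 3, platform_id = "TOY",
                        samples = NULL, intensities = NULL) {
  if (is.null(samples)) {
    samples <- tibble::tibble(
      sample_id = c("c1", "c2", "d1", "d2"),
      condition = c("control", "control", "disease", "disease"),
      subset = "s1"
    )
  }
  if (is.null(intensities)) {
    intensities <- outer(seq_len(n_probes) * 10, seq_len(nrow(samples)), `+`)
    dimnames(intensities) <- list(sprintf("p%02d", seq_len(n_probes)), samples$sample_id)
  }
  cdm_dataset(intensities, samples, platform_id)
}

# Exhaustive hypergeometric upper-tail oracle: enumerate every possible draw
# of size L from a background of size T_total with TG "category" elements and
# count draws capturing >= CG of them. Independent of phyper.
enum_hyper_tail <- function(CG, L, TG, T_total) {
  if (L == 0) return(as.numeric(CG <= 0))
  draws <- utils::combn(T_total, L)
  hits <- colSums(draws <= TG) # elements 1..TG are the category members
  mean(hits >= CG)
}

# Brute-force document scan oracle for semantic hit counting.
enum_count_hits <- function(docs, genes, required_tags = NULL, forbidden_tags = NULL,
                            mode = c("and", "or")) {
  mode <- match.arg(mode)
  n <- 0L
  for (i in seq_len(nrow(docs))) {
    if (!any(docs$genes[[i]] %in% genes)) next
    tags <- docs$tags[[i]]
    ok <- TRUE
    if (!is.null(required_tags)) {
      ok <- if (mode == "and") all(required_tags %in% tags) else any(required_tags %in% tags)
    }
    if (ok && !is.null(forbidden_tags) && any(forbidden_tags %in% tags)) ok <- FALSE
    if (ok) n <- n + 1L
  }
  n
}

# Hand-built six-document corpus used by the semantic tests.
toy_corpus <- function() {
  docs <- tibble::tibble(
    document_id = paste0("d", 1:6),
    genes = list("A", c("A", "B"), "B", "C", c("A", "C"), "B"),
    tags = list(
      c("disease", "stress"), "disease", c("disease", "stress"),
      "cancer", c("stress", "oncogene"), c("tumor_suppressor", "disease")
    )
  )
  compactdm:::as_cdm_corpus(docs)
}

# Minimal consistency-record table for tier-rule unit tests: one row per
# probe with the fields assign_tiers() consumes.
tier_records <- function(...) {
  rows <- list(...)
  recs <- dplyr::bind_rows(purrr::map(rows, function(r) {
    tibble::tibble(
      probe_id = r[["probe_id"]],
      gene_symbol = r[["gene"]],
      platform_id = r[["platform"]],
      pcs = r[["pcs"]] %||% 2,
      direction = r[["direction"]],
      mean_intensity = r[["mean_intensity"]] %||% 1000,
      n_comparisons = 3L,
      passed_intensity_filter = TRUE,
      high_pcs = r[["high_pcs"]] %||% TRUE
    )
  }))
  recs
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Small simulated study shared by pipeline-level tests (cheap but full
# structure: 2 primary platforms + auxiliary).
small_sim <- function(seed = 42, n_genes = 400) {
  simulate_study(n_genes = n_genes, n_per_group = 6, seed = seed)
}
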