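#' Parse a Boolean tag delimiter
#'
#' Delimiters restrict literature queries the way additional PubMed search
#' terms do: Boolean expressions over topic tags with `AND`, `OR`, `NOT`
#' (case-insensitive) and parentheses, e.g.
#' `"disease AND (stress OR cancer)"`.
#'
#' @param expr Delimiter string, or `NULL` for no constraint.
#' @param vocabulary Character vector of allowed tags.
#' @return A quoted R expression over tag indicator vectors, or `NULL`.
#' @export
parse_delimiter <- function(expr, vocabulary) {
  if (is.null(expr) || !nzchar(trimws(expr))) return(NULL)
  tokens <- stringr::str_match_all(expr, "\\(|\\)|[A-Za-z0-9_'-]+")[[1]][, 1]
  residue <- gsub("\\(|\\)|[A-Za-z0-9_'-]+|\\s", "", expr)
  if (nzchar(residue)) {
    abort_parse(sprintf("unexpected character(s) in delimiter: '%s'", residue))
  }
  mapped <- vapply(tokens, function(tk) {
    switch(tolower(tk),
      "and" = "&", "or" = "|", "not" = "!",
      "(" = "(", ")" = ")",
      {
        tag <- tolower(tk)
        if (!tag %in% tolower(vocabulary)) {
          abort_parse(sprintf("unknown tag '%s' in delimiter", tk))
        }
        sprintf(".tags[[\"%s\"]]", vocabulary[match(tag, tolower(vocabulary))])
      }
    )
  }, character(1))
  parsed <- tryCatch(
    str2lang(paste(mapped, collapse = " ")),
    error = function(e) abort_parse(sprintf("malformed delimiter expression: %s", expr))
  )
  parsed
}

# docs x tags logical incidence, named list of indicator vectors
corpus_tag_indicators <- function(corpus) {
  vocab <- attr(corpus, "vocabulary") %||% sort(unique(unlist(corpus$tags)))
  out <- lapply(vocab, function(tg) {
    vapply(corpus$tags, function(t) tg %in% t, logical(1))
  })
  names(out) <- vocab
  out
}

delimiter_mask <- function(corpus, delimiter) {
  if (is.null(delimiter)) return(rep(TRUE, nrow(corpus)))
  parsed <- if (is.language(delimiter)) {
    delimiter
  } else {
    parse_delimiter(delimiter, attr(corpus, "vocabulary") %||% unique(unlist(corpus$tags)))
  }
  if (is.null(parsed)) return(rep(TRUE, nrow(corpus)))
  eval(parsed, envir = list(.tags = corpus_tag_indicators(corpus)))
}

#' Count literature hits for a gene list
#'
#' Number of documents mentioning at least one listed gene (the Boolean-OR
#' query over gene symbols) and, when a delimiter is given, also satisfying
#' the tag expression.
#'
#' @param corpus A `cdm_corpus`.
#' @param genes Character vector of gene symbols.
#' @param delimiter Boolean tag expression string, or `NULL` for the
#'   unrestricted query.
#' @return Integer hit count.
#' @export
count_hits <- function(corpus, genes, delimiter = NULL) {
  genes <- normalize_gene_symbols(genes)
  if (length(genes) == 0) {
    warn("empty gene list: 0 hits")
    return(0L)
  }
  gene_mask <- vapply(corpus$genes, function(g) any(g %in% genes), logical(1))
  sum(gene_mask & delimiter_mask(corpus, delimiter))
}

#' Semantic-tag profile of gene lists
#'
#' For each gene list and each delimiter, counts the delimited hits, the
#' total (undelimited) hits and their ratio — the fraction of a list's
#' literature that carries the delimiter's topic.
#'
#' @param corpus A `cdm_corpus`.
#' @param gene_lists Named list of character vectors.
#' @param delimiters Named character vector of Boolean tag expressions.
#' @return Tibble of class `cdm_semantic`: `list_label`, `delimiter`,
#'   `hits`, `total_hits`, `ratio`.
#' @export
semantic_profile <- function(corpus, gene_lists, delimiters) {
  if (is.null(names(gene_lists))) abort_validation("`gene_lists` must be named")
  if (is.null(names(delimiters))) names(delimiters) <- delimiters
  rows <- purrr::imap(gene_lists, function(genes, label) {
    total <- count_hits(corpus, genes, NULL)
    purrr::imap(delimiters, function(expr, dname) {
      hits <- count_hits(corpus, genes, expr)
      tibble::tibble(
        list_label = label, delimiter = dname,
        hits = hits, total_hits = total,
        ratio = if (total > 0) hits / total else NA_real_
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  structure(out, class = c("cdm_semantic", class(tibble::tibble())))
}

#' Size-matched random-control semantic profile
#'
#' Draws `n_resamples` random gene lists of the given size from the
#' measured expression background (excluding the query genes, so the control
#' does not absorb the association under test), profiles each, and averages
#' the ratios.
#'
#' @param corpus A `cdm_corpus`.
#' @param background Character vector of genes to sample from.
#' @param size Control list size (match the tier list under study).
#' @param delimiters Named character vector of delimiters.
#' @param n_resamples Number of control draws averaged; default 50.
#' @param seed Mandatory integer seed.
#' @param exclude Genes removed from the sampling frame (the query list).
#' @return `cdm_semantic` tibble with `list_label = "random_control"`;
#'   `ratio` is the mean over resamples, `hits`/`total_hits` are summed.
#' @export
random_control_profile <- function(corpus, background, size, delimiters,
                                   n_resamples = 50, seed, exclude = NULL) {
  frame <- setdiff(unique(normalize_gene_symbols(background)), normalize_gene_symbols(exclude %||% character()))
  if (length(frame) < size) abort_validation("background smaller than requested control size")
  profiles <- with_seed(seed, {
    lapply(seq_len(n_resamples), function(i) {
      draw <- sample(frame, size)
      semantic_profile(corpus, list(random_control = draw), delimiters)
    })
  })
  all <- dplyr::bind_rows(profiles)
  out <- dplyr::summarise(
    dplyr::group_by(all, .data$list_label, .data$delimiter),
    hits = sum(.data$hits), total_hits = sum(.data$total_hits),
    ratio = mean(.data$ratio, na.rm = TRUE), .groups = "drop"
  )
  structure(out, class = c("cdm_semantic", class(tibble::tibble())))
}

#' Fold enrichment of tier lists over the random control
#'
#' The ratio of ratios: how much more often a tier list's literature carries
#' a topic tag than the literature of a size-matched random control.
#' Undefined control ratios are flagged (`NA` fold), not thrown.
#'
#' @param tier_profile `cdm_semantic` tibble for the tier lists.
#' @param control_profile `cdm_semantic` tibble for the random control.
#' @return `tier_profile` with `control_ratio` and `fold_vs_control`
#'   columns.
#' @export
relative_enrichment <- function(tier_profile, control_profile) {
  ctrl <- control_profile[, c("delimiter", "ratio")]
  names(ctrl)[2] <- "control_ratio"
  out <- dplyr::left_join(tibble::as_tibble(tier_profile), ctrl, by = "delimiter")
  out$fold_vs_control <- ifelse(
    is.na(out$control_ratio) | out$control_ratio == 0,
    NA_real_, out$ratio / out$control_ratio
  )
  structure(out, class = c("cdm_semantic", class(tibble::tibble())))
}

#' Split-half variance of a semantic ratio
#'
#' Variation of the delimited/total hit ratio is estimated by dividing the
#' gene list into `k_splits` random equal subsets, repeating the query per
#' subset and pooling the variance of the per-split ratios (the pooled
#' variance is attributed equally to each split).
#'
#' @param corpus A `cdm_corpus`.
#' @param genes Character vector of gene symbols.
#' @param delimiter Boolean tag expression.
#' @param k_splits Number of equal splits; default 2.
#' @param seed Mandatory integer seed for the split.
#' @return List with `ratios` (per split), `variance` (pooled sample
#'   variance) and `per_split_variance` (`variance / k_splits`).
#' @export
subset_variance <- function(corpus, genes, delimiter, k_splits = 2, seed) {
  genes <- unique(normalize_gene_symbols(genes))
  if (k_splits < 2) abort_validation("`k_splits` must be >= 2")
  if (length(genes) < k_splits) abort_validation("gene list smaller than `k_splits`")
  splits <- with_seed(seed, {
    shuffled <- sample(genes)
    split(shuffled, rep_len(seq_len(k_splits), length(shuffled)))
  })
  ratios <- vapply(splits, function(g) {
    total <- count_hits(corpus, g, NULL)
    if (total == 0) return(NA_real_)
    count_hits(corpus, g, delimiter) / total
  }, numeric(1))
  v <- var(ratios, na.rm = TRUE)
  list(ratios = unname(ratios), variance = v, per_split_variance = v / k_splits)
}

#' Oncogene vs tumor-suppressor hit ratio
#'
#' Ratio of documents tagged as oncogene-related to documents tagged as
#' tumor-suppressor-related among a gene list's literature. A zero
#' denominator yields an infinite ratio with `flagged_infinite = TRUE`
#' rather than an error.
#'
#' @param corpus A `cdm_corpus` whose vocabulary includes both tags.
#' @param genes Character vector of gene symbols.
#' @param oncogene_tag,suppressor_tag Tag names; defaults `"oncogene"` and
#'   `"tumor_suppressor"`.
#' @return List with `oncogene_hits`, `suppressor_hits`, `ratio`,
#'   `flagged_infinite`.
#' @export
onco_suppressor_ratio <- function(corpus, genes, oncogene_tag = "oncogene",
                                  suppressor_tag = "tumor_suppressor") {
  vocab <- attr(corpus, "vocabulary")
  if (!all(c(oncogene_tag, suppressor_tag) %in% vocab)) {
    abort_validation("corpus vocabulary must include both the oncogene and suppressor tags")
  }
  onc <- count_hits(corpus, genes, oncogene_tag)
  sup <- count_hits(corpus, genes, suppressor_tag)
  list(
    oncogene_hits = onc, suppressor_hits = sup,
    ratio = if (sup > 0) onc / sup else Inf,
    flagged_infinite = sup == 0
  )
}
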