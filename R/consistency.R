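#' Welch's unequal-variance two-sample t-test
#'
#' Two-tailed p-value from the unequal-variance t statistic with
#' Welch-Satterthwaite degrees of freedom, the per-subset test applied to
#' every probe. Implemented in closed form; when both groups have zero
#' variance and equal means the p-value is 1 (no evidence of change), and
#' when both variances are zero with unequal means the p-value is the
#' documented floor `p_floor`.
#'
#' @param control,disease Numeric intensity vectors with at least 2 finite
#'   values each.
#' @param p_floor Smallest reportable p-value, so that `-log10(p)` stays
#'   finite. Default `1e-300`.
#' @return Two-sided p-value in `(0, 1]`.
#' @export
#' @examples
#' welch_test(c(10, 12, 11), c(14, 16, 15))
welch_test <- function(control, disease, p_floor = 1e-300) {
  control <- control[is.finite(control)]
  disease <- disease[is.finite(disease)]
  if (length(control) < 2 || length(disease) < 2) {
    abort_validation("each group needs >= 2 finite values")
  }
  drop(welch_test_matrix(
    matrix(control, nrow = 1), matrix(disease, nrow = 1),
    p_floor = p_floor
  )$p_value)
}

# Row-wise Welch test over probe x sample matrices; NA-aware. Returns
# mean_control, mean_disease, p_value per row.
welch_test_matrix <- function(Xc, Xd, p_floor = 1e-300) {
  stats_of <- function(X) {
    n <- rowSums(!is.na(X))
    m <- rowMeans(X, na.rm = TRUE)
    ss <- rowSums((X - m)^2, na.rm = TRUE)
    v <- ifelse(n > 1, ss / (n - 1), NA_real_)
    list(n = n, m = m, v = v)
  }
  c_ <- stats_of(Xc)
  d_ <- stats_of(Xd)
  if (any(c_$n < 2) || any(d_$n < 2)) {
    abort_validation("each group needs >= 2 finite values for every probe")
  }
  se2 <- c_$v / c_$n + d_$v / d_$n
  tt <- (c_$m - d_$m) / sqrt(se2)
  df <- se2^2 / ((c_$v / c_$n)^2 / (c_$n - 1) + (d_$v / d_$n)^2 / (d_$n - 1))
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(c_$m[degenerate] == d_$m[degenerate], 1, p_floor)
  p <- pmin(pmax(p, p_floor), 1)
  list(mean_control = c_$m, mean_disease = d_$m, p_value = p)
}

#' Retain the top-intensity fraction of probes
#'
#' Probes are ranked by their mean intensity over all samples (control and
#' disease pooled) and the upper `fraction` retained — low-intensity signals
#' are unlikely to exceed hybridization noise and are excluded from
#' consistency scoring. The cut keeps `ceiling(fraction * n)` probes; ties at
#' the boundary are broken by lexicographically smaller probe id so the
#' selection is deterministic.
#'
#' @param dataset A [cdm_dataset()].
#' @param fraction Fraction in (0, 1] to retain; default 0.40.
#' @return Character vector of retained probe ids.
#' @export
filter_top_intensity <- function(dataset, fraction = 0.4) {
  if (!inherits(dataset, "cdm_dataset")) abort_validation("`dataset` must be a cdm_dataset")
  n <- nrow(dataset$intensities)
  if (n == 0) abort_validation("empty dataset")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort_validation("`fraction` must be in (0, 1]")
  }
  means <- rowMeans(dataset$intensities, na.rm = TRUE)
  top_k_ids(rownames(dataset$intensities), means, top_n_count(fraction, n))
}

# Enumerate the case/control comparisons a dataset supports. Subsets that
# contain both conditions are compared within themselves (tissue-locus
# design); condition-pure subsets are crossed, every control split against
# every disease split (cohort-split design, "four separate values" for 2x2).
build_comparisons <- function(samples) {
  tab <- dplyr::count(samples, .data$subset, .data$condition)
  wide <- tidyr::pivot_wider(tab,
    names_from = "condition", values_from = "n", values_fill = 0
  )
  if (!"control" %in% names(wide)) wide$control <- 0L
  if (!"disease" %in% names(wide)) wide$disease <- 0L
  usable <- wide[(wide$control >= 2) == (wide$control > 0) &
    (wide$disease >= 2) == (wide$disease > 0), ]
  dropped <- setdiff(wide$subset, usable$subset)
  if (length(dropped) > 0) {
    warn(sprintf(
      "subset(s) with < 2 samples in a represented condition dropped: %s",
      paste(dropped, collapse = ", ")
    ))
  }
  mixed <- usable$subset[usable$control >= 2 & usable$disease >= 2]
  pure_c <- usable$subset[usable$control >= 2 & usable$disease == 0]
  pure_d <- usable$subset[usable$disease >= 2 & usable$control == 0]
  ids_of <- function(sub, cond) {
    samples$sample_id[samples$subset == sub & samples$condition == cond]
  }
  rows <- list()
  for (s in mixed) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      subset_id = s,
      control_samples = list(ids_of(s, "control")),
      disease_samples = list(ids_of(s, "disease"))
    )
  }
  for (sc in pure_c) {
    for (sd in pure_d) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        subset_id = paste(sc, sd, sep = "|"),
        control_samples = list(ids_of(sc, "control")),
        disease_samples = list(ids_of(sd, "disease"))
      )
    }
  }
  if (length(rows) == 0) {
    abort_validation("dataset supports no case/control comparison (need >= 2 samples per group)")
  }
  dplyr::bind_rows(rows)
}

#' Per-subset test results for a dataset
#'
#' Runs the Welch test for every probe in every supported case/control
#' comparison and reports group means, p-values and their negative decimal
#' logarithms — the raw material of the Primary Consistency Score.
#'
#' @param dataset A [cdm_dataset()].
#' @param probe_ids Probes to test; default all.
#' @param p_floor Smallest reportable p-value.
#' @return Tibble with columns `probe_id`, `subset_id`, `mean_control`,
#'   `mean_disease`, `p_value`, `neg_log10_p`.
#' @export
subset_tests <- function(dataset, probe_ids = NULL, p_floor = 1e-300) {
  if (is.null(probe_ids)) probe_ids <- rownames(dataset$intensities)
  X <- dataset$intensities[probe_ids, , drop = FALSE]
  comparisons <- build_comparisons(dataset$samples)
  res <- purrr::pmap(comparisons, function(subset_id, control_samples, disease_samples) {
    w <- welch_test_matrix(
      X[, control_samples, drop = FALSE],
      X[, disease_samples, drop = FALSE],
      p_floor = p_floor
    )
    tibble::tibble(
      probe_id = probe_ids,
      subset_id = subset_id,
      mean_control = w$mean_control,
      mean_disease = w$mean_disease,
      p_value = w$p_value,
      neg_log10_p = -log10(w$p_value)
    )
  })
  dplyr::bind_rows(res)
}

#' Primary Consistency Score of one probe
#'
#' The arithmetic mean of `-log10(p)` over a probe's subset tests: a probe
#' scores highly only when the case/control difference replicates across
#' independent tissue subsets or cohort splits, not when a single comparison
#' is extreme.
#'
#' @param subset_results Tibble of subset test results (needs column
#'   `neg_log10_p`), all for the same probe.
#' @return The PCS, a non-negative scalar.
#' @export
#' @examples
#' compute_pcs(tibble::tibble(neg_log10_p = -log10(c(0.01, 0.001, 0.1, 1))))
compute_pcs <- function(subset_results) {
  if (is.null(subset_results) || nrow(subset_results) == 0) {
    abort_validation("need >= 1 subset result")
  }
  mean(subset_results$neg_log10_p)
}

#' Direction of expression change of one probe
#'
#' Sign of the mean over subsets of `log(mean_disease / mean_control)`:
#' ratios of group-average intensities give the fold change, and the
#' log-ratio average aggregates them symmetrically. Exactly balanced ratios
#' give direction 0.
#'
#' @param subset_results Tibble with columns `mean_control`, `mean_disease`.
#' @return `+1`, `-1` or `0`.
#' @export
compute_direction <- function(subset_results) {
  if (is.null(subset_results) || nrow(subset_results) == 0) {
    abort_validation("need >= 1 subset result")
  }
  if (any(subset_results$mean_control <= 0 | subset_results$mean_disease <= 0)) {
    abort_validation("group means must be positive to form fold-change ratios")
  }
  sign(mean(log(subset_results$mean_disease / subset_results$mean_control)))
}

#' Score differential-expression consistency for one dataset
#'
#' The per-dataset evidence table: probes are intensity-filtered (upper 40%
#' by pooled mean intensity by default), each retained probe is Welch-tested
#' in every subset comparison, the negative log p-values are averaged into
#' the Primary Consistency Score (PCS) and the aggregate fold-change
#' direction is recorded. Probes with more than `max_missing` missing samples
#' are excluded before analysis.
#'
#' @param dataset A [cdm_dataset()].
#' @param annotation Optional probe annotation tibble (columns `probe_id`,
#'   `gene_symbol`) used to attach gene symbols.
#' @param intensity_fraction Top-intensity fraction retained (default 0.40).
#' @param p_floor Smallest reportable p-value (default 1e-300).
#' @param max_missing Maximum tolerated fraction of missing samples per
#'   probe (default 0.2).
#' @return Tibble of class `cdm_consistency` with one row per probe:
#'   `probe_id`, `gene_symbol`, `platform_id`, `pcs`, `direction`,
#'   `mean_intensity`, `n_comparisons`, `passed_intensity_filter`. Probes
#'   outside the intensity filter keep `NA` scores.
#' @export
score_consistency <- function(dataset, annotation = NULL, intensity_fraction = 0.4,
                              p_floor = 1e-300, max_missing = 0.2) {
  X <- dataset$intensities
  miss <- rowMeans(is.na(X))
  if (any(miss > max_missing)) {
    inform(sprintf(
      "excluding %d probe(s) with > %.0f%% missing samples",
      sum(miss > max_missing), 100 * max_missing
    ))
    X <- X[miss <= max_missing, , drop = FALSE]
    dataset$intensities <- X
  }
  kept <- filter_top_intensity(dataset, intensity_fraction)
  tests <- subset_tests(dataset, kept, p_floor = p_floor)
  scored <- dplyr::summarise(
    dplyr::group_by(tests, .data$probe_id),
    pcs = mean(.data$neg_log10_p),
    direction = sign(mean(log(.data$mean_disease / .data$mean_control))),
    n_comparisons = dplyr::n(),
    .groups = "drop"
  )
  out <- tibble::tibble(
    probe_id = rownames(X),
    platform_id = dataset$platform_id,
    mean_intensity = rowMeans(X, na.rm = TRUE),
    passed_intensity_filter = rownames(X) %in% kept
  )
  out <- dplyr::left_join(out, scored, by = "probe_id")
  if (!is.null(annotation)) {
    ann <- annotation[, c("probe_id", "gene_symbol")]
    out <- dplyr::left_join(out, ann, by = "probe_id")
  } else {
    out$gene_symbol <- NA_character_
  }
  out <- out[, c(
    "probe_id", "gene_symbol", "platform_id", "pcs", "direction",
    "mean_intensity", "n_comparisons", "passed_intensity_filter"
  )]
  structure(out, class = c("cdm_consistency", class(tibble::tibble())))
}

#' Expected recall across platform combinations
#'
#' `REC = C(N, m) * P(m)`: with `N` independent platforms and `m`-way
#' intersections, each combination contributing `P(m)` strong mechanistic
#' associates, the total recall of true positives grows with the number of
#' contributing platform combinations.
#'
#' @param n_platforms Number of independent platforms `N`.
#' @param m Intersection order, `1 <= m <= N`.
#' @param per_combination_yield Associates per combination, `P(m)`.
#' @return The recall estimate.
#' @export
#' @examples
#' estimate_recall(3, 2, 10)
estimate_recall <- function(n_platforms, m, per_combination_yield) {
  if (m < 1 || m > n_platforms) abort_validation("need 1 <= m <= n_platforms")
  choose(n_platforms, m) * per_combination_yield
}

#' Probability that a mechanistic hypothesis is fully correct
#'
#' `PEC = q^n`: a hypothesis chaining `n` genes from a list whose fraction of
#' bona-fide mechanistically relevant members is `q` is experimentally
#' correct only when every step is. Distilling lists (raising `q`) pays off
#' exponentially in hypothesis complexity `n`.
#'
#' @param q True-positive fraction of the gene list, in `[0, 1]`.
#' @param n Number of steps in the hypothesis.
#' @return The probability `q^n`.
#' @export
#' @examples
#' compute_pec(0.5, 3)
compute_pec <- function(q, n) {
  if (!is.numeric(q) || q < 0 || q > 1) abort_validation("`q` must be in [0, 1]")
  if (n < 1) abort_validation("`n` must be a positive integer")
  q^n
}
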