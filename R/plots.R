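#' Plot an enrichment report
#'
#' Bar chart of enrichment coefficients for the top terms, shaded by FDR.
#'
#' @param object A `cdm_enrichment` tibble.
#' @param n_terms Terms shown; default 20.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cdm_enrichment <- function(object, n_terms = 20, ...) {
  df <- utils::head(tibble::as_tibble(object), n_terms)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$ENR,
    y = stats::reorder(.data$term_name, .data$ENR),
    fill = .data$fdr
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_gradient(low = "#2c7bb6", high = "#d7191c") +
    ggplot2::labs(
      x = "enrichment coefficient (ENR)", y = NULL, fill = "FDR",
      title = "Expression-matched functional enrichment"
    ) +
    ggplot2::theme_minimal()
}

#' Plot tier composition
#'
#' Gene counts per consistency tier, split by consensus direction of
#' expression change.
#'
#' @param object A `cdm_tiers` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cdm_tiers <- function(object, ...) {
  df <- tibble::as_tibble(object[, c("tier", "consensus_direction")])
  df$direction <- factor(
    dplyr::case_when(
      df$consensus_direction > 0 ~ "up",
      df$consensus_direction < 0 ~ "down",
      TRUE ~ "discordant"
    ),
    levels = c("down", "up", "discordant")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tier, fill = .data$direction)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(values = c(down = "#1b7837", up = "#c51b7d", discordant = "grey60")) +
    ggplot2::labs(
      x = "consistency tier", y = "genes",
      title = "Tier composition and direction of change"
    ) +
    ggplot2::theme_minimal()
}

#' Plot semantic-tag enrichment
#'
#' Grouped bars of delimited/total hit ratios (or the fold over the random
#' control when present) per gene list and delimiter.
#'
#' @param object A `cdm_semantic` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cdm_semantic <- function(object, ...) {
  df <- tibble::as_tibble(object)
  yvar <- if ("fold_vs_control" %in% names(df)) "fold_vs_control" else "ratio"
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$list_label, y = .data[[yvar]], fill = .data$delimiter
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL,
      y = if (yvar == "fold_vs_control") "fold vs random control" else "hit ratio",
      title = "Literature semantic-tag enrichment"
    ) +
    ggplot2::theme_minimal()
}

#' Plot sub-network scores
#'
#' @param object A `cdm_subnetworks` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cdm_subnetworks <- function(object, ...) {
  df <- tibble::as_tibble(object[, c("subnetwork_id", "score", "focus_molecules")])
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$subnetwork_id), y = .data$score, fill = .data$focus_molecules
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "sub-network", y = expression(-log[10] ~ p),
      fill = "focus\nmolecules", title = "Sub-network non-randomness scores"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-tier intensity against the rank-matched control
#'
#' @param summary_table Output of [report_intensity_summary()].
#' @return A ggplot object.
#' @export
plot_intensity_summary <- function(summary_table) {
  df <- tidyr::pivot_longer(
    summary_table[, c("tier", "mean_intensity", "control_mean")],
    -"tier",
    names_to = "group", values_to = "mean"
  )
  df$group <- ifelse(df$group == "mean_intensity", "tier genes", "rank-matched control")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tier, y = .data$mean, fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "mean intensity (arbitrary units)", fill = NULL,
      title = "Expression intensity by consistency tier"
    ) +
    ggplot2::theme_minimal()
}
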