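#' Kaplan-Meier plot for a median-split survival result
#'
#' Step curves per diagnosis-by-stratum group, faceted by gene set, with the
#' log-rank fdr annotated per facet.
#'
#' @param object A [survival_by_score()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survival_result <- function(object, ...) {
  km <- object$km |>
    group_by(.data$set, .data$stratum_label) |>
    dplyr::group_modify(~ bind_rows(
      tibble(time = 0, survival = 1), select(.x, "time", "survival"))) |>
    ungroup()
  lab <- mutate(object$tests,
                label = sprintf("fdr = %.3g", .data$fdr))
  ggplot2::ggplot(km, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$stratum_label)) +
    ggplot2::geom_step() +
    ggplot2::geom_text(data = lab, inherit.aes = FALSE, x = Inf, y = Inf,
                       hjust = 1.1, vjust = 1.5,
                       ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::facet_wrap(~set) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months since biopsy", y = "graft survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Co-occurrence ratio curves
#'
#' @param curves A [cooccurrence_curve()] result (rows from one or more
#'   samples / pairs may be bound together).
#' @return A ggplot object.
#' @export
plot_cooccurrence <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$distance, .data$ratio,
                               group = interaction(.data$sample_id,
                                                   .data$query),
                               colour = .data$query)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~anchor) +
    ggplot2::labs(x = "distance (µm)", y = "co-occurrence ratio") +
    ggplot2::theme_minimal()
}

#' Gene-set score distributions by diagnosis and stratum
#'
#' @param strat A [median_stratify()] result.
#' @param cohort The matching [bulk_cohort()] (to attach diagnoses).
#' @return A ggplot object.
#' @export
plot_scores <- function(strat, cohort) {
  d <- dplyr::inner_join(strat, cohort$clinical,
                         by = c(sample = "sample_id"))
  ggplot2::ggplot(d, ggplot2::aes(.data$diagnosis, .data$score,
                                  colour = .data$stratum)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(~set) +
    ggplot2::labs(y = "score (log2 vs control)") +
    ggplot2::theme_minimal()
}
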