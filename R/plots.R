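# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of a cross-model flux comparison
#'
#' Log10 fold change against -log10 Welch p, colored by significance
#' call; reactions absent from one model are drawn as triangles.
#'
#' @param object A `flux_comparison` from [compare_reaction_fluxes()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flux_comparison
#' @export
autoplot.flux_comparison <- function(object, ...) {
  cfg <- attr(object, "config")
  d <- tibble::as_tibble(object)
  d$log_fold <- log10(d$fold_change)
  d$mlog_p <- -log10(pmax(d$t_p, 1e-300))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_fold, y = .data$mlog_p)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$significant,
                                     shape = .data$absent_in != ""),
                        alpha = 0.8) +
    ggplot2::geom_vline(xintercept = log10(cfg$fold_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(cfg$t_test_cutoff),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log10 fold change of |mean flux|",
                  y = "-log10 Welch p",
                  color = "significant", shape = "absent in one model") +
    ggplot2::theme_minimal()
}

#' Bar chart of subsystem enrichment
#'
#' @param object An `enrichment_result` from [flux_enrichment()].
#' @param ... Unused.
#' @return A ggplot of -log10 adjusted p per subsystem; the 0.05 line
#'   is dashed.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$subsystem <- stats::reorder(d$subsystem, -d$adjusted_p)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$subsystem,
                                  y = -log10(pmax(.data$adjusted_p, 1e-300)),
                                  fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "steelblue")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10 BH-adjusted p", fill = "p < 0.05") +
    ggplot2::theme_minimal()
}

#' Flux distributions of selected reactions in a sample
#'
#' @param object A `flux_sample` from [sample_flux_space()].
#' @param reactions Reaction ids to show (default: the 9 with the
#'   largest flux variance).
#' @param ... Unused.
#' @return A faceted ggplot of per-reaction flux histograms.
#' @method autoplot flux_sample
#' @export
autoplot.flux_sample <- function(object, reactions = NULL, ...) {
  if (is.null(reactions)) {
    v <- apply(object$samples, 2, stats::var)
    reactions <- object$reactions[order(-v)][seq_len(min(9, length(v)))]
  }
  d <- tidy.flux_sample(object)
  d <- d[d$reaction_id %in% reactions, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$flux)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", color = NA) +
    ggplot2::facet_wrap(~reaction_id, scales = "free") +
    ggplot2::labs(x = "flux (mmol/gDW/h)", y = "samples") +
    ggplot2::theme_minimal()
}
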