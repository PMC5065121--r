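#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the distribution of fitness effects
#'
#' Violin-and-point view of per-strain mean fitness by condition, with
#' dashed lines at the classification cutoffs, in the style of the
#' bean plots used for pooled-screen fitness distributions.
#'
#' @param fitness Tibble `strain_id`, `condition`, `mean_fitness`
#'   (e.g. `tidy(fit)`).
#' @param cutoff Cutoff drawn as dashed lines (default 0.10).
#' @return A ggplot object.
#' @export
plot_dfe <- function(fitness, cutoff = 0.10) {
  ggplot2::ggplot(fitness,
                  ggplot2::aes(x = .data$condition,
                               y = .data$mean_fitness)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.25, size = 0.4) +
    ggplot2::geom_hline(yintercept = c(-cutoff, cutoff),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0, colour = "black") +
    ggplot2::labs(x = NULL, y = "relative fitness (log2 / generation)")
}

#' Distribution-of-fitness-effects plot for a fit object
#' @param object A `barseq_fit`.
#' @param cutoff Cutoff drawn as dashed lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot barseq_fit
#' @export
autoplot.barseq_fit <- function(object, cutoff = 0.10, ...) {
  plot_dfe(object$fitness, cutoff = cutoff)
}

#' Plot a deterministic selection trajectory
#'
#' @param scenario A [selection_scenario()].
#' @param generations Upper bound of the generation axis (default: a
#'   little past fixation).
#' @param thresholds Frequencies marked with horizontal reference lines.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(scenario, generations = NULL,
                            thresholds = c(0.05, 0.5)) {
  if (is.null(generations)) {
    generations <- ceiling(1.1 * fixation_time(scenario))
  }
  traj <- selection_trajectory(scenario, 0:generations)
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$generation,
                                     y = .data$frequency)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "generation", y = "mutant frequency")
}

#' Plot per-gene recurrence across evolve-and-resequence samples
#'
#' @param catalog A [mutation_catalog()].
#' @param max_genes Show at most this many of the most recurrent genes.
#' @return A ggplot object.
#' @export
plot_recurrence <- function(catalog, max_genes = 30) {
  rc <- head(recurrence_counts(catalog), max_genes)
  ggplot2::ggplot(rc, ggplot2::aes(x = stats::reorder(.data$gene,
                                                      .data$n_samples),
                                   y = .data$n_samples)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "samples with a mutation")
}
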