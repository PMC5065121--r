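#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a bar-seq fitness fit
#'
#' @param x A `barseq_fit` from [fit_fitness()].
#' @param replicates Return per-replicate slopes instead of the
#'   replicate-averaged fitness.
#' @param ... Unused.
#' @return A tibble: per strain and condition, the mean fitness and the
#'   number of replicates (or the per-replicate slopes).
#' @method tidy barseq_fit
#' @export
tidy.barseq_fit <- function(x, replicates = FALSE, ...) {
  if (replicates) x$replicate_fitness else x$fitness
}

#' One-row summary of a bar-seq fitness fit
#'
#' @param x A `barseq_fit`.
#' @param ... Unused.
#' @return One-row tibble: strain/condition/replicate counts, fitness
#'   range, and the number of strains dropped by the count filter.
#' @method glance barseq_fit
#' @export
glance.barseq_fit <- function(x, ...) {
  tibble::tibble(
    n_strains = dplyr::n_distinct(x$fitness$strain_id),
    n_conditions = dplyr::n_distinct(x$fitness$condition),
    max_replicates = max(x$fitness$n_replicates),
    min_fitness = min(x$fitness$mean_fitness),
    max_fitness = max(x$fitness$mean_fitness),
    n_dropped = length(x$dropped)
  )
}

#' @rdname tidy.barseq_fit
#' @method tidy contingency_result
#' @export
tidy.contingency_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic %||% NA_real_,
                 p_value = x$p_value, method = x$method)
}

#' @rdname glance.barseq_fit
#' @method glance dfe_summary
#' @export
glance.dfe_summary <- function(x, ...) {
  dplyr::left_join(
    x$totals,
    dplyr::select(dplyr::filter(x$enrichment, .data$class == "beneficial"),
                  "cutoff", enrichment_p = "p_value"),
    by = "cutoff"
  ) |>
    dplyr::mutate(control_fraction = x$control_fraction)
}
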