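#' Fraction of control strains inside the neutral fitness window
#'
#' The cutoff used to call strains beneficial or deleterious is
#' calibrated on the control collection: the window `[-halfwidth,
#' +halfwidth]` should contain nearly all control strains (98.2% at
#' +/-10% in the calibrating screen).
#'
#' @param control_fitness Fitness values of the control strains.
#' @param halfwidth Half-width of the neutral window (default 0.10).
#' @return Fraction of values inside the closed window.
#' @export
#' @examples
#' control_window_fraction(c(-0.05, 0, 0.05)) # 1
control_window_fraction <- function(control_fitness, halfwidth = 0.10) {
  if (length(control_fitness) == 0) {
    stop("empty control fitness vector", call. = FALSE)
  }
  mean(control_fitness >= -halfwidth & control_fitness <= halfwidth)
}

#' Classify fitness values into beneficial / neutral / deleterious
#'
#' Strict cutoffs: beneficial iff fitness is greater than `+cutoff`,
#' deleterious iff less than `-cutoff`; values exactly at the boundary
#' are neutral.
#'
#' @param mean_fitness Numeric vector of fitness values.
#' @param cutoff Positive cutoff (default 0.10, i.e. a 10% fitness
#'   change).
#' @return Factor with levels deleterious, neutral, beneficial.
#' @export
#' @examples
#' classify_fitness(c(0.428, 0.10, -0.15))
classify_fitness <- function(mean_fitness, cutoff = 0.10) {
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  cut(mean_fitness, breaks = c(-Inf, -cutoff, cutoff, Inf),
      labels = c("deleterious", "neutral", "beneficial"),
      right = FALSE) |>
    (\(x) {
      # cut() cannot express (strictly > cutoff, strictly < -cutoff)
      # with one orientation, so fix the boundaries explicitly
      x[mean_fitness == -cutoff] <- "neutral"
      x[mean_fitness == cutoff] <- "neutral"
      x
    })()
}

#' Summarize a distribution of fitness effects against a control pool
#'
#' For each cutoff: per-condition class counts of the test strains
#' (strain x condition events), deduplicated strain-level beneficial
#' counts, cross-condition overlap of beneficial strains, the control
#' window fraction, and 2x2 chi-square enrichment tests of the test
#' collections against the control collection (beneficial vs not, and
#' deleterious vs not).
#'
#' @param fitness Tibble with `strain_id`, `condition`, `mean_fitness`
#'   (a `barseq_fit$fitness`, or any table of the same shape).
#' @param control_ids Strain ids forming the control collection; must be
#'   disjoint from no test strain (ids not in `control_ids` are tests).
#' @param cutoffs Cutoffs at which to classify (default 0.10 and 0.05).
#' @param correct Apply Yates continuity correction to the enrichment
#'   chi-square (default `FALSE`).
#' @return A `dfe_summary` list: `$by_condition`, `$totals`,
#'   `$overlap`, `$enrichment`, `$control_fraction`.
#' @export
dfe_summary <- function(fitness, control_ids = character(),
                        cutoffs = c(0.10, 0.05), correct = FALSE) {
  is_control <- fitness$strain_id %in% control_ids
  test <- fitness[!is_control, ]
  control <- fitness[is_control, ]
  if (nrow(control) == 0) {
    warning("no control strains; enrichment test skipped", call. = FALSE)
  }

  per_cutoff <- purrr::map(cutoffs, function(cutoff) {
    cls <- dplyr::mutate(test,
                         class = classify_fitness(.data$mean_fitness, cutoff))
    by_condition <- cls |>
      dplyr::summarise(
        n_beneficial = sum(.data$class == "beneficial"),
        n_deleterious = sum(.data$class == "deleterious"),
        n_neutral = sum(.data$class == "neutral"),
        .by = "condition"
      ) |>
      dplyr::mutate(cutoff = cutoff, .before = 1)
    beneficial_strains <- cls |>
      dplyr::filter(.data$class == "beneficial") |>
      dplyr::distinct(.data$strain_id, .data$condition)
    n_per_strain <- dplyr::count(beneficial_strains, .data$strain_id)
    totals <- tibble::tibble(
      cutoff = cutoff,
      n_beneficial_events = sum(by_condition$n_beneficial),
      n_deleterious_events = sum(by_condition$n_deleterious),
      n_beneficial_strains = nrow(n_per_strain),
      n_multi_condition = sum(n_per_strain$n > 1)
    )
    enrichment <- if (nrow(control) == 0) {
      NULL
    } else {
      ctl_cls <- classify_fitness(control$mean_fitness, cutoff)
      purrr::map_dfr(c("beneficial", "deleterious"), function(direction) {
        tab <- rbind(
          test = c(sum(cls$class == direction),
                   sum(cls$class != direction)),
          control = c(sum(ctl_cls == direction), sum(ctl_cls != direction))
        )
        if (sum(tab[, 1]) == 0) {
          # no strain in this class anywhere: proportions identical,
          # nothing to test
          stat <- 0
          p <- 1
        } else {
          ht <- suppressWarnings(chisq.test(tab, correct = correct))
          stat <- unname(ht$statistic)
          p <- ht$p.value
        }
        tibble::tibble(cutoff = cutoff, class = direction,
                       n_test = tab[1, 1], n_control = tab[2, 1],
                       statistic = stat, p_value = p)
      })
    }
    list(by_condition = by_condition, totals = totals,
         enrichment = enrichment,
         beneficial = dplyr::mutate(beneficial_strains, cutoff = cutoff,
                                    .before = 1))
  })

  structure(
    list(
      by_condition = purrr::map_dfr(per_cutoff, "by_condition"),
      totals = purrr::map_dfr(per_cutoff, "totals"),
      enrichment = purrr::map_dfr(per_cutoff, "enrichment"),
      beneficial = purrr::map_dfr(per_cutoff, "beneficial"),
      control_fraction = if (nrow(control) > 0) {
        control_window_fraction(control$mean_fitness,
                                halfwidth = max(cutoffs))
      } else {
        NA_real_
      },
      cutoffs = cutoffs
    ),
    class = "dfe_summary"
  )
}

#' @export
print.dfe_summary <- function(x, ...) {
  cat("<dfe_summary> cutoffs:", paste(x$cutoffs, collapse = ", "), "\n")
  if (!is.na(x$control_fraction)) {
    cat(sprintf("control strains inside +/-%.2g window: %.1f%%\n",
                max(x$cutoffs), 100 * x$control_fraction))
  }
  print(x$by_condition)
  invisible(x)
}
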