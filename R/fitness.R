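#' Pseudocount-normalized barcode frequencies
#'
#' Adds a pseudocount to every barcode count of a sample (so that later
#' log ratios never divide by zero) and normalizes to the incremented
#' total, returning frequencies that sum to 1.
#'
#' @param counts Non-negative count vector for one sample.
#' @param pseudocount Count added to every barcode before normalization
#'   (default 10).
#' @return Frequency vector summing to 1.
#' @export
#' @examples
#' normalize_counts(c(0, 90)) # (10/110, 100/110)
normalize_counts <- function(counts, pseudocount = 10) {
  if (length(counts) == 0) stop("empty count vector", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  x <- counts + pseudocount
  x / sum(x)
}

#' Per-strain log2 frequency ratios to the generation-0 sample
#'
#' @param freqs Long tibble with columns `strain_id`, `timepoint`,
#'   `frequency` for one sample series; frequencies must be strictly
#'   positive (guaranteed upstream by the pseudocount).
#' @param t0 Reference timepoint (default generation 0).
#' @return The tibble with a `log_ratio` column,
#'   `log2(f(t) / f(t0))`; the `t0` rows are exactly 0.
#' @export
log_ratios <- function(freqs, t0 = 0) {
  if (!t0 %in% freqs$timepoint) {
    stop("reference timepoint t0 = ", t0, " not present", call. = FALSE)
  }
  if (any(freqs$frequency <= 0)) {
    stop("non-positive frequency; normalize with a pseudocount first",
         call. = FALSE)
  }
  ref <- freqs |>
    dplyr::filter(.data$timepoint == t0) |>
    dplyr::select("strain_id", f0 = "frequency")
  freqs |>
    dplyr::inner_join(ref, by = "strain_id") |>
    dplyr::mutate(log_ratio = log2(.data$frequency / .data$f0)) |>
    dplyr::select(-"f0")
}

#' Fitness slopes from log-ratio series over the steady-state window
#'
#' Ordinary least-squares slope (intercept free) of the log2 ratio on
#' generation, restricted to timepoints inside the closed window
#' (default generations 6 through 20, the steady-state phase of the
#' chemostat; the generation-0 reference point is excluded by default).
#' Units are log2 per generation.
#'
#' @param log_ratios Long tibble with `strain_id`, `timepoint`,
#'   `log_ratio`.
#' @param window Closed generation interval used for the regression.
#' @param include_t0 Also include the reference point (0, 0) in the fit.
#' @return Tibble `strain_id`, `fitness` (slope, log2/generation).
#' @export
estimate_fitness <- function(log_ratios, window = c(6, 20),
                             include_t0 = FALSE) {
  keep <- log_ratios$timepoint >= window[1] &
    log_ratios$timepoint <= window[2]
  if (include_t0) keep <- keep | log_ratios$timepoint == 0
  used <- log_ratios[keep, ]
  n_t <- dplyr::n_distinct(used$timepoint)
  if (n_t < 2) {
    stop("fewer than 2 timepoints inside window [", window[1], ", ",
         window[2], "]", call. = FALSE)
  }
  # identical design for every strain, so the OLS slope is
  # cov(t, y) / var(t) computed per strain
  used |>
    dplyr::summarise(
      fitness = cov(.data$timepoint, .data$log_ratio) /
        var(.data$timepoint),
      .by = "strain_id"
    )
}

#' Average replicate fitness measurements
#'
#' @param replicate_fitness Tibble with `strain_id`, `replicate`,
#'   `fitness` (and optionally `condition`).
#' @return Tibble with `strain_id` (and `condition` if present),
#'   `mean_fitness` (arithmetic mean over available replicates) and
#'   `n_replicates`; strains measured in a single replicate keep that
#'   value with `n_replicates = 1`.
#' @export
#' @examples
#' average_replicates(tibble::tibble(
#'   strain_id = c("a", "a", "b"), replicate = c(1, 2, 1),
#'   fitness = c(0.10, 0.14, 0.2)
#' ))
average_replicates <- function(replicate_fitness) {
  by <- intersect(c("strain_id", "condition"), names(replicate_fitness))
  replicate_fitness |>
    dplyr::summarise(
      mean_fitness = mean(.data$fitness),
      n_replicates = dplyr::n(),
      .by = dplyr::all_of(by)
    )
}

#' Fit per-strain relative fitness from a bar-seq counts table
#'
#' The full fitness computation of the screen: per sample, counts are
#' pseudocount-normalized to frequencies; per replicate, log2 ratios to
#' the generation-0 sample are regressed on generation over the
#' steady-state window; replicate slopes are averaged. Optionally the
#' fitness scale is re-centered on the median of a control strain set
#' (or of all strains), which removes the common population-mean term
#' when the pool is not neutral on average.
#'
#' @param counts Long counts tibble (`strain_id`, `condition`,
#'   `replicate`, `timepoint`, `count`), e.g. from
#'   [simulate_competition()] or [count_barcodes()].
#' @param pseudocount Pseudocount for [normalize_counts()].
#' @param window Regression window in generations, closed interval.
#' @param include_t0 Include the generation-0 reference point in the
#'   regression.
#' @param center `"none"` (default; raw slopes), `"control"` (subtract
#'   the per-condition median fitness of `control_ids`), or `"median"`
#'   (subtract the per-condition median over all strains).
#' @param control_ids Strain ids of the control collection, required for
#'   `center = "control"`.
#' @param min_total Minimum summed count per strain ([filter_counts()]);
#'   set to 0 to keep everything.
#' @return A `barseq_fit` object; its `$fitness` element is a tibble
#'   `strain_id`, `condition`, `mean_fitness`, `n_replicates`, and
#'   `$replicate_fitness` holds the per-replicate slopes. Use
#'   [tidy()][generics::tidy] / [glance()][generics::glance] to extract
#'   tibble summaries.
#' @export
#' @examples
#' pool <- build_pool(100, seed = 1)
#' sim <- simulate_competition(pool, competition_design(), seed = 2)
#' fit <- fit_fitness(sim$counts)
#' fit
fit_fitness <- function(counts, pseudocount = 10, window = c(6, 20),
                        include_t0 = FALSE,
                        center = c("none", "control", "median"),
                        control_ids = NULL, min_total = 20) {
  center <- match.arg(center)
  if (center == "control" && is.null(control_ids)) {
    stop("center = \"control\" requires control_ids", call. = FALSE)
  }
  counts <- filter_counts(counts, min_total = min_total)

  replicate_fitness <- counts |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::group_modify(function(df, key) {
      freqs <- df |>
        dplyr::mutate(
          frequency = normalize_counts(.data$count, pseudocount),
          .by = "timepoint"
        )
      freqs |>
        log_ratios(t0 = 0) |>
        estimate_fitness(window = window, include_t0 = include_t0)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("strain_id", "condition", "replicate", "fitness")

  fitness <- average_replicates(replicate_fitness)

  if (center != "none") {
    centers <- fitness |>
      dplyr::filter(center == "median" |
                      .data$strain_id %in% control_ids) |>
      dplyr::summarise(center_value = median(.data$mean_fitness),
                       .by = "condition")
    shift <- function(df, col) {
      df |>
        dplyr::left_join(centers, by = "condition") |>
        dplyr::mutate({{ col }} := {{ col }} - .data$center_value) |>
        dplyr::select(-"center_value")
    }
    fitness <- shift(fitness, mean_fitness)
    replicate_fitness <- shift(replicate_fitness, fitness)
  }

  structure(
    list(fitness = fitness, replicate_fitness = replicate_fitness,
         params = list(pseudocount = pseudocount, window = window,
                       include_t0 = include_t0, center = center,
                       min_total = min_total),
         dropped = attr(counts, "dropped")),
    class = "barseq_fit"
  )
}

#' @export
print.barseq_fit <- function(x, ...) {
  cat("<barseq_fit>:", dplyr::n_distinct(x$fitness$strain_id), "strains,",
      dplyr::n_distinct(x$fitness$condition), "condition(s);",
      "window [", x$params$window[1], ",", x$params$window[2], "],",
      "pseudocount", x$params$pseudocount, ",",
      "centering:", x$params$center, "\n")
  cat("fitness range:",
      sprintf("%.3f to %.3f", min(x$fitness$mean_fitness),
              max(x$fitness$mean_fitness)), "log2/generation\n")
  invisible(x)
}
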