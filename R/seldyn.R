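#' Deterministic haploid selection scenario
#'
#' A single beneficial (or deleterious) lineage with per-generation
#' selection coefficient `s` in a large asexual population of size `N`,
#' starting from frequency `p0`. Dynamics are deterministic
#' discrete-generation selection with no drift and no establishment
#' phase; "fixation" is operationalized as reaching frequency
#' `1 - 1/N`.
#'
#' @param s Per-generation selection coefficient (> -1).
#' @param N Population size (default 1e9, a chemostat-scale culture).
#' @param p0 Initial frequency (default `1/N`, a single founding cell).
#' @return A `selection_scenario` object.
#' @export
#' @examples
#' selection_scenario(s = 0.10)
selection_scenario <- function(s, N = 1e9, p0 = 1 / N) {
  if (s <= -1) stop("s must be > -1", call. = FALSE)
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)", call. = FALSE)
  if (N < 1 / p0) {
    warning("population size N < 1/p0: less than one founding cell",
            call. = FALSE)
  }
  structure(list(s = s, N = N, p0 = p0), class = "selection_scenario")
}

#' @export
print.selection_scenario <- function(x, ...) {
  cat(sprintf("<selection_scenario> s = %g, N = %g, p0 = %g\n",
              x$s, x$N, x$p0))
  invisible(x)
}

#' Frequency trajectory of a selected lineage
#'
#' Closed-form deterministic frequency after `t` generations:
#' `p_t = p0 (1+s)^t / (1 - p0 + p0 (1+s)^t)`, the solution of the
#' per-generation recursion `p' = p (1+s) / (1 + p s)`.
#'
#' @param scenario A [selection_scenario()].
#' @param t Vector of non-negative generation numbers.
#' @return Tibble `generation`, `frequency`.
#' @export
#' @examples
#' selection_trajectory(selection_scenario(0.1, p0 = 0.5), 0:5)
selection_trajectory <- function(scenario, t) {
  stopifnot(inherits(scenario, "selection_scenario"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  # odds form is numerically stable for large t
  log_odds <- log(scenario$p0 / (1 - scenario$p0)) + t * log1p(scenario$s)
  tibble::tibble(generation = t,
                 frequency = stats::plogis(log_odds))
}

#' Generations for a selected lineage to reach a frequency threshold
#'
#' Smallest integer `t` with `p_t >= threshold`. Computed in closed form
#' from the odds solution
#' `t = ceil( log[ odds(threshold) / odds(p0) ] / log(1+s) )` and, when
#' `method = "iterate"`, by stepping the recursion
#' `p' = p (1+s) / (1 + p s)` generation by generation; the two agree.
#'
#' @param scenario A [selection_scenario()].
#' @param threshold Target frequency in (0, 1). Use `1 - 1/N` for
#'   fixation.
#' @param method `"closed_form"` (default) or `"iterate"`.
#' @return Integer number of generations (0 when `p0` already meets the
#'   threshold).
#' @export
#' @examples
#' sc <- selection_scenario(0.10, p0 = 1e-9)
#' time_to_frequency(sc, 0.05)        # detection at 5%
#' time_to_frequency(sc, 1 - 1e-9)    # fixation
time_to_frequency <- function(scenario, threshold,
                              method = c("closed_form", "iterate")) {
  method <- match.arg(method)
  stopifnot(inherits(scenario, "selection_scenario"))
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  if (threshold <= scenario$p0) return(0L)
  if (scenario$s <= 0) {
    stop("threshold above p0 is unreachable with s <= 0", call. = FALSE)
  }
  if (method == "closed_form") {
    odds_ratio <- log(threshold / (1 - threshold)) -
      log(scenario$p0 / (1 - scenario$p0))
    as.integer(ceiling(odds_ratio / log1p(scenario$s)))
  } else {
    p <- scenario$p0
    t <- 0L
    while (p < threshold) {
      p <- p * (1 + scenario$s) / (1 + p * scenario$s)
      t <- t + 1L
    }
    t
  }
}

#' Time for a beneficial lineage to fix
#'
#' Convenience wrapper: [time_to_frequency()] at the fixation threshold
#' `1 - 1/N`.
#'
#' @inheritParams time_to_frequency
#' @return Integer number of generations.
#' @export
fixation_time <- function(scenario, method = c("closed_form", "iterate")) {
  time_to_frequency(scenario, 1 - 1 / scenario$N, method = method)
}
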