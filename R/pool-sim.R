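#' Describe a distribution of fitness effects for a synthetic pool
#'
#' A DFE mixture assigns each strain a per-generation selection coefficient
#' `s` drawn from a mixture of a point mass at neutrality, a uniform
#' deleterious component, and a uniform beneficial component. The default
#' (90% neutral, 5% deleterious on U(-0.3, 0), 5% beneficial on U(0, 0.4))
#' gives a mostly-neutral pool with a minority of strains of effect sizes
#' spanning the range seen in nutrient-limited yeast screens.
#'
#' @param p_neutral,p_deleterious,p_beneficial Mixture weights; must sum to 1.
#' @param deleterious_range,beneficial_range Ranges of the uniform components.
#'   Deleterious values must stay above -1 (a strain cannot lose more than
#'   all of its growth).
#' @return A `dfe_mixture` list used by [build_pool()].
#' @export
#' @examples
#' dfe_mixture() # the default 90/5/5 mixture
#' dfe_mixture(1, 0, 0) # an all-neutral (control-like) pool
dfe_mixture <- function(p_neutral = 0.90, p_deleterious = 0.05,
                        p_beneficial = 0.05,
                        deleterious_range = c(-0.3, 0),
                        beneficial_range = c(0, 0.4)) {
  w <- c(p_neutral, p_deleterious, p_beneficial)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("mixture weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (deleterious_range[1] <= -1) {
    stop("deleterious selection coefficients must be > -1", call. = FALSE)
  }
  structure(
    list(p_neutral = p_neutral, p_deleterious = p_deleterious,
         p_beneficial = p_beneficial,
         deleterious_range = deleterious_range,
         beneficial_range = beneficial_range),
    class = "dfe_mixture"
  )
}

draw_dfe <- function(n, dfe) {
  component <- sample.int(3L, n, replace = TRUE,
                          prob = c(dfe$p_neutral, dfe$p_deleterious,
                                   dfe$p_beneficial))
  s <- numeric(n)
  ndel <- sum(component == 2L)
  nben <- sum(component == 3L)
  s[component == 2L] <- runif(ndel, dfe$deleterious_range[1],
                              dfe$deleterious_range[2])
  s[component == 3L] <- runif(nben, dfe$beneficial_range[1],
                              dfe$beneficial_range[2])
  s
}

random_barcodes <- function(n, width) {
  # rejection-sample until all barcodes are unique; collisions are rare
  # for 4^20 possible 20-mers but must not survive into a catalog
  bc <- character(0)
  while (length(bc) < n) {
    need <- n - length(bc)
    new <- vapply(seq_len(need), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = "")
    }, character(1))
    bc <- unique(c(bc, new))
  }
  bc
}

#' Build a synthetic barcoded strain pool
#'
#' Creates a catalog of uniquely barcoded strains with true per-generation
#' selection coefficients drawn from a [dfe_mixture()], plus an optional
#' control collection of neutral strains (barcoded wild types at a neutral
#' locus, so their true fitness is exactly 0).
#'
#' @param n_strains Number of test strains.
#' @param dfe A [dfe_mixture()] describing the test strains' fitness effects.
#' @param n_control Number of neutral control strains appended to the pool.
#' @param collection Collection label for the test strains.
#' @param seed Optional integer seed; the catalog is deterministic given it.
#' @return A tibble with columns `strain_id`, `barcode` (20-mer), `gene`,
#'   `collection`, `true_fitness`.
#' @export
#' @examples
#' pool <- build_pool(20, dfe_mixture(), n_control = 5, seed = 1)
#' dplyr::count(pool, collection)
build_pool <- function(n_strains, dfe = dfe_mixture(), n_control = 0,
                       collection = "haploid_deletion", seed = NULL) {
  if (n_strains <= 0) stop("n_strains must be positive", call. = FALSE)
  if (!inherits(dfe, "dfe_mixture")) {
    stop("`dfe` must be created with dfe_mixture()", call. = FALSE)
  }
  collection <- match.arg(collection, collection_levels())
  build <- function() {
    n <- n_strains + n_control
    tibble::tibble(
      strain_id = c(sprintf("strain_%05d", seq_len(n_strains)),
                    if (n_control > 0) sprintf("control_%05d", seq_len(n_control))),
      barcode = random_barcodes(n, BARCODE_WIDTH),
      gene = c(sprintf("GENE%05d", seq_len(n_strains)),
               if (n_control > 0) rep("neutral_locus", n_control)),
      collection = c(rep(collection, n_strains),
                     rep("control", n_control)),
      true_fitness = c(draw_dfe(n_strains, dfe), rep(0, n_control))
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Describe a pooled competition experiment
#'
#' Holds the design of one competition: the limiting-nutrient condition,
#' the sampled generations, the number of replicate cultures, the expected
#' sequencing depth, and the 6-mer multiplex tag assigned to each
#' (replicate, timepoint) sample.
#'
#' @param condition Condition label (e.g. `"sulfate"`, `"glucose"`,
#'   `"phosphate"`).
#' @param timepoints Ordered integer generations at which samples are taken;
#'   must start at 0 and be strictly increasing. The default samples every
#'   three generations across a 20-generation competition.
#' @param replicates Number of replicate competitions (default 2).
#' @param depth Expected total reads per sample. `NULL` (default) means
#'   462 reads per strain, resolved when the pool size is known.
#' @param tag_map Optional tibble with columns `sample`, `replicate`,
#'   `timepoint`, `tag`; generated automatically when omitted.
#' @return A `competition_design` object.
#' @export
#' @examples
#' competition_design("sulfate")
competition_design <- function(condition = "glucose",
                               timepoints = c(0, 3, 6, 9, 12, 15, 18, 20),
                               replicates = 2, depth = NULL,
                               tag_map = NULL) {
  timepoints <- as.integer(timepoints)
  if (timepoints[1] != 0L) {
    stop("the first timepoint must be generation 0", call. = FALSE)
  }
  if (any(diff(timepoints) <= 0)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (is.null(tag_map)) {
    samples <- tidyr::expand_grid(replicate = seq_len(replicates),
                                  timepoint = timepoints)
    tag_map <- samples |>
      dplyr::mutate(
        sample = sprintf("%s_r%d_t%02d", condition, .data$replicate,
                         .data$timepoint),
        tag = default_tags(nrow(samples))
      ) |>
      dplyr::select("sample", "replicate", "timepoint", "tag")
  }
  validate_tag_map(tag_map)
  structure(
    list(condition = condition, timepoints = timepoints,
         replicates = as.integer(replicates), depth = depth,
         tag_map = tag_map),
    class = "competition_design"
  )
}

# deterministic, distinct 6-mers: enumerate base-4 in tag order
default_tags <- function(n) {
  if (n > 4^TAG_WIDTH) stop("too many samples for 6-mer tags", call. = FALSE)
  alphabet <- c("A", "C", "G", "T")
  vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(TAG_WIDTH)
    for (k in seq_len(TAG_WIDTH)) {
      digits[k] <- i %% 4L
      i <- i %/% 4L
    }
    paste(alphabet[rev(digits) + 1L], collapse = "")
  }, character(1))
}

validate_tag_map <- function(tag_map) {
  stopifnot(all(c("sample", "replicate", "timepoint", "tag") %in%
                  names(tag_map)))
  if (anyDuplicated(tag_map$tag)) {
    stop("multiplex tags must be unique", call. = FALSE)
  }
  if (any(nchar(tag_map$tag) != TAG_WIDTH)) {
    stop("multiplex tags must be exactly 6 bases", call. = FALSE)
  }
  invisible(tag_map)
}

#' @export
print.competition_design <- function(x, ...) {
  cat("<competition_design>\n")
  cat("  condition:  ", x$condition, "\n")
  cat("  timepoints: ", paste(x$timepoints, collapse = ", "), "\n")
  cat("  replicates: ", x$replicates, "\n")
  cat("  depth:      ",
      if (is.null(x$depth)) "462 reads/strain" else x$depth, "\n")
  invisible(x)
}

#' Deterministic relative-growth propagation of strain frequencies
#'
#' Propagates a frequency vector `t` generations forward under
#' deterministic selection: `f_i(t) = f_i(0) (1+s_i)^t / sum_j f_j(0)
#' (1+s_j)^t`. Drift is ignored, which is appropriate for chemostat pools
#' of ~1e9 cells.
#'
#' @param f0 Initial frequency vector (sums to 1).
#' @param s Per-generation selection coefficients, all > -1.
#' @param t Non-negative integer number of generations.
#' @return Frequency vector after `t` generations, in the input order.
#' @export
#' @examples
#' propagate_frequencies(c(0.5, 0.5), c(0, 0.1), 10)
propagate_frequencies <- function(f0, s, t) {
  if (length(s) == 1L) s <- rep(s, length(f0))
  stopifnot(length(f0) == length(s))
  if (any(f0 < 0)) {
    stop("negative frequency at position ", which(f0 < 0)[1], call. = FALSE)
  }
  if (abs(sum(f0) - 1) > 1e-8) {
    stop("initial frequencies must sum to 1", call. = FALSE)
  }
  if (any(s <= -1)) {
    stop("selection coefficient <= -1 at position ", which(s <= -1)[1],
         call. = FALSE)
  }
  if (length(t) != 1L || t < 0) {
    stop("t must be a single non-negative number of generations",
         call. = FALSE)
  }
  # work in logs so large t and strong selection do not overflow
  logw <- log(f0) + t * log1p(s)
  w <- exp(logw - max(logw[is.finite(logw)]))
  w[f0 == 0] <- 0
  w / sum(w)
}

#' True per-timepoint strain frequencies for a pool under a design
#'
#' @param catalog A pool catalog from [build_pool()].
#' @param design A [competition_design()].
#' @param f0 Optional initial frequencies (default: equal proportions,
#'   as in a freshly mixed pool).
#' @return A tibble `strain_id`, `timepoint`, `frequency`; within each
#'   timepoint the frequencies sum to 1.
#' @export
truth_frequencies <- function(catalog, design, f0 = NULL) {
  n <- nrow(catalog)
  if (is.null(f0)) f0 <- rep(1 / n, n)
  purrr::map_dfr(design$timepoints, function(t) {
    tibble::tibble(
      strain_id = catalog$strain_id,
      timepoint = t,
      frequency = propagate_frequencies(f0, catalog$true_fitness, t)
    )
  })
}

#' Multinomial sequencing counts from strain frequencies
#'
#' Models the sequencing readout of one sample as a single multinomial
#' draw of `depth` reads over the strain frequencies.
#'
#' @param freqs Frequency vector summing to 1.
#' @param depth Non-negative integer total read count.
#' @return Integer vector of counts summing exactly to `depth`. Draws use
#'   R's RNG stream, so results are reproducible under [set.seed()].
#' @export
#' @examples
#' set.seed(1)
#' sample_counts(c(0.5, 0.3, 0.2), 1000)
sample_counts <- function(freqs, depth) {
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8) {
    stop("freqs must be a frequency vector summing to 1", call. = FALSE)
  }
  if (depth == 0) return(integer(length(freqs)))
  as.integer(rmultinom(1, size = depth, prob = freqs)[, 1])
}

#' Simulate a pooled competition experiment
#'
#' Propagates the pool deterministically to each sampled generation and
#' draws per-sample sequencing counts. With `sampling = "none"` the
#' expected (real-valued) counts `depth * frequency` are returned instead
#' of multinomial draws, which is useful for noise-free oracle checks.
#'
#' @param catalog Pool catalog from [build_pool()].
#' @param design A [competition_design()].
#' @param seed Optional integer seed for the sequencing draws.
#' @param sampling `"multinomial"` (default) or `"none"`.
#' @return A `competition_sim` list with elements `counts` (long tibble:
#'   `strain_id`, `condition`, `replicate`, `timepoint`, `count`), `truth`
#'   (from [truth_frequencies()]), `catalog` and `design`.
#' @export
#' @examples
#' pool <- build_pool(50, seed = 1)
#' sim <- simulate_competition(pool, competition_design(), seed = 2)
#' head(sim$counts)
simulate_competition <- function(catalog, design, seed = NULL,
                                 sampling = c("multinomial", "none")) {
  sampling <- match.arg(sampling)
  depth <- if (is.null(design$depth)) 462 * nrow(catalog) else design$depth
  truth <- truth_frequencies(catalog, design)
  freq_by_t <- split(truth$frequency, truth$timepoint)

  draw_all <- function() {
    tidyr::expand_grid(replicate = seq_len(design$replicates),
                       timepoint = design$timepoints) |>
      purrr::pmap_dfr(function(replicate, timepoint) {
        f <- freq_by_t[[as.character(timepoint)]]
        counts <- if (sampling == "multinomial") {
          sample_counts(f, depth)
        } else {
          depth * f
        }
        tibble::tibble(
          strain_id = catalog$strain_id,
          condition = design$condition,
          replicate = replicate,
          timepoint = timepoint,
          count = counts
        )
      })
  }
  counts <- if (is.null(seed)) draw_all() else withr::with_seed(seed, draw_all())
  structure(
    list(counts = counts, truth = truth, catalog = catalog, design = design,
         depth = depth, sampling = sampling),
    class = "competition_sim"
  )
}

#' @export
print.competition_sim <- function(x, ...) {
  cat("<competition_sim>:", nrow(x$catalog), "strains,",
      x$design$replicates, "replicate(s),",
      length(x$design$timepoints), "timepoints,",
      format(x$depth, big.mark = ","), "reads/sample (",
      x$sampling, " sampling)\n")
  invisible(x)
}
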