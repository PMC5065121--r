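#' @noRd
run_header <- function(seed = NULL, params = list()) {
  c(
    paste0("# barseqfit ", as.character(utils::packageVersion("barseqfit"))),
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (length(params) > 0) {
      paste0("# ", names(params), ": ",
             vapply(params, function(p) paste(format(p, digits = 6),
                                              collapse = ","),
                    character(1)))
    }
  )
}

#' Write a tibble as TSV with a commented provenance header
#'
#' All tabular outputs of the pipeline carry `#`-prefixed header lines
#' recording the package version, the seed, and the parameters of the
#' run; [read_barseq_tsv()] skips them.
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @param seed,params Provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
write_barseq_tsv <- function(x, path, seed = NULL, params = list()) {
  writeLines(run_header(seed, params), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_barseq_tsv()]
#'
#' @param path File path.
#' @return A tibble (header comment lines are skipped).
#' @export
read_barseq_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Read and validate a strain catalog TSV
#'
#' The catalog format is TSV with columns `strain_id`, `barcode`,
#' `gene`, `collection`, `true_fitness` (the last may be absent for real
#' pools). Barcodes must be 20-mers over A/C/G/T; malformed rows are
#' rejected with their line numbers. Barcodes occurring under more than
#' one entry are flagged `ambiguous` with a warning (their reads will be
#' discarded by the counter, the treatment of barcodes shared between
#' genes).
#'
#' @param x Path to a catalog TSV, or a data frame of the same shape.
#' @return The validated catalog tibble with a logical `ambiguous`
#'   column added.
#' @export
validate_catalog <- function(x) {
  catalog <- if (is.character(x)) read_barseq_tsv(x) else tibble::as_tibble(x)
  required <- c("strain_id", "barcode", "gene", "collection")
  missing <- setdiff(required, names(catalog))
  if (length(missing) > 0) {
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_len <- which(nchar(catalog$barcode) != BARCODE_WIDTH)
  if (length(bad_len) > 0) {
    stop("barcode of wrong length at data line(s): ",
         paste(head(bad_len, 5), collapse = ", "), call. = FALSE)
  }
  bad_alpha <- which(!grepl("^[ACGT]+$", catalog$barcode))
  if (length(bad_alpha) > 0) {
    stop("barcode with characters outside A/C/G/T at data line(s): ",
         paste(head(bad_alpha, 5), collapse = ", "), call. = FALSE)
  }
  dup <- catalog$barcode %in% ambiguous_barcodes(catalog)
  if (any(dup)) {
    warning(sum(dup), " catalog entries share barcodes with another entry; ",
            "flagged ambiguous and excluded from counting", call. = FALSE)
  }
  dplyr::mutate(catalog, ambiguous = dup)
}

#' Run the full simulate-count-fit-classify pipeline
#'
#' One reproducible end-to-end run: build (or accept) a pool, simulate
#' the competition, optionally round-trip the reads through FASTQ
#' generation and exact-match counting, fit fitness, classify the
#' distribution of fitness effects, and (when an evolve-and-resequence
#' catalog is supplied) predict drivers. When `outdir` is given, each
#' stage's table is written as TSV with a provenance header; re-running
#' the same config is byte-identical.
#'
#' @param config A list. Recognized fields (all optional unless noted):
#'   `seed` (integer, required), `n_strains`, `n_control`, `dfe`
#'   (a [dfe_mixture()]), `pool` (a ready-made catalog tibble,
#'   overriding the three above), `condition`, `timepoints`,
#'   `replicates`, `depth`, `sampling` (`"multinomial"`/`"none"`),
#'   `via_fastq` (logical: exercise the FASTQ round trip), `pseudocount`,
#'   `window`, `include_t0`, `center`, `min_total`, `cutoffs`,
#'   `e_catalog` (a [mutation_catalog()]), `driver_cutoff`,
#'   `driver_secondary`, `outdir`.
#' @return A list with `catalog`, `sim`, `counts`, `fit`, `dfe`, and
#'   `drivers` (`NULL` when no mutation catalog was given).
#' @export
#' @examples
#' res <- run_pipeline(list(seed = 1, n_strains = 50, depth = 50 * 462))
#' res$fit
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  seed <- as.integer(config$seed)

  catalog <- config$pool %||% build_pool(
    n_strains = config$n_strains %||% 2000,
    dfe = config$dfe %||% dfe_mixture(),
    n_control = config$n_control %||% 0,
    seed = seed
  )
  design <- competition_design(
    condition = config$condition %||% "glucose",
    timepoints = config$timepoints %||% c(0, 3, 6, 9, 12, 15, 18, 20),
    replicates = config$replicates %||% 2,
    depth = config$depth
  )
  sim <- simulate_competition(catalog, design, seed = seed + 1L,
                              sampling = config$sampling %||% "multinomial")
  message("simulated ", nrow(catalog), " strains, ",
          nrow(design$tag_map), " samples at depth ", sim$depth)

  if (isTRUE(config$via_fastq)) {
    fq <- tempfile(fileext = ".fastq")
    on.exit(unlink(fq), add = TRUE)
    write_competition_fastq(sim, fq)
    reads <- read_fastq(fq)
    counted <- count_barcodes(reads, catalog, design$tag_map,
                              condition = design$condition)
    message("counted ", sum(counted$sample_stats$assigned), " of ",
            nrow(reads), " reads (", counted$unmatched, " unmatched tags)")
    counts <- counted$counts
  } else {
    counts <- sim$counts
  }

  fit <- fit_fitness(
    counts,
    pseudocount = config$pseudocount %||% 10,
    window = config$window %||% c(6, 20),
    include_t0 = isTRUE(config$include_t0),
    center = config$center %||% "none",
    control_ids = catalog$strain_id[catalog$collection == "control"],
    min_total = config$min_total %||% 20
  )

  control_ids <- catalog$strain_id[catalog$collection == "control"]
  dfe <- if (length(control_ids) > 0) {
    dfe_summary(fit$fitness, control_ids,
                cutoffs = config$cutoffs %||% c(0.10, 0.05))
  } else {
    NULL
  }

  drivers <- NULL
  if (!is.null(config$e_catalog)) {
    fitness_by_gene <- fit$fitness |>
      dplyr::left_join(
        dplyr::select(catalog, "strain_id", "gene", "collection"),
        by = "strain_id"
      )
    drivers <- predict_drivers(
      config$e_catalog, fitness_by_gene,
      cutoff = config$driver_cutoff %||% 0.10,
      secondary = config$driver_secondary %||% 0.05
    )
  } else {
    message("no evolve-and-resequence catalog supplied; driver stage skipped")
  }

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    prm <- list(condition = design$condition,
                timepoints = design$timepoints,
                replicates = design$replicates, depth = sim$depth,
                pseudocount = fit$params$pseudocount,
                window = fit$params$window, center = fit$params$center)
    write_barseq_tsv(catalog, file.path(config$outdir, "catalog.tsv"),
                     seed, prm)
    write_barseq_tsv(counts, file.path(config$outdir, "counts.tsv"),
                     seed, prm)
    write_barseq_tsv(fit$fitness, file.path(config$outdir, "fitness.tsv"),
                     seed, prm)
    if (!is.null(drivers)) {
      write_barseq_tsv(drivers, file.path(config$outdir, "drivers.tsv"),
                       seed, prm)
    }
  }

  list(catalog = catalog, sim = sim, counts = counts, fit = fit,
       dfe = dfe, drivers = drivers)
}
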