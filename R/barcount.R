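#' Demultiplex reads by exact 6-mer sample tag
#'
#' Bins each read by its first six bases, which must equal one of the
#' design's multiplex tags exactly; no mismatches are tolerated. Reads
#' whose leading 6-mer matches no tag are left unassigned (`sample` is
#' `NA`).
#'
#' @param reads Tibble with a `sequence` column (and optionally
#'   `read_id`), or a character vector of sequences.
#' @param tag_map Tibble with columns `sample` and `tag`
#'   (as in [competition_design()]), or a named character vector
#'   `c(sample = tag, ...)`.
#' @return The read tibble with a `sample` column added; the number of
#'   unmatched reads is attached as attribute `"unmatched"`.
#' @export
#' @examples
#' reads <- tibble::tibble(sequence = c("AAAAAAGGG", "CCCCCCGGG", "NNNNNNGGG"))
#' tags <- tibble::tibble(sample = c("s1", "s2"), tag = c("AAAAAA", "CCCCCC"))
#' demultiplex(reads, tags)
demultiplex <- function(reads, tag_map) {
  if (is.character(reads)) reads <- tibble::tibble(sequence = reads)
  if (!is.data.frame(tag_map)) {
    tag_map <- tibble::tibble(sample = names(tag_map), tag = unname(tag_map))
  }
  if (anyDuplicated(tag_map$tag)) {
    stop("duplicate multiplex tags", call. = FALSE)
  }
  if (any(nchar(tag_map$tag) != TAG_WIDTH)) {
    stop("tags must be exactly ", TAG_WIDTH, " bases", call. = FALSE)
  }
  lead <- substr(reads$sequence, 1L, TAG_WIDTH)
  idx <- match(lead, tag_map$tag)
  out <- dplyr::mutate(reads, sample = tag_map$sample[idx])
  attr(out, "unmatched") <- sum(is.na(idx))
  out
}

ambiguous_barcodes <- function(catalog) {
  catalog$barcode[duplicated(catalog$barcode) |
                    duplicated(catalog$barcode, fromLast = TRUE)]
}

#' Assign reads to strains by exact barcode match
#'
#' Extracts the 20-base barcode at the fixed read offset (position 17 for
#' the default layout) and increments a strain's count only on a perfect
#' match to its catalog barcode. Barcodes shared by more than one catalog
#' entry are excluded before counting and their reads tallied as
#' ambiguous, mirroring the discard rule for barcodes assigned to
#' multiple genes. Reads shorter than the layout or with no perfect match
#' are unassigned.
#'
#' @param reads Tibble with a `sequence` column, or character vector of
#'   sequences, for one sample.
#' @param catalog Pool catalog with `strain_id` and `barcode` (20-mers).
#' @param barcode_start 1-based offset of the barcode in the read.
#' @return A list with `counts` (tibble `strain_id`, `count`, zero rows
#'   for unambiguous strains never seen), `assigned`, `unassigned` and
#'   `ambiguous` read totals.
#' @export
assign_barcodes <- function(reads, catalog, barcode_start = BARCODE_START) {
  if (is.character(reads)) reads <- tibble::tibble(sequence = reads)
  if (any(nchar(catalog$barcode) != BARCODE_WIDTH)) {
    stop("catalog barcodes must be ", BARCODE_WIDTH, "-mers", call. = FALSE)
  }
  amb <- unique(ambiguous_barcodes(catalog))
  keep <- !catalog$barcode %in% amb
  usable <- catalog[keep, ]

  bc_end <- barcode_start + BARCODE_WIDTH - 1L
  full_length <- nchar(reads$sequence) >= bc_end
  bc <- substr(reads$sequence[full_length], barcode_start, bc_end)

  n_ambiguous <- sum(bc %in% amb)
  idx <- match(bc, usable$barcode)
  tallied <- tabulate(idx, nbins = nrow(usable))
  n_assigned <- sum(tallied)
  list(
    counts = tibble::tibble(strain_id = usable$strain_id,
                            count = as.integer(tallied)),
    assigned = n_assigned,
    unassigned = nrow(reads) - n_assigned - n_ambiguous,
    ambiguous = n_ambiguous
  )
}

#' Count barcodes across all samples of a multiplexed read set
#'
#' Runs [demultiplex()] then [assign_barcodes()] per sample and assembles
#' a long counts table with per-sample accounting (demultiplexed,
#' assigned, unassigned, ambiguous; the three categories always sum to
#' the demultiplexed total).
#'
#' @param reads Read tibble or character vector (e.g. from
#'   [read_fastq()]).
#' @param catalog Pool catalog.
#' @param tag_map Tibble with `sample`, `replicate`, `timepoint`, `tag`
#'   (a design's `tag_map`), or named vector `c(sample = tag)`.
#' @param condition Condition label attached to the counts.
#' @param barcode_start 1-based barcode offset in the read.
#' @return A list with `counts` (long tibble `strain_id`, `condition`,
#'   `replicate`, `timepoint`, `count` when the tag map carries
#'   replicate/timepoint, else `strain_id`, `sample`, `count`),
#'   `sample_stats` (accounting tibble) and `unmatched` (reads matching
#'   no tag).
#' @export
count_barcodes <- function(reads, catalog, tag_map, condition = NULL,
                           barcode_start = BARCODE_START) {
  if (!is.data.frame(tag_map)) {
    tag_map <- tibble::tibble(sample = names(tag_map), tag = unname(tag_map))
  }
  demux <- demultiplex(reads, tag_map)
  per_sample <- purrr::map(
    setNames(tag_map$sample, tag_map$sample),
    function(smp) {
      assign_barcodes(dplyr::filter(demux, .data$sample == smp),
                      catalog, barcode_start = barcode_start)
    }
  )
  counts <- purrr::imap_dfr(per_sample, function(res, smp) {
    dplyr::mutate(res$counts, sample = smp, .after = "strain_id")
  })
  sample_stats <- purrr::imap_dfr(per_sample, function(res, smp) {
    tibble::tibble(sample = smp,
                   demultiplexed = res$assigned + res$unassigned +
                     res$ambiguous,
                   assigned = res$assigned,
                   unassigned = res$unassigned,
                   ambiguous = res$ambiguous)
  })
  if (all(c("replicate", "timepoint") %in% names(tag_map))) {
    counts <- counts |>
      dplyr::left_join(
        dplyr::select(tag_map, "sample", "replicate", "timepoint"),
        by = "sample"
      ) |>
      dplyr::mutate(condition = condition %||% "unknown") |>
      dplyr::select("strain_id", "condition", "replicate", "timepoint",
                    "count")
  }
  list(counts = counts, sample_stats = sample_stats,
       unmatched = attr(demux, "unmatched"))
}

#' Drop strains with too few reads across the samples of a screen
#'
#' Removes strains whose summed count over all samples of one
#' competition run falls below `min_total` (default 20, the screen's
#' discard rule: strains with fewer than 20 counts across the samples are
#' dropped). The comparison is strict: a row sum of exactly `min_total`
#' is kept.
#'
#' @param counts Long counts tibble with `strain_id` and `count`.
#' @param min_total Minimum summed count per strain.
#' @return The filtered tibble; dropped strain ids are attached as
#'   attribute `"dropped"` and reported via a message.
#' @export
#' @examples
#' counts <- tibble::tibble(strain_id = c("a", "a", "b", "b"),
#'                          count = c(10, 10, 9, 10))
#' filter_counts(counts) # keeps a (sum 20), drops b (sum 19)
filter_counts <- function(counts, min_total = 20) {
  if (min_total < 0) stop("min_total must be >= 0", call. = FALSE)
  if (nrow(counts) == 0) {
    attr(counts, "dropped") <- character(0)
    return(counts)
  }
  totals <- counts |>
    dplyr::summarise(total = sum(.data$count), .by = "strain_id")
  dropped <- totals$strain_id[totals$total < min_total]
  out <- dplyr::filter(counts, !.data$strain_id %in% dropped)
  if (length(dropped) > 0) {
    message(length(dropped), " strain(s) dropped with < ", min_total,
            " total counts")
  }
  attr(out, "dropped") <- dropped
  out
}
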