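#' Generate multiplexed bar-seq reads for one sample
#'
#' Emits one 36-base read per counted molecule, laid out as the 6-mer
#' sample tag, a 10-base constant spacer, then the strain's 20-base
#' barcode. This fixed layout is what the counting side of the package
#' parses; real instruments put the tag in the PCR primer, and the spacer
#' stands in for the common primer sequence.
#'
#' @param counts Named integer vector, or tibble with columns `strain_id`
#'   and `count`, of reads per strain.
#' @param catalog Pool catalog with `strain_id` and `barcode`.
#' @param tag 6-mer multiplex tag for this sample.
#' @return A tibble with columns `read_id` and `sequence` (one row per
#'   read). Order is deterministic: catalog order, reads of one strain
#'   consecutive.
#' @export
#' @examples
#' pool <- build_pool(3, seed = 1)
#' generate_reads(c(strain_00001 = 2, strain_00002 = 1), pool, "AAAAAA")
generate_reads <- function(counts, catalog, tag) {
  if (nchar(tag) != TAG_WIDTH) {
    stop("tag must be exactly ", TAG_WIDTH, " bases", call. = FALSE)
  }
  if (is.data.frame(counts)) {
    counts <- setNames(counts$count, counts$strain_id)
  }
  counts <- counts[counts > 0]
  unknown <- setdiff(names(counts), catalog$strain_id)
  if (length(unknown) > 0) {
    stop("unknown strain id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(counts) == 0) {
    return(tibble::tibble(read_id = character(), sequence = character()))
  }
  barcode <- setNames(catalog$barcode, catalog$strain_id)[names(counts)]
  strain <- rep(names(counts), times = counts)
  tibble::tibble(
    read_id = sprintf("%s_%s_%06d", tag, strain, seq_along(strain)),
    sequence = paste0(tag, SPACER, rep(barcode, times = counts))
  )
}

#' Write reads to a FASTQ file
#'
#' Writes standard 4-line FASTQ with constant Phred-33 quality "I"
#' (Q40) for every base; the pipeline applies no quality filtering, so
#' qualities are placeholders. A `.gz` path is compressed transparently.
#'
#' @param reads Tibble with `read_id` and `sequence` columns
#'   (from [generate_reads()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  quals <- Biostrings::BStringSet(
    setNames(strrep("I", nchar(reads$sequence)), reads$read_id)
  )
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ path (optionally gzipped).
#' @return A tibble with columns `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = names(x), sequence = as.character(x))
}

#' Write a simulated competition as one multiplexed FASTQ file
#'
#' Generates reads for every sample of the simulation, tagged per the
#' design's tag map, and writes them to a single multiplexed FASTQ.
#' Counts must be integers (multinomial sampling).
#'
#' @param sim A `competition_sim` from [simulate_competition()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_competition_fastq <- function(sim, path) {
  if (sim$sampling != "multinomial") {
    stop("FASTQ output requires integer counts (multinomial sampling)",
         call. = FALSE)
  }
  reads <- sim$design$tag_map |>
    purrr::pmap_dfr(function(sample, replicate, timepoint, tag) {
      cts <- sim$counts |>
        dplyr::filter(.data$replicate == !!replicate,
                      .data$timepoint == !!timepoint) |>
        dplyr::select("strain_id", "count")
      generate_reads(cts, sim$catalog, tag)
    })
  write_fastq(reads, path)
}
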