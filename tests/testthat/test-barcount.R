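test_that("demultiplexing bins reads only on exact leading 6-mers", {
  tags <- tibble::tibble(sample = c("a", "b", "c"),
                         tag = c("AAAAAA", "CCCCCC", "GGGGGG"))
  one_tag <- demultiplex(rep(make_read("AAAAAA", toy_catalog()$barcode[1]), 8),
                         tags)
  expect_identical(sum(one_tag$sample == "a"), 8L)
  expect_identical(attr(one_tag, "unmatched"), 0L)

  # edit distance 1 from a known tag is still unmatched
  near <- demultiplex(make_read("AAAAAT", toy_catalog()$barcode[1]), tags)
  expect_true(is.na(near$sample))
  expect_identical(attr(near, "unmatched"), 1L)

  # 30 good reads across 3 tags + 5 corrupt
  bc <- toy_catalog()$barcode[1]
  reads <- c(rep(make_read("AAAAAA", bc), 10),
             rep(make_read("CCCCCC", bc), 10),
             rep(make_read("GGGGGG", bc), 10),
             rep(make_read("TTTTTT", bc), 5))
  out <- demultiplex(reads, tags)
  expect_identical(as.integer(table(out$sample)[c("a", "b", "c")]),
                   c(10L, 10L, 10L))
  expect_identical(attr(out, "unmatched"), 5L)

  expect_error(demultiplex(reads, tibble::tibble(sample = c("a", "b"),
                                                 tag = rep("AAAAAA", 2))),
               "duplicate")
})

test_that("barcode assignment is perfect-match only, with ambiguity discard", {
  cat <- toy_catalog()
  good <- make_read("AAAAAA", cat$barcode[2])
  flipped <- paste0("A", substr(cat$barcode[2], 2, 20)) # 1-base mismatch
  mismatch <- make_read("AAAAAA", flipped)
  res <- assign_barcodes(c(good, good, mismatch), cat)
  expect_identical(res$counts$count[res$counts$strain_id == "s2"], 2L)
  expect_identical(res$unassigned, 1L)
  expect_identical(res$ambiguous, 0L)

  # a read shorter than the layout is unassigned
  short <- assign_barcodes(substr(good, 1, 30), cat)
  expect_identical(short$unassigned, 1L)

  # barcode present under two gene entries: excluded, reads -> ambiguous
  cat2 <- dplyr::bind_rows(cat,
                           tibble::tibble(strain_id = "s4",
                                          barcode = cat$barcode[1],
                                          gene = "OTHERGENE",
                                          collection = "haploid_deletion",
                                          true_fitness = 0))
  amb_reads <- rep(make_read("AAAAAA", cat$barcode[1]), 7)
  res2 <- assign_barcodes(c(amb_reads, good), cat2)
  expect_identical(res2$ambiguous, 7L)
  expect_false("s1" %in% res2$counts$strain_id)
  expect_identical(res2$counts$count[res2$counts$strain_id == "s2"], 1L)
})

test_that("production counter equals a naive per-read linear scan", {
  # brute-force oracle on a random pool of <= 50 strains, including an
  # engineered duplicate barcode and corrupted reads
  pool <- build_pool(40, seed = 8)
  pool$barcode[40] <- pool$barcode[39] # shared barcode, two genes
  tag <- "ACGTCA"
  withr::with_seed(9, {
    picks <- sample(nrow(pool), 300, replace = TRUE)
    reads <- make_read(tag, pool$barcode[picks])
    corrupt <- sample(300, 20)
    substr(reads[corrupt], 25, 25) <- "N"
  })

  res <- assign_barcodes(reads, pool)

  amb <- pool$barcode[duplicated(pool$barcode) |
                        duplicated(pool$barcode, fromLast = TRUE)]
  keep <- pool[!pool$barcode %in% amb, ]
  naive <- setNames(integer(nrow(keep)), keep$strain_id)
  naive_amb <- 0L
  for (r in reads) {
    b <- substr(r, 17, 36)
    if (b %in% amb) {
      naive_amb <- naive_amb + 1L
    } else {
      hit <- which(keep$barcode == b)
      if (length(hit) == 1) naive[hit] <- naive[hit] + 1L
    }
  }
  expect_identical(setNames(res$counts$count, res$counts$strain_id), naive)
  expect_identical(res$ambiguous, naive_amb)
  # accounting identity
  expect_identical(res$assigned + res$unassigned + res$ambiguous,
                   length(reads))
})

test_that("per-sample accounting identity holds through count_barcodes", {
  pool <- build_pool(15, seed = 10)
  des <- competition_design("phosphate", replicates = 1, depth = 800)
  sim <- simulate_competition(pool, des, seed = 11)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_competition_fastq(sim, fq)
  reads <- read_fastq(fq)
  # corrupt some tags so the unmatched path is exercised
  reads$sequence[1:3] <- paste0("NNNNNN", substr(reads$sequence[1:3], 7, 36))
  out <- count_barcodes(reads, pool, des$tag_map, condition = "phosphate")
  expect_identical(sum(out$sample_stats$demultiplexed) + out$unmatched,
                   nrow(reads))
  expect_true(all(out$sample_stats$demultiplexed ==
                    out$sample_stats$assigned +
                    out$sample_stats$unassigned +
                    out$sample_stats$ambiguous))
})

test_that("the low-count filter uses a strict row-sum threshold and is idempotent", {
  counts <- tibble::tibble(
    strain_id = rep(c("keep20", "drop19", "big"), each = 2),
    count = c(10, 10, 9, 10, 500, 500)
  )
  out <- suppressMessages(filter_counts(counts))
  expect_setequal(unique(out$strain_id), c("keep20", "big"))
  expect_identical(attr(out, "dropped"), "drop19")

  # idempotent (up to the dropped-ids bookkeeping attribute)
  strip <- function(x) `attr<-`(x, "dropped", NULL)
  again <- filter_counts(out)
  expect_identical(strip(again), strip(out))

  # min_total = 0 is the identity; the empty table passes through
  expect_identical(strip(filter_counts(counts, 0)), counts)
  empty <- counts[0, ]
  expect_identical(nrow(filter_counts(empty)), 0L)
  expect_error(filter_counts(counts, -1), "min_total")
})
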