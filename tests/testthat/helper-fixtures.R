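# Small deterministic fixtures shared across tests. Everything is built in
# code; no files are read.

# a fixed catalog with hand-written barcodes (A/C/G/T only, length 20)
toy_catalog <- function() {
  tibble::tibble(
    strain_id = c("s1", "s2", "s3"),
    barcode = c(
      "AAAACCCCGGGGTTTTACGT",
      "CCCCGGGGTTTTAAAACGTA",
      "GGGGTTTTAAAACCCCGTAC"
    ),
    gene = c("GENE1", "GENE2", "GENE3"),
    collection = "haploid_deletion",
    true_fitness = c(0, 0.1, -0.1)
  )
}

# build one 36-base read from the package layout (tag + 10-base spacer +
# barcode); spacer content is irrelevant to exact-match counting
make_read <- function(tag, barcode, spacer = "CGCTGATCAG") {
  paste0(tag, spacer, barcode)
}

# a mutation catalog with the printed per-class x ploidy margins of the
# haploid/diploid comparison: 1017 haploid and 150 diploid records, of
# which 118 and 5 are stop-gained
ploidy_margin_catalog <- function() {
  rows <- list(
    c("stop_gained", "haploid", 118),
    c("stop_gained", "diploid", 5),
    c("nonsynonymous", "haploid", 899),
    c("nonsynonymous", "diploid", 145)
  )
  purrr::map_dfr(rows, function(r) {
    n <- as.integer(r[3])
    tibble::tibble(
      gene = sprintf("g_%s_%s_%04d", r[1], r[2], seq_len(n)),
      sample_id = sprintf("smp_%s_%04d", r[2], seq_len(n)),
      condition = "glucose",
      ploidy = r[2],
      sample_type = "population",
      mclass = r[1]
    )
  }) |>
    mutation_catalog()
}

# exact two-sided rank-sum p-value by full enumeration of group
# assignments (independent oracle for wilcox.test on tiny samples)
enumerate_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  combos <- utils::combn(n, length(x))
  w_all <- apply(combos, 2, function(idx) {
    sum(ranks[idx]) - length(x) * (length(x) + 1) / 2
  })
  mu <- length(x) * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# exact two-sided Fisher p for a 2x2 by hypergeometric enumeration
enumerate_fisher_p <- function(tab) {
  m <- sum(tab[1, ]) # row 1 total
  k <- sum(tab[, 1]) # col 1 total
  n_other <- sum(tab) - m
  probs <- stats::dhyper(0:min(m, k), m, n_other, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n_other, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
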