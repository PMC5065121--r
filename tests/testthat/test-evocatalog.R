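test_that("impact mapping is total on the class vocabulary", {
  expect_identical(
    impact_of(c("stop_gained", "start_lost", "stop_lost", "frameshift")),
    rep("high", 4)
  )
  expect_identical(impact_of(c("nonsynonymous", "codon_indel")),
                   rep("moderate", 2))
  expect_identical(impact_of("synonymous"), "low")
  expect_identical(impact_of(c("upstream", "intron", "intergenic")),
                   rep("modifier", 3))
  expect_error(impact_of("missense"), "unknown")
})

test_that("recurrence counts distinct mutated samples per gene", {
  cat <- tibble::tibble(
    gene = c("A", "A", "A", "B"),
    sample_id = c("s1", "s2", "s1", "s1") # A twice in s1: counts once
  )
  rc <- recurrence_counts(cat)
  expect_identical(rc$n_samples[rc$gene == "A"], 2L)
  expect_identical(rc$n_samples[rc$gene == "B"], 1L)
  expect_identical(recurrent_genes(cat), "A")
  empty <- recurrence_counts(cat[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("per-class ploidy contingency reproduces the printed stop-gained signal", {
  cat <- ploidy_margin_catalog()
  res <- ploidy_contingency(cat, "stop_gained")
  expect_identical(sum(res$table[1, ]), 123L) # 118 haploid + 5 diploid
  expect_identical(as.integer(colSums(res$table)), c(1017L, 150L))
  expect_lt(abs(res$p_value - 0.003), 5e-4)

  # proportionally identical table: uncorrected statistic exactly 0, p = 1
  prop <- mutation_catalog(tibble::tibble(
    gene = sprintf("g%03d", 1:110),
    sample_id = sprintf("s%03d", 1:110),
    condition = "glucose",
    ploidy = rep(c("haploid", "diploid"), c(100, 10)),
    sample_type = "clone",
    mclass = c(rep("stop_gained", 10), rep("nonsynonymous", 90),
               rep("stop_gained", 1), rep("nonsynonymous", 9))
  ))
  res0 <- ploidy_contingency(prop, "stop_gained", correct = FALSE)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  one_ploidy <- dplyr::filter(prop, ploidy == "haploid")
  expect_error(ploidy_contingency(one_ploidy, "stop_gained"),
               "both ploidies")
  expect_error(ploidy_contingency(prop, "frameshift"), "zero margin")
})

test_that("Yates-corrected statistic equals the textbook formula", {
  withr::with_seed(5, {
    for (i in 1:15) {
      tab <- matrix(sample(5:80, 4, replace = TRUE), 2)
      E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (min(abs(tab - E)) < 0.5) next # R caps the correction there
      textbook <- sum((abs(tab - E) - 0.5)^2 / E)
      expect_equal(unname(chisq.test(tab, correct = TRUE)$statistic),
                   textbook, tolerance = 1e-10)
    }
  })
})

test_that("Fisher tests agree with hypergeometric enumeration", {
  tab <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(fisher.test(tab)$p.value, enumerate_fisher_p(tab),
               tolerance = 1e-10)
  cat <- mutation_catalog(tibble::tibble(
    gene = sprintf("g%d", 1:8),
    sample_id = sprintf("s%d", 1:8),
    condition = "glucose",
    ploidy = rep(c("haploid", "diploid"), each = 4),
    sample_type = "clone",
    mclass = c(rep("stop_gained", 3), "synonymous",
               "stop_gained", rep("synonymous", 3))
  ))
  res <- ploidy_contingency(cat, "stop_gained", method = "fisher")
  expect_equal(res$p_value, enumerate_fisher_p(tab), tolerance = 1e-10)

  # the overall spectrum heterogeneity test runs on the full k x 2 table
  het <- withr::with_seed(6, mutation_spectrum_test(ploidy_margin_catalog()))
  expect_true(het$p_value >= 0 && het$p_value <= 1)
})

test_that("gene-length bias test matches exact rank enumeration", {
  cat <- tibble::tibble(
    gene = c("R1", "R1", "R2", "R2", "S1", "S2", "S3"),
    sample_id = c("a", "b", "a", "c", "a", "b", "c")
  )
  ann <- tibble::tibble(gene = c("R1", "R2", "S1", "S2", "S3"),
                        length = c(5000, 6000, 1000, 1100, 1200))
  res <- length_bias(cat, ann)
  expect_gt(res$median_recurrent, res$median_singleton)
  expect_equal(res$p_value,
               enumerate_ranksum_p(c(5000, 6000), c(1000, 1100, 1200)),
               tolerance = 1e-10)

  # identical length multisets between groups: no signal, p = 1
  cat_same <- tibble::tibble(
    gene = c("R1", "R1", "R2", "R2", "S1", "S2"),
    sample_id = c("a", "b", "a", "c", "a", "b")
  )
  ann_same <- tibble::tibble(gene = c("R1", "R2", "S1", "S2"),
                             length = c(1000, 1100, 1000, 1100))
  expect_equal(length_bias(cat_same, ann_same)$p_value, 1)

  # shifting singleton lengths far up reverses the direction
  ann_shift <- dplyr::mutate(ann,
                             length = ifelse(grepl("^S", gene),
                                             length + 1e6, length))
  res_shift <- length_bias(cat, ann_shift)
  expect_lt(res_shift$median_recurrent, res_shift$median_singleton)

  expect_warning(length_bias(cat, ann[-3, ]), "without length")
  expect_error(length_bias(cat[cat$gene == "S1", ], ann), "at least one")
})

test_that("driver prediction applies the fitness-band rule per condition", {
  catalog <- mutation_catalog(tibble::tibble(
    gene = c("G1", "G2", "G3", "G1"),
    sample_id = c("p1", "p1", "p2", "p2"),
    condition = c("sulfate", "sulfate", "sulfate", "glucose"),
    ploidy = "haploid",
    sample_type = c("population", "population", "clone", "clone"),
    mclass = "nonsynonymous"
  ))
  fitness <- tibble::tibble(
    gene = c("G1", "G1", "G2"),
    condition = c("sulfate", "sulfate", "sulfate"),
    collection = c("low_copy_plasmid", "haploid_deletion", "haploid_deletion"),
    mean_fitness = c(0.15, 0.02, 0.07)
  )
  ann <- suppressMessages(predict_drivers(catalog, fitness))
  status <- setNames(ann$driver_status, paste(ann$gene, ann$condition))
  expect_identical(unname(status["G1 sulfate"]), "predicted_beneficial")
  expect_identical(unname(status["G2 sulfate"]), "intermediate")
  expect_identical(unname(status["G3 sulfate"]), "absent_from_screen")
  expect_identical(unname(status["G1 glucose"]), "absent_from_screen")

  # lowering the cutoff never shrinks the predicted set
  ann_low <- suppressMessages(predict_drivers(catalog, fitness,
                                              cutoff = 0.05))
  was <- ann$driver_status == "predicted_beneficial"
  now <- ann_low$driver_status == "predicted_beneficial"
  expect_true(all(now[was]))

  # mean-across-collections summary uses the mean, not the max
  ann_mean <- suppressMessages(predict_drivers(catalog, fitness,
                                               statistic = "mean"))
  expect_equal(ann_mean$screen_fitness[ann_mean$gene == "G1" &
                                         ann_mean$condition == "sulfate"],
               rep(0.085, 1))
})

test_that("strict matching restricts high-impact calls to deletion collections", {
  catalog <- mutation_catalog(tibble::tibble(
    gene = "G1", sample_id = "p1", condition = "sulfate",
    ploidy = "haploid", sample_type = "clone", mclass = "stop_gained"
  ))
  fitness <- tibble::tibble(
    gene = "G1", condition = "sulfate",
    collection = "high_copy_plasmid", mean_fitness = 0.3
  )
  loose <- predict_drivers(catalog, fitness)
  strict <- predict_drivers(catalog, fitness, strict = TRUE)
  expect_identical(loose$driver_status, "predicted_beneficial")
  expect_identical(strict$driver_status, "absent_from_screen")
})

test_that("per-sample driver stats summarize burden and compare sample types", {
  ann <- tibble::tibble(
    sample_id = c(rep("p1", 4), rep("c1", 2), rep("p2", 3)),
    sample_type = c(rep("population", 4), rep("clone", 2),
                    rep("population", 3)),
    driver_status = c("predicted_beneficial", "predicted_beneficial",
                      "not_predicted", "absent_from_screen",
                      "predicted_beneficial", "not_predicted",
                      "not_predicted", "not_predicted", "intermediate")
  )
  st <- per_sample_driver_stats(ann)
  expect_equal(st$samples$ratio[st$samples$sample_id == "p1"], 0.5)
  expect_equal(st$overall$mean_drivers, mean(c(2, 1, 0)))
  expect_equal(st$overall$driver_fraction, 3 / 9)
  # permuting record order changes nothing
  st2 <- per_sample_driver_stats(ann[sample(nrow(ann)), ])
  expect_equal(dplyr::arrange(st$samples, sample_id),
               dplyr::arrange(st2$samples, sample_id))
  expect_equal(st$overall, st2$overall)
})

test_that("found-vs-not-found splits beneficials by catalog membership", {
  fitness <- tibble::tibble(
    gene = c("F1", "F2", "N1", "N2", "low"),
    condition = "sulfate",
    mean_fitness = c(0.3, 0.4, 0.12, 0.11, 0.05)
  )
  catalog <- tibble::tibble(gene = c("F1", "F2"), condition = "sulfate")
  res <- found_vs_notfound(fitness, catalog, "sulfate")
  expect_identical(c(res$n_found, res$n_notfound), c(2L, 2L))
  expect_gt(res$median_found, res$median_notfound)
  expect_equal(res$p_value,
               enumerate_ranksum_p(c(0.3, 0.4), c(0.12, 0.11)),
               tolerance = 1e-10)

  # excluding the top gene removes exactly its entries from the found group
  res_ex <- found_vs_notfound(fitness, catalog, "sulfate",
                              exclude_gene = "F2")
  expect_identical(res_ex$n_found, 1L)
  expect_identical(res_ex$n_notfound, 2L)

  # identical groups carry no signal
  flat <- dplyr::mutate(fitness, mean_fitness = c(0.3, 0.4, 0.3, 0.4, 0.05))
  expect_equal(found_vs_notfound(flat, catalog, "sulfate")$p_value, 1)

  empty_group <- dplyr::filter(fitness, gene %in% c("F1", "F2", "low"))
  expect_warning(out <- found_vs_notfound(empty_group, catalog, "sulfate"),
                 "empty")
  expect_true(is.na(out$p_value))
})

test_that("mutation_catalog validates its closed vocabularies", {
  base <- tibble::tibble(gene = "G", sample_id = "s", condition = "glucose",
                         ploidy = "haploid", sample_type = "clone",
                         mclass = "stop_gained")
  expect_identical(mutation_catalog(base)$impact, "high")
  expect_error(mutation_catalog(dplyr::mutate(base, ploidy = "triploid")),
               "ploidy")
  expect_error(mutation_catalog(dplyr::mutate(base, sample_type = "colony")),
               "sample_type")
  expect_error(mutation_catalog(dplyr::select(base, -mclass)), "missing")
  expect_error(mutation_catalog(dplyr::mutate(base, frequency = 1.4)),
               "frequency")
})
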