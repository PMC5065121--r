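#' Functional impact class of a mutation class
#'
#' Maps the mutation-class vocabulary of an evolve-and-resequence
#' catalog onto SNPeff-style impact classes: stop gained/lost, start
#' lost and frameshifts are high impact; non-synonymous substitutions
#' and in-frame codon indels are moderate; synonymous substitutions are
#' low; upstream, intron and intergenic changes are modifiers.
#'
#' @param mclass Character vector of mutation classes (see
#'   [mutation_catalog()] for the vocabulary).
#' @return Character vector of impacts
#'   (`"high"`, `"moderate"`, `"low"`, `"modifier"`).
#' @export
#' @examples
#' impact_of(c("stop_gained", "synonymous", "upstream"))
impact_of <- function(mclass) {
  map <- c(stop_gained = "high", start_lost = "high", stop_lost = "high",
           frameshift = "high",
           nonsynonymous = "moderate", codon_indel = "moderate",
           synonymous = "low",
           upstream = "modifier", intron = "modifier",
           intergenic = "modifier")
  unknown <- setdiff(unique(mclass), names(map))
  if (length(unknown) > 0) {
    stop("unknown mutation class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(map[mclass])
}

#' Assemble a mutation catalog tibble
#'
#' Validates and normalizes a table of mutations observed in
#' evolve-and-resequence samples: one row per (gene, sample) mutation
#' event, with the sample's ploidy, type (sequenced clone or whole
#' population), condition and mutation class. An `impact` column is
#' derived with [impact_of()].
#'
#' @param x Data frame with columns `gene`, `sample_id`, `condition`,
#'   `ploidy` (`"haploid"`/`"diploid"`), `sample_type`
#'   (`"clone"`/`"population"`), `mclass`; optional `frequency`
#'   (in `[0, 1]`) and `study`.
#' @return A validated tibble with an added `impact` column.
#' @export
mutation_catalog <- function(x) {
  required <- c("gene", "sample_id", "condition", "ploidy", "sample_type",
                "mclass")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_ploidy <- setdiff(unique(x$ploidy), c("haploid", "diploid"))
  if (length(bad_ploidy) > 0) {
    stop("ploidy must be haploid or diploid", call. = FALSE)
  }
  bad_type <- setdiff(unique(x$sample_type), c("clone", "population"))
  if (length(bad_type) > 0) {
    stop("sample_type must be clone or population", call. = FALSE)
  }
  if ("frequency" %in% names(x)) {
    f <- x$frequency[!is.na(x$frequency)]
    if (any(f < 0 | f > 1)) stop("frequency must be in [0, 1]", call. = FALSE)
  }
  tibble::as_tibble(x) |>
    dplyr::mutate(impact = impact_of(.data$mclass))
}

#' Per-gene recurrence across evolve-and-resequence samples
#'
#' Counts, for every gene, the number of distinct samples in which it
#' was mutated (several mutations of one gene in the same sample count
#' once). Genes hit in more than one sample are candidate targets of
#' repeated adaptation.
#'
#' @param catalog Mutation catalog (see [mutation_catalog()]).
#' @param by_condition Count recurrence within each condition instead of
#'   over the whole catalog.
#' @return Tibble `gene`, `n_samples` (plus `condition` when
#'   `by_condition`), sorted by decreasing recurrence.
#' @export
#' @examples
#' cat <- tibble::tibble(gene = c("A", "A", "B"),
#'                       sample_id = c("s1", "s2", "s1"))
#' recurrence_counts(cat)
recurrence_counts <- function(catalog, by_condition = FALSE) {
  if (nrow(catalog) == 0) {
    out <- tibble::tibble(gene = character(), n_samples = integer())
    if (by_condition) out <- dplyr::mutate(out, condition = character(),
                                           .before = 1)
    return(out)
  }
  keys <- if (by_condition) c("condition", "gene") else "gene"
  catalog |>
    dplyr::distinct(dplyr::pick(dplyr::all_of(c(keys, "sample_id")))) |>
    dplyr::count(dplyr::pick(dplyr::all_of(keys)), name = "n_samples") |>
    dplyr::arrange(dplyr::desc(.data$n_samples))
}

#' Genes recurrently mutated above a sample-count threshold
#'
#' @param catalog Mutation catalog.
#' @param min_samples Minimum number of distinct mutated samples
#'   (default 2, i.e. "more than one sample").
#' @return Character vector of gene names.
#' @export
recurrent_genes <- function(catalog, min_samples = 2) {
  rc <- recurrence_counts(catalog)
  rc$gene[rc$n_samples >= min_samples]
}

new_contingency_result <- function(table, statistic, p_value, method) {
  structure(
    list(table = table, statistic = unname(statistic),
         p_value = p_value, method = method),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("<contingency_result>", x$method, "\n")
  print(x$table)
  cat(sprintf("statistic = %.4g, p = %.4g\n",
              x$statistic %||% NA_real_, x$p_value))
  invisible(x)
}

#' Does a mutation class segregate by ploidy?
#'
#' Builds the 2x2 table (this class vs all other classes) x (haploid vs
#' diploid) from the catalog's record counts and tests it; the default
#' is a chi-square test with Yates continuity correction, with Fisher's
#' exact test available.
#'
#' @param catalog Mutation catalog.
#' @param mclass Mutation class to test against the rest.
#' @param method `"chisq"` (Yates-corrected by default) or `"fisher"`.
#' @param correct Continuity correction for the chi-square.
#' @return A `contingency_result` with the 2x2 table, statistic
#'   (chi-square only) and p-value.
#' @export
ploidy_contingency <- function(catalog, mclass,
                               method = c("chisq", "fisher"),
                               correct = TRUE) {
  method <- match.arg(method)
  counts <- dplyr::count(catalog, .data$ploidy)
  n <- setNames(counts$n, counts$ploidy)
  if (any(!c("haploid", "diploid") %in% names(n))) {
    stop("both ploidies must be present in the catalog", call. = FALSE)
  }
  in_class <- dplyr::count(dplyr::filter(catalog, .data$mclass == !!mclass),
                           .data$ploidy)
  k <- setNames(rep(0L, 2), c("haploid", "diploid"))
  k[in_class$ploidy] <- in_class$n
  tab <- rbind(c(k[["haploid"]], k[["diploid"]]),
               c(n[["haploid"]] - k[["haploid"]],
                 n[["diploid"]] - k[["diploid"]]))
  dimnames(tab) <- list(class = c(mclass, "other"),
                        ploidy = c("haploid", "diploid"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in the 2x2 table for class ", mclass, call. = FALSE)
  }
  if (method == "chisq") {
    ht <- suppressWarnings(chisq.test(tab, correct = correct))
    new_contingency_result(tab, ht$statistic, ht$p.value,
                           if (correct) "chi-square (Yates)" else "chi-square")
  } else {
    ht <- fisher.test(tab)
    new_contingency_result(tab, NULL, ht$p.value, "Fisher exact")
  }
}

#' Overall heterogeneity of the mutation spectrum between ploidies
#'
#' Fisher's exact test on the full (mutation class) x (ploidy) table.
#' For tables too large for the exact network algorithm, the p-value is
#' estimated by Monte Carlo simulation (seed the RNG for
#' reproducibility).
#'
#' @param catalog Mutation catalog.
#' @param simulate Force Monte Carlo estimation; by default the exact
#'   test is attempted first and simulation is the fallback.
#' @param B Number of Monte Carlo replicates.
#' @return A `contingency_result`.
#' @export
mutation_spectrum_test <- function(catalog, simulate = FALSE, B = 10000) {
  tab <- table(factor(catalog$mclass,
                      levels = intersect(mclass_levels(),
                                         unique(catalog$mclass))),
               factor(catalog$ploidy, levels = c("haploid", "diploid")))
  ht <- if (simulate) {
    fisher.test(tab, simulate.p.value = TRUE, B = B)
  } else {
    tryCatch(
      fisher.test(tab, workspace = 2e6),
      error = function(e) fisher.test(tab, simulate.p.value = TRUE, B = B)
    )
  }
  new_contingency_result(unclass(tab), NULL, ht$p.value,
                         paste0("Fisher exact",
                                if (grepl("simulated", ht$method))
                                  " (Monte Carlo)" else ""))
}

#' Are recurrently mutated genes longer than singletons?
#'
#' Two-sided Wilcoxon rank-sum test comparing the lengths of genes
#' mutated in more than one sample against genes mutated in exactly one
#' sample. Recurrent targets tending to be longer is the expected
#' gene-length bias of recurrence-based driver calling.
#'
#' @param catalog Mutation catalog.
#' @param annotations Tibble `gene`, `length` (bp, positive). Catalog
#'   genes without a length are dropped with a warning.
#' @return One-row tibble with group sizes, median lengths, the rank-sum
#'   statistic and the two-sided p-value.
#' @export
length_bias <- function(catalog, annotations) {
  rc <- recurrence_counts(catalog)
  rc <- dplyr::left_join(rc, annotations, by = "gene")
  if (anyNA(rc$length)) {
    warning(sum(is.na(rc$length)), " gene(s) without length annotation dropped",
            call. = FALSE)
    rc <- dplyr::filter(rc, !is.na(.data$length))
  }
  recurrent <- rc$length[rc$n_samples > 1]
  singleton <- rc$length[rc$n_samples == 1]
  if (length(recurrent) == 0 || length(singleton) == 0) {
    stop("need at least one recurrent and one singleton gene", call. = FALSE)
  }
  ht <- suppressWarnings(wilcox.test(recurrent, singleton,
                                     alternative = "two.sided"))
  tibble::tibble(
    n_recurrent = length(recurrent), n_singleton = length(singleton),
    median_recurrent = median(recurrent), median_singleton = median(singleton),
    statistic = unname(ht$statistic), p_value = ht$p.value
  )
}

#' Predict which catalog mutations are drivers from the fitness screen
#'
#' Labels every mutation of an evolve-and-resequence catalog by the
#' fitness its gene showed in the pooled screen under the same
#' condition: `predicted_beneficial` when any collection measured a
#' fitness of at least `cutoff` for the gene in that condition,
#' `intermediate` when the best value is at least `secondary` but below
#' `cutoff`, `not_predicted` when measured but below `secondary`, and
#' `absent_from_screen` when the gene/condition was not measured.
#'
#' @param catalog Mutation catalog.
#' @param fitness Tibble `gene`, `condition`, `mean_fitness` (and
#'   optionally `collection`); typically a screen's fitness table joined
#'   to its strain catalog.
#' @param cutoff Driver cutoff (default 0.10).
#' @param secondary Lower bound of the intermediate band (default 0.05).
#' @param statistic Summary over collections measuring the same gene and
#'   condition: `"max"` (default; any collection reaching the cutoff) or
#'   `"mean"`.
#' @param strict Restrict the gene match by mutation impact: high-impact
#'   mutations may only match deletion collections and modifiers only
#'   plasmid (amplification) collections; requires a `collection` column
#'   and an `impact` column. Off by default.
#' @return The catalog with `screen_fitness` (the summarized fitness,
#'   `NA` when absent) and `driver_status` columns.
#' @export
predict_drivers <- function(catalog, fitness, cutoff = 0.10,
                            secondary = 0.05,
                            statistic = c("max", "mean"), strict = FALSE) {
  statistic <- match.arg(statistic)
  unmatched <- setdiff(unique(catalog$condition), unique(fitness$condition))
  if (length(unmatched) > 0) {
    message("condition(s) with no screen data: ",
            paste(unmatched, collapse = ", "))
  }
  summary_stat <- function(x) {
    if (length(x) == 0) return(NA_real_)
    if (statistic == "max") max(x) else mean(x)
  }
  if (strict) {
    if (!"collection" %in% names(fitness)) {
      stop("strict matching requires a collection column in `fitness`",
           call. = FALSE)
    }
    deletion <- c("haploid_deletion", "het_diploid_deletion")
    plasmid <- c("low_copy_plasmid", "high_copy_plasmid")
    summarize_for <- function(impact) {
      keep <- switch(impact,
                     high = dplyr::filter(fitness, .data$collection %in% deletion),
                     modifier = dplyr::filter(fitness, .data$collection %in% plasmid),
                     fitness)
      dplyr::summarise(keep,
                       screen_fitness = summary_stat(.data$mean_fitness),
                       .by = c("gene", "condition")) |>
        dplyr::mutate(impact = impact)
    }
    summary_tbl <- purrr::map_dfr(unique(catalog$impact), summarize_for)
    out <- dplyr::left_join(catalog, summary_tbl,
                            by = c("gene", "condition", "impact"))
  } else {
    summary_tbl <- fitness |>
      dplyr::summarise(
        screen_fitness = summary_stat(.data$mean_fitness),
        .by = c("gene", "condition")
      )
    out <- dplyr::left_join(catalog, summary_tbl,
                            by = c("gene", "condition"))
  }
  dplyr::mutate(out, driver_status = dplyr::case_when(
    is.na(.data$screen_fitness) ~ "absent_from_screen",
    .data$screen_fitness >= cutoff ~ "predicted_beneficial",
    .data$screen_fitness >= secondary ~ "intermediate",
    TRUE ~ "not_predicted"
  ))
}

#' Per-sample driver burden and clone-versus-population comparison
#'
#' For each sequenced sample (clone or population): the number of
#' predicted driver mutations, the total mutation count and their ratio;
#' then group means per sample type, overall means, and a two-sided
#' Wilcoxon rank-sum test of the per-sample driver ratio between clones
#' and populations.
#'
#' @param annotated A catalog labeled by [predict_drivers()].
#' @return A list with `samples` (per-sample tibble), `by_type` (group
#'   means), `overall` (one-row tibble: mean drivers per sample and
#'   overall driver fraction) and `test` (Wilcoxon comparison, `NULL`
#'   when a sample type is missing).
#' @export
per_sample_driver_stats <- function(annotated) {
  samples <- annotated |>
    dplyr::summarise(
      n_drivers = sum(.data$driver_status == "predicted_beneficial"),
      n_total = dplyr::n(),
      ratio = .data$n_drivers / .data$n_total,
      .by = c("sample_id", "sample_type")
    )
  by_type <- samples |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      mean_drivers = mean(.data$n_drivers),
      mean_ratio = mean(.data$ratio),
      .by = "sample_type"
    )
  overall <- tibble::tibble(
    n_samples = nrow(samples),
    mean_drivers = mean(samples$n_drivers),
    driver_fraction = sum(samples$n_drivers) / sum(samples$n_total)
  )
  test <- NULL
  if (dplyr::n_distinct(samples$sample_type) == 2) {
    ht <- suppressWarnings(wilcox.test(
      ratio ~ sample_type, data = samples, alternative = "two.sided"
    ))
    test <- tibble::tibble(statistic = unname(ht$statistic),
                           p_value = ht$p.value)
  }
  list(samples = samples, by_type = by_type, overall = overall, test = test)
}

#' Compare fitness of beneficial mutations found vs not found in evolution
#'
#' Splits the screen's beneficial entries in one condition (fitness
#' strictly above `cutoff`) into genes that were mutated in the
#' evolve-and-resequence catalog under the same condition ("found") and
#' genes that never were ("not found"), and compares the two fitness
#' distributions with a two-sided Wilcoxon rank-sum test. A named gene
#' (e.g. a dominant driver) can be excluded to ask whether the signal
#' survives without it.
#'
#' @param fitness Tibble `gene`, `condition`, `mean_fitness`.
#' @param catalog Mutation catalog.
#' @param condition Condition to compare within.
#' @param cutoff Beneficial cutoff (default 0.10, strict).
#' @param exclude_gene Optional gene name dropped from both groups.
#' @return One-row tibble with group sizes, medians, rank-sum statistic
#'   and p-value (`NA` with a warning when a group is empty).
#' @export
found_vs_notfound <- function(fitness, catalog, condition, cutoff = 0.10,
                              exclude_gene = NULL) {
  beneficial <- fitness |>
    dplyr::filter(.data$condition == !!condition,
                  .data$mean_fitness > cutoff)
  if (!is.null(exclude_gene)) {
    beneficial <- dplyr::filter(beneficial, !.data$gene %in% exclude_gene)
  }
  mutated <- unique(catalog$gene[catalog$condition == condition])
  found <- beneficial$mean_fitness[beneficial$gene %in% mutated]
  notfound <- beneficial$mean_fitness[!beneficial$gene %in% mutated]
  out <- tibble::tibble(
    condition = condition,
    n_found = length(found), n_notfound = length(notfound),
    median_found = if (length(found)) median(found) else NA_real_,
    median_notfound = if (length(notfound)) median(notfound) else NA_real_,
    statistic = NA_real_, p_value = NA_real_
  )
  if (length(found) == 0 || length(notfound) == 0) {
    warning("one group is empty; no test performed", call. = FALSE)
    return(out)
  }
  ht <- suppressWarnings(wilcox.test(found, notfound,
                                     alternative = "two.sided"))
  dplyr::mutate(out, statistic = unname(ht$statistic), p_value = ht$p.value)
}
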