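#' Per-family species richness in a region and time bin
#'
#' @inheritParams families_in
#' @return A tibble `family`, `species_count` (summed over records; families
#'   with no recorded counts are dropped).
#' @export
family_richness <- function(occ, region, time_bin) {
  if (!"species_count" %in% names(occ)) {
    abort("Occurrence table has no species_count column.",
      class = "polarphylo_schema_error")
  }
  sub <- occ[occ$region == region & occ$time_bin == time_bin, , drop = FALSE]
  out <- dplyr::summarise(dplyr::group_by(sub, .data$family),
    species_count = sum(.data$species_count, na.rm = TRUE), .groups = "drop")
  out[!is.na(out$species_count) & out$species_count > 0, ]
}

test_result <- function(test, statistic, p_value, n) {
  tibble(test = test, statistic = unname(statistic),
    p_value = unname(p_value), n = n)
}

#' Cross-region correlation of family species richness
#'
#' Spearman rank correlation of per-family species counts for the families
#' shared by two regions in one time bin (two-sided test).
#'
#' @inheritParams families_in
#' @param region_a,region_b The two regions.
#' @return A one-row `TestResult` tibble (`test`, `statistic`, `p_value`, `n`).
#' @export
richness_correlation <- function(occ, region_a, region_b, time_bin) {
  paired <- shared_richness(occ, region_a, region_b, time_bin)
  ct <- suppressWarnings(
    cor.test(paired$count_a, paired$count_b, method = "spearman"))
  test_result("Spearman rank correlation", ct$estimate, ct$p.value, nrow(paired))
}

#' Paired test of family species richness between regions
#'
#' Wilcoxon signed-rank test on the per-family species counts of shared
#' families (two-sided).
#'
#' @inheritParams richness_correlation
#' @return A one-row `TestResult` tibble.
#' @export
paired_richness_test <- function(occ, region_a, region_b, time_bin) {
  paired <- shared_richness(occ, region_a, region_b, time_bin)
  wt <- suppressWarnings(
    wilcox.test(paired$count_a, paired$count_b, paired = TRUE))
  p <- if (is.na(wt$p.value)) 1 else wt$p.value # all differences zero
  test_result("Wilcoxon signed-rank (paired)", wt$statistic, p, nrow(paired))
}

shared_richness <- function(occ, region_a, region_b, time_bin) {
  ra <- family_richness(occ, region_a, time_bin)
  rb <- family_richness(occ, region_b, time_bin)
  paired <- dplyr::inner_join(ra, rb, by = "family", suffix = c("_a", "_b"))
  names(paired) <- c("family", "count_a", "count_b")
  if (nrow(paired) < 3L) {
    abort("Fewer than 3 shared families with species counts.",
      class = "polarphylo_validation_error")
  }
  paired
}

#' Compare a numeric variable between extinct and surviving families
#'
#' Two-sample Kolmogorov-Smirnov test of the distribution of `values` (e.g.
#' species richness or body size) across the two classes of an extinction
#' labeling.
#'
#' @param labeling A labeling tibble (`family`, `extinct`).
#' @param values Named numeric vector (names = families) or a tibble with
#'   columns `family` and `value`.
#' @return A one-row `TestResult` tibble.
#' @export
extinction_ks_test <- function(labeling, values) {
  check_labeling(labeling)
  if (is.data.frame(values)) {
    values <- stats::setNames(values$value, values$family)
  }
  v <- values[labeling$family]
  ext <- v[labeling$extinct]
  sur <- v[!labeling$extinct]
  ext <- ext[!is.na(ext)]
  sur <- sur[!is.na(sur)]
  if (!length(ext) || !length(sur)) {
    abort("Both extinct and surviving groups need values.",
      class = "polarphylo_validation_error")
  }
  kt <- suppressWarnings(ks.test(ext, sur))
  test_result("Kolmogorov-Smirnov (extinct vs surviving)", kt$statistic,
    kt$p.value, length(ext) + length(sur))
}

#' Two-sample distribution tests on grouped numeric data
#'
#' Thin wrappers over the standard two-sample Kolmogorov-Smirnov and
#' Kruskal-Wallis tests, returning the package's tidy `TestResult` row.
#'
#' @param x,y Numeric samples.
#' @return A one-row `TestResult` tibble.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) {
    abort("Empty group.", class = "polarphylo_validation_error")
  }
  kt <- suppressWarnings(ks.test(x, y))
  test_result("Kolmogorov-Smirnov (two-sample)", kt$statistic, kt$p.value,
    length(x) + length(y))
}

#' @rdname ks_two_sample
#' @param values Numeric vector of observations.
#' @param groups Grouping factor of the same length.
#' @export
kruskal_groups <- function(values, groups) {
  if (length(unique(groups)) < 2L) {
    abort("Kruskal-Wallis needs at least two groups.",
      class = "polarphylo_validation_error")
  }
  kt <- kruskal.test(values, as.factor(groups))
  test_result("Kruskal-Wallis", kt$statistic, kt$p.value, length(values))
}

#' Association between a family category and extinction status
#'
#' Chi-square test on the contingency table of a categorical family
#' attribute (functional category, order, ...) against extinct/surviving
#' status.
#'
#' @param labeling A labeling tibble (`family`, `extinct`).
#' @param categories A tibble with columns `family` and `category` (or
#'   `order`, renamed internally).
#' @param simulate_p Use Monte-Carlo p-values for sparse tables (passed to
#'   [stats::chisq.test()]).
#' @return A one-row `TestResult` tibble.
#' @export
category_association_test <- function(labeling, categories, simulate_p = FALSE) {
  check_labeling(labeling)
  if ("order" %in% names(categories) && !"category" %in% names(categories)) {
    categories <- dplyr::rename(categories, category = "order")
  }
  df <- dplyr::inner_join(labeling, categories, by = "family")
  if (!nrow(df)) {
    abort("No families with both a label and a category.",
      class = "polarphylo_validation_error")
  }
  tab <- table(df$category, df$extinct)
  ct <- suppressWarnings(chisq.test(tab, simulate.p.value = simulate_p))
  test_result("Chi-square (category x extinction)", ct$statistic, ct$p.value,
    nrow(df))
}
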