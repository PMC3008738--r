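#' Lyellian survivorship percentage with exact binomial CI
#'
#' The Lyellian percentage is the percent of genera in a fossil time interval
#' that survive to the Recent. The 95% confidence interval is the exact
#' Clopper-Pearson binomial interval on the proportion, reported on the
#' percent scale (beta-quantile closed form; at 0 or n survivors the
#' corresponding bound is exactly 0 or 100).
#'
#' @param n_surviving Number of genera surviving to the Recent.
#' @param n_total Number of genera in the interval (>= 1). Both arguments are
#'   vectorized.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with columns `n_genera`, `n_surviving`,
#'   `percent_surviving`, `ci_low`, `ci_high`, `method`.
#' @examples
#' lyellian(5, 10) # 50%, CI about (18.7, 81.3)
#' @export
lyellian <- function(n_surviving, n_total, conf_level = 0.95) {
  if (any(n_total < 1)) {
    abort("n_total must be >= 1.", class = "polarphylo_validation_error")
  }
  if (any(n_surviving < 0) || any(n_surviving > n_total)) {
    abort("n_surviving must lie in [0, n_total].",
      class = "polarphylo_validation_error")
  }
  ci <- clopper_pearson(n_surviving, n_total, conf_level)
  tibble(
    n_genera = as.integer(n_total), n_surviving = as.integer(n_surviving),
    percent_surviving = 100 * n_surviving / n_total,
    ci_low = 100 * ci$lower, ci_high = 100 * ci$upper,
    method = "Clopper-Pearson exact binomial"
  )
}

# exact binomial interval via beta quantiles (vectorized)
clopper_pearson <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  lower <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  list(lower = lower, upper = upper)
}

#' Genus-level extinction-cascade null for family extinction
#'
#' Tests whether independent genus-level turnover can explain family-level
#' extinction patterns. Per replicate, a fixed number of genera --
#' `round((1 - survival_fraction) * N)` with half-up rounding, the draw count
#' implied by the regional Lyellian percentage -- is drawn without
#' replacement from the (region, bin) genus list and marked extinct; a family
#' goes extinct iff all of its genera are drawn. Per replicate the family
#' extinction count and the MPD/MNTD of the extinct family set (on the
#' calibrated tree's patristic matrix) are recorded, along with whether each
#' named co-extinction event occurred (all families in the named set
#' extinct). Replicates with fewer than two extinct families on the tree
#' record missing MPD/MNTD and are excluded from those summaries (their
#' counts are retained); the number of such replicates is reported.
#'
#' @param occ Occurrence tibble; every (region, bin) record must carry a
#'   genus. Genus lists are deduplicated within the bin; subgenus strings
#'   count as distinct genera unless aliased upstream.
#' @param tree Calibrated global [ape::phylo] (for per-replicate MPD/MNTD).
#' @param region,time_bin Which fauna to randomize.
#' @param survival_fraction Proportion of genera surviving (e.g. a Lyellian
#'   percentage / 100), in `[0, 1]`.
#' @param n_reps Number of replicates (default 10000).
#' @param seed Integer seed.
#' @param events Optional named list of character vectors; each names a set
#'   of families whose joint extinction frequency is tracked (e.g. an order's
#'   families via [read_order_table()]).
#' @return A `polar_cascade` list: `reps` (per-replicate tibble with
#'   `n_extinct_families`, `mpd`, `mntd`, one logical column per event),
#'   `summary` (one-row tibble: mean, sd, and mean +/- 1.96 sd interval of
#'   the extinction count, MPD/MNTD summaries, replicate bookkeeping) and
#'   `event_freq` (tibble of per-event frequencies).
#' @export
cascade_null <- function(occ, tree, region, time_bin, survival_fraction,
                         n_reps = 10000, seed = NULL, events = NULL) {
  if (survival_fraction < 0 || survival_fraction > 1) {
    abort("survival_fraction must be in [0, 1].",
      class = "polarphylo_validation_error")
  }
  assert_calibrated(tree)
  gen <- genera_in(occ, region, time_bin) # errors if any genus missing
  fam_of_genus <- gen$family
  fams <- unique(fam_of_genus)
  fam_sizes <- table(factor(fam_of_genus, levels = fams))
  n_gen <- nrow(gen)
  n_extinct_gen <- round_half_up((1 - survival_fraction) * n_gen)
  fam_idx <- match(fam_of_genus, fams)
  on_tree <- fams %in% tree$tip.label
  dmat <- if (sum(on_tree) >= 2L) {
    patristic_matrix(tree)[fams[on_tree], fams[on_tree]]
  } else NULL
  if (!is.null(events)) {
    bad <- vapply(events, function(e) length(setdiff(e, fams)) > 0, logical(1L))
    if (any(bad)) {
      warn(paste0("Event set(s) with families absent from the fauna (frequency will be 0): ",
        paste(names(events)[bad], collapse = ", ")))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  mpd_f <- metric_fun("mpd")
  mntd_f <- metric_fun("mntd")
  rep_rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    drawn <- sample.int(n_gen, n_extinct_gen)
    hit <- tabulate(fam_idx[drawn], nbins = length(fams))
    extinct <- hit == as.integer(fam_sizes)
    ext_fams <- fams[extinct]
    ext_tree <- intersect(ext_fams, rownames(dmat) %||% character())
    metr <- if (length(ext_tree) >= 2L) {
      idx <- match(ext_tree, rownames(dmat))
      c(mpd_f(idx, dmat), mntd_f(idx, dmat))
    } else c(NA_real_, NA_real_)
    ev <- if (is.null(events)) NULL else {
      vapply(events, function(e) all(e %in% ext_fams), logical(1L))
    }
    rep_rows[[r]] <- c(list(n_extinct_families = sum(extinct),
      mpd = metr[1L], mntd = metr[2L]), as.list(ev))
  }
  reps <- dplyr::bind_rows(rep_rows)
  counts <- reps$n_extinct_families
  n_missing <- sum(is.na(reps$mpd))
  if (n_missing > 0) {
    rlang::inform(sprintf(
      "%d of %d replicates had < 2 extinct families on the tree; excluded from MPD/MNTD summaries.",
      n_missing, n_reps))
  }
  summ <- tibble(
    region = region, time_bin = time_bin,
    n_genera = n_gen, n_families = length(fams),
    n_genera_drawn = n_extinct_gen,
    survival_fraction = survival_fraction,
    n_reps = as.integer(n_reps),
    mean_extinct_families = mean(counts),
    sd_extinct_families = stats::sd(counts),
    ci_low = mean(counts) - 1.96 * stats::sd(counts),
    ci_high = mean(counts) + 1.96 * stats::sd(counts),
    mean_mpd = mean(reps$mpd, na.rm = TRUE),
    mean_mntd = mean(reps$mntd, na.rm = TRUE),
    n_reps_metric_missing = as.integer(n_missing),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  event_freq <- if (is.null(events)) {
    tibble(event = character(), frequency = numeric())
  } else {
    tibble(event = names(events),
      frequency = vapply(names(events), function(e) mean(reps[[e]]), numeric(1L)))
  }
  structure(list(reps = reps, summary = summ, event_freq = event_freq),
    class = "polar_cascade")
}

round_half_up <- function(x) floor(x + 0.5)

#' @export
print.polar_cascade <- function(x, ...) {
  s <- x$summary
  cat("Genus-level extinction-cascade null\n")
  cat(sprintf("  %s / %s: %d genera in %d families; %d drawn per rep (survival %.2f)\n",
    s$region, s$time_bin, s$n_genera, s$n_families, s$n_genera_drawn,
    s$survival_fraction))
  cat(sprintf("  extinct families: %.2f +/- %.2f  (95%% interval %.2f-%.2f), %d reps\n",
    s$mean_extinct_families, s$sd_extinct_families, s$ci_low, s$ci_high, s$n_reps))
  if (nrow(x$event_freq)) {
    cat("  co-extinction event frequencies:\n")
    for (i in seq_len(nrow(x$event_freq))) {
      cat(sprintf("    %-24s %.4f\n", x$event_freq$event[i], x$event_freq$frequency[i]))
    }
  }
  invisible(x)
}

#' @rdname cascade_null
#' @param x A `polar_cascade` object.
#' @param ... Unused.
#' @method tidy polar_cascade
#' @export
tidy.polar_cascade <- function(x, ...) x$reps

#' @rdname cascade_null
#' @method glance polar_cascade
#' @export
glance.polar_cascade <- function(x, ...) x$summary

#' Plot the cascade-null family-extinction distribution
#'
#' Histogram of per-replicate family extinction counts, with the optional
#' observed count marked.
#'
#' @param object A `polar_cascade` object.
#' @param observed Optional observed family-extinction count to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot polar_cascade
#' @export
autoplot.polar_cascade <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(object$reps,
      ggplot2::aes(x = .data$n_extinct_families)) +
    ggplot2::geom_bar(fill = "grey70", colour = "grey40") +
    ggplot2::labs(x = "Families extinct per replicate", y = "Replicates",
      title = "Genus-cascade null") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "firebrick",
      linewidth = 1)
  }
  p
}
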