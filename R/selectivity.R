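#' Mean pairwise distance of a family set
#'
#' Arithmetic mean of the patristic distances over all unordered pairs of the
#' member families, in Myr.
#'
#' @param members Character vector of at least two family names.
#' @param dist A patristic distance matrix (see [patristic_matrix()]).
#' @return MPD in Myr.
#' @export
mpd <- function(members, dist) {
  sub <- dist_submatrix(members, dist)
  mean(sub[upper.tri(sub)])
}

#' Mean nearest-taxon distance of a family set
#'
#' Mean over member families of the distance to the closest other member, in
#' Myr. Always `<=` MPD on the same set.
#'
#' @inheritParams mpd
#' @return MNTD in Myr.
#' @export
mntd <- function(members, dist) {
  sub <- dist_submatrix(members, dist)
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

dist_submatrix <- function(members, dist) {
  members <- unique(as.character(members))
  if (length(members) < 2L) {
    abort("At least two families are required for distance metrics.",
      class = "polarphylo_undefined_error")
  }
  unknown <- setdiff(members, rownames(dist))
  if (length(unknown)) {
    abort(paste0("Families not in the distance matrix: ",
      paste(unknown, collapse = ", ")), class = "polarphylo_key_error")
  }
  dist[members, members, drop = FALSE]
}

metric_fun <- function(metric) {
  switch(metric,
    mpd = function(idx, d) {
      sub <- d[idx, idx]
      mean(sub[upper.tri(sub)])
    },
    mntd = function(idx, d) {
      sub <- d[idx, idx]
      diag(sub) <- Inf
      mean(apply(sub, 1L, min))
    },
    abort(paste0("Unknown metric: ", metric))
  )
}

#' Standardized effect size of extinction clustering
#'
#' Measures whether the families that went regionally extinct are more
#' closely related than expected by chance. The observed MPD and/or MNTD of
#' the extinct set is compared against a null distribution obtained by
#' drawing uniformly random same-size subsets of the regional tree's tips --
#' the exact set-valued equivalent of shuffling tip labels on the regional
#' tree. SES = (observed - null mean) / null sd, with the sample (n-1)
#' standard deviation; negative SES indicates phylogenetic clumping. The
#' primary p-value is one-tailed for clustering with the add-one correction
#' `p = (#\{null <= observed\} + 1) / (n_rand + 1)`, which can never return
#' exactly zero; a two-tailed version is also reported.
#'
#' Distances are taken from the supplied tree's patristic matrix. When the
#' regional tree is a true subtree of the calibrated global tree the two
#' matrices agree, so either the global or the regional tree may be passed;
#' families in the matrix but absent from the labeling never affect the
#' result.
#'
#' @param labeling A tibble with columns `family` and logical `extinct`
#'   (see [label_extinctions()]). All families must be tips of `tree`.
#' @param tree The calibrated [ape::phylo] (global or regional).
#' @param metric Character vector, any of `"mpd"`, `"mntd"`.
#' @param n_rand Number of null randomizations (default 10000).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return A `polar_ses` tibble with one row per metric and columns
#'   `metric`, `observed`, `null_mean`, `null_sd`, `ses`, `p_low`, `p_high`,
#'   `n_extinct`, `n_pool`, `n_rand`, `seed`. Null draws are kept in the
#'   `null_draws` attribute for plotting.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' lab <- tibble::tibble(family = c("A", "B", "C", "D"),
#'                       extinct = c(TRUE, TRUE, FALSE, FALSE))
#' ses_phylo(lab, tr, metric = "mpd", n_rand = 999, seed = 1)
#' @export
ses_phylo <- function(labeling, tree, metric = c("mpd", "mntd"),
                      n_rand = 10000, seed = NULL) {
  metric <- match.arg(metric, several.ok = TRUE)
  assert_calibrated(tree)
  check_labeling(labeling)
  pool <- labeling$family
  unknown <- setdiff(pool, tree$tip.label)
  if (length(unknown)) {
    abort(paste0("Labeled families not on the tree: ",
      paste(unknown, collapse = ", ")), class = "polarphylo_key_error")
  }
  extinct <- labeling$family[labeling$extinct]
  k <- length(extinct)
  if (k < 2L) {
    abort("At least two extinct families are required.",
      class = "polarphylo_undefined_error")
  }
  if (k >= length(pool)) {
    abort("Degenerate null: every labeled family is extinct.",
      class = "polarphylo_degenerate_error")
  }
  dmat <- patristic_matrix(tree)[pool, pool]
  if (!is.null(seed)) set.seed(seed)
  n_pool <- length(pool)
  draws <- lapply(seq_len(n_rand), function(i) sample.int(n_pool, k))
  rows <- lapply(metric, function(m) {
    f <- metric_fun(m)
    obs <- f(match(extinct, pool), dmat)
    null <- vapply(draws, f, numeric(1L), d = dmat)
    null_sd <- stats::sd(null)
    if (null_sd == 0) {
      abort("Degenerate null: zero variance across randomizations.",
        class = "polarphylo_degenerate_error")
    }
    p_low <- (sum(null <= obs) + 1) / (n_rand + 1)
    p_high <- (sum(null >= obs) + 1) / (n_rand + 1)
    list(
      row = tibble(
        metric = m, observed = obs, null_mean = mean(null), null_sd = null_sd,
        ses = (obs - mean(null)) / null_sd,
        p_low = p_low, p_high = min(1, 2 * min(p_low, p_high)),
        n_extinct = k, n_pool = n_pool, n_rand = as.integer(n_rand),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
      ),
      null = null
    )
  })
  out <- dplyr::bind_rows(lapply(rows, `[[`, "row"))
  attr(out, "null_draws") <- stats::setNames(lapply(rows, `[[`, "null"), metric)
  attr(out, "region") <- attr(labeling, "region")
  class(out) <- c("polar_ses", class(out))
  out
}

check_labeling <- function(labeling) {
  if (!is.data.frame(labeling) ||
      !all(c("family", "extinct") %in% names(labeling))) {
    abort("`labeling` must be a data frame with columns family, extinct.",
      class = "polarphylo_schema_error")
  }
  if (!is.logical(labeling$extinct) || anyNA(labeling$extinct)) {
    abort("`extinct` must be logical with no missing values.",
      class = "polarphylo_validation_error")
  }
  if (anyDuplicated(labeling$family)) {
    abort("Duplicate families in the labeling.",
      class = "polarphylo_validation_error")
  }
  invisible(labeling)
}

#' @export
print.polar_ses <- function(x, ...) {
  region <- attr(x, "region")
  cat("Phylogenetic extinction selectivity (tip-shuffle null)\n")
  if (!is.null(region)) cat("Region:", region, "\n")
  cat(sprintf("Extinct families: %d of %d; %d randomizations\n",
    x$n_extinct[1], x$n_pool[1], x$n_rand[1]))
  print(as_tibble(x)[, c("metric", "observed", "null_mean", "null_sd",
    "ses", "p_low")], ...)
  invisible(x)
}

#' @rdname ses_phylo
#' @param x A `polar_ses` object.
#' @param ... Unused.
#' @method tidy polar_ses
#' @export
tidy.polar_ses <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "polar_ses")
  out
}

#' @rdname ses_phylo
#' @method glance polar_ses
#' @export
glance.polar_ses <- function(x, ...) {
  tibble(
    n_extinct = x$n_extinct[1], n_pool = x$n_pool[1], n_rand = x$n_rand[1],
    min_p_low = min(x$p_low), min_ses = min(x$ses)
  )
}

#' Plot an SES null distribution against the observed value
#'
#' Histogram of the null metric draws with the observed value as a vertical
#' line; one panel per metric.
#'
#' @param object A `polar_ses` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot polar_ses
#' @export
autoplot.polar_ses <- function(object, ...) {
  draws <- attr(object, "null_draws")
  null_df <- dplyr::bind_rows(lapply(names(draws), function(m) {
    tibble(metric = m, value = draws[[m]])
  }))
  obs_df <- tibble(metric = object$metric, observed = object$observed)
  ggplot2::ggplot(null_df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(data = obs_df,
      ggplot2::aes(xintercept = .data$observed), colour = "firebrick",
      linewidth = 1) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "Distance (Myr)", y = "Null draws",
      title = "Observed vs. tip-shuffle null") +
    ggplot2::theme_minimal()
}
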