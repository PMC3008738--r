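#' Sum of sister-clade differences for a binary trait
#'
#' The raw d value behind the Fritz-Purvis D statistic. Internal node values
#' are estimated tips-to-root as the arithmetic mean of the node's children
#' (polytomies handled natively by averaging over all children; no
#' branch-length weighting); d is the sum over edges of the absolute
#' difference between child and parent values. Clumped traits yield small d,
#' scattered traits large d.
#'
#' @param tree An [ape::phylo].
#' @param states Binary trait: a logical or 0/1 numeric vector named by tip
#'   label, or an extinction labeling tibble (columns `family`, `extinct`).
#' @return The d value (dimensionless).
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' trait_d_score(tr, c(A = 1, B = 1, C = 0, D = 0)) # 1, clumped
#' trait_d_score(tr, c(A = 1, B = 0, C = 1, D = 0)) # 2, scattered
#' @export
trait_d_score <- function(tree, states) {
  s <- as_binary_states(tree, states)
  if (all(s == s[1L])) {
    abort("Trait has no variation; D is undefined.",
      class = "polarphylo_constant_trait_error")
  }
  d_scores(tree, matrix(s, ncol = 1L))[1L]
}

as_binary_states <- function(tree, states) {
  if (is.data.frame(states)) {
    check_labeling(states)
    states <- stats::setNames(as.numeric(states$extinct), states$family)
  }
  if (is.logical(states)) states <- as.numeric(states)
  if (is.null(names(states))) {
    abort("Trait vector must be named by tip label.",
      class = "polarphylo_validation_error")
  }
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing)) {
    abort(paste0("Trait missing for tips: ", paste(missing, collapse = ", ")),
      class = "polarphylo_validation_error")
  }
  s <- states[tree$tip.label]
  if (!all(s %in% c(0, 1))) {
    abort("Trait must be binary (0/1 or logical).",
      class = "polarphylo_validation_error")
  }
  unname(s)
}

# vectorized d over columns of a tip-state matrix (Ntip x m), tips in
# tree$tip.label order
d_scores <- function(tree, state_mat) {
  n <- ape::Ntip(tree)
  ntot <- n + tree$Nnode
  m <- ncol(state_mat)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  V <- matrix(0, nrow = ntot, ncol = m)
  V[seq_len(n), ] <- state_mat
  cnt <- integer(ntot)
  # postorder guarantees a child's subtree is complete before its edge is
  # visited, so divide-by-count can be done lazily on first use as a child
  for (k in seq_len(nrow(po))) {
    p <- po[k, 1L]
    ch <- po[k, 2L]
    if (ch > n && cnt[ch] > 0L) {
      V[ch, ] <- V[ch, ] / cnt[ch]
      cnt[ch] <- 0L
    }
    V[p, ] <- V[p, ] + V[ch, ]
    cnt[p] <- cnt[p] + 1L
  }
  root <- po[nrow(po), 1L]
  V[root, ] <- V[root, ] / cnt[root]
  .colSums(abs(V[po[, 2L], , drop = FALSE] - V[po[, 1L], , drop = FALSE]),
    nrow(po), m)
}

# Brownian-motion tip simulation: root value 0, each edge adds a normal
# increment with variance proportional to its length. Returns Ntip x m matrix.
simulate_brownian_tips <- function(tree, m = 1L) {
  assert_calibrated(tree)
  if (sum(tree$edge.length) <= 0) {
    abort("Total tree length is zero; Brownian simulation is undefined.",
      class = "polarphylo_degenerate_error")
  }
  n <- ape::Ntip(tree)
  cw <- ape::reorder.phylo(tree, "cladewise")
  V <- matrix(0, nrow = n + tree$Nnode, ncol = m)
  for (k in seq_len(nrow(cw$edge))) {
    p <- cw$edge[k, 1L]
    ch <- cw$edge[k, 2L]
    V[ch, ] <- V[p, ] + rnorm(m, sd = sqrt(max(cw$edge.length[k], 0)))
  }
  V[seq_len(n), , drop = FALSE]
}

# threshold a continuous tip-trait matrix so that exactly k tips per column
# are in state 1 (rank-based; random tie-breaking keeps prevalence exact)
threshold_by_rank <- function(trait_mat, k) {
  apply(trait_mat, 2L, function(x) {
    as.numeric(rank(-x, ties.method = "random") <= k)
  })
}

#' Fritz-Purvis D statistic for a binary extinction trait
#'
#' Locates the observed sum of sister-clade differences d between two
#' reference points: its expectation under a phylogenetically random trait
#' (tip shuffles preserving prevalence) and under a trait evolved by Brownian
#' motion and thresholded to the observed prevalence. D =
#' (d_obs - mean d_Brownian) / (mean d_random - mean d_Brownian), so D of 1
#' indicates a random trait distribution and 0 the clumping expected under
#' Brownian evolution; D is invariant to swapping the two state labels up to
#' Monte-Carlo error because both nulls are prevalence-matched.
#'
#' The Brownian null simulates a continuous character edge-wise with variance
#' proportional to branch length and marks the k highest-ranked tips as
#' state-1, k being the observed count, so prevalence is identical across
#' nulls. Polytomies are retained (nodal means over all children), so no
#' random topology resolution occurs.
#'
#' @param labeling Binary trait: an extinction-labeling tibble or a named
#'   vector, as for [trait_d_score()]. Both states must be present.
#' @param tree The calibrated [ape::phylo]; branch lengths drive the Brownian
#'   null.
#' @param n_sims Simulations per null (default 1000).
#' @param seed Integer seed.
#' @return A `polar_d` list with elements `d_obs`, `mean_d_random`,
#'   `mean_d_brownian`, `D`, `p_random` (fraction of random-null d values
#'   `<=` d_obs, i.e. evidence of clumping against the shuffle null),
#'   `p_brownian` (fraction of Brownian-null d values `>=` d_obs), `n_sims`,
#'   `seed`, plus the two null d distributions.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' phylo_d(c(A = 1, B = 1, C = 0, D = 0), tr, n_sims = 200, seed = 1)
#' @export
phylo_d <- function(labeling, tree, n_sims = 1000, seed = NULL) {
  assert_calibrated(tree)
  s <- as_binary_states(tree, labeling)
  if (all(s == s[1L])) {
    abort("Trait has no variation; D is undefined.",
      class = "polarphylo_constant_trait_error")
  }
  n <- length(s)
  k <- sum(s == 1)
  if (!is.null(seed)) set.seed(seed)
  d_obs <- d_scores(tree, matrix(s, ncol = 1L))[1L]
  shuffles <- vapply(seq_len(n_sims), function(i) {
    out <- numeric(n)
    out[sample.int(n, k)] <- 1
    out
  }, numeric(n))
  d_rand <- d_scores(tree, shuffles)
  bm <- simulate_brownian_tips(tree, n_sims)
  d_brown <- d_scores(tree, threshold_by_rank(bm, k))
  denom <- mean(d_rand) - mean(d_brown)
  if (denom <= 0) {
    abort("Nulls indistinguishable: random and Brownian expectations coincide.",
      class = "polarphylo_degenerate_error")
  }
  structure(
    list(
      d_obs = d_obs,
      mean_d_random = mean(d_rand),
      mean_d_brownian = mean(d_brown),
      D = (d_obs - mean(d_brown)) / denom,
      p_random = (sum(d_rand <= d_obs) + 1) / (n_sims + 1),
      p_brownian = (sum(d_brown >= d_obs) + 1) / (n_sims + 1),
      n_sims = as.integer(n_sims),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      n_tips = n, n_state1 = k,
      null_random = d_rand, null_brownian = d_brown
    ),
    class = "polar_d"
  )
}

#' @export
print.polar_d <- function(x, ...) {
  cat("Fritz-Purvis D statistic\n")
  cat(sprintf("  d observed      : %.4f  (%d of %d tips in state 1)\n",
    x$d_obs, x$n_state1, x$n_tips))
  cat(sprintf("  E[d] random     : %.4f\n", x$mean_d_random))
  cat(sprintf("  E[d] Brownian   : %.4f\n", x$mean_d_brownian))
  cat(sprintf("  D               : %.4f  (1 = random, 0 = Brownian clumping)\n", x$D))
  cat(sprintf("  p (vs random)   : %.4f   p (vs Brownian): %.4f   n_sims: %d\n",
    x$p_random, x$p_brownian, x$n_sims))
  invisible(x)
}

#' @rdname phylo_d
#' @param x A `polar_d` object.
#' @param ... Unused.
#' @method tidy polar_d
#' @export
tidy.polar_d <- function(x, ...) {
  tibble(
    d_obs = x$d_obs, mean_d_random = x$mean_d_random,
    mean_d_brownian = x$mean_d_brownian, D = x$D,
    p_random = x$p_random, p_brownian = x$p_brownian,
    n_sims = x$n_sims, seed = x$seed
  )
}

#' @rdname phylo_d
#' @method glance polar_d
#' @export
glance.polar_d <- function(x, ...) tidy(x)

#' Plot the two D-statistic null distributions
#'
#' Density of the random-shuffle and Brownian-threshold d distributions with
#' the observed d as a vertical line.
#'
#' @param object A `polar_d` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot polar_d
#' @export
autoplot.polar_d <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(null = "random shuffle", d = object$null_random),
    tibble(null = "Brownian threshold", d = object$null_brownian)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, fill = .data$null)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = object$d_obs, colour = "firebrick",
      linewidth = 1) +
    ggplot2::labs(x = "Sum of sister-clade differences (d)", y = "Density",
      fill = NULL,
      title = sprintf("D = %.3f (1 = random, 0 = Brownian)", object$D)) +
    ggplot2::theme_minimal()
}
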