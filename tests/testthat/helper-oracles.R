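# Independent brute-force oracles used to pin down the fast implementations.
# These deliberately avoid the package's own code paths (and cophenetic()).

# the 4-tip unit tree used in many worked examples
unit_tree <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")

random_bifurcating_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# patristic distance by explicit path walking over the edge table
oracle_patristic <- function(tree) {
  n <- ape::Ntip(tree)
  edge_len <- function(a, b) {
    hit <- which(tree$edge[, 1] == a & tree$edge[, 2] == b |
                 tree$edge[, 1] == b & tree$edge[, 2] == a)
    tree$edge.length[hit]
  }
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      path <- ape::nodepath(tree, i, j)
      len <- sum(vapply(seq_len(length(path) - 1),
        function(k) edge_len(path[k], path[k + 1]), numeric(1)))
      d[i, j] <- d[j, i] <- len
    }
  }
  d
}

# double-loop MPD / MNTD over a named distance matrix
oracle_mpd <- function(members, d) {
  tot <- 0; np <- 0
  for (i in seq_along(members)) {
    for (j in seq_along(members)) {
      if (i < j) {
        tot <- tot + d[members[i], members[j]]
        np <- np + 1
      }
    }
  }
  tot / np
}

oracle_mntd <- function(members, d) {
  mins <- vapply(seq_along(members), function(i) {
    min(vapply(setdiff(seq_along(members), i),
      function(j) d[members[i], members[j]], numeric(1)))
  }, numeric(1))
  mean(mins)
}

# exhaustive same-size-subset null for SES: all C(n, k) subsets
oracle_null_values <- function(pool, k, d, metric = oracle_mpd) {
  apply(utils::combn(pool, k), 2, function(s) metric(s, d))
}

# exhaustive genus-cascade enumeration: all C(N, n_draw) genus draws
oracle_cascade <- function(genus_family, n_draw, events = NULL) {
  fams <- unique(genus_family)
  sizes <- table(factor(genus_family, levels = fams))
  draws <- utils::combn(length(genus_family), n_draw)
  per_draw <- apply(draws, 2, function(idx) {
    hit <- table(factor(genus_family[idx], levels = fams))
    extinct <- fams[hit == sizes]
    c(count = length(extinct),
      vapply(events, function(e) as.numeric(all(e %in% extinct)), numeric(1)))
  })
  if (is.null(dim(per_draw))) per_draw <- rbind(count = per_draw)
  list(
    expected_count = mean(per_draw["count", ]),
    sd_count = stats::sd(per_draw["count", ]),
    event_prob = if (!is.null(events)) {
      rowMeans(per_draw[names(events), , drop = FALSE])
    }
  )
}

# tiny synthetic calibrated tree shared by stochastic tests
synthetic_calibrated_tree <- function(n = 64, seed = 1) {
  sim <- simulate_tree(sim_config(seed = seed, n_families = n))
  calibrate_ages(sim$tree, sim$ages)
}
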