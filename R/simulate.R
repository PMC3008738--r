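#' Configuration for the synthetic polar-fauna generator
#'
#' Bundles the parameters of the synthetic data that every stage of the
#' analysis can be exercised on: a birth-death family tree with fossil
#' first-appearance ages, two overlapping regional faunas with right-skewed
#' genus richness, and an extinction regime per region. Defaults emulate the
#' empirical setting the package targets: a 67-family tree with polytomies,
#' two polar regions of 40 and 35 families sharing 27, one region with
#' phylogenetically clustered extinction at prevalence 0.5 (20 of 40
#' families) and one with random extinction at prevalence ~0.34 (12 of 35).
#'
#' @param seed Master seed.
#' @param n_families Number of tips of the global tree.
#' @param birth,death Speciation and extinction rates of the birth-death
#'   tree, per Myr.
#' @param age_range First-appearance age range (Ma): the tree root is scaled
#'   to the upper bound and tip first appearances are floored at the lower.
#' @param polytomy_tol Internal edges shorter than this fraction of the root
#'   age are collapsed into polytomies.
#' @param genus_p Geometric parameter for per-family genus richness
#'   (`rgeom(p) + 1`); small p gives the long right tail of many one-genus
#'   families that the cascade test depends on.
#' @param region_sizes Integer vector of length 2: families per region
#'   (default `NULL`: the 40/35-of-67 proportions scaled to `n_families`).
#' @param overlap Fraction of the smaller region's families shared between
#'   the regions.
#' @param regime Extinction regime per region: `"random"` or
#'   `"brownian_threshold"`, recycled to length 2.
#' @param prevalence Extinction prevalence (proportion of the region's
#'   families marked extinct), recycled to length 2.
#' @param noise_sd Noise added to the Brownian trait before thresholding,
#'   as a multiple of the trait's standard deviation (0 = pure Brownian
#'   clustering).
#' @param earlier,later Time-bin names used in the occurrence table.
#' @param regions Region names.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 67L,
                       birth = 0.06, death = 0.03,
                       age_range = c(5, 520),
                       polytomy_tol = 0.01,
                       genus_p = 0.4,
                       region_sizes = NULL,
                       overlap = 27 / 35,
                       regime = c("brownian_threshold", "random"),
                       prevalence = c(0.5, 12 / 35),
                       noise_sd = 0,
                       earlier = "Paleocene-Eocene", later = "Modern",
                       regions = c("RegionA", "RegionB")) {
  if (is.null(region_sizes)) {
    # keep the default 40/35-of-67 regional proportions at any tree size
    region_sizes <- pmax(2L, as.integer(round(n_families * c(40, 35) / 67)))
  }
  stopifnot(birth > 0, death >= 0, n_families >= 4,
    length(age_range) == 2, age_range[1] > 0, age_range[2] > age_range[1],
    genus_p > 0, genus_p < 1, overlap >= 0, overlap <= 1,
    length(region_sizes) == 2, all(region_sizes >= 2),
    sum(region_sizes) - round(overlap * min(region_sizes)) <= n_families)
  regime <- rep_len(match.arg(regime, c("random", "brownian_threshold"),
    several.ok = TRUE), 2L)
  prevalence <- rep_len(prevalence, 2L)
  stopifnot(all(prevalence > 0), all(prevalence < 1), noise_sd >= 0)
  structure(list(
    seed = as.integer(seed), n_families = as.integer(n_families),
    birth = birth, death = death, age_range = age_range,
    polytomy_tol = polytomy_tol, genus_p = genus_p,
    region_sizes = as.integer(region_sizes), overlap = overlap,
    regime = regime, prevalence = prevalence, noise_sd = noise_sd,
    earlier = earlier, later = later, regions = regions
  ), class = "sim_config")
}

#' Simulate a family tree with fossil first-appearance ages
#'
#' Draws a birth-death tree conditioned on the requested number of extant
#' tips, rescales it so the root sits at the top of the first-appearance age
#' range, collapses very short internal edges into polytomies, and draws each
#' family's first-appearance age uniformly within its subtending edge's age
#' interval (floored at the bottom of the age range), so that calibrating the
#' tree with [calibrate_ages()] is self-consistent: every calibrated node age
#' lies within the true node's age and no edge goes negative.
#'
#' @param config A [sim_config()].
#' @return A list with `tree` (the true [ape::phylo], Myr branch lengths)
#'   and `ages` (tibble `family`, `first_appearance_ma`).
#' @export
simulate_tree <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- NULL
  for (attempt in 1:25) {
    tree <- tryCatch(
      ape::rphylo(config$n_families, birth = config$birth, death = config$death),
      error = function(e) NULL)
    if (!is.null(tree)) break
  }
  if (is.null(tree)) {
    abort("Birth-death simulation failed after 25 attempts.",
      class = "polarphylo_simulation_error")
  }
  tree$tip.label <- sprintf("Fam%02d", seq_len(config$n_families))
  h <- ape::node.depth.edgelength(tree)
  root_age <- max(h[seq_len(ape::Ntip(tree))])
  tree$edge.length <- tree$edge.length * config$age_range[2] / root_age
  tree <- ape::di2multi(tree, tol = config$polytomy_tol * config$age_range[2])
  ages_all <- node_ages(tree)
  parent_age <- ages_all[tree$edge[, 1L]]
  tip_edge <- tree$edge[, 2L] <= ape::Ntip(tree)
  lo <- pmin(config$age_range[1], 0.5 * parent_age[tip_edge])
  fa <- runif(sum(tip_edge), min = lo, max = parent_age[tip_edge])
  ages <- tibble(
    family = tree$tip.label[tree$edge[tip_edge, 2L]],
    first_appearance_ma = fa
  )
  list(tree = tree, ages = ages[order(ages$family), ])
}

#' Simulate an extinction labeling on a set of families
#'
#' Marks `round(prevalence * n)` families extinct, either uniformly at
#' random or by thresholding a Brownian-motion trait evolved on the tree at
#' the rank giving exactly that prevalence (the phylogenetically clustered
#' regime). Gaussian noise of `noise_sd` trait standard deviations is added
#' before thresholding, so clustering degrades gracefully from perfect
#' (noise 0) to none (large noise).
#'
#' @param tree Calibrated [ape::phylo] containing all `families`.
#' @param families Families at risk (tips of `tree`).
#' @param prevalence Proportion marked extinct (the count is clamped to
#'   `[1, n - 1]`).
#' @param regime `"random"` or `"brownian_threshold"`.
#' @param noise_sd See [sim_config()].
#' @param seed Optional integer seed.
#' @return A labeling tibble (`family`, `extinct`).
#' @export
simulate_extinction <- function(tree, families, prevalence,
                                regime = c("random", "brownian_threshold"),
                                noise_sd = 0, seed = NULL) {
  regime <- match.arg(regime)
  families <- unique(as.character(families))
  stopifnot(all(families %in% tree$tip.label), length(families) >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- length(families)
  k <- min(max(round_half_up(prevalence * n), 1L), n - 1L)
  extinct <- if (regime == "random") {
    families[sample.int(n, k)]
  } else {
    sub <- prune_to(tree, families)
    z <- drop(simulate_brownian_tips(sub, 1L))
    if (noise_sd > 0) z <- z + rnorm(n, sd = noise_sd * stats::sd(z))
    sub$tip.label[rank(-z, ties.method = "random") <= k]
  }
  tibble(family = families, extinct = families %in% extinct)
}

#' Simulate two-region occurrence tables with an extinction event
#'
#' Builds the earlier-bin faunas of two regions sharing the configured
#' fraction of families, assigns geometric genus richness and lognormal
#' shell sizes, then applies the per-region extinction regime: the later bin
#' contains each region's surviving families (with all their genera).
#'
#' @param tree The (true or calibrated) [ape::phylo] from [simulate_tree()];
#'   branch lengths are required for the Brownian regime.
#' @param config A [sim_config()].
#' @return An occurrence tibble with columns `region`, `time_bin`, `family`,
#'   `genus`, `species_count`, `length_mm`, `height_mm`.
#' @export
simulate_faunas <- function(tree, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"), ape::Ntip(tree) >= 4)
  set.seed(config$seed + 1L)
  tips <- tree$tip.label
  n_shared <- round_half_up(config$overlap * min(config$region_sizes))
  shared <- sample(tips, n_shared)
  rest <- setdiff(tips, shared)
  uniq_n <- config$region_sizes - n_shared
  uniqA <- sample(rest, uniq_n[1])
  uniqB <- sample(setdiff(rest, uniqA), uniq_n[2])
  region_fams <- list(c(shared, uniqA), c(shared, uniqB))
  # one global genus roster per family, shared across regions
  all_fams <- unique(unlist(region_fams))
  n_genera <- rgeom(length(all_fams), config$genus_p) + 1L
  roster <- stats::setNames(lapply(seq_along(all_fams), function(i) {
    sprintf("%s_g%02d", all_fams[i], seq_len(n_genera[i]))
  }), all_fams)
  rows <- list()
  for (r in 1:2) {
    fams <- region_fams[[r]]
    lab <- simulate_extinction(tree, fams, config$prevalence[r],
      regime = config$regime[r], noise_sd = config$noise_sd)
    survivors <- lab$family[!lab$extinct]
    for (bin_fams in list(c(config$earlier, list(fams)),
                          c(config$later, list(survivors)))) {
      bin <- bin_fams[[1]]
      for (f in bin_fams[[2]]) {
        g <- roster[[f]]
        len <- rlnorm(length(g), meanlog = log(20), sdlog = 0.6)
        rows[[length(rows) + 1L]] <- tibble(
          region = config$regions[r], time_bin = bin, family = f, genus = g,
          species_count = rpois(length(g), 1) + 1L,
          length_mm = len,
          height_mm = len * runif(length(g), 0.4, 1)
        )
      }
    }
  }
  as_occurrence_table(dplyr::bind_rows(rows), source = "simulated fauna")
}

#' Simulate a complete synthetic polar dataset
#'
#' Convenience wrapper: tree + first-appearance ages + two-region occurrence
#' table, ready for the full analysis pipeline.
#'
#' @param config A [sim_config()].
#' @return A list with `tree` (true tree), `ages`, `calibrated` (the tree
#'   calibrated from the simulated first appearances), `occurrences` and
#'   `config`.
#' @export
simulate_polar_dataset <- function(config = sim_config()) {
  sim <- simulate_tree(config)
  cal <- calibrate_ages(sim$tree, sim$ages)
  occ <- simulate_faunas(cal, config)
  list(tree = sim$tree, ages = sim$ages, calibrated = cal,
    occurrences = occ, config = config)
}
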