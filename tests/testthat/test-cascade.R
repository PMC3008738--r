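test_that("Lyellian percentages carry exact binomial intervals", {
  full <- lyellian(10, 10)
  expect_equal(full$percent_surviving, 100)
  expect_equal(full$ci_high, 100)
  expect_equal(full$ci_low, 69.15, tolerance = 0.01)

  none <- lyellian(0, 10)
  expect_equal(none$percent_surviving, 0)
  expect_equal(none$ci_low, 0)
  expect_equal(none$ci_high, 30.85, tolerance = 0.01)

  half <- lyellian(5, 10)
  expect_equal(half$percent_surviving, 50)
  expect_equal(half$ci_low, 18.71, tolerance = 0.01)
  expect_equal(half$ci_high, 81.29, tolerance = 0.01)

  # independent oracle: stats::binom.test implements the same exact interval
  for (case in list(c(3, 17), c(12, 40), c(87, 100))) {
    mine <- lyellian(case[1], case[2])
    ref <- binom.test(case[1], case[2])$conf.int * 100
    expect_equal(c(mine$ci_low, mine$ci_high), as.numeric(ref),
      tolerance = 1e-8)
  }
  expect_error(lyellian(1, 0), class = "polarphylo_validation_error")
  expect_error(lyellian(5, 4), class = "polarphylo_validation_error")
})

toy_fauna <- function(genus_family, region = "R", bin = "B") {
  tibble::tibble(region = region, time_bin = bin,
    family = genus_family, genus = paste0("g", seq_along(genus_family)))
}

toy_tree <- function(families) {
  ages <- stats::setNames(seq(50, by = 25, length.out = length(families)),
    families)
  calibrate_ages(parse_newick(paste0("(", paste(families, collapse = ","), ");")),
    ages)
}

test_that("cascade null matches exhaustive draw enumeration on toy faunas", {
  # F1 = {g1}, F2 = {g2, g3, g4}; draw 2 of 4 (survival 0.5):
  # F1 extinct in 3 of 6 draws, F2 never -> expected 0.5 extinct families
  gf <- c("F1", "F2", "F2", "F2")
  occ <- toy_fauna(gf)
  tr <- calibrate_ages(parse_newick("(F1,F2);"), c(F1 = 10, F2 = 10))
  res <- suppressMessages(cascade_null(occ, tr, "R", "B",
    survival_fraction = 0.5, n_reps = 8000, seed = 1,
    events = list(F1_gone = "F1")))
  oracle <- oracle_cascade(gf, 2, events = list(F1_gone = "F1"))
  expect_equal(oracle$expected_count, 0.5)
  mc_se <- oracle$sd_count / sqrt(8000)
  expect_lt(abs(res$summary$mean_extinct_families - oracle$expected_count),
    3 * mc_se)
  expect_lt(abs(res$event_freq$frequency - oracle$event_prob), 3 * mc_se)

  # larger fauna, still exhaustively enumerable (12 genera, C(12,6) draws)
  gf2 <- rep(paste0("F", 1:5), c(1, 1, 2, 3, 5))
  occ2 <- toy_fauna(gf2)
  tr2 <- toy_tree(paste0("F", 1:5))
  ev <- list(both_singletons = c("F1", "F2"), F3_gone = "F3")
  res2 <- suppressMessages(cascade_null(occ2, tr2, "R", "B",
    survival_fraction = 0.5, n_reps = 8000, seed = 2, events = ev))
  oracle2 <- oracle_cascade(gf2, 6, events = ev)
  expect_lt(abs(res2$summary$mean_extinct_families - oracle2$expected_count),
    3 * oracle2$sd_count / sqrt(8000))
  for (e in names(ev)) {
    p <- oracle2$event_prob[e]
    se <- sqrt(p * (1 - p) / 8000)
    expect_lt(abs(res2$event_freq$frequency[res2$event_freq$event == e] - p),
      3 * se + 1e-9)
  }
})

test_that("survival extremes and event closed forms behave", {
  gf <- rep(paste0("F", 1:4), c(1, 2, 2, 3))
  occ <- toy_fauna(gf)
  tr <- toy_tree(paste0("F", 1:4))
  all_live <- cascade_null(occ, tr, "R", "B", 1.0, n_reps = 50, seed = 3)
  expect_true(all(all_live$reps$n_extinct_families == 0))
  all_die <- cascade_null(occ, tr, "R", "B", 0.0, n_reps = 50, seed = 4)
  expect_true(all(all_die$reps$n_extinct_families == 4))

  # one-genus family: extinction probability is hypergeometric = k/N
  res <- suppressMessages(cascade_null(occ, tr, "R", "B", 0.625,
    n_reps = 10000, seed = 5, events = list(F1 = "F1")))
  expect_equal(res$summary$n_genera_drawn, 3) # round((1-0.625)*8)
  p <- 3 / 8
  expect_lt(abs(res$event_freq$frequency - p), 3 * sqrt(p * (1 - p) / 10000))
})

test_that("lower survival stochastically increases family extinction", {
  sim <- simulate_polar_dataset(sim_config(seed = 41, n_families = 20,
    region_sizes = c(12L, 10L), overlap = 0.5))
  means <- vapply(c(0.8, 0.5, 0.2), function(s) {
    suppressMessages(cascade_null(sim$occurrences, sim$calibrated, "RegionA",
      "Paleocene-Eocene", s, n_reps = 400, seed = 42))$summary$mean_extinct_families
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("cascade validates its inputs", {
  occ <- toy_fauna(c("F1", "F2"))
  tr <- calibrate_ages(parse_newick("(F1,F2);"), c(F1 = 10, F2 = 10))
  expect_error(cascade_null(occ, tr, "R", "B", 1.2, n_reps = 5),
    class = "polarphylo_validation_error")
  occ_bad <- occ
  occ_bad$genus[1] <- NA
  expect_error(cascade_null(occ_bad, tr, "R", "B", 0.5, n_reps = 5),
    class = "polarphylo_validation_error")
})

test_that("exact binomial intervals achieve nominal coverage", {
  set.seed(911)
  for (n in c(15, 60)) {
    for (p in c(0.2, 0.7)) {
      x <- rbinom(4000, n, p)
      ci <- lyellian(x, rep(n, 4000))
      cover <- mean(ci$ci_low <= 100 * p & 100 * p <= ci$ci_high)
      expect_gte(cover, 0.94)
    }
  }
})
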