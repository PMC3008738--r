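test_that("MPD and MNTD match hand values and the pair-enumeration oracle", {
  d <- patristic_matrix(unit_tree())
  expect_equal(mpd(c("A", "B"), d), 2)
  expect_equal(mntd(c("A", "B"), d), 2)
  expect_equal(mpd(c("A", "B", "C"), d), (2 + 4 + 4) / 3)
  expect_equal(mntd(c("A", "B", "C"), d), (2 + 2 + 4) / 3)
  expect_error(mpd("A", d), class = "polarphylo_undefined_error")
  expect_error(mpd(c("A", "Z"), d), class = "polarphylo_key_error")

  for (seed in 1:20) {
    tr <- random_bifurcating_tree(10, seed)
    dm <- patristic_matrix(tr)
    members <- sample(tr$tip.label, sample(2:10, 1))
    expect_equal(mpd(members, dm), oracle_mpd(members, dm), tolerance = 1e-12)
    expect_equal(mntd(members, dm), oracle_mntd(members, dm), tolerance = 1e-12)
    expect_lte(mntd(members, dm), mpd(members, dm) + 1e-12)
  }
})

test_that("MPD and MNTD agree with picante on a fixed community", {
  tr <- random_bifurcating_tree(12, 42)
  dm <- patristic_matrix(tr)
  members <- tr$tip.label[c(1, 3, 5, 7, 9)]
  comm <- matrix(as.numeric(tr$tip.label %in% members), nrow = 1,
    dimnames = list("site", tr$tip.label))
  expect_equal(mpd(members, dm),
    unname(picante::mpd(comm, dm)), tolerance = 1e-10)
  expect_equal(mntd(members, dm),
    unname(picante::mntd(comm, dm)), tolerance = 1e-10)
})

test_that("SES converges to the exhaustive subset-enumeration null", {
  tu <- unit_tree()
  d <- patristic_matrix(tu)
  # all C(4,2) = 6 subsets: MPD values 2,2,4,4,4,4
  null_vals <- oracle_null_values(tu$tip.label, 2, d)
  expect_setequal(round(sort(null_vals), 10), c(2, 2, 4, 4, 4, 4))
  expect_equal(mean(null_vals), 10 / 3)
  expect_equal(sd(null_vals), 1.0327956, tolerance = 1e-6)
  # enumeration SES with the sample sd of the 6 values
  expect_equal((2 - mean(null_vals)) / sd(null_vals), -1.2909944,
    tolerance = 1e-6)

  lab <- tibble::tibble(family = tu$tip.label,
    extinct = tu$tip.label %in% c("A", "B"))
  res <- ses_phylo(lab, tu, metric = "mpd", n_rand = 20000, seed = 5)
  expect_equal(res$observed, 2)
  expect_equal(res$null_mean, mean(null_vals), tolerance = 0.02)
  # Monte-Carlo sd converges to the population sd of the 6-value null
  pop_sd <- sqrt(mean((null_vals - mean(null_vals))^2))
  expect_equal(res$null_sd, pop_sd, tolerance = 0.02)
  expect_equal(res$ses, (2 - mean(null_vals)) / pop_sd, tolerance = 0.05)
  # p_low: 2 of 6 null values <= observed, with the +1/+1 correction
  expect_equal(res$p_low, 1 / 3, tolerance = 0.02)
})

test_that("SES is seeded-reproducible and respects its preconditions", {
  cal <- synthetic_calibrated_tree(16, seed = 3)
  lab <- simulate_extinction(cal, cal$tip.label, 0.4, "random", seed = 9)
  a <- ses_phylo(lab, cal, n_rand = 500, seed = 7)
  b <- ses_phylo(lab, cal, n_rand = 500, seed = 7)
  expect_identical(tidy(a), tidy(b))

  one <- lab
  one$extinct <- c(TRUE, rep(FALSE, nrow(one) - 1))
  expect_error(ses_phylo(one, cal, n_rand = 10),
    class = "polarphylo_undefined_error")
  all_ext <- lab
  all_ext$extinct <- TRUE
  expect_error(ses_phylo(all_ext, cal, n_rand = 10),
    class = "polarphylo_degenerate_error")
})

test_that("SES ignores tree tips absent from the labeling", {
  cal <- synthetic_calibrated_tree(20, seed = 11)
  pool <- cal$tip.label[1:12]
  lab <- tibble::tibble(family = pool, extinct = seq_along(pool) <= 5)
  on_full <- ses_phylo(lab, cal, metric = "mpd", n_rand = 2000, seed = 13)
  on_pruned <- ses_phylo(lab, prune_to(cal, pool), metric = "mpd",
    n_rand = 2000, seed = 13)
  expect_equal(tidy(on_full), tidy(on_pruned))
})

test_that("random extinct sets give SES centred on zero", {
  cal <- synthetic_calibrated_tree(32, seed = 21)
  set.seed(77)
  ses_vals <- vapply(1:150, function(i) {
    lab <- tibble::tibble(family = cal$tip.label,
      extinct = seq_len(32) %in% sample.int(32, 10))
    ses_phylo(lab, cal, metric = "mpd", n_rand = 200)$ses
  }, numeric(1))
  expect_lt(abs(mean(ses_vals)), 3 * sd(ses_vals) / sqrt(length(ses_vals)) + 0.1)
})
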