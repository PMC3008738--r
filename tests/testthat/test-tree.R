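test_that("newick parsing handles lengths, polytomies and errors", {
  tr <- parse_newick("(A,B);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_null(tr$edge.length)

  tr4 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(ape::Ntip(tr4), 4)
  expect_equal(tr4$Nnode, 3) # two cherries plus the root
  expect_equal(sum(tr4$edge.length), 6)

  poly <- parse_newick("((A,B,C),D);")
  expect_equal(ape::Ntip(poly), 4)
  expect_equal(poly$Nnode, 2) # 3-way polytomy kept as-is

  expect_error(parse_newick("((A,B);"), "unclosed", class = "polarphylo_parse_error")
  expect_error(parse_newick("(A,B))();"), "character 6", class = "polarphylo_parse_error")
  expect_error(parse_newick("(A,B)"), "';'", class = "polarphylo_parse_error")
  expect_error(parse_newick("(A,A);"), "Duplicate",
    class = "polarphylo_validation_error")
})

test_that("trees round-trip through write/parse", {
  for (seed in 1:10) {
    tr <- random_bifurcating_tree(8, seed)
    path <- withr::local_tempfile(fileext = ".nwk")
    write_family_tree(tr, path)
    back <- read_family_tree(path)
    expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE))
  }
})

test_that("fossil calibration follows the oldest-descendant rule", {
  tr <- parse_newick("((A,B),C);")
  cal <- calibrate_ages(tr, c(A = 100, B = 50, C = 200))
  ages <- node_ages(cal)
  n <- ape::Ntip(cal)
  expect_equal(unname(ages[seq_len(n)]), c(0, 0, 0))
  root <- n + 1L
  expect_equal(unname(ages[root]), 200)
  expect_equal(sort(unname(ages[-seq_len(n)])), c(100, 200))
  expect_equal(total_branch_length(cal), 500)

  cherry <- calibrate_ages(parse_newick("(A,B);"), c(A = 10, B = 10))
  expect_equal(total_branch_length(cherry), 20)

  expect_error(calibrate_ages(tr, c(A = 100, B = 50)), "C",
    class = "polarphylo_calibration_error")
})

test_that("calibration is idempotent, ultrametric, and monotone in input ages", {
  for (seed in 1:20) {
    tr <- random_bifurcating_tree(12, seed)
    ages <- stats::setNames(runif(12, 10, 400), tr$tip.label)
    cal <- calibrate_ages(tr, ages)
    # ultrametric: all root-to-tip depths equal
    h <- ape::node.depth.edgelength(cal)
    depths <- h[seq_len(12)]
    expect_lt(diff(range(depths)), 1e-9)
    # idempotent: recalibrating with the same table changes nothing
    cal2 <- calibrate_ages(cal, ages)
    expect_equal(cal2$edge.length, cal$edge.length)
    # monotone: raising one family's age never decreases any node age
    bump <- sample(names(ages), 1)
    ages2 <- ages
    ages2[bump] <- ages2[bump] * 2
    expect_true(all(node_ages(calibrate_ages(tr, ages2)) >=
      node_ages(cal) - 1e-9))
  }
})

test_that("total branch length requires calibration", {
  expect_error(total_branch_length(parse_newick("((A,B),C);")),
    class = "polarphylo_uncalibrated_error")
})

test_that("node counts cover balanced, star and pruned trees", {
  expect_equal(node_count(parse_newick("((A,B),(C,D));")), 7)
  expect_equal(node_count(parse_newick("(A,B,C,D);")), 5)
  for (seed in 1:10) {
    tr <- random_bifurcating_tree(10, seed)
    keep <- sample(tr$tip.label, 5)
    pruned <- prune_to(tr, keep)
    # brute-force recount on the pruned structure
    expect_equal(node_count(pruned), ape::Ntip(pruned) + pruned$Nnode)
    expect_equal(ape::Ntip(pruned), 5)
  }
})

test_that("patristic distances match a path-walking oracle", {
  tu <- unit_tree()
  d <- patristic_matrix(tu)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))

  for (seed in 1:10) {
    tr <- random_bifurcating_tree(10, seed)
    expect_equal(patristic_matrix(tr), oracle_patristic(tr), tolerance = 1e-12)
  }

  # ultrametric identity d(i, j) = 2 * age(MRCA)
  cal <- calibrate_ages(parse_newick("((A,B),C);"), c(A = 100, B = 50, C = 200))
  dc <- patristic_matrix(cal)
  expect_equal(dc["A", "B"], 200)
  expect_equal(dc["A", "C"], 400)
})

test_that("pruning drops the root stem and preserves distances", {
  cal <- calibrate_ages(parse_newick("((A,B),C);"), c(A = 100, B = 50, C = 200))
  kept <- prune_to(cal, c("A", "B"))
  expect_equal(total_branch_length(kept), 200) # stem above MRCA(A,B) dropped

  expect_true(ape::all.equal.phylo(prune_to(cal, c("A", "B", "C")), cal))
  expect_error(prune_to(cal, character()), class = "polarphylo_validation_error")
  expect_error(prune_to(cal, "Z"), class = "polarphylo_key_error")

  stub <- prune_to(cal, "A")
  expect_equal(ape::Ntip(stub), 1)
  expect_equal(total_branch_length(stub), 0)

  for (seed in 1:20) {
    tr <- random_bifurcating_tree(10, seed)
    d_full <- patristic_matrix(tr)
    keep <- sample(tr$tip.label, sample(2:8, 1))
    pruned <- prune_to(tr, keep)
    expect_equal(patristic_matrix(pruned)[keep, keep], d_full[keep, keep],
      tolerance = 1e-12)
    expect_lte(total_branch_length(pruned), sum(tr$edge.length) + 1e-12)
  }
})

test_that("regional trees report families missing from the global tree", {
  cal <- calibrate_ages(parse_newick("((A,B),C);"), c(A = 100, B = 50, C = 200))
  expect_warning(rt <- regional_tree(cal, c("A", "B", "Nope")), "Nope")
  expect_setequal(rt$tip.label, c("A", "B"))
  expect_error(suppressWarnings(regional_tree(cal, "Nope")),
    class = "polarphylo_validation_error")
  expect_error(suppressWarnings(regional_tree(cal, c("A", "Nope"))),
    class = "polarphylo_validation_error")
  expect_equal(ape::Ntip(suppressWarnings(
    regional_tree(cal, c("A", "Nope"), allow_single = TRUE))), 1)
})
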