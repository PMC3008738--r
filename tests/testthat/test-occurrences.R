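toy_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("occurrence CSVs are parsed, trimmed and deduplicated", {
  path <- toy_csv(c(
    "region,time_bin,family,genus,species_count",
    "Antarctic,Paleocene-Eocene,Veneridae ,Venus,2",
    "Antarctic,Paleocene-Eocene,Veneridae,Venus,3",
    "Antarctic,Paleocene-Eocene,Mactridae,Mactra,1",
    "Arctic,Modern,Mytilidae,Mytilus,4"
  ))
  occ <- read_occurrences(path)
  expect_equal(nrow(occ), 3) # duplicate (region,bin,family,genus) collapsed
  ven <- occ[occ$family == "Veneridae", ]
  expect_equal(ven$species_count, 5) # counts summed on collapse

  empty <- read_occurrences(toy_csv("region,time_bin,family"))
  expect_equal(nrow(empty), 0)

  expect_error(read_occurrences(toy_csv(c("region,family", "a,b"))),
    "time_bin", class = "polarphylo_schema_error")
  expect_error(read_occurrences(toy_csv(c(
    "region,time_bin,family,species_count", "a,b,c,not_a_number"))),
    "row", class = "polarphylo_row_error")
})

test_that("family aliases are applied before indexing", {
  occ <- as_occurrence_table(
    tibble::tibble(region = "R", time_bin = "B",
      family = c("OldName", "Veneridae")),
    aliases = tibble::tibble(old_name = "OldName", canonical_name = "Veneridae"))
  expect_equal(nrow(occ), 1)
  expect_equal(occ$family, "Veneridae")
})

test_that("families_in is order-invariant and quiet-empty on unknown bins", {
  occ <- as_occurrence_table(tibble::tibble(
    region = "R", time_bin = "B",
    family = c("Veneridae", "Mactridae", "Veneridae")))
  expect_setequal(families_in(occ, "R", "B"), c("Veneridae", "Mactridae"))
  shuffled <- as_occurrence_table(occ[c(2, 1), ])
  expect_equal(families_in(shuffled, "R", "B"), families_in(occ, "R", "B"))
  expect_message(out <- families_in(occ, "R", "nope"), "No records")
  expect_length(out, 0)
})

test_that("extinction labeling is the exact earlier-bin partition", {
  occ <- as_occurrence_table(tibble::tibble(
    region = "R",
    time_bin = c("early", "early", "early", "late"),
    family = c("F1", "F2", "F3", "F2")))
  lab <- label_extinctions(occ, "R", "early", "late")
  expect_setequal(lab$family[lab$extinct], c("F1", "F3"))
  expect_setequal(lab$family[!lab$extinct], "F2")
  # partition: extinct + survivor covers the earlier bin exactly, disjointly
  expect_setequal(lab$family, families_in(occ, "R", "early"))
  expect_equal(anyDuplicated(lab$family), 0L)

  same <- as_occurrence_table(tibble::tibble(
    region = "R", time_bin = rep(c("early", "late"), each = 2),
    family = rep(c("F1", "F2"), 2)))
  expect_equal(sum(label_extinctions(same, "R", "early", "late")$extinct), 0)

  expect_error(label_extinctions(occ, "R", "nope", "late"),
    class = "polarphylo_validation_error")
})

test_that("body size is log2 of the geometric shell dimension", {
  expect_equal(body_size(16, 4), 3)
  expect_equal(body_size(1, 1), 0)
  expect_equal(body_size(2, 8), 2)
  expect_equal(body_size(3, 7), body_size(7, 3)) # symmetric
  expect_true(body_size(10, 5) < body_size(12, 5)) # increasing in each arg
  expect_true(body_size(10, 5) < body_size(10, 6))
  expect_error(body_size(0, 5), class = "polarphylo_domain_error")
  expect_error(body_size(5, -1), class = "polarphylo_domain_error")
})

test_that("genus-level access fails fast on missing genera", {
  occ <- tibble::tibble(region = "R", time_bin = "B",
    family = c("F1", "F2"), genus = c("g1", NA))
  expect_error(genera_in(occ, "R", "B"), class = "polarphylo_validation_error")
  occ$genus <- c("g1", "g2")
  expect_equal(nrow(genera_in(occ, "R", "B")), 2)
})
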