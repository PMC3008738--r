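#' Parse a newick string into a family-level tree
#'
#' Reads a single rooted (possibly polytomous) tree whose tips are family
#' names. Branch lengths, when present, are interpreted as millions of years
#' (Myr). Internal node labels are preserved on round-trip but ignored by all
#' computations.
#'
#' @param text A newick string (single tree, terminated by `;`).
#' @return An [ape::phylo] object.
#' @seealso [read_family_tree()] to read from a file, [write_family_tree()].
#' @examples
#' parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' parse_newick("((A,B,C),D);") # polytomies are first-class
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    abort("Malformed newick string: parser failed.", class = "polarphylo_parse_error")
  }
  validate_family_tree(tree)
  tree
}

# cheap structural scan so parse errors can name a character offset,
# which ape::read.tree does not report
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("Malformed newick: unmatched ')' at character %d.", i),
          class = "polarphylo_parse_error")
      }
    }
  }
  if (depth != 0L) {
    abort(sprintf("Malformed newick: %d unclosed '(' at end of string.", depth),
      class = "polarphylo_parse_error")
  }
  if (!grepl(";", text, fixed = TRUE)) {
    abort(sprintf("Malformed newick: missing terminating ';' (string length %d).",
      nchar(text)), class = "polarphylo_parse_error")
  }
  invisible(TRUE)
}

validate_family_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("Duplicate tip labels: ", paste(dup, collapse = ", ")),
      class = "polarphylo_validation_error")
  }
  if (any(!nzchar(tree$tip.label))) {
    abort("Empty tip labels are not allowed.", class = "polarphylo_validation_error")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < -1e-9)) {
    abort("Negative branch lengths are not allowed.",
      class = "polarphylo_validation_error")
  }
  invisible(tree)
}

#' Read / write a family-level tree in newick format
#'
#' @param path Path to a newick file containing a single tree.
#' @return `read_family_tree()` returns an [ape::phylo]; `write_family_tree()`
#'   returns `path` invisibly.
#' @export
read_family_tree <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' @rdname read_family_tree
#' @param tree An [ape::phylo] object.
#' @export
write_family_tree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a table of family first-appearance ages
#'
#' A two-column CSV with header `family,first_appearance_ma`; ages are Ma
#' before present and must be positive.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `family` and `first_appearance_ma`.
#' @export
read_age_table <- function(path) {
  ages <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("family", "first_appearance_ma")
  if (!all(req %in% names(ages))) {
    abort(paste0("Age table must have columns: ", paste(req, collapse = ", ")),
      class = "polarphylo_schema_error")
  }
  ages <- dplyr::select(ages, dplyr::all_of(req))
  if (any(!is.finite(ages$first_appearance_ma)) || any(ages$first_appearance_ma <= 0)) {
    abort("First-appearance ages must be finite and > 0 Ma.",
      class = "polarphylo_validation_error")
  }
  tibble::as_tibble(ages)
}

# accepts a tibble (family, first_appearance_ma) or a named numeric vector
as_age_vector <- function(ages) {
  if (is.data.frame(ages)) {
    if (!all(c("family", "first_appearance_ma") %in% names(ages))) {
      abort("Age table must have columns family, first_appearance_ma.",
        class = "polarphylo_schema_error")
    }
    out <- stats::setNames(as.numeric(ages$first_appearance_ma), ages$family)
  } else if (is.numeric(ages) && !is.null(names(ages))) {
    out <- ages
  } else {
    abort("`ages` must be a data frame or a named numeric vector.")
  }
  if (anyDuplicated(names(out))) {
    abort("Duplicate family names in the age table.",
      class = "polarphylo_validation_error")
  }
  out
}

#' Calibrate node ages from family first-appearance dates
#'
#' Scales a family-level topology so that every internal node is assigned the
#' age of the oldest family it subtends (the fossil-calibration rule for
#' composite supertrees whose tips carry first-appearance ages). Tips are set
#' to `tip_age` (0 Ma = Recent by default), so the calibrated tree is
#' ultrametric and each edge length, in Myr, is `age(parent) - age(child)`.
#'
#' The rule is idempotent: calibrating an already-calibrated tree with the
#' same age table reproduces it exactly.
#'
#' @param tree An [ape::phylo] with tips named by family.
#' @param ages A tibble (`family`, `first_appearance_ma`) or a named numeric
#'   vector of first-appearance ages in Ma; every tip must be present.
#' @param tip_age Age assigned to the tips, Ma (default 0 = Recent).
#' @return The tree with calibrated `edge.length` (Myr).
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' cal <- calibrate_ages(tr, c(A = 100, B = 50, C = 200))
#' total_branch_length(cal) # 500 Myr
#' @export
calibrate_ages <- function(tree, ages, tip_age = 0) {
  stopifnot(inherits(tree, "phylo"))
  fa <- as_age_vector(ages)
  missing <- setdiff(tree$tip.label, names(fa))
  if (length(missing)) {
    abort(paste0("Families missing from the age table: ",
      paste(missing, collapse = ", ")), class = "polarphylo_calibration_error")
  }
  if (any(fa[tree$tip.label] <= 0)) {
    abort("First-appearance ages must be > 0 Ma.",
      class = "polarphylo_validation_error")
  }
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  age <- numeric(n + m)
  age[seq_len(n)] <- fa[tree$tip.label]
  # tips-to-root max propagation: each node takes the oldest descendant tip
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    p <- po[k, 1L]
    if (age[p] < age[po[k, 2L]]) age[p] <- age[po[k, 2L]]
  }
  age[seq_len(n)] <- tip_age
  if (any(age[tree$edge[, 1L]] < age[tree$edge[, 2L]] - 1e-12)) {
    abort("tip_age exceeds a calibrated node age; edges would be negative.",
      class = "polarphylo_calibration_error")
  }
  tree$edge.length <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  tree
}

#' Node ages of an ultrametric calibrated tree
#'
#' Recovers node ages (Ma) from edge lengths, assuming all tips sit at
#' `tip_age`.
#'
#' @inheritParams calibrate_ages
#' @return Numeric vector of ages, indexed by ape node number (tips first).
#' @export
node_ages <- function(tree, tip_age = 0) {
  assert_calibrated(tree)
  h <- ape::node.depth.edgelength(tree)
  tip_age + max(h[seq_len(ape::Ntip(tree))]) - h
}

assert_calibrated <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    abort("Tree has no branch lengths; calibrate it first (see calibrate_ages()).",
      class = "polarphylo_uncalibrated_error")
  }
  invisible(tree)
}

#' Total branch length of a calibrated tree, in Myr
#'
#' The sum over all edges of `age(parent) - age(child)`: the tree-wide
#' analogue of Faith's phylogenetic diversity with families as terminal taxa.
#' The root stem (`root.edge`), if any, is excluded.
#'
#' @inheritParams node_ages
#' @return Total branch length (Myr).
#' @export
total_branch_length <- function(tree) {
  assert_calibrated(tree)
  sum(tree$edge.length)
}

#' Node count of a tree (tips + internal nodes)
#'
#' Counts tips plus internal nodes after suppressing unifurcations, the
#' node-based companion to [total_branch_length()] for phylogenetic-diversity
#' accounting.
#'
#' @param tree An [ape::phylo].
#' @return Integer count.
#' @export
node_count <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) == 1L) return(1L)
  tree <- ape::collapse.singles(tree)
  ape::Ntip(tree) + tree$Nnode
}

#' Patristic distance matrix between families
#'
#' Pairwise path-length distances (Myr) between all tips of a calibrated
#' tree. On an ultrametric tree `d(i, j) = 2 * age(MRCA(i, j))`.
#'
#' @inheritParams node_ages
#' @return A symmetric numeric matrix with family names as dimnames.
#' @export
patristic_matrix <- function(tree) {
  assert_calibrated(tree)
  stats::cophenetic(tree)
}

#' Prune a tree to a set of families
#'
#' Retains only the named tips, suppresses the resulting unifurcations
#' (merging their edge lengths) and drops the root stem above the new most
#' recent common ancestor, so that branches with no surviving descendants do
#' not count towards retained length. Patristic distances among kept tips are
#' unchanged.
#'
#' @param tree An [ape::phylo].
#' @param keep Character vector of tip labels to keep (subset of the tips,
#'   at least one).
#' @return The pruned [ape::phylo]. A single kept tip yields a degenerate
#'   one-tip stub of total length zero.
#' @export
prune_to <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(as.character(keep))
  if (length(keep) == 0L) {
    abort("`keep` must contain at least one family.",
      class = "polarphylo_validation_error")
  }
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    abort(paste0("Families not on the tree: ", paste(unknown, collapse = ", ")),
      class = "polarphylo_key_error")
  }
  if (length(keep) == 1L) {
    return(single_tip_stub(keep))
  }
  out <- ape::keep.tip(tree, keep)
  out$root.edge <- NULL # stem above the surviving MRCA is not retained
  out
}

single_tip_stub <- function(label) {
  structure(
    list(
      edge = matrix(c(2L, 1L), nrow = 1L),
      tip.label = label,
      edge.length = 0,
      Nnode = 1L
    ),
    class = "phylo", order = "cladewise"
  )
}

#' Regional subtree of the global family tree
#'
#' Prunes the global calibrated tree to the families recorded in a region.
#' Families absent from the tree are reported with a warning, never silently
#' dropped, since missing tips bias diversity totals downward.
#'
#' @param global The global calibrated [ape::phylo].
#' @param families Character vector of family names present in the region.
#' @param allow_single Permit a degenerate one-tip result (default `FALSE`,
#'   since distance-based metrics are undefined on it).
#' @return The regional [ape::phylo].
#' @export
regional_tree <- function(global, families, allow_single = FALSE) {
  stopifnot(inherits(global, "phylo"))
  families <- unique(as.character(families))
  present <- intersect(families, global$tip.label)
  absent <- setdiff(families, global$tip.label)
  if (length(absent)) {
    warn(paste0("Families absent from the global tree (dropped from the regional tree): ",
      paste(absent, collapse = ", ")))
  }
  if (length(present) == 0L) {
    abort("No regional family occurs on the global tree.",
      class = "polarphylo_validation_error")
  }
  if (length(present) == 1L && !allow_single) {
    abort("Only one regional family is on the tree; set allow_single = TRUE for a one-tip stub.",
      class = "polarphylo_validation_error")
  }
  prune_to(global, present)
}
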