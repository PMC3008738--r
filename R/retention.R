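#' Phylogenetic-diversity retention through time
#'
#' Quantifies how much of a regional fauna's evolutionary history survives
#' from an earlier to a later time bin, in two currencies: total branch
#' length (Myr) and node count of the regional subtrees. By default the
#' later tree is the earlier tree pruned to its survivors
#' (`mode = "survivors"`), so `later` must be a subset of `earlier`; faunal
#' additions in the later bin are excluded because later-bin additions are
#' minimum estimates only. `mode = "full_list"` instead builds the later tree
#' from the later faunal list as given (persisting or newly recorded sister
#' families then contribute retained history).
#'
#' @param global The calibrated global [ape::phylo].
#' @param earlier Character vector: families present in the earlier bin.
#' @param later Character vector: surviving families (`mode = "survivors"`)
#'   or the full later-bin faunal list (`mode = "full_list"`).
#' @param mode `"survivors"` (default) or `"full_list"`.
#' @param region Optional region name carried into the result.
#' @return A `polar_retention` tibble (one row) with branch-length and
#'   node-count totals for both bins and `retained_`/`loss_` fractions for
#'   each metric.
#' @examples
#' tr <- calibrate_ages(parse_newick("((A,B),C);"),
#'                      c(A = 100, B = 50, C = 200))
#' retention(tr, earlier = c("A", "B", "C"), later = c("A", "B"))
#' @export
retention <- function(global, earlier, later, mode = c("survivors", "full_list"),
                      region = NA_character_) {
  mode <- match.arg(mode)
  assert_calibrated(global)
  earlier <- unique(as.character(earlier))
  later <- unique(as.character(later))
  if (length(later) == 0L) {
    abort("Survivor/later set is empty.", class = "polarphylo_validation_error")
  }
  if (mode == "survivors" && length(setdiff(later, earlier))) {
    abort(paste0("Survivors not present in the earlier bin: ",
      paste(setdiff(later, earlier), collapse = ", ")),
      class = "polarphylo_validation_error")
  }
  tr_early <- regional_tree(global, earlier, allow_single = TRUE)
  tr_late <- regional_tree(global, later, allow_single = TRUE)
  bl_early <- total_branch_length(tr_early)
  bl_late <- total_branch_length(tr_late)
  nd_early <- node_count(tr_early)
  nd_late <- node_count(tr_late)
  out <- tibble(
    region = region, mode = mode,
    n_families_earlier = length(earlier), n_families_later = length(later),
    branch_length_earlier = bl_early, branch_length_later = bl_late,
    node_count_earlier = nd_early, node_count_later = nd_late,
    retained_branch_length = bl_late / bl_early,
    loss_branch_length = 1 - bl_late / bl_early,
    retained_node_count = nd_late / nd_early,
    loss_node_count = 1 - nd_late / nd_early
  )
  class(out) <- c("polar_retention", class(out))
  out
}

#' @export
print.polar_retention <- function(x, ...) {
  cat("Phylogenetic-diversity retention\n")
  cat(sprintf("  mode: %s;  families %d -> %d\n",
    x$mode[1], x$n_families_earlier[1], x$n_families_later[1]))
  cat(sprintf("  branch length: %.2f -> %.2f Myr  (loss %.1f%%)\n",
    x$branch_length_earlier[1], x$branch_length_later[1],
    100 * x$loss_branch_length[1]))
  cat(sprintf("  node count   : %d -> %d        (loss %.1f%%)\n",
    x$node_count_earlier[1], x$node_count_later[1],
    100 * x$loss_node_count[1]))
  invisible(x)
}

#' @rdname retention
#' @param x A `polar_retention` object.
#' @param ... Unused.
#' @method tidy polar_retention
#' @export
tidy.polar_retention <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "polar_retention")
  out
}

#' Plot retained vs lost phylogenetic diversity
#'
#' Side-by-side bars of retained and lost fractions for the branch-length
#' and node-count metrics, faceted by region when several retention rows are
#' bound together.
#'
#' @param object A `polar_retention` tibble (rows may cover several regions
#'   or modes).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot polar_retention
#' @export
autoplot.polar_retention <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object),
    cols = c("loss_branch_length", "loss_node_count"),
    names_to = "metric", values_to = "loss")
  df$metric <- ifelse(df$metric == "loss_branch_length",
    "Branch length (Myr)", "Node count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$loss,
      fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~region) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
      limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Phylogenetic history lost", fill = "Mode") +
    ggplot2::theme_minimal()
}
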