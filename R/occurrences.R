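#' Read a regional faunal occurrence table
#'
#' Occurrence records are tidy rows of (`region`, `time_bin`, `family`) with
#' optional `genus`, `species_count`, `length_mm`, `height_mm` and `order`
#' columns. Values are whitespace-trimmed (case preserved); duplicate
#' (`region`, `time_bin`, `family`, `genus`) rows are collapsed with summed
#' `species_count`. An optional alias table (`old_name`, `canonical_name`)
#' maps synonymous family names onto a canonical spelling before indexing;
#' taxonomic vetting beyond that is left to data curation.
#'
#' @param path Path to a CSV file with at least `region,time_bin,family`
#'   headers.
#' @param aliases Optional alias CSV path or data frame with columns
#'   `old_name`, `canonical_name`.
#' @return A tibble of normalized occurrence records.
#' @export
read_occurrences <- function(path, aliases = NULL) {
  occ <- readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character()))
  as_occurrence_table(occ, aliases = aliases, source = path)
}

#' Normalize a data frame of occurrence records
#'
#' @param occ A data frame with at least `region`, `time_bin`, `family`.
#' @inheritParams read_occurrences
#' @param source Label used in error messages (default "data frame").
#' @return A tibble of normalized occurrence records.
#' @export
as_occurrence_table <- function(occ, aliases = NULL, source = "data frame") {
  req <- c("region", "time_bin", "family")
  miss <- setdiff(req, names(occ))
  if (length(miss)) {
    abort(paste0("Missing required column(s) in ", source, ": ",
      paste(miss, collapse = ", ")), class = "polarphylo_schema_error")
  }
  occ <- tibble::as_tibble(occ)
  opt_chr <- intersect(c("genus", "order"), names(occ))
  opt_num <- intersect(c("species_count", "length_mm", "height_mm"), names(occ))
  occ <- dplyr::mutate(occ, dplyr::across(dplyr::all_of(c(req, opt_chr)),
    ~ trimws(as.character(.x))))
  for (col in opt_num) {
    raw <- occ[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(num))
    if (length(bad)) {
      abort(sprintf("Non-numeric %s in %s at row(s): %s", col, source,
        paste(bad, collapse = ", ")), class = "polarphylo_row_error")
    }
    occ[[col]] <- num
  }
  if (any(!nzchar(occ$family))) {
    abort("Empty family names are not allowed.", class = "polarphylo_validation_error")
  }
  if ("species_count" %in% names(occ) &&
      any(occ$species_count < 0, na.rm = TRUE)) {
    abort("species_count must be nonnegative.", class = "polarphylo_validation_error")
  }
  for (col in intersect(c("length_mm", "height_mm"), names(occ))) {
    if (any(occ[[col]] <= 0, na.rm = TRUE)) {
      abort(paste0(col, " must be > 0 when present."),
        class = "polarphylo_validation_error")
    }
  }
  occ <- apply_family_aliases(occ, aliases)
  # collapse duplicate (region, time_bin, family, genus) rows, summing counts
  grp <- intersect(c("region", "time_bin", "family", "genus", "order"), names(occ))
  occ <- dplyr::summarise(
    dplyr::group_by(occ, dplyr::across(dplyr::all_of(grp))),
    dplyr::across(dplyr::any_of("species_count"), ~ if (all(is.na(.x))) NA_real_ else sum(.x, na.rm = TRUE)),
    dplyr::across(dplyr::any_of(c("length_mm", "height_mm")), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
  dplyr::mutate(occ, dplyr::across(dplyr::any_of(c("length_mm", "height_mm")),
    ~ ifelse(is.nan(.x), NA_real_, .x)))
}

apply_family_aliases <- function(occ, aliases) {
  if (is.null(aliases)) return(occ)
  if (is.character(aliases) && length(aliases) == 1L) {
    aliases <- readr::read_csv(aliases, show_col_types = FALSE)
  }
  if (!all(c("old_name", "canonical_name") %in% names(aliases))) {
    abort("Alias table must have columns old_name, canonical_name.",
      class = "polarphylo_schema_error")
  }
  map <- stats::setNames(aliases$canonical_name, aliases$old_name)
  hit <- occ$family %in% names(map)
  occ$family[hit] <- unname(map[occ$family[hit]])
  occ
}

#' Families recorded in a region and time bin
#'
#' @param occ An occurrence tibble (see [read_occurrences()]).
#' @param region,time_bin Region and time-bin names.
#' @return Character vector of distinct family names (empty, with a message,
#'   if the region/bin has no records).
#' @export
families_in <- function(occ, region, time_bin) {
  hit <- occ$region == region & occ$time_bin == time_bin
  fams <- sort(unique(occ$family[hit]))
  if (length(fams) == 0L) {
    rlang::inform(sprintf("No records for region '%s', time bin '%s'.", region, time_bin))
  }
  fams
}

#' Genera recorded in a region and time bin
#'
#' @inheritParams families_in
#' @return A tibble with columns `family`, `genus` (distinct pairs).
#' @export
genera_in <- function(occ, region, time_bin) {
  if (!"genus" %in% names(occ)) {
    abort("Occurrence table has no genus column.", class = "polarphylo_schema_error")
  }
  sub <- occ[occ$region == region & occ$time_bin == time_bin, , drop = FALSE]
  if (any(is.na(sub$genus) | !nzchar(sub$genus))) {
    abort("Genus-level operations require a genus on every record.",
      class = "polarphylo_validation_error")
  }
  dplyr::distinct(sub, .data$family, .data$genus)
}

#' Label regional extinctions between two time bins
#'
#' A family present in the earlier bin is marked extinct iff it is absent
#' from the later bin; presence in the later bin is read directly from the
#' table (vetting of modern additions is upstream data curation). The result
#' partitions the earlier-bin family set exactly.
#'
#' @inheritParams families_in
#' @param earlier,later Names of the earlier and later time bins.
#' @return A tibble with columns `family`, `extinct` (logical); attributes
#'   `region`, `earlier`, `later`.
#' @export
label_extinctions <- function(occ, region, earlier, later) {
  fam_early <- families_in(occ, region, earlier)
  if (length(fam_early) == 0L) {
    abort(sprintf("Earlier bin '%s' has no families for region '%s'.", earlier, region),
      class = "polarphylo_validation_error")
  }
  fam_late <- unique(occ$family[occ$region == region & occ$time_bin == later])
  out <- tibble(family = fam_early, extinct = !(fam_early %in% fam_late))
  attr(out, "region") <- region
  attr(out, "earlier") <- earlier
  attr(out, "later") <- later
  out
}

#' Bivalve body-size metric from shell dimensions
#'
#' The geometric-mean size proxy `log2(sqrt(length * height))`, in log2 mm.
#'
#' @param length_mm,height_mm Shell length and height in mm (> 0). Vectorized.
#' @return Numeric vector of log2 sizes.
#' @examples
#' body_size(16, 4) # 3
#' @export
body_size <- function(length_mm, height_mm) {
  if (any(length_mm <= 0, na.rm = TRUE) || any(height_mm <= 0, na.rm = TRUE)) {
    abort("Shell dimensions must be > 0 mm.", class = "polarphylo_domain_error")
  }
  log2(sqrt(length_mm * height_mm))
}

#' Read order-level family groupings
#'
#' @param path CSV with header `family,order`.
#' @return A tibble with columns `family`, `order`.
#' @export
read_order_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("family", "order") %in% names(tab))) {
    abort("Order table must have columns family, order.",
      class = "polarphylo_schema_error")
  }
  dplyr::distinct(tibble::as_tibble(tab[, c("family", "order")]))
}
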