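#' Aggregate taxa counts to a taxonomic rank
#'
#' Collapses the taxa-by-sample table to per-(group, sample) richness and
#' abundance summaries: `n` is the number of member taxa detected (count > 0)
#' and `y` the summed member counts (recovered abundance). Sample depth `tau`
#' is frozen from the full input table before any filtering, and `n_plus` is
#' the per-sample total observed richness.
#'
#' Taxa whose rank is `"unassigned"` are, by default, pooled into one
#' pseudo-group per parent rank value (`"unassigned@<parent>"`) so that
#' per-sample depth is conserved; `unassigned = "drop"` removes them instead.
#'
#' @param counts Validated count tibble (see [read_count_table()]).
#' @param taxonomy Taxonomy tibble (see [parse_taxonomy()]); aligned with
#'   [align_taxonomy()] internally.
#' @param rank Aggregation rank, default `"genus"`.
#' @param unassigned `"pool"` (default) or `"drop"`.
#' @param strict Passed to [align_taxonomy()].
#' @return A tibble of class `genus_aggregate` in long format with columns
#'   `group`, `sample`, `n`, `y`, `tau`, `n_plus`, carrying the rank as an
#'   attribute. All (group, sample) cells are present, including zeros.
#' @export
aggregate_by_rank <- function(counts, taxonomy, rank = "genus",
                              unassigned = c("pool", "drop"), strict = TRUE) {
  unassigned <- match.arg(unassigned)
  rank <- match.arg(rank, c("genus", "family", "order", "class", "phylum"))
  counts <- validate_counts(counts)
  taxonomy <- align_taxonomy(counts, taxonomy, strict = strict)
  sample_ids <- setdiff(names(counts), "taxon_id")
  depths <- sample_depths(counts)
  if (any(depths$tau == 0)) {
    inform(paste0("sample(s) with zero depth: ",
                  paste(depths$sample[depths$tau == 0], collapse = ", ")))
  }

  grp <- taxonomy[[rank]]
  parent <- .ranks[max(match(rank, .ranks) - 1L, 1L)]
  is_un <- grp == "unassigned"
  if (unassigned == "pool") {
    grp[is_un] <- paste0("unassigned@", taxonomy[[parent]][is_un])
  }
  keep <- if (unassigned == "drop") !is_un else rep(TRUE, length(grp))

  long <- counts[keep, ] |>
    dplyr::mutate(.group = grp[keep]) |>
    tidyr::pivot_longer(dplyr::all_of(sample_ids),
                        names_to = "sample", values_to = "count") |>
    dplyr::group_by(.data$.group, .data$sample) |>
    dplyr::summarise(n = sum(.data$count > 0), y = sum(.data$count), .groups = "drop") |>
    dplyr::rename(group = ".group")

  # complete the grid so absent (group, sample) cells are explicit zeros
  long <- tidyr::complete(long, .data$group, sample = sample_ids,
                          fill = list(n = 0L, y = 0))
  long <- long |>
    dplyr::left_join(depths, by = "sample") |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(n_plus = sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$group, match(.data$sample, sample_ids))

  structure(long, class = c("genus_aggregate", class(long)),
            rank = rank, sample_ids = sample_ids)
}

#' @export
print.genus_aggregate <- function(x, ...) {
  cat("<genus_aggregate> rank:", attr(x, "rank"),
      "|", dplyr::n_distinct(x$group), "groups x",
      dplyr::n_distinct(x$sample), "samples\n")
  NextMethod()
}

# per-sample tibble (sample, tau, n_plus) in sample order
aggregate_samples <- function(agg) {
  agg |>
    dplyr::distinct(.data$sample, .data$tau, .data$n_plus) |>
    dplyr::arrange(match(.data$sample, attr(agg, "sample_ids") %||% unique(agg$sample)))
}
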