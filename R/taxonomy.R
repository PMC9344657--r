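.ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
.rank_prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__",
                    order = "o__", family = "f__", genus = "g__")

#' Parse a taxonomy table
#'
#' Maps each taxon to a six-rank lineage (kingdom..genus). Two dialects are
#' supported: QIIME-style semicolon-delimited strings
#' (`"k__Bacteria;p__...;g__Pseudomonas"`) in a two-column table, or one
#' column per rank. Empty rank tokens (e.g. `"g__"`) become `"unassigned"`;
#' tokens beyond genus (species) are dropped with a message. A rank below a
#' missing rank is demoted to `"unassigned"` so lineages stay consistent.
#'
#' @param x Path to a TSV file, or a data frame. Two-column input is treated
#'   as `qiime_string`; seven-column input as `rank_columns` unless `dialect`
#'   says otherwise.
#' @param dialect `"auto"`, `"qiime_string"` or `"rank_columns"`.
#' @return A tibble with columns `taxon_id`, `kingdom`, ..., `genus`.
#' @export
parse_taxonomy <- function(x, dialect = c("auto", "qiime_string", "rank_columns")) {
  dialect <- match.arg(dialect)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- readr::read_tsv(x, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  }
  x <- as_tibble(x)
  if (dialect == "auto") dialect <- if (ncol(x) <= 2L) "qiime_string" else "rank_columns"
  names(x)[1] <- "taxon_id"
  if (dialect == "qiime_string") {
    stopifnot(ncol(x) >= 2L)
    lin <- parse_qiime_lineages(x[[2]])
    out <- dplyr::bind_cols(tibble(taxon_id = as.character(x$taxon_id)), lin)
  } else {
    have <- intersect(tolower(names(x)), .ranks)
    if (length(have) == 0L && ncol(x) >= 7L) {
      names(x)[2:7] <- .ranks
    } else {
      names(x) <- tolower(names(x))
    }
    out <- tibble(taxon_id = as.character(x$taxon_id))
    for (r in .ranks) {
      v <- if (r %in% names(x)) as.character(x[[r]]) else NA_character_
      v[is.na(v) | !nzchar(trimws(v))] <- "unassigned"
      out[[r]] <- trimws(v)
    }
  }
  out
}

parse_qiime_lineages <- function(strings) {
  toks <- strsplit(as.character(strings), ";", fixed = TRUE)
  n_extra <- sum(vapply(toks, length, integer(1)) > 6L)
  if (n_extra > 0L) {
    inform(paste0(n_extra, " lineage(s) had tokens beyond genus (species level); ignored"))
  }
  rows <- lapply(toks, function(tk) {
    tk <- trimws(tk)
    out <- rep("unassigned", 6L)
    for (i in seq_len(min(length(tk), 6L))) {
      v <- sub(paste0("^", .rank_prefixes[i]), "", tk[i])
      v <- sub("^[kpcofg]__", "", v)  # tolerate misordered prefixes
      if (nzchar(v)) out[i] <- v
    }
    out
  })
  m <- do.call(rbind, rows)
  colnames(m) <- .ranks
  as_tibble(m)
}

#' Align a taxonomy with a count table
#'
#' @param counts Validated count tibble.
#' @param taxonomy Tibble from [parse_taxonomy()].
#' @param strict If `TRUE` (default), a taxon present in the counts but absent
#'   from the taxonomy is an error; otherwise it receives an all-unassigned
#'   lineage with a message.
#' @return Taxonomy tibble with one row per count-table taxon, in order.
#' @export
align_taxonomy <- function(counts, taxonomy, strict = TRUE) {
  missing <- setdiff(counts$taxon_id, taxonomy$taxon_id)
  if (length(missing)) {
    if (strict) {
      abort(paste0(length(missing), " taxa in counts missing from taxonomy, e.g. '",
                   missing[1], "'"))
    }
    inform(paste0(length(missing), " taxa missing from taxonomy; assigned all-unassigned lineages"))
    fill <- tibble(taxon_id = missing)
    for (r in .ranks) fill[[r]] <- "unassigned"
    taxonomy <- dplyr::bind_rows(taxonomy, fill)
  }
  taxonomy[match(counts$taxon_id, taxonomy$taxon_id), , drop = FALSE]
}
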