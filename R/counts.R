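#' Read a taxa-by-sample count table
#'
#' Reads an OTU/ASV count matrix with taxa as rows and samples as columns.
#' The first column must hold taxon identifiers and the header row sample
#' identifiers. Counts must be non-negative integers: richness counting is
#' undefined on relative abundances, so fractional tables are rejected.
#'
#' @param path Path to the file.
#' @param format One of `"tsv"`, `"csv"`, or `"biom"` (BIOM-JSON; requires the
#'   biomformat package).
#' @return A tibble with a `taxon_id` character column followed by one integer
#'   column per sample, validated by [validate_counts()].
#' @export
read_count_table <- function(path, format = c("tsv", "csv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("count table not found: ", path))
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("BIOM input requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    tbl <- tibble(taxon_id = rownames(m)) |>
      dplyr::bind_cols(as_tibble(m))
    return(validate_counts(tbl))
  }
  delim <- if (format == "tsv") "\t" else ","
  raw <- tryCatch(
    readr::read_delim(path, delim = delim, col_types = readr::cols(),
                      progress = FALSE, show_col_types = FALSE),
    error = function(e) abort(paste0("malformed count table '", path, "': ", conditionMessage(e)))
  )
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    abort(paste0("count table '", path, "' is empty or has no sample columns"))
  }
  names(raw)[1] <- "taxon_id"
  raw$taxon_id <- as.character(raw$taxon_id)
  validate_counts(raw)
}

#' Validate a count table
#'
#' Checks the invariants of a taxa-by-sample count tibble: unique taxon and
#' sample identifiers, and integral non-negative counts.
#'
#' @param counts A tibble: `taxon_id` column plus one numeric column per sample.
#' @return The validated tibble (counts coerced to integer-valued doubles).
#' @export
validate_counts <- function(counts) {
  counts <- as_tibble(counts)
  if (!"taxon_id" %in% names(counts)) {
    stopifnot(ncol(counts) >= 2L)
    names(counts)[1] <- "taxon_id"
  }
  sample_ids <- setdiff(names(counts), "taxon_id")
  if (length(sample_ids) == 0L) abort("count table has no sample columns")
  dup_t <- counts$taxon_id[duplicated(counts$taxon_id)]
  if (length(dup_t)) abort(paste0("duplicated taxon ID(s): ", paste(unique(dup_t), collapse = ", ")))
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) abort(paste0("duplicated sample ID(s): ", paste(unique(dup_s), collapse = ", ")))
  for (s in sample_ids) {
    v <- counts[[s]]
    if (!is.numeric(v)) abort(paste0("non-numeric counts in sample column '", s, "'"))
    bad <- which(!is_wholenumber(v) | v < 0)
    if (length(bad)) {
      abort(paste0("invalid count (negative, NaN or non-integer) in sample '", s,
                   "', taxon '", counts$taxon_id[bad[1]], "'"))
    }
    counts[[s]] <- round(v)
  }
  counts
}

#' Write a count table to TSV
#'
#' @param counts A validated count tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Per-sample depths of a count table
#'
#' @param counts A validated count tibble.
#' @return A tibble with columns `sample` and `tau` (column sum, i.e. depth).
#' @export
sample_depths <- function(counts) {
  sample_ids <- setdiff(names(counts), "taxon_id")
  tibble(sample = sample_ids,
         tau = unname(vapply(sample_ids, function(s) sum(counts[[s]]), numeric(1))))
}
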