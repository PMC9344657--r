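#' Read a sample design table
#'
#' @param path CSV file with a `sample_id` column and covariate columns.
#' @return A tibble.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) abort(paste0("design table not found: ", path))
  d <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                       show_col_types = FALSE)
  if (!"sample_id" %in% names(d)) names(d)[1] <- "sample_id"
  d$sample_id <- as.character(d$sample_id)
  if (anyDuplicated(d$sample_id)) abort("duplicated sample_id in design table")
  d
}

#' Build a design matrix from a sample table
#'
#' Expands categorical covariates to treatment-coded indicators with the
#' lexicographically first level as reference (overridable via `ref`), and
#' prepends an intercept. Checks full column rank on the samples used.
#'
#' @param design Tibble with `sample_id` plus covariate columns, or a design
#'   matrix already carrying sample IDs as rownames (returned unchanged).
#' @param samples Character vector giving the sample order to align to;
#'   default: the design table's own order.
#' @param ref Named list: covariate -> reference level.
#' @return Numeric matrix (samples x terms) with rownames = sample IDs and an
#'   `(Intercept)` first column.
#' @export
design_matrix <- function(design, samples = NULL, ref = list()) {
  if (is.matrix(design)) {
    if (is.null(rownames(design))) abort("design matrix must have sample IDs as rownames")
    if (!is.null(samples)) design <- design[samples, , drop = FALSE]
    return(design)
  }
  design <- as_tibble(design)
  if (!"sample_id" %in% names(design)) abort("design needs a sample_id column")
  if (!is.null(samples)) {
    miss <- setdiff(samples, design$sample_id)
    if (length(miss)) abort(paste0("samples missing from design: ", paste(miss, collapse = ", ")))
    design <- design[match(samples, design$sample_id), , drop = FALSE]
  }
  covars <- setdiff(names(design), "sample_id")
  df <- as.data.frame(design[covars], stringsAsFactors = FALSE)
  for (v in covars) {
    if (is.character(df[[v]]) || is.factor(df[[v]]) || is.logical(df[[v]])) {
      lev <- sort(unique(as.character(df[[v]])))
      if (!is.null(ref[[v]])) lev <- c(ref[[v]], setdiff(lev, ref[[v]]))
      df[[v]] <- factor(as.character(df[[v]]), levels = lev)
    }
  }
  X <- if (length(covars)) {
    model.matrix(as.formula(paste("~", paste(sprintf("`%s`", covars), collapse = "+"))), df)
  } else {
    matrix(1, nrow(design), 1, dimnames = list(NULL, "(Intercept)"))
  }
  rownames(X) <- design$sample_id
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    abort(paste0("design matrix is rank deficient; offending column(s): ",
                 paste(drop_cols, collapse = ", ")))
  }
  X
}
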