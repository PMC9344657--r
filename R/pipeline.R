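#' Run the full differential-richness pipeline
#'
#' Orchestrates an end-to-end run: read counts/taxonomy/design, aggregate to
#' genus level, fit the technical trend, fit genus-specific and sample-wide
#' differential richness models, compute richness-estimator tables and
#' diagnostics, and write every artifact (TSV/JSON) plus a manifest with
#' content hashes to `out_dir`. A serialized copy of the configuration is
#' written first, so any run is reconstructible from its output directory.
#'
#' @param config A list (or path to a JSON/YAML file parsed by the caller)
#'   with elements: `counts`, `taxonomy`, `design` (paths), `count_format`
#'   (default `"tsv"`), `trend` (list of [fit_trend()] args), `min_nonzero`,
#'   `bootstrap` (list with `B`; `NULL` to skip), `seed`, `out_dir`.
#' @return Invisibly, a tibble manifest (`file`, `md5`).
#' @export
run_pipeline <- function(config) {
  required <- c("counts", "taxonomy", "design", "out_dir")
  miss <- setdiff(required, names(config))
  if (length(miss)) abort(paste0("config missing field(s): ", paste(miss, collapse = ", ")))
  for (f in c("counts", "taxonomy", "design")) {
    if (!file.exists(config[[f]])) abort(paste0("input not found: ", config[[f]]))
  }
  seed <- as.integer(config$seed %||% 1L)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config, file.path(config$out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  counts <- read_count_table(config$counts, format = config$count_format %||% "tsv")
  taxonomy <- parse_taxonomy(config$taxonomy)
  design <- read_design(config$design)
  agg <- aggregate_by_rank(counts, taxonomy)
  X <- design_matrix(design, samples = aggregate_samples(agg)$sample)

  trend <- do.call(fit_trend, c(list(agg), config$trend %||% list()))
  trend_to_json(trend, file.path(config$out_dir, "trend_fit.json"))
  readr::write_tsv(tidy(trend), file.path(config$out_dir, "trend_genus_effects.tsv"),
                   progress = FALSE)

  dr_g <- genus_differential(agg, trend, X, min_nonzero = config$min_nonzero %||% 5)
  readr::write_tsv(dr_g, file.path(config$out_dir, "dr_genus.tsv"), progress = FALSE)
  dr_s <- samplewide_differential_richness(agg, trend, X)
  readr::write_tsv(dplyr::mutate(tidy(dr_s), dispersion = dr_s$dispersion,
                                 n = dr_s$n, status = dr_s$status),
                   file.path(config$out_dir, "dr_samplewide.tsv"), progress = FALSE)
  if (!is.null(config$bootstrap)) {
    bt <- bootstrap_t_ci(agg, X, trend = trend,
                         B = config$bootstrap$B %||% 199,
                         seed = child_seed(seed, "bootstrap"))
    readr::write_tsv(bt, file.path(config$out_dir, "dr_samplewide_bootstrap.tsv"),
                     progress = FALSE)
  }

  rich <- samplewide_richness_table(counts)
  readr::write_tsv(rich, file.path(config$out_dir, "richness_samplewide.tsv"),
                   progress = FALSE)
  da <- differential_abundance(agg, X)
  readr::write_tsv(da, file.path(config$out_dir, "differential_abundance.tsv"),
                   progress = FALSE)
  contrast <- colnames(X)[min(2, ncol(X))]
  conf <- tryCatch(
    confounding_diagnostic(dplyr::filter(dr_g, .data$term == contrast),
                           dplyr::filter(da, .data$term == contrast)),
    error = function(e) NULL)
  if (!is.null(conf)) {
    readr::write_tsv(conf, file.path(config$out_dir, "confounding.tsv"), progress = FALSE)
  }
  amc <- accumulation_model_comparison(agg, trend, X)
  readr::write_tsv(amc, file.path(config$out_dir, "model_comparison.tsv"),
                   progress = FALSE)
  repl <- replicability_summary(counts, taxonomy)
  readr::write_tsv(repl$per_genus, file.path(config$out_dir, "replicability_per_genus.tsv"),
                   progress = FALSE)
  readr::write_tsv(repl$study, file.path(config$out_dir, "replicability_study.tsv"),
                   progress = FALSE)

  files <- sort(list.files(config$out_dir, full.names = FALSE))
  manifest <- tibble(file = files,
                     md5 = vapply(file.path(config$out_dir, files),
                                  function(p) unname(tools::md5sum(p)), character(1),
                                  USE.NAMES = FALSE))
  readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"), progress = FALSE)
  invisible(manifest)
}
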