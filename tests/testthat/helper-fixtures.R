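# Small in-code fixtures shared across tests.

toy_counts <- function() {
  tibble::tibble(
    taxon_id = c("t1", "t2", "t3"),
    s1 = c(5, 2, 0),
    s2 = c(0, 1, 3)
  )
}

toy_taxonomy <- function() {
  tibble::tibble(
    taxon_id = c("t1", "t2", "t3"),
    lineage = c(
      "k__Bacteria;p__Proteobacteria;c__Gamma;o__Pseudomonadales;f__Pseudomonadaceae;g__Pseudomonas",
      "k__Bacteria;p__Proteobacteria;c__Gamma;o__Pseudomonadales;f__Pseudomonadaceae;g__Pseudomonas",
      "k__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Lactobacillaceae;g__Lactobacillus"
    )
  )
}

# deterministic accumulation data: z = a + b * log y + noise, many genera
linear_trend_agg <- function(a = 1, b = 0.8, sd = 0.1, n_genus = 40,
                             n_sample = 20, seed = 42, genus_offsets = 0) {
  set.seed(seed)
  genus_offsets <- rep_len(genus_offsets, n_genus)
  rows <- list()
  for (g in seq_len(n_genus)) {
    log_y <- runif(n_sample, 2, 9)
    z <- a + genus_offsets[g] + b * log_y + rnorm(n_sample, 0, sd)
    rows[[g]] <- tibble::tibble(
      group = sprintf("G%02d", g),
      sample = sprintf("s%03d", seq_len(n_sample)),
      n = pmax(1, round(exp(z))), y = round(exp(log_y)))
  }
  d <- dplyr::bind_rows(rows)
  d <- d |>
    dplyr::group_by(sample) |>
    dplyr::mutate(tau = sum(y), n_plus = sum(n)) |>
    dplyr::ungroup()
  structure(d, class = c("genus_aggregate", class(d)),
            rank = "genus", sample_ids = unique(d$sample))
}

# exact (pre-rounded) version: n is already the exp of an exact linear z
exact_linear_agg <- function(a = 2, b = 0.5, n_points = 120, seed = 3) {
  set.seed(seed)
  log_y <- seq(2, 9, length.out = n_points)
  tibble::tibble(group = rep(sprintf("G%02d", 1:12), length.out = n_points),
                 sample = sprintf("s%03d", seq_len(n_points)),
                 n = exp(a + b * log_y), y = exp(log_y),
                 tau = sum(exp(log_y)), n_plus = sum(exp(a + b * log_y)))
}

two_group_design <- function(n_per_group, prefix = "s") {
  tibble::tibble(
    sample_id = sprintf("%s%03d", prefix, seq_len(2 * n_per_group)),
    group = rep(c("A", "B"), each = n_per_group))
}

small_survey <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(simulate_survey(survey_config(
        G = 20, n_per_group = 12, depth = 1e4, seed = 11)))
    }
    cache
  }
})
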