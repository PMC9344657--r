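#' Observed richness of an abundance vector
#'
#' @param v Integer counts of detected taxa (entries >= 1). Zeros are dropped.
#' @return Number of detected taxa.
#' @export
observed_richness <- function(v) {
  v <- v[v > 0]
  length(v)
}

#' Chao1 asymptotic richness
#'
#' Classic Chao1 \eqn{S_{obs} + f_1^2 / (2 f_2)} when doubletons are present;
#' the bias-corrected form \eqn{S_{obs} + f_1(f_1-1)/(2(f_2+1))} when
#' \eqn{f_2 = 0}. Standard errors follow the classical asymptotic variance of
#' the variant used; the variant is recorded because downstream
#' inverse-variance regressions consume the SEs.
#'
#' @param v Abundance vector (zeros dropped).
#' @param bias_corrected Force the bias-corrected form regardless of `f2`.
#' @return One-row tibble: `estimator`, `estimate`, `se`, `variant`,
#'   `undefined` flag.
#' @export
chao1 <- function(v, bias_corrected = FALSE) {
  v <- v[v > 0]
  S <- length(v)
  if (S == 0L) {
    return(tibble(estimator = "chao1", estimate = 0, se = 0,
                  variant = "classic", undefined = FALSE))
  }
  f1 <- sum(v == 1)
  f2 <- sum(v == 2)
  if (f2 > 0 && !bias_corrected) {
    est <- S + f1^2 / (2 * f2)
    r <- f1 / f2
    va <- f2 * (r^2 / 2 + r^3 + r^4 / 4)
    variant <- "classic"
  } else {
    est <- S + f1 * (f1 - 1) / (2 * (f2 + 1))
    if (f1 > 0) {
      va <- f1 * (f1 - 1) / (2 * (f2 + 1)) +
        f1 * (2 * f1 - 1)^2 / (4 * (f2 + 1)^2) +
        f1^2 * f2 * (f1 - 1)^2 / (4 * (f2 + 1)^4)
    } else {
      va <- 0
    }
    variant <- "bias_corrected"
  }
  tibble(estimator = "chao1", estimate = est, se = sqrt(max(va, 0)),
         variant = variant, undefined = FALSE)
}

#' ACE asymptotic richness
#'
#' Abundance-based coverage estimator with rare/abundant cutoff
#' (default 10): \eqn{S_{abund} + S_{rare}/C + (f_1/C)\gamma^2} with sample
#' coverage \eqn{C = 1 - f_1/N_{rare}} and squared coefficient of variation
#' \eqn{\gamma^2} truncated at 0. When every rare taxon is a singleton the
#' coverage is 0 and the estimate is flagged undefined. The standard error is
#' taken from `vegan::estimateR` when available (and `NA` otherwise).
#'
#' @param v Abundance vector (zeros dropped).
#' @param rare_cutoff Counts `<= rare_cutoff` define the rare class.
#' @return One-row tibble: `estimator`, `estimate`, `se`, `variant`,
#'   `undefined`.
#' @export
ace <- function(v, rare_cutoff = 10) {
  v <- v[v > 0]
  S <- length(v)
  if (S == 0L) {
    return(tibble(estimator = "ace", estimate = 0, se = 0,
                  variant = paste0("cutoff", rare_cutoff), undefined = FALSE))
  }
  rare <- v[v <= rare_cutoff]
  S_ab <- sum(v > rare_cutoff)
  S_r <- length(rare)
  if (S_r == 0L) {
    return(tibble(estimator = "ace", estimate = as.numeric(S), se = 0,
                  variant = paste0("cutoff", rare_cutoff), undefined = FALSE))
  }
  N_r <- sum(rare)
  f1 <- sum(rare == 1)
  C <- 1 - f1 / N_r
  if (C <= 0) {
    return(tibble(estimator = "ace", estimate = NA_real_, se = NA_real_,
                  variant = paste0("cutoff", rare_cutoff), undefined = TRUE))
  }
  fi <- tabulate(rare, nbins = rare_cutoff)
  i <- seq_len(rare_cutoff)
  g2 <- max(S_r / C * sum(i * (i - 1) * fi) / (N_r * (N_r - 1)) - 1, 0)
  est <- S_ab + S_r / C + f1 / C * g2
  se <- NA_real_
  if (requireNamespace("vegan", quietly = TRUE) && rare_cutoff == 10) {
    er <- tryCatch(vegan::estimateR(v), error = function(e) NULL)
    if (!is.null(er)) se <- unname(er["se.ACE"])
  }
  tibble(estimator = "ace", estimate = est, se = se,
         variant = paste0("cutoff", rare_cutoff), undefined = FALSE)
}

#' Sample-wide richness estimates for every sample
#'
#' @param counts Validated count tibble.
#' @param estimators Subset of `c("observed", "chao1", "ace")`.
#' @return Long tibble: `sample`, `estimator`, `estimate`, `se`, `variant`,
#'   `undefined`.
#' @export
samplewide_richness_table <- function(counts, estimators = c("observed", "chao1", "ace")) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  sample_ids <- setdiff(names(counts), "taxon_id")
  purrr::map_dfr(sample_ids, function(s) {
    v <- counts[[s]]
    purrr::map_dfr(estimators, function(e) {
      if (e == "observed") {
        tibble(estimator = "observed", estimate = observed_richness(v),
               se = NA_real_, variant = NA_character_, undefined = FALSE)
      } else if (e == "chao1") chao1(v) else ace(v)
    }) |> dplyr::mutate(sample = s, .before = 1)
  })
}

#' Genus-wise asymptotic richness estimates
#'
#' Applies an estimator to each genus's member-taxon counts within each
#' sample. Undefined cells are flagged, not imputed; a genus absent from a
#' sample gets estimate 0.
#'
#' @param counts Validated count tibble.
#' @param taxonomy Taxonomy tibble.
#' @param estimator `"chao1"`, `"ace"`, or `"observed"`.
#' @param rank Aggregation rank (default genus).
#' @param unassigned Passed to [aggregate_by_rank()]'s pooling rule.
#' @return Long tibble: `group`, `sample`, `estimate`, `se`, `variant`,
#'   `undefined`.
#' @export
genus_asymptotic_table <- function(counts, taxonomy, estimator = c("chao1", "ace", "observed"),
                                   rank = "genus", unassigned = "pool") {
  estimator <- match.arg(estimator)
  counts <- validate_counts(counts)
  taxonomy <- align_taxonomy(counts, taxonomy)
  grp <- taxonomy[[rank]]
  if (unassigned == "pool") {
    parent <- .ranks[max(match(rank, .ranks) - 1L, 1L)]
    un <- grp == "unassigned"
    grp[un] <- paste0("unassigned@", taxonomy[[parent]][un])
  }
  sample_ids <- setdiff(names(counts), "taxon_id")
  m <- as.matrix(counts[sample_ids])
  split_idx <- split(seq_len(nrow(counts)), grp)
  purrr::map_dfr(names(split_idx), function(g) {
    sub <- m[split_idx[[g]], , drop = FALSE]
    if (estimator == "observed") {
      return(tibble(group = g, sample = sample_ids,
                    estimate = as.numeric(colSums(sub > 0)), se = NA_real_,
                    variant = NA_character_, undefined = FALSE))
    }
    if (estimator == "chao1") {
      res <- chao1_vec(colSums(sub > 0), colSums(sub == 1), colSums(sub == 2))
      return(dplyr::mutate(res, group = g, sample = sample_ids, .before = 1))
    }
    purrr::map_dfr(seq_along(sample_ids), function(j) {
      dplyr::mutate(ace(sub[, j])[c("estimate", "se", "variant", "undefined")],
                    group = g, sample = sample_ids[j], .before = 1)
    })
  })
}

# vectorized Chao1 over per-unit frequency summaries (S_obs, f1, f2)
chao1_vec <- function(S, f1, f2) {
  classic <- f2 > 0
  est <- se <- numeric(length(S))
  variant <- ifelse(classic, "classic", "bias_corrected")
  r <- ifelse(classic, f1 / pmax(f2, 1), 0)
  est[classic] <- (S + f1^2 / (2 * pmax(f2, 1)))[classic]
  se[classic] <- sqrt(pmax(f2 * (r^2 / 2 + r^3 + r^4 / 4), 0))[classic]
  bc <- !classic
  est[bc] <- (S + f1 * (f1 - 1) / (2 * (f2 + 1)))[bc]
  va_bc <- f1 * (f1 - 1) / (2 * (f2 + 1)) +
    f1 * (2 * f1 - 1)^2 / (4 * (f2 + 1)^2) +
    f1^2 * f2 * (f1 - 1)^2 / (4 * (f2 + 1)^4)
  se[bc] <- sqrt(pmax(va_bc, 0))[bc] * (f1[bc] > 0)
  est[S == 0] <- 0; se[S == 0] <- 0
  tibble(estimate = est, se = se, variant = variant, undefined = FALSE)
}
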