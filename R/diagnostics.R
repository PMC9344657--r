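#' Per-genus differential relative abundance
#'
#' Negative-binomial GLM of the recovered genus abundance on the design with
#' log sample depth as offset, so coefficients are log fold changes of
#' relative abundance. Genera entirely absent from a design cell are flagged
#' as separated rather than estimated.
#'
#' @param agg A `genus_aggregate` tibble.
#' @param X Design matrix or design tibble.
#' @param genera Genus labels (default all).
#' @param min_nonzero Minimum samples with the genus detected.
#' @param pseudo_ratio Alternative simple statistic: log ratio of group-mean
#'   relative abundances with a 0.5 pseudo-count, for sensitivity checks
#'   (returned instead of the GLM estimate when `TRUE`; needs a two-level
#'   second design column).
#' @return Tibble: `group`, `term`, `estimate`, `se`, `statistic`, `p.value`,
#'   `status`, `n`.
#' @export
differential_abundance <- function(agg, X, genera = NULL, min_nonzero = 5,
                                   pseudo_ratio = FALSE) {
  agg <- as_tibble(agg)
  X <- design_matrix(X)
  genera <- genera %||% unique(agg$group)
  purrr::map_dfr(genera, function(g) {
    d <- dplyr::filter(agg, .data$group == g)
    d <- d[match(rownames(X), d$sample), , drop = FALSE]
    n_nz <- sum(d$y > 0)
    if (n_nz < min_nonzero) {
      return(tibble(group = g, term = NA_character_, estimate = NA_real_,
                    se = NA_real_, statistic = NA_real_, p.value = NA_real_,
                    status = "too_few_detections", n = n_nz))
    }
    if (pseudo_ratio) {
      gv <- X[, 2]
      ra <- d$y / d$tau
      m1 <- mean(ra[gv == max(gv)]) + 0.5 / mean(d$tau)
      m0 <- mean(ra[gv == min(gv)]) + 0.5 / mean(d$tau)
      return(tibble(group = g, term = colnames(X)[2], estimate = log(m1 / m0),
                    se = NA_real_, statistic = NA_real_, p.value = NA_real_,
                    status = "pseudo_ratio", n = nrow(d)))
    }
    # a genus absent from an entire design cell separates the GLM
    cells <- apply(X, 1, paste, collapse = "\r")
    if (any(tapply(d$y, cells, function(v) all(v == 0)))) {
      return(tibble(group = g, term = NA_character_, estimate = NA_real_,
                    se = NA_real_, statistic = NA_real_, p.value = NA_real_,
                    status = "separated", n = n_nz))
    }
    fit <- fit_count_glm(d$y, X, family = "nb", offset = log(d$tau))
    zst <- fit$estimate / fit$se
    tibble(group = g, term = colnames(X), estimate = unname(fit$estimate),
           se = unname(fit$se), statistic = unname(zst),
           p.value = 2 * pnorm(-abs(zst)), status = fit$status, n = fit$n)
  })
}

#' Confounding diagnostic: richness vs abundance fold changes
#'
#' Correlates per-genus differential-richness log fold changes with matched
#' differential-abundance log fold changes. Under abundance-dependent false
#' taxa generation, uncontrolled richness contrasts track abundance
#' contrasts; a trend-controlled method should show no correlation.
#'
#' @param dr Tibble with columns `group` and `estimate` (differential
#'   richness LFCs), e.g. a filtered [genus_differential()] result.
#' @param da Tibble with columns `group` and `estimate` (differential
#'   abundance LFCs), e.g. from [differential_abundance()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_pairs Minimum matched genera.
#' @return One-row tibble of class `confounding_report`: `r`, `conf.low`,
#'   `conf.high`, `p.value`, `n_pairs`, `n_dropped`, `method`; the matched
#'   pairs are attached as attribute `"pairs"`.
#' @export
confounding_diagnostic <- function(dr, da, method = c("pearson", "spearman"),
                                   min_pairs = 10) {
  method <- match.arg(method)
  pairs <- dplyr::inner_join(
    dplyr::select(as_tibble(dr), "group", dr_lfc = "estimate"),
    dplyr::select(as_tibble(da), "group", da_lfc = "estimate"),
    by = "group")
  n0 <- nrow(pairs)
  pairs <- dplyr::filter(pairs, is.finite(.data$dr_lfc), is.finite(.data$da_lfc))
  if (nrow(pairs) < min_pairs) abort("fewer matched genera than min_pairs")
  if (sd(pairs$dr_lfc) == 0 || sd(pairs$da_lfc) == 0) {
    abort("zero variance in one of the fold-change vectors")
  }
  ct <- suppressWarnings(cor.test(pairs$dr_lfc, pairs$da_lfc, method = method))
  out <- tibble(r = unname(ct$estimate),
                conf.low = if (!is.null(ct$conf.int)) ct$conf.int[1] else NA_real_,
                conf.high = if (!is.null(ct$conf.int)) ct$conf.int[2] else NA_real_,
                p.value = ct$p.value, n_pairs = nrow(pairs),
                n_dropped = n0 - nrow(pairs), method = method)
  attr(out, "pairs") <- pairs
  class(out) <- c("confounding_report", class(out))
  out
}

#' Scatter plot of a confounding report
#'
#' @param object A `confounding_report`.
#' @param ... Unused.
#' @export
autoplot.confounding_report <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$da_lfc, y = .data$dr_lfc)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::labs(x = "differential abundance LFC", y = "differential richness LFC",
                  title = sprintf("r = %.2f (%s)", object$r, object$method)) +
    ggplot2::theme_minimal()
}

#' Accumulation model comparison (pseudo-R-squared and AIC)
#'
#' Compares two negative-binomial regressions explaining taxa accumulation:
#' (i) the fitted technical trend covariate alone, and (ii) the trend plus
#' genus identity (genus scope only), log sample depth, and the design.
#' McFadden's pseudo-R-squared is \eqn{1 - \ell_{fit}/\ell_{null}} against an
#' intercept-only negative-binomial null with its own dispersion.
#' `use_abundance = TRUE` substitutes log recovered abundance for the trend
#' covariate.
#'
#' @param agg A `genus_aggregate` tibble.
#' @param trend A `trend_fit`.
#' @param X Design matrix or design tibble.
#' @param scope `"genus_specific"` (response: per-cell \eqn{n_{gj}} over
#'   detected cells) or `"sample_wide"` (response: \eqn{n_{+j}}).
#' @param use_abundance Replace the trend covariate with log abundance.
#' @return Tibble: `model`, `pseudo_r2`, `aic`, `loglik`, `loglik_null`, `n`,
#'   `status`.
#' @export
accumulation_model_comparison <- function(agg, trend, X,
                                          scope = c("genus_specific", "sample_wide"),
                                          use_abundance = FALSE) {
  scope <- match.arg(scope)
  agg <- as_tibble(agg)
  X <- design_matrix(X)
  if (scope == "genus_specific") {
    d <- dplyr::filter(agg, .data$n >= 1)
    cov1 <- if (use_abundance) log(d$y) else evaluate_trend(trend, d$group, log(d$y))
    y <- d$n
    Xs <- X[d$sample, , drop = FALSE]
    gf <- factor(d$group)
    Ggenus <- model.matrix(~g, data.frame(g = gf))[, -1, drop = FALSE]
    X1 <- cbind(`(Intercept)` = 1, cov = cov1)
    X2 <- cbind(X1, Ggenus, log_depth = log(d$tau), Xs[, -1, drop = FALSE])
    X2 <- X2[, qr(X2)$pivot[seq_len(qr(X2)$rank)], drop = FALSE]
  } else {
    tc <- samplewise_trend_covariate(agg, trend)
    sm <- aggregate_samples(agg) |> dplyr::left_join(tc, by = "sample")
    sm <- dplyr::filter(sm, is.finite(.data$T), .data$tau > 0)
    y <- sm$n_plus
    cov1 <- if (use_abundance) log(sm$tau) else sm$T
    Xs <- X[sm$sample, , drop = FALSE]
    X1 <- cbind(`(Intercept)` = 1, cov = cov1)
    X2 <- cbind(X1, log_depth = log(sm$tau), Xs[, -1, drop = FALSE])
    X2 <- X2[, qr(X2)$pivot[seq_len(qr(X2)$rank)], drop = FALSE]
  }
  null_fit <- fit_count_glm(y, matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)")),
                            family = "nb")
  fits <- list(trend_only = fit_count_glm(y, X1, family = "nb"),
               full = fit_count_glm(y, X2, family = "nb"))
  purrr::map_dfr(names(fits), function(nm) {
    f <- fits[[nm]]
    tibble(model = nm,
           pseudo_r2 = max(0, 1 - f$loglik / null_fit$loglik),
           aic = f$aic, loglik = f$loglik, loglik_null = null_fit$loglik,
           n = f$n, status = f$status)
  })
}

#' Sub-genus taxon replicability summary
#'
#' For each genus, the fraction of member taxa whose prevalence (fraction of
#' samples with count > 0) is at or below each cutoff; plus, per cutoff, the
#' study-level fraction of detected genera for which that taxon fraction
#' exceeds one half.
#'
#' @param counts Validated count tibble.
#' @param taxonomy Taxonomy tibble.
#' @param prevalence_cutoffs Default `c(0.10, 0.50)`.
#' @param rank,unassigned Aggregation rule (as in [aggregate_by_rank()]).
#' @return List with `per_genus` (tibble: `group`, `n_taxa`, `cutoff`,
#'   `fraction`) and `study` (tibble: `cutoff`,
#'   `fraction_genera_majority_low`).
#' @export
replicability_summary <- function(counts, taxonomy,
                                  prevalence_cutoffs = c(0.10, 0.50),
                                  rank = "genus", unassigned = "pool") {
  counts <- validate_counts(counts)
  taxonomy <- align_taxonomy(counts, taxonomy)
  sample_ids <- setdiff(names(counts), "taxon_id")
  if (length(sample_ids) < 2) abort("replicability needs at least 2 samples")
  grp <- taxonomy[[rank]]
  if (unassigned == "pool") {
    parent <- .ranks[max(match(rank, .ranks) - 1L, 1L)]
    un <- grp == "unassigned"
    grp[un] <- paste0("unassigned@", taxonomy[[parent]][un])
  }
  m <- as.matrix(counts[sample_ids])
  prev <- rowMeans(m > 0)
  detected <- prev > 0
  per_genus <- purrr::map_dfr(prevalence_cutoffs, function(cut) {
    tibble(group = grp[detected], prev = prev[detected]) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(n_taxa = dplyr::n(),
                       fraction = mean(.data$prev <= cut), .groups = "drop") |>
      dplyr::mutate(cutoff = cut)
  })
  study <- per_genus |>
    dplyr::group_by(.data$cutoff) |>
    dplyr::summarise(fraction_genera_majority_low = mean(.data$fraction > 0.5),
                     .groups = "drop")
  list(per_genus = dplyr::relocate(per_genus, "group", "n_taxa", "cutoff", "fraction"),
       study = study)
}
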