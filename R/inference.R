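# Shared GLM plumbing: Poisson / negative-binomial count regressions fitted
# by IRLS (stats::glm, MASS::glm.nb), with NB->Poisson fallback when the
# profiled dispersion is numerically zero.
fit_count_glm <- function(y, X, family = c("poisson", "nb"), offset = NULL,
                          maxit = 50, epsilon = 1e-8) {
  family <- match.arg(family)
  nm <- paste0("x", seq_len(ncol(X)))
  dat <- as.data.frame(X)
  names(dat) <- nm
  dat$.y <- y
  rhs <- paste(nm, collapse = " + ")
  if (!is.null(offset)) {
    dat$.off <- offset
    rhs <- paste0(rhs, " + offset(.off)")
  }
  fml <- as.formula(paste("`.y` ~ 0 +", rhs))
  status <- "ok"
  family_used <- family
  theta <- Inf
  fit <- NULL
  if (family == "nb") {
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(fml, data = dat,
                                    control = stats::glm.control(maxit = maxit, epsilon = epsilon))),
      error = function(e) NULL)
    if (!is.null(fit)) theta <- fit$theta
    if (is.null(fit) || !is.finite(theta) || 1 / theta < 1e-8) {
      if (!is.null(fit)) status <- "nb_dispersion_zero_poisson_fallback"
      else status <- "nb_failed_poisson_fallback"
      fit <- NULL
      family_used <- "poisson"
    }
  }
  if (is.null(fit)) {
    fit <- suppressWarnings(glm(fml, family = poisson(), data = dat,
                                control = list(maxit = maxit, epsilon = epsilon)))
    theta <- Inf
  }
  converged <- isTRUE(fit$converged)
  if (!converged && status == "ok") status <- "not_converged"
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  est_all <- coef(fit)  # keeps NA for aliased columns
  se <- setNames(rep(NA_real_, length(est_all)), names(est_all))
  se[rownames(co)] <- co[, 2]
  est <- est_all
  if (any(abs(est) > 15, na.rm = TRUE)) status <- paste0(status, ";possible_separation")
  names(est) <- names(se) <- colnames(X)
  list(estimate = est, se = se, vcov = vcov(fit),
       dispersion = if (is.finite(theta)) 1 / theta else 0,
       theta = theta, converged = converged, status = status,
       family = family_used, loglik = as.numeric(logLik(fit)),
       aic = AIC(fit), n = length(y), iter = fit$iter %||% NA_integer_,
       fitted = fit$fitted.values)
}

new_dr_fit <- function(fit, kind, trend_term = "trend", level = 0.95, extra = list()) {
  est <- fit$estimate; se <- fit$se
  zst <- est / se
  ci <- wald_ci(est, se, level)
  terms <- tibble(term = names(est), estimate = unname(est), se = unname(se),
                  statistic = unname(zst), p.value = 2 * pnorm(-abs(zst)),
                  conf.low = unname(ci$low), conf.high = unname(ci$high))
  structure(c(list(terms = terms, kind = kind, family = fit$family,
                   dispersion = fit$dispersion, converged = fit$converged,
                   status = fit$status, n = fit$n, loglik = fit$loglik,
                   aic = fit$aic, trend_term = trend_term, level = level),
              extra),
            class = "dr_fit")
}

#' Genus-specific differential richness
#'
#' Fits the genus-level model
#' \deqn{\log E[n_{gj}] = X_j^T \mu_g + \nu_g \hat f_t(g, \log y_{gj})}
#' by a Poisson log-linear GLM on the samples where the genus is detected
#' (\eqn{y_{gj} > 0}). By default the fitted technical trend enters as an
#' offset (\eqn{\nu_g} pinned at 1, its typical empirical value); setting
#' `offset_trend = FALSE` estimates \eqn{\nu_g} freely.
#'
#' @param agg A `genus_aggregate` tibble.
#' @param trend A `trend_fit` from [fit_trend()].
#' @param X Design matrix (see [design_matrix()]) or design tibble.
#' @param genus Genus (group) label to fit.
#' @param min_nonzero Minimum number of samples with the genus detected.
#' @param variance `"poisson"` (default for genus-specific fits) or `"nb"`.
#' @param offset_trend Pin \eqn{\nu_g = 1} by using the trend as an offset
#'   (default). A free coefficient (`offset_trend = FALSE`) is available, but
#'   its sampling error propagates into group contrasts in proportion to the
#'   genus's abundance difference, re-introducing abundance-aligned noise
#'   when the within-genus abundance spread is small.
#' @param use_genus_effect Evaluate the trend with the genus's retained
#'   effect (default) or with the abundance smooth only.
#' @param level Confidence level for Wald intervals.
#' @return A `dr_fit` object; see [tidy.dr_fit()] and [glance.dr_fit()].
#' @export
genus_differential_richness <- function(agg, trend, X, genus, min_nonzero = 5,
                                        variance = c("poisson", "nb"),
                                        offset_trend = TRUE,
                                        use_genus_effect = TRUE, level = 0.95) {
  variance <- match.arg(variance)
  d <- dplyr::filter(as_tibble(agg), .data$group == genus, .data$y > 0)
  if (nrow(d) < min_nonzero) {
    abort(paste0("genus '", genus, "' detected in ", nrow(d),
                 " samples; need at least ", min_nonzero))
  }
  X <- design_matrix(X)
  Xs <- X[d$sample, , drop = FALSE]
  if (qr(Xs)$rank < ncol(Xs)) {
    abort(paste0("design rank deficient on samples where genus '", genus, "' is detected"))
  }
  ft <- evaluate_trend(trend, if (use_genus_effect) genus else NULL, log(d$y))
  if (offset_trend) {
    fit <- fit_count_glm(d$n, Xs, family = variance, offset = ft)
  } else {
    fit <- fit_count_glm(d$n, cbind(Xs, trend = ft), family = variance)
  }
  new_dr_fit(fit, kind = "genus",
             extra = list(genus = genus, offset_trend = offset_trend,
                          nu = if (offset_trend) 1 else unname(fit$estimate["trend"])))
}

#' Genus-specific differential richness for many genera
#'
#' Maps [genus_differential_richness()] over genera, returning one long tidy
#' table with Benjamini-Hochberg adjustment within each coefficient family
#' (i.e. across genera, per term). Genera failing the detection threshold or
#' erroring are reported with `status` and NA estimates.
#'
#' @inheritParams genus_differential_richness
#' @param genera Genus labels; default all groups in `agg`.
#' @param ... Passed to [genus_differential_richness()].
#' @return Tibble: `group`, `term`, `estimate`, `se`, `statistic`, `p.value`,
#'   `p.adjust`, `conf.low`, `conf.high`, `nu`, `status`, `n`.
#' @export
genus_differential <- function(agg, trend, X, genera = NULL, min_nonzero = 5, ...) {
  genera <- genera %||% unique(as_tibble(agg)$group)
  rows <- purrr::map_dfr(genera, function(g) {
    res <- tryCatch(
      genus_differential_richness(agg, trend, X, g, min_nonzero = min_nonzero, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      return(tibble(group = g, term = NA_character_, estimate = NA_real_,
                    se = NA_real_, statistic = NA_real_, p.value = NA_real_,
                    conf.low = NA_real_, conf.high = NA_real_,
                    nu = NA_real_, status = conditionMessage(res), n = NA_integer_))
    }
    dplyr::mutate(res$terms, group = g, nu = res$nu %||% NA_real_,
                  status = res$status, n = res$n, .before = 1)
  })
  rows |>
    dplyr::group_by(.data$term) |>
    dplyr::mutate(p.adjust = ifelse(is.na(.data$term), NA_real_,
                                    p.adjust(.data$p.value, method = "BH")),
                  .after = "p.value") |>
    dplyr::ungroup()
}

# per-sample technical covariate: log sum over detected member genera of
# exp(f_t(g, log y_gj)); NA where no member genus is detected
samplewise_trend_covariate <- function(agg, trend, genus_set = NULL,
                                       use_genus_effect = TRUE) {
  d <- dplyr::filter(as_tibble(agg), .data$y > 0)
  if (!is.null(genus_set)) d <- dplyr::filter(d, .data$group %in% genus_set)
  d$ft <- evaluate_trend(trend, if (use_genus_effect) d$group else NULL, log(d$y))
  samples <- aggregate_samples(agg)$sample
  out <- d |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(T = log(sum(exp(.data$ft))), .groups = "drop")
  tibble(sample = samples) |> dplyr::left_join(out, by = "sample")
}

#' Sample-wide differential richness
#'
#' Fits the sample-wide model
#' \deqn{\log E[n_{+j}] = X_j^T \zeta + \gamma \log \sum_{g: y_{gj} > 0}
#' e^{\hat f_t(g, \log y_{gj})}}
#' with a negative-binomial variance function (ML dispersion), falling back
#' to Poisson when the dispersion is numerically zero. The response is total
#' observed richness per sample.
#'
#' @inheritParams genus_differential_richness
#' @param variance `"nb"` (default for sample-wide fits) or `"poisson"`.
#' @param offset_trend Pin \eqn{\gamma = 1}.
#' @return A `dr_fit`.
#' @export
samplewide_differential_richness <- function(agg, trend, X, variance = c("nb", "poisson"),
                                             offset_trend = FALSE,
                                             use_genus_effect = TRUE, level = 0.95) {
  variance <- match.arg(variance)
  collection_differential_richness(agg, trend, X, genus_set = NULL,
                                   variance = variance, offset_trend = offset_trend,
                                   use_genus_effect = use_genus_effect,
                                   level = level, .kind = "samplewide")
}

#' Differential richness for a collection of genera
#'
#' Fits the collection-level model: the response is the summed observed
#' richness over the collection's member genera, and the technical covariate
#' sums \eqn{e^{\hat f_t}} over the member genera detected in each sample.
#' With the full genus set this reduces exactly to the sample-wide model.
#'
#' @inheritParams samplewide_differential_richness
#' @param genus_set Character vector of member genera (`NULL` = all).
#' @param .kind Internal label.
#' @return A `dr_fit`.
#' @export
collection_differential_richness <- function(agg, trend, X, genus_set = NULL,
                                             variance = c("nb", "poisson"),
                                             offset_trend = FALSE,
                                             use_genus_effect = TRUE,
                                             level = 0.95, .kind = "collection") {
  variance <- match.arg(variance)
  agg <- as_tibble(agg)
  if (!is.null(genus_set)) {
    if (!length(genus_set)) abort("genus_set is empty")
    sub <- dplyr::filter(agg, .data$group %in% genus_set)
    if (!nrow(sub) || all(sub$y == 0)) abort("collection never detected in any sample")
  } else sub <- agg
  resp <- sub |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_k = sum(.data$n), .groups = "drop")
  tc <- samplewise_trend_covariate(agg, trend = trend, genus_set = genus_set,
                                   use_genus_effect = use_genus_effect)
  d <- dplyr::inner_join(resp, tc, by = "sample")
  drop_n <- sum(!is.finite(d$T))
  if (drop_n) {
    inform(paste0(drop_n, " sample(s) with no detected member genus dropped"))
    d <- dplyr::filter(d, is.finite(.data$T))
  }
  if (nrow(d) < 3) abort("too few samples with the collection detected")
  X <- design_matrix(X)
  Xs <- X[d$sample, , drop = FALSE]
  lv <- apply(Xs[, -1, drop = FALSE], 2, function(c) length(unique(c)))
  if (ncol(Xs) > 1 && any(lv < 2)) abort("a design column is constant on the usable samples")
  if (offset_trend) {
    fit <- fit_count_glm(d$n_k, Xs, family = variance, offset = d$T)
  } else {
    fit <- fit_count_glm(d$n_k, cbind(Xs, trend = d$T), family = variance)
  }
  new_dr_fit(fit, kind = .kind,
             extra = list(genus_set = genus_set, offset_trend = offset_trend,
                          gamma = if (offset_trend) 1 else unname(fit$estimate["trend"]),
                          samples = d$sample))
}

#' Inverse-variance weighted meta-regression of richness estimates
#'
#' Weighted least squares of (log-transformed) richness estimates on a design
#' matrix with fixed-effect weights \eqn{1/SE^2}; the coefficient covariance
#' is \eqn{(X^T W X)^{-1}} (known-variance convention). With the log
#' transform, SEs are mapped by the delta method (\eqn{SE/\widehat S}) so
#' coefficients are on the same natural-log fold-change scale as the GLMs.
#' Cells with non-finite or non-positive estimates or SEs are dropped and
#' counted.
#'
#' @param estimates,ses Numeric vectors, one entry per sample (aligned with
#'   the rows of `X`).
#' @param X Design matrix or design tibble.
#' @param log_transform Analyze `log(estimate)` (default `TRUE`).
#' @param level Confidence level.
#' @return A `dr_fit` (kind `"meta"`), with a `dropped` count.
#' @export
weighted_meta_regression <- function(estimates, ses, X, log_transform = TRUE,
                                     level = 0.95) {
  X <- design_matrix(X)
  stopifnot(length(estimates) == nrow(X), length(ses) == length(estimates))
  ok <- is.finite(estimates) & is.finite(ses) & ses > 0
  if (log_transform) ok <- ok & estimates > 0
  dropped <- sum(!ok)
  if (sum(ok) < ncol(X)) abort("too few usable cells for weighted regression")
  yv <- if (log_transform) log(estimates[ok]) else estimates[ok]
  sv <- if (log_transform) ses[ok] / estimates[ok] else ses[ok]
  Xs <- X[ok, , drop = FALSE]
  W <- 1 / sv^2
  XtWX <- crossprod(Xs, Xs * W)
  V <- tryCatch(chol2inv(chol(XtWX)), error = function(e) solve(XtWX))
  b <- drop(V %*% crossprod(Xs, yv * W))
  se <- sqrt(diag(V))
  fit <- list(estimate = setNames(b, colnames(X)), se = setNames(se, colnames(X)),
              vcov = V, dispersion = NA_real_, theta = NA_real_,
              converged = TRUE, status = "ok", family = "gaussian_wls",
              loglik = NA_real_, aic = NA_real_, n = sum(ok), fitted = drop(Xs %*% b))
  new_dr_fit(fit, kind = "meta", level = level,
             extra = list(dropped = dropped, log_transform = log_transform))
}

#' @export
print.dr_fit <- function(x, ...) {
  cat("<dr_fit>", x$kind, "|", x$family, "| n =", x$n,
      if (!is.na(x$dispersion)) paste("| dispersion =", signif(x$dispersion, 3)),
      "|", x$status, "\n")
  print(x$terms)
  invisible(x)
}

#' Tidy a differential richness fit
#'
#' @param x,object A `dr_fit`.
#' @param ... Unused.
#' @return `tidy`: per-term tibble (estimate on the natural-log fold-change
#'   scale, Wald SE/statistic/p, confidence interval). `glance`: one-row
#'   model summary (variance family, dispersion, convergence, n).
#' @export
tidy.dr_fit <- function(x, ...) x$terms

#' @rdname tidy.dr_fit
#' @export
glance.dr_fit <- function(x, ...) {
  tibble(kind = x$kind, family = x$family, dispersion = x$dispersion,
         converged = x$converged, status = x$status, n = x$n,
         loglik = x$loglik, aic = x$aic,
         trend_coef = x$nu %||% x$gamma %||% NA_real_)
}

#' Coefficient plot for a differential richness fit
#'
#' @param object A `dr_fit`.
#' @param ... Unused.
#' @export
autoplot.dr_fit <- function(object, ...) {
  ggplot2::ggplot(object$terms,
                  ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "log fold change", y = NULL) +
    ggplot2::theme_minimal()
}
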