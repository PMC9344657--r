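# Refit the spline trend on new data, keeping the original fit's knots,
# constraint basis, penalty and GCV-selected smoothing parameter fixed
# (lambda is treated as a tuning constant under resampling). Genus effects
# are re-estimated and re-filtered. `Om` may be precomputed.
spline_refit_core <- function(fit, x, z, g, Om = NULL, light = FALSE) {
  B <- bspline_eval(fit$knots, x)
  Bc <- B %*% fit$Z
  if (is.null(Om)) Om <- crossprod(fit$Z, bspline_penalty(fit$knots) %*% fit$Z)
  tab <- table(g)
  eligible <- intersect(fit$genus_effects$group,
                        names(tab)[tab >= (fit$min_points %||% 3)])
  m <- length(eligible)
  G <- NULL
  if (m >= 2L) {
    G <- matrix(0, length(z), m - 1L)
    for (i in seq_len(m - 1L)) G[g == eligible[i], i] <- 1
    G[g == eligible[m], ] <- -1
  }
  X <- cbind(1, Bc, G)
  pb <- ncol(Bc)
  D0 <- matrix(0, ncol(X), ncol(X))
  D0[1 + seq_len(pb), 1 + seq_len(pb)] <- Om
  M <- crossprod(X)
  A <- M + fit$lambda * D0
  Ainv <- tryCatch(chol2inv(chol(A)), error = function(e) solve(A))
  beta <- drop(Ainv %*% crossprod(X, z))
  rss <- sum((z - X %*% beta)^2)
  edf <- sum(Ainv * M)
  sigma2 <- rss / max(length(z) - edf, 1)
  V <- sigma2 * Ainv %*% M %*% Ainv
  out <- fit
  out$kappa <- beta[1]
  out$b_spline <- beta[1 + seq_len(pb)]
  out$V_kf <- V[c(1, 1 + seq_len(pb)), c(1, 1 + seq_len(pb)), drop = FALSE]
  out$sigma2 <- sigma2; out$edf <- edf; out$n <- length(z)
  if (!light) out$data <- tibble(group = g, log_y = x, z = z)
  if (m >= 2L) {
    gi <- 1 + pb + seq_len(m - 1L)
    L <- rbind(diag(m - 1L), rep(-1, m - 1L))
    eff <- drop(L %*% beta[gi])
    se <- sqrt(pmax(diag(L %*% V[gi, gi, drop = FALSE] %*% t(L)), 0))
    zs <- eff / se
    pv <- 2 * pnorm(-abs(zs))
    pa <- p.adjust(pv, "BH")
    ge <- list(group = eligible, estimate = eff, se = se, statistic = zs,
               p.value = pv, p.adjust = pa, retained = pa <= fit$alpha_G)
    out$genus_effects <- if (light) ge else as_tibble(ge)
  } else {
    out$genus_effects <- fit$genus_effects[0, ]
  }
  out
}

spline_refit <- function(fit, dat) {
  dat <- dplyr::filter(as_tibble(dat), .data$n >= 1)
  spline_refit_core(fit, log(dat$y), log(dat$n), as.character(dat$group))
}

refit_trend <- function(fit, dat) {
  if (fit$method == "spline") spline_refit(fit, dat)
  else fit_trend(dat, method = "loess", span = fit$span)
}

# lean NB fit (glm.fit + theta.ml, no formula/model.frame overhead) for the
# bootstrap loop; same ML target as MASS::glm.nb
fit_nb_fast <- function(y, X) {
  fp <- glm.fit(X, y, family = poisson())
  mu <- fp$fitted.values
  th <- tryCatch(suppressWarnings(MASS::theta.ml(y, mu, limit = 25)),
                 error = function(e) Inf)
  fit <- fp
  if (is.finite(th) && 1 / th >= 1e-8) {
    for (it in 1:4) {
      fam <- MASS::negative.binomial(theta = th)
      fit <- suppressWarnings(glm.fit(X, y, family = fam, mustart = mu))
      mu <- fit$fitted.values
      th_new <- tryCatch(suppressWarnings(MASS::theta.ml(y, mu, limit = 25)),
                         error = function(e) th)
      if (!is.finite(th_new)) break
      if (abs(th_new - th) < 1e-4 * th) { th <- th_new; break }
      th <- th_new
    }
  }
  R <- qr.R(fit$qr)
  cov <- chol2inv(R)
  list(estimate = setNames(fit$coefficients, colnames(X)),
       se = setNames(sqrt(diag(cov)), colnames(X)))
}

# fast evaluation used inside the bootstrap loop: kappa + f_R + retained effect
trend_eval_fast <- function(fit, g, x) {
  B <- bspline_eval(fit$knots, x) %*% fit$Z
  val <- fit$kappa + drop(B %*% fit$b_spline)
  ge <- fit$genus_effects
  if (length(ge$group) && any(ge$retained)) {
    idx <- match(g, ge$group)
    hit <- !is.na(idx) & ge$retained[pmax(idx, 1L)]
    val[hit] <- val[hit] + ge$estimate[idx[hit]]
  }
  val
}

#' Bootstrap-t confidence intervals for sample-wide or collection models
#'
#' Nonparametric bootstrap of samples, stratified by design cell (unique
#' design-matrix rows). Each resample refits the technical trend (with the
#' smoothing parameter fixed at the original GCV choice) and then the
#' count GLM; the studentized pivot \eqn{(\hat\beta^* - \hat\beta)/SE^*} uses
#' each refit's Wald SE, and the returned interval is the percentile-t
#' interval. This propagates uncertainty in the fitted trend into the
#' richness contrast.
#'
#' @param agg A `genus_aggregate` tibble.
#' @param X Design matrix or design tibble.
#' @param trend Optional pre-fitted `trend_fit` (spline method required for
#'   the fast resampling path); fitted from `agg` via `trend_args` if `NULL`.
#' @param genus_set `NULL` for the sample-wide model, else a collection.
#' @param B Number of bootstrap resamples (>= 199).
#' @param seed Integer seed; resampling is fully reproducible.
#' @param level Confidence level (default 0.95).
#' @param trend_args List of arguments for [fit_trend()].
#' @param variance Passed to the GLM (default `"nb"`).
#' @param max_fail Error out if more than this fraction of resample fits fail.
#' @return Tibble: `term`, `estimate`, `se`, `conf.low`, `conf.high`,
#'   `B_used`, `failures`, plus the original fit as attribute `"fit"`.
#' @export
bootstrap_t_ci <- function(agg, X, trend = NULL, genus_set = NULL, B = 199,
                           seed = 1L, level = 0.95, trend_args = list(),
                           variance = "nb", max_fail = 0.1) {
  if (B < 199) abort("B must be at least 199")
  agg <- as_tibble(agg)
  X <- design_matrix(X)
  samples <- rownames(X)
  cells <- apply(X, 1, paste, collapse = "\r")
  split_cells <- split(seq_along(samples), cells)
  if (any(lengths(split_cells) < 2)) {
    abort("bootstrap needs at least 2 samples per design cell")
  }
  trend <- trend %||% do.call(fit_trend, c(list(agg), trend_args))
  if (trend$method != "spline") abort("bootstrap_t_ci requires a spline trend fit")
  fit0 <- collection_differential_richness(agg, trend, X, genus_set = genus_set,
                                           variance = variance)
  est0 <- fit0$terms$estimate
  se0 <- fit0$terms$se
  terms <- fit0$terms$term

  # per-sample precomputed pieces, in the row order of X
  agg_s <- split(agg[c("group", "n", "y")], factor(agg$sample, levels = samples))
  fit_cells <- lapply(agg_s, function(d) {
    d <- d[d$n >= 1, ]
    list(g = as.character(d$group), x = log(d$y), z = log(d$n))
  })
  member <- lapply(agg_s, function(d) {
    if (!is.null(genus_set)) d <- d[d$group %in% genus_set, ]
    dd <- d[d$y > 0, ]
    list(g = as.character(dd$group), x = log(dd$y), resp = sum(d$n))
  })
  Om <- crossprod(trend$Z, bspline_penalty(trend$knots) %*% trend$Z)
  glm_family <- variance

  tmat <- matrix(NA_real_, B, length(terms))
  failures <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- unlist(lapply(split_cells, function(ii) sample(ii, length(ii), replace = TRUE)),
                    use.names = FALSE)
      res <- tryCatch({
        xs <- unlist(lapply(fit_cells[idx], `[[`, "x"), use.names = FALSE)
        zs <- unlist(lapply(fit_cells[idx], `[[`, "z"), use.names = FALSE)
        gs <- unlist(lapply(fit_cells[idx], `[[`, "g"), use.names = FALSE)
        tr_b <- spline_refit_core(trend, xs, zs, gs, Om = Om, light = TRUE)
        xm <- unlist(lapply(member[idx], `[[`, "x"), use.names = FALSE)
        gm <- unlist(lapply(member[idx], `[[`, "g"), use.names = FALSE)
        lens <- vapply(member[idx], function(m) length(m$x), integer(1))
        ft <- trend_eval_fast(tr_b, gm, xm)
        Tj <- log(drop(rowsum(exp(ft), rep(seq_along(idx), lens))))
        use <- which(lens > 0)
        yb <- vapply(member[idx], `[[`, numeric(1), "resp")[use]
        Xb <- cbind(X[idx[use], , drop = FALSE], trend = Tj)
        fb <- if (glm_family == "nb") fit_nb_fast(yb, Xb)
              else fit_count_glm(yb, Xb, family = glm_family)
        (fb$estimate - est0) / fb$se
      }, error = function(e) NULL)
      if (is.null(res) || any(!is.finite(res))) failures <- failures + 1L
      else tmat[b, ] <- res
    }
  })
  if (failures > max_fail * B) {
    abort(paste0("bootstrap failed in ", failures, " of ", B, " resamples"))
  }
  a <- (1 - level) / 2
  out <- purrr::map_dfr(seq_along(terms), function(j) {
    tj <- tmat[, j][is.finite(tmat[, j])]
    # (B+1)p order-statistic convention for bootstrap quantiles
    qs <- quantile(tj, c(1 - a, a), names = FALSE, type = 6)
    tibble(term = terms[j], estimate = est0[j], se = se0[j],
           conf.low = est0[j] - qs[1] * se0[j],
           conf.high = est0[j] - qs[2] * se0[j],
           B_used = length(tj), failures = failures)
  })
  attr(out, "fit") <- fit0
  out
}
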