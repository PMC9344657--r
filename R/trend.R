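#' Fit the technical taxa-accumulation trend
#'
#' Models the log of observed within-genus richness, \eqn{z_{gj} = \log
#' n_{gj}}, as an intercept plus a smooth function of log recovered abundance
#' plus genus fixed effects:
#' \deqn{z_{gj} = \kappa + f_R(\log y_{gj}) + f_G(g) + \epsilon_{gj}.}
#' The smooth is a cubic B-spline penalized by its integrated squared second
#' derivative, with the smoothing parameter chosen by generalized
#' cross-validation over a 40-point log-spaced grid (ties broken toward the
#' smoother fit). Genus effects are unpenalized under a sum-to-zero
#' constraint; each is tested against zero (Wald) and only effects surviving
#' Benjamini-Hochberg correction at `alpha_G` are retained in the evaluated
#' trend. Cells with zero observed richness are excluded (the response is a
#' log count of detected taxa).
#'
#' The fitted object is the abundance-dependent technical control
#' \eqn{\hat f_t(g, \log y) = \kappa + \hat f_R(\log y) + \hat f_G(g)} used
#' as a covariate by the differential-richness models.
#'
#' @param agg A `genus_aggregate` tibble (or any tibble with columns `group`,
#'   `n`, `y`).
#' @param method `"spline"` (default) or `"loess"`. The loess alternative
#'   fits one pooled smooth (a net average within-genus accumulation curve)
#'   with no genus effects.
#' @param min_points_per_genus Genera with fewer detected cells contribute to
#'   the smooth but receive no genus effect (default 3).
#' @param alpha_G BH level for retaining genus effects (default 0.05).
#' @param span Loess span (method = "loess" only), in (0, 1].
#' @param include_interaction Add per-genus linear-in-log-abundance deviation
#'   columns for diagnostics; they never enter the evaluated trend.
#' @param max_interior_knots Cap on interior knots placed at quantiles of the
#'   observed log abundances (default 30).
#' @return An object of class `trend_fit`.
#' @seealso [evaluate_trend()], [trend_to_json()]
#' @export
fit_trend <- function(agg, method = c("spline", "loess"),
                      min_points_per_genus = 3, alpha_G = 0.05,
                      span = 0.75, include_interaction = FALSE,
                      max_interior_knots = 30) {
  method <- match.arg(method)
  dat <- dplyr::filter(as_tibble(agg), .data$n >= 1)
  if (nrow(dat) < 10) abort("trend fitting needs at least 10 cells with detected richness")
  x <- log(dat$y)
  z <- log(dat$n)
  g <- as.character(dat$group)
  if (length(unique(x)) < 10) abort("trend fitting needs at least 10 distinct log-abundance values")
  if (method == "loess") {
    return(fit_trend_loess_impl(x, z, span))
  }
  fit_trend_spline_impl(x, z, g, min_points_per_genus, alpha_G,
                        include_interaction, max_interior_knots)
}

# ---- spline machinery -------------------------------------------------------

trend_knots <- function(x, max_interior = 30) {
  ux <- sort(unique(x))
  lo <- ux[1]; hi <- ux[length(ux)]
  n_int <- min(max_interior, max(2L, floor(length(ux) / 4)))
  probs <- seq(0, 1, length.out = n_int + 2L)[-c(1L, n_int + 2L)]
  interior <- unique(as.numeric(quantile(x, probs, type = 7)))
  interior <- interior[interior > lo & interior < hi]
  list(boundary = c(lo, hi), interior = interior,
       all = c(rep(lo, 4L), interior, rep(hi, 4L)))
}

bspline_eval <- function(knots, x, derivs = 0L) {
  lo <- knots$boundary[1]; hi <- knots$boundary[2]
  xc <- pmin(pmax(x, lo), hi)  # constant extrapolation outside the data range
  splines::splineDesign(knots$all, xc, ord = 4L,
                        derivs = rep(derivs, length(xc)), outer.ok = FALSE)
}

# exact integral of products of second derivatives: piecewise linear, so
# two-point Gauss-Legendre per inter-knot interval is exact
bspline_penalty <- function(knots) {
  brk <- unique(c(knots$boundary[1], knots$interior, knots$boundary[2]))
  p <- length(knots$interior) + 4L
  Om <- matrix(0, p, p)
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    h <- b - a
    if (h <= 0) next
    tq <- (a + b) / 2 + c(-1, 1) * h / (2 * sqrt(3))
    D2 <- splines::splineDesign(knots$all, tq, ord = 4L, derivs = c(2L, 2L))
    Om <- Om + (h / 2) * crossprod(D2)
  }
  Om
}

fit_trend_spline_impl <- function(x, z, g, min_points_per_genus, alpha_G,
                                  include_interaction, max_interior_knots) {
  n <- length(z)
  knots <- trend_knots(x, max_interior_knots)
  B <- bspline_eval(knots, x)
  p <- ncol(B)
  # remove the constant direction confounded with the intercept:
  # constrain sum_i f_R(x_i) = 0 and reparameterize through its null space
  C <- colSums(B)
  qrC <- qr(matrix(C, ncol = 1))
  Z <- qr.Q(qrC, complete = TRUE)[, -1, drop = FALSE]
  Bc <- B %*% Z
  Om <- crossprod(Z, bspline_penalty(knots) %*% Z)

  tab <- table(g)
  eligible <- names(tab)[tab >= min_points_per_genus]
  m <- length(eligible)
  G <- NULL
  if (m >= 2L) {
    G <- matrix(0, n, m - 1L, dimnames = list(NULL, eligible[-m]))
    for (i in seq_len(m - 1L)) G[g == eligible[i], i] <- 1
    G[g == eligible[m], ] <- -1
  }
  Xi <- NULL
  if (include_interaction && m >= 2L) {
    xc <- x - mean(x)
    Xi <- G * xc
    colnames(Xi) <- paste0("ix:", colnames(G))
  }
  X <- cbind(`(Intercept)` = 1, Bc, G, Xi)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    abort("trend design is rank deficient; too few points relative to genera/knots")
  }

  M <- crossprod(X)
  Xz <- crossprod(X, z)
  pb <- ncol(Bc)
  D0 <- matrix(0, ncol(X), ncol(X))
  D0[1 + seq_len(pb), 1 + seq_len(pb)] <- Om

  lam_scale <- sum(diag(M)[1 + seq_len(pb)]) / max(sum(diag(Om)), .Machine$double.eps)
  grid <- lam_scale * 10^seq(-4, 4, length.out = 40)
  gcv <- edf_g <- numeric(length(grid))
  for (k in seq_along(grid)) {
    A <- M + grid[k] * D0
    Ainv <- tryCatch(chol2inv(chol(A)), error = function(e) solve(A))
    edf <- sum(Ainv * M)  # tr(Ainv %*% M)
    beta <- Ainv %*% Xz
    rss <- sum((z - X %*% beta)^2)
    edf_g[k] <- edf
    gcv[k] <- n * rss / (n - edf)^2
  }
  best <- max(which(gcv <= min(gcv) + 1e-12))  # ties toward larger lambda
  lambda <- grid[best]
  A <- M + lambda * D0
  Ainv <- tryCatch(chol2inv(chol(A)), error = function(e) solve(A))
  beta <- drop(Ainv %*% Xz)
  fitted <- drop(X %*% beta)
  rss <- sum((z - fitted)^2)
  edf <- sum(Ainv * M)
  sigma2 <- rss / max(n - edf, 1)
  V <- sigma2 * Ainv %*% M %*% Ainv

  kappa <- beta[1]
  b_spl <- beta[1 + seq_len(pb)]
  V_kf <- V[c(1, 1 + seq_len(pb)), c(1, 1 + seq_len(pb)), drop = FALSE]

  genus_effects <- tibble(group = character(), estimate = numeric(),
                          se = numeric(), statistic = numeric(),
                          p.value = numeric(), p.adjust = numeric(),
                          retained = logical())
  if (m >= 2L) {
    gi <- 1 + pb + seq_len(m - 1L)
    bg <- beta[gi]
    L <- rbind(diag(m - 1L), rep(-1, m - 1L))
    eff <- drop(L %*% bg)
    Vg <- L %*% V[gi, gi, drop = FALSE] %*% t(L)
    se <- sqrt(pmax(diag(Vg), 0))
    zstat <- eff / se
    pval <- 2 * pnorm(-abs(zstat))
    padj <- p.adjust(pval, method = "BH")
    genus_effects <- tibble(group = eligible, estimate = eff, se = se,
                            statistic = zstat, p.value = pval,
                            p.adjust = padj, retained = padj <= alpha_G)
  }
  interaction_effects <- NULL
  if (!is.null(Xi)) {
    ii <- 1 + pb + (m - 1L) + seq_len(ncol(Xi))
    interaction_effects <- tibble(group = eligible[-m], slope_dev = beta[ii])
  }

  structure(list(
    method = "spline", kappa = kappa, knots = knots, Z = Z, b_spline = b_spl,
    V_kf = V_kf, genus_effects = genus_effects,
    interaction_effects = interaction_effects,
    lambda = lambda, sigma2 = sigma2, edf = edf, gcv = gcv[best],
    gcv_path = tibble(lambda = grid, gcv = gcv, edf = edf_g),
    alpha_G = alpha_G, min_points = min_points_per_genus,
    n = n, range = knots$boundary,
    data = tibble(group = g, log_y = x, z = z)
  ), class = "trend_fit")
}

fit_trend_loess_impl <- function(x, z, span) {
  stopifnot(span > 0, span <= 1)
  lo <- loess(z ~ x, span = span, degree = 2,
              control = stats::loess.control(surface = "direct"))
  grid_x <- seq(min(x), max(x), length.out = 200)
  pr <- predict(lo, newdata = data.frame(x = grid_x), se = TRUE)
  structure(list(
    method = "loess", kappa = 0, span = span,
    grid = tibble(log_y = grid_x, value = as.numeric(pr$fit),
                  se = as.numeric(pr$se.fit)),
    genus_effects = tibble(group = character(), estimate = numeric(),
                           se = numeric(), statistic = numeric(),
                           p.value = numeric(), p.adjust = numeric(),
                           retained = logical()),
    lambda = NA_real_, sigma2 = NA_real_, edf = NA_real_, gcv = NA_real_,
    n = length(x), range = range(x),
    data = tibble(group = NA_character_, log_y = x, z = z)
  ), class = "trend_fit")
}

#' Evaluate the fitted technical trend
#'
#' Returns \eqn{\hat f_t(g, \log y) = \kappa + \hat f_R(\log y) + \hat
#' f_G(g)}, where the genus effect is included only if it was BH-retained;
#' unseen genera (and all genera under the loess method) contribute 0.
#' Evaluation outside the observed log-abundance range clamps to the range
#' boundary (constant extrapolation).
#'
#' @param fit A `trend_fit`.
#' @param genus Character vector of genus labels (recycled against `log_y`);
#'   `NULL` for no genus contribution.
#' @param log_y Numeric log recovered abundances (natural log).
#' @param se Also return the pointwise SE of \eqn{\kappa + \hat f_R} (spline
#'   method) or of the loess curve.
#' @return Numeric vector, or a tibble with `value` and `se` when `se = TRUE`.
#' @export
evaluate_trend <- function(fit, genus = NULL, log_y, se = FALSE) {
  stopifnot(inherits(fit, "trend_fit"))
  if (any(!is.finite(log_y))) abort("log_y must be finite")
  if (fit$method == "spline") {
    B <- bspline_eval(fit$knots, log_y) %*% fit$Z
    base <- fit$kappa + drop(B %*% fit$b_spline)
    if (se) {
      Xe <- cbind(1, B)
      sev <- sqrt(pmax(rowSums((Xe %*% fit$V_kf) * Xe), 0))
    }
  } else {
    base <- approx(fit$grid$log_y, fit$grid$value, xout = log_y, rule = 2)$y
    if (se) sev <- approx(fit$grid$log_y, fit$grid$se, xout = log_y, rule = 2)$y
  }
  eff <- rep(0, length(log_y))
  if (!is.null(genus) && nrow(fit$genus_effects)) {
    genus <- rep_len(as.character(genus), length(log_y))
    ge <- fit$genus_effects
    idx <- match(genus, ge$group)
    hit <- !is.na(idx) & ge$retained[pmax(idx, 1L)]
    eff[hit] <- ge$estimate[idx[hit]]
  }
  val <- base + eff
  if (se) tibble(value = val, se = sev) else val
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit>", x$method, "| n =", x$n)
  if (x$method == "spline") {
    cat(" | lambda =", signif(x$lambda, 4), "| edf =", round(x$edf, 2),
        "| sigma2 =", signif(x$sigma2, 4),
        "\n  genus effects:", nrow(x$genus_effects), "tested,",
        sum(x$genus_effects$retained), "retained (BH <=", x$alpha_G, ")\n")
  } else cat(" | span =", x$span, "\n")
  invisible(x)
}

#' @rdname fit_trend
#' @param x,object A `trend_fit`.
#' @param ... Unused.
#' @export
tidy.trend_fit <- function(x, ...) x$genus_effects

#' @rdname fit_trend
#' @export
glance.trend_fit <- function(x, ...) {
  tibble(method = x$method, n = x$n, lambda = x$lambda, edf = x$edf,
         sigma2 = x$sigma2, gcv = x$gcv,
         n_genus_effects = nrow(x$genus_effects),
         n_retained = sum(x$genus_effects$retained))
}

#' Plot a fitted accumulation trend
#'
#' Scatter of log observed richness against log recovered abundance with the
#' fitted curve \eqn{\kappa + \hat f_R} overlaid.
#'
#' @param object A `trend_fit`.
#' @param ... Unused.
#' @export
autoplot.trend_fit <- function(object, ...) {
  grid_x <- seq(object$range[1], object$range[2], length.out = 200)
  curve <- tibble(log_y = grid_x, value = evaluate_trend(object, NULL, grid_x))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$log_y, y = .data$z)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.7) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$value),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "log recovered abundance", y = "log observed richness",
                  title = "Within-genus taxa accumulation trend") +
    ggplot2::theme_minimal()
}

# ---- serialization ----------------------------------------------------------

#' Serialize / restore a trend fit as JSON
#'
#' Stores knots, coefficients and the genus-effect table with full numeric
#' precision, so a restored fit evaluates identically.
#'
#' @param fit A `trend_fit`.
#' @param path Output (input) path.
#' @return `path` invisibly; `trend_from_json` returns a `trend_fit`.
#' @export
trend_to_json <- function(fit, path) {
  stopifnot(inherits(fit, "trend_fit"))
  obj <- unclass(fit)
  obj$data <- NULL
  obj$gcv_path <- NULL
  obj$genus_effects <- as.data.frame(fit$genus_effects)
  if (!is.null(obj$interaction_effects)) {
    obj$interaction_effects <- as.data.frame(obj$interaction_effects)
  }
  if (!is.null(obj$grid)) obj$grid <- as.data.frame(obj$grid)
  if (fit$method == "spline") {
    obj$Z <- as.list(as.data.frame(fit$Z))
    obj$V_kf <- as.list(as.data.frame(fit$V_kf))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname trend_to_json
#' @export
trend_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$genus_effects <- as_tibble(obj$genus_effects %||%
    tibble(group = character(), estimate = numeric(), se = numeric(),
           statistic = numeric(), p.value = numeric(), p.adjust = numeric(),
           retained = logical()))
  if (identical(obj$method, "spline")) {
    obj$Z <- do.call(cbind, lapply(obj$Z, as.numeric))
    obj$V_kf <- do.call(cbind, lapply(obj$V_kf, as.numeric))
    obj$knots$boundary <- as.numeric(obj$knots$boundary)
    obj$knots$interior <- as.numeric(obj$knots$interior)
    obj$knots$all <- as.numeric(obj$knots$all)
  } else {
    obj$grid <- as_tibble(obj$grid)
  }
  obj$range <- as.numeric(obj$range)
  structure(obj, class = "trend_fit")
}
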