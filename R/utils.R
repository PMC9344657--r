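#' @importFrom rlang %||% .data abort warn inform
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats coef glm loess lm model.matrix na.omit offset p.adjust
#'   pnorm poisson predict qnorm quantile rbinom rexp rlnorm rmultinom rnorm
#'   rpois runif sd setNames var approx cor cor.test logLik AIC vcov optim
#'   as.formula
#' @importFrom utils head modifyList
NULL

# Deterministic fan-out of one user seed into per-stage child seeds. Adding a
# new stage id never perturbs the streams of existing stages.
child_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  (as.integer(seed) %% 1000000L) * 2011L + (h %% 10007L) * 17L + as.integer(index)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

wald_ci <- function(estimate, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  list(low = estimate - z * se, high = estimate + z * se)
}
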