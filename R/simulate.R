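#' Configure a synthetic marker-gene survey
#'
#' Defines a two-group survey whose observed taxa are a mixture of true taxa
#' and spurious ("false") taxa generated at a rate increasing with the
#' genus's recovered abundance: \eqn{F_{gj} \sim
#' \mathrm{Poisson}(\alpha\, y_{gj}^{\beta})}. False-taxon reads are moved
#' from the genus's true taxa, so sample depth is conserved exactly.
#'
#' Defaults describe a survey of `G = 60` genera, 30 samples per group at
#' depth 5e4, with `alpha = 0.01`, `beta = 1`; per-genus true richness is
#' uniform on 10..40 and within-genus taxon abundances follow a geometric
#' profile (ratio 0.6) over a log-normal genus composition.
#'
#' @param G Number of genera.
#' @param n_per_group Samples per group (two groups, A and B).
#' @param depth Sample depth \eqn{\tau_j} (scalar).
#' @param depth_sd_log SD of log-normal depth variation around `depth`
#'   (0 = fixed depths).
#' @param richness_range Inclusive range the per-genus true richness is drawn
#'   from (uniformly).
#' @param profile `"geometric"` or `"even"` within-genus taxon profile.
#' @param profile_ratio Geometric ratio (ignored for `"even"`).
#' @param base_sd_log SD of the log-normal genus baseline composition.
#' @param abundance_lfc Per-genus log fold change (group B vs A) of genus
#'   relative abundance; scalar or length-`G` vector.
#' @param richness_lfc Per-genus log fold change of true richness in group B;
#'   scalar or length-`G`.
#' @param alpha,beta False-taxa mean-function parameters (\eqn{\alpha \ge 0},
#'   \eqn{\beta \ge 0}).
#' @param pool_size False-taxon identity pool size \eqn{M_g} per genus.
#' @param extra_size,extra_prob Each false taxon's count is
#'   `1 + Binomial(extra_size, extra_prob)` reads (before feasibility caps),
#'   keeping false taxa in the low-frequency regime.
#' @param conserve_reads Move reads from true taxa (default); `FALSE` creates
#'   false reads on top (depth no longer conserved) for sensitivity analysis.
#' @param seed Integer seed.
#' @return A `survey_config` list.
#' @export
survey_config <- function(G = 60, n_per_group = 30, depth = 5e4,
                          depth_sd_log = 0, richness_range = c(10, 40),
                          profile = c("geometric", "even"), profile_ratio = 0.6,
                          base_sd_log = 1, abundance_lfc = 0, richness_lfc = 0,
                          alpha = 0.01, beta = 1, pool_size = 1000,
                          extra_size = 3, extra_prob = 0.1,
                          conserve_reads = TRUE, seed = 1L) {
  profile <- match.arg(profile)
  stopifnot(alpha >= 0, beta >= 0, pool_size >= 1, G >= 2, n_per_group >= 2)
  structure(list(G = G, n_per_group = n_per_group, depth = depth,
                 depth_sd_log = depth_sd_log, richness_range = richness_range,
                 profile = profile, profile_ratio = profile_ratio,
                 base_sd_log = base_sd_log,
                 abundance_lfc = rep_len(abundance_lfc, G),
                 richness_lfc = rep_len(richness_lfc, G),
                 alpha = alpha, beta = beta, pool_size = pool_size,
                 extra_size = extra_size, extra_prob = extra_prob,
                 conserve_reads = conserve_reads, seed = as.integer(seed)),
            class = "survey_config")
}

#' Simulate a taxa-count survey with known truth
#'
#' Per sample: (1) true-taxon counts are one multinomial draw of size
#' \eqn{\tau_j} over all true taxa (group-adjusted genus composition times
#' the within-genus profile); (2) recovered genus abundances \eqn{y_{gj}}
#' are computed; (3) the number of false taxa is drawn as
#' \eqn{F_{gj} \sim \mathrm{Poisson}(\alpha y_{gj}^{\beta})}; (4) false-taxon
#' identities are drawn uniformly without replacement from the genus's pool;
#' (5) each false taxon receives at least one read taken from the genus's
#' true taxa, with total false reads capped at \eqn{y_{gj}/2} (infeasible
#' demand is truncated with a warning), so genus totals and sample depth are
#' conserved.
#'
#' @param config A [survey_config()].
#' @return A list of class `survey`: `counts` (tibble), `taxonomy` (tibble),
#'   `design` (tibble `sample_id`, `group`), `truth` (per-cell tibble with
#'   true detected richness, false-taxon count and `y`), `config`.
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  set.seed(config$seed)
  G <- config$G
  n <- 2L * config$n_per_group
  genus_ids <- sprintf("Genus%03d", seq_len(G))
  sample_ids <- sprintf("s%03d", seq_len(n))
  grp <- rep(c("A", "B"), each = config$n_per_group)

  n0 <- sample(config$richness_range[1]:config$richness_range[2], G, replace = TRUE)
  nB <- pmax(1L, as.integer(round(n0 * exp(config$richness_lfc))))
  n_max <- pmax(n0, nB)

  base <- rlnorm(G, 0, config$base_sd_log)
  pA <- base / sum(base)
  pBu <- base * exp(config$abundance_lfc)
  pB <- pBu / sum(pBu)

  profile_w <- function(k) {
    if (config$profile == "even") rep(1 / k, k)
    else {
      w <- config$profile_ratio^(seq_len(k) - 1)
      w / sum(w)
    }
  }

  true_ids <- unlist(lapply(seq_len(G), function(g)
    sprintf("%s_t%03d", genus_ids[g], seq_len(n_max[g]))), use.names = FALSE)
  taxon_genus <- rep(seq_len(G), n_max)
  # per-group probability vector over all true taxa
  probs_for <- function(active_n, p_genus) {
    pr <- numeric(length(true_ids))
    off <- c(0L, cumsum(n_max))
    for (g in seq_len(G)) {
      k <- active_n[g]
      w <- profile_w(k)
      pr[off[g] + seq_len(k)] <- p_genus[g] * w
    }
    pr
  }
  prA <- probs_for(n0, pA)
  prB <- probs_for(nB, pB)

  tau <- if (config$depth_sd_log > 0) {
    round(rlnorm(n, log(config$depth), config$depth_sd_log))
  } else rep(config$depth, n)

  M <- config$pool_size
  false_ids_all <- unlist(lapply(genus_ids, function(g)
    sprintf("%s_f%04d", g, seq_len(M))), use.names = FALSE)
  true_mat <- matrix(0, length(true_ids), n, dimnames = list(true_ids, sample_ids))
  false_mat <- matrix(0, length(false_ids_all), n,
                      dimnames = list(false_ids_all, sample_ids))
  truth_rows <- vector("list", n)
  truncated <- 0L
  off <- c(0L, cumsum(n_max))

  for (j in seq_len(n)) {
    pr <- if (grp[j] == "A") prA else prB
    cnt <- as.numeric(rmultinom(1, tau[j], pr))
    Fg <- integer(G); tdet <- integer(G); yg <- numeric(G)
    for (g in seq_len(G)) {
      ii <- off[g] + seq_len(n_max[g])
      y <- sum(cnt[ii])
      yg[g] <- y
      if (y == 0 || config$alpha == 0) { tdet[g] <- sum(cnt[ii] > 0); next }
      Fdraw <- rpois(1, config$alpha * y^config$beta)
      Fcap <- min(Fdraw, M, floor(y / 2))
      if (Fcap < Fdraw) truncated <- truncated + 1L
      if (Fcap > 0) {
        ids <- sample.int(M, Fcap)
        fc <- 1L + rbinom(Fcap, config$extra_size, config$extra_prob)
        # respect the feasibility cap on total reassigned reads
        budget <- floor(y / 2)
        while (sum(fc) > budget) fc[which.max(fc)] <- fc[which.max(fc)] - 1L
        if (config$conserve_reads) {
          pool <- rep.int(seq_len(n_max[g]), cnt[ii])
          rem <- if (length(pool) == 1L) pool else sample(pool, sum(fc))
          cnt[ii] <- cnt[ii] - tabulate(rem, nbins = n_max[g])
        }
        false_mat[(g - 1L) * M + ids, j] <- fc
        Fg[g] <- Fcap
      }
      tdet[g] <- sum(cnt[ii] > 0)
    }
    true_mat[, j] <- cnt
    truth_rows[[j]] <- tibble(sample = sample_ids[j], group = genus_ids,
                              y = yg, true_detected = tdet, n_false = Fg)
  }
  if (truncated > 0) warn(paste0("false-taxa demand truncated in ", truncated, " cells"))

  used_false <- rowSums(false_mat) > 0
  counts <- dplyr::bind_rows(
    dplyr::bind_cols(tibble(taxon_id = true_ids), as_tibble(true_mat)),
    dplyr::bind_cols(tibble(taxon_id = false_ids_all[used_false]),
                     as_tibble(false_mat[used_false, , drop = FALSE]))
  )
  tax_genus <- c(genus_ids[taxon_genus], genus_ids[(which(used_false) - 1L) %/% M + 1L])
  gidx <- match(tax_genus, genus_ids)
  taxonomy <- tibble(
    taxon_id = counts$taxon_id,
    kingdom = "Bacteria",
    phylum = sprintf("Phylum%02d", (gidx - 1L) %/% 10L + 1L),
    class = sprintf("Class%02d", (gidx - 1L) %/% 6L + 1L),
    order = sprintf("Order%02d", (gidx - 1L) %/% 4L + 1L),
    family = sprintf("Family%02d", (gidx - 1L) %/% 2L + 1L),
    genus = tax_genus
  )
  design <- tibble(sample_id = sample_ids, group = grp)
  truth <- dplyr::bind_rows(truth_rows)
  structure(list(counts = validate_counts(counts), taxonomy = taxonomy,
                 design = design, truth = truth, config = config,
                 true_richness = tibble(group = genus_ids, n_A = n0, n_B = nB)),
            class = "survey")
}

#' @export
print.survey <- function(x, ...) {
  cat("<survey>", x$config$G, "genera,", nrow(x$design), "samples, depth ~",
      format(x$config$depth, big.mark = ","), "| alpha =", x$config$alpha,
      "beta =", x$config$beta, "\n")
  invisible(x)
}

#' Aggregate a simulated survey to genus level
#'
#' @param survey A `survey`.
#' @param ... Passed to [aggregate_by_rank()].
#' @return A `genus_aggregate` tibble.
#' @export
survey_aggregate <- function(survey, ...) {
  aggregate_by_rank(survey$counts, survey$taxonomy, ...)
}

#' Design matrix of a simulated survey
#'
#' @param survey A `survey`.
#' @return Design matrix with intercept and `groupB` indicator.
#' @export
survey_design <- function(survey) design_matrix(survey$design)

#' Null-richness confounding scenario
#'
#' Convenience wrapper generating the scenario where true richness is equal
#' in both groups while genus abundances differ: any apparent richness
#' difference is purely technical. The abundance log-fold-change
#' distribution is `"heterogeneous"` (normal, mean 0, SD `log(4)/2`),
#' `"asymmetric"` (exponential, all positive, mean `log 2`), `"none"`, or a
#' user-supplied numeric vector.
#'
#' @param n_per_group,G,depth,alpha,beta,seed See [survey_config()].
#' @param lfc LFC distribution label or numeric vector.
#' @param ... Further arguments to [survey_config()].
#' @return A `survey` (its `config` records the drawn LFCs).
#' @export
null_richness_confounding_scenario <- function(n_per_group = 30, G = 60,
                                               depth = 5e4, alpha = 0.01,
                                               beta = 1, lfc = "heterogeneous",
                                               seed = 1L, ...) {
  if (is.character(lfc)) {
    lfc <- match.arg(lfc, c("heterogeneous", "symmetric", "asymmetric", "none"))
    lfc_vec <- with_seed(child_seed(seed, "lfc"), switch(lfc,
      heterogeneous = rnorm(G, 0, log(4) / 2),
      symmetric = rnorm(G, 0, log(4) / 2),
      asymmetric = rexp(G, rate = 1 / log(2)),
      none = rep(0, G)))
  } else lfc_vec <- rep_len(lfc, G)
  cfg <- survey_config(G = G, n_per_group = n_per_group, depth = depth,
                       alpha = alpha, beta = beta, abundance_lfc = lfc_vec,
                       richness_lfc = 0, seed = seed, ...)
  simulate_survey(cfg)
}
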