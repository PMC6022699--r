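#' Simulate two-sample GWAS summary statistics
#'
#' Generates two independent cohorts from the same configuration (sub-seeds
#' derived from the master seed) and computes per-SNP summary statistics by
#' simple regression: the exposure on dosage in the first cohort, the outcome
#' on dosage in the second. This mirrors the two-sample Mendelian
#' randomisation setting in which instrument-exposure and
#' instrument-outcome effects come from non-overlapping samples.
#'
#' @param config a [sim_config()] object (its `n_individuals` is ignored).
#' @param n_exposure_cohort,n_outcome_cohort sample sizes of the two cohorts.
#' @return List with elements `exposure` and `outcome`, each a GWAS summary
#'   `data.frame` with columns `variant, ea, oa, eaf, beta, se, info` (and a
#'   logical `monomorphic` flag; zero-variance SNPs are flagged, never
#'   silently dropped).
#' @export
simulate_two_sample_stats <- function(config,
                                      n_exposure_cohort = 10000L,
                                      n_outcome_cohort = 10000L) {
  stopifnot(inherits(config, "sim_config"))
  one <- function(n, sub, which) {
    cfg <- config
    cfg$n_individuals <- as.integer(n)
    cfg$seed <- derive_seed(config$seed, sub)
    cohort <- simulate_cohort(cfg)
    truth <- attr(cohort, "truth")
    trait <- if (which == "exposure") truth$exposure else truth$outcome
    g <- as.matrix(cohort[truth$snps])
    y <- cohort[[trait]]
    gc <- scale(g, scale = FALSE)
    denom <- colSums(gc^2)
    mono <- denom == 0
    beta <- se <- rep(NA_real_, ncol(g))
    yc <- y - mean(y)
    beta[!mono] <- colSums(gc[, !mono, drop = FALSE] * yc) / denom[!mono]
    rss <- sum(yc^2) - beta^2 * denom
    se[!mono] <- sqrt(rss[!mono] / (n - 2) / denom[!mono])
    data.frame(
      variant = truth$snps,
      ea = "A", oa = "G",
      eaf = colMeans(g) / 2,
      beta = beta, se = se, info = 1.0,
      monomorphic = mono,
      stringsAsFactors = FALSE
    )
  }
  list(
    exposure = one(n_exposure_cohort, "exposure_cohort", "exposure"),
    outcome = one(n_outcome_cohort, "outcome_cohort", "outcome")
  )
}

#' Simulate instrument-level summary statistics directly
#'
#' Draws per-SNP estimated effects from their sampling distributions:
#' \eqn{\hat\gamma_j \sim N(\gamma_j, se_\gamma^2)} and
#' \eqn{\hat\Gamma_j \sim N(\beta\gamma_j + \alpha_j, se_\Gamma^2)}.
#' This is the standard summary-level construction used to calibrate MR
#' estimators (type-I error of the Egger intercept, weighted-median
#' robustness) over many replicates without regenerating individual-level
#' cohorts.
#'
#' @param m number of instruments.
#' @param beta true causal effect.
#' @param gamma_range range of true instrument strengths (uniform draw).
#' @param alphas per-SNP direct (pleiotropic) outcome effects; scalar
#'   recycled.
#' @param se_gamma,se_outcome sampling SEs of the exposure and outcome
#'   associations (scalars or length-m).
#' @param seed integer seed.
#' @return An [instrument_set()].
#' @export
simulate_summary_instruments <- function(m = 30L,
                                         beta = 0.05,
                                         gamma_range = c(0.08, 0.20),
                                         alphas = 0,
                                         se_gamma = 0.005,
                                         se_outcome = 0.01,
                                         seed = 1L) {
  if (length(alphas) == 1L) alphas <- rep(alphas, m)
  stopifnot(length(alphas) == m)
  set.seed(derive_seed(seed, "summary"))
  gamma <- stats::runif(m, gamma_range[1], gamma_range[2])
  se_g <- rep_len(se_gamma, m)
  se_o <- rep_len(se_outcome, m)
  gamma_hat <- stats::rnorm(m, gamma, se_g)
  Gamma_hat <- stats::rnorm(m, beta * gamma + alphas, se_o)
  inst <- instrument_set(
    variant = sprintf("snp_%03d", seq_len(m)),
    beta_exposure = gamma_hat, se_exposure = se_g,
    beta_outcome = Gamma_hat, se_outcome = se_o,
    eaf = rep(0.3, m), info = rep(1.0, m)
  )
  attr(inst, "truth") <- list(beta = beta, gamma = gamma, alphas = alphas)
  inst
}
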