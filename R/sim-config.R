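#' Simulation configuration for synthetic cohorts
#'
#' Builds and validates the configuration object consumed by
#' [simulate_genotypes()], [simulate_cohort()] and
#' [simulate_two_sample_stats()]. The generative model is the standard
#' instrumental-variable structure: independent SNP dosages with additive
#' effects `gamma` on a blood-index exposure, a configurable causal effect
#' `causal_beta` of the exposure on a cognitive outcome, optional direct
#' (pleiotropic) SNP effects `pleiotropy_alphas` on the outcome, a shared
#' latent confounder with linear loadings on both traits, and demographic
#' covariates (age, sex, education, assessment centre) entering the outcome.
#'
#' Default effect scales are calibrated so that, at the default sample size,
#' the exposure and outcome have variance close to 1, instruments have
#' F-statistics well above 10, and covariates explain roughly 30% of
#' outcome variance — the regime a well-powered biobank-style analysis
#' assumes.
#'
#' @param n_individuals number of subjects.
#' @param m_snps number of independent instrument SNPs.
#' @param allele_freq_range length-2 numeric, effect-allele frequency range,
#'   strictly inside (0, 1).
#' @param gamma_effects per-SNP exposure effects (exposure units per effect
#'   allele); recycled scalar allowed. Default spreads effects over
#'   0.08–0.20.
#' @param causal_beta exposure-to-outcome causal effect (outcome units per
#'   exposure unit).
#' @param pleiotropy_alphas per-SNP direct outcome effects (outcome units per
#'   allele); default 0.
#' @param confounder_sd standard deviation of the latent confounder.
#' @param confounder_loading_exposure,confounder_loading_outcome linear
#'   loadings of the confounder on exposure and outcome.
#' @param noise_sd_exposure,noise_sd_outcome residual noise SDs.
#' @param age_effect,sex_effect,education_effect effects of the standardised
#'   covariates on the outcome.
#' @param centre_effects per-centre fixed effects (length defines the number
#'   of assessment centres).
#' @param disease_prevalence target prevalence used when disease labels are
#'   requested from the liability threshold model.
#' @param seed master integer seed; every stochastic component derives its
#'   own sub-seed from it.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_individuals = 2000L,
                       m_snps = 30L,
                       allele_freq_range = c(0.1, 0.5),
                       gamma_effects = NULL,
                       causal_beta = 0.05,
                       pleiotropy_alphas = 0,
                       confounder_sd = 1,
                       confounder_loading_exposure = 0.3,
                       confounder_loading_outcome = 0.3,
                       noise_sd_exposure = 0.81,
                       noise_sd_outcome = 0.84,
                       age_effect = -0.45,
                       sex_effect = 0.1,
                       education_effect = 0.3,
                       centre_effects = c(0, 0.02, -0.02, 0.01),
                       disease_prevalence = 0.10,
                       seed = 1L) {
  stopifnot_number(n_individuals, "n_individuals", lower = 1)
  stopifnot_number(m_snps, "m_snps", lower = 1)
  if (length(allele_freq_range) != 2L || any(!is.finite(allele_freq_range)) ||
      any(allele_freq_range <= 0) || any(allele_freq_range >= 1) ||
      allele_freq_range[1] > allele_freq_range[2]) {
    stop("'allele_freq_range' must be an ordered pair strictly inside (0, 1)",
         call. = FALSE)
  }
  if (is.null(gamma_effects)) {
    gamma_effects <- seq(0.08, 0.20, length.out = m_snps)
  }
  if (length(gamma_effects) == 1L) gamma_effects <- rep(gamma_effects, m_snps)
  if (length(pleiotropy_alphas) == 1L) {
    pleiotropy_alphas <- rep(pleiotropy_alphas, m_snps)
  }
  if (length(gamma_effects) != m_snps || length(pleiotropy_alphas) != m_snps) {
    stop("'gamma_effects' and 'pleiotropy_alphas' must have length m_snps",
         call. = FALSE)
  }
  for (nm in c("confounder_sd", "noise_sd_exposure", "noise_sd_outcome")) {
    stopifnot_number(get(nm), nm, lower = 0)
  }
  stopifnot_number(disease_prevalence, "disease_prevalence",
                   lower = 0, upper = 1, strict = TRUE)
  stopifnot_number(seed, "seed", lower = 0, upper = 2^31 - 1)

  structure(list(
    n_individuals = as.integer(n_individuals),
    m_snps = as.integer(m_snps),
    allele_freq_range = as.numeric(allele_freq_range),
    gamma_effects = as.numeric(gamma_effects),
    causal_beta = as.numeric(causal_beta),
    pleiotropy_alphas = as.numeric(pleiotropy_alphas),
    confounder_sd = as.numeric(confounder_sd),
    confounder_loading_exposure = as.numeric(confounder_loading_exposure),
    confounder_loading_outcome = as.numeric(confounder_loading_outcome),
    noise_sd_exposure = as.numeric(noise_sd_exposure),
    noise_sd_outcome = as.numeric(noise_sd_outcome),
    age_effect = as.numeric(age_effect),
    sex_effect = as.numeric(sex_effect),
    education_effect = as.numeric(education_effect),
    centre_effects = as.numeric(centre_effects),
    disease_prevalence = as.numeric(disease_prevalence),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d subjects, m = %d SNPs, eaf in [%.2f, %.2f]\n",
              x$n_individuals, x$m_snps,
              x$allele_freq_range[1], x$allele_freq_range[2]))
  cat(sprintf("  causal beta = %g; pleiotropic SNPs: %d; confounder loadings (%g, %g)\n",
              x$causal_beta, sum(x$pleiotropy_alphas != 0),
              x$confounder_loading_exposure, x$confounder_loading_outcome))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}
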