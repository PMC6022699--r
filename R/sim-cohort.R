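#' Simulate additive genotype dosages
#'
#' Draws an `n x m` matrix of independent biallelic dosages, column `j`
#' Binomial(2, f_j) with `f_j` uniform in `allele_freq_range` (or fixed
#' frequencies when supplied). No linkage disequilibrium is simulated:
#' instruments are modelled as independent validated loci.
#'
#' @param config a [sim_config()] object.
#' @param freqs optional vector of fixed allele frequencies (length
#'   `m_snps`), overriding the uniform draw.
#' @return Dosage matrix with columns `snp_001, ...` and attribute
#'   `"freq"` holding the generating allele frequencies.
#' @export
simulate_genotypes <- function(config, freqs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$m_snps
  set.seed(derive_seed(config$seed, "genotypes"))
  if (is.null(freqs)) {
    freqs <- stats::runif(m, config$allele_freq_range[1],
                          config$allele_freq_range[2])
  }
  if (length(freqs) != m || any(!is.finite(freqs)) ||
      any(freqs <= 0) || any(freqs >= 1)) {
    stop("allele frequencies must be finite and strictly inside (0, 1)",
         call. = FALSE)
  }
  g <- vapply(freqs, function(f) stats::rbinom(n, 2L, f), numeric(n))
  if (n == 1L) g <- matrix(g, nrow = 1L)
  colnames(g) <- sprintf("snp_%03d", seq_len(m))
  attr(g, "freq") <- freqs
  g
}

#' Simulate a cross-sectional cohort with known causal structure
#'
#' Generates one subject-level table with demographic covariates, genotype
#' dosages, a blood-index exposure and a cognitive outcome following
#' \deqn{x_i = \sum_j \gamma_j g_{ij} + \lambda_x c_i + \epsilon_{x,i}}
#' \deqn{y_i = \beta x_i + \sum_j \alpha_j g_{ij} + \lambda_y c_i +
#'       \mathrm{covariates}_i + \epsilon_{y,i}}
#' with `c_i` the latent confounder (retained in the output so tests can
#' condition on the truth). Disease labels, when requested, come from a
#' liability threshold on age + confounder + independent noise, with the
#' threshold set analytically for the configured prevalence.
#'
#' @param config a [sim_config()] object.
#' @param exposure_name,outcome_name column names for the simulated blood
#'   measure and cognitive outcome.
#' @param assign_disease if `TRUE`, label subjects `"case"`/`"control"` by
#'   the liability threshold model; otherwise `disease` is `"none"`.
#' @return A `data.frame` (one row per subject) with attribute `"truth"`
#'   carrying the generative parameters.
#' @export
simulate_cohort <- function(config,
                            exposure_name = "MCH",
                            outcome_name = "reasoning",
                            assign_disease = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  g <- simulate_genotypes(config)

  set.seed(derive_seed(config$seed, "covariates"))
  age <- stats::runif(n, 40, 70)
  sex <- stats::rbinom(n, 1L, 0.5)
  education <- sample(0:4, n, replace = TRUE)
  centre <- factor(sample(seq_along(config$centre_effects), n, replace = TRUE))

  set.seed(derive_seed(config$seed, "confounder"))
  conf <- stats::rnorm(n, 0, config$confounder_sd)

  set.seed(derive_seed(config$seed, "noise_exposure"))
  eps_x <- stats::rnorm(n, 0, config$noise_sd_exposure)
  set.seed(derive_seed(config$seed, "noise_outcome"))
  eps_y <- stats::rnorm(n, 0, config$noise_sd_outcome)

  x <- drop(g %*% config$gamma_effects) +
    config$confounder_loading_exposure * conf + eps_x

  age_z <- (age - 55) / (30 / sqrt(12))  # uniform(40,70) standardisation
  edu_z <- (education - 2) / stats::sd(0:4)
  cov_term <- config$age_effect * age_z +
    config$sex_effect * sex +
    config$education_effect * edu_z +
    config$centre_effects[as.integer(centre)]

  y <- config$causal_beta * x + drop(g %*% config$pleiotropy_alphas) +
    config$confounder_loading_outcome * conf + cov_term + eps_y

  disease <- rep("none", n)
  if (assign_disease) {
    set.seed(derive_seed(config$seed, "liability"))
    liab <- 0.3 * age_z + 0.2 * conf + stats::rnorm(n)
    sd_liab <- sqrt(0.3^2 + (0.2 * config$confounder_sd)^2 + 1)
    thr <- stats::qnorm(1 - config$disease_prevalence, sd = sd_liab)
    disease <- ifelse(liab > thr, "case", "control")
  }

  out <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    age = age, sex = sex, education = education, centre = centre,
    confounder = conf,
    disease = disease,
    stringsAsFactors = FALSE
  )
  out[[exposure_name]] <- x
  out[[outcome_name]] <- y
  out <- cbind(out, as.data.frame(g))
  attr(out, "truth") <- list(
    gamma = config$gamma_effects, alpha = config$pleiotropy_alphas,
    beta = config$causal_beta,
    lambda = c(exposure = config$confounder_loading_exposure,
               outcome = config$confounder_loading_outcome),
    freq = attr(g, "freq"),
    exposure = exposure_name, outcome = outcome_name,
    snps = colnames(g)
  )
  out
}

#' Simulate a multi-measure, multi-outcome screening cohort
#'
#' Produces the null (or sparsely planted) grid the association screen is
#' validated on: independent standardised blood measures, cognitive outcomes
#' driven by the demographic covariates plus optional planted
#' measure-to-outcome effects, residual noise scaled so each outcome has
#' variance close to 1 (planted betas are therefore approximately
#' standardised effects).
#'
#' @param n subjects.
#' @param measures,outcomes character vectors of column names to generate.
#' @param planted optional data.frame with columns `measure`, `outcome`,
#'   `beta` giving planted effects; all other cells are null.
#' @param noise_sd residual outcome noise SD.
#' @param seed integer seed.
#' @return A cohort `data.frame` with covariates, measures and outcomes.
#' @export
simulate_screen_cohort <- function(n,
                                   measures = sprintf("blood_%02d", 1:10),
                                   outcomes = sprintf("cog_%d", 1:5),
                                   planted = NULL,
                                   noise_sd = 0.84,
                                   seed = 1L) {
  set.seed(derive_seed(seed, "covariates"))
  age <- stats::runif(n, 40, 70)
  sex <- stats::rbinom(n, 1L, 0.5)
  education <- sample(0:4, n, replace = TRUE)
  centre <- factor(sample(1:4, n, replace = TRUE))
  age_z <- (age - 55) / (30 / sqrt(12))
  edu_z <- (education - 2) / stats::sd(0:4)
  cov_term <- -0.45 * age_z + 0.1 * sex + 0.3 * edu_z +
    c(0, 0.02, -0.02, 0.01)[as.integer(centre)]

  set.seed(derive_seed(seed, "measures"))
  X <- matrix(stats::rnorm(n * length(measures)), n,
              dimnames = list(NULL, measures))

  set.seed(derive_seed(seed, "noise_outcome"))
  Y <- matrix(stats::rnorm(n * length(outcomes), 0, noise_sd), n,
              dimnames = list(NULL, outcomes)) + cov_term
  if (!is.null(planted)) {
    for (k in seq_len(nrow(planted))) {
      pm <- as.character(planted$measure[k])
      po <- as.character(planted$outcome[k])
      if (!pm %in% measures || !po %in% outcomes) {
        stop("planted effect refers to an unknown measure or outcome")
      }
      Y[, po] <- Y[, po] + planted$beta[k] * X[, pm]
    }
  }
  data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    age = age, sex = sex, education = education, centre = centre,
    X, Y, stringsAsFactors = FALSE
  )
}
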