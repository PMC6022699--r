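# Shared fixture builders; everything is generated in code at test time.

# Small hand-specified instrument set used by estimator unit tests.
fixture_instruments <- function(m = 5, seed = 42) {
  set.seed(seed)
  gamma <- runif(m, 0.05, 0.2)
  instrument_set(
    variant = sprintf("rs%03d", seq_len(m)),
    ea = "A", oa = "G",
    eaf = runif(m, 0.1, 0.5),
    info = 1,
    beta_exposure = gamma,
    se_exposure = runif(m, 0.004, 0.01),
    beta_outcome = 0.05 * gamma + rnorm(m, 0, 0.01),
    se_outcome = runif(m, 0.008, 0.015)
  )
}

# Independent WLS oracle computed via lm()'s QR route: origin-constrained
# for IVW, two-parameter for Egger. Fixed-effect SEs are the model SEs
# rescaled by the residual standard deviation.
oracle_wls <- function(inst, intercept = FALSE) {
  g <- inst$beta_exposure
  G <- inst$beta_outcome
  if (intercept) {
    flip <- ifelse(g < 0, -1, 1)
    g <- g * flip; G <- G * flip
  }
  w <- 1 / inst$se_outcome^2
  fit <- if (intercept) lm(G ~ g, weights = w) else lm(G ~ 0 + g, weights = w)
  sm <- summary(fit)
  coefs <- coef(fit)
  se_fixed <- sm$coefficients[, 2] / sm$sigma
  list(coef = coefs, se = se_fixed)
}

# GWAS summary table fixture for harmonisation tests.
fixture_gwas <- function(variants, ea, oa, beta, se = 0.01, eaf = 0.3,
                         info = 1) {
  data.frame(variant = variants, ea = ea, oa = oa, eaf = eaf,
             beta = beta, se = se, info = info, stringsAsFactors = FALSE)
}
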