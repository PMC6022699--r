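test_that("Wald ratios follow the ratio and delta-method formulas", {
  inst <- instrument_set("rs1", beta_exposure = 0.1, se_exposure = 0.01,
                         beta_outcome = 0.02, se_outcome = 0.004)
  wr <- wald_ratios(inst)
  expect_equal(wr$ratio, 0.2)
  expect_equal(wr$se, 0.04)

  inst0 <- instrument_set("rs1", beta_exposure = 0.1, se_exposure = 0.01,
                          beta_outcome = 0, se_outcome = 0.004)
  expect_equal(wald_ratios(inst0)$ratio, 0)

  # second-order delta method adds the exposure-uncertainty term
  wr2 <- wald_ratios(inst, second_order = TRUE)
  expect_equal(wr2$se,
               sqrt(0.004^2 / 0.1^2 + 0.02^2 * 0.01^2 / 0.1^4))
  # zero exposure effect excluded with warning
  inst2 <- instrument_set(c("a", "b"),
                          beta_exposure = c(0, 0.1), se_exposure = 0.01,
                          beta_outcome = c(0.1, 0.02), se_outcome = 0.004)
  expect_warning(wrz <- wald_ratios(inst2), "zero exposure")
  expect_equal(nrow(wrz), 1L)
})

test_that("IVW collapses to the Wald ratio for one instrument and averages equal weights", {
  one <- instrument_set("rs1", beta_exposure = 0.1, se_exposure = 0.01,
                        beta_outcome = 0.02, se_outcome = 0.004)
  fit <- mr_ivw(one)
  expect_identical(fit$beta, 0.02 / 0.1)
  expect_identical(fit$se, 0.004 / 0.1)

  two <- instrument_set(c("a", "b"),
                        beta_exposure = c(0.1, 0.1), se_exposure = 0.01,
                        beta_outcome = c(0.02, 0.04), se_outcome = 0.005)
  expect_equal(mr_ivw(two)$beta, 0.3)
})

test_that("IVW and Egger match independent QR-based WLS oracles", {
  for (seed in c(1, 7, 23, 99)) {
    inst <- fixture_instruments(m = 8, seed = seed)
    ivw <- mr_ivw(inst)
    oi <- oracle_wls(inst, intercept = FALSE)
    expect_equal(ivw$beta, unname(oi$coef), tolerance = 1e-12)
    expect_equal(ivw$se, unname(oi$se), tolerance = 1e-12)

    egg <- mr_egger(inst)
    oe <- oracle_wls(inst, intercept = TRUE)
    expect_equal(egg$intercept, unname(oe$coef[1]), tolerance = 1e-12)
    expect_equal(egg$beta, unname(oe$coef[2]), tolerance = 1e-12)
    expect_equal(egg$intercept_se, unname(oe$se[1]), tolerance = 1e-12)
    expect_equal(egg$se, unname(oe$se[2]), tolerance = 1e-12)
  }
})

test_that("Egger recovers an exact line and rejects collinear instruments", {
  g <- c(0.05, 0.1, 0.15, 0.2)
  inst <- instrument_set(paste0("rs", 1:4),
                         beta_exposure = g, se_exposure = 0.01,
                         beta_outcome = 0.01 + 0.05 * g, se_outcome = 0.01)
  fit <- mr_egger(inst)
  expect_equal(fit$intercept, 0.01, tolerance = 1e-12)
  expect_equal(fit$beta, 0.05, tolerance = 1e-12)

  coll <- instrument_set(paste0("rs", 1:3),
                         beta_exposure = c(0.1, 0.1, 0.1),
                         se_exposure = 0.01,
                         beta_outcome = c(0.01, 0.02, 0.03),
                         se_outcome = 0.01)
  expect_error(mr_egger(coll), "collinear")
})

test_that("weighted median interpolates the cumulative weight at one half", {
  inst <- instrument_set(paste0("rs", 1:3),
                         beta_exposure = c(0.1, 0.1, 0.1),
                         se_exposure = 0.01,
                         beta_outcome = c(0.01, 0.02, 0.09),
                         se_outcome = 0.01)
  fit <- mr_weighted_median(inst, n_boot = 200, seed = 4)
  expect_equal(fit$beta, 0.2)  # middle order statistic under equal weights

  same <- instrument_set(paste0("rs", 1:4),
                         beta_exposure = 0.1, se_exposure = 0.01,
                         beta_outcome = 0.03, se_outcome = 0.01)
  expect_equal(mr_weighted_median(same, n_boot = 200, seed = 1)$beta, 0.3)
  expect_error(mr_weighted_median(inst[1:2, ], n_boot = 100, seed = 1),
               "at least 3")
})

test_that("weighted median resists 30% invalid instruments where IVW does not", {
  inst <- simulate_summary_instruments(
    m = 10, beta = 0.05, gamma_range = c(0.08, 0.12),
    alphas = c(rep(0, 7), rep(0.05, 3)),
    se_gamma = 0.005, se_outcome = 0.005, seed = 17)
  med <- mr_weighted_median(inst, n_boot = 200, seed = 17)
  ivw <- mr_ivw(inst)
  expect_lt(abs(med$beta - 0.05), 0.1)
  expect_gt(ivw$beta, med$beta)  # pulled upward by directional pleiotropy
})

test_that("estimates are invariant to instrument order and equivariant to exposure units", {
  inst <- fixture_instruments(m = 9, seed = 5)
  perm <- inst[sample(nrow(inst)), ]
  class(perm) <- class(inst)
  expect_equal(mr_ivw(perm)$beta, mr_ivw(inst)$beta, tolerance = 1e-14)
  expect_equal(mr_egger(perm)$beta, mr_egger(inst)$beta, tolerance = 1e-14)

  k <- 3.7  # exposure rescaled by k: gamma scales by k, estimates by 1/k
  scaled <- instrument_set(inst$variant,
                           beta_exposure = k * inst$beta_exposure,
                           se_exposure = k * inst$se_exposure,
                           beta_outcome = inst$beta_outcome,
                           se_outcome = inst$se_outcome)
  expect_equal(mr_ivw(scaled)$beta, mr_ivw(inst)$beta / k, tolerance = 1e-12)
  expect_equal(mr_egger(scaled)$beta, mr_egger(inst)$beta / k,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(scaled, n_boot = 100, seed = 2)$beta,
               mr_weighted_median(inst, n_boot = 100, seed = 2)$beta / k,
               tolerance = 1e-12)
})

test_that("one-sample per-SNP associations recover the generative effects", {
  cfg <- sim_config(n_individuals = 20000, m_snps = 30, causal_beta = 0.05,
                    seed = 1)
  co <- simulate_cohort(cfg)
  truth <- attr(co, "truth")
  inst <- estimate_snp_associations(co, "MCH", "reasoning")
  # gamma estimates near truth
  expect_lt(max(abs(inst$beta_exposure - truth$gamma) / inst$se_exposure), 4.5)
  # with no pleiotropy the IVW slope through the origin recovers beta
  # (per-replicate SD of the estimate is ~0.016 at this problem size)
  expect_lt(abs(mr_ivw(inst)$beta - 0.05), 0.05)

  # exposure driven by a single SNP with no noise: gamma exact
  cfg0 <- sim_config(n_individuals = 500, m_snps = 1, gamma_effects = 0.1,
                     confounder_loading_exposure = 0, noise_sd_exposure = 0,
                     seed = 2)
  co0 <- simulate_cohort(cfg0)
  inst0 <- estimate_snp_associations(co0, "MCH", "reasoning")
  expect_equal(inst0$beta_exposure, 0.1, tolerance = 1e-10)

  cfg1 <- sim_config(n_individuals = 500, m_snps = 3, seed = 2)
  co1 <- simulate_cohort(cfg1)
  co1$snp_002 <- 1  # monomorphic column dropped with warning
  expect_warning(instm <- estimate_snp_associations(co1, "MCH", "reasoning"),
                 "monomorphic")
  expect_equal(nrow(instm), 2L)
})

test_that("instrument filtering applies info, exclusion-list and region rules", {
  inst <- instrument_set(sprintf("rs%d", 1:10),
                         beta_exposure = 0.1, se_exposure = 0.01,
                         beta_outcome = 0.005, se_outcome = 0.01,
                         info = c(rep(1, 8), 0.85, 0.95),
                         chrom = "19",
                         pos = c(1:7 * 1000, 45409000, 45410000, 45411000))
  # info 0.85 removed, 0.95 kept
  f1 <- suppressMessages(filter_instruments(inst, info_min = 0.9))
  expect_equal(nrow(f1), 9L)

  # APOE/TOMM40-style excluded region, 0-based half-open
  region <- data.frame(chrom = "19", start = 45409000, end = 45411000)
  f2 <- suppressMessages(
    filter_instruments(inst, excluded_regions = region))
  expect_false(any(c("rs8", "rs9") %in% f2$variant))
  expect_true("rs10" %in% f2$variant)  # end is exclusive

  f3 <- suppressMessages(
    filter_instruments(inst, exclusion_list = c("rs1", "rs2")))
  expect_equal(attr(f3, "removed")[["exclusion_list"]], 2)

  expect_error(
    suppressMessages(filter_instruments(inst, info_min = 1.1)),
    "dominant criterion: info")
  # identity when nothing triggers
  all_good <- suppressMessages(filter_instruments(inst[1:8, ]))
  expect_equal(nrow(all_good), 8L)
})

test_that("harmonisation aligns alleles, flips swapped effects and drops palindromes", {
  exp_tab <- fixture_gwas(sprintf("rs%d", 1:10),
                          ea = c(rep("A", 8), "A", "C"),
                          oa = c(rep("G", 8), "T", "G"),
                          beta = seq(0.05, 0.14, by = 0.01))
  out_tab <- exp_tab
  out_tab$beta <- 0.02
  # same alleles: identity join
  h1 <- suppressMessages(harmonise(exp_tab[1:8, ], out_tab[1:8, ]))
  expect_equal(nrow(h1), 8L)
  expect_equal(h1$beta_outcome, rep(0.02, 8))

  # swapped alleles in the outcome table: sign flip
  sw <- out_tab[1:8, ]
  sw$ea <- "G"; sw$oa <- "A"; sw$eaf <- 0.7
  h2 <- suppressMessages(harmonise(exp_tab[1:8, ], sw))
  expect_equal(h2$beta_outcome, rep(-0.02, 8))

  # 2 palindromic of 10 shared -> 8 retained
  h3 <- suppressMessages(harmonise(exp_tab, out_tab))
  expect_equal(nrow(h3), 8L)
  expect_setequal(attr(h3, "drops")$reason, "palindromic")

  # incompatible allele pair dropped with reason
  bad <- out_tab[1:8, ]
  bad$ea[3] <- "T"
  h4 <- suppressMessages(harmonise(exp_tab[1:8, ], bad))
  expect_equal(nrow(h4), 7L)
  expect_true("allele_mismatch" %in% attr(h4, "drops")$reason)
})

test_that("run_mr returns requested fits with per-SNP diagnostics and per-method errors", {
  inst <- fixture_instruments(m = 10, seed = 12)
  res <- run_mr(inst, n_boot = 200, seed = 3)
  expect_named(res$fits, c("ivw", "weighted_median", "egger"))
  expect_equal(nrow(res$diagnostics), 10L)
  expect_true(all(c("ratio", "se", "weight") %in% names(res$diagnostics)))

  single <- run_mr(inst, methods = "ivw")
  expect_named(single$fits, "ivw")

  # per-method failure (too few SNPs for median/egger) doesn't kill the rest
  small <- inst[1:2, ]; class(small) <- class(inst)
  res2 <- run_mr(small, n_boot = 100, seed = 1)
  expect_true("ivw" %in% names(res2$fits))
  expect_true(all(c("weighted_median", "egger") %in% names(res2$errors)))

  tab <- as.data.frame(res)
  expect_equal(tab$method, c("ivw", "weighted_median", "egger"))
  expect_true(all(tab$ci_low <= tab$beta & tab$beta <= tab$ci_high))
})

test_that("two-stage least squares agrees with IVW on a clean simulation", {
  cfg <- sim_config(n_individuals = 5000, m_snps = 10, causal_beta = 0.08,
                    seed = 41)
  co <- simulate_cohort(cfg)
  tsls <- mr_tsls(co, "MCH", "reasoning")
  inst <- estimate_snp_associations(co, "MCH", "reasoning")
  ivw <- mr_ivw(inst)
  expect_equal(tsls$beta, ivw$beta, tolerance = 0.05)
  expect_equal(tsls$method, "tsls")
})
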