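test_that("residualisation removes technical variation and only that", {
  set.seed(3)
  n <- 500
  device <- rbinom(n, 1, 0.5)
  noise <- rnorm(n, 0, 0.5)
  cohort <- data.frame(measure = 2 * device + noise,
                       device = device,
                       constant_cov = 1)
  # constant technical covariate: residual = measure - mean
  r0 <- suppressWarnings(residualise_measure(cohort, "measure", "constant_cov"))
  expect_equal(r0, cohort$measure - mean(cohort$measure), tolerance = 1e-12)
  # measure exactly linear in device
  cohort$linear <- 3 * cohort$device + 1
  expect_equal(residualise_measure(cohort, "linear", "device"),
               rep(0, n), tolerance = 1e-10)
  # residual variance equals the generative noise variance within 5%
  r <- residualise_measure(cohort, "measure", "device")
  expect_equal(var(r), var(noise), tolerance = 0.05)
  expect_equal(mean(r), 0, tolerance = 1e-12)

  cohort$flat <- 5
  expect_error(residualise_measure(cohort, "flat", "device"), "constant")
  # aliased technical column dropped with warning
  cohort$device2 <- cohort$device
  expect_warning(residualise_measure(cohort, "measure",
                                     c("device", "device2")),
                 "aliased")
})

test_that("outcome transforms match their definitions", {
  expect_equal(transform_outcome(1000, "reaction_time"), log(1000))
  expect_equal(transform_outcome(c(5, 7), "continuous"), c(5, 7))
  expect_equal(transform_outcome(0, "visual_memory"), 0)  # ln(0 + 1)
  expect_message(
    out <- transform_outcome(c(100, -1, 50), "reaction_time"),
    "excluded 1")
  expect_true(is.na(out[2]))
  expect_error(transform_outcome(-2, "visual_memory"), "non-negative")
})

test_that("fit_association recovers planted and exact effects", {
  # noiseless outcome: beta exact, p -> 0
  n <- 200
  cohort <- data.frame(age = runif(n, 61, 80), sex = rbinom(n, 1, 0.5),
                       education = sample(0:4, n, TRUE),
                       centre = factor(sample(1:3, n, TRUE)),
                       measure = rnorm(n))
  cohort$outcome <- 0.5 * cohort$measure
  # lm warns that a zero-residual fit makes its summary unreliable; the
  # exactness of the coefficient is the point here
  fit <- suppressWarnings(fit_association(cohort, "measure", "outcome"))
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_lt(fit$p, 1e-100)

  # planted standardised effect recovered within its sampling band
  co <- simulate_screen_cohort(
    10000, planted = data.frame(measure = "blood_01", outcome = "cog_1",
                                beta = 0.04), seed = 11)
  fit2 <- fit_association(co, "blood_01", "cog_1", age_min = 0)
  expect_gt(fit2$beta, 0.03)
  expect_lt(fit2$beta, 0.05)

  # age filter is strict
  expect_true(all(fit_association(co, "blood_01", "cog_1",
                                  age_min = 60)$n_used < nrow(co)))

  # binary outcome uses the logistic link
  co$binary_out <- rbinom(nrow(co), 1, plogis(0.5 * co$blood_02))
  fitb <- fit_association(co, "blood_02", "binary_out", age_min = 0,
                          outcome_kind = "binary")
  expect_equal(fitb$beta, 0.5, tolerance = 0.15)
  co$oneclass <- 1
  expect_error(fit_association(co, "blood_02", "oneclass", age_min = 0,
                               outcome_kind = "binary"), "single class")
})

test_that("BH adjustment over the screen grid follows the step-up rule", {
  co <- simulate_screen_cohort(400, measures = c("m1", "m2"),
                               outcomes = c("o1", "o2"), seed = 5)
  sc <- run_screen(co, c("m1", "m2"), c("o1", "o2"), age_min = 0)
  expect_equal(sc$p_adj, p.adjust(sc$p, "BH"))
  expect_true(all(sc$p_adj >= sc$p))

  # hand-computed BH: p (0.01, 0.02, 0.03, 0.04) -> all 0.04
  # (step-up: p_(i) * 4 / i = 0.04 at every rank after cumulative minima)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))

  # single test: p_adj = p; all p = 1 stays 1
  sc1 <- run_screen(co, "m1", "o1", age_min = 0)
  expect_equal(sc1$p_adj, sc1$p)

  # per-fit failures become flagged rows, not aborts
  co$flat <- 1
  sc2 <- run_screen(co, c("m1", "flat"), "o1", age_min = 0)
  expect_equal(nrow(sc2), 2L)
  expect_true(any(nzchar(sc2$note)))
})

test_that("residualise-then-regress equals the joint fit under orthogonality", {
  # technical covariate constructed orthogonal to the model covariates
  set.seed(8)
  n <- 400
  cohort <- data.frame(age = runif(n, 61, 80), sex = rbinom(n, 1, 0.5),
                       education = sample(0:4, n, TRUE),
                       centre = factor(sample(1:2, n, TRUE)))
  Z <- model.matrix(~ age + sex + education + centre, cohort)
  tech_raw <- rnorm(n)
  cohort$device <- qr.resid(qr(Z), tech_raw)  # orthogonal by construction
  cohort$measure <- rnorm(n) + 0.5 * cohort$device
  cohort$outcome <- 0.3 * cohort$measure + rnorm(n)

  two_stage <- fit_association(cohort, "measure", "outcome", age_min = 0,
                               technical_covariates = "device")
  joint <- fit_association(cohort, "measure", "outcome",
                           covariates = c("age", "sex", "education",
                                          "centre", "device"),
                           age_min = 0)
  # the measure coefficient on the residualised scale matches the joint fit
  expect_equal(two_stage$beta, joint$beta, tolerance = 1e-8)
})

test_that("anaemia classification reproduces the NICE rule with strict thresholds", {
  grid <- expand.grid(HGB = c(12.0, 12.5, 13.0), sex = c(1, 0))
  got <- classify_anaemia(grid)
  # males (sex 1): < 13 anaemic; females: < 12 anaemic
  expect_equal(got, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  grid$HGB[1] <- NA
  expect_message(got2 <- classify_anaemia(grid), "missing HGB")
  expect_true(is.na(got2[1]))
})

test_that("case-control matching pairs within sex and caliper without reuse", {
  # controls identical in age/sex: perfect pairing
  cases <- data.frame(disease = "case", age = c(70, 75), sex = c(1, 0))
  ctrls <- data.frame(disease = "control", age = c(70, 75), sex = c(1, 0))
  m <- match_case_control(rbind(cases, ctrls), seed = 2)
  expect_equal(nrow(m), 4L)
  expect_equal(attr(m, "age_differences"), c(0, 0))

  # one case, one same-sex control 2 years apart, caliper 5: matched
  d <- data.frame(disease = c("case", "control"), age = c(70, 72),
                  sex = c(1, 1))
  m2 <- match_case_control(d, caliper = 5, seed = 1)
  expect_equal(nrow(m2), 2L)

  # cross-sex or out-of-caliper controls are never used
  d3 <- data.frame(disease = c("case", "control", "control"),
                   age = c(70, 70, 80), sex = c(1, 0, 1))
  expect_error(match_case_control(d3, seed = 1), "no case could be matched")

  # larger simulated cohort: no control reused, no cross-sex pair,
  # paper-style n: every matched case contributes exactly 2 rows
  cfg <- sim_config(n_individuals = 4000, seed = 19)
  co <- simulate_cohort(cfg, assign_disease = TRUE)
  mm <- match_case_control(co, case_label = "case", seed = 5)
  expect_equal(nrow(mm) %% 2, 0)
  ctrl_rows <- mm[mm$disease != "case", ]
  expect_false(any(duplicated(ctrl_rows$subject_id)))
  for (pid in unique(mm$pair_id)) {
    pair <- mm[mm$pair_id == pid, ]
    expect_equal(pair$sex[1], pair$sex[2])
    expect_lte(abs(pair$age[1] - pair$age[2]), 2)
  }
})
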