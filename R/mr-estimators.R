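#' @title Mendelian randomisation estimators
#' @description Wald ratios, inverse-variance weighted (IVW), weighted
#'   median and MR-Egger causal-effect estimators operating on an
#'   [instrument_set()]. All report the causal effect in outcome units per
#'   exposure unit, 95% confidence limits (z = 1.959964) and a two-sided
#'   p-value.
#' @name mr_estimators
NULL

new_mr_fit <- function(method, beta, se, n_snps,
                       intercept = NULL, intercept_se = NULL,
                       p = NULL, intercept_p = NULL) {
  if (is.null(p)) p <- two_sided_p(beta / se)
  fit <- list(
    method = method,
    beta = beta, se = se,
    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
    p = p,
    intercept = intercept, intercept_se = intercept_se,
    intercept_p = intercept_p,
    n_snps = n_snps
  )
  class(fit) <- "mr_fit"
  fit
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("MR fit (%s, %d SNPs)\n", x$method, x$n_snps))
  cat(sprintf("  beta = %.4f [%.4f, %.4f], se = %.4f, p = %.3g\n",
              x$beta, x$ci_low, x$ci_high, x$se, x$p))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.4f (se %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' Per-SNP Wald ratio estimates
#'
#' The ratio estimate for SNP j is the outcome regression coefficient
#' divided by the exposure coefficient, \eqn{\beta_j = \Gamma_j / \gamma_j}.
#' Its standard error uses the first-order delta method
#' \eqn{se(\Gamma_j)/|\gamma_j|} by default; `second_order = TRUE` adds the
#' exposure-uncertainty term
#' \eqn{\sqrt{se_\Gamma^2/\gamma^2 + \Gamma^2 se_\gamma^2 / \gamma^4}}.
#'
#' @param instruments an [instrument_set()].
#' @param second_order use the second-order delta-method SE.
#' @return data.frame `variant, ratio, se, weight` (weight = 1/se^2). SNPs
#'   with a zero exposure effect are excluded with a warning.
#' @export
wald_ratios <- function(instruments, second_order = FALSE) {
  stopifnot(inherits(instruments, "instrument_set"))
  zero <- instruments$beta_exposure == 0
  if (any(zero)) {
    warning(sprintf("excluding %d SNP(s) with zero exposure effect",
                    sum(zero)))
    instruments <- instruments[!zero, , drop = FALSE]
  }
  if (nrow(instruments) == 0L) stop("no usable instruments", call. = FALSE)
  g <- instruments$beta_exposure
  G <- instruments$beta_outcome
  ratio <- G / g
  se <- if (second_order) {
    sqrt(instruments$se_outcome^2 / g^2 +
           G^2 * instruments$se_exposure^2 / g^4)
  } else {
    instruments$se_outcome / abs(g)
  }
  data.frame(variant = instruments$variant, ratio = ratio, se = se,
             weight = 1 / se^2, stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimator
#'
#' Weighted average of the per-SNP Wald ratios with weights `1/se_j^2`
#' (first-order SEs), algebraically identical to weighted least squares of
#' outcome effects on exposure effects through the origin with weights
#' `se_outcome^-2`. Fixed-effect by default: `se = (sum w_j)^{-1/2}`.
#' `random_effects = TRUE` applies the multiplicative random-effects
#' inflation `max(1, sigma)` from the weighted residual dispersion.
#'
#' @param instruments an [instrument_set()] (one instrument allowed; the
#'   fit then equals the Wald ratio).
#' @param random_effects multiplicative random-effects SE inflation.
#' @return An `mr_fit`.
#' @export
mr_ivw <- function(instruments, random_effects = FALSE) {
  wr <- wald_ratios(instruments)
  w <- wr$weight
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("non-finite or non-positive weights", call. = FALSE)
  }
  m <- nrow(wr)
  if (m == 1L) {
    # single instrument: the IVW estimate is the Wald ratio identically
    return(new_mr_fit("ivw", wr$ratio, wr$se, 1L))
  }
  beta <- sum(w * wr$ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  if (random_effects && m > 1L) {
    sigma2 <- sum(w * (wr$ratio - beta)^2) / (m - 1)
    se <- se * sqrt(max(1, sigma2))
  }
  new_mr_fit("ivw", beta, se, m)
}

weighted_median_estimate <- function(ratio, weight) {
  ord <- order(ratio)
  b <- ratio[ord]
  w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Weighted median of the per-SNP ratio estimates: with cumulative
#' normalised weights \eqn{s_j = (\sum_{k \le j} w_k - w_j/2)/\sum w_k} over
#' ratio-sorted SNPs, the estimate interpolates linearly where `s` crosses
#' 0.5. Consistent when at least half of the total weight comes from valid
#' instruments. The standard error is estimated by parametric bootstrap,
#' resampling the per-SNP exposure and outcome effects from their normal
#' sampling distributions.
#'
#' @param instruments an [instrument_set()] with at least 3 SNPs.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed for the bootstrap (required for
#'   reproducibility).
#' @return An `mr_fit`.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(instruments, "instrument_set"))
  if (nrow(instruments) < 3L) {
    stop("weighted median requires at least 3 instruments", call. = FALSE)
  }
  wr <- wald_ratios(instruments)
  if (any(!is.finite(wr$weight))) stop("non-finite weights", call. = FALSE)
  beta <- weighted_median_estimate(wr$ratio, wr$weight)

  m <- nrow(instruments)
  set.seed(derive_seed(seed, "boot"))
  boots <- vapply(seq_len(n_boot), function(b) {
    g <- stats::rnorm(m, instruments$beta_exposure, instruments$se_exposure)
    G <- stats::rnorm(m, instruments$beta_outcome, instruments$se_outcome)
    ok <- g != 0
    ratio <- G[ok] / g[ok]
    se <- instruments$se_outcome[ok] / abs(g[ok])
    weighted_median_estimate(ratio, 1 / se^2)
  }, numeric(1))
  se <- stats::sd(boots)
  new_mr_fit("weighted_median", beta, se, m)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a
#' free intercept, weights `se_outcome^-2`, after orienting all instruments
#' to positive exposure effects (both signs flipped where needed). The
#' slope is the causal estimate (valid under the InSIDE assumption); a
#' non-zero intercept indicates directional pleiotropy. Fixed-effect
#' standard errors from the weighted normal equations by default;
#' `random_effects = TRUE` applies multiplicative inflation `max(1, sigma)`,
#' and `df_t = TRUE` uses a t reference distribution with m - 2 degrees of
#' freedom instead of the normal.
#'
#' @param instruments an [instrument_set()] with at least 3 SNPs.
#' @param random_effects multiplicative random-effects SE inflation.
#' @param df_t use t(m - 2) p-values instead of normal.
#' @return An `mr_fit` with `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(instruments, random_effects = FALSE, df_t = FALSE) {
  stopifnot(inherits(instruments, "instrument_set"))
  m <- nrow(instruments)
  if (m < 3L) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  flip <- sign(instruments$beta_exposure)
  flip[flip == 0] <- 1
  g <- instruments$beta_exposure * flip
  G <- instruments$beta_outcome * flip
  if (stats::sd(g) == 0) {
    stop("instrument strengths collinear", call. = FALSE)
  }
  w <- 1 / instruments$se_outcome^2
  X <- cbind(intercept = 1, slope = g)
  XtWX <- crossprod(X, w * X)
  theta <- drop(solve(XtWX, crossprod(X, w * G)))
  V <- solve(XtWX)
  if (random_effects) {
    resid <- G - drop(X %*% theta)
    sigma2 <- sum(w * resid^2) / (m - 2)
    V <- V * max(1, sigma2)
  }
  se <- sqrt(diag(V))
  pfun <- if (df_t) {
    function(z) 2 * stats::pt(-abs(z), df = m - 2)
  } else {
    two_sided_p
  }
  new_mr_fit("egger",
             beta = theta[["slope"]], se = se[["slope"]], n_snps = m,
             p = pfun(theta[["slope"]] / se[["slope"]]),
             intercept = theta[["intercept"]],
             intercept_se = se[["intercept"]],
             intercept_p = pfun(theta[["intercept"]] / se[["intercept"]]))
}

#' Individual-level two-stage least squares
#'
#' Optional estimator for one-sample MR at the individual level: stage one
#' regresses the exposure on all instrument dosages (plus covariates),
#' stage two regresses the outcome on the fitted exposure (plus
#' covariates). Offered alongside the summary-level estimators; note the
#' weighted median is a different estimator despite sometimes being
#' described together with two-stage least squares.
#'
#' @param cohort cohort data.frame with dosage columns.
#' @param exposure,outcome column names.
#' @param covariates covariate column names.
#' @param snps dosage column names.
#' @return An `mr_fit` (method `"tsls"`).
#' @export
mr_tsls <- function(cohort, exposure, outcome,
                    covariates = c("age", "sex", "education", "centre"),
                    snps = grep("^snp_", names(cohort), value = TRUE)) {
  rhs1 <- c(snps, covariates)
  stage1 <- stats::lm(stats::reformulate(rhs1, response = exposure),
                      data = cohort)
  cohort$.fitted_exposure <- stats::fitted(stage1)
  rhs2 <- c(".fitted_exposure", covariates)
  stage2 <- stats::lm(stats::reformulate(rhs2, response = outcome),
                      data = cohort)
  sm <- summary(stage2)$coefficients
  new_mr_fit("tsls",
             beta = sm[".fitted_exposure", 1],
             se = sm[".fitted_exposure", 2],
             n_snps = length(snps))
}

#' Run a set of MR estimators with diagnostics
#'
#' Applies the requested estimators to a filtered instrument set and
#' returns the fits together with a per-SNP diagnostics table (ratio
#' estimates, SEs and weights) for funnel-style symmetry checks. Failures
#' of individual methods are caught and reported per method; the remaining
#' fits are still returned.
#'
#' @param instruments an [instrument_set()].
#' @param methods subset of `c("ivw", "weighted_median", "egger")`.
#' @param n_boot,seed weighted-median bootstrap controls.
#' @param random_effects passed to [mr_ivw()] and [mr_egger()].
#' @return List of class `"mr_results"`: `fits` (named list of `mr_fit` or
#'   `try-error` messages), `diagnostics` (per-SNP table), `errors`.
#' @export
run_mr <- function(instruments,
                   methods = c("ivw", "weighted_median", "egger"),
                   n_boot = 1000L, seed = 1L, random_effects = FALSE) {
  methods <- match.arg(methods, c("ivw", "weighted_median", "egger"),
                       several.ok = TRUE)
  fits <- list()
  errors <- list()
  for (mth in methods) {
    res <- tryCatch(switch(mth,
      ivw = mr_ivw(instruments, random_effects = random_effects),
      weighted_median = mr_weighted_median(instruments, n_boot = n_boot,
                                           seed = seed),
      egger = mr_egger(instruments, random_effects = random_effects)
    ), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[mth]] <- conditionMessage(res)
    } else {
      fits[[mth]] <- res
    }
  }
  diagnostics <- tryCatch(wald_ratios(instruments), error = function(e) NULL)
  structure(list(fits = fits, diagnostics = diagnostics, errors = errors),
            class = "mr_results")
}

#' Tabulate MR fits
#'
#' @param x an `"mr_results"` object from [run_mr()].
#' @param ... unused.
#' @return data.frame with one row per fitted method (beta, CI, p, and the
#'   Egger intercept columns where applicable).
#' @export
as.data.frame.mr_results <- function(x, ...) {
  rows <- lapply(x$fits, function(f) {
    data.frame(method = f$method, n_snps = f$n_snps,
               beta = f$beta, se = f$se,
               ci_low = f$ci_low, ci_high = f$ci_high, p = f$p,
               intercept = f$intercept %||% NA_real_,
               intercept_se = f$intercept_se %||% NA_real_,
               intercept_p = f$intercept_p %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mr_results <- function(x, ...) {
  cat("Mendelian randomisation results\n")
  for (f in x$fits) print(f)
  if (length(x$errors)) {
    for (nm in names(x$errors)) {
      cat(sprintf("  %s: failed (%s)\n", nm, x$errors[[nm]]))
    }
  }
  invisible(x)
}
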