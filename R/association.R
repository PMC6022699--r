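#' Residualise a blood measure on technical covariates
#'
#' Returns the measure minus its least-squares fit on technical covariates
#' (e.g. analyser device and acquisition route), so that technical
#' variation is removed without entering the cognitive model itself.
#' Residuals have zero mean. Aliased (rank-deficient) technical columns are
#' dropped with a warning; a constant measure is an error.
#'
#' @param cohort data.frame.
#' @param measure numeric measure column name.
#' @param technical_covariates character vector of technical covariate
#'   column names.
#' @return Numeric residual vector (NA where inputs are missing).
#' @export
residualise_measure <- function(cohort, measure, technical_covariates) {
  y <- cohort[[measure]]
  if (!is.numeric(y)) stop("'", measure, "' must be numeric", call. = FALSE)
  if (stats::sd(y, na.rm = TRUE) == 0) {
    stop("'", measure, "' is constant; nothing to residualise", call. = FALSE)
  }
  miss <- setdiff(technical_covariates, names(cohort))
  if (length(miss)) {
    stop("missing technical covariates: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(technical_covariates, response = measure),
                   data = cohort, na.action = stats::na.exclude)
  if (anyNA(stats::coef(fit))) {
    warning("rank-deficient technical design; aliased columns dropped: ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  }
  unname(stats::resid(fit))
}

#' Transform a cognitive outcome for modelling
#'
#' Applies the outcome-specific transform used for the cognitive tests:
#' natural log for mean reaction time (non-positive values excluded, set to
#' NA with a message of the count), `log(count + 1)` for visual-memory
#' mismatch counts (the offset admits zero mismatches), identity for the
#' remaining outcomes. Binary outcomes (prospective memory) pass through
#' and are modelled with a logistic link downstream.
#'
#' @param values numeric outcome vector.
#' @param outcome_kind one of `"continuous"`, `"reaction_time"`,
#'   `"visual_memory"`, `"binary"`.
#' @param offset offset added before the visual-memory log.
#' @return Transformed numeric vector.
#' @export
transform_outcome <- function(values,
                              outcome_kind = c("continuous", "reaction_time",
                                               "visual_memory", "binary"),
                              offset = 1) {
  outcome_kind <- match.arg(outcome_kind)
  switch(outcome_kind,
    reaction_time = {
      bad <- !is.na(values) & values <= 0
      if (any(bad)) {
        message(sprintf("transform_outcome: excluded %d non-positive reaction times",
                        sum(bad)))
        values[bad] <- NA_real_
      }
      log(values)
    },
    visual_memory = {
      if (any(values < 0, na.rm = TRUE)) {
        stop("visual-memory counts must be non-negative", call. = FALSE)
      }
      log(values + offset)
    },
    values
  )
}

#' Fit one blood-measure / cognitive-outcome association
#'
#' General linear model with the (transformed) cognitive test as outcome and
#' the (optionally residualised) blood measure as the main exposure,
#' adjusted for age, sex, education and assessment centre, on subjects
#' above `age_min`. Continuous outcomes use ordinary least squares; binary
#' outcomes (prospective memory) a logistic GLM. Complete cases per fit.
#'
#' @param cohort data.frame.
#' @param blood_measure,outcome column names.
#' @param covariates covariate column names.
#' @param age_min retain subjects with age strictly greater (0 disables).
#' @param outcome_kind passed to [transform_outcome()].
#' @param technical_covariates optional; when given the measure is first
#'   residualised with [residualise_measure()].
#' @return One-row data.frame: `blood_measure, outcome, beta, se, p,
#'   n_used`.
#' @export
fit_association <- function(cohort, blood_measure, outcome,
                            covariates = c("age", "sex", "education",
                                           "centre"),
                            age_min = 60,
                            outcome_kind = "continuous",
                            technical_covariates = NULL) {
  if (!is.null(technical_covariates)) {
    cohort[[blood_measure]] <-
      residualise_measure(cohort, blood_measure, technical_covariates)
  }
  cohort[[outcome]] <- transform_outcome(cohort[[outcome]], outcome_kind)
  dat <- cohort[cohort$age > age_min, , drop = FALSE]
  vars <- c(outcome, blood_measure, covariates)
  dat <- dat[stats::complete.cases(dat[vars]), vars, drop = FALSE]
  fml <- stats::reformulate(c(blood_measure, covariates), response = outcome)
  if (outcome_kind == "binary") {
    classes <- unique(dat[[outcome]])
    if (length(classes) < 2L) {
      stop("binary outcome has a single class", call. = FALSE)
    }
    fit <- stats::glm(fml, data = dat, family = stats::binomial())
  } else {
    fit <- stats::lm(fml, data = dat)
  }
  if (nrow(dat) <= length(stats::coef(fit))) {
    stop("fewer rows than parameters", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  if (!blood_measure %in% rownames(sm)) {
    stop("blood measure aliased in the design", call. = FALSE)
  }
  data.frame(
    blood_measure = blood_measure, outcome = outcome,
    beta = sm[blood_measure, 1], se = sm[blood_measure, 2],
    p = sm[blood_measure, 4], n_used = nrow(dat),
    stringsAsFactors = FALSE
  )
}

#' Run the blood-measure by cognitive-outcome association screen
#'
#' Fits every measure-outcome pair with [fit_association()] and applies
#' Benjamini-Hochberg adjustment across all raw p-values of the grid (the
#' global Table-1-shaped family). Per-fit errors become flagged rows (NA
#' estimates with the message in `note`) rather than aborting the screen.
#'
#' @param cohort data.frame.
#' @param blood_measures,outcomes character vectors of column names.
#' @param covariates covariate column names.
#' @param outcome_kinds optional named character vector mapping outcome
#'   names to kinds (default `"continuous"`).
#' @param age_min,technical_covariates passed to [fit_association()].
#' @return data.frame of class `"association_screen"` with columns
#'   `blood_measure, outcome, beta, se, p, p_adj, n_used, note`, sorted by
#'   raw p.
#' @export
run_screen <- function(cohort, blood_measures, outcomes,
                       covariates = c("age", "sex", "education", "centre"),
                       outcome_kinds = NULL,
                       age_min = 60,
                       technical_covariates = NULL) {
  stopifnot(length(blood_measures) >= 1L, length(outcomes) >= 1L)
  rows <- list()
  k <- 0L
  for (m in blood_measures) {
    for (o in outcomes) {
      k <- k + 1L
      kind <- if (!is.null(outcome_kinds) && o %in% names(outcome_kinds)) {
        outcome_kinds[[o]]
      } else "continuous"
      res <- tryCatch(
        fit_association(cohort, m, o, covariates = covariates,
                        age_min = age_min, outcome_kind = kind,
                        technical_covariates = technical_covariates),
        error = function(e) {
          data.frame(blood_measure = m, outcome = o,
                     beta = NA_real_, se = NA_real_, p = NA_real_,
                     n_used = NA_integer_, note = conditionMessage(e),
                     stringsAsFactors = FALSE)
        })
      if (is.null(res$note)) res$note <- ""
      rows[[k]] <- res
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  class(out) <- c("association_screen", "data.frame")
  out
}

#' Reshape a screen into the measures-by-outcomes matrix layout
#'
#' @param screen an `"association_screen"` from [run_screen()].
#' @param value `"beta"`, `"p"` or `"p_adj"`.
#' @return Wide data.frame, one row per blood measure, one column per
#'   outcome.
#' @export
screen_table <- function(screen, value = c("beta", "p", "p_adj")) {
  value <- match.arg(value)
  wide <- stats::reshape(
    as.data.frame(screen)[c("blood_measure", "outcome", value)],
    idvar = "blood_measure", timevar = "outcome", direction = "wide")
  names(wide) <- sub(paste0("^", value, "\\."), "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Classify anaemia from haemoglobin and sex
#'
#' NICE rule: anaemic if haemoglobin is strictly below 13 g/100 mL for
#' males or strictly below 12 g/100 mL for females. Missing haemoglobin
#' gives a missing label, with the count reported.
#'
#' @param cohort data.frame.
#' @param hgb_col haemoglobin column (g/100 mL).
#' @param sex_col sex column; `male_code` marks males.
#' @param male_code value of `sex_col` identifying males (default `1`).
#' @return Logical vector (`TRUE` = anaemic, NA where HGB missing).
#' @export
classify_anaemia <- function(cohort, hgb_col = "HGB", sex_col = "sex",
                             male_code = 1) {
  hgb <- cohort[[hgb_col]]
  male <- cohort[[sex_col]] == male_code
  out <- ifelse(male, hgb < 13, hgb < 12)
  n_miss <- sum(is.na(hgb))
  if (n_miss > 0) {
    message(sprintf("classify_anaemia: %d subjects with missing HGB", n_miss))
  }
  out
}
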