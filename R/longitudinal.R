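#' Per-subject rate of change of a blood measure
#'
#' For each subject with at least `min_visits` visits, fits the linear
#' model `measure = b0 + b1 * age + e` by ordinary least squares and
#' records the slope (measure units per year), intercept, residual SD,
#' per-subject mean level and mean age. Subjects with too few visits, or
#' with all visits at an identical age (slope undefined), are excluded and
#' counted.
#'
#' @param visits visit-level data.frame.
#' @param measure name of the measure column.
#' @param min_visits minimum visits per retained subject (default 3; 2 is
#'   permitted for two-point slopes).
#' @param subject_col,age_col,group_col column names.
#' @return data.frame of slope records (one row per subject), with
#'   attribute `"n_excluded"`.
#' @export
per_subject_slope <- function(visits, measure = "value", min_visits = 3L,
                              subject_col = "subject", age_col = "age",
                              group_col = "group") {
  if (min_visits < 2L) stop("'min_visits' must be at least 2", call. = FALSE)
  parts <- split(visits, visits[[subject_col]])
  recs <- list()
  n_excluded <- 0L
  for (id in names(parts)) {
    d <- parts[[id]]
    d <- d[is.finite(d[[measure]]) & is.finite(d[[age_col]]), , drop = FALSE]
    a <- d[[age_col]]
    y <- d[[measure]]
    if (nrow(d) < min_visits || stats::var(a) == 0) {
      n_excluded <- n_excluded + 1L
      next
    }
    ac <- a - mean(a)
    slope <- sum(ac * y) / sum(ac^2)
    intercept <- mean(y) - slope * mean(a)
    rss <- sum((y - intercept - slope * a)^2)
    df <- nrow(d) - 2L
    recs[[id]] <- data.frame(
      subject = id,
      measure = measure,
      slope = slope,
      intercept = intercept,
      n_visits = nrow(d),
      resid_sd = if (df > 0) sqrt(rss / df) else 0,
      group = if (group_col %in% names(d)) d[[group_col]][1] else NA_character_,
      mean_level = mean(y),
      mean_age = mean(a),
      stringsAsFactors = FALSE
    )
  }
  if (n_excluded > 0L) {
    message(sprintf("per_subject_slope: %d subject(s) excluded (< %d visits or no age spread)",
                    n_excluded, min_visits))
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) stop("no subject retained", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Compare rate-of-change distributions between two groups
#'
#' For each measure, compares the per-subject slopes of the two groups with
#' a Welch (unequal-variance) unpaired t-test on the means and a two-sample
#' Kolmogorov-Smirnov test on the distributions, then applies
#' Benjamini-Hochberg FDR adjustment across measures within each test
#' family. Measures where either group has fewer than two subjects are
#' flagged (NA statistics) rather than fatal.
#'
#' @param records slope records (possibly several measures stacked).
#' @param value_col column holding the per-subject quantity (default
#'   `"slope"`).
#' @param group_col grouping column; must have exactly two levels.
#' @param measure_col measure identifier column.
#' @return data.frame: per measure, `t_stat, t_p, ks_stat, ks_p` and the
#'   FDR-adjusted `t_p_adj, ks_p_adj`, plus group sizes.
#' @export
compare_groups <- function(records, value_col = "slope",
                           group_col = "group", measure_col = "measure") {
  groups <- unique(records[[group_col]])
  if (length(groups) != 2L) {
    stop("'", group_col, "' must have exactly two levels", call. = FALSE)
  }
  out <- lapply(split(records, records[[measure_col]]), function(d) {
    x <- d[[value_col]][d[[group_col]] == groups[1]]
    y <- d[[value_col]][d[[group_col]] == groups[2]]
    if (length(x) < 2L || length(y) < 2L) {
      return(data.frame(measure = d[[measure_col]][1],
                        n1 = length(x), n2 = length(y),
                        t_stat = NA_real_, t_p = NA_real_,
                        ks_stat = NA_real_, ks_p = NA_real_,
                        note = "group with < 2 subjects",
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(x, y)
    ks <- suppressWarnings(stats::ks.test(x, y))
    data.frame(measure = d[[measure_col]][1],
               n1 = length(x), n2 = length(y),
               t_stat = unname(tt$statistic), t_p = tt$p.value,
               ks_stat = unname(ks$statistic), ks_p = ks$p.value,
               note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$t_p_adj <- stats::p.adjust(out$t_p, method = "BH")
  out$ks_p_adj <- stats::p.adjust(out$ks_p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Split subjects into MMSE extremes
#'
#' Returns the bottom and top `fraction` of subjects by MMSE score
#' (`floor(n * fraction)` per tail), ties broken by stable subject-id
#' order, for use with [compare_groups()].
#'
#' @param subjects data.frame with one row per subject.
#' @param mmse_col MMSE column name.
#' @param id_col subject-id column name (tie-break order).
#' @param fraction tail fraction (default 0.20).
#' @return The extreme subjects with a new `group` column
#'   (`"low"`/`"high"`).
#' @export
mmse_extremes_split <- function(subjects, mmse_col = "mmse",
                                id_col = "subject", fraction = 0.20) {
  n <- nrow(subjects)
  k <- floor(n * fraction)
  if (k < 2L) {
    stop("too few subjects for both extreme groups (need >= 2 per tail)",
         call. = FALSE)
  }
  mmse <- subjects[[mmse_col]]
  if (length(unique(mmse)) == 1L) {
    stop("all MMSE scores equal; extremes split undefined", call. = FALSE)
  }
  ord <- order(mmse, subjects[[id_col]])
  low <- subjects[ord[seq_len(k)], , drop = FALSE]
  high <- subjects[ord[seq(n - k + 1L, n)], , drop = FALSE]
  low$group <- "low"
  high$group <- "high"
  out <- rbind(low, high)
  rownames(out) <- NULL
  out
}

#' Linear model of MMSE on rate of change
#'
#' Per measure, ordinary least squares of the continuous MMSE score on the
#' per-subject slope with correction for the given covariates (age and sex
#' by default); the reported beta is the slope coefficient.
#'
#' @param records slope records joined with per-subject `mmse` and
#'   covariate columns.
#' @param mmse_col,slope_col column names.
#' @param covariates covariate column names.
#' @param measure_col measure identifier column.
#' @return data.frame: per measure, `beta, se, p, n`.
#' @export
mmse_linear_model <- function(records, mmse_col = "mmse",
                              slope_col = "slope",
                              covariates = c("mean_age", "sex"),
                              measure_col = "measure") {
  out <- lapply(split(records, records[[measure_col]]), function(d) {
    vars <- c(mmse_col, slope_col, covariates)
    d <- d[stats::complete.cases(d[vars]), , drop = FALSE]
    fml <- stats::reformulate(c(slope_col, covariates), response = mmse_col)
    fit <- stats::lm(fml, data = d)
    sm <- summary(fit)$coefficients
    if (!slope_col %in% rownames(sm)) {
      stop("rank-deficient MMSE model for measure ", d[[measure_col]][1],
           call. = FALSE)
    }
    data.frame(measure = d[[measure_col]][1],
               beta = sm[slope_col, 1], se = sm[slope_col, 2],
               p = sm[slope_col, 4], n = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Rank correlation between per-subject slope and mean level
#'
#' Spearman correlation between the rate of change and the per-subject mean
#' of the measure: a check that the rate of change carries information not
#' already in the mean.
#'
#' @param records slope records.
#' @param slope_col,mean_col column names.
#' @return List with `rho` and `p` (two-sided); `rho = NA` with a warning
#'   for constant input.
#' @export
slope_vs_mean_correlation <- function(records, slope_col = "slope",
                                      mean_col = "mean_level") {
  x <- records[[slope_col]]
  y <- records[[mean_col]]
  if (length(x) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant slope or mean vector; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
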