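#' Simulate longitudinal blood-measure visits
#'
#' Each subject receives a true linear age trend: the per-subject slope is
#' drawn from its group's distribution and the observed measure at each
#' visit is `intercept + slope * age + noise`, the same linear model the
#' rate-of-change analysis later fits per subject.
#'
#' @param n_subjects subjects per group.
#' @param visits_per_subject number of visits (>= 2).
#' @param group_slopes named list, one entry per group, each `c(mean, sd)`
#'   of the true slope distribution (measure units per year).
#' @param measurement_sd visit-level measurement noise SD.
#' @param baseline_age_range age range (years) at first visit.
#' @param visit_spacing years between visits.
#' @param level_mean,level_sd distribution of the measure level at first
#'   visit.
#' @param seed integer seed.
#' @return Visit-level `data.frame` with columns `subject, group, age,
#'   value` plus attribute `"truth"` holding the drawn per-subject slopes.
#' @export
simulate_longitudinal <- function(n_subjects = 35L,
                                  visits_per_subject = 3L,
                                  group_slopes = list(
                                    AD = c(-0.05, 0.02),
                                    control = c(0.0, 0.02)
                                  ),
                                  measurement_sd = 0.05,
                                  baseline_age_range = c(65, 85),
                                  visit_spacing = 1,
                                  level_mean = 4.5,
                                  level_sd = 0.4,
                                  seed = 1L) {
  if (visits_per_subject < 2L) {
    stop("'visits_per_subject' must be at least 2", call. = FALSE)
  }
  stopifnot(length(group_slopes) >= 1L, !is.null(names(group_slopes)))
  set.seed(derive_seed(seed, "visits"))
  rows <- list()
  truth <- list()
  sid <- 0L
  for (grp in names(group_slopes)) {
    gs <- group_slopes[[grp]]
    for (i in seq_len(n_subjects)) {
      sid <- sid + 1L
      slope <- stats::rnorm(1, gs[1], gs[2])
      age0 <- stats::runif(1, baseline_age_range[1], baseline_age_range[2])
      level <- stats::rnorm(1, level_mean, level_sd)
      ages <- age0 + (seq_len(visits_per_subject) - 1L) * visit_spacing
      value <- level + slope * (ages - age0) +
        stats::rnorm(visits_per_subject, 0, measurement_sd)
      id <- sprintf("L%04d", sid)
      rows[[sid]] <- data.frame(
        subject = id, group = grp, age = ages, value = value,
        stringsAsFactors = FALSE
      )
      truth[[id]] <- slope
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- unlist(truth)
  out
}
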