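#' Greedy age- and sex-matched case-control selection
#'
#' Pairs every case with one unused control of the same sex and nearest age
#' within a caliper, visiting cases in a seeded random order (greedy
#' nearest-neighbour). Cases with no eligible control are dropped and
#' counted. A control is never reused and never paired across sexes.
#'
#' @param cohort data.frame with a disease label, age and sex column.
#' @param case_label label value identifying cases; every other label is a
#'   potential control.
#' @param label_col,age_col,sex_col column names.
#' @param caliper maximum allowed absolute age difference (years).
#' @param seed integer seed for the case visiting order.
#' @return The matched sub-cohort (cases + paired controls) with a
#'   `pair_id` column; attributes `"n_dropped"` (unmatched cases) and
#'   `"age_differences"`.
#' @export
match_case_control <- function(cohort, case_label = "case",
                               label_col = "disease",
                               age_col = "age", sex_col = "sex",
                               caliper = 2, seed = 1L) {
  is_case <- cohort[[label_col]] == case_label
  case_idx <- which(is_case)
  ctrl_idx <- which(!is_case)
  if (length(case_idx) == 0L) stop("no cases with label '", case_label, "'",
                                   call. = FALSE)
  set.seed(derive_seed(seed, "match"))
  case_order <- sample(case_idx)

  used <- logical(nrow(cohort))
  pairs <- list()
  n_dropped <- 0L
  age <- cohort[[age_col]]
  sex <- cohort[[sex_col]]
  for (ci in case_order) {
    elig <- ctrl_idx[!used[ctrl_idx] &
                       sex[ctrl_idx] == sex[ci] &
                       abs(age[ctrl_idx] - age[ci]) <= caliper]
    if (length(elig) == 0L) {
      n_dropped <- n_dropped + 1L
      next
    }
    best <- elig[order(abs(age[elig] - age[ci]), elig)][1]
    used[best] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(case = ci, control = best)
  }
  if (length(pairs) == 0L) stop("no case could be matched", call. = FALSE)
  if (n_dropped > 0L) {
    message(sprintf("match_case_control: %d case(s) without eligible control dropped",
                    n_dropped))
  }
  pm <- do.call(rbind, pairs)
  rows <- as.vector(t(pm))
  out <- cohort[rows, , drop = FALSE]
  out$pair_id <- rep(seq_len(nrow(pm)), each = 2L)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "age_differences") <- abs(age[pm[, "case"]] - age[pm[, "control"]])
  out
}
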