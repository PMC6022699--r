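# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-sided 95% interval multiplier used throughout.
Z95 <- 1.959964

# Deterministically derive a component sub-seed from a master seed, so that a
# single master seed drives every stochastic component without the streams
# colliding. Kept below .Machine$integer.max.
derive_seed <- function(seed, component) {
  offsets <- c(
    genotypes = 101L, confounder = 211L, noise_exposure = 307L,
    noise_outcome = 401L, covariates = 503L, visits = 601L,
    expression = 701L, exposure_cohort = 811L, outcome_cohort = 907L,
    boot = 1009L, match = 1103L, liability = 1201L, trait = 1301L,
    measures = 1409L, summary = 1511L, sets = 1601L
  )
  if (!component %in% names(offsets)) {
    stop("unknown seed component: ", component)
  }
  as.integer((as.numeric(seed) * 48271 + offsets[[component]]) %% 2147483647)
}

stopifnot_number <- function(x, name, lower = -Inf, upper = Inf,
                             strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower && x < upper else x >= lower && x <= upper)
  if (!ok) {
    stop(sprintf("'%s' must be a finite number in %s%g, %g%s",
                 name,
                 if (strict) "(" else "[", lower, upper,
                 if (strict) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

# Standardise a numeric vector; constant input maps to zeros rather than NaN.
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

# Minimal fixed-width markdown table for report output.
md_table <- function(df, digits = 4) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(signif(x, digits), format = "g") else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, rule, body), collapse = "\n")
}
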