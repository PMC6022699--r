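#' Construct an instrument set
#'
#' The central MR input: per SNP, the estimated effect on the exposure
#' (`beta_exposure`, with standard error) and on the outcome
#' (`beta_outcome`, with standard error), on a shared effect-allele
#' orientation. Validates uniqueness of variant ids and positivity of
#' standard errors.
#'
#' @param variant character variant ids (unique).
#' @param beta_exposure,se_exposure SNP-to-exposure effects and SEs.
#' @param beta_outcome,se_outcome SNP-to-outcome effects and SEs.
#' @param ea,oa effect / other alleles (optional).
#' @param eaf effect-allele frequency in (0, 1) (optional).
#' @param info imputation info score in \[0, 1\] (optional, default 1).
#' @param chrom,pos optional genomic coordinates (used by region filters).
#' @return data.frame of class `"instrument_set"`.
#' @export
instrument_set <- function(variant, beta_exposure, se_exposure,
                           beta_outcome, se_outcome,
                           ea = NULL, oa = NULL, eaf = NULL, info = NULL,
                           chrom = NULL, pos = NULL) {
  m <- length(variant)
  if (anyDuplicated(variant)) {
    stop("duplicate variant ids in instrument set", call. = FALSE)
  }
  if (any(se_exposure <= 0) || any(se_outcome <= 0)) {
    stop("standard errors must be strictly positive", call. = FALSE)
  }
  out <- data.frame(
    variant = as.character(variant),
    ea = if (is.null(ea)) NA_character_ else as.character(ea),
    oa = if (is.null(oa)) NA_character_ else as.character(oa),
    eaf = if (is.null(eaf)) NA_real_ else as.numeric(eaf),
    info = if (is.null(info)) 1.0 else as.numeric(info),
    beta_exposure = as.numeric(beta_exposure),
    se_exposure = as.numeric(se_exposure),
    beta_outcome = as.numeric(beta_outcome),
    se_outcome = as.numeric(se_outcome),
    stringsAsFactors = FALSE
  )
  if (!is.null(chrom)) out$chrom <- as.character(chrom)
  if (!is.null(pos)) out$pos <- as.numeric(pos)
  stopifnot(nrow(out) == m)
  class(out) <- c("instrument_set", "data.frame")
  out
}

#' Filter instruments by quality and exclusion criteria
#'
#' Retains SNPs with imputation info score strictly above `info_min`, not
#' present in `exclusion_list` (variants with known direct outcome
#' associations, e.g. an APOE/TOMM40-style list for a cognition outcome),
#' and not inside any excluded genomic region (0-based half-open intervals;
#' a BED file path or a data.frame with `chrom,start,end`). Per-criterion
#' removal counts are attached as attribute `"removed"` and reported via
#' `message()`.
#'
#' @param instruments an [instrument_set()].
#' @param info_min info-score threshold (retain strictly greater).
#' @param exclusion_list character vector of variant ids to exclude.
#' @param excluded_regions BED path or data.frame `chrom,start,end`.
#' @return Filtered [instrument_set()]; error naming the dominant criterion
#'   if nothing survives.
#' @export
filter_instruments <- function(instruments, info_min = 0.9,
                               exclusion_list = NULL,
                               excluded_regions = NULL) {
  stopifnot(inherits(instruments, "instrument_set"))
  if (nrow(instruments) == 0L) stop("empty instrument set", call. = FALSE)
  low_info <- !(instruments$info > info_min)
  excluded <- if (is.null(exclusion_list)) {
    rep(FALSE, nrow(instruments))
  } else {
    instruments$variant %in% exclusion_list
  }
  in_region <- rep(FALSE, nrow(instruments))
  if (!is.null(excluded_regions)) {
    if (is.character(excluded_regions)) {
      excluded_regions <- read_bed_regions(excluded_regions)
    }
    if (!all(c("chrom", "pos") %in% names(instruments))) {
      stop("region filtering requires 'chrom' and 'pos' columns",
           call. = FALSE)
    }
    for (k in seq_len(nrow(excluded_regions))) {
      in_region <- in_region |
        (instruments$chrom == excluded_regions$chrom[k] &
           instruments$pos >= excluded_regions$start[k] &
           instruments$pos < excluded_regions$end[k])
    }
  }
  removed <- c(info = sum(low_info), exclusion_list = sum(excluded & !low_info),
               region = sum(in_region & !low_info & !excluded))
  keep <- !(low_info | excluded | in_region)
  if (!any(keep)) {
    dominant <- names(which.max(removed))
    stop("all instruments removed; dominant criterion: ", dominant,
         call. = FALSE)
  }
  out <- instruments[keep, , drop = FALSE]
  class(out) <- c("instrument_set", "data.frame")
  attr(out, "removed") <- removed
  message(sprintf(
    "filter_instruments: removed %d (info <= %g), %d (exclusion list), %d (region); %d retained",
    removed[["info"]], info_min, removed[["exclusion_list"]],
    removed[["region"]], nrow(out)))
  out
}

#' Harmonise two GWAS summary tables into an instrument set
#'
#' Joins exposure and outcome summary statistics on variant id and aligns
#' the outcome effects to the exposure's effect allele: when effect/other
#' alleles are swapped the outcome beta sign is flipped (and its frequency
#' complemented); incompatible allele pairs are dropped with a reason.
#' Strand-ambiguous palindromic SNPs (A/T and C/G) are dropped by default
#' because their orientation cannot be resolved without strand information.
#'
#' @param exposure_stats,outcome_stats data.frames with columns
#'   `variant, ea, oa, eaf, beta, se, info` (see [read_gwas_table()]).
#' @param drop_palindromic drop A/T and C/G SNPs (default `TRUE`).
#' @return [instrument_set()] with attribute `"drops"`, a data.frame of
#'   dropped variants and reasons.
#' @export
harmonise <- function(exposure_stats, outcome_stats, drop_palindromic = TRUE) {
  shared <- merge(exposure_stats, outcome_stats, by = "variant",
                  suffixes = c("_exp", "_out"))
  if (nrow(shared) == 0L) stop("no overlapping variant ids", call. = FALSE)
  ea_e <- toupper(shared$ea_exp); oa_e <- toupper(shared$oa_exp)
  ea_o <- toupper(shared$ea_out); oa_o <- toupper(shared$oa_out)

  palindromic <- paste0(ea_e, oa_e) %in% c("AT", "TA", "CG", "GC")
  same <- ea_e == ea_o & oa_e == oa_o
  swapped <- ea_e == oa_o & oa_e == ea_o & !same

  beta_out <- shared$beta_out
  eaf_out <- shared$eaf_out
  beta_out[swapped] <- -beta_out[swapped]
  eaf_out[swapped] <- 1 - eaf_out[swapped]

  reason <- rep(NA_character_, nrow(shared))
  reason[!(same | swapped)] <- "allele_mismatch"
  if (drop_palindromic) reason[palindromic & is.na(reason)] <- "palindromic"
  keep <- is.na(reason)
  drops <- data.frame(variant = shared$variant[!keep],
                      reason = reason[!keep], stringsAsFactors = FALSE)
  if (!any(keep)) stop("no instruments left after harmonisation", call. = FALSE)

  out <- instrument_set(
    variant = shared$variant[keep],
    ea = ea_e[keep], oa = oa_e[keep],
    eaf = shared$eaf_exp[keep],
    info = pmin(shared$info_exp[keep], shared$info_out[keep]),
    beta_exposure = shared$beta_exp[keep],
    se_exposure = shared$se_exp[keep],
    beta_outcome = beta_out[keep],
    se_outcome = shared$se_out[keep]
  )
  attr(out, "drops") <- drops
  if (nrow(drops)) {
    message(sprintf("harmonise: dropped %d variants (%s)",
                    nrow(drops),
                    paste(sprintf("%s: %d", names(table(drops$reason)),
                                  table(drops$reason)), collapse = ", ")))
  }
  out
}

#' Estimate per-SNP exposure and outcome associations in one sample
#'
#' One-sample MR input: for each SNP, the exposure and the outcome are
#' regressed on dosage plus the covariate set, on the same subjects.
#' Implemented by residualising exposure, outcome and dosages on the
#' covariates once (Frisch–Waugh) and then computing each per-SNP slope and
#' its standard error with the correct residual degrees of freedom, which is
#' numerically identical to fitting the full regression per SNP.
#'
#' @param cohort cohort data.frame (e.g. from [simulate_cohort()]).
#' @param exposure,outcome column names of the exposure and the outcome.
#' @param covariates character vector of covariate column names (may be
#'   empty for unadjusted associations).
#' @param snps character vector of dosage column names; defaults to columns
#'   matching `^snp_`.
#' @return [instrument_set()] with per-SNP effects, SEs and allele
#'   frequencies (`info = 1`). Monomorphic SNPs are dropped with a warning.
#' @export
estimate_snp_associations <- function(cohort, exposure, outcome,
                                      covariates = c("age", "sex",
                                                     "education", "centre"),
                                      snps = grep("^snp_", names(cohort),
                                                  value = TRUE)) {
  stopifnot(length(snps) >= 1L)
  n <- nrow(cohort)
  g <- as.matrix(cohort[snps])
  if (length(covariates)) {
    Z <- stats::model.matrix(
      stats::reformulate(covariates), data = cohort)
  } else {
    Z <- matrix(1, n, 1)
  }
  qz <- qr(Z)
  res <- qr.resid(qz, cbind(cohort[[exposure]], cohort[[outcome]], g))
  xr <- res[, 1]; yr <- res[, 2]
  gr <- res[, -(1:2), drop = FALSE]
  denom <- colSums(gr^2)
  mono <- denom < .Machine$double.eps * n
  if (any(mono)) {
    warning(sprintf("dropping %d monomorphic SNP(s): %s", sum(mono),
                    paste(snps[mono], collapse = ", ")))
    if (all(mono)) stop("all SNPs monomorphic", call. = FALSE)
    gr <- gr[, !mono, drop = FALSE]
    g <- g[, !mono, drop = FALSE]
    denom <- denom[!mono]
    snps <- snps[!mono]
  }
  df <- n - qz$rank - 1L
  slope_se <- function(v) {
    b <- colSums(gr * v) / denom
    rss <- pmax(sum(v^2) - b^2 * denom, 0)
    se <- sqrt(rss / df / denom)
    list(b = b, se = se)
  }
  ex <- slope_se(xr)
  ou <- slope_se(yr)
  # exact noiseless fits give se = 0; floor at a tiny positive value so the
  # instrument-set invariant (se > 0) holds
  eps <- .Machine$double.xmin
  instrument_set(
    variant = snps,
    ea = "A", oa = "G",
    eaf = colMeans(g) / 2,
    info = 1.0,
    beta_exposure = ex$b, se_exposure = pmax(ex$se, eps),
    beta_outcome = ou$b, se_outcome = pmax(ou$se, eps)
  )
}
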