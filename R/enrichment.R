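#' Per-gene linear-model statistics against a subject trait
#'
#' For every gene, ordinary least squares of expression on the trait (plus
#' optional covariates); the gene statistic is the t-statistic of the trait
#' coefficient. All genes are fitted in one QR decomposition of the shared
#' design. Moderated (empirical-Bayes) statistics are deliberately not
#' used: the enrichment stage consumes only the gene-level ranking and
#' significance, for which plain per-gene t-statistics suffice.
#'
#' @param expression numeric matrix, genes x samples, gene ids as rownames.
#' @param trait numeric per-sample trait.
#' @param covariates optional data.frame/matrix of per-sample covariates.
#' @return data.frame `gene, stat, p, flag`; zero-variance genes get
#'   `stat = 0, p = 1, flag = "zero_variance"`, perfect fits are capped at
#'   `|t| = 1e12` with `p = 0`.
#' @export
gene_model_stat <- function(expression, trait, covariates = NULL) {
  n <- ncol(expression)
  if (length(trait) != n) {
    stop("'trait' must have one value per sample", call. = FALSE)
  }
  X <- cbind(intercept = 1, trait = trait)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  p <- ncol(X)
  if (n <= p) stop("more parameters than samples", call. = FALSE)
  Y <- t(expression)                     # n x G
  qx <- qr(X)
  B <- qr.coef(qx, Y)
  R <- Y - X %*% B
  df <- n - p
  sigma2 <- colSums(R^2) / df
  xtxinv_tt <- chol2inv(qr.R(qx))[2, 2]
  se <- sqrt(sigma2 * xtxinv_tt)
  b <- B[2, ]
  tstat <- ifelse(se > 0, b / se, ifelse(b == 0, 0, sign(b) * 1e12))
  tstat <- pmin(pmax(tstat, -1e12), 1e12)
  pval <- 2 * stats::pt(-abs(tstat), df = df)
  zero_var <- apply(expression, 1L, stats::sd) == 0
  stat <- ifelse(zero_var, 0, tstat)
  pval <- ifelse(zero_var, 1, pval)
  data.frame(
    gene = rownames(expression) %||% sprintf("gene_%05d", seq_len(nrow(expression))),
    stat = unname(stat), p = unname(pval),
    flag = ifelse(zero_var, "zero_variance", ""),
    stringsAsFactors = FALSE
  )
}

#' Per-gene permutation correlation statistics
#'
#' Pearson correlation of each gene with the trait; significance by
#' permutation of the trait across samples with the add-one estimator
#' \eqn{p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\}) / (1 + n_{perm})}, so p is
#' bounded below by `1/(1 + n_perm)` and the procedure is deterministic
#' under a fixed seed.
#'
#' @param expression numeric matrix, genes x samples.
#' @param trait numeric per-sample trait (non-constant).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return data.frame `gene, stat, p, flag` where `stat` is the observed
#'   correlation and `p` the permutation p-value.
#' @export
gene_permutation_stat <- function(expression, trait, n_perm = 1000L,
                                  seed = 1L) {
  if (stats::sd(trait) == 0) stop("constant trait", call. = FALSE)
  if (n_perm < 100L) stop("'n_perm' must be at least 100", call. = FALSE)
  if (length(trait) != ncol(expression)) {
    stop("'trait' must have one value per sample", call. = FALSE)
  }
  Y <- t(expression)                     # n x G
  zero_var <- apply(Y, 2L, stats::sd) == 0
  r_obs <- suppressWarnings(as.vector(stats::cor(trait, Y)))
  r_obs[zero_var] <- 0

  set.seed(derive_seed(seed, "trait"))
  perms <- vapply(seq_len(n_perm), function(b) sample(trait), trait)
  r_perm <- suppressWarnings(abs(stats::cor(perms, Y)))  # n_perm x G
  r_perm[!is.finite(r_perm)] <- 0
  count <- colSums(r_perm >= matrix(abs(r_obs), n_perm, ncol(Y), byrow = TRUE))
  pval <- (1 + count) / (1 + n_perm)
  pval[zero_var] <- 1
  data.frame(
    gene = rownames(expression) %||% sprintf("gene_%05d", seq_len(ncol(Y))),
    stat = r_obs, p = pval,
    flag = ifelse(zero_var, "zero_variance", ""),
    stringsAsFactors = FALSE
  )
}

#' Distribution-based (KS) gene-set enrichment
#'
#' For each gene set, compares the distribution of the gene-level statistic
#' for genes inside the set against all scored genes outside it with a
#' two-sided two-sample Kolmogorov-Smirnov test — a distributional-shift
#' test rather than an overlap count. Sets with fewer than `min_size`
#' scored members are skipped (logged in attribute `"skipped"`).
#' Benjamini-Hochberg adjustment is applied across tested sets.
#'
#' @param gene_stats data.frame from [gene_model_stat()] or
#'   [gene_permutation_stat()] (columns `gene`, `stat`).
#' @param gene_sets named list of gene-id vectors (see [read_gmt()]).
#' @param min_size minimum scored genes per set (default 10).
#' @param stat_col column of `gene_stats` to compare (default `"stat"`;
#'   `"p"` compares significance values instead).
#' @return data.frame `pathway, n_genes, D, p, p_adj`, sorted by p.
#' @export
ks_enrichment <- function(gene_stats, gene_sets, min_size = 10L,
                          stat_col = "stat") {
  stats_vec <- stats::setNames(gene_stats[[stat_col]], gene_stats$gene)
  rows <- list()
  skipped <- character()
  for (nm in names(gene_sets)) {
    members <- unique(gene_sets[[nm]])
    inside <- stats_vec[names(stats_vec) %in% members]
    outside <- stats_vec[!names(stats_vec) %in% members]
    if (length(inside) < min_size || length(outside) < 1L) {
      skipped <- c(skipped, nm)
      next
    }
    ks <- suppressWarnings(stats::ks.test(inside, outside))
    rows[[nm]] <- data.frame(
      pathway = nm, n_genes = length(inside),
      D = unname(ks$statistic), p = ks$p.value,
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped)) {
    message(sprintf("ks_enrichment: skipped %d set(s) below min_size: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  }
  if (length(rows) == 0L) stop("no gene set passed 'min_size'", call. = FALSE)
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
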