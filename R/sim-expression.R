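#' Simulate a pathway-structured expression matrix
#'
#' Genes in the planted pathway have expression
#' `effect_size * z(trait) + N(0, 1)` so their correlation with the
#' subject-level trait is `effect_size / sqrt(1 + effect_size^2)`; all other
#' genes are independent standard-normal noise. With `effect_size = 0` the
#' planted pathway is indistinguishable from background.
#'
#' @param n_genes total number of genes (rows).
#' @param n_samples number of samples (columns); must match `length(trait)`.
#' @param pathways named list of gene-id character vectors (gene-set map).
#' @param planted_pathway name of the pathway to associate with the trait.
#' @param trait per-sample trait values (e.g. an MCH rate of change).
#' @param effect_size association strength on the expression SD scale.
#' @param seed integer seed.
#' @return Numeric matrix (genes x samples) with gene ids as rownames.
#' @export
simulate_expression <- function(n_genes, n_samples,
                                pathways, planted_pathway,
                                trait, effect_size = 0.5, seed = 1L) {
  if (!planted_pathway %in% names(pathways)) {
    stop("'planted_pathway' not found in 'pathways'", call. = FALSE)
  }
  planted <- unique(pathways[[planted_pathway]])
  if (length(planted) == 0L) {
    stop("planted pathway is empty", call. = FALSE)
  }
  if (length(trait) != n_samples) {
    stop("'trait' must have one value per sample", call. = FALSE)
  }
  members <- unique(unlist(pathways, use.names = FALSE))
  if (length(members) > n_genes) {
    stop("'n_genes' smaller than the number of distinct pathway genes",
         call. = FALSE)
  }
  filler <- setdiff(sprintf("gene_%05d", seq_len(n_genes + length(members))),
                    members)
  genes <- c(members, filler[seq_len(n_genes - length(members))])

  set.seed(derive_seed(seed, "expression"))
  expr <- matrix(stats::rnorm(length(genes) * n_samples),
                 nrow = length(genes),
                 dimnames = list(genes, sprintf("sample_%03d", seq_len(n_samples))))
  tz <- zscore(trait)
  idx <- which(genes %in% planted)
  expr[idx, ] <- expr[idx, ] + effect_size * matrix(tz, length(idx), n_samples,
                                                    byrow = TRUE)
  expr
}

#' Build random gene sets over a gene universe
#'
#' Utility for simulations and demos: draws `n_sets` disjoint-by-chance
#' random gene sets of a given size from `genes`, named `set_01, ...`.
#'
#' @param genes character vector, the gene universe.
#' @param n_sets number of sets.
#' @param set_size genes per set.
#' @param seed integer seed.
#' @return Named list of character vectors.
#' @export
random_gene_sets <- function(genes, n_sets = 20L, set_size = 50L, seed = 1L) {
  if (set_size > length(genes)) {
    stop("'set_size' larger than the gene universe", call. = FALSE)
  }
  set.seed(derive_seed(seed, "sets"))
  sets <- lapply(seq_len(n_sets), function(i) sample(genes, set_size))
  names(sets) <- sprintf("set_%02d", seq_len(n_sets))
  sets
}
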