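# Readers and writers for the plain-text formats the pipeline exchanges.

#' Write a data frame as TSV
#'
#' Thin wrapper around [utils::write.table()] with the conventions used for
#' every table the pipeline emits (tab separator, header, no quoting, no row
#' names), so outputs are byte-stable under identical inputs.
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a GWAS summary-statistics table
#'
#' Expects the tab-separated layout `variant ea oa eaf beta se info`
#' (extra columns are kept). Validates required columns and numeric ranges.
#'
#' @param path TSV file path.
#' @return data.frame of summary statistics.
#' @export
read_gwas_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("variant", "ea", "oa", "eaf", "beta", "se", "info")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop("GWAS table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$se <= 0, na.rm = TRUE)) {
    stop("GWAS table contains non-positive standard errors", call. = FALSE)
  }
  x
}

#' Read a GMT gene-set file
#'
#' Tab-delimited: set name, description, then member genes. Duplicate genes
#' within a set are removed with a warning; a line with fewer than three
#' fields is an error reporting the line number.
#'
#' @param path GMT file path.
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(setNames(list(), character()))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate genes in set '%s' deduplicated", f[1]))
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
  }
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character gene vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Minimal BED reader for instrument exclusion regions: first three columns
# chrom / start / end, 0-based half-open, as in the BED convention.
read_bed_regions <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(x) < 3L) stop("BED file needs at least 3 columns", call. = FALSE)
  data.frame(chrom = as.character(x[[1]]),
             start = as.numeric(x[[2]]),
             end = as.numeric(x[[3]]),
             stringsAsFactors = FALSE)
}
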