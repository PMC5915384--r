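#' Construct a multi-tissue per-CpG methylome matrix
#'
#' Holds per-CpG methylation fractions (beta values) for a panel of named
#' tissues, with genomic coordinates. This is the input to marker discovery:
#' rows are CpG sites sorted by (chrom, pos), columns are tissues.
#'
#' @param sites Data frame with columns `chrom` and `pos` (1-based position
#'   of the CpG cytosine).
#' @param beta Numeric matrix, `nrow(sites)` x `length(tissues)`, values in
#'   `[0, 1]` or `NA`.
#' @param tissues Character vector of tissue names; defaults to
#'   `colnames(beta)`.
#' @param coverage Optional matrix of read depths, same shape as `beta`.
#' @return An object of class `methylome_matrix`.
#' @export
methylome_matrix <- function(sites, beta, tissues = colnames(beta),
                             coverage = NULL) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  beta <- as.matrix(beta)
  if (nrow(beta) != nrow(sites))
    stop("beta must have one row per site")
  if (is.null(tissues) || length(tissues) != ncol(beta))
    stop("tissues must name every beta column")
  if (nrow(beta) > 0 && !all(is.na(beta))) {
    rng <- range(beta, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop("beta values must lie in [0, 1]")
  }
  if (!is.null(coverage)) {
    coverage <- as.matrix(coverage)
    stopifnot(identical(dim(coverage), dim(beta)))
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, c("chrom", "pos"), drop = FALSE]
  sites$pos <- as.integer(sites$pos)
  rownames(sites) <- NULL
  beta <- beta[ord, , drop = FALSE]
  colnames(beta) <- tissues
  if (!is.null(coverage)) coverage <- coverage[ord, , drop = FALSE]
  structure(list(sites = sites, tissues = tissues, beta = beta,
                 coverage = coverage),
            class = "methylome_matrix")
}

#' @export
print.methylome_matrix <- function(x, ...) {
  cat(sprintf("<methylome_matrix> %d CpG sites x %d tissues\n",
              nrow(x$sites), length(x$tissues)))
  cat("  tissues:", paste(utils::head(x$tissues, 8), collapse = ", "),
      if (length(x$tissues) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.methylome_matrix <- function(x) dim(x$beta)

#' Read a methylome matrix from a wide TSV
#'
#' Expects columns `chrom`, `pos`, then one beta column per tissue.
#'
#' @param path TSV path.
#' @return A [methylome_matrix()].
#' @export
read_methylome <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("chrom", "pos") %in% names(df)))
    stop("methylome TSV must have 'chrom' and 'pos' columns")
  tissues <- setdiff(names(df), c("chrom", "pos"))
  if (length(tissues) == 0L) stop("no tissue beta columns found")
  methylome_matrix(df[c("chrom", "pos")],
                   as.matrix(df[tissues]), tissues)
}

#' Write a methylome matrix to a wide TSV
#'
#' @param mat A `methylome_matrix`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_methylome <- function(mat, path) {
  stopifnot(inherits(mat, "methylome_matrix"))
  df <- cbind(mat$sites, as.data.frame(mat$beta))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
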