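#' Scan a methylome matrix for tissue-specific unmethylated marker regions
#'
#' Finds candidate marker regions: short runs of consecutive CpG sites that
#' are heavily methylated in every background tissue and unmethylated in
#' every target tissue. A window of `min_cpg` or more consecutive sites
#' qualifies when (i) the genomic span from its first to its last CpG
#' cytosine, inclusive, is strictly less than `max_span_bp`; (ii) its
#' region-mean beta exceeds `background_min_meth` in every background
#' tissue; and (iii) its region-mean beta is below `target_max_meth` in
#' every target tissue. Overlapping qualifying windows are merged, so each
#' discovered locus is reported exactly once as a maximal candidate.
#'
#' With `per_cpg = TRUE` the methylation criteria are applied to every CpG
#' individually rather than to the region mean — stricter, and sensitive to
#' single-site noise. By default a tissue with missing beta anywhere in a
#' window fails that window (conservative); `na_action = "ignore"` computes
#' means over observed values instead.
#'
#' @param mat A [methylome_matrix()].
#' @param target_tissues,background_tissues Tissue names; must be disjoint
#'   and present in `mat`.
#' @param max_span_bp Maximum genomic span (bp, exclusive bound) from first
#'   to last CpG of a window. Default 100.
#' @param min_cpg Minimum number of CpG sites in a window. Default 5.
#' @param background_min_meth Region-mean beta every background tissue must
#'   exceed. Default 0.8.
#' @param target_max_meth Region-mean beta every target tissue must stay
#'   below. Default 0.2.
#' @param per_cpg Apply the thresholds per CpG instead of per region mean.
#' @param na_action `"fail"` (default) or `"ignore"` for missing betas.
#' @return Data frame of class `marker_candidates`, one row per merged
#'   candidate, sorted by coordinate: `chrom`, `start`, `end` (1-based
#'   inclusive, from first CpG C to the G of the last CpG), `n_cpg`,
#'   `span_bp` (first to last C), `background_min_beta` (minimum over
#'   background tissues of the region-mean), `target_max_beta` (maximum over
#'   target tissues), `separation` (`background_min_beta - target_max_beta`),
#'   `passes` (always `TRUE`), plus list columns `cpg_positions` and
#'   `target_means`.
#' @examples
#' m <- make_methylome(n_sites = 200, tissue_names = c("heart", "liver", "blood"),
#'                     planted = list(list(at = 100, n_cpg = 6, span_bp = 90,
#'                                    target_beta = 0.05, background_beta = 0.95)),
#'                     target_tissues = "heart", seed = 1)
#' scan_markers(m, "heart", c("liver", "blood"))
#' @export
scan_markers <- function(mat, target_tissues, background_tissues,
                         max_span_bp = 100, min_cpg = 5,
                         background_min_meth = 0.8, target_max_meth = 0.2,
                         per_cpg = FALSE, na_action = c("fail", "ignore")) {
  stopifnot(inherits(mat, "methylome_matrix"))
  na_action <- match.arg(na_action)
  unknown <- setdiff(c(target_tissues, background_tissues), mat$tissues)
  if (length(unknown))
    stop("unknown tissue name(s): ", paste(unknown, collapse = ", "))
  if (length(intersect(target_tissues, background_tissues)))
    stop("target and background tissues must be disjoint")
  if (nrow(mat$sites) == 0L) {
    warning("empty methylome matrix; no candidates")
    return(.empty_candidates())
  }

  out <- list()
  for (chr in unique(mat$sites$chrom)) {
    idx <- which(mat$sites$chrom == chr)
    pos <- mat$sites$pos[idx]
    bt <- mat$beta[idx, target_tissues, drop = FALSE]
    bb <- mat$beta[idx, background_tissues, drop = FALSE]
    runs <- .qualifying_runs(pos, bt, bb, max_span_bp, min_cpg,
                             background_min_meth, target_max_meth,
                             per_cpg, na_action)
    for (r in runs) {
      out[[length(out) + 1L]] <-
        .candidate_row(chr, pos, bt, bb, r[1L], r[2L], na_action)
    }
  }
  if (!length(out)) return(.empty_candidates())
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("marker_candidates", "data.frame")
  res
}

# All maximal merged qualifying windows on one chromosome, as (i, j) site
# index pairs. Enumerates every window allowed by the span bound (spans are
# short, so the inner loop is narrow), then merges overlapping qualifiers.
.qualifying_runs <- function(pos, bt, bb, max_span_bp, min_cpg,
                             background_min_meth, target_max_meth,
                             per_cpg, na_action) {
  n <- length(pos)
  qual <- list()
  for (i in seq_len(n)) {
    j <- i + min_cpg - 1L
    if (j > n) break
    while (j <= n && (pos[j] - pos[i] + 1L) < max_span_bp) {
      if (.window_passes(bt, bb, i, j, background_min_meth, target_max_meth,
                         per_cpg, na_action))
        qual[[length(qual) + 1L]] <- c(i, j)
      j <- j + 1L
    }
  }
  if (!length(qual)) return(list())
  q <- do.call(rbind, qual)
  q <- q[order(q[, 1L], q[, 2L]), , drop = FALSE]
  merged <- list()
  cur <- q[1L, ]
  for (k in seq_len(nrow(q))[-1L]) {
    if (q[k, 1L] <= cur[2L]) {
      cur[2L] <- max(cur[2L], q[k, 2L])
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- q[k, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  merged
}

.window_passes <- function(bt, bb, i, j, background_min_meth, target_max_meth,
                           per_cpg, na_action) {
  t_vals <- bt[i:j, , drop = FALSE]
  b_vals <- bb[i:j, , drop = FALSE]
  if (na_action == "fail" && (anyNA(t_vals) || anyNA(b_vals)))
    return(FALSE)
  if (per_cpg) {
    ok_t <- all(t_vals < target_max_meth, na.rm = TRUE)
    ok_b <- all(b_vals > background_min_meth, na.rm = TRUE)
    # with na_action = "ignore", a tissue entirely NA yields vacuous truth;
    # require at least one observed value per tissue
    if (na_action == "ignore" &&
        (any(colSums(!is.na(t_vals)) == 0L) || any(colSums(!is.na(b_vals)) == 0L)))
      return(FALSE)
    return(ok_t && ok_b)
  }
  tm <- colMeans(t_vals, na.rm = (na_action == "ignore"))
  bm <- colMeans(b_vals, na.rm = (na_action == "ignore"))
  if (anyNA(tm) || anyNA(bm)) return(FALSE)
  all(tm < target_max_meth) && all(bm > background_min_meth)
}

.candidate_row <- function(chr, pos, bt, bb, i, j, na_action) {
  narm <- na_action == "ignore"
  tm <- colMeans(bt[i:j, , drop = FALSE], na.rm = narm)
  bm <- colMeans(bb[i:j, , drop = FALSE], na.rm = narm)
  df <- data.frame(
    chrom = chr,
    start = as.integer(pos[i]),
    end = as.integer(pos[j] + 1L),   # include the G of the last CpG
    n_cpg = as.integer(j - i + 1L),
    span_bp = as.integer(pos[j] - pos[i] + 1L),
    background_min_beta = min(bm),
    target_max_beta = max(tm),
    separation = min(bm) - max(tm),
    passes = TRUE,
    stringsAsFactors = FALSE
  )
  df$cpg_positions <- list(pos[i:j])
  df$target_means <- list(tm)
  df
}

.empty_candidates <- function() {
  df <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                   n_cpg = integer(0), span_bp = integer(0),
                   background_min_beta = numeric(0),
                   target_max_beta = numeric(0), separation = numeric(0),
                   passes = logical(0), stringsAsFactors = FALSE)
  df$cpg_positions <- list()
  df$target_means <- list()
  class(df) <- c("marker_candidates", "data.frame")
  df
}

#' Rank marker candidates by tissue separation
#'
#' Orders candidates by descending separation score — the gap between the
#' lowest background region-mean methylation and the highest target
#' region-mean methylation — with deterministic coordinate tie-breaking.
#' A larger separation promises a cleaner signal-to-noise ratio in the
#' downstream counting assay.
#'
#' @param candidates Output of [scan_markers()].
#' @return The same data frame, reordered.
#' @export
rank_candidates <- function(candidates) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0L) stop("no candidates to rank")
  ord <- order(-candidates$separation, candidates$chrom, candidates$start)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write marker candidates as BED6+
#'
#' Emits 0-based half-open coordinates (the BED convention) with extra
#' columns `n_cpg`, `target_max_beta`, `background_min_beta`.
#'
#' @param candidates Output of [scan_markers()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_candidates_bed <- function(candidates, path) {
  bed <- data.frame(
    chrom = candidates$chrom,
    start = candidates$start - 1L,   # to 0-based half-open
    end = candidates$end,
    name = sprintf("marker_%d", seq_len(nrow(candidates))),
    score = pmin(1000L, as.integer(round(candidates$separation * 1000))),
    strand = ".",
    n_cpg = candidates$n_cpg,
    target_max_beta = candidates$target_max_beta,
    background_min_beta = candidates$background_min_beta
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
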