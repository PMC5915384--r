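#' Mean-quality read filter
#'
#' A read passes when its mean Phred quality is at least `q_min` (boundary
#' inclusive). Amplicon reads are short and errors are what convert a
#' methylated molecule into an apparent unmethylated one, so a simple mean
#' quality gate on the whole read is the first funnel stage.
#'
#' @param seq Character vector of read sequences.
#' @param qual Character vector of Phred+33 quality strings, same lengths.
#' @param q_min Minimum mean Phred quality. Default 30.
#' @return Logical vector, `TRUE` for reads that pass.
#' @export
quality_filter <- function(seq, qual, q_min = 30) {
  stopifnot(length(seq) == length(qual))
  if (any(nchar(seq) != nchar(qual)))
    stop("sequence/quality length mismatch for read(s): ",
         paste(utils::head(which(nchar(seq) != nchar(qual)), 5), collapse = ", "))
  vapply(qual, function(q) mean(.phred(q)) >= q_min, logical(1L),
         USE.NAMES = FALSE)
}

# Wildcarded similarity of one read against one target: CpG cytosines in the
# converted template match both C and T so methylation state cannot affect
# target assignment. Returns dist, similarity and the template->read map.
.align_to_target <- function(read, target) {
  tmpl <- target$converted_template_meth  # identical to unmeth outside CpGs
  res <- .wildcard_align_cpp(read, tmpl, target$cpg_sites)
  res$similarity <- 1 - res$dist / nchar(tmpl)
  res
}

#' Assign a read to its best-matching amplicon target
#'
#' Computes, for each target, the global edit-distance similarity of the
#' read against the target's bisulfite-converted template with CpG positions
#' treated as wildcards (C and T both match, so the molecule's methylation
#' state does not bias assignment). The best target is returned if its
#' similarity reaches `min_similarity`; ties are broken by target order.
#'
#' @param read A single read sequence (post-bisulfite basecalls).
#' @param targets Non-empty list of [amplicon_target()] objects.
#' @param min_similarity Minimum fraction similarity (1 − edit distance /
#'   template length). Default 0.8.
#' @return List with `target` (name, or `NA` if no target reaches the
#'   threshold), `similarity` (best similarity over targets), and
#'   `alignment` (internal alignment of the best target, reused by
#'   [call_molecule()]).
#' @export
match_read <- function(read, targets, min_similarity = 0.8) {
  if (!length(targets)) stop("targets must be non-empty")
  if (inherits(targets, "amplicon_target")) targets <- list(targets)
  best <- NULL
  best_k <- NA_integer_
  for (k in seq_along(targets)) {
    a <- .align_to_target(read, targets[[k]])
    if (is.null(best) || a$similarity > best$similarity) {
      best <- a
      best_k <- k
    }
  }
  matched <- best$similarity >= min_similarity
  list(
    target = if (matched) targets[[best_k]]$name else NA_character_,
    similarity = best$similarity,
    alignment = if (matched) best else NULL
  )
}

#' Call per-CpG methylation states on a matched read
#'
#' For each expected CpG of the target, the aligned read dinucleotide at the
#' CpG position decides the state: `CG` is methylated (bisulfite left the C
#' untouched), `TG` is unmethylated (the C was converted), and anything else
#' — including a deletion or a sequencing error at either base — is
#' ambiguous. A molecule counts as target-tissue-derived only when every
#' expected CpG is observed and unmethylated (`fully_unmethylated`), so
#' partial patterns never contribute to the signal.
#'
#' The non-CpG conversion rate (converted / (converted + retained) among
#' reference cytosines outside CpG context) is reported as a per-molecule
#' bisulfite conversion QC measure.
#'
#' @param read A single read sequence.
#' @param target The [amplicon_target()] the read matched.
#' @param alignment Optional alignment from [match_read()]; recomputed if
#'   missing.
#' @param read_id Optional identifier carried into the result.
#' @return One-row data frame (class `molecule_call`): `read_id`, `target`,
#'   `similarity`, `n_cpg`, `n_meth`, `n_unmeth`, `n_ambiguous`,
#'   `fully_unmethylated`, `fully_methylated`, `noncpg_conversion_rate`,
#'   plus list column `cpg_states`.
#' @export
call_molecule <- function(read, target, alignment = NULL, read_id = NA_character_) {
  stopifnot(inherits(target, "amplicon_target"))
  if (is.null(alignment)) alignment <- .align_to_target(read, target)
  map <- alignment$tpos_to_read
  rchars <- strsplit(read, "", fixed = TRUE)[[1L]]
  at <- function(tpos) {
    ri <- map[tpos]
    if (is.na(ri)) "-" else rchars[ri]
  }
  states <- vapply(target$cpg_sites, function(p) {
    dinuc <- paste0(at(p), at(p + 1L))
    if (dinuc == "CG") "methylated"
    else if (dinuc == "TG") "unmethylated"
    else "ambiguous"
  }, character(1L))

  # conversion QC over non-CpG reference cytosines
  ref <- strsplit(target$reference_seq, "", fixed = TRUE)[[1L]]
  non_cpg_c <- setdiff(which(ref == "C"), target$cpg_sites)
  obs <- vapply(non_cpg_c, at, character(1L))
  n_conv <- sum(obs == "T")
  n_ret <- sum(obs == "C")
  conv_rate <- if (n_conv + n_ret > 0) n_conv / (n_conv + n_ret) else NA_real_

  n_unmeth <- sum(states == "unmethylated")
  n_meth <- sum(states == "methylated")
  out <- data.frame(
    read_id = read_id,
    target = target$name,
    similarity = alignment$similarity,
    n_cpg = length(states),
    n_meth = n_meth,
    n_unmeth = n_unmeth,
    n_ambiguous = sum(states == "ambiguous"),
    fully_unmethylated = n_unmeth == length(states),
    fully_methylated = n_meth == length(states),
    noncpg_conversion_rate = conv_rate,
    stringsAsFactors = FALSE
  )
  out$cpg_states <- list(states)
  class(out) <- c("molecule_call", "data.frame")
  out
}
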