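#' Summarise molecule calls into a per-sample quantification
#'
#' Collapses per-molecule CpG calls into the sample-level read funnel and
#' the assay's output quantity. A molecule is *valid* when every expected
#' CpG was observed unambiguously, and counts as target-derived only when
#' all of them are unmethylated. The unmethylated fraction
#' (`n_fully_unmethylated / n_valid`) multiplied by the total cfDNA
#' concentration gives target-tissue genome equivalents per ml plasma:
#' `fraction * cfdna_conc_ng_per_ml * 1000 / pg_per_genome` (with 3.3 pg per
#' haploid genome, 3.3 ng of cfDNA is 1000 genome equivalents).
#'
#' The cfDNA concentration should be measured *before* bisulfite conversion;
#' bisulfite degrades most input DNA but affects methylated and unmethylated
#' molecules equally, so the fraction — and therefore copies/ml — is
#' unbiased by degradation.
#'
#' @param calls Data frame of [call_molecule()] rows (matched reads only).
#' @param cfdna_conc_ng_per_ml Total cfDNA mass concentration (ng per ml
#'   plasma), pre-bisulfite. `NA` yields `NA` copies/ml.
#' @param pg_per_genome Mass of one haploid genome equivalent in picograms.
#'   Default 3.3.
#' @param sample_id Sample identifier.
#' @param n_reads_total,n_quality_pass Upstream funnel counts; default to
#'   the number of calls when the funnel is not tracked.
#' @param conversion_qc_min Optional minimum per-molecule non-CpG conversion
#'   rate; molecules below it are dropped before counting (off by default).
#' @return An object of class `sample_quant`: a list with `sample_id`,
#'   `n_reads_total`, `n_quality_pass`, `n_matched`, `n_valid`,
#'   `n_fully_unmethylated`, `unmethylated_fraction`,
#'   `cfdna_conc_ng_per_ml`, `pg_per_genome`, `genome_equivalents_per_ml`.
#' @export
quantify_sample <- function(calls, cfdna_conc_ng_per_ml = NA_real_,
                            pg_per_genome = 3.3, sample_id = "sample",
                            n_reads_total = NULL, n_quality_pass = NULL,
                            conversion_qc_min = NULL) {
  if (!is.na(cfdna_conc_ng_per_ml) && cfdna_conc_ng_per_ml < 0)
    stop("cfdna_conc_ng_per_ml must be non-negative")
  stopifnot(pg_per_genome > 0)
  n_matched <- nrow(calls)
  if (!is.null(conversion_qc_min) && n_matched > 0) {
    keep <- !is.na(calls$noncpg_conversion_rate) &
      calls$noncpg_conversion_rate >= conversion_qc_min
    calls <- calls[keep, , drop = FALSE]
  }
  n_valid <- if (n_matched) sum(calls$n_ambiguous == 0L) else 0L
  n_unmeth <- if (n_matched) sum(calls$fully_unmethylated & calls$n_ambiguous == 0L) else 0L
  if (is.null(n_quality_pass)) n_quality_pass <- n_matched
  if (is.null(n_reads_total)) n_reads_total <- n_quality_pass
  if (n_valid == 0L) {
    frac <- 0
    if (n_matched > 0L || n_reads_total > 0L)
      warning("no valid molecules for sample '", sample_id,
              "'; unmethylated fraction reported as 0")
  } else {
    frac <- n_unmeth / n_valid
  }
  structure(list(
    sample_id = sample_id,
    n_reads_total = as.integer(n_reads_total),
    n_quality_pass = as.integer(n_quality_pass),
    n_matched = as.integer(n_matched),
    n_valid = as.integer(n_valid),
    n_fully_unmethylated = as.integer(n_unmeth),
    unmethylated_fraction = frac,
    cfdna_conc_ng_per_ml = cfdna_conc_ng_per_ml,
    pg_per_genome = pg_per_genome,
    genome_equivalents_per_ml = frac * cfdna_conc_ng_per_ml * 1000 / pg_per_genome
  ), class = "sample_quant")
}

#' @export
print.sample_quant <- function(x, ...) {
  cat(sprintf("<sample_quant> %s\n", x$sample_id))
  cat(sprintf("  reads: %d total -> %d quality-pass -> %d matched -> %d valid\n",
              x$n_reads_total, x$n_quality_pass, x$n_matched, x$n_valid))
  cat(sprintf("  fully unmethylated: %d (fraction %.4g)\n",
              x$n_fully_unmethylated, x$unmethylated_fraction))
  cat(sprintf("  genome equivalents/ml plasma: %.4g (cfDNA %.3g ng/ml)\n",
              x$genome_equivalents_per_ml, x$cfdna_conc_ng_per_ml))
  invisible(x)
}

#' Pool sense- and antisense-strand quantifications
#'
#' Bisulfite conversion leaves the two strands of a locus non-complementary,
#' so the sense and antisense markers are assayed as independent biomarkers
#' in the same solution. This pools their molecule counts — fraction =
#' (sum of fully unmethylated) / (sum of valid) — and recomputes copies/ml
#' from the pooled fraction, retaining the per-strand quantities for
#' concordance checks. If one strand contributed no valid molecules the
#' pooled result equals the other strand (with a warning).
#'
#' @param sense,antisense `sample_quant` objects for the same sample.
#' @return A `sample_quant` with the pooled funnel, plus a `per_strand`
#'   element holding the two inputs.
#' @export
combine_strand_markers <- function(sense, antisense) {
  stopifnot(inherits(sense, "sample_quant"), inherits(antisense, "sample_quant"))
  if (!identical(sense$sample_id, antisense$sample_id))
    stop("sense and antisense quantifications are from different samples (",
         sense$sample_id, " vs ", antisense$sample_id, ")")
  if (!isTRUE(all.equal(sense$cfdna_conc_ng_per_ml, antisense$cfdna_conc_ng_per_ml)))
    stop("sense and antisense quantifications carry different cfDNA concentrations")
  if (sense$n_valid == 0L || antisense$n_valid == 0L)
    warning("one strand has no valid molecules; pooled result equals the other strand")
  n_valid <- sense$n_valid + antisense$n_valid
  n_unmeth <- sense$n_fully_unmethylated + antisense$n_fully_unmethylated
  frac <- if (n_valid > 0L) n_unmeth / n_valid else 0
  out <- structure(list(
    sample_id = sense$sample_id,
    n_reads_total = sense$n_reads_total + antisense$n_reads_total,
    n_quality_pass = sense$n_quality_pass + antisense$n_quality_pass,
    n_matched = sense$n_matched + antisense$n_matched,
    n_valid = n_valid,
    n_fully_unmethylated = n_unmeth,
    unmethylated_fraction = frac,
    cfdna_conc_ng_per_ml = sense$cfdna_conc_ng_per_ml,
    pg_per_genome = sense$pg_per_genome,
    genome_equivalents_per_ml =
      frac * sense$cfdna_conc_ng_per_ml * 1000 / sense$pg_per_genome
  ), class = "sample_quant")
  out$per_strand <- list(sense = sense, antisense = antisense)
  out
}

# Batch engine: align + call every read against the target set without
# per-read data-frame overhead. Returns the molecule-call table for matched
# reads plus funnel counts.
.process_reads <- function(reads, targets, q_min, min_similarity) {
  n_total <- nrow(reads)
  pass <- if (n_total) quality_filter(reads$seq, reads$qual, q_min = q_min) else logical(0)
  kept <- reads[pass, , drop = FALSE]
  n <- nrow(kept)
  tnames <- vapply(targets, `[[`, "", "name")
  ref_chars <- lapply(targets, function(t) strsplit(t$reference_seq, "", fixed = TRUE)[[1L]])
  noncpg_c <- lapply(seq_along(targets), function(k)
    setdiff(which(ref_chars[[k]] == "C"), targets[[k]]$cpg_sites))

  target_i <- integer(n); sim <- numeric(n)
  n_meth <- integer(n); n_unmeth <- integer(n); n_amb <- integer(n)
  conv <- numeric(n)
  states_l <- vector("list", n)

  for (r in seq_len(n)) {
    read <- kept$seq[r]
    best <- NULL; best_k <- 0L
    for (k in seq_along(targets)) {
      a <- .align_to_target(read, targets[[k]])
      if (is.null(best) || a$similarity > best$similarity) { best <- a; best_k <- k }
    }
    sim[r] <- best$similarity
    if (best$similarity < min_similarity) { target_i[r] <- 0L; next }
    target_i[r] <- best_k
    tg <- targets[[best_k]]
    map <- best$tpos_to_read
    rc <- strsplit(read, "", fixed = TRUE)[[1L]]
    base_at <- function(tp) {
      ri <- map[tp]
      if (is.na(ri)) "-" else rc[ri]
    }
    st <- vapply(tg$cpg_sites, function(p) {
      d <- paste0(base_at(p), base_at(p + 1L))
      if (d == "CG") "methylated" else if (d == "TG") "unmethylated" else "ambiguous"
    }, character(1L))
    states_l[[r]] <- st
    n_meth[r] <- sum(st == "methylated")
    n_unmeth[r] <- sum(st == "unmethylated")
    n_amb[r] <- sum(st == "ambiguous")
    obs <- vapply(noncpg_c[[best_k]], base_at, character(1L))
    nc <- sum(obs == "T"); nr <- sum(obs == "C")
    conv[r] <- if (nc + nr > 0) nc / (nc + nr) else NA_real_
  }

  matched <- target_i > 0L
  calls <- data.frame(
    read_id = kept$read_id[matched],
    target = tnames[target_i[matched]],
    similarity = sim[matched],
    n_cpg = vapply(targets[target_i[matched]], `[[`, 0L, "n_cpg"),
    n_meth = n_meth[matched],
    n_unmeth = n_unmeth[matched],
    n_ambiguous = n_amb[matched],
    fully_unmethylated = n_unmeth[matched] ==
      vapply(targets[target_i[matched]], `[[`, 0L, "n_cpg"),
    fully_methylated = n_meth[matched] ==
      vapply(targets[target_i[matched]], `[[`, 0L, "n_cpg"),
    noncpg_conversion_rate = conv[matched],
    stringsAsFactors = FALSE
  )
  calls$cpg_states <- states_l[matched]
  list(calls = calls, n_reads_total = n_total, n_quality_pass = n)
}

#' Run the full bisulfite amplicon quantification pipeline
#'
#' Takes raw amplicon reads through the complete funnel — mean-quality
#' filtering, wildcarded similarity matching to the target templates,
#' per-CpG methylation calling, molecule counting — and returns per-target
#' and (optionally) strand-pooled sample quantifications.
#'
#' @param reads Data frame with columns `read_id`, `seq`, `qual`, or a path
#'   to a FASTQ file.
#' @param targets A single [amplicon_target()] or a list of them (e.g. the
#'   sense and antisense markers of one locus).
#' @param cfdna_conc_ng_per_ml Total cfDNA concentration, pre-bisulfite.
#' @param sample_id Sample identifier.
#' @param q_min Mean Phred threshold for [quality_filter()]. Default 30.
#' @param min_similarity Matching threshold for [match_read()]. Default 0.8.
#' @param pg_per_genome Picograms per haploid genome equivalent. Default 3.3.
#' @param conversion_qc_min Optional per-molecule conversion-QC threshold
#'   (see [quantify_sample()]).
#' @param combine_strands Pool a sense/antisense target pair into one
#'   quantification via [combine_strand_markers()]. Default `TRUE`.
#' @return List with `calls` (per-molecule table), `per_target` (named list
#'   of `sample_quant`, one per target), and `combined` (strand-pooled
#'   `sample_quant` when exactly one sense and one antisense target are
#'   present, otherwise the single target's quantification).
#' @examples
#' tg <- amplicon_target("demo", "ATCGGACGTACGTTACGAACGTTTACGGATCGA")
#' sim <- make_reads(tg, sim_config(n_molecules = 200, cardiac_fraction = 0.5,
#'                                  seed = 42))
#' res <- amplicon_quantify(sim$reads, tg, cfdna_conc_ng_per_ml = 16.5)
#' res$combined
#' @export
amplicon_quantify <- function(reads, targets, cfdna_conc_ng_per_ml = NA_real_,
                              sample_id = "sample", q_min = 30,
                              min_similarity = 0.8, pg_per_genome = 3.3,
                              conversion_qc_min = NULL, combine_strands = TRUE) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  stopifnot(is.data.frame(reads),
            all(c("read_id", "seq", "qual") %in% names(reads)))
  if (inherits(targets, "amplicon_target")) targets <- list(targets)
  proc <- .process_reads(reads, targets, q_min, min_similarity)
  tnames <- vapply(targets, `[[`, "", "name")
  per_target <- lapply(tnames, function(nm) {
    quantify_sample(proc$calls[proc$calls$target == nm, , drop = FALSE],
                    cfdna_conc_ng_per_ml = cfdna_conc_ng_per_ml,
                    pg_per_genome = pg_per_genome, sample_id = sample_id,
                    n_reads_total = proc$n_reads_total,
                    n_quality_pass = proc$n_quality_pass,
                    conversion_qc_min = conversion_qc_min)
  })
  names(per_target) <- tnames
  strands <- vapply(targets, `[[`, "", "strand")
  combined <- NULL
  if (length(targets) == 1L) {
    combined <- per_target[[1L]]
  } else if (combine_strands && sum(strands == "sense") == 1L &&
             sum(strands == "antisense") == 1L) {
    s <- per_target[[which(strands == "sense")]]
    a <- per_target[[which(strands == "antisense")]]
    # funnel totals are shared across the multiplexed pair; pool counts only
    combined <- combine_strand_markers(s, a)
    combined$n_reads_total <- proc$n_reads_total
    combined$n_quality_pass <- proc$n_quality_pass
  }
  list(calls = proc$calls, per_target = per_target, combined = combined)
}
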