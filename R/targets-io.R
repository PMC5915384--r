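# Target definitions on disk: a TSV of annotations plus a FASTA of
# reference sequences keyed by target name.

#' Read amplicon target definitions
#'
#' Loads targets from a tab-separated annotation file (columns `name`,
#' `chrom`, `start`, `end`, `strand`, `primer_fwd`, `primer_rev`; coordinates
#' 1-based inclusive) and a FASTA file of unconverted reference sequences
#' whose record names match the `name` column.
#'
#' @param tsv Path to the target annotation TSV.
#' @param fasta Path to the reference FASTA.
#' @return Named list of [amplicon_target()] objects, in TSV order.
#' @seealso [write_targets()]
#' @export
read_targets <- function(tsv, fasta) {
  ann <- read.delim(tsv, stringsAsFactors = FALSE)
  required <- c("name", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(ann))
  if (length(missing))
    stop("target TSV is missing columns: ", paste(missing, collapse = ", "))
  seqs <- Biostrings::readDNAStringSet(fasta)
  out <- lapply(seq_len(nrow(ann)), function(i) {
    nm <- ann$name[i]
    if (!nm %in% names(seqs))
      stop("no FASTA record for target '", nm, "'")
    amplicon_target(
      name = nm,
      reference_seq = as.character(seqs[[nm]]),
      chrom = ann$chrom[i], start = ann$start[i], end = ann$end[i],
      strand = ann$strand[i],
      primer_fwd = if ("primer_fwd" %in% names(ann)) ann$primer_fwd[i] else "",
      primer_rev = if ("primer_rev" %in% names(ann)) ann$primer_rev[i] else ""
    )
  })
  names(out) <- ann$name
  out
}

#' Write amplicon target definitions
#'
#' Inverse of [read_targets()]: writes the annotation TSV and the reference
#' FASTA for a list of targets.
#'
#' @param targets List of `amplicon_target` objects.
#' @param tsv,fasta Output paths.
#' @return Invisibly, the annotation data frame.
#' @export
write_targets <- function(targets, tsv, fasta) {
  stopifnot(length(targets) >= 1L)
  ann <- do.call(rbind, lapply(targets, function(t) {
    data.frame(name = t$name, chrom = t$chrom, start = t$start, end = t$end,
               strand = t$strand, primer_fwd = t$primer_fwd,
               primer_rev = t$primer_rev, stringsAsFactors = FALSE)
  }))
  write.table(ann, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  seqs <- Biostrings::DNAStringSet(vapply(targets, `[[`, "", "reference_seq"))
  names(seqs) <- vapply(targets, `[[`, "", "name")
  Biostrings::writeXStringSet(seqs, fasta)
  invisible(ann)
}

#' Read a FASTQ file into a data frame
#'
#' @param path FASTQ file (optionally gzipped).
#' @return A data frame with columns `read_id`, `seq`, `qual` (Phred+33).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    read_id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads Data frame with columns `read_id`, `seq`, `qual`.
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)),
            all(nchar(reads$seq) == nchar(reads$qual)))
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- reads$read_id
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}
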