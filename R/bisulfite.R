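#' In-silico bisulfite conversion
#'
#' Applies the bisulfite conversion chemistry to a DNA sequence: every
#' unmethylated cytosine is deaminated to uracil and read as thymine. In
#' mammalian DNA methylation is confined to CpG dinucleotides, so a cytosine
#' outside CpG context is always converted, while a CpG cytosine is converted
#' only if unmethylated. `cpg_methylated` selects between the two idealised
#' templates: the fully methylated molecule (CpG cytosines retained as C) and
#' the fully unmethylated molecule (all cytosines read as T).
#'
#' CpG context is evaluated on the input (unconverted) sequence. `N` bases
#' pass through unchanged, and a cytosine followed by `N` is treated as
#' non-CpG (converted).
#'
#' @param seq Character vector of DNA sequences (A/C/G/T/N).
#' @param cpg_methylated Logical; if `TRUE`, CpG cytosines are protected from
#'   conversion (methylated molecule), otherwise every cytosine converts.
#' @return Character vector of converted sequences, same lengths as input.
#' @examples
#' bisulfite_convert("TTCGATC")                        # "TTTGATT"
#' bisulfite_convert("TTCGATC", cpg_methylated = TRUE) # "TTCGATT"
#' @export
bisulfite_convert <- function(seq, cpg_methylated = FALSE) {
  stopifnot(is.logical(cpg_methylated), length(cpg_methylated) == 1L)
  vapply(seq, function(s) {
    s <- .check_dna(s)
    if (cpg_methylated) {
      # protect C only in CG context; lookahead does not consume the G
      gsub("C(?!G)", "T", s, perl = TRUE)
    } else {
      gsub("C", "T", s, fixed = TRUE)
    }
  }, character(1L), USE.NAMES = FALSE)
}

#' Locate CpG sites in a sequence
#'
#' Returns the 1-based positions of the cytosine of every CG dinucleotide.
#' A CpG whose C or G is an `N` is not reported.
#'
#' @param seq A single DNA sequence.
#' @return Strictly increasing integer vector of C positions (1-based);
#'   `integer(0)` if the sequence contains no CpG.
#' @examples
#' find_cpg_sites("CGCG")   # c(1, 3)
#' find_cpg_sites("AAAA")   # integer(0)
#' @export
find_cpg_sites <- function(seq) {
  s <- .check_dna(seq)
  hits <- gregexpr("CG", s, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

#' Construct an amplicon target
#'
#' An amplicon target bundles a genomic reference sequence with the two
#' idealised bisulfite-converted templates (fully methylated and fully
#' unmethylated) and the positions of its CpG sites. Reads are matched and
#' called against these templates: outside CpG context the two templates are
#' identical, and at each CpG the unmethylated template carries T where the
#' methylated template carries C.
#'
#' Genomic coordinates are 1-based inclusive (the Bioconductor convention);
#' `end - start + 1` must equal the reference length when coordinates are
#' supplied.
#'
#' @param name Target identifier.
#' @param reference_seq Uppercase genomic (unconverted) DNA sequence.
#' @param chrom,start,end Optional genomic coordinates (1-based inclusive).
#' @param strand `"sense"` or `"antisense"`.
#' @param primer_fwd,primer_rev Optional primer sequences (annotation only).
#' @return An object of class `amplicon_target`: a list with elements
#'   `name`, `chrom`, `start`, `end`, `strand`, `reference_seq`,
#'   `converted_template_unmeth`, `converted_template_meth`, `cpg_sites`
#'   (1-based offsets of CpG cytosines within the template), `n_cpg`,
#'   `primer_fwd`, `primer_rev`.
#' @examples
#' tg <- amplicon_target("demo", "ATCGGACGTACGTT")
#' tg$n_cpg
#' tg$converted_template_unmeth
#' @export
amplicon_target <- function(name, reference_seq, chrom = NA_character_,
                            start = NA_integer_, end = NA_integer_,
                            strand = c("sense", "antisense"),
                            primer_fwd = "", primer_rev = "") {
  strand <- match.arg(strand)
  ref <- .check_dna(reference_seq, what = "reference_seq")
  cpg <- find_cpg_sites(ref)
  if (length(cpg) < 1L)
    stop("amplicon target '", name, "' contains no CpG site")
  if (!is.na(start) && !is.na(end)) {
    start <- as.integer(start); end <- as.integer(end)
    if (start > end) stop("start must be <= end")
    if (end - start + 1L != nchar(ref))
      stop("coordinate span (", end - start + 1L,
           ") does not match reference length (", nchar(ref), ")")
  }
  obj <- structure(list(
    name = as.character(name),
    chrom = as.character(chrom),
    start = start,
    end = end,
    strand = strand,
    reference_seq = ref,
    converted_template_unmeth = bisulfite_convert(ref, cpg_methylated = FALSE),
    converted_template_meth = bisulfite_convert(ref, cpg_methylated = TRUE),
    cpg_sites = cpg,
    n_cpg = length(cpg),
    primer_fwd = toupper(primer_fwd),
    primer_rev = toupper(primer_rev)
  ), class = "amplicon_target")
  obj
}

#' @export
print.amplicon_target <- function(x, ...) {
  coords <- if (!is.na(x$start)) sprintf(" %s:%d-%d", x$chrom, x$start, x$end) else ""
  cat(sprintf("<amplicon_target> %s (%s strand)%s\n", x$name, x$strand, coords))
  cat(sprintf("  %d bp, %d CpG sites at offsets: %s\n", nchar(x$reference_seq),
              x$n_cpg, paste(x$cpg_sites, collapse = ", ")))
  invisible(x)
}

#' Derive the antisense-strand target of a sense amplicon
#'
#' After bisulfite conversion the two strands of a locus are no longer
#' complementary, so each strand can be assayed as an independent biomarker
#' with its own primers. This builds the antisense target: the reference is
#' reverse complemented and the converted templates and CpG offsets are
#' recomputed on that strand. Because CG is its own reverse complement the
#' CpG count is preserved.
#'
#' @param target An `amplicon_target` with `strand = "sense"`.
#' @param name Name for the derived target; defaults to `"<name>_AS"`.
#' @return A new `amplicon_target` with `strand = "antisense"`.
#' @examples
#' s <- amplicon_target("demo", "ATCGGACGTACGTT")
#' as <- antisense_template(s)
#' as$n_cpg == s$n_cpg
#' @export
antisense_template <- function(target, name = paste0(target$name, "_AS")) {
  stopifnot(inherits(target, "amplicon_target"))
  if (target$strand != "sense")
    stop("antisense_template() expects a sense-strand target")
  amplicon_target(
    name = name,
    reference_seq = .reverse_complement(target$reference_seq),
    chrom = target$chrom, start = target$start, end = target$end,
    strand = "antisense",
    primer_fwd = target$primer_rev, primer_rev = target$primer_fwd
  )
}

#' Genomic span of 1-based inclusive coordinates
#'
#' Convenience for the width of a region printed in the 1-based inclusive
#' convention used by genome browsers (e.g. a 90 bp amplicon printed as
#' start 124692462, end 124692551).
#'
#' @param start,end 1-based inclusive coordinates.
#' @return Integer width `end - start + 1`.
#' @export
region_width <- function(start, end) {
  stopifnot(all(end >= start))
  as.integer(end) - as.integer(start) + 1L
}
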