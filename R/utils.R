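# Internal helpers shared across modules.

# Validate a single DNA string; returns the uppercased string.
# Reports the first offending character and its 1-based position.
.check_dna <- function(seq, allow_n = TRUE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single non-NA character string")
  s <- toupper(seq)
  pattern <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- regexpr(pattern, s)
  if (bad != -1L)
    stop(sprintf("invalid base '%s' in %s at position %d",
                 substr(s, bad, bad), what, as.integer(bad)))
  s
}

# Phred+33 quality string -> integer vector of phred scores.
.phred <- function(qual) {
  utf8ToInt(qual) - 33L
}

.int_to_qual <- function(q) {
  intToUtf8(pmax(0L, pmin(41L, as.integer(round(q)))) + 33L)
}

# Seed handling: when `seed` is given, run with a locally-set RNG state and
# restore the caller's state afterwards.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

.reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
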