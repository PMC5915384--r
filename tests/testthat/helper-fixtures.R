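# Deterministic fixtures and independent oracles used across test files.

# A 90 bp reference with exactly six CpG sites and three lone (non-CpG)
# cytosines -- the structural shape of a cardiomyocyte marker amplicon.
fixture_ref_90bp <- function() {
  base <- strsplit(paste(rep("ATTGA", 18), collapse = ""), "")[[1]]
  cpg <- c(5, 21, 35, 50, 64, 83)
  for (p in cpg) {
    base[p] <- "C"
    base[p + 1] <- "G"
  }
  for (p in c(10, 40, 70)) base[p] <- "C"   # next base is never G
  paste(base, collapse = "")
}

fixture_target <- function(name = "marker_S") {
  amplicon_target(name, fixture_ref_90bp(),
                  chrom = "chr12", start = 124692462L, end = 124692551L,
                  strand = "sense")
}

# Independent CpG counter: scans dinucleotides one by one.
count_cg_dinucleotides <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- 0L
  for (i in seq_len(length(ch) - 1L))
    if (ch[i] == "C" && ch[i + 1L] == "G") n <- n + 1L
  n
}

# Brute-force marker-scan oracle: checks EVERY contiguous site run against
# the criteria, then merges overlapping qualifying runs by pairwise
# fix-point merging (a different algorithm from the package's sweep).
brute_scan <- function(mat, target_tissues, background_tissues,
                       max_span_bp = 100, min_cpg = 5,
                       background_min_meth = 0.8, target_max_meth = 0.2) {
  out <- NULL
  for (chr in unique(mat$sites$chrom)) {
    sel <- mat$sites$chrom == chr
    pos <- mat$sites$pos[sel]
    B <- mat$beta[sel, , drop = FALSE]
    n <- length(pos)
    qual <- list()
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j - i + 1 < min_cpg) next
        if (pos[j] - pos[i] + 1 >= max_span_bp) next
        if (anyNA(B[i:j, c(target_tissues, background_tissues)])) next
        tm <- colMeans(B[i:j, target_tissues, drop = FALSE])
        bm <- colMeans(B[i:j, background_tissues, drop = FALSE])
        if (all(tm < target_max_meth) && all(bm > background_min_meth))
          qual[[length(qual) + 1L]] <- c(i, j)
      }
    }
    if (!length(qual)) next
    iv <- do.call(rbind, qual)
    repeat {
      merged_any <- FALSE
      k <- 1L
      while (k < nrow(iv)) {
        l <- k + 1L
        while (l <= nrow(iv)) {
          if (iv[k, 1] <= iv[l, 2] && iv[l, 1] <= iv[k, 2]) {
            iv[k, ] <- c(min(iv[k, 1], iv[l, 1]), max(iv[k, 2], iv[l, 2]))
            iv <- iv[-l, , drop = FALSE]
            merged_any <- TRUE
          } else l <- l + 1L
        }
        k <- k + 1L
      }
      if (!merged_any) break
    }
    out <- rbind(out, data.frame(chrom = chr, start = pos[iv[, 1]],
                                 end = pos[iv[, 2]] + 1L,
                                 n_cpg = iv[, 2] - iv[, 1] + 1L))
  }
  if (is.null(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpg = integer(0)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force AUC: all pairwise case/control comparisons, ties scoring 1/2.
brute_auc <- function(controls, cases) {
  s <- 0
  for (x in controls) for (y in cases)
    s <- s + (y > x) + 0.5 * (y == x)
  s / (length(controls) * length(cases))
}

# Random methylome with (optionally) one planted qualifying marker.
random_methylome <- function(seed, n_sites = 120, plant = TRUE) {
  tissues <- c("heart", paste0("bg", 1:5))
  planted <- if (plant) {
    at <- 20 + (seed %% 60)
    list(list(at = at, n_cpg = 5 + (seed %% 3), span_bp = 70 + (seed %% 25),
              target_beta = 0.05, background_beta = 0.95))
  } else list()
  make_methylome(n_sites, tissues, planted = planted,
                 target_tissues = "heart", seed = seed)
}

# Reads for a multiplexed sense + antisense run: simulate each strand's
# amplicon separately and pool the FASTQ records under unique ids.
sim_both_strands <- function(tg, as, n_molecules, cardiac_fraction, seed) {
  half <- floor(n_molecules / 2)
  s <- make_reads(tg, sim_config(n_molecules = half,
                                 cardiac_fraction = cardiac_fraction,
                                 seed = seed))$reads
  a <- make_reads(as, sim_config(n_molecules = n_molecules - half,
                                 cardiac_fraction = cardiac_fraction,
                                 seed = seed + 1L))$reads
  s$read_id <- paste0("S_", s$read_id)
  a$read_id <- paste0("AS_", a$read_id)
  rbind(s, a)
}

# Quality string with an exact mean Phred value (constant per base).
qual_const <- function(len, q) {
  paste(rep(intToUtf8(q + 33L), len), collapse = "")
}
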