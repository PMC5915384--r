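test_that("mean-quality filtering is deterministic and boundary-inclusive", {
  seq40 <- strrep("A", 10)
  expect_true(quality_filter(seq40, qual_const(10, 40)))
  expect_false(quality_filter(seq40, qual_const(10, 2)))
  # half Q40 / half Q20: mean exactly 30 passes at q_min = 30
  mixed <- paste0(qual_const(5, 40), qual_const(5, 20))
  expect_true(quality_filter(seq40, mixed, q_min = 30))
  expect_error(quality_filter("ACGT", "III"), "length mismatch")
})

test_that("reads match their target regardless of methylation state", {
  tg <- fixture_target()
  as <- antisense_template(tg)
  targets <- list(tg, as)
  # identity to either converted template scores 1.0: CpG wildcarding means
  # methylation cannot reduce similarity
  for (tmpl in c(tg$converted_template_unmeth, tg$converted_template_meth)) {
    m <- match_read(tmpl, targets)
    expect_identical(m$target, tg$name)
    expect_equal(m$similarity, 1.0)
  }
  m <- match_read(as$converted_template_meth, targets)
  expect_identical(m$target, as$name)
})

test_that("reads below 80% similarity are left unassigned", {
  # non-repetitive 100 bp target so scattered substitutions cannot be
  # absorbed by a cheaper gapped alignment
  set.seed(33)
  ref <- paste(c("C", "G", sample(c("A", "T", "G"), 98, replace = TRUE)),
               collapse = "")
  tg <- amplicon_target("lowsim", ref)
  tmpl <- strsplit(tg$converted_template_unmeth, "")[[1]]
  flip <- list(A = "T", T = "G", G = "A")
  idx <- seq(5, 100, by = 3)[1:25]
  for (p in idx) tmpl[p] <- flip[[tmpl[p]]]
  read <- paste(tmpl, collapse = "")
  m <- match_read(read, list(tg))
  # independent oracle: plain edit distance (the lone CpG is untouched)
  expect_identical(as.integer(adist(read, tg$converted_template_unmeth)), 25L)
  expect_equal(m$similarity, 1 - 25 / 100)
  expect_true(is.na(m$target))
})

test_that("wildcarded similarity agrees with plain edit distance off-CpG", {
  tg <- fixture_target()
  set.seed(21)
  for (i in 1:20) {
    meth <- i %% 2 == 0
    tmpl <- if (meth) tg$converted_template_meth else tg$converted_template_unmeth
    ch <- strsplit(tmpl, "")[[1]]
    protected <- c(tg$cpg_sites, tg$cpg_sites + 1L)
    k <- sample(0:8, 1)
    idx <- sample(setdiff(seq_along(ch), protected), k)
    for (p in idx) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    read <- paste(ch, collapse = "")
    got <- match_read(read, list(tg))$similarity
    # pure methylation patterns make the wildcard irrelevant, so base::adist
    # against the corresponding plain template is an independent oracle
    want <- 1 - as.integer(adist(read, tmpl)) / nchar(tmpl)
    expect_equal(got, want, label = paste("iteration", i))
  }
})

test_that("CpG states are called from the aligned dinucleotide", {
  tg <- fixture_target()
  cm <- call_molecule(tg$converted_template_unmeth, tg)
  expect_identical(cm$cpg_states[[1]], rep("unmethylated", 6))
  expect_true(cm$fully_unmethylated)
  expect_false(cm$fully_methylated)

  cm <- call_molecule(tg$converted_template_meth, tg)
  expect_identical(cm$cpg_states[[1]], rep("methylated", 6))
  expect_false(cm$fully_unmethylated)
  expect_true(cm$fully_methylated)

  # five TG + one CG: a partial pattern is NOT counted as target-derived
  ch <- strsplit(tg$converted_template_unmeth, "")[[1]]
  ch[tg$cpg_sites[3]] <- "C"
  cm <- call_molecule(paste(ch, collapse = ""), tg)
  expect_identical(cm$n_unmeth, 5L)
  expect_identical(cm$n_meth, 1L)
  expect_false(cm$fully_unmethylated)

  # a sequencing error at a CpG C, or a deletion, makes the site ambiguous
  ch <- strsplit(tg$converted_template_unmeth, "")[[1]]
  ch[tg$cpg_sites[1]] <- "A"
  cm <- call_molecule(paste(ch, collapse = ""), tg)
  expect_identical(cm$n_ambiguous, 1L)
  del <- paste(ch[-tg$cpg_sites[2]], collapse = "")
  cm <- call_molecule(del, tg)
  expect_gte(cm$n_ambiguous, 2L)
  expect_false(cm$fully_unmethylated)
})

test_that("non-CpG conversion rate counts converted vs retained cytosines", {
  tg <- fixture_target()
  ref <- strsplit(tg$reference_seq, "")[[1]]
  noncpg <- setdiff(which(ref == "C"), tg$cpg_sites)
  expect_length(noncpg, 3L)
  # fully converted molecule: rate 1
  expect_equal(call_molecule(tg$converted_template_unmeth, tg)$noncpg_conversion_rate, 1)
  # retain one non-CpG cytosine: rate 2/3
  ch <- strsplit(tg$converted_template_unmeth, "")[[1]]
  ch[noncpg[1]] <- "C"
  expect_equal(call_molecule(paste(ch, collapse = ""), tg)$noncpg_conversion_rate, 2 / 3)
})

test_that("genome-equivalent arithmetic follows fraction x mass / genome mass", {
  tg <- fixture_target()
  unmeth_call <- function(n) {
    do.call(rbind, replicate(n, call_molecule(tg$converted_template_unmeth, tg),
                             simplify = FALSE))
  }
  meth_call <- function(n) {
    do.call(rbind, replicate(n, call_molecule(tg$converted_template_meth, tg),
                             simplify = FALSE))
  }
  # fraction 0 -> 0 copies/ml regardless of concentration
  q <- quantify_sample(meth_call(10), cfdna_conc_ng_per_ml = 50)
  expect_equal(q$genome_equivalents_per_ml, 0)
  # fraction 1 at 3.3 ng/ml and 3.3 pg/genome -> 1000 copies/ml
  q <- quantify_sample(unmeth_call(10), cfdna_conc_ng_per_ml = 3.3)
  expect_equal(q$genome_equivalents_per_ml, 1000)
  # fraction 0.001 at 16.5 ng/ml -> 5 copies/ml
  calls <- rbind(unmeth_call(1), meth_call(999))
  q <- quantify_sample(calls, cfdna_conc_ng_per_ml = 16.5)
  expect_equal(q$unmethylated_fraction, 0.001)
  expect_equal(q$genome_equivalents_per_ml, 5)
  expect_error(quantify_sample(calls, cfdna_conc_ng_per_ml = -1), "non-negative")
})

test_that("funnel counts are conserved at every stage", {
  tg <- fixture_target()
  as <- antisense_template(tg)
  reads <- sim_both_strands(tg, as, 4000, cardiac_fraction = 0.2, seed = 31)
  res <- amplicon_quantify(reads, list(tg, as), cfdna_conc_ng_per_ml = 10)
  for (q in c(res$per_target, list(res$combined))) {
    expect_lte(q$n_fully_unmethylated, q$n_valid)
    expect_lte(q$n_valid, q$n_matched)
    expect_lte(q$n_matched, q$n_quality_pass)
    expect_lte(q$n_quality_pass, q$n_reads_total)
    expect_gte(q$genome_equivalents_per_ml, 0)
    expect_true(q$unmethylated_fraction >= 0 && q$unmethylated_fraction <= 1)
  }
  expect_identical(res$combined$n_reads_total, nrow(reads))
})

test_that("strand pooling averages counts, not fractions", {
  tg <- fixture_target()
  mk <- function(n_unmeth, n_valid, conc = 33) {
    calls <- do.call(rbind, c(
      replicate(n_unmeth, call_molecule(tg$converted_template_unmeth, tg),
                simplify = FALSE),
      replicate(n_valid - n_unmeth, call_molecule(tg$converted_template_meth, tg),
                simplify = FALSE)))
    quantify_sample(calls, cfdna_conc_ng_per_ml = conc, sample_id = "s1")
  }
  a <- mk(10, 1000)
  b <- mk(0, 1000)
  pooled <- combine_strand_markers(a, b)
  expect_equal(pooled$unmethylated_fraction, 10 / 2000)
  expect_identical(pooled$n_valid, 2000L)
  expect_equal(pooled$genome_equivalents_per_ml,
               10 / 2000 * 33 * 1000 / 3.3)
  # identical strands pool to themselves
  same <- combine_strand_markers(a, a)
  expect_equal(same$unmethylated_fraction, a$unmethylated_fraction)
  # a strand with no valid molecules: pooled result equals the other strand
  no_calls <- data.frame(n_ambiguous = integer(0),
                         fully_unmethylated = logical(0),
                         noncpg_conversion_rate = numeric(0))
  empty <- quantify_sample(no_calls, cfdna_conc_ng_per_ml = 33,
                           sample_id = "s1")
  expect_warning(p2 <- combine_strand_markers(a, empty), "other strand")
  expect_equal(p2$unmethylated_fraction, a$unmethylated_fraction)
  # sample identity is enforced
  c_other <- mk(1, 10)
  c_other$sample_id <- "s2"
  expect_error(combine_strand_markers(a, c_other), "different samples")
})

test_that("methylated background reads almost never count as unmethylated", {
  # converting a 6-CpG methylated molecule into an apparently fully
  # unmethylated one requires an independent C->T corruption at every CpG,
  # so the false-positive rate collapses multiplicatively
  tg <- fixture_target()
  cfg <- sim_config(n_molecules = 20000, cardiac_fraction = 0,
                    per_base_error = 0.01, bisulfite_survival = c(1, 1),
                    seed = 77)
  sim <- make_reads(tg, cfg)
  res <- amplicon_quantify(sim$reads, tg)
  expect_lt(res$combined$unmethylated_fraction, 1e-4)
  expect_gt(res$combined$n_valid, 0L)
})
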