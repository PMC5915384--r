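test_that("identical configurations reproduce byte-identical outputs", {
  tg <- fixture_target()
  cfg <- sim_config(n_molecules = 500, cardiac_fraction = 0.1, seed = 123)
  a <- make_reads(tg, cfg)
  b <- make_reads(tg, cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(a$reads, f1)
  write_fastq(b$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the reads
  c <- make_reads(tg, sim_config(n_molecules = 500, cardiac_fraction = 0.1,
                                 seed = 124))
  expect_false(identical(a$reads$seq, c$reads$seq))
  # cohort and droplet generators are equally reproducible
  expect_identical(make_cohort(20, 20, seed = 5), make_cohort(20, 20, seed = 5))
  wells <- data.frame(well = "A01", sample_id = "s", target_copies = 100,
                      background_copies = 100)
  expect_identical(make_droplets(wells, n_droplets = 2000, seed = 7),
                   make_droplets(wells, n_droplets = 2000, seed = 7))
})

test_that("read origin labels match their pre-noise CpG patterns", {
  tg <- fixture_target()
  cfg <- sim_config(n_molecules = 400, cardiac_fraction = 0.5,
                    conversion_efficiency = 1, inappropriate_conversion = 0,
                    per_base_error = 0, bisulfite_survival = c(1, 1),
                    seed = 17)
  sim <- make_reads(tg, cfg)
  expect_identical(nrow(sim$reads), 400L)
  origin <- sim$truth$origin[match(sim$reads$read_id, sim$truth$read_id)]
  expect_identical(
    sim$reads$seq == tg$converted_template_unmeth, origin == "cardiac")
  expect_identical(
    sim$reads$seq == tg$converted_template_meth, origin == "leukocyte")
})

test_that("pure mixtures propagate exactly through the pipeline", {
  tg <- fixture_target()
  noise_free <- function(f) sim_config(n_molecules = 300, cardiac_fraction = f,
                                       conversion_efficiency = 1,
                                       inappropriate_conversion = 0,
                                       per_base_error = 0,
                                       bisulfite_survival = c(1, 1), seed = 18)
  all_cardiac <- make_reads(tg, noise_free(1))
  expect_true(all(all_cardiac$reads$seq == tg$converted_template_unmeth))
  none <- make_reads(tg, noise_free(0))
  res <- amplicon_quantify(none$reads, tg)
  expect_identical(res$combined$n_fully_unmethylated, 0L)
})

test_that("bisulfite degradation thins reads without biasing the fraction", {
  tg <- fixture_target()
  cfg_lo <- sim_config(n_molecules = 30000, cardiac_fraction = 0.2,
                       bisulfite_survival = c(0.1, 0.1), seed = 19)
  cfg_hi <- sim_config(n_molecules = 30000, cardiac_fraction = 0.2,
                       bisulfite_survival = c(0.4, 0.4), seed = 19)
  lo <- amplicon_quantify(make_reads(tg, cfg_lo)$reads, tg)$combined
  hi <- amplicon_quantify(make_reads(tg, cfg_hi)$reads, tg)$combined
  # read depth scales with survival...
  expect_gt(hi$n_valid, 2.5 * lo$n_valid)
  # ...but the two estimates agree: methylated and unmethylated molecules
  # are lost at the same rate, so the expected fraction is survival-free
  p <- (lo$n_fully_unmethylated + hi$n_fully_unmethylated) /
    (lo$n_valid + hi$n_valid)
  se_diff <- sqrt(p * (1 - p) * (1 / lo$n_valid + 1 / hi$n_valid))
  expect_lt(abs(lo$unmethylated_fraction - hi$unmethylated_fraction),
            3 * se_diff)
})

test_that("simulated quality strings give the quality filter real work", {
  tg <- fixture_target()
  sim <- make_reads(tg, sim_config(n_molecules = 4000, cardiac_fraction = 0,
                                   seed = 20))
  expect_true(all(nchar(sim$reads$qual) == nchar(sim$reads$seq)))
  pass <- quality_filter(sim$reads$seq, sim$reads$qual)
  expect_gt(mean(pass), 0.5)             # most reads are usable
  expect_true(all(quality_filter(sim$reads$seq, sim$reads$qual, q_min = 0)))
  expect_false(any(quality_filter(sim$reads$seq, sim$reads$qual, q_min = 41.5)))
})

test_that("methylome generator plants qualify if and only if constructed to", {
  tissues <- c("heart", paste0("bg", 1:5))
  none <- make_methylome(150, tissues, target_tissues = "heart", seed = 21)
  expect_identical(nrow(scan_markers(none, "heart", paste0("bg", 1:5))), 0L)
  good <- make_methylome(150, tissues,
                         planted = list(list(at = 70, n_cpg = 6, span_bp = 90,
                                             target_beta = 0.05,
                                             background_beta = 0.95)),
                         target_tissues = "heart", seed = 21)
  expect_identical(nrow(scan_markers(good, "heart", paste0("bg", 1:5))), 1L)
  # a plant whose background tissues are only half methylated is rejected
  weak <- make_methylome(150, tissues,
                         planted = list(list(at = 70, n_cpg = 6, span_bp = 90,
                                             target_beta = 0.05,
                                             background_beta = 0.5)),
                         target_tissues = "heart", seed = 21)
  expect_identical(nrow(scan_markers(weak, "heart", paste0("bg", 1:5))), 0L)
  expect_error(
    make_methylome(150, tissues,
                   planted = list(list(at = 70, n_cpg = 6),
                                  list(at = 72, n_cpg = 6)),
                   target_tissues = "heart", seed = 21),
    "overlap")
  expect_error(
    make_methylome(20, tissues,
                   planted = list(list(at = 18, n_cpg = 6)),
                   target_tissues = "heart"),
    "outside")
})

test_that("cohort generator supports the cutoff and ROC workflows", {
  same <- make_cohort(400, 400, control_rng = function(n) rpois(n, 3),
                      case_rng = function(n) rpois(n, 3), seed = 22)
  auc_same <- roc_auc(same$copies_per_ml[same$group == "control"],
                      same$copies_per_ml[same$group == "case"])$auc
  expect_lt(abs(auc_same - 0.5), 0.05)
  apart <- make_cohort(50, 50, control_rng = function(n) rpois(n, 1),
                       case_rng = function(n) rpois(n, 1) + 100, seed = 7)
  ctrl <- apart$copies_per_ml[apart$group == "control"]
  case <- apart$copies_per_ml[apart$group == "case"]
  expect_equal(roc_auc(ctrl, case)$auc, 1)
  # mean + 3 SD of the controls calls every case positive
  cut <- control_cutoff(ctrl)
  expect_true(all(case >= cut))
  expect_equal(roc_auc(ctrl, case, cutoff = cut)$sensitivity, 1)
})
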