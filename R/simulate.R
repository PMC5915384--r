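#' Simulation configuration for bisulfite amplicon reads
#'
#' Bundles the noise model for [make_reads()]. Defaults describe a typical
#' well-run bisulfite amplicon experiment: 99% conversion of unmethylated
#' cytosines, 0.5% inappropriate conversion of methylated CpGs, 0.1%
#' per-base sequencing error, and bisulfite-induced loss of 60-90% of input
#' molecules (survival drawn uniformly from 0.1-0.4 per run, mean 75%
#' degradation). Quality strings follow a two-state good/bad-cycle model so
#' the quality filter has realistic work to do.
#'
#' @param n_molecules Number of input molecules before degradation.
#' @param cardiac_fraction Fraction of molecules from the target tissue
#'   (fully unmethylated at all CpGs); the rest are background (fully
#'   methylated).
#' @param conversion_efficiency Probability an unmethylated C is converted.
#' @param inappropriate_conversion Probability a methylated CpG C is
#'   wrongly converted.
#' @param per_base_error Per-base sequencing substitution error rate.
#' @param bisulfite_survival Length-2 range for the per-run molecule
#'   survival probability; a single value fixes it.
#' @param q_good,q_bad Mean Phred quality of good and bad cycles.
#' @param p_good_to_bad,p_bad_to_good Per-cycle transition probabilities of
#'   the quality state chain.
#' @param p_start_good Probability a read starts in the good state.
#' @param seed Optional RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_molecules = 1000, cardiac_fraction = 0.01,
                       conversion_efficiency = 0.99,
                       inappropriate_conversion = 0.005,
                       per_base_error = 0.001,
                       bisulfite_survival = c(0.1, 0.4),
                       q_good = 38, q_bad = 10,
                       p_good_to_bad = 0.02, p_bad_to_good = 0.3,
                       p_start_good = 0.98, seed = NULL) {
  if (length(bisulfite_survival) == 1L)
    bisulfite_survival <- rep(bisulfite_survival, 2L)
  probs <- c(cardiac_fraction, conversion_efficiency,
             inappropriate_conversion, per_base_error,
             p_good_to_bad, p_bad_to_good, p_start_good)
  stopifnot(all(probs >= 0 & probs <= 1), n_molecules >= 0,
            all(bisulfite_survival > 0 & bisulfite_survival <= 1),
            bisulfite_survival[1] <= bisulfite_survival[2])
  structure(list(
    n_molecules = n_molecules, cardiac_fraction = cardiac_fraction,
    conversion_efficiency = conversion_efficiency,
    inappropriate_conversion = inappropriate_conversion,
    per_base_error = per_base_error,
    bisulfite_survival = bisulfite_survival,
    q_good = q_good, q_bad = q_bad,
    p_good_to_bad = p_good_to_bad, p_bad_to_good = p_bad_to_good,
    p_start_good = p_start_good, seed = seed
  ), class = "sim_config")
}

#' Simulate bisulfite amplicon reads for a target
#'
#' Generates a spike-in-style read set: each input molecule is
#' target-derived (all CpGs unmethylated) with probability
#' `cardiac_fraction`, otherwise background (all CpGs methylated). Bisulfite
#' chemistry is applied per cytosine (conversion efficiency for
#' unmethylated Cs, inappropriate conversion for methylated CpG Cs), a
#' random survival factor drops molecules to mimic bisulfite degradation,
#' sequencing substitution errors are layered on the converted sequence,
#' and Phred qualities come from a two-state cycle model. The truth table
#' records every input molecule's origin, so downstream estimates can be
#' validated read by read.
#'
#' Degradation removes methylated and unmethylated molecules alike, so it
#' reduces counts but leaves the expected unmethylated fraction unchanged.
#'
#' @param target An [amplicon_target()].
#' @param config A [sim_config()].
#' @return List with `reads` (data frame `read_id`, `seq`, `qual`), `truth`
#'   (data frame `molecule_id`, `origin`, `survived`, `read_id`),
#'   `survival` (the drawn survival probability), and `config`.
#' @export
make_reads <- function(target, config = sim_config()) {
  stopifnot(inherits(target, "amplicon_target"), inherits(config, "sim_config"))
  .with_seed(config$seed, {
    n <- config$n_molecules
    origin <- ifelse(runif(n) < config$cardiac_fraction, "cardiac", "leukocyte")
    s <- runif(1, config$bisulfite_survival[1], config$bisulfite_survival[2])
    survived <- runif(n) < s
    idx <- which(survived)
    k <- length(idx)

    ref <- strsplit(target$reference_seq, "", fixed = TRUE)[[1L]]
    L <- length(ref)
    cpg_c <- target$cpg_sites
    noncpg_c <- setdiff(which(ref == "C"), cpg_c)

    m <- matrix(rep(ref, each = k), nrow = k, ncol = L)
    if (k > 0) {
      unmeth <- origin[idx] == "cardiac"
      # non-CpG cytosines: unmethylated on both molecule classes
      for (p in noncpg_c)
        m[runif(k) < config$conversion_efficiency, p] <- "T"
      # CpG cytosines: conversion depends on the molecule's methylation
      for (p in cpg_c) {
        conv <- ifelse(unmeth,
                       runif(k) < config$conversion_efficiency,
                       runif(k) < config$inappropriate_conversion)
        m[conv, p] <- "T"
      }
      # sequencing substitution errors on the converted basecalls
      err <- which(matrix(runif(k * L) < config$per_base_error, k, L))
      if (length(err)) {
        bases <- c("A", "C", "G", "T")
        cur <- m[err]
        m[err] <- vapply(cur, function(b)
          sample(setdiff(bases, b), 1L), character(1L))
      }
    }
    seqs <- if (k > 0) do.call(paste0, lapply(seq_len(L), function(j) m[, j]))
            else character(0)
    quals <- .sim_qualities(k, L, config)
    read_id <- if (k > 0) sprintf("mol%06d", idx) else character(0)
    list(
      reads = data.frame(read_id = read_id, seq = seqs, qual = quals,
                         stringsAsFactors = FALSE),
      truth = data.frame(
        molecule_id = sprintf("mol%06d", seq_len(n)),
        origin = origin,
        survived = survived,
        read_id = ifelse(survived, sprintf("mol%06d", seq_len(n)), NA_character_),
        stringsAsFactors = FALSE
      ),
      survival = s,
      config = config
    )
  })
}

# Two-state (good/bad cycle) Phred quality simulator; returns Phred+33
# strings for k reads of length L.
.sim_qualities <- function(k, L, config) {
  if (k == 0L) return(character(0))
  q <- matrix(0L, k, L)
  good <- runif(k) < config$p_start_good
  for (j in seq_len(L)) {
    if (j > 1L) {
      flip_gb <- runif(k) < config$p_good_to_bad
      flip_bg <- runif(k) < config$p_bad_to_good
      good <- ifelse(good, !flip_gb, flip_bg)
    }
    mu <- ifelse(good, config$q_good, config$q_bad)
    q[, j] <- pmax(2L, pmin(41L, as.integer(round(mu + rnorm(k, 0, 2)))))
  }
  vapply(seq_len(k), function(i) intToUtf8(q[i, ] + 33L), character(1L))
}

#' Simulate a multi-tissue methylome matrix with planted markers
#'
#' Emulates the whole-genome bisulfite input to marker discovery: CpG sites
#' at random spacings whose beta values are high in every tissue (clipped
#' normal around `background_beta_mean`), plus optional planted marker
#' regions — runs of CpGs squeezed into a short span, unmethylated in the
#' target tissues and highly methylated in all others. Planted runs are
#' flanked by >100 bp gaps so their discovery is decided by the scan
#' criteria, not by accidental mergers with neighbouring sites.
#'
#' @param n_sites Total number of CpG sites.
#' @param tissue_names All tissue names (targets plus backgrounds).
#' @param planted List of plants, each a list with `at` (site index of the
#'   run start), `n_cpg`, `span_bp` (first-to-last C, inclusive),
#'   `target_beta`, `background_beta`.
#' @param target_tissues Tissues in which plants are unmethylated.
#' @param chrom Chromosome name for all sites.
#' @param background_beta_mean,beta_noise_sd Clipped-normal parameters for
#'   non-planted beta values.
#' @param min_gap,max_gap Range of inter-CpG spacings (bp) outside plants.
#' @param seed Optional RNG seed.
#' @return A [methylome_matrix()].
#' @export
make_methylome <- function(n_sites, tissue_names, planted = list(),
                           target_tissues = character(0), chrom = "chr12",
                           background_beta_mean = 0.85, beta_noise_sd = 0.05,
                           min_gap = 10, max_gap = 200, seed = NULL) {
  stopifnot(n_sites >= 1, length(tissue_names) >= 1,
            all(target_tissues %in% tissue_names))
  for (p in planted) {
    stopifnot(all(c("at", "n_cpg") %in% names(p)))
    if (p$at < 1 || p$at + p$n_cpg - 1L > n_sites)
      stop("planted run at index ", p$at, " falls outside the matrix")
  }
  if (length(planted) > 1L) {
    iv <- do.call(rbind, lapply(planted, function(p) c(p$at, p$at + p$n_cpg - 1L)))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[-1L, 1L] <= iv[-nrow(iv), 2L]))
      stop("planted runs overlap")
  }
  .with_seed(seed, {
    gaps <- sample(seq(min_gap, max_gap), n_sites, replace = TRUE)
    # impose plant geometry on the spacings, with wide flanking gaps
    for (p in planted) {
      span <- if (is.null(p$span_bp)) 90L else as.integer(p$span_bp)
      i <- p$at; nc <- p$n_cpg
      if (nc > 1L) {
        inner <- diff(round(seq(0, span - 1L, length.out = nc)))
        gaps[(i + 1L):(i + nc - 1L)] <- inner
      }
      gaps[i] <- 150L                                 # gap into the run
      if (i + nc <= n_sites) gaps[i + nc] <- 150L     # gap out of the run
    }
    pos <- as.integer(cumsum(gaps))
    beta <- matrix(
      pmin(1, pmax(0, rnorm(n_sites * length(tissue_names),
                            background_beta_mean, beta_noise_sd))),
      nrow = n_sites, ncol = length(tissue_names),
      dimnames = list(NULL, tissue_names)
    )
    bg_tissues <- setdiff(tissue_names, target_tissues)
    for (p in planted) {
      rows <- p$at:(p$at + p$n_cpg - 1L)
      tb <- if (is.null(p$target_beta)) 0.05 else p$target_beta
      bb <- if (is.null(p$background_beta)) 0.95 else p$background_beta
      beta[rows, target_tissues] <- tb
      beta[rows, bg_tissues] <- bb
    }
    methylome_matrix(data.frame(chrom = chrom, pos = pos), beta, tissue_names)
  })
}

#' Simulate a case/control cohort of copies-per-ml values
#'
#' @param n_controls,n_cases Group sizes.
#' @param control_rng,case_rng Functions of `n` returning non-negative
#'   draws, e.g. `function(n) rpois(n, 1)`.
#' @param seed Optional RNG seed.
#' @param path Optional CSV output path.
#' @return Data frame with `sample_id`, `group` (`"control"`/`"case"`),
#'   `copies_per_ml`.
#' @export
make_cohort <- function(n_controls, n_cases,
                        control_rng = function(n) rpois(n, 1),
                        case_rng = function(n) rpois(n, 1) + 100,
                        seed = NULL, path = NULL) {
  stopifnot(n_controls >= 1, n_cases >= 1)
  .with_seed(seed, {
    ctrl <- control_rng(n_controls)
    case <- case_rng(n_cases)
    if (any(c(ctrl, case) < 0)) stop("cohort values must be non-negative")
    df <- data.frame(
      sample_id = c(sprintf("ctrl%03d", seq_len(n_controls)),
                    sprintf("case%03d", seq_len(n_cases))),
      group = rep(c("control", "case"), c(n_controls, n_cases)),
      copies_per_ml = c(ctrl, case),
      stringsAsFactors = FALSE
    )
    if (!is.null(path)) write.csv(df, path, row.names = FALSE)
    df
  })
}

#' Simulate a plate of ddPCR wells as a droplet table
#'
#' Runs [simulate_droplets()] for each requested well (including
#' template-free NTC wells, which receive background molecules only) and
#' returns the long-format droplet table the ddPCR analysis consumes.
#'
#' @param wells Data frame with columns `well`, `sample_id`,
#'   `target_copies`, `background_copies`.
#' @param n_droplets Droplets per well. Default 20000.
#' @param p_detect,fp_rate,amp_neg,amp_pos,amp_sd Passed to
#'   [simulate_droplets()].
#' @param seed RNG seed; each well uses a sub-seed derived from it.
#' @param path Optional CSV output path.
#' @return Data frame with `droplet_id`, `amplitude_ch1`, `amplitude_ch2`,
#'   `well`, `sample_id`.
#' @export
make_droplets <- function(wells, n_droplets = 20000,
                          p_detect = c(0.95, 0.95), fp_rate = c(2e-4, 2e-4),
                          amp_neg = c(1000, 1000), amp_pos = c(5000, 5000),
                          amp_sd = c(120, 120), seed = 1, path = NULL) {
  stopifnot(is.data.frame(wells),
            all(c("well", "sample_id", "target_copies", "background_copies")
                %in% names(wells)))
  out <- lapply(seq_len(nrow(wells)), function(i) {
    ds <- simulate_droplets(
      n_droplets = n_droplets,
      target_copies = wells$target_copies[i],
      background_copies = wells$background_copies[i],
      p_detect = p_detect, fp_rate = fp_rate,
      amp_neg = amp_neg, amp_pos = amp_pos, amp_sd = amp_sd,
      seed = seed * 1000L + i
    )
    data.frame(
      droplet_id = sprintf("%s_d%05d", wells$well[i], seq_len(n_droplets)),
      amplitude_ch1 = ds$amplitude_ch1,
      amplitude_ch2 = ds$amplitude_ch2,
      well = wells$well[i],
      sample_id = wells$sample_id[i],
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, out)
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}

#' Analyse a droplet table against an NTC well
#'
#' Convenience wrapper tying the ddPCR pieces together: thresholds are set
#' from the named NTC well ([set_thresholds()]), every other well is gated
#' and counted ([count_positives()]), and concentrations are estimated from
#' dual-positive (default) or single-channel counts ([poisson_quantify()]).
#'
#' @param droplets Droplet table as produced by [make_droplets()] (or read
#'   from a CSV with the same columns).
#' @param ntc_well Name of the negative template control well.
#' @param k SD multiplier for [set_thresholds()]. Default 5.
#' @param mode `"dual"`, `"ch1"`, or `"ch2"` scoring.
#' @param droplet_volume_nl,plasma_equiv_ml Passed to [poisson_quantify()].
#' @return Data frame with one row per non-NTC well: `well`, `sample_id`,
#'   `n_droplets`, `n_pos_ch1`, `n_pos_ch2`, `n_dual_pos`, `n_positive`,
#'   `lambda_hat`, `copies_per_ul_reaction`, `copies_per_ml_plasma`.
#' @export
ddpcr_analyze <- function(droplets, ntc_well, k = 5,
                          mode = c("dual", "ch1", "ch2"),
                          droplet_volume_nl = 0.85, plasma_equiv_ml = NULL) {
  mode <- match.arg(mode)
  stopifnot(ntc_well %in% droplets$well)
  ntc <- droplets[droplets$well == ntc_well, ]
  thr <- set_thresholds(droplet_set(ntc$amplitude_ch1, ntc$amplitude_ch2), k = k)
  wells <- setdiff(unique(droplets$well), ntc_well)
  rows <- lapply(wells, function(w) {
    d <- droplets[droplets$well == w, ]
    ds <- count_positives(droplet_set(d$amplitude_ch1, d$amplitude_ch2), thr)
    npos <- switch(mode,
                   dual = ds$counts[["n_dual_pos"]],
                   ch1 = ds$counts[["n_pos_ch1"]],
                   ch2 = ds$counts[["n_pos_ch2"]])
    q <- if (npos < ds$n_droplets)
      poisson_quantify(npos, ds$n_droplets, droplet_volume_nl, plasma_equiv_ml)
    else list(lambda_hat = Inf, copies_per_ul_reaction = Inf,
              copies_per_ml_plasma = Inf)
    data.frame(well = w, sample_id = d$sample_id[1L],
               n_droplets = ds$n_droplets,
               n_pos_ch1 = ds$counts[["n_pos_ch1"]],
               n_pos_ch2 = ds$counts[["n_pos_ch2"]],
               n_dual_pos = ds$counts[["n_dual_pos"]],
               n_positive = npos,
               lambda_hat = q$lambda_hat,
               copies_per_ul_reaction = q$copies_per_ul_reaction,
               copies_per_ml_plasma = if (is.null(plasma_equiv_ml)) NA_real_
                                      else q$copies_per_ml_plasma,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
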