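#' Theoretical tissue signal-to-noise ratio
#'
#' Ratio of the fully unmethylated molecule percentage in the target tissue
#' to that in a background tissue. For reporting, the ratio is also rounded
#' to two significant figures (e.g. heart 89% vs leukocytes 0.006% gives
#' 14833.3, reported as 15,000).
#'
#' @param target_unmeth_pct Percent fully unmethylated molecules in the
#'   target tissue.
#' @param background_unmeth_pct Same for the background tissue; a zero
#'   background yields an infinite ratio (report a counting-limit floor for
#'   the background instead).
#' @return List with `ratio` and `reported` (two significant figures).
#' @examples
#' signal_to_noise(89, 0.006)$reported  # 15000
#' signal_to_noise(89, 0.2)$ratio       # 445
#' @export
signal_to_noise <- function(target_unmeth_pct, background_unmeth_pct) {
  if (target_unmeth_pct < 0 || background_unmeth_pct < 0)
    stop("unmethylated percentages must be non-negative")
  ratio <- if (background_unmeth_pct == 0) Inf
           else target_unmeth_pct / background_unmeth_pct
  list(ratio = ratio, reported = signif(ratio, 2))
}

#' Spike-in linearity of the sequencing assay
#'
#' Runs the full amplicon pipeline on synthetic target-into-background DNA
#' mixtures at the given true fractions and fits estimated vs true fraction
#' by least squares. A slope near 1, intercept near 0 and R-squared near 1
#' demonstrate that molecule counting recovers the mixed-in tissue fraction
#' across the dilution series.
#'
#' @param true_fractions At least 3 distinct target fractions in `[0, 1]`.
#' @param target An [amplicon_target()].
#' @param config A [sim_config()]; its `cardiac_fraction` is overridden per
#'   mixture point.
#' @param seed RNG seed; each mixture uses a sub-seed derived from it.
#' @return Object of class `spike_in_series`: list with `points` (data frame
#'   of `true_fraction`, `estimated_fraction`, `n_molecules`, `n_valid`),
#'   `slope`, `intercept`, `r_squared`.
#' @export
spike_in_eval <- function(true_fractions, target, config = sim_config(),
                          seed = 1) {
  if (length(unique(true_fractions)) < 3L)
    stop("need at least 3 distinct true fractions")
  stopifnot(all(true_fractions >= 0 & true_fractions <= 1))
  pts <- lapply(seq_along(true_fractions), function(i) {
    cfg <- config
    cfg$cardiac_fraction <- true_fractions[i]
    cfg$seed <- seed * 1000L + i
    sim <- make_reads(target, cfg)
    q <- amplicon_quantify(sim$reads, target)$combined
    data.frame(true_fraction = true_fractions[i],
               estimated_fraction = q$unmethylated_fraction,
               n_molecules = cfg$n_molecules,
               n_valid = q$n_valid)
  })
  pts <- do.call(rbind, pts)
  fit <- lm(estimated_fraction ~ true_fraction, data = pts)
  structure(list(points = pts,
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared),
            class = "spike_in_series")
}

#' @export
print.spike_in_series <- function(x, ...) {
  cat(sprintf("<spike_in_series> %d points: slope %.4f, intercept %.2e, R^2 %.4f\n",
              nrow(x$points), x$slope, x$intercept, x$r_squared))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Limit of detection under bisulfite degradation
#'
#' Bisulfite treatment destroys most input DNA (60-90%, on average 75%), so
#' whether a handful of target genomes is detected is a question of
#' molecule survival. For each candidate input genome count this simulates
#' molecule recovery — each genome survives independently with probability
#' drawn from `survival` — applies the detection rule (by default: at least
#' `min_molecules = 1` surviving target molecule observed) across
#' replicates, and reports the smallest count detected in at least
#' `detect_prob` of replicates.
#'
#' The analytic companion for a fixed survival probability `s` is
#' `P(detect) = 1 - (1 - s)^n`; see [lod_analytic()].
#'
#' @param genome_counts Integer vector of candidate input genome counts.
#' @param n_replicates Simulation replicates per count. Default 200.
#' @param survival Either a length-2 range for per-run uniform draw of the
#'   survival probability (default `c(0.1, 0.4)`) or a single fixed value.
#' @param min_molecules Detection rule: minimum surviving molecules.
#' @param detect_prob Required detection frequency. Default 0.95.
#' @param seed RNG seed.
#' @return List with `lod_genomes` (smallest qualifying count, `NA` if
#'   none) and `detection` (data frame of count vs detection frequency).
#' @export
limit_of_detection <- function(genome_counts, n_replicates = 200,
                               survival = c(0.1, 0.4), min_molecules = 1,
                               detect_prob = 0.95, seed = 1) {
  if (!length(genome_counts)) stop("genome_counts must be non-empty")
  stopifnot(all(genome_counts >= 0), all(survival > 0), all(survival <= 1))
  if (length(survival) == 1L) survival <- rep(survival, 2L)
  .with_seed(seed, {
    freq <- vapply(genome_counts, function(n) {
      s <- runif(n_replicates, survival[1L], survival[2L])
      recovered <- rbinom(n_replicates, size = n, prob = s)
      mean(recovered >= min_molecules)
    }, numeric(1L))
    ok <- which(freq >= detect_prob)
    list(
      lod_genomes = if (length(ok)) min(genome_counts[ok]) else NA_integer_,
      detection = data.frame(genomes = genome_counts, detection_freq = freq)
    )
  })
}

#' Analytic limit of detection for fixed molecule survival
#'
#' Smallest genome count `n` with `1 - (1 - s)^n >= detect_prob`, the
#' closed form behind [limit_of_detection()] when survival is constant and
#' the detection rule is at least one surviving molecule.
#'
#' @param survival Fixed per-molecule survival probability in (0, 1].
#' @param detect_prob Required detection probability. Default 0.95.
#' @return Integer genome count.
#' @examples
#' lod_analytic(0.25)  # 11
#' @export
lod_analytic <- function(survival, detect_prob = 0.95) {
  stopifnot(survival > 0, survival <= 1, detect_prob > 0, detect_prob < 1)
  if (survival == 1) return(1L)
  as.integer(ceiling(log(1 - detect_prob) / log(1 - survival)))
}

#' Healthy-control cutoff for a positive signal
#'
#' Mean plus three sample standard deviations (n-1 denominator) of the
#' control group's copies/ml values — the conventional rule for calling a
#' sample positive against a healthy baseline.
#'
#' @param control_values Numeric vector of at least 2 control copies/ml.
#' @param k SD multiplier. Default 3.
#' @return The cutoff (copies/ml).
#' @examples
#' control_cutoff(c(1, 2, 3))  # 2 + 3*1 = 5
#' @export
control_cutoff <- function(control_values, k = 3) {
  if (length(control_values) < 2L)
    stop("need at least 2 control values")
  mean(control_values) + k * sd(control_values)
}

#' ROC curve and AUC for a case/control biomarker
#'
#' The area under the ROC curve is computed as the Mann-Whitney U statistic
#' normalised by `n_controls * n_cases` — the probability that a randomly
#' chosen case exceeds a randomly chosen control, ties counting one half.
#' Curve points are reported over all unique observed thresholds, scoring a
#' sample positive when its value is at or above the threshold.
#'
#' @param control_values,case_values Non-empty numeric vectors (copies/ml).
#' @param cutoff Optional cutoff at which to report sensitivity and
#'   specificity (e.g. from [control_cutoff()]).
#' @return Object of class `roc_result`: list with `auc`, `curve` (data
#'   frame of `threshold`, `sensitivity`, `specificity`), and, when
#'   `cutoff` is given, `sensitivity` and `specificity` at that cutoff.
#' @examples
#' roc_auc(c(0, 2), c(1, 3))$auc  # 0.75
#' @export
roc_auc <- function(control_values, case_values, cutoff = NULL) {
  n1 <- length(control_values); n2 <- length(case_values)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  r <- rank(c(control_values, case_values))  # midranks handle ties as 1/2
  u <- sum(r[(n1 + 1L):(n1 + n2)]) - n2 * (n2 + 1) / 2
  auc <- u / (n1 * n2)
  thr <- sort(unique(c(control_values, case_values)))
  curve <- data.frame(
    threshold = c(thr, Inf),
    sensitivity = vapply(c(thr, Inf), function(t) mean(case_values >= t), 0),
    specificity = vapply(c(thr, Inf), function(t) mean(control_values < t), 0)
  )
  out <- list(auc = auc, curve = curve)
  if (!is.null(cutoff)) {
    out$sensitivity <- mean(case_values >= cutoff)
    out$specificity <- mean(control_values < cutoff)
  }
  structure(out, class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d thresholds)\n",
              x$auc, nrow(x$curve)))
  if (!is.null(x$sensitivity))
    cat(sprintf("  at cutoff: sensitivity %.3f, specificity %.3f\n",
                x$sensitivity, x$specificity))
  invisible(x)
}
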