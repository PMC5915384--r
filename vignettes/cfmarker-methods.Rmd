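---
title: "Methylation-marker discovery and cell-free DNA quantification with cfmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-marker discovery and cell-free DNA quantification with cfmarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmarker)
```

## The problem

Dying cells shed nucleosome-sized fragments of genomic DNA into plasma.
Because every cell type carries a characteristic DNA methylation profile,
cell-free DNA (cfDNA) fragments can be traced to their tissue of origin by
their CpG methylation pattern even though their sequence is identical to the
host genome. A locus that is unmethylated *only* in one cell type — for
example a CpG cluster near a cardiomyocyte-specific gene — turns into a
counting assay for death of that cell type: bisulfite-convert plasma cfDNA,
amplify the locus, and count molecules in which *every* CpG reads as
unmethylated. `cfmarker` implements this workflow end to end: marker
discovery from multi-tissue methylomes, the sequencing-based counting assay,
its droplet-digital-PCR (ddPCR) variant, evaluation utilities, and synthetic
data generators that emulate every input.

## Marker discovery

`scan_markers()` searches a per-CpG beta-value matrix (rows: CpG sites,
columns: tissues) for windows satisfying four criteria:

* at least `min_cpg = 5` consecutive CpG sites,
* genomic span from first to last CpG cytosine strictly below
  `max_span_bp = 100` (short enough to be covered by one cfDNA fragment and
  one amplicon),
* region-mean methylation above `background_min_meth = 0.8` in **every**
  background tissue,
* region-mean methylation below `target_max_meth = 0.2` in **every** target
  tissue.

The background threshold of 80% is the conventional criterion for "fully
methylated elsewhere"; no symmetric number is established for "unmethylated
in the target", so the default 0.2 simply mirrors it and is exposed as a
parameter. The criteria are applied to the *region mean* per tissue because
single-CpG beta values from whole-genome bisulfite sequencing are noisy at
ordinary coverage; a stricter `per_cpg = TRUE` mode applies the thresholds
to every site individually. Missing beta values fail a window by default
(`na_action = "fail"`): an unobserved background tissue is treated as
potential cross-reactivity, not as evidence of specificity.

Qualifying windows that overlap are merged, so each locus is reported once
as a maximal candidate; `rank_candidates()` orders candidates by the
separation score (lowest background mean minus highest target mean), the
quantity that bounds the attainable signal-to-noise ratio.

Coordinates are 1-based inclusive throughout, the genome-browser and
Bioconductor convention; `write_candidates_bed()` converts to 0-based
half-open at the BED boundary. A 90-bp amplicon printed as
`chr12:124692462-124692551` therefore has `region_width(124692462,
124692551) == 90`.

## The sequencing assay

Bisulfite treatment converts unmethylated cytosine to uracil (read as T)
and leaves methylated CpG cytosines as C. `bisulfite_convert()` applies the
rule in silico; `amplicon_target()` stores both idealised templates of an
amplicon (fully methylated and fully unmethylated), which differ only at
CpG cytosines. Because conversion destroys strand complementarity, the two
strands of one locus are independent biomarkers: `antisense_template()`
derives the antisense target, whose CpG count always equals the sense
count (CG is its own reverse complement).

Reads flow through a fixed funnel, and every stage's count is retained so
the chain `n_fully_unmethylated <= n_valid <= n_matched <= n_quality_pass
<= n_reads_total` can be audited:

1. **Quality** (`quality_filter()`): mean Phred at least `q_min = 30`,
   boundary inclusive. Standard amplicon practice; configurable because the
   appropriate gate depends on chemistry.
2. **Matching** (`match_read()`): global Levenshtein similarity against the
   converted template with CpG positions wildcarded (C and T both match),
   so a molecule's methylation state cannot bias which target it is
   assigned to or whether it is assigned at all. A read is kept when
   similarity is at least `min_similarity = 0.8`. The wildcarded
   alignment is a small C++ dynamic program whose traceback is reused for
   calling.
3. **Calling** (`call_molecule()`): at each expected CpG the aligned read
   dinucleotide decides the state — `CG` methylated, `TG` unmethylated,
   anything else (sequencing error, deletion) ambiguous. CpG context is
   defined on the unconverted reference, never on the read, so errors at
   the G cannot create phantom sites. A molecule is *valid* only when no
   site is ambiguous; molecules with any ambiguous site are excluded from
   numerator and denominator alike.
4. **Counting** (`quantify_sample()`): the signal is the fraction of valid
   molecules unmethylated at *every* CpG. Requiring the complete pattern is
   what gives the assay its specificity: with six CpGs, a methylated
   background molecule only masquerades as target if six independent
   corruptions line up, so the false-positive rate collapses
   multiplicatively.

Copies per ml plasma are `fraction x cfdna_conc_ng_per_ml x 1000 /
pg_per_genome`, with 3.3 pg per haploid genome equivalent by default (the
textbook human value; configurable). The cfDNA concentration must be
measured before bisulfite conversion: the treatment degrades 60–90% of the
DNA, but methylated and unmethylated molecules are lost at the same rate,
so the fraction — and hence copies/ml — is unbiased by degradation.

`combine_strand_markers()` pools the sense and antisense counts (sum of
fully unmethylated over sum of valid) rather than averaging the two
fractions, so a strand with deeper coverage carries proportionally more
weight; per-strand values are retained for concordance checks.

## The ddPCR assay

Probes are short, so a single TaqMan probe can interrogate only two or
three CpGs — not enough for full specificity. The dual-probe design places
two probes on adjacent CpG clusters of the same amplicon and scores only
droplets positive in both channels: a dual-positive droplet reports one
original molecule unmethylated at all five covered cytosines. With
independent per-probe false-positive rates \(f_1, f_2\), target-free
droplets are dual-positive at rate \(f_1 f_2\) — the multiplicative noise
suppression that single-probe scoring lacks; `specificity_gain()` reports
the measured fold improvement.

`set_thresholds()` gates each channel at the negative-template-control
mean plus `k = 5` SDs. The positive and negative amplitude clouds in this
assay are widely separated, so the result is insensitive to `k` over a
broad range; `k` is exposed because the rule "based on the NTC amplitude"
does not pin down a multiplier. Droplets exactly at threshold are negative.
`poisson_quantify()` inverts droplet occupancy, which is Poisson under
random partitioning: \(\hat\lambda = -\ln(1 - p_{pos})\), copies/µL
\(= 1000\,\hat\lambda / v\) with droplet volume \(v = 0.85\) nL (QX100
class). Saturated wells (all droplets positive) are an error, not an
estimate.

## Evaluation utilities

* `signal_to_noise()`: ratio of fully unmethylated percentages between
  tissues, with a two-significant-figure reported value.
* `spike_in_eval()`: runs the full pipeline on simulated target-into-
  background dilutions and fits estimated vs true fraction.
* `limit_of_detection()`: simulates per-molecule bisulfite survival
  (uniform on 0.1–0.4 by default, matching 60–90% degradation) and reports
  the smallest input genome count detected in at least 95% of replicates —
  0.95 operationalises "robust detection"; `lod_analytic()` gives the
  closed form \(\lceil \ln(1-p)/\ln(1-s) \rceil\) for fixed survival.
* `control_cutoff()`: mean plus three sample SDs (n−1 denominator) of the
  healthy controls.
* `roc_auc()`: rank-based Mann–Whitney AUC with midrank tie handling,
  computed per sample; repeated samples per patient are treated as
  independent, which is optimistic when within-patient correlation is
  strong — aggregate per patient upstream if that matters.

## What the simulators do and do not emulate

`make_reads()` draws each molecule's origin (target: all CpGs
unmethylated; background: all methylated), applies per-cytosine conversion
(efficiency 0.99), inappropriate conversion of methylated CpGs (0.005),
per-base substitution error (0.001), molecule loss at a survival
probability drawn from 0.1–0.4, and a two-state good/bad-cycle quality
model. These noise defaults are literature-typical for well-run bisulfite
amplicon experiments rather than measured values of any one instrument.
The generator does **not** emulate intermediate (partially methylated)
molecules, PCR amplification bias or chimeras, indel sequencing errors,
primer artefacts, or cfDNA fragment-length effects. Passing tests
demonstrate that the *counting and calling machinery* is correct under the
stated noise model — not that any particular wet-lab protocol achieves
these error rates. One visible consequence of the model: with 99%
conversion per CpG, a six-CpG fully unmethylated molecule is called as
such only ~94% of the time (0.99^6), so pipeline estimates sit a few
percent below the true mixed-in fraction — exactly as a real assay's
conversion shortfall would, and well inside the binomial error band at the
depths used here.

`make_methylome()` plants qualifying marker runs into an otherwise
high-methylation background (clipped normal, mean 0.85, SD 0.05) and
flanks each plant with >100 bp gaps so that recovery is decided by the
scan criteria rather than by accidental window mergers. `make_droplets()`
and `make_cohort()` provide the ddPCR and cohort inputs in the same
dialects the analysis functions read.

All generators take a `seed` and restore the caller's RNG state; identical
configurations produce byte-identical FASTQ/CSV output.

## Numerical and design choices

* Edit-distance matching uses unit costs and deterministic tie-breaking
  (diagonal preferred, then deletion); ties across targets resolve to the
  first target in the list.
* Degenerate inputs are explicit: zero valid molecules yields fraction 0
  with a warning; an all-positive ddPCR well and a saturated estimator are
  errors; constant NTC amplitudes give a zero-width threshold with a
  warning.
* Window span is measured from first to last CpG cytosine, inclusive, and
  compared strictly (`< max_span_bp`).
* Strand pooling (not averaging) is the default for multiplexed
  sense/antisense runs; per-strand results remain available.
* Problem sizes in the test-suite and acceptance script — 50,000 simulated
  molecules for spike-in recovery, 20,000-droplet wells, 200 simulations
  per ddPCR recovery point, 100 planted methylomes, brute-force scan
  oracles up to 400 sites — were chosen so the statistical assertions have
  comfortable power while the whole suite runs in minutes on one core.

## Limitations

Marker discovery assumes the supplied methylome panel spans the tissues
that actually contribute to cfDNA; a tissue absent from the panel can
cross-react silently. The pipeline assumes amplicon-length reads covering
the whole template (no paired-end merging, UMI handling, or
demultiplexing). The binary origin model cannot represent partially
methylated molecules, which in real data occur at low frequency in
intermediate tissues. Clinical performance figures (cohort AUCs,
correlations with protein markers) depend on patient material and are out
of scope for simulation.

## A worked example

```{r example, eval = FALSE}
# 1. discover a marker in a synthetic 26-tissue methylome
tissues <- c("heart_lv", "heart_rv", "heart_ra", paste0("tissue", 1:23))
meth <- make_methylome(500, tissues,
                       planted = list(list(at = 250, n_cpg = 6, span_bp = 90,
                                           target_beta = 0.05,
                                           background_beta = 0.95)),
                       target_tissues = tissues[1:3], seed = 1)
cand <- scan_markers(meth, tissues[1:3], tissues[-(1:3)])

# 2. quantify a 0.1% spike-in with the sequencing assay
tg <- amplicon_target("marker_S", strrep("ATTGACG", 13))  # toy 6+ CpG target
sim <- make_reads(tg, sim_config(n_molecules = 50000, cardiac_fraction = 0.001,
                                 seed = 1))
amplicon_quantify(sim$reads, tg, cfdna_conc_ng_per_ml = 16.5)$combined

# 3. ddPCR with dual-probe scoring
wells <- data.frame(well = c("A01", "H12"), sample_id = c("s1", "NTC"),
                    target_copies = c(1000, 0), background_copies = c(5000, 0))
ddpcr_analyze(make_droplets(wells, seed = 1), ntc_well = "H12")
```
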