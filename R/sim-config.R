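#' Configuration for the synthetic methylome generator
#'
#' Collects and validates every knob of the synthetic-data module.  The
#' defaults describe the study conditions the generator is meant to emulate:
#' a balanced 3-vs-3 bisulfite experiment at ~30X merged-CpG coverage with a
#' small nonconversion error, sparse mosaic gene-body methylation biased
#' towards 5' exons, and a set of planted differentially methylated windows.
#'
#' @param seed integer seed; identical configurations (including the seed)
#'   produce byte-identical output.
#' @param n_chromosomes number of chromosomes to simulate.
#' @param chrom_length chromosome length in bp.
#' @param n_genes total number of genes across all chromosomes.
#' @param exons_per_gene exons per gene.
#' @param exon_length,intron_length fixed exon and intron lengths in bp.
#'   The default exon length of 176 bp matches the median exon length of the
#'   genome the simulation emulates, which is also why downstream DMR
#'   calling uses 200 bp windows.
#' @param cpg_density per-bp Bernoulli probability of starting a CpG
#'   dinucleotide.
#' @param n_samples_per_group biological replicates per group (default 3).
#' @param coverage_mean expected total read depth at a strand-merged CpG
#'   (each strand draws from a negative binomial with mean
#'   `coverage_mean / 2`).
#' @param coverage_dispersion negative-binomial dispersion `phi` so that
#'   `Var = mu + phi * mu^2` per strand.
#' @param nonconversion_rate probability that an unmethylated cytosine fails
#'   bisulfite conversion and reads as methylated.
#' @param frac_methylated_genes fraction of genes carrying gene-body
#'   methylation.
#' @param methylated_level true methylation probability `pi` at first-exon
#'   CpGs of methylated genes.
#' @param five_prime_decay multiplicative decay of `pi` per exon rank
#'   (rank r exons sit at `methylated_level * five_prime_decay^(r-1)`;
#'   introns at half the level of the preceding exon).
#' @param n_true_dmrs number of 200 bp windows with a planted group
#'   difference; windows lie entirely within methylated-gene spans and
#'   contain at least 2 CpGs.
#' @param dmr_delta absolute methylation-probability difference planted at
#'   every CpG of a true DMR window.
#' @param dmr_hyper_care_frac fraction of planted DMRs hypermethylated in
#'   the "care" group (the remainder are hypermethylated in "nocare").
#' @param pi_jitter_sd optional per-sample beta-distributed jitter of `pi`
#'   (standard deviation scale; 0 disables, the default, since within-group
#'   biological variance of methylation is not part of the emulated design).
#' @param n_lambda_sites number of cytosine sites on the unmethylated
#'   lambda spike-in pseudo-chromosome.
#' @param de_frac,as_frac,sel_frac sizes of the differential-expression,
#'   alternative-splicing and positive-selection gene sets as fractions of
#'   the gene universe.
#' @param overlap_odds_ratio target pairwise odds ratio between generated
#'   gene sets (1 = independent membership).
#' @param expression_rho target Spearman correlation between true gene
#'   methylation and generated expression.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 20, n_chromosomes = 1)
#' cfg$coverage_mean
sim_config <- function(seed = 1L,
                       n_chromosomes = 5L,
                       chrom_length = 1e5,
                       n_genes = 200L,
                       exons_per_gene = 5L,
                       exon_length = 176L,
                       intron_length = 150L,
                       cpg_density = 0.02,
                       n_samples_per_group = 3L,
                       coverage_mean = 30,
                       coverage_dispersion = 0.2,
                       nonconversion_rate = 0.005,
                       frac_methylated_genes = 0.25,
                       methylated_level = 0.7,
                       five_prime_decay = 0.7,
                       n_true_dmrs = 50L,
                       dmr_delta = 0.20,
                       dmr_hyper_care_frac = 0.84,
                       pi_jitter_sd = 0,
                       n_lambda_sites = 2000L,
                       de_frac = 0.13,
                       as_frac = 0.055,
                       sel_frac = 0.02,
                       overlap_odds_ratio = 1,
                       expression_rho = 0.24) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    cpg_density = cpg_density,
    n_samples_per_group = as.integer(n_samples_per_group),
    coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion,
    nonconversion_rate = nonconversion_rate,
    frac_methylated_genes = frac_methylated_genes,
    methylated_level = methylated_level,
    five_prime_decay = five_prime_decay,
    n_true_dmrs = as.integer(n_true_dmrs),
    dmr_delta = dmr_delta,
    dmr_hyper_care_frac = dmr_hyper_care_frac,
    pi_jitter_sd = pi_jitter_sd,
    n_lambda_sites = as.integer(n_lambda_sites),
    de_frac = de_frac,
    as_frac = as_frac,
    sel_frac = sel_frac,
    overlap_odds_ratio = overlap_odds_ratio,
    expression_rho = expression_rho
  )
  probs <- c("cpg_density", "nonconversion_rate", "frac_methylated_genes",
             "methylated_level", "five_prime_decay", "dmr_delta",
             "dmr_hyper_care_frac", "de_frac", "as_frac", "sel_frac")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("'%s' must be a probability in [0, 1]", p))
    }
  }
  counts <- c("n_chromosomes", "chrom_length", "n_genes", "exons_per_gene",
              "exon_length", "intron_length", "n_samples_per_group",
              "n_lambda_sites")
  zero_ok <- c("n_genes", "n_lambda_sites")
  for (p in counts) {
    if (is.na(cfg[[p]]) || cfg[[p]] < ifelse(p %in% zero_ok, 0L, 1L)) {
      stop(sprintf("'%s' must be a positive count", p))
    }
  }
  if (cfg$n_true_dmrs < 0L) stop("'n_true_dmrs' must be non-negative")
  if (cfg$coverage_mean < 0) stop("'coverage_mean' must be non-negative")
  if (cfg$coverage_dispersion <= 0) {
    stop("'coverage_dispersion' must be positive")
  }
  if (cfg$overlap_odds_ratio < 0) {
    stop("'overlap_odds_ratio' must be non-negative")
  }
  if (abs(cfg$expression_rho) > 1) {
    stop("'expression_rho' must lie in [-1, 1]")
  }
  if (cfg$pi_jitter_sd < 0) stop("'pi_jitter_sd' must be non-negative")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic methylome configuration\n")
  cat(sprintf("  genome : %d chromosome(s) x %d bp, %d genes (%d exons each)\n",
              x$n_chromosomes, x$chrom_length, x$n_genes, x$exons_per_gene))
  cat(sprintf("  design : %d vs %d samples, ~%gX merged coverage, eps = %g\n",
              x$n_samples_per_group, x$n_samples_per_group,
              x$coverage_mean, x$nonconversion_rate))
  cat(sprintf("  truth  : %.0f%% methylated genes at pi = %g, %d planted DMRs (delta = %g)\n",
              100 * x$frac_methylated_genes, x$methylated_level,
              x$n_true_dmrs, x$dmr_delta))
  invisible(x)
}
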