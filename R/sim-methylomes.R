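#' Generate per-sample bisulfite count tables from a ground truth
#'
#' Draws, for every CpG and every sample, a per-strand coverage from a
#' negative binomial (mean `coverage_mean / 2` per strand so that the
#' merged CpG coverage averages `coverage_mean`) and a methylated read
#' count from `Binomial(n, pi + (1 - pi) * eps)`, where `eps` is the
#' nonconversion rate.  An unmethylated lambda spike-in is emitted as a
#' pseudo-chromosome named `"lambda"` in the same format (`pi = 0`, so its
#' only methylation signal is nonconversion error).
#'
#' With `pi_jitter_sd > 0` each sample's `pi` is drawn from a beta
#' distribution centred on the true value, adding within-group biological
#' variance; the default is no jitter.
#'
#' @param annotation a `meth_annotation`.
#' @param truth a `meth_truth` covering every CpG of the annotation.
#' @param config the [sim_config()].
#' @return Named list of stranded count data.frames (`chrom`, `pos`,
#'   `strand`, `m`, `n`), one per sample (`care_1`, ..., `nocare_1`, ...),
#'   each including the lambda pseudo-chromosome.  The plus-strand C of a
#'   CpG is reported at `pos`, its minus-strand partner at `pos + 1`.
#'   A `groups` attribute maps sample names to group labels.
#' @export
generate_methylomes <- function(annotation, truth, config) {
  stopifnot(inherits(annotation, "meth_annotation"),
            inherits(truth, "meth_truth"))
  if (nrow(truth$cpg) != nrow(annotation$cpg)) {
    stop("ground truth does not cover the annotation's CpG set")
  }
  set.seed(config$seed + 3003L)
  g <- config$n_samples_per_group
  samples <- c(sprintf("care_%d", seq_len(g)),
               sprintf("nocare_%d", seq_len(g)))
  groups <- setNames(rep(c("care", "nocare"), each = g), samples)

  cpg <- truth$cpg
  n_cpg <- nrow(cpg)
  mu_strand <- config$coverage_mean / 2
  size <- 1 / config$coverage_dispersion
  lam_pos <- if (config$n_lambda_sites > 0L) {
    as.integer((seq_len(config$n_lambda_sites) - 1L) * 2L)
  } else integer()

  draw_strand <- function(pi_vec) {
    n <- as.integer(rnbinom(length(pi_vec), mu = mu_strand, size = size))
    p <- pi_vec + (1 - pi_vec) * config$nonconversion_rate
    m <- as.integer(rbinom(length(pi_vec), n, p))
    list(m = m, n = n)
  }

  out <- lapply(samples, function(s) {
    pi_s <- if (groups[[s]] == "care") cpg$pi_care else cpg$pi_nocare
    if (config$pi_jitter_sd > 0 && n_cpg > 0L) {
      # beta jitter with mean pi and sd ~ pi_jitter_sd (clamped)
      v <- pmin(config$pi_jitter_sd^2, pi_s * (1 - pi_s) * 0.99)
      jit <- pi_s
      ok <- v > 0 & pi_s > 0 & pi_s < 1
      if (any(ok)) {
        k <- pi_s[ok] * (1 - pi_s[ok]) / v[ok] - 1
        jit[ok] <- stats::rbeta(sum(ok), pi_s[ok] * k, (1 - pi_s[ok]) * k)
      }
      pi_s <- jit
    }
    plus <- draw_strand(pi_s)
    minus <- draw_strand(pi_s)
    lam_plus <- draw_strand(rep(0, length(lam_pos)))
    lam_minus <- draw_strand(rep(0, length(lam_pos)))
    df <- data.frame(
      chrom = c(rep(cpg$chrom, 2L), rep("lambda", 2L * length(lam_pos))),
      pos = c(cpg$pos, cpg$pos + 1L, lam_pos, lam_pos + 1L),
      strand = c(rep(c("+", "-"), each = n_cpg),
                 rep(c("+", "-"), each = length(lam_pos))),
      m = c(plus$m, minus$m, lam_plus$m, lam_minus$m),
      n = c(plus$n, minus$n, lam_plus$n, lam_minus$n),
      stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$pos, df$strand), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(out) <- samples
  attr(out, "groups") <- groups
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [generate_annotation()], [generate_truth()],
#' [generate_methylomes()], [generate_gene_sets()] and
#' [generate_expression()] for one configuration.
#'
#' @param config a [sim_config()].
#' @return List with elements `config`, `annotation`, `truth`,
#'   `methylomes` (with its `groups` attribute), `gene_sets` and
#'   `expression`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(seed = 42, n_genes = 20,
#'                                    n_chromosomes = 1, n_true_dmrs = 2))
#' names(study)
simulate_study <- function(config) {
  annotation <- generate_annotation(config)
  truth <- generate_truth(annotation, config)
  methylomes <- generate_methylomes(annotation, truth, config)
  gene_sets <- generate_gene_sets(annotation, config)
  expression <- generate_expression(truth, config)
  list(config = config, annotation = annotation, truth = truth,
       methylomes = methylomes, gene_sets = gene_sets,
       expression = expression)
}
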