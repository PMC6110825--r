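test_that("identical configurations reproduce identical output", {
  cfg <- small_config(seed = 11)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  t1 <- generate_truth(a1, cfg)
  m1 <- generate_methylomes(a1, t1, cfg)
  m2 <- generate_methylomes(a2, generate_truth(a2, cfg), cfg)
  expect_identical(m1, m2)
})

test_that("degenerate configurations are handled", {
  cfg <- sim_config(seed = 3, n_genes = 0, n_chromosomes = 1,
                    chrom_length = 2e4, n_true_dmrs = 0,
                    frac_methylated_genes = 0)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$genes), 0)
  expect_gt(nrow(ann$cpg), 0)  # CpGs are emitted even without genes
  expect_error(sim_config(cpg_density = 1.2), "probability")
  expect_error(sim_config(overlap_odds_ratio = -1), "non-negative")
  # too many genes for the chromosome
  expect_error(
    generate_annotation(sim_config(n_genes = 100, n_chromosomes = 1,
                                   chrom_length = 5e3)),
    "cannot place")
})

test_that("CpG placement follows the Bernoulli density model", {
  cfg <- sim_config(seed = 5, n_chromosomes = 1, chrom_length = 1e6,
                    n_genes = 10, n_true_dmrs = 0, cpg_density = 0.02)
  ann <- generate_annotation(cfg)
  expected <- 0.02 * 1e6
  sdv <- sqrt(1e6 * 0.02 * 0.98)
  # adjacency thinning removes ~ density^2 * L positions, well within 4 SD
  expect_lt(abs(nrow(ann$cpg) - expected), 4 * sdv)
  expect_true(all(diff(ann$cpg$pos) > 1))  # no overlapping dinucleotides
})

test_that("ground truth plants DMRs inside methylated genes at exact delta", {
  cfg <- small_config(seed = 7)
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  tw <- truth$dmr_windows
  expect_equal(nrow(tw), cfg$n_true_dmrs)
  expect_true(all(tw$gene_id %in% truth$methylated_genes))
  genes <- ann$genes
  gi <- match(tw$gene_id, genes$gene_id)
  expect_true(all(tw$start >= genes$start[gi] & tw$end <= genes$end[gi]))
  d <- truth$cpg$pi_care - truth$cpg$pi_nocare
  in_dmr <- rep(FALSE, nrow(truth$cpg))
  for (i in seq_len(nrow(tw))) {
    hit <- truth$cpg$chrom == tw$chrom[i] & truth$cpg$pos >= tw$start[i] &
      truth$cpg$pos < tw$end[i]
    in_dmr <- in_dmr | hit
    expect_true(all(abs(d[hit] - tw$delta[i]) < 1e-12))
  }
  # outside planted windows the two groups share the same truth
  expect_true(all(d[!in_dmr] == 0))
  expect_true(all(truth$cpg$pi_care >= 0 & truth$cpg$pi_care <= 1))
})

test_that("count draws respect the binomial error model at the extremes", {
  cfg <- sim_config(seed = 9, n_chromosomes = 1, chrom_length = 2e4,
                    n_genes = 5, n_true_dmrs = 0, nonconversion_rate = 0,
                    frac_methylated_genes = 0, n_lambda_sites = 100)
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  meth <- generate_methylomes(ann, truth, cfg)
  for (d in meth) expect_true(all(d$m == 0))  # pi = 0, eps = 0

  cfg1 <- sim_config(seed = 9, n_chromosomes = 1, chrom_length = 2e4,
                     n_genes = 5, n_true_dmrs = 0,
                     frac_methylated_genes = 1, methylated_level = 1,
                     five_prime_decay = 1, n_lambda_sites = 0)
  ann1 <- generate_annotation(cfg1)
  truth1 <- generate_truth(ann1, cfg1)
  # force every CpG fully methylated (including intergenic ones)
  truth1$cpg$pi_care <- 1
  truth1$cpg$pi_nocare <- 1
  meth1 <- generate_methylomes(ann1, truth1, cfg1)
  for (d in meth1) expect_true(all(d$m == d$n))
})

test_that("pooled lambda methylation matches the nonconversion rate", {
  cfg <- sim_config(seed = 13, n_chromosomes = 1, chrom_length = 1e4,
                    n_genes = 2, n_true_dmrs = 0,
                    frac_methylated_genes = 0, n_lambda_sites = 10000)
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  meth <- generate_methylomes(ann, truth, cfg)
  lam <- do.call(rbind, split_lambda(meth)$lambda)
  frac <- sum(lam$m) / sum(lam$n)
  se <- sqrt(cfg$nonconversion_rate * (1 - cfg$nonconversion_rate) /
               sum(lam$n))
  expect_lt(abs(frac - cfg$nonconversion_rate), 4 * se)
})

test_that("lambda estimate converges with spike-in depth", {
  # law-of-large-numbers check at three coverage levels
  errs <- vapply(c(5, 30, 120), function(cov) {
    cfg <- sim_config(seed = 17, n_chromosomes = 1, chrom_length = 5e3,
                      n_genes = 1, n_true_dmrs = 0,
                      frac_methylated_genes = 0, coverage_mean = cov,
                      n_lambda_sites = 4000)
    meth <- generate_methylomes(generate_annotation(cfg),
                                generate_truth(generate_annotation(cfg),
                                               cfg), cfg)
    lam <- do.call(rbind, split_lambda(meth)$lambda)
    c(err = abs(sum(lam$m) / sum(lam$n) - cfg$nonconversion_rate),
      n = sum(lam$n))
  }, numeric(2))
  eps <- 0.005
  for (j in 1:3) {
    expect_lt(errs["err", j], 4 * sqrt(eps * (1 - eps) / errs["n", j]))
  }
})

test_that("gene-set overlap follows the configured odds ratio", {
  ann <- fake_annotation(5000)
  # independence: chi-square rejects in at most ~5% of seeds
  rej <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s, overlap_odds_ratio = 1, de_frac = 0.1,
                      as_frac = 0.1)
    gs <- generate_gene_sets(ann, cfg)
    overlap_chisq(gs$de, gs$as_genes)$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.05)

  # enriched: realized odds ratio near the target in most seeds
  ors <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s, overlap_odds_ratio = 10, de_frac = 0.1,
                      as_frac = 0.1)
    gs <- generate_gene_sets(ann, cfg)
    observed_odds_ratio(gs$de$members, gs$as_genes$members,
                        ann$genes$gene_id)
  }, numeric(1))
  expect_gte(mean(ors >= 5 & ors <= 20), 0.90)
})

test_that("empty gene sets and splice-event containment behave", {
  ann <- fake_annotation(100)
  cfg0 <- sim_config(seed = 2, de_frac = 0, as_frac = 0, sel_frac = 0)
  gs0 <- generate_gene_sets(ann, cfg0)
  expect_length(gs0$de$members, 0)
  expect_equal(nrow(gs0$splice_events), 0)

  cfg <- sim_config(seed = 2, as_frac = 0.2)
  gs <- generate_gene_sets(ann, cfg)
  ev <- gs$splice_events
  expect_true(all(ev$gene_id %in% gs$as_genes$members))
  gi <- match(ev$gene_id, ann$genes$gene_id)
  expect_true(all(ev$start >= ann$genes$start[gi] &
                    ev$end <= ann$genes$end[gi]))
  expect_true(all(ev$end > ev$start))
})

test_that("expression generator hits the target rank correlation", {
  mk_truth <- function(n, seed) {
    set.seed(seed)
    # mosaic methylome shape: most genes unmethylated, rest spread out
    pi <- numeric(n)
    k <- round(0.3 * n)
    pi[sample.int(n, k)] <- stats::rbeta(k, 2, 2)
    structure(list(gene_pi = setNames(pi, sprintf("g%06d", seq_len(n)))),
              class = "meth_truth")
  }
  truth <- mk_truth(2000, 21)
  e0 <- generate_expression(truth, sim_config(seed = 21,
                                              expression_rho = 0))
  expect_lt(abs(cor(truth$gene_pi, e0, method = "spearman")), 0.1)

  e1 <- generate_expression(truth, sim_config(seed = 21,
                                              expression_rho = 1))
  expect_equal(cor(truth$gene_pi, e1, method = "spearman"), 1)

  truth10 <- mk_truth(10000, 22)
  e <- generate_expression(truth10, sim_config(seed = 22,
                                               expression_rho = 0.24))
  rho <- cor(truth10$gene_pi, e, method = "spearman")
  expect_gte(rho, 0.20)
  expect_lte(rho, 0.28)
  expect_error(generate_expression(truth,
                                   sim_config(expression_rho = 1.5)),
               "expression_rho")
})
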