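# small builder for aligned per-sample call tables
toy_calls <- function(pos, m, n, methylated) {
  data.frame(chrom = "chr1", pos = pos, strand = "merged", m = m, n = n,
             p_value = NA_real_, q_value = NA_real_,
             methylated = methylated, stringsAsFactors = FALSE)
}

test_that("site filters apply the stated rules in order", {
  pos <- c(10L, 20L, 30L, 40L)
  # site 10: significant in one sample, good coverage -> retained
  # site 20: significant nowhere -> removed at step 1
  # site 30: significant, but zero coverage in sample 2 -> removed
  # site 40: significant, but coverage 171 in sample 2 -> removed
  s1 <- toy_calls(pos, m = c(5L, 0L, 5L, 5L), n = c(10L, 10L, 10L, 10L),
                  methylated = c(TRUE, FALSE, TRUE, TRUE))
  s2 <- toy_calls(pos, m = c(0L, 0L, 0L, 0L), n = c(170L, 10L, 0L, 171L),
                  methylated = FALSE)
  f <- filter_sites(list(s1 = s1, s2 = s2))
  expect_equal(f$sites$pos, 10L)
  expect_equal(attr(f, "filter_counts"),
               c(input = 4L, significant_in_one = 3L,
                 covered_everywhere = 2L, below_max_cov = 1L))
  s3 <- toy_calls(c(10L, 25L), 0L, 5L, FALSE)
  expect_error(filter_sites(list(s1 = s1, s3 = s3)), "universe")
})

test_that("window tiling is a half-open partition", {
  mk <- function(pos) {
    calls <- toy_calls(pos, m = 1L, n = 10L, methylated = TRUE)
    filter_sites(list(a = calls, b = calls))
  }
  wm <- bin_windows(mk(c(50L, 150L)))
  expect_equal(wm$windows[, c("start", "end", "cpg_count")],
               data.frame(start = 0L, end = 200L, cpg_count = 2L))

  # a lone CpG leaves its window under the >= 2 CpG rule
  expect_equal(nrow(bin_windows(mk(250L))$windows), 0)

  # boundary site belongs to the right-hand window (half-open tiling)
  wm2 <- bin_windows(mk(c(199L, 200L, 201L)))
  expect_equal(wm2$windows$start, 200L)
  expect_equal(wm2$windows$cpg_count, 2L)

  # partition: with min_cpg = 1 every retained site is in exactly one window
  pos <- sort(sample.int(5000L, 300L)) - 1L
  wm3 <- bin_windows(mk(pos), min_cpg = 1L)
  expect_equal(sum(wm3$windows$cpg_count), length(pos))
  expect_equal(sum(wm3$N[, "a"]), 300 * 10)
})

test_that("closed-form window test equals the binomial GLM LRT", {
  set.seed(61)
  groups <- setNames(rep(c("care", "nocare"), each = 3),
                     c("c1", "c2", "c3", "n1", "n2", "n3"))
  N <- matrix(rnbinom(60, mu = 80, size = 5) + 1, 10, 6,
              dimnames = list(NULL, names(groups)))
  pi_w <- runif(10, 0.05, 0.95)
  M <- matrix(rbinom(60, as.vector(N), rep(pi_w, 6)), 10, 6)
  wm <- make_window_matrix(M, N)
  tested <- test_windows(wm, groups, backend = "glm")
  for (i in 1:10) {
    df <- data.frame(m = M[i, ], n = N[i, ], g = factor(groups))
    fit1 <- glm(cbind(m, n - m) ~ g, family = binomial, data = df)
    fit0 <- glm(cbind(m, n - m) ~ 1, family = binomial, data = df)
    p_glm <- anova(fit0, fit1, test = "Chisq")$`Pr(>Chi)`[2L]
    expect_equal(tested$p_value[i], p_glm, tolerance = 1e-8)
  }
  # diff sign: positive means higher in the case ("care") group
  expect_equal(tested$diff,
               100 * (rowSums(M[, 1:3]) / rowSums(N[, 1:3]) -
                        rowSums(M[, 4:6]) / rowSums(N[, 4:6])))
})

test_that("fisher backend equals brute-force hypergeometric enumeration", {
  # independent oracle: two-sided Fisher p as the sum of all tables with
  # probability not exceeding the observed one
  brute_fisher <- function(m1, n1, m2, n2) {
    k <- m1 + m2
    lo <- max(0L, k - n2)
    hi <- min(n1, k)
    x <- lo:hi
    pr <- dhyper(x, n1, n2, k)
    sum(pr[pr <= dhyper(m1, n1, n2, k) * (1 + 1e-7)])
  }
  groups <- c(a = "care", b = "nocare")
  set.seed(62)
  for (rep in 1:25) {
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    m1 <- sample(0:n1, 1); m2 <- sample(0:n2, 1)
    wm <- make_window_matrix(matrix(c(m1, m2), 1,
                                    dimnames = list(NULL, c("a", "b"))),
                             matrix(c(n1, n2), 1))
    p <- test_windows(wm, groups, backend = "fisher")$p_value
    expect_equal(p, brute_fisher(m1, n1, m2, n2), tolerance = 1e-10)
  }
  # worked example: 30/100 vs 10/100 in a single pooled table
  wm <- make_window_matrix(matrix(c(30, 10), 1,
                                  dimnames = list(NULL, c("a", "b"))),
                           matrix(c(100, 100), 1))
  tested <- test_windows(wm, groups, backend = "fisher")
  expect_equal(tested$p_value, brute_fisher(30, 100, 10, 100),
               tolerance = 1e-10)
  expect_equal(tested$diff, 20)
})

test_that("DMR thresholds and edge conventions hold", {
  groups <- setNames(rep(c("care", "nocare"), each = 2),
                     c("c1", "c2", "n1", "n2"))
  # identical pooled proportions: diff 0, p ~ 1, not a DMR
  wm <- make_window_matrix(
    matrix(20, 1, 4, dimnames = list(NULL, names(groups))),
    matrix(100, 1, 4))
  tested <- test_windows(wm, groups)
  expect_equal(tested$diff, 0)
  expect_gt(tested$p_value, 0.99)
  expect_false(call_dmrs(tested)$is_dmr)

  # significant q but small difference is not a DMR
  fake <- data.frame(chrom = "chr1", start = 0L, end = 200L,
                     cpg_count = 3L, level_case = 0.23,
                     level_control = 0.20, diff = 3,
                     p_value = 1e-6)
  expect_false(call_dmrs(fake)$is_dmr)
  # ... but the same q with diff exactly 5 is (inclusive boundary)
  fake$diff <- 5
  expect_true(call_dmrs(fake)$is_dmr)

  # BH identity for a single tested window
  fake$p_value <- 0.001
  fake$diff <- 10
  one <- call_dmrs(fake)
  expect_equal(one$q_value, 0.001)
  expect_true(one$is_dmr)

  # a window untested in one group is excluded from the FDR family
  wm0 <- make_window_matrix(
    matrix(c(5, 9, 5, 9, 0, 0, 0, 0), 2, 4,
           dimnames = list(NULL, names(groups))),
    matrix(c(10, 10, 10, 10, 0, 0, 0, 0), 2, 4))
  t0 <- test_windows(wm0, groups)
  expect_true(all(is.na(t0$p_value)))
  expect_warning(call_dmrs(t0), "no testable windows")
})

test_that("window p-values are super-uniform under an exchangeable null", {
  set.seed(63)
  nw <- 6000L
  groups <- setNames(rep(c("care", "nocare"), each = 3),
                     c("c1", "c2", "c3", "n1", "n2", "n3"))
  N <- matrix(rnbinom(nw * 6, mu = 90, size = 5) + 2, nw, 6,
              dimnames = list(NULL, names(groups)))
  pi_w <- rep(runif(nw, 0.1, 0.9), 6)
  M <- matrix(rbinom(nw * 6, as.vector(N), pi_w), nw, 6)
  tested <- test_windows(make_window_matrix(M, N), groups)
  p <- tested$p_value
  grid <- seq(0.01, 0.99, by = 0.01)
  ecdfv <- vapply(grid, function(t) mean(p <= t), numeric(1))
  expect_true(all(ecdfv <= grid + 0.10))
})

test_that("false discoveries stay at the nominal rate on null genomes", {
  groups <- setNames(rep(c("care", "nocare"), each = 3),
                     c("c1", "c2", "c3", "n1", "n2", "n3"))
  total_dmrs <- 0
  total_windows <- 0
  for (s in 1:10) {
    set.seed(700 + s)
    nw <- 500L
    N <- matrix(rnbinom(nw * 6, mu = 90, size = 5) + 2, nw, 6,
                dimnames = list(NULL, names(groups)))
    pi_w <- rep(runif(nw, 0.1, 0.9), 6)
    M <- matrix(rbinom(nw * 6, as.vector(N), pi_w), nw, 6)
    d <- call_dmrs(test_windows(make_window_matrix(M, N), groups))
    total_dmrs <- total_dmrs + sum(d$is_dmr)
    total_windows <- total_windows + nw
  }
  expect_lte(total_dmrs / 10, 0.01 * 500)
})

test_that("DMR annotation maps windows to overlapping genes", {
  genes <- data.frame(gene_id = c("A", "B"), chrom = "chr1",
                      start = c(0L, 300L), end = c(250L, 500L),
                      stringsAsFactors = FALSE)
  dmrs <- data.frame(chrom = "chr1", start = c(100L, 240L, 600L),
                     end = c(300L, 440L, 800L),
                     is_dmr = c(TRUE, TRUE, TRUE),
                     stringsAsFactors = FALSE)
  ann <- annotate_dmrs(dmrs, genes)
  # half-open adjacency: [100,300) does not touch B starting at 300
  expect_equal(ann$gene_ids[[1L]], "A")
  expect_equal(ann$gene_ids[[2L]], c("A", "B"))  # spans both genes
  expect_equal(ann$gene_ids[[3L]], character(0)) # intergenic
  expect_setequal(attr(ann, "dm_genes"), c("A", "B"))
})
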