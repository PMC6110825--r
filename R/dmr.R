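#' Filter the shared CpG site universe before DMR calling
#'
#' Applies, in order: (1) keep sites with a significant methylation call
#' (`q < 0.05`) in at least one sample, to diminish background noise;
#' (2) remove sites with no coverage in any sample; (3) remove sites with
#' coverage above `max_cov` in any sample (a PCR-artifact guard).  The
#' counts surviving each step are recorded so the filtration can be
#' audited.
#'
#' @param calls_list named list of per-sample site-call data.frames from
#'   [call_site_methylation()], all over the same site universe.
#' @param max_cov per-sample coverage ceiling (default 170).
#' @return List of class `meth_matrix`: `sites` (data.frame `chrom`,
#'   `pos`), `M` and `N` (sites x samples count matrices), `groups`
#'   placeholder `NULL`, and attribute `filter_counts` with the site tally
#'   after each step.
#' @export
filter_sites <- function(calls_list, max_cov = 170L) {
  samples <- names(calls_list)
  if (length(samples) < 2L) stop("need at least two samples")
  ref <- calls_list[[1L]]
  key <- paste(ref$chrom, ref$pos)
  for (s in samples[-1L]) {
    k <- paste(calls_list[[s]]$chrom, calls_list[[s]]$pos)
    if (length(k) != length(key) || !all(k == key)) {
      stop("samples do not share a common site universe; align sites ",
           "before filtering")
    }
  }
  M <- matrix(vapply(calls_list, function(d) as.numeric(d$m),
                     numeric(nrow(ref))),
              nrow(ref), length(samples), dimnames = list(NULL, samples))
  N <- matrix(vapply(calls_list, function(d) as.numeric(d$n),
                     numeric(nrow(ref))),
              nrow(ref), length(samples), dimnames = list(NULL, samples))
  sig <- matrix(vapply(calls_list, function(d) d$methylated,
                       logical(nrow(ref))),
                nrow(ref), length(samples))
  n0 <- nrow(ref)
  keep1 <- rowSums(sig) >= 1L
  keep2 <- keep1 & apply(N >= 1L, 1L, all)
  keep3 <- keep2 & apply(N <= max_cov, 1L, all)
  counts <- c(input = n0, significant_in_one = sum(keep1),
              covered_everywhere = sum(keep2),
              below_max_cov = sum(keep3))
  structure(
    list(sites = ref[keep3, c("chrom", "pos"), drop = FALSE],
         M = M[keep3, , drop = FALSE], N = N[keep3, , drop = FALSE]),
    class = "meth_matrix", filter_counts = counts)
}

#' Tile filtered sites into fixed windows
#'
#' Assigns each retained CpG to the fixed non-overlapping window
#' `[floor(pos / size) * size, ... + size)` on its chromosome (half-open,
#' so a site at exactly a window boundary belongs to the right-hand
#' window), sums per-sample counts within windows, and drops windows with
#' fewer than `min_cpg` CpGs.  Every retained CpG lies in exactly one
#' window.
#'
#' @param mat a `meth_matrix` from [filter_sites()].
#' @param size window size in bp (default 200, approximating the median
#'   exon length of the emulated genome).
#' @param min_cpg minimum CpG count per tested window (default 2).
#' @return List of class `window_matrix`: `windows` (data.frame `chrom`,
#'   `start`, `end`, `cpg_count`) and per-sample `M`, `N` matrices.
#' @export
bin_windows <- function(mat, size = 200L, min_cpg = 2L) {
  stopifnot(inherits(mat, "meth_matrix"))
  ws <- (mat$sites$pos %/% size) * size
  k <- paste(mat$sites$chrom, ws, sep = "\r")
  if (length(k) == 0L) {
    return(structure(list(
      windows = data.frame(chrom = character(), start = integer(),
                           end = integer(), cpg_count = integer(),
                           stringsAsFactors = FALSE),
      M = mat$M[0L, , drop = FALSE], N = mat$N[0L, , drop = FALSE]),
      class = "window_matrix"))
  }
  M <- rowsum(mat$M, k)
  N <- rowsum(mat$N, k)
  cnt <- as.integer(rowsum(rep(1L, length(k)), k)[, 1L])
  parts <- strsplit(rownames(M), "\r", fixed = TRUE)
  win <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    start = as.integer(vapply(parts, `[`, character(1), 2L)),
    stringsAsFactors = FALSE)
  win$end <- win$start + as.integer(size)
  win$cpg_count <- cnt
  keep <- cnt >= min_cpg
  ord <- order(win$chrom[keep], win$start[keep])
  rownames(M) <- rownames(N) <- NULL
  structure(list(
    windows = {
      w <- win[keep, , drop = FALSE][ord, , drop = FALSE]
      rownames(w) <- NULL
      w
    },
    M = M[keep, , drop = FALSE][ord, , drop = FALSE],
    N = N[keep, , drop = FALSE][ord, , drop = FALSE]),
    class = "window_matrix")
}

# Closed-form likelihood-ratio test of a binomial GLM with one binary
# covariate, vectorized over windows.  With a group-only design the MLE
# fitted probabilities are the group-pooled proportions, so the glm
# deviance difference reduces to a 2x2 G-statistic on pooled counts;
# equality with stats::glm is asserted in the test suite.
lrt_group <- function(m1, n1, m2, n2) {
  xlogy <- function(x, y) ifelse(x > 0, x * log(y), 0)
  ll <- function(m, n, p) xlogy(m, p) + xlogy(n - m, 1 - p)
  p1 <- ifelse(n1 > 0, m1 / n1, 0)
  p2 <- ifelse(n2 > 0, m2 / n2, 0)
  p0 <- (m1 + m2) / (n1 + n2)
  g <- 2 * (ll(m1, n1, p1) + ll(m2, n2, p2) - ll(m1 + m2, n1 + n2, p0))
  pchisq(pmax(g, 0), df = 1L, lower.tail = FALSE)
}

#' Test windows for differential methylation between two groups
#'
#' The default `"glm"` backend is the replicate-aware binomial
#' logistic-regression likelihood-ratio test of per-sample `(m, n)` on
#' group membership (computed in closed form; no overdispersion
#' correction).  The `"fisher"` backend pools counts within groups and
#' applies a two-sided Fisher exact test, useful as a small-sample oracle.
#' The methylation difference is reported in percentage points from
#' coverage-weighted pooled group levels, positive when the first group
#' (`case`) is higher.
#'
#' Windows where either group has zero total coverage are untested
#' (`NA` p-value) and are excluded from the downstream FDR family.
#'
#' @param wm a `window_matrix` from [bin_windows()].
#' @param groups named character vector mapping sample names (columns of
#'   the matrices) to exactly two group labels.
#' @param case the group whose excess methylation counts as a positive
#'   difference (default `"care"` when present, else the first label).
#' @param backend `"glm"` (default) or `"fisher"`.
#' @return The window data.frame with `level_case`, `level_control`,
#'   `diff` (percentage points), `p_value`.
#' @export
test_windows <- function(wm, groups, case = NULL,
                         backend = c("glm", "fisher")) {
  stopifnot(inherits(wm, "window_matrix"))
  backend <- match.arg(backend)
  samples <- colnames(wm$M)
  if (!all(samples %in% names(groups))) {
    stop("'groups' must name every sample")
  }
  g <- groups[samples]
  labs <- unique(g)
  if (length(labs) != 2L) stop("exactly two group labels required")
  if (is.null(case)) case <- if ("care" %in% labs) "care" else labs[1L]
  control <- setdiff(labs, case)
  i1 <- which(g == case)
  i2 <- which(g == control)
  m1 <- rowSums(wm$M[, i1, drop = FALSE])
  n1 <- rowSums(wm$N[, i1, drop = FALSE])
  m2 <- rowSums(wm$M[, i2, drop = FALSE])
  n2 <- rowSums(wm$N[, i2, drop = FALSE])
  testable <- n1 > 0 & n2 > 0
  p <- rep(NA_real_, nrow(wm$windows))
  if (backend == "glm") {
    p[testable] <- lrt_group(m1[testable], n1[testable], m2[testable],
                             n2[testable])
  } else {
    idx <- which(testable)
    p[idx] <- vapply(idx, function(i) {
      fisher.test(matrix(c(m1[i], n1[i] - m1[i], m2[i], n2[i] - m2[i]),
                         2L))$p.value
    }, numeric(1))
  }
  out <- wm$windows
  out$level_case <- ifelse(n1 > 0, m1 / n1, NA_real_)
  out$level_control <- ifelse(n2 > 0, m2 / n2, NA_real_)
  out$diff <- 100 * (out$level_case - out$level_control)
  out$p_value <- p
  attr(out, "case") <- case
  attr(out, "control") <- control
  out
}

#' Call DMRs from tested windows
#'
#' Benjamini-Hochberg adjusts the p-values of tested windows (untested
#' `NA` windows are excluded from the family) and flags a window as a DMR
#' when `q < q_threshold` and `|diff| >= min_diff` percentage points.
#'
#' @param tested output of [test_windows()].
#' @param q_threshold FDR ceiling (default 0.01).
#' @param min_diff minimum absolute methylation difference in percentage
#'   points (default 5, inclusive).
#' @return A `dmr_result` data.frame adding `q_value` and `is_dmr`;
#'   `summary()` reports the DMR count and the fraction hypermethylated in
#'   the case group.
#' @export
call_dmrs <- function(tested, q_threshold = 0.01, min_diff = 5) {
  out <- tested
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  if (!any(ok)) {
    warning("no testable windows; returning empty DMR set")
  } else {
    out$q_value[ok] <- p.adjust(out$p_value[ok], method = "BH")
  }
  out$is_dmr <- !is.na(out$q_value) & out$q_value < q_threshold &
    abs(out$diff) >= min_diff
  class(out) <- c("dmr_result", class(tested))
  attr(out, "q_threshold") <- q_threshold
  attr(out, "min_diff") <- min_diff
  attr(out, "case") <- attr(tested, "case")
  attr(out, "control") <- attr(tested, "control")
  out
}

#' @export
summary.dmr_result <- function(object, ...) {
  n_dmr <- sum(object$is_dmr)
  hyper <- if (n_dmr > 0) mean(object$diff[object$is_dmr] > 0) else
    NA_real_
  res <- list(n_tested = sum(!is.na(object$p_value)),
              n_windows = nrow(object), n_dmr = n_dmr,
              frac_hyper_case = hyper, case = attr(object, "case"),
              control = attr(object, "control"))
  class(res) <- "summary.dmr_result"
  res
}

#' @export
print.summary.dmr_result <- function(x, ...) {
  cat(sprintf("%d / %d windows tested, %d DMRs\n", x$n_tested,
              x$n_windows, x$n_dmr))
  if (!is.na(x$frac_hyper_case)) {
    cat(sprintf("  %.0f%% hypermethylated in '%s'\n",
                100 * x$frac_hyper_case, x$case))
  }
  invisible(x)
}

#' Annotate DMRs with overlapping genes
#'
#' Adds, to every window, the identifiers of all genes whose span
#' intersects it (half-open interval semantics on both sides); a DMR may
#' be intergenic (no gene) or span several genes, which is how a DMR count
#' can map to a larger gene count.
#'
#' @param dmrs a `dmr_result` (or any window data.frame with `chrom`,
#'   `start`, `end`).
#' @param genes gene data.frame (`gene_id`, `chrom`, `start`, `end`).
#' @return The input with a `gene_ids` list-column; the set of genes
#'   hit by significant DMRs is in attribute `dm_genes`.
#' @export
annotate_dmrs <- function(dmrs, genes) {
  w_gr <- GenomicRanges::GRanges(
    dmrs$chrom, IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  g_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  h <- GenomicRanges::findOverlaps(w_gr, g_gr)
  ids <- split(genes$gene_id[S4Vectors::subjectHits(h)],
               factor(S4Vectors::queryHits(h), levels = seq_len(nrow(dmrs))))
  out <- dmrs
  out$gene_ids <- lapply(ids, as.character)
  dm <- if (!is.null(out$is_dmr)) {
    sort(unique(unlist(out$gene_ids[out$is_dmr])))
  } else sort(unique(unlist(out$gene_ids)))
  attr(out, "dm_genes") <- dm
  out
}

#' Run the full DMR analysis
#'
#' Chains per-sample site calling, site filtering, window tiling, the
#' between-group window test and DMR calling; optionally annotates the
#' calls with gene models.
#'
#' @param counts_list named list of merged count data.frames (genome
#'   sites only, no lambda rows).
#' @param groups named group labels per sample.
#' @param epsilon nonconversion rate (a `conversion_control` or numeric).
#' @param genes optional gene data.frame for annotation.
#' @param site_alpha per-site methylation-call FDR (default 0.05).
#' @param max_cov coverage ceiling (default 170).
#' @param window_size,min_cpg tiling parameters (defaults 200 bp, 2 CpGs).
#' @param q_threshold,min_diff DMR thresholds (defaults 0.01 and 5).
#' @param backend window test backend, `"glm"` or `"fisher"`.
#' @param case group treated as positive-difference direction.
#' @return List: `calls` (per-sample site calls), `filtered`
#'   (`meth_matrix`), `binned` (`window_matrix`), `dmrs` (`dmr_result`).
#' @export
run_dmr_analysis <- function(counts_list, groups, epsilon, genes = NULL,
                             site_alpha = 0.05, max_cov = 170L,
                             window_size = 200L, min_cpg = 2L,
                             q_threshold = 0.01, min_diff = 5,
                             backend = "glm", case = NULL) {
  calls <- lapply(counts_list, call_site_methylation, control = epsilon,
                  alpha = site_alpha)
  filtered <- filter_sites(calls, max_cov = max_cov)
  binned <- bin_windows(filtered, size = window_size, min_cpg = min_cpg)
  tested <- test_windows(binned, groups, case = case, backend = backend)
  dmrs <- call_dmrs(tested, q_threshold = q_threshold,
                    min_diff = min_diff)
  if (!is.null(genes)) dmrs <- annotate_dmrs(dmrs, genes)
  list(calls = calls, filtered = filtered, binned = binned, dmrs = dmrs)
}
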