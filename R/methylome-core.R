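#' Estimate the bisulfite nonconversion rate from a lambda spike-in
#'
#' Pools methylated and total read counts over every cytosine of the
#' unmethylated lambda control: since the spike-in carries no methylation,
#' any methylated reads are conversion failures and the pooled ratio
#' estimates the nonconversion rate `eps` used as the null expectation of
#' the per-site binomial test.
#'
#' @param lambda_sites count data.frame (`m`, `n` columns; stranded or
#'   merged) restricted to the lambda control chromosome.
#' @return List of class `conversion_control`: `epsilon`, `lambda_m`,
#'   `lambda_n`.
#' @export
#' @examples
#' estimate_nonconversion(data.frame(m = c(1, 2, 0), n = c(100, 100, 100)))
estimate_nonconversion <- function(lambda_sites) {
  m <- sum(lambda_sites$m)
  n <- sum(lambda_sites$n)
  if (!length(lambda_sites$n) || n <= 0) {
    stop("no lambda control coverage: supply an explicit nonconversion ",
         "rate instead of relying on a default")
  }
  structure(list(epsilon = m / n, lambda_m = m, lambda_n = n),
            class = "conversion_control")
}

#' @export
print.conversion_control <- function(x, ...) {
  cat(sprintf("Nonconversion rate: %.4g (%d / %d lambda reads)\n",
              x$epsilon, x$lambda_m, x$lambda_n))
  invisible(x)
}

#' Merge CpG strands into one record per dinucleotide
#'
#' A CpG carries a cytosine on each strand one bp apart; counts from the
#' minus-strand G (at `pos + 1`) are summed into the plus-strand C
#' coordinate so each dinucleotide is represented by one methylation
#' value.  Unpaired strands pass through as merged singletons at the
#' plus-strand C coordinate.  Total reads are conserved.
#'
#' @param sites stranded count data.frame (`chrom`, `pos`, `strand`, `m`,
#'   `n`).
#' @return Merged data.frame (`chrom`, `pos`, `strand = "merged"`, `m`,
#'   `n`), sorted by position.
#' @export
merge_strands <- function(sites) {
  if (!all(sites$strand %in% c("+", "-"))) {
    stop("input must be strand-resolved (+/-)")
  }
  key <- paste(sites$chrom, sites$pos, sites$strand)
  if (anyDuplicated(key)) {
    stop("duplicate records for the same (site, strand)")
  }
  cpos <- ifelse(sites$strand == "-", sites$pos - 1L, sites$pos)
  k <- paste(sites$chrom, cpos, sep = "\r")
  m <- rowsum(sites$m, k)
  n <- rowsum(sites$n, k)
  parts <- strsplit(rownames(m), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[`, character(1), 2L)),
    strand = "merged", m = as.integer(m[, 1L]), n = as.integer(n[, 1L]),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strand-discordance (hemimethylation) by coverage
#'
#' For every CpG covered on both strands, computes the absolute difference
#' of the strand-wise methylation fractions and averages it within bins of
#' total (both-strand) coverage.  Under purely strand-symmetric
#' methylation, discordance is binomial sampling noise and shrinks as
#' coverage grows — the diagnostic used to attribute apparent
#' hemimethylation to low coverage.
#'
#' @param sites stranded count data.frame for one sample.
#' @param breaks coverage-bin breakpoints (total reads over both strands).
#' @return data.frame `bin`, `midpoint`, `n_sites`, `mean_discordance`.
#' @export
hemimethylation_by_coverage <- function(sites,
                                        breaks = c(0, 2, 5, 10, 20, 40,
                                                   80, Inf)) {
  plus <- sites[sites$strand == "+", , drop = FALSE]
  minus <- sites[sites$strand == "-", , drop = FALSE]
  key_p <- paste(plus$chrom, plus$pos)
  key_m <- paste(minus$chrom, minus$pos - 1L)
  i <- match(key_p, key_m)
  ok <- !is.na(i)
  p <- plus[ok, , drop = FALSE]
  q <- minus[i[ok], , drop = FALSE]
  both <- p$n > 0 & q$n > 0
  p <- p[both, , drop = FALSE]
  q <- q[both, , drop = FALSE]
  disc <- abs(p$m / p$n - q$m / q$n)
  cov <- p$n + q$n
  bin <- cut(cov, breaks = breaks, right = TRUE)
  mids <- (head(breaks, -1) + breaks[-1]) / 2
  agg <- tapply(disc, bin, mean)
  cnt <- tapply(disc, bin, length)
  out <- data.frame(bin = levels(bin), midpoint = mids,
                    n_sites = as.integer(ifelse(is.na(cnt), 0L, cnt)),
                    mean_discordance = as.numeric(agg),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call per-site methylation status against the nonconversion null
#'
#' Tests each (merged) CpG for methylation above the bisulfite conversion
#' error: under the null a site is unmethylated and its methylated reads
#' arise at rate `eps`, so the one-sided p-value is the exact upper
#' binomial tail `P[X >= m | X ~ Binomial(n, eps)]`.  P-values are
#' Benjamini-Hochberg adjusted across all tested sites within the sample
#' and a site is called methylated when `q < alpha`.
#'
#' Edge conventions: `m = 0` gives `p = 1`; `n = 0` gives `p = 1`; with
#' `eps = 0` any `m > 0` gives `p = 0`.
#'
#' @param sites merged count data.frame for one sample.
#' @param control a `conversion_control` from [estimate_nonconversion()],
#'   or a bare numeric nonconversion rate.
#' @param alpha FDR threshold for the methylated call (default 0.05).
#' @return The input with `p_value`, `q_value` and `methylated` columns.
#' @export
call_site_methylation <- function(sites, control, alpha = 0.05) {
  eps <- if (inherits(control, "conversion_control")) control$epsilon
  else as.numeric(control)
  if (is.na(eps) || eps < 0 || eps >= 1) {
    stop("nonconversion rate must lie in [0, 1)")
  }
  p <- pbinom(sites$m - 1L, sites$n, eps, lower.tail = FALSE)
  p[sites$n == 0L] <- 1
  out <- sites
  out$p_value <- p
  out$q_value <- p.adjust(p, method = "BH")
  out$methylated <- out$q_value < alpha
  out
}

#' Gene-body methylation levels and the methylated-gene set
#'
#' The gene-level methylation of a sample is the coverage-weighted level
#' `sum(m) / sum(n)` over every CpG whose merged coordinate falls inside
#' the gene span (introns included).  A gene with no covered CpG in a
#' sample carries `NA` (undefined, not zero) and does not contribute to
#' that sample's cutoff decision.  A gene is classed methylated when its
#' level is strictly greater than `cutoff` in at least one sample.
#'
#' @param counts_list named list of merged count data.frames, one per
#'   sample.
#' @param genes gene data.frame (`gene_id`, `chrom`, `start`, `end`;
#'   0-based half-open).
#' @param cutoff methylated-gene threshold on the level (default 0.05,
#'   strict `>`).
#' @return List: `levels` (genes x samples matrix of levels, `NA` where
#'   undefined), `m`, `n` (matching count matrices) and
#'   `methylated_genes` (character vector).
#' @export
gene_methylation_levels <- function(counts_list, genes, cutoff = 0.05) {
  samples <- names(counts_list)
  gm <- matrix(0, nrow(genes), length(samples),
               dimnames = list(genes$gene_id, samples))
  gn <- gm
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  for (s in samples) {
    df <- counts_list[[s]]
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$pos + 1L, width = 1L))
    h <- GenomicRanges::findOverlaps(gr, gene_gr)
    if (length(h)) {
      qs <- S4Vectors::queryHits(h)
      sj <- S4Vectors::subjectHits(h)
      ms <- rowsum(df$m[qs], sj)
      ns <- rowsum(df$n[qs], sj)
      idx <- as.integer(rownames(ms))
      gm[idx, s] <- ms[, 1L]
      gn[idx, s] <- ns[, 1L]
    }
  }
  levels <- ifelse(gn > 0, gm / gn, NA_real_)
  meth <- rownames(levels)[apply(levels > cutoff, 1L,
                                 function(x) any(x, na.rm = TRUE))]
  list(levels = levels, m = gm, n = gn, methylated_genes = meth)
}

#' Methylation and CpG density per gene feature (metaplot table)
#'
#' Pools counts across samples and summarises methylation level and CpG
#' density per feature class: upstream flank, exons by 5'-to-3' rank,
#' introns by rank, and downstream flank.  In mosaic insect methylomes
#' this profile shows the characteristic bias towards 5' exons.
#'
#' @param counts_list named list of merged count data.frames (or a single
#'   data.frame).
#' @param annotation a `meth_annotation` (needs `genes` and `exons`).
#' @param flank flank width in bp (default 200).
#' @return data.frame `feature`, `n_cpg`, `total_bp`, `cpg_per_bp`, `m`,
#'   `n`, `level`; empty when no genes are annotated.
#' @export
feature_metaplot <- function(counts_list, annotation, flank = 200L) {
  if (is.data.frame(counts_list)) counts_list <- list(sample = counts_list)
  genes <- annotation$genes
  exons <- annotation$exons
  if (nrow(genes) == 0L) {
    return(data.frame(feature = character(), n_cpg = integer(),
                      total_bp = integer(), cpg_per_bp = numeric(),
                      m = integer(), n = integer(), level = numeric(),
                      stringsAsFactors = FALSE))
  }
  # pooled counts across samples keyed by merged position
  pool <- do.call(rbind, counts_list)
  k <- paste(pool$chrom, pool$pos, sep = "\r")
  pm <- rowsum(pool$m, k)
  pn <- rowsum(pool$n, k)
  parts <- strsplit(rownames(pm), "\r", fixed = TRUE)
  sites <- data.frame(chrom = vapply(parts, `[`, character(1), 1L),
                      pos = as.integer(vapply(parts, `[`, character(1),
                                              2L)),
                      m = as.numeric(pm[, 1L]), n = as.numeric(pn[, 1L]),
                      stringsAsFactors = FALSE)

  # feature intervals: exon_<rank>, intron_<rank>, upstream, downstream
  feat <- list()
  feat$exon <- data.frame(feature = sprintf("exon_%d", exons$exon_rank),
                          chrom = exons$chrom, start = exons$start,
                          end = exons$end, stringsAsFactors = FALSE)
  intr <- do.call(rbind, lapply(split(exons, exons$gene_id), function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2L) return(NULL)
    # intron rank follows transcription: between exon ranks r and r+1
    left_rank <- ex$exon_rank[-nrow(ex)]
    right_rank <- ex$exon_rank[-1L]
    rank <- pmin(left_rank, right_rank)
    data.frame(feature = sprintf("intron_%d", rank), chrom = ex$chrom[-1L],
               start = ex$end[-nrow(ex)], end = ex$start[-1L],
               stringsAsFactors = FALSE)
  }))
  feat$intron <- intr
  feat$up <- data.frame(
    feature = "upstream",
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+", pmax(0L, genes$start - flank),
                   genes$end),
    end = ifelse(genes$strand == "+", genes$start, genes$end + flank),
    stringsAsFactors = FALSE)
  feat$down <- data.frame(
    feature = "downstream",
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+", genes$end,
                   pmax(0L, genes$start - flank)),
    end = ifelse(genes$strand == "+", genes$end + flank, genes$start),
    stringsAsFactors = FALSE)
  fv <- do.call(rbind, feat)
  fv <- fv[fv$end > fv$start, , drop = FALSE]

  fgr <- GenomicRanges::GRanges(fv$chrom,
                                IRanges::IRanges(fv$start + 1L, fv$end))
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos + 1L,
                                                 width = 1L))
  h <- GenomicRanges::findOverlaps(sgr, fgr)
  f_of_hit <- fv$feature[S4Vectors::subjectHits(h)]
  m_sum <- tapply(sites$m[S4Vectors::queryHits(h)], f_of_hit, sum)
  n_sum <- tapply(sites$n[S4Vectors::queryHits(h)], f_of_hit, sum)
  cpg_cnt <- tapply(rep(1L, length(h)), f_of_hit, sum)
  bp <- tapply(fv$end - fv$start, fv$feature, sum)

  feats <- names(bp)
  ord <- order(match(sub("_.*", "", feats),
                     c("upstream", "exon", "intron", "downstream")),
               suppressWarnings(as.integer(sub(".*_", "", feats))))
  feats <- feats[ord]
  get0n <- function(x, f) ifelse(f %in% names(x), as.numeric(x[f]), 0)
  out <- data.frame(
    feature = feats,
    n_cpg = as.integer(vapply(feats, function(f) get0n(cpg_cnt, f),
                              numeric(1))),
    total_bp = as.integer(bp[feats]),
    m = vapply(feats, function(f) get0n(m_sum, f), numeric(1)),
    n = vapply(feats, function(f) get0n(n_sum, f), numeric(1)),
    stringsAsFactors = FALSE)
  out$cpg_per_bp <- out$n_cpg / out$total_bp
  out$level <- ifelse(out$n > 0, out$m / out$n, NA_real_)
  rownames(out) <- NULL
  out[, c("feature", "n_cpg", "total_bp", "cpg_per_bp", "m", "n", "level")]
}
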