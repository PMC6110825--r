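#' Generate a synthetic gene annotation and CpG map
#'
#' Places non-overlapping genes with ordered exons on each chromosome and
#' scatters CpG dinucleotides by an independent per-bp Bernoulli trial
#' (positions one bp apart are thinned so dinucleotides never overlap).
#' Coordinates are 0-based half-open throughout; the recorded CpG position
#' is the plus-strand cytosine, whose minus-strand partner sits at
#' `pos + 1`.
#'
#' @param config a [sim_config()].
#' @return A list with class `meth_annotation`:
#'   \describe{
#'     \item{genes}{data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.}
#'     \item{exons}{data.frame `gene_id`, `exon_rank` (1 = 5'-most),
#'       `chrom`, `start`, `end`, `strand`.}
#'     \item{cpg}{data.frame `chrom`, `pos` of every CpG.}
#'     \item{chrom_lengths}{named integer vector.}
#'   }
#' @export
#' @examples
#' ann <- generate_annotation(sim_config(seed = 1, n_genes = 10,
#'                                       n_chromosomes = 1))
#' nrow(ann$genes)
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1001L)
  L <- config$chrom_length
  n_chr <- config$n_chromosomes
  chroms <- sprintf("chr%d", seq_len(n_chr))
  gene_len <- config$exons_per_gene * config$exon_length +
    (config$exons_per_gene - 1L) * config$intron_length

  # round-robin gene allocation across chromosomes
  genes_per_chr <- tabulate(rep(seq_len(n_chr), length.out = config$n_genes),
                            nbins = n_chr)
  gene_rows <- list()
  exon_rows <- list()
  gid <- 0L
  for (ci in seq_len(n_chr)) {
    k <- genes_per_chr[ci]
    if (k == 0L) next
    slot <- L %/% k
    if (gene_len + 2L > slot) {
      stop(sprintf(
        "cannot place %d genes of %d bp on a %d bp chromosome", k,
        gene_len, L))
    }
    offsets <- floor(runif(k, 0, slot - gene_len - 1L))
    starts <- (seq_len(k) - 1L) * slot + offsets
    strands <- sample(c("+", "-"), k, replace = TRUE)
    for (i in seq_len(k)) {
      gid <- gid + 1L
      id <- sprintf("gene_%05d", gid)
      gstart <- starts[i]
      ex_starts <- gstart +
        (seq_len(config$exons_per_gene) - 1L) *
          (config$exon_length + config$intron_length)
      ex_ends <- ex_starts + config$exon_length
      rank <- seq_len(config$exons_per_gene)
      if (strands[i] == "-") rank <- rev(rank)  # rank 1 = 5'-most
      gene_rows[[gid]] <- data.frame(
        gene_id = id, chrom = chroms[ci], start = gstart,
        end = gstart + gene_len, strand = strands[i],
        stringsAsFactors = FALSE)
      exon_rows[[gid]] <- data.frame(
        gene_id = id, exon_rank = rank, chrom = chroms[ci],
        start = ex_starts, end = ex_ends, strand = strands[i],
        stringsAsFactors = FALSE)
    }
  }
  genes <- if (gid > 0L) do.call(rbind, gene_rows) else
    data.frame(gene_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  exons <- if (gid > 0L) do.call(rbind, exon_rows) else
    data.frame(gene_id = character(), exon_rank = integer(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  if (gid > 0L) {
    exons <- exons[order(exons$chrom, exons$start), , drop = FALSE]
    rownames(exons) <- NULL
  }

  cpg <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- which(runif(L - 1L) < config$cpg_density) - 1L
    if (length(pos) > 1L) {
      # forbid overlapping dinucleotides: keep the first of adjacent pairs
      keep <- c(TRUE, diff(pos) > 1L)
      pos <- pos[keep]
    }
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  rownames(cpg) <- NULL
  structure(
    list(genes = genes, exons = exons, cpg = cpg,
         chrom_lengths = setNames(rep(L, n_chr), chroms)),
    class = "meth_annotation")
}

#' Generate per-CpG methylation ground truth with planted DMRs
#'
#' Assigns each CpG a true methylation probability per group.  CpGs outside
#' methylated genes are unmethylated (`pi = 0`); within a methylated gene,
#' exon-rank r CpGs sit at `methylated_level * five_prime_decay^(r-1)` and
#' intron CpGs at half the level of the preceding exon, reproducing the
#' 5'-exon bias of mosaic insect methylomes.  `n_true_dmrs` window-aligned
#' 200 bp regions inside methylated genes (with >= 2 CpGs) receive a planted
#' group difference of exactly `dmr_delta` at every CpG; a fraction
#' `dmr_hyper_care_frac` of them are hypermethylated in the "care" group.
#'
#' @param annotation a `meth_annotation` from [generate_annotation()].
#' @param config the same [sim_config()].
#' @param window_size planted-DMR window size in bp (default 200, matching
#'   the DMR caller's tiling).
#' @return A list of class `meth_truth`:
#'   \describe{
#'     \item{cpg}{the annotation's CpG table with `pi_care`, `pi_nocare`.}
#'     \item{dmr_windows}{data.frame `chrom`, `start`, `end`, `delta`
#'       (signed, care minus nocare), `gene_id`.}
#'     \item{methylated_genes}{character vector of truly methylated genes.}
#'     \item{gene_pi}{named per-gene mean true methylation (group average),
#'       0 for genes without CpGs.}
#'   }
#' @export
generate_truth <- function(annotation, config, window_size = 200L) {
  stopifnot(inherits(annotation, "meth_annotation"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 2002L)
  cpg <- annotation$cpg
  genes <- annotation$genes
  n_meth <- round(config$frac_methylated_genes * nrow(genes))
  meth_genes <- if (n_meth > 0L) sort(sample(genes$gene_id, n_meth)) else
    character()

  pi_base <- numeric(nrow(cpg))
  if (nrow(cpg) > 0L && length(meth_genes) > 0L) {
    cpg_gr <- GenomicRanges::GRanges(cpg$chrom,
                                     IRanges::IRanges(cpg$pos + 1L,
                                                      width = 1L))
    mg <- genes[genes$gene_id %in% meth_genes, , drop = FALSE]
    mex <- annotation$exons[annotation$exons$gene_id %in% meth_genes, ,
                            drop = FALSE]
    gene_gr <- GenomicRanges::GRanges(mg$chrom,
                                      IRanges::IRanges(mg$start + 1L,
                                                       mg$end))
    ex_gr <- GenomicRanges::GRanges(mex$chrom,
                                    IRanges::IRanges(mex$start + 1L,
                                                     mex$end))
    level_of_rank <- function(r) {
      config$methylated_level * config$five_prime_decay^(r - 1)
    }
    # exonic CpGs: level of their exon's rank
    hits <- GenomicRanges::findOverlaps(cpg_gr, ex_gr, select = "first")
    in_ex <- !is.na(hits)
    pi_base[in_ex] <- level_of_rank(mex$exon_rank[hits[in_ex]])
    # intragenic non-exonic CpGs: half the preceding (5'-ward) exon's level
    ghit <- GenomicRanges::findOverlaps(cpg_gr, gene_gr, select = "first")
    in_intron <- !is.na(ghit) & !in_ex
    if (any(in_intron)) {
      idx <- which(in_intron)
      g <- ghit[idx]
      # preceding exon in transcription order; exon blocks are laid out
      # left-to-right, so the flanking exon index depends on strand
      rank_prev <- vapply(seq_along(idx), function(j) {
        gene <- mg$gene_id[g[j]]
        ex <- mex[mex$gene_id == gene, , drop = FALSE]
        p <- cpg$pos[idx[j]]
        if (ex$strand[1L] == "+") {
          ex$exon_rank[max(which(ex$start <= p))]
        } else {
          ex$exon_rank[min(which(ex$end > p + 1L)) ]
        }
      }, numeric(1))
      pi_base[idx] <- 0.5 * level_of_rank(rank_prev)
    }
  }
  pi_care <- pi_base
  pi_nocare <- pi_base

  # plant DMRs: tile methylated-gene spans into window_size-aligned windows
  dmr_windows <- data.frame(chrom = character(), start = integer(),
                            end = integer(), delta = numeric(),
                            gene_id = character(), stringsAsFactors = FALSE)
  if (config$n_true_dmrs > 0L && length(meth_genes) > 0L) {
    mg <- genes[genes$gene_id %in% meth_genes, , drop = FALSE]
    cand <- do.call(rbind, lapply(seq_len(nrow(mg)), function(i) {
      w0 <- ceiling(mg$start[i] / window_size) * window_size
      ws <- seq(w0, by = window_size,
                length.out = max(0L, (mg$end[i] - w0) %/% window_size))
      if (length(ws) == 0L) return(NULL)
      data.frame(chrom = mg$chrom[i], start = as.integer(ws),
                 end = as.integer(ws + window_size), gene_id = mg$gene_id[i],
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(cand) && nrow(cand) > 0L) {
      ncpg <- vapply(seq_len(nrow(cand)), function(i) {
        sum(cpg$chrom == cand$chrom[i] & cpg$pos >= cand$start[i] &
              cpg$pos < cand$end[i])
      }, integer(1))
      cand <- cand[ncpg >= 2L, , drop = FALSE]
    }
    if (is.null(cand) || nrow(cand) < config$n_true_dmrs) {
      stop("not enough eligible windows inside methylated genes to plant ",
           config$n_true_dmrs, " DMRs; enlarge the genome or reduce ",
           "'n_true_dmrs'")
    }
    pick <- cand[sort(sample.int(nrow(cand), config$n_true_dmrs)), ,
                 drop = FALSE]
    n_hyper <- round(config$dmr_hyper_care_frac * nrow(pick))
    hyper_care <- rep(FALSE, nrow(pick))
    if (n_hyper > 0L) hyper_care[sample.int(nrow(pick), n_hyper)] <- TRUE
    pick$delta <- ifelse(hyper_care, config$dmr_delta, -config$dmr_delta)
    for (i in seq_len(nrow(pick))) {
      in_w <- cpg$chrom == pick$chrom[i] & cpg$pos >= pick$start[i] &
        cpg$pos < pick$end[i]
      base <- pmin(pi_base[in_w], 1 - config$dmr_delta)
      if (pick$delta[i] > 0) {
        pi_nocare[in_w] <- base
        pi_care[in_w] <- base + config$dmr_delta
      } else {
        pi_care[in_w] <- base
        pi_nocare[in_w] <- base + config$dmr_delta
      }
    }
    dmr_windows <- pick[, c("chrom", "start", "end", "delta", "gene_id")]
    rownames(dmr_windows) <- NULL
  }

  cpg$pi_care <- pi_care
  cpg$pi_nocare <- pi_nocare

  gene_pi <- setNames(rep(0, nrow(genes)), genes$gene_id)
  if (nrow(cpg) > 0L && nrow(genes) > 0L) {
    cpg_gr <- GenomicRanges::GRanges(cpg$chrom,
                                     IRanges::IRanges(cpg$pos + 1L,
                                                      width = 1L))
    all_gr <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start + 1L,
                                                      genes$end))
    h <- GenomicRanges::findOverlaps(cpg_gr, all_gr)
    if (length(h) > 0L) {
      avg <- (cpg$pi_care + cpg$pi_nocare)[S4Vectors::queryHits(h)] / 2
      means <- tapply(avg, genes$gene_id[S4Vectors::subjectHits(h)], mean)
      gene_pi[names(means)] <- as.numeric(means)
    }
  }
  structure(
    list(cpg = cpg, dmr_windows = dmr_windows,
         methylated_genes = meth_genes, gene_pi = gene_pi),
    class = "meth_truth")
}
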