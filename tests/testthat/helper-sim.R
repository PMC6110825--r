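# shared fixtures for the test suite; everything is generated in code

# a genome small enough for repeated simulation in loops
small_config <- function(seed = 1L, n_true_dmrs = 50L, ...) {
  sim_config(seed = seed, n_chromosomes = 4L, chrom_length = 5e4,
             n_genes = 100L, n_true_dmrs = n_true_dmrs, ...)
}

# split a simulated methylome list into genome and lambda parts
split_lambda <- function(methylomes) {
  list(genome = lapply(methylomes, function(d) d[d$chrom != "lambda", ]),
       lambda = lapply(methylomes, function(d) d[d$chrom == "lambda", ]))
}

# merged genome counts per sample
merged_counts <- function(methylomes) {
  lapply(split_lambda(methylomes)$genome, merge_strands)
}

# window key for comparing called vs planted DMR windows
window_key <- function(d) paste(d$chrom, d$start, sep = ":")

# a window_matrix built directly from per-sample window counts, bypassing
# the genome machinery (for calibration tests that need many windows)
make_window_matrix <- function(M, N, chrom = "chr1") {
  nw <- nrow(M)
  if (is.null(colnames(M))) colnames(M) <- colnames(N)
  if (is.null(colnames(N))) colnames(N) <- colnames(M)
  structure(list(
    windows = data.frame(chrom = chrom,
                         start = (seq_len(nw) - 1L) * 200L,
                         end = seq_len(nw) * 200L,
                         cpg_count = 2L, stringsAsFactors = FALSE),
    M = M, N = N), class = "window_matrix")
}

# minimal annotation object for gene-set generation tests
fake_annotation <- function(n_genes) {
  genes <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n_genes)),
    chrom = rep("chr1", n_genes),
    start = (seq_len(n_genes) - 1L) * 1000L,
    end = (seq_len(n_genes) - 1L) * 1000L + 500L,
    strand = rep("+", n_genes),
    stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = genes$gene_id,
                      exon_rank = rep(1L, n_genes),
                      chrom = genes$chrom, start = genes$start,
                      end = genes$end, strand = genes$strand,
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons,
                 chrom_lengths = c(chr1 = n_genes * 1000L)),
            class = "meth_annotation")
}

# 2x2 odds ratio between two member vectors over a universe
observed_odds_ratio <- function(a, b, universe) {
  ia <- universe %in% a
  ib <- universe %in% b
  t11 <- sum(ia & ib); t10 <- sum(ia & !ib)
  t01 <- sum(!ia & ib); t00 <- sum(!ia & !ib)
  (t11 * t00) / (t10 * t01)
}
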