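#' Read and write Bismark-style cytosine reports
#'
#' The on-disk dialect is a headerless TSV with columns chrom, 1-based
#' position, strand (`+`/`-`), methylated count, unmethylated count and
#' context; only `CpG` context rows are kept on reading.  In memory,
#' positions are 0-based and counts are stored as methylated `m` and total
#' `n = m + u`.
#'
#' @param path file path.
#' @param df a stranded or merged count data.frame with columns `chrom`,
#'   `pos`, `strand`, `m`, `n`.
#' @return `read_cytosine_report()` returns a data.frame with columns
#'   `chrom`, `pos` (0-based), `strand`, `m`, `n`.
#' @export
read_cytosine_report <- function(path) {
  cols <- c(chrom = "character", pos = "integer", strand = "character",
            count_m = "integer", count_u = "integer", context = "character")
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, col.names = names(cols),
               colClasses = unname(cols), quote = "",
               stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) return(NULL)
      stop("malformed cytosine report '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), m = integer(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  bad <- which(is.na(df$pos) | is.na(df$count_m) | is.na(df$count_u) |
                 df$count_m < 0 | df$count_u < 0 |
                 !df$strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop(sprintf("malformed cytosine report '%s': invalid row at line %d",
                 path, bad[1L]), call. = FALSE)
  }
  df <- df[df$context == "CpG", , drop = FALSE]
  out <- data.frame(chrom = df$chrom, pos = df$pos - 1L,
                    strand = df$strand, m = df$count_m,
                    n = df$count_m + df$count_u, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname read_cytosine_report
#' @export
write_cytosine_report <- function(df, path) {
  stopifnot(all(c("chrom", "pos", "strand", "m", "n") %in% names(df)))
  if (any(df$m > df$n)) stop("methylated count exceeds total count")
  out <- data.frame(chrom = df$chrom, pos = df$pos + 1L,
                    strand = df$strand, count_m = df$m,
                    count_u = df$n - df$m, context = "CpG")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write and read gene models as GFF3
#'
#' Gene and exon features are exported through `rtracklayer`, converting
#' between the package's 0-based half-open data.frames and GFF3's 1-based
#' closed coordinates.
#'
#' @param annotation a `meth_annotation` (or any list with `genes` and
#'   `exons` data.frames in the same layout).
#' @param path GFF3 file path.
#' @return `read_gene_models()` returns a list with `genes` and `exons`
#'   data.frames (0-based half-open).
#' @export
write_gene_models <- function(annotation, path) {
  genes <- annotation$genes
  exons <- annotation$exons
  gr_g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand, type = "gene", ID = genes$gene_id)
  gr_e <- GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(exons$start + 1L, exons$end),
    strand = exons$strand, type = "exon",
    ID = sprintf("%s.exon%d", exons$gene_id, exons$exon_rank),
    Parent = exons$gene_id)
  rtracklayer::export(c(gr_g, gr_e), path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  g <- df[df$type == "gene", , drop = FALSE]
  e <- df[df$type == "exon", , drop = FALSE]
  parent <- vapply(e$Parent, function(p) as.character(p)[1L], character(1))
  rank <- as.integer(sub(".*\\.exon", "", e$ID))
  genes <- data.frame(gene_id = as.character(g$ID),
                      chrom = as.character(g$seqnames),
                      start = g$start - 1L, end = g$end,
                      strand = as.character(g$strand),
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = parent, exon_rank = rank,
                      chrom = as.character(e$seqnames),
                      start = e$start - 1L, end = e$end,
                      strand = as.character(e$strand),
                      stringsAsFactors = FALSE)
  list(genes = genes, exons = exons)
}

#' Read and write gene-set files and splice-event BED
#'
#' Gene sets are stored one identifier per line; splice events as BED6
#' (0-based half-open) with the gene identifier in the name column and the
#' event type in the score-adjacent strand-free columns.
#'
#' @param ids character vector of gene identifiers.
#' @param path file path.
#' @param events data.frame `gene_id`, `chrom`, `start`, `end`,
#'   `event_type`.
#' @return Readers return the stored object.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname write_gene_list
#' @export
write_splice_events <- function(events, path) {
  bed <- data.frame(chrom = events$chrom, start = events$start,
                    end = events$end, name = events$gene_id,
                    score = match(events$event_type, splice_event_types()),
                    strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_splice_events <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "name", "score",
                                  "strand"),
                    stringsAsFactors = FALSE)
  data.frame(gene_id = bed$name, chrom = bed$chrom, start = bed$start,
             end = bed$end, event_type = splice_event_types()[bed$score],
             stringsAsFactors = FALSE)
}

splice_event_types <- function() {
  c("differential-exon-usage", "skipped-exon", "retained-intron",
    "alt-5p", "alt-3p", "mutually-exclusive")
}

#' Write DMR calls as BED6 plus an extended TSV
#'
#' @param dmrs a `dmr_result` data.frame from [call_dmrs()].
#' @param bed_path,tsv_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_dmrs <- function(dmrs, bed_path = NULL, tsv_path = NULL) {
  sig <- dmrs[dmrs$is_dmr, , drop = FALSE]
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = sig$chrom, start = sig$start, end = sig$end,
                      name = sprintf("DMR_%04d", seq_len(nrow(sig))),
                      score = round(-log10(pmax(sig$q_value, 1e-300)), 3),
                      strand = ".")
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    out <- dmrs
    if (!is.null(out$gene_ids)) {
      out$gene_ids <- vapply(out$gene_ids, paste, character(1),
                             collapse = ",")
    }
    write.table(out, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(bed_path, tsv_path))
}
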