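#' Construct a gene set over an explicit universe
#'
#' @param name set label.
#' @param members character vector of member gene identifiers.
#' @param universe character vector of the tested gene universe; members
#'   must be a subset.  Universes are always explicit — enrichment tests
#'   over an expression-filtered universe and over the full annotation are
#'   different questions and are never inferred silently.
#' @return Object of class `gene_set`.
#' @export
gene_set <- function(name, members, universe) {
  members <- unique(as.character(members))
  universe <- unique(as.character(universe))
  if (!all(members %in% universe)) {
    stop("gene set '", name, "' has members outside its universe")
  }
  structure(list(name = name, members = members, universe = universe),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set '%s': %d of %d genes\n", x$name,
              length(x$members), length(x$universe)))
  invisible(x)
}

#' Exclusive intersections of gene sets (UpSet-style counts)
#'
#' For every combination of membership across the supplied sets, counts
#' the genes belonging to exactly that combination.  Counts are mutually
#' exclusive and sum to the size of the union of all members.
#'
#' @param sets list of [gene_set()] objects on a shared universe.
#' @return data.frame with one logical column per set plus `count`,
#'   restricted to non-empty combinations and sorted by decreasing count.
#' @export
intersect_sets <- function(sets) {
  if (length(sets) < 2L) stop("need at least two sets")
  uni <- sets[[1L]]$universe
  for (s in sets[-1L]) {
    if (!setequal(s$universe, uni)) {
      stop("sets must share a common universe")
    }
  }
  nm <- vapply(sets, `[[`, character(1), "name")
  union_ids <- unique(unlist(lapply(sets, `[[`, "members")))
  if (length(union_ids) == 0L) {
    out <- as.data.frame(matrix(logical(), 0L, length(sets),
                                dimnames = list(NULL, nm)))
    out$count <- integer()
    return(out)
  }
  memb <- vapply(sets, function(s) union_ids %in% s$members,
                 logical(length(union_ids)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = 1L)
  key <- apply(memb + 0L, 1L, paste, collapse = "")
  cnt <- table(key)
  pat <- do.call(rbind, lapply(names(cnt), function(k) {
    as.logical(as.integer(strsplit(k, "")[[1L]]))
  }))
  out <- as.data.frame(pat)
  names(out) <- nm
  out$count <- as.integer(cnt)
  out <- out[order(-out$count), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chi-square test of overlap between two gene sets
#'
#' Builds the 2x2 in/out-of-set table over the shared universe and applies
#' Pearson's chi-square test (continuity correction off by default).  The
#' odds ratio uses Haldane's 0.5 correction when any cell is zero.  A
#' degenerate margin (a set empty or equal to the universe) yields
#' statistic 0 and `p = 1` with a warning, since no association is
#' estimable.
#'
#' @param a,b [gene_set()] objects on the same universe.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return Object of class `overlap_test`: `table` (2x2), `statistic`,
#'   `p_value`, `odds_ratio`, `set_a`, `set_b`.
#' @export
overlap_chisq <- function(a, b, correct = FALSE) {
  if (!setequal(a$universe, b$universe)) {
    stop("sets must share a common universe")
  }
  uni <- a$universe
  if (length(uni) == 0L) stop("empty universe")
  in_a <- uni %in% a$members
  in_b <- uni %in% b$members
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                nrow = 2L,
                dimnames = list(c("in_b", "out_b"), c("in_a", "out_a")))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    warning("degenerate margin: one set is empty or spans the universe")
    stat <- 0
    p <- 1
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    stat <- unname(ct$statistic)
    p <- ct$p.value
  }
  t2 <- tab + if (any(tab == 0L)) 0.5 else 0
  or <- (t2[1L, 1L] * t2[2L, 2L]) / (t2[1L, 2L] * t2[2L, 1L])
  structure(
    list(table = tab, statistic = stat, p_value = p, odds_ratio = or,
         set_a = a$name, set_b = b$name),
    class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Overlap of '%s' and '%s' (universe %d):\n", x$set_a,
              x$set_b, sum(x$table)))
  cat(sprintf("  X-squared = %.4g, p = %.4g, odds ratio = %.3g\n",
              x$statistic, x$p_value, x$odds_ratio))
  invisible(x)
}

#' Correlate gene-body methylation with expression
#'
#' Spearman rank correlation (mid-rank ties, large-sample p-value)
#' between per-gene methylation levels averaged across samples and
#' per-gene expression values, over the genes present in both tables;
#' genes with undefined methylation are excluded.
#'
#' @param gene_meth named numeric vector of gene methylation levels (e.g.
#'   `rowMeans(gene_methylation_levels(...)$levels, na.rm = TRUE)`).
#' @param expression named numeric vector of expression values.
#' @return List: `rho`, `p_value`, `n` genes used.
#' @export
methylation_expression_correlation <- function(gene_meth, expression) {
  common <- intersect(names(gene_meth), names(expression))
  x <- gene_meth[common]
  y <- expression[common]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) stop("fewer than 3 genes with paired values")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("constant vector: correlation undefined")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Spatial overlap between DMRs and splice events
#'
#' Reports every (DMR, splice event) pair whose intervals share at least
#' one bp (half-open semantics: abutting intervals do not overlap), plus
#' a per-gene concordance summary of genes carrying both a DMR and a
#' splice event and the subset where the two directly overlap.
#'
#' @param dmrs data.frame of DMR windows (`chrom`, `start`, `end`;
#'   0-based half-open).  If an `is_dmr` column is present only
#'   significant windows are used.  A `gene_ids` list-column (from
#'   [annotate_dmrs()]) feeds the per-gene summary.
#' @param events splice-event data.frame (`gene_id`, `chrom`, `start`,
#'   `end`, `event_type`).
#' @return List: `pairs` (data.frame `dmr_index`, `event_index`,
#'   `overlap_bp`, `gene_id`, `event_type`) and `summary`
#'   (`genes_with_both`, `genes_with_direct_overlap`).
#' @export
spatial_overlap <- function(dmrs, events) {
  if (!is.null(dmrs$is_dmr)) dmrs <- dmrs[dmrs$is_dmr, , drop = FALSE]
  empty_pairs <- data.frame(dmr_index = integer(), event_index = integer(),
                            overlap_bp = integer(), gene_id = character(),
                            event_type = character(),
                            stringsAsFactors = FALSE)
  dmr_genes <- if (!is.null(dmrs$gene_ids)) {
    unique(unlist(dmrs$gene_ids))
  } else character()
  both <- intersect(dmr_genes, unique(events$gene_id))
  if (nrow(dmrs) == 0L || nrow(events) == 0L) {
    return(list(pairs = empty_pairs,
                summary = list(genes_with_both = sort(both),
                               genes_with_direct_overlap = character())))
  }
  d_gr <- GenomicRanges::GRanges(dmrs$chrom,
                                 IRanges::IRanges(dmrs$start + 1L,
                                                  dmrs$end))
  e_gr <- GenomicRanges::GRanges(events$chrom,
                                 IRanges::IRanges(events$start + 1L,
                                                  events$end))
  h <- GenomicRanges::findOverlaps(d_gr, e_gr, minoverlap = 1L)
  qi <- S4Vectors::queryHits(h)
  si <- S4Vectors::subjectHits(h)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(d_gr[qi], e_gr[si]))
  pairs <- data.frame(dmr_index = qi, event_index = si,
                      overlap_bp = as.integer(ov),
                      gene_id = events$gene_id[si],
                      event_type = events$event_type[si],
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       summary = list(
         genes_with_both = sort(both),
         genes_with_direct_overlap = sort(unique(pairs$gene_id))))
}
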