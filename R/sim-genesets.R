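#' Sample an overlap count from Fisher's noncentral hypergeometric
#'
#' Number of successes when `nB` items are drawn from a universe of `N`
#' containing `nA` marked items, with membership odds ratio `psi` between
#' the two sets.  `psi = 1` reduces to the central hypergeometric
#' (independent sets); the pmf is computed directly in log space.
#'
#' @param N universe size.
#' @param nA,nB marginal set sizes.
#' @param psi odds ratio (>= 0).
#' @return A single integer overlap count.
#' @keywords internal
rnoncentral_overlap <- function(N, nA, nB, psi) {
  amin <- max(0L, nB - (N - nA))
  amax <- min(nA, nB)
  if (amin == amax) return(amin)
  a <- amin:amax
  lw <- lchoose(nA, a) + lchoose(N - nA, nB - a)
  lw <- lw + if (psi > 0) a * log(psi) else ifelse(a == amin, 0, -Inf)
  w <- exp(lw - max(lw))
  sample(a, 1L, prob = w)
}

#' Generate expression/splicing/selection gene sets and splice events
#'
#' Builds three gene sets over the annotated gene universe — differentially
#' expressed (DE), alternatively spliced (AS) and positively selected —
#' whose pairwise overlaps follow `overlap_odds_ratio` in expectation
#' (overlap counts drawn from Fisher's noncentral hypergeometric).  The AS
#' set is the union of two largely mutually exclusive subsets mirroring
#' exon-usage versus event-based splicing calls, and each AS gene receives
#' one splice-event interval lying inside one of its exons.
#'
#' @param annotation a `meth_annotation`.
#' @param config the [sim_config()]; set sizes are
#'   `round(*_frac * n_genes)`.
#' @return List with `de`, `as_genes`, `sel` ([gene_set()] objects on the
#'   annotated universe), `as_deu`/`as_events` (the two AS subsets) and
#'   `splice_events`, a data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `event_type`) with 0-based half-open intervals.
#' @export
generate_gene_sets <- function(annotation, config) {
  stopifnot(inherits(annotation, "meth_annotation"))
  if (config$overlap_odds_ratio < 0) {
    stop("'overlap_odds_ratio' must be non-negative")
  }
  set.seed(config$seed + 4004L)
  universe <- annotation$genes$gene_id
  N <- length(universe)
  if (N == 0L) stop("gene universe is empty")
  n_de <- round(config$de_frac * N)
  n_as <- round(config$as_frac * N)
  n_sel <- round(config$sel_frac * N)
  psi <- config$overlap_odds_ratio

  de <- if (n_de > 0L) sort(sample(universe, n_de)) else character()
  draw_vs <- function(ref, k) {
    if (k == 0L) return(character())
    a <- rnoncentral_overlap(N, length(ref), k, psi)
    inside <- if (a > 0L) sample(ref, a) else character()
    rest <- setdiff(universe, ref)
    outside <- if (k - a > 0L) sample(rest, k - a) else character()
    sort(c(inside, outside))
  }
  as_ids <- draw_vs(de, n_as)
  sel_ids <- draw_vs(de, n_sel)

  # split AS genes into largely mutually exclusive exon-usage vs
  # event-based subsets
  n_deu <- round(0.6 * length(as_ids))
  deu_ids <- if (n_deu > 0L) sort(sample(as_ids, n_deu)) else character()
  ev_ids <- setdiff(as_ids, deu_ids)

  events <- NULL
  if (length(as_ids) > 0L) {
    ex <- annotation$exons
    ev_types <- c("skipped-exon", "retained-intron", "alt-5p", "alt-3p",
                  "mutually-exclusive")
    events <- do.call(rbind, lapply(as_ids, function(g) {
      gx <- ex[ex$gene_id == g, , drop = FALSE]
      if (nrow(gx) == 0L) return(NULL)
      e <- gx[sample.int(nrow(gx), 1L), , drop = FALSE]
      w <- e$end - e$start
      s <- e$start + w %/% 4L
      data.frame(gene_id = g, chrom = e$chrom, start = s,
                 end = s + max(1L, w %/% 2L),
                 event_type = if (g %in% deu_ids) "differential-exon-usage"
                 else sample(ev_types, 1L),
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(events)) {
    events <- data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         event_type = character(), stringsAsFactors = FALSE)
  }
  list(
    de = gene_set("de", de, universe),
    as_genes = gene_set("as", as_ids, universe),
    sel = gene_set("sel", sel_ids, universe),
    as_deu = gene_set("as_deu", deu_ids, universe),
    as_events = gene_set("as_events", ev_ids, universe),
    splice_events = events)
}

#' Generate per-gene expression values with a target methylation correlation
#'
#' Produces one expression value per gene such that the Spearman rank
#' correlation between true gene-body methylation (`truth$gene_pi`, heavy
#' with ties at 0) and expression approximates `expression_rho`.
#' Expression is a monotone transform of the methylation mid-ranks plus
#' Gaussian noise whose scale is solved by bisection against the realized
#' Spearman coefficient on the generated vector itself; `rho = 1` returns
#' an exact monotone copy and `rho = 0` pure noise.  Targets above the
#' tie-limited maximum fall back to the monotone copy.
#'
#' @param truth a `meth_truth`.
#' @param config the [sim_config()].
#' @return Named numeric vector of expression values (one per gene).
#' @export
generate_expression <- function(truth, config) {
  stopifnot(inherits(truth, "meth_truth"))
  rho <- config$expression_rho
  if (abs(rho) > 1) stop("'expression_rho' must lie in [-1, 1]")
  g <- truth$gene_pi
  n <- length(g)
  set.seed(config$seed + 5005L)
  if (n == 0L) return(setNames(numeric(), character()))
  if (rho == 0) return(setNames(rnorm(n), names(g)))
  r <- rank(g, ties.method = "average")
  signal <- sign(rho) * r
  if (abs(rho) == 1) return(setNames(signal, names(g)))
  e <- rnorm(n) * stats::sd(r)
  realized <- function(sigma) {
    suppressWarnings(cor(g, signal + sigma * e, method = "spearman"))
  }
  lo <- 0; hi <- 1
  while (abs(realized(hi)) > abs(rho) && hi < 1e6) hi <- hi * 2
  for (i in seq_len(60L)) {
    mid <- (lo + hi) / 2
    if (abs(realized(mid)) > abs(rho)) lo <- mid else hi <- mid
  }
  sigma <- (lo + hi) / 2
  # ties cap the achievable |rho| for any positive noise; if even
  # near-zero noise undershoots the target, return the monotone copy
  if (abs(realized(sigma)) < abs(rho) - 0.02) sigma <- 0
  setNames(signal + sigma * e, names(g))
}
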