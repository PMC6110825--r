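#' Enumerate balanced non-original sample relabelings
#'
#' Lists every distinct way of re-partitioning the samples into two equal
#' groups, collapsing complementary label swaps to one canonical partition
#' and excluding the original assignment.  For `g` samples per group this
#' yields `choose(2g, g) / 2 - 1` relabelings — nine for the 3-vs-3
#' design.
#'
#' @param groups named character vector: the original sample-to-group
#'   assignment (exactly two labels, equal sizes).
#' @return List of named character vectors (same names and labels as
#'   `groups`), in deterministic lexicographic order, with attribute
#'   `canonical_key` on each element.
#' @export
#' @examples
#' g <- setNames(rep(c("care", "nocare"), each = 3),
#'               c("c1", "c2", "c3", "n1", "n2", "n3"))
#' length(enumerate_relabelings(g))  # 9
enumerate_relabelings <- function(groups) {
  labs <- unique(groups)
  if (length(labs) != 2L) stop("exactly two groups required")
  sizes <- table(factor(groups, levels = labs))
  if (sizes[1L] != sizes[2L]) {
    stop("unbalanced designs are not supported by the relabeling scheme")
  }
  ids <- names(groups)
  g <- as.integer(sizes[1L])
  anchor <- ids[1L]
  others <- ids[-1L]
  combos <- if (g >= 2L) combn(others, g - 1L, simplify = FALSE) else
    list(character())
  orig_side <- sort(ids[groups == groups[[anchor]]])
  lab_anchor <- groups[[anchor]]
  lab_other <- setdiff(labs, lab_anchor)
  out <- list()
  for (cb in combos) {
    side <- sort(c(anchor, cb))
    if (identical(side, orig_side)) next
    asg <- setNames(ifelse(ids %in% side, lab_anchor, lab_other), ids)
    attr(asg, "canonical_key") <- paste(side, collapse = "|")
    out[[length(out) + 1L]] <- asg
  }
  keys <- vapply(out, attr, character(1), "canonical_key")
  out[order(keys)]
}

#' Per-region DMR probabilities under all relabelings
#'
#' Re-runs the complete window-level differential-methylation analysis —
#' group test, Benjamini-Hochberg correction within the relabeling's own
#' family, and the DMR thresholds — under every balanced relabeling, and
#' records for each region the number `k` of relabelings in which it is
#' called a DMR.  The probability `k / K` feeds the region-independent
#' null of the genome-wide DMR count.
#'
#' @param wm the observed `window_matrix` (same windows and filters as the
#'   real analysis).
#' @param relabelings list from [enumerate_relabelings()].
#' @param q_threshold,min_diff,backend,case DMR-calling parameters,
#'   matching the observed analysis.
#' @return data.frame of the windows with `k` and `prob`; attribute `K`
#'   holds the number of relabelings.
#' @export
region_dmr_probabilities <- function(wm, relabelings, q_threshold = 0.01,
                                     min_diff = 5, backend = "glm",
                                     case = NULL) {
  stopifnot(inherits(wm, "window_matrix"))
  K <- length(relabelings)
  if (K == 0L) stop("empty relabeling list")
  k <- integer(nrow(wm$windows))
  for (rl in relabelings) {
    d <- call_dmrs(test_windows(wm, rl, case = case, backend = backend),
                   q_threshold = q_threshold, min_diff = min_diff)
    k <- k + as.integer(d$is_dmr)
  }
  out <- wm$windows
  out$k <- k
  out$prob <- k / K
  attr(out, "K") <- K
  out
}

#' Monte-Carlo null distribution of the genome-wide DMR count
#'
#' Draws `n_iter` region-independent realizations: each region is a DMR
#' with its own probability, independently of all others, and the
#' genome-wide count is tallied per draw.
#'
#' @param table a region-probability data.frame (needs a `prob` column)
#'   or a bare numeric probability vector.
#' @param n_iter number of draws (default 50000).
#' @param seed integer seed stored with the draws.
#' @return Object of class `qam_null`: `draws`, `mean`, `max`,
#'   `quantiles` (2.5/25/50/75/97.5%), `seed`, `n_iter`.
#' @export
simulate_null <- function(table, n_iter = 50000L, seed = 1L) {
  probs <- if (is.data.frame(table)) table$prob else as.numeric(table)
  if (any(is.na(probs) | probs < 0 | probs > 1)) {
    stop("region probabilities must lie in [0, 1]")
  }
  if (n_iter < 1L) stop("'n_iter' must be at least 1")
  set.seed(seed)
  draws <- integer(n_iter)
  # regions sharing a probability contribute a binomial block per draw
  tab <- table(probs[probs > 0])
  for (i in seq_along(tab)) {
    p <- as.numeric(names(tab)[i])
    draws <- draws + rbinom(n_iter, size = as.integer(tab[i]), prob = p)
  }
  structure(
    list(draws = draws, mean = mean(draws), max = max(draws),
         quantiles = quantile(draws, c(0.025, 0.25, 0.5, 0.75, 0.975)),
         seed = seed, n_iter = as.integer(n_iter)),
    class = "qam_null")
}

#' @export
print.qam_null <- function(x, ...) {
  cat(sprintf(
    "QAM null: %d draws, mean %.1f, max %d (95%% central [%g, %g])\n",
    x$n_iter, x$mean, x$max, x$quantiles[[1L]], x$quantiles[[5L]]))
  invisible(x)
}

#' Exact Poisson-binomial pmf of the null DMR count
#'
#' The genome-wide count under the region-independent null is a sum of
#' independent non-identical Bernoulli variables, i.e. Poisson-binomial;
#' its pmf over `0..R` is computed by iterative convolution (dynamic
#' programming), giving a closed-form check on the Monte-Carlo null.
#'
#' @param table region-probability data.frame or numeric vector, as in
#'   [simulate_null()].
#' @return Numeric pmf named `"0"`..`"R"`; sums to 1 and has mean
#'   `sum(prob)` exactly.
#' @export
#' @examples
#' null_distribution_exact(c(0.5, 0.5))  # 0.25 0.50 0.25
null_distribution_exact <- function(table) {
  probs <- if (is.data.frame(table)) table$prob else as.numeric(table)
  if (any(is.na(probs) | probs < 0 | probs > 1)) {
    stop("region probabilities must lie in [0, 1]")
  }
  pmf <- 1
  for (p in probs) {
    pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  }
  names(pmf) <- as.character(seq_along(pmf) - 1L)
  pmf
}

#' Summarize the QAM comparison of observed vs null DMR counts
#'
#' Reports the null mean and maximum, an add-one empirical p-value
#' `(1 + #\{draws >= observed\}) / (1 + n_iter)` (ties with the observed
#' count are included in the tail), and the per-DMR chance percentage
#' `100 * null_mean / observed` — the expected fraction of the observed
#' DMRs attributable to chance.
#'
#' @param null a `qam_null`, a bare numeric vector of null draws, or an
#'   exact pmf from [null_distribution_exact()] (named numeric summing to
#'   1); for an exact pmf the tail probability replaces the add-one
#'   estimator.
#' @param observed_dmrs observed genome-wide DMR count.
#' @return Object of class `qam_summary`: `observed_dmrs`, `null_mean`,
#'   `null_max`, `empirical_p`, `per_dmr_chance_pct` (`NA` when
#'   `observed_dmrs` is 0).
#' @export
#' @examples
#' draws <- rep(c(38L, 39L), c(40000, 10000))  # mean 38.2
#' summarize_qam(draws, observed_dmrs = 206)
summarize_qam <- function(null, observed_dmrs) {
  if (observed_dmrs < 0) stop("'observed_dmrs' must be non-negative")
  if (inherits(null, "qam_null") || (is.numeric(null) && is.null(names(null)))) {
    draws <- if (inherits(null, "qam_null")) null$draws else null
    null_mean <- mean(draws)
    null_max <- max(draws)
    p <- (1 + sum(draws >= observed_dmrs)) / (1 + length(draws))
  } else if (is.numeric(null)) {
    # exact pmf
    support <- as.integer(names(null))
    null_mean <- sum(support * null)
    null_max <- max(support[null > 0])
    p <- sum(null[support >= observed_dmrs])
  } else {
    stop("'null' must be a qam_null, a draw vector, or an exact pmf")
  }
  structure(
    list(observed_dmrs = observed_dmrs, null_mean = null_mean,
         null_max = null_max, empirical_p = p,
         per_dmr_chance_pct = if (observed_dmrs > 0)
           100 * null_mean / observed_dmrs else NA_real_),
    class = "qam_summary")
}

#' @export
print.qam_summary <- function(x, ...) {
  cat(sprintf("Observed DMRs: %d\n", x$observed_dmrs))
  cat(sprintf("QAM null: mean %.1f, max %g, empirical p = %.3g\n",
              x$null_mean, x$null_max, x$empirical_p))
  if (!is.na(x$per_dmr_chance_pct)) {
    cat(sprintf("Chance a given DMR arose randomly: %.1f%%\n",
                x$per_dmr_chance_pct))
  }
  invisible(x)
}

#' Run the QAM validation for an analysed study
#'
#' Given the binned window matrix and the observed DMR result, enumerates
#' all balanced relabelings, computes per-region DMR probabilities, draws
#' the region-independent Monte-Carlo null and summarizes it against the
#' observed DMR count.
#'
#' @param binned the observed `window_matrix`.
#' @param groups original sample-to-group assignment.
#' @param observed_dmrs observed DMR count (e.g.
#'   `sum(result$dmrs$is_dmr)`).
#' @param n_iter,seed Monte-Carlo settings.
#' @param q_threshold,min_diff,backend,case DMR-calling parameters.
#' @return List: `relabelings`, `region_probs`, `null` (`qam_null`),
#'   `summary` (`qam_summary`).
#' @export
run_qam <- function(binned, groups, observed_dmrs, n_iter = 50000L,
                    seed = 1L, q_threshold = 0.01, min_diff = 5,
                    backend = "glm", case = NULL) {
  rel <- enumerate_relabelings(groups)
  tab <- region_dmr_probabilities(binned, rel, q_threshold = q_threshold,
                                  min_diff = min_diff, backend = backend,
                                  case = case)
  null <- simulate_null(tab, n_iter = n_iter, seed = seed)
  list(relabelings = rel, region_probs = tab, null = null,
       summary = summarize_qam(null, observed_dmrs))
}
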