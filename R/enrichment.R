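#' Signed -log10 p ranking metric
#'
#' Ranks genes by `-log10(p) * sign(log2FC)` in descending order; zero
#' p-values are clamped to the smallest positive double before the log.
#' Ties are broken by absolute log2FC (larger first) and then gene id.
#'
#' @param fit data.frame with `gene`, `logFC`, `p` for one coefficient
#'   (subset a long fit table first), or a `stimsig_fit` together with
#'   `coefficient`.
#' @param coefficient coefficient to rank when `fit` is a `stimsig_fit`.
#' @return named numeric vector of statistics, sorted in ranking order.
#' @export
rank_metric <- function(fit, coefficient = NULL) {
  tab <- if (inherits(fit, "stimsig_fit")) fit$table else fit
  if (!is.null(coefficient)) tab <- tab[tab$coefficient == coefficient, ]
  stopifnot(all(c("gene", "logFC", "p") %in% colnames(tab)))
  if (anyNA(tab$p) || anyNA(tab$logFC)) stop("missing p or logFC values")
  if (anyDuplicated(tab$gene)) stop("duplicate genes in the ranking input")
  p <- pmax(tab$p, .Machine$double.xmin)
  stat <- -log10(p) * sign(tab$logFC)
  ord <- order(-stat, -abs(tab$logFC), tab$gene)
  stats::setNames(stat[ord], tab$gene[ord])
}

#' Fisher's exact test for gene-set over-representation
#'
#' Two-sided exact test on the 2x2 overlap table of a query gene list
#' against one annotation set (or each set of a collection, with BH
#' adjustment across sets) within a gene universe. The two-sided p sums the
#' hypergeometric probabilities of all tables no more probable than the
#' observed one ([stats::fisher.test()]); the odds ratio is the sample
#' estimate `(a d) / (b c)`.
#'
#' @param query character vector of query genes (subset of `universe`).
#' @param sets one character vector, or a named list of them (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all eligible genes.
#' @return data.frame: `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `odds_ratio`, `p`, `padj`.
#' @export
fisher_enrichment <- function(query, sets, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) stop("query genes must lie in the universe")
  if (!is.list(sets)) sets <- list(set = sets)
  rows <- lapply(names(sets), function(nm) {
    ann <- unique(intersect(sets[[nm]], universe))
    a <- length(intersect(query, ann))
    b <- length(query) - a
    cc <- length(ann) - a
    d <- length(universe) - a - b - cc
    p <- min(1, stats::fisher.test(matrix(c(a, b, cc, d), 2),
                                   alternative = "two.sided")$p.value)
    data.frame(set = nm, overlap = a, set_size = length(ann),
               query_size = length(query), universe_size = length(universe),
               odds_ratio = (a * d) / (b * cc), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

## Weighted running-sum enrichment score from sorted hit positions.
## Hits add |stat|^exponent / sum over the set; misses subtract 1/(N - m).
running_sum_es <- function(pos, absw, N) {
  m <- length(pos)
  w <- if (sum(absw) > 0) absw / sum(absw) else rep(1 / m, m)
  cumw <- cumsum(w)
  miss <- (pos - seq_len(m)) / (N - m)
  top <- cumw - miss         # running sum right after each hit
  bot <- top - w             # right before each hit
  es_pos <- max(top)
  es_neg <- min(bot)
  if (es_pos >= -es_neg) es_pos else es_neg
}

#' Preranked running-sum enrichment with a permutation null
#'
#' Weighted Kolmogorov-Smirnov-style enrichment score on a ranked gene
#' list: set members add their normalized `|stat|^exponent`, non-members
#' subtract `1/(N - m)`, and the score is the signed maximum deviation of
#' the running sum. The null distribution permutes gene labels (random sets
#' of equal size); the p-value uses the matching-sign tail with a +1
#' pseudo-count, and the normalized score divides by the mean magnitude of
#' same-sign null scores.
#'
#' @param ranked named statistic vector from [rank_metric()] (re-sorted
#'   decreasingly if needed).
#' @param geneset character vector; its intersection with the list must be
#'   non-empty and not the whole list.
#' @param exponent weighting exponent (1 = weight by statistic; 0 = classic
#'   unweighted KS).
#' @param n_perm number of gene-label permutations.
#' @return one-row data.frame: `es`, `nes`, `p`, `overlap`, `set_size`,
#'   `universe_size`.
#' @export
preranked_es <- function(ranked, geneset, exponent = 1, n_perm = 1000) {
  if (is.unsorted(rev(ranked))) ranked <- sort(ranked, decreasing = TRUE)
  N <- length(ranked)
  hits <- which(names(ranked) %in% geneset)
  m <- length(hits)
  if (m == 0) stop("gene set has no member in the ranked list")
  if (m == N) stop("gene set covers the whole ranked list")
  absr <- abs(ranked)^exponent
  es <- running_sum_es(hits, absr[hits], N)
  null_es <- vapply(seq_len(n_perm), function(i) {
    pos <- sort.int(sample.int(N, m))
    running_sum_es(pos, absr[pos], N)
  }, 0)
  if (es >= 0) {
    p <- (1 + sum(null_es >= es)) / (1 + sum(null_es >= 0))
    denom <- mean(null_es[null_es >= 0])
  } else {
    p <- (1 + sum(null_es <= es)) / (1 + sum(null_es < 0))
    denom <- -mean(null_es[null_es < 0])
  }
  nes <- if (is.finite(denom) && denom > 0) es / denom else NA_real_
  data.frame(es = es, nes = nes, p = min(p, 1), overlap = m, set_size = m,
             universe_size = N)
}

#' CERNO rank test
#'
#' Fisher-combination statistic over the ranks of the set members in the
#' ranked list: `-2 * sum(log(rank_i / N))`, compared against a chi-squared
#' distribution with `2 * m` degrees of freedom (upper tail). With a
#' collection, BH adjustment is applied across sets.
#'
#' @param ranked named statistic vector from [rank_metric()].
#' @param sets one character vector or a named list of them.
#' @return data.frame: `set`, `statistic`, `df`, `p`, `padj`, `overlap`,
#'   `universe_size`.
#' @export
cerno_test <- function(ranked, sets) {
  if (is.unsorted(rev(ranked))) ranked <- sort(ranked, decreasing = TRUE)
  N <- length(ranked)
  if (!is.list(sets)) sets <- list(set = sets)
  rows <- lapply(names(sets), function(nm) {
    r <- which(names(ranked) %in% sets[[nm]])
    if (!length(r)) stop("gene set '", nm, "' has no member in the ranked list")
    stat <- -2 * sum(log(r / N))
    df <- 2 * length(r)
    data.frame(set = nm, statistic = stat, df = df,
               p = stats::pchisq(stat, df, lower.tail = FALSE),
               overlap = length(r), universe_size = N,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Random-sampling overlap test with a normalized enrichment score
#'
#' Compares the observed overlap of a query gene set with a reference set
#' against overlaps of uniformly drawn query-sized sets from the universe
#' (the overlap of such a draw is hypergeometric, and is sampled as such).
#' NES is the observed overlap divided by the mean null overlap; the
#' two-sided p doubles the smaller tail, each with a +1 pseudo-count, and
#' is capped at 1.
#'
#' @param query,reference character vectors (subsets of `universe`).
#' @param universe character vector of eligible genes.
#' @param n_draws number of random draws (>= 100).
#' @return one-row data.frame: `overlap`, `expected`, `nes`, `p`,
#'   `query_size`, `reference_size`, `universe_size`.
#' @export
sampling_overlap_test <- function(query, reference, universe, n_draws = 10000) {
  universe <- unique(universe)
  query <- unique(query); reference <- unique(reference)
  if (!all(query %in% universe) || !all(reference %in% universe)) {
    stop("query and reference must be subsets of the universe")
  }
  if (length(query) > length(universe)) stop("|query| exceeds |universe|")
  if (n_draws < 100) stop("n_draws must be >= 100")
  o <- length(intersect(query, reference))
  null <- stats::rhyper(n_draws, m = length(reference),
                        n = length(universe) - length(reference),
                        k = length(query))
  p_hi <- (1 + sum(null >= o)) / (1 + n_draws)
  p_lo <- (1 + sum(null <= o)) / (1 + n_draws)
  data.frame(overlap = o, expected = mean(null), nes = o / mean(null),
             p = min(1, 2 * min(p_hi, p_lo)),
             query_size = length(query), reference_size = length(reference),
             universe_size = length(universe))
}
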