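#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors via [edgeR::calcNormFactors()]: the
#' reference library is the one whose upper quartile is closest to the mean
#' upper quartile; each sample's factor is 2 to the weighted mean of
#' gene-wise log ratios (M) against the reference after trimming 30% on M
#' and 5% on A; factors are rescaled to geometric mean 1. Pure depth
#' differences are carried by the library sizes, so scaled copies of the
#' same composition get factor 1.
#'
#' @param counts genes x samples count matrix.
#' @return named numeric vector of normalization factors, one per sample.
#' @export
tmm_factors <- function(counts) {
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stop("all-zero library: ", paste(colnames(counts)[lib <= 0], collapse = ", "))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Log2 counts per million
#'
#' `log2((count + 0.5) / (lib * factor + 1) * 1e6)`, the voom convention of
#' half-count and one-read offsets that keeps zeros finite.
#'
#' @param counts genes x samples count matrix.
#' @param factors normalization factors from [tmm_factors()]; defaults to 1.
#' @param lib_sizes library sizes; default column sums.
#' @return matrix of log2-CPM values with the effective library sizes
#'   (`lib * factor`) in attribute `eff_lib`.
#' @export
log2_cpm <- function(counts, factors = NULL, lib_sizes = NULL) {
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  eff <- lib_sizes * factors
  out <- log2(t((t(counts) + 0.5) / (eff + 1)) * 1e6)
  attr(out, "eff_lib") <- stats::setNames(eff, colnames(counts))
  out
}

#' Low-expression gene filter
#'
#' Keeps genes whose average log2-CPM across samples is at least zero
#' (genes averaging below zero, i.e. under one read per million, are
#' excluded).
#'
#' @param norm log2-CPM matrix from [log2_cpm()].
#' @return named logical vector, `TRUE` for genes to keep.
#' @export
filter_low_expression <- function(norm) {
  if (nrow(norm) == 0) {
    return(stats::setNames(logical(0), character(0)))
  }
  keep <- rowMeans(norm) >= 0
  stats::setNames(keep, rownames(norm))
}

#' Voom-style mean-variance precision weights
#'
#' Fits each gene by unweighted least squares on the log2-CPM scale,
#' smooths the square-root residual standard deviation against mean
#' log2-count with lowess, and converts the trend predicted at each fitted
#' value into an inverse-variance observation weight
#' (`weight = trend^-4`). Fitted square-root standard deviations are clamped
#' below at a small floor for stability on small simulations.
#'
#' @param counts genes x samples count matrix (genes already filtered).
#' @param design model matrix (samples x coefficients), full column rank.
#' @param factors optional TMM factors.
#' @param span lowess span for the trend.
#' @param sd_floor lower clamp for the fitted square-root residual SD.
#' @return list with `weights` (genes x samples matrix), `norm` (the
#'   log2-CPM matrix used) and `trend` (data.frame of the smoothed curve).
#' @export
mean_variance_weights <- function(counts, design, factors = NULL,
                                  span = 0.5, sd_floor = 1e-3) {
  n <- ncol(counts)
  p <- ncol(design)
  if (qr(design)$rank < p) stop("rank-deficient design")
  if (n <= p) stop("no residual degrees of freedom for the variance trend")
  lib <- colSums(counts)
  if (is.null(factors)) factors <- rep(1, n)
  eff <- lib * factors
  norm <- log2_cpm(counts, factors = factors, lib_sizes = lib)

  if (nrow(counts) < 2) {
    warning("fewer than 2 genes: returning unit weights")
    w <- matrix(1, nrow(counts), n, dimnames = dimnames(counts))
    return(list(weights = w, norm = norm, trend = NULL))
  }

  fit <- stats::lm.fit(design, t(norm))
  fitted <- t(design %*% fit$coefficients)          # genes x samples
  res <- t(fit$residuals)
  sigma <- sqrt(rowSums(res^2) / (n - p))

  # mean log2-count per gene; the trend lives on the count (not CPM) scale
  sx <- rowMeans(norm) + mean(log2(eff + 1)) - log2(1e6)
  sy <- sqrt(pmax(sigma, 0))
  lo <- stats::lowess(sx, sy, f = span)
  lf <- stats::approxfun(lo$x, lo$y, rule = 2, ties = list("ordered", mean))

  fitted_count <- fitted + matrix(log2(eff + 1), nrow(counts), n, byrow = TRUE) -
    log2(1e6)
  pred <- pmax(lf(fitted_count), sd_floor)
  w <- matrix(pred, nrow(counts), n)^(-4)
  dimnames(w) <- dimnames(counts)
  list(weights = w, norm = norm,
       trend = data.frame(x = lo$x, sqrt_sd = lo$y))
}
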