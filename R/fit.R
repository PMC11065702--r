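#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (sorted p-values are multiplied by `m / rank`,
#' cumulative minima taken from the largest down, capped at 1, and returned
#' in input order), delegated to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs propagated).
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  pp <- p[!is.na(p)]
  if (length(pp) && (any(pp < 0) || any(pp > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

## One-variance-component profile log-likelihood pieces. With observation
## precisions w (diagonal), batch indicator Z and variance ratio
## lambda = sigma_batch^2 / sigma_e^2, the unit-scale covariance is
## V0 = diag(1/w) + lambda Z Z'. Z'diag(w)Z is diagonal (batches are
## disjoint), so Woodbury gives O(n) solves and the determinant lemma an
## O(q) log-determinant.
ranint_solve <- function(x, w, batch_idx, sw, lambda) {
  wx <- w * x
  if (lambda == 0) return(wx)
  gs <- rowsum(wx, batch_idx)                        # Z' w x, q x k
  adj <- gs / (1 / lambda + sw)                      # q x k
  wx - w * adj[batch_idx, , drop = FALSE]
}

ranint_profile <- function(y, X, w, batch_idx, sw, lambda) {
  n <- length(y)
  ViX <- ranint_solve(X, w, batch_idx, sw, lambda)
  Viy <- ranint_solve(matrix(y, ncol = 1), w, batch_idx, sw, lambda)
  XtViX <- crossprod(X, ViX)
  beta <- solve(XtViX, crossprod(ViX, y))
  r <- y - X %*% beta
  rss <- sum(r * ranint_solve(matrix(r, ncol = 1), w, batch_idx, sw, lambda))
  logdet <- -sum(log(w)) + sum(log1p(lambda * sw))
  sigma2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(ll = ll, beta = drop(beta), XtViX = XtViX, rss = rss)
}

fit_gene_random <- function(y, X, w, batch_idx, lambda_max = 1e4, tol = 1e-8) {
  sw <- drop(rowsum(w, batch_idx))
  obj <- function(lam) -ranint_profile(y, X, w, batch_idx, sw, lam)$ll
  opt <- stats::optimize(obj, interval = c(0, lambda_max), tol = tol)
  lambda <- if (obj(0) <= opt$objective) 0 else opt$minimum
  fit <- ranint_profile(y, X, w, batch_idx, sw, lambda)
  df <- length(y) - ncol(X)
  sigma2 <- fit$rss / df                      # residual-df scaling for Wald SEs
  se <- sqrt(sigma2 * diag(solve(fit$XtViX)))
  list(beta = fit$beta, se = se, df = df, lambda = lambda)
}

#' Per-gene weighted linear models with optional random intercept
#'
#' Fits one model per gene on the normalized log2-CPM response. In fixed
#' mode the batch factor (if any) enters as fixed-effect dummy columns and
#' coefficients are tested with two-sided t-tests on the weighted residual
#' variance. In random mode the batch enters as a one-variance-component
#' random intercept fitted by maximum likelihood (profile likelihood over
#' the batch/residual variance ratio, Brent search at tolerance 1e-8) with
#' Wald t-tests on the residual degrees of freedom of the fixed part. If
#' the batch factor is confounded with the design (jointly rank deficient),
#' the fit falls back to fixed mode without the batch term, with a warning.
#'
#' @param y response matrix (genes x samples), e.g. filtered log2-CPM.
#' @param design model matrix (samples x coefficients).
#' @param weights optional observation weights (genes x samples), e.g. from
#'   [mean_variance_weights()].
#' @param batch optional batch factor (length = samples).
#' @param batch_mode `"fixed"` or `"random"`.
#' @return long data.frame: `gene`, `coefficient`, `logFC`, `se`, `df`,
#'   `t`, `p`, `padj` (BH within each coefficient across genes), and
#'   `converged`.
#' @export
fit_linear_models <- function(y, design, weights = NULL, batch = NULL,
                              batch_mode = c("fixed", "random")) {
  batch_mode <- match.arg(batch_mode)
  y <- as.matrix(y)
  n <- ncol(y)
  stopifnot(nrow(design) == n)
  if (is.null(weights)) weights <- matrix(1, nrow(y), n)
  stopifnot(all(dim(weights) == dim(y)), all(weights > 0))

  if (qr(design)$rank < ncol(design)) {
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased_columns(design), collapse = ", "))
  }

  use_random <- FALSE
  X <- design
  batch_idx <- NULL
  if (!is.null(batch)) {
    batch <- factor(batch)
    if (nlevels(batch) < 2) {
      warning("batch factor has a single level; ignored")
      batch <- NULL
    }
  }
  if (!is.null(batch)) {
    Zd <- stats::model.matrix(~batch)[, -1, drop = FALSE]
    confounded <- qr(cbind(design, Zd))$rank < ncol(design) + ncol(Zd)
    if (batch_mode == "random") {
      if (confounded) {
        warning("batch factor is confounded with the design; ",
                "falling back to fixed mode without the batch term")
      } else {
        use_random <- TRUE
        batch_idx <- as.integer(batch)
      }
    } else {
      if (confounded) {
        warning("batch factor is confounded with the design and was dropped")
      } else {
        colnames(Zd) <- paste0("batch_", levels(batch)[-1])
        X <- cbind(design, Zd)
      }
    }
  }

  p <- ncol(X)
  if (n - p < 1 && !use_random) stop("no residual degrees of freedom")

  genes <- rownames(y)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(y)))
  res <- vector("list", nrow(y))
  for (g in seq_len(nrow(y))) {
    yy <- y[g, ]
    ww <- weights[g, ]
    if (use_random) {
      f <- fit_gene_random(yy, X, ww, batch_idx)
      beta <- f$beta; se <- f$se; df <- f$df
    } else {
      sw <- sqrt(ww)
      qrx <- qr(X * sw)
      beta <- qr.coef(qrx, yy * sw)
      r <- yy - drop(X %*% beta)
      df <- n - p
      sigma2 <- sum(ww * r^2) / df
      XtWX_inv <- chol2inv(qr.R(qrx))
      se <- sqrt(sigma2 * diag(XtWX_inv))
    }
    tval <- beta / se
    res[[g]] <- data.frame(
      gene = genes[g], coefficient = colnames(X)[seq_along(beta)],
      logFC = unname(beta), se = unname(se), df = df, t = unname(tval),
      p = 2 * stats::pt(-abs(tval), df), converged = TRUE,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  out$padj <- NA_real_
  for (cf in unique(out$coefficient)) {
    i <- out$coefficient == cf
    out$padj[i] <- bh_adjust(out$p[i])
  }
  rownames(out) <- NULL
  out
}

aliased_columns <- function(X) {
  q <- qr(X)
  if (q$rank == ncol(X)) return(character(0))
  colnames(X)[q$pivot[-seq_len(q$rank)]]
}

#' End-to-end differential-expression fit
#'
#' Runs the full engine on raw counts: TMM factors, log2-CPM, the
#' low-expression filter, voom-style precision weights and per-gene linear
#' models built from the sample sheet. The default formula fits the
#' stimulation x mutant interaction model (condition and genotype main
#' effects, wild type and the unstimulated condition as reference levels,
#' plus their interaction).
#'
#' @param counts genes x samples count matrix.
#' @param samples sample sheet; rows are matched to count columns by
#'   `sample_id`. `genotype` and `condition` are coerced to factors in
#'   order of first appearance unless already factors, so put the reference
#'   level (wild type / unstimulated) first.
#' @param formula design formula over sample-sheet columns; default
#'   `~ condition * genotype`.
#' @param batch name of the batch column (default `experiment_id` when
#'   present), or `NULL` for none.
#' @param batch_mode `"fixed"` or `"random"` intercept handling of batch.
#' @return object of class `stimsig_fit`: list with `table` (the long
#'   result of [fit_linear_models()]), `design`, `norm`, `weights`,
#'   `factors` and the factor metadata needed by [interaction_effects()].
#' @export
fit_expression <- function(counts, samples, formula = ~ condition * genotype,
                           batch = if ("experiment_id" %in% colnames(samples))
                             "experiment_id" else NULL,
                           batch_mode = c("fixed", "random")) {
  batch_mode <- match.arg(batch_mode)
  stopifnot(all(samples$sample_id %in% colnames(counts)))
  counts <- counts[, samples$sample_id, drop = FALSE]

  vars <- all.vars(formula)
  for (v in vars) {
    if (!v %in% colnames(samples)) stop("sample sheet lacks column '", v, "'")
    if (!is.factor(samples[[v]])) {
      samples[[v]] <- factor(samples[[v]], levels = unique(samples[[v]]))
    }
  }

  factors <- tmm_factors(counts)
  norm0 <- log2_cpm(counts, factors = factors)
  keep <- filter_low_expression(norm0)
  if (!any(keep)) stop("no gene passes the low-expression filter")
  counts <- counts[keep, , drop = FALSE]

  design <- stats::model.matrix(formula, data = samples)
  mv <- mean_variance_weights(counts, design, factors = factors)
  batch_vec <- if (!is.null(batch)) samples[[batch]] else NULL
  table <- fit_linear_models(mv$norm, design, weights = mv$weights,
                             batch = batch_vec, batch_mode = batch_mode)
  structure(list(
    table = table, design = design, norm = mv$norm, weights = mv$weights,
    factors = factors, formula = formula,
    levels = lapply(samples[vars], levels)
  ), class = "stimsig_fit")
}

#' @export
print.stimsig_fit <- function(x, ...) {
  cat("stimsig_fit:", length(unique(x$table$gene)), "genes x",
      length(unique(x$table$coefficient)), "coefficients\n")
  invisible(x)
}

#' Reshape an interaction fit to one row per gene and mutant
#'
#' Extracts, for each mutant genotype and non-baseline condition, the
#' stimulation main effect (wild-type response), the mutant main effect
#' (unstimulated mutant versus wild type), the interaction coefficient and
#' their adjusted p-values — the input expected by
#' [classify_signatures()].
#'
#' @param fit a `stimsig_fit` from [fit_expression()] with the default
#'   interaction formula, or any long fit table plus explicit metadata.
#' @param condition_var,genotype_var names of the factors (defaults match
#'   [fit_expression()]).
#' @return data.frame: `gene`, `genotype`, `condition`, `beta_stim`,
#'   `beta_mut`, `beta_int`, `padj_stim`, `padj_mut`, `padj_int`.
#' @export
interaction_effects <- function(fit, condition_var = "condition",
                                genotype_var = "genotype") {
  stopifnot(inherits(fit, "stimsig_fit"))
  tab <- fit$table
  cond_levels <- fit$levels[[condition_var]]
  geno_levels <- fit$levels[[genotype_var]]
  if (is.null(cond_levels) || is.null(geno_levels)) {
    stop("fit lacks factor levels for '", condition_var, "'/'", genotype_var, "'")
  }
  grab <- function(coef_name) {
    sub <- tab[tab$coefficient == coef_name, c("gene", "logFC", "padj")]
    if (!nrow(sub)) stop("coefficient '", coef_name, "' not found in fit")
    sub
  }
  out <- list()
  for (g in geno_levels[-1]) {
    for (cc in cond_levels[-1]) {
      c_stim <- paste0(condition_var, cc)
      c_mut <- paste0(genotype_var, g)
      c_int <- paste0(condition_var, cc, ":", genotype_var, g)
      s <- grab(c_stim); m <- grab(c_mut); i <- grab(c_int)
      stopifnot(identical(s$gene, m$gene), identical(s$gene, i$gene))
      out[[paste(g, cc)]] <- data.frame(
        gene = s$gene, genotype = g, condition = cc,
        beta_stim = s$logFC, beta_mut = m$logFC, beta_int = i$logFC,
        padj_stim = s$padj, padj_mut = m$padj, padj_int = i$padj,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
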