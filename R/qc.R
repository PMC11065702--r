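#' Hard metric thresholds per sample
#'
#' First-stage QC: a sample fails when any metric falls strictly below its
#' threshold. RNA samples are checked for total reads (10^6), alignment rate
#' (0.5) and exome alignment rate (0.3); ATAC samples for total reads
#' (5 x 10^6), peak count (10^3), alignment rate (0.5) and FRiP (0.025).
#' Values exactly at a threshold pass ("below" is strict).
#'
#' @param metrics data.frame with a `sample_id` column plus, for RNA,
#'   `total_reads`, `alignment_rate`, `exome_rate`; for ATAC, `total_reads`,
#'   `alignment_rate`, `frip`, `n_peaks`.
#' @param assay `"rna"` or `"atac"`.
#' @param thresholds named list overriding the defaults above.
#' @return data.frame with `sample_id`, `pass`, and `fail_reason`
#'   (comma-separated metric names, `NA` when passing).
#' @export
metric_filter <- function(metrics, assay = c("rna", "atac"), thresholds = list()) {
  assay <- match.arg(assay)
  defaults <- switch(assay,
    rna = list(total_reads = 1e6, alignment_rate = 0.5, exome_rate = 0.3),
    atac = list(total_reads = 5e6, n_peaks = 1e3, alignment_rate = 0.5,
                frip = 0.025)
  )
  thr <- utils::modifyList(defaults, thresholds)
  if (!"sample_id" %in% colnames(metrics)) stop("metrics need a sample_id column")
  for (m in names(thr)) {
    if (!m %in% colnames(metrics)) {
      stop("missing metric '", m, "' (required for assay ", assay, ")")
    }
    if (anyNA(metrics[[m]])) {
      stop("missing value of metric '", m, "' for sample ",
           metrics$sample_id[which(is.na(metrics[[m]]))[1]])
    }
  }
  fails <- sapply(names(thr), function(m) metrics[[m]] < thr[[m]])
  fails <- matrix(fails, nrow = nrow(metrics),
                  dimnames = list(NULL, names(thr)))
  reason <- apply(fails, 1, function(f) {
    if (any(f)) paste(names(thr)[f], collapse = ",") else NA_character_
  })
  data.frame(sample_id = metrics$sample_id,
             pass = !apply(fails, 1, any),
             fail_reason = reason,
             stringsAsFactors = FALSE)
}

## Spearman correlation matrix over columns; rows are the (filtered)
## expression features.
spearman_cor <- function(expr) {
  stats::cor(expr, method = "spearman")
}

#' Mean replicate correlation per sample
#'
#' For each sample, the mean Spearman correlation against every other sample
#' of its replicate group (same genotype, cell type and treatment).
#' Singleton groups have nothing to correlate against and pass by
#' convention (mean correlation `NA`, warning issued).
#'
#' @param expr normalized expression matrix (features x samples); compute it
#'   on log2-CPM of genes passing the low-expression filter.
#' @param groups replicate group per column (character or factor).
#' @return data.frame with `sample_id`, `group`, `mean_cor`.
#' @export
replicate_correlations <- function(expr, groups) {
  stopifnot(ncol(expr) == length(groups))
  ids <- colnames(expr)
  if (is.null(ids)) stop("expr needs column names (sample ids)")
  out <- data.frame(sample_id = ids, group = as.character(groups),
                    mean_cor = NA_real_, stringsAsFactors = FALSE)
  for (g in unique(out$group)) {
    idx <- which(out$group == g)
    if (length(idx) < 2) {
      warning("singleton replicate group '", g, "': sample passes by convention")
      next
    }
    cm <- spearman_cor(expr[, idx, drop = FALSE])
    diag(cm) <- NA
    out$mean_cor[idx] <- rowMeans(cm, na.rm = TRUE)
  }
  out
}

#' Data-driven correlation cutoff
#'
#' The outlier cutoff is the average Spearman correlation across all
#' cross-pairs between two clearly distinct reference groups (in the study
#' design: wild-type macrophages versus wild-type CD8 T cells). For cultured
#' samples the strong culture effect makes that estimate unusable and a
#' fixed cutoff of 0.5 is returned regardless of the data.
#'
#' @param expr normalized expression matrix (features x samples).
#' @param group_a,group_b column ids (or indices) of the two reference groups.
#' @param cultured logical; if `TRUE`, return the fixed cultured-sample
#'   cutoff 0.5.
#' @return scalar cutoff.
#' @export
derive_correlation_cutoff <- function(expr, group_a, group_b, cultured = FALSE) {
  if (cultured) return(0.5)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both reference groups must be non-empty")
  }
  cm <- spearman_cor(expr[, c(group_a, group_b), drop = FALSE])
  ia <- seq_along(group_a)
  ib <- length(group_a) + seq_along(group_b)
  mean(cm[ia, ib])
}

#' Replicate-correlation outlier removal with keep-top-3 rescue
#'
#' Second-stage QC: within each replicate group, samples whose mean
#' replicate Spearman correlation falls below the cutoff are excluded.
#' Groups of three or fewer samples are kept whole. When fewer than three
#' samples of a larger group survive the cutoff, the three samples with the
#' highest correlations with each other are kept instead (exhaustive search
#' over all triples, maximizing the mean pairwise correlation; ties broken
#' by lexicographic sample id).
#'
#' @param expr normalized expression matrix (features x samples).
#' @param groups replicate group per column.
#' @param cutoff correlation cutoff, typically from
#'   [derive_correlation_cutoff()].
#' @return data.frame (one row per sample): `sample_id`, `group`,
#'   `mean_cor`, `cutoff`, `decision` (`"kept"`, `"excluded"` or
#'   `"rescued"`).
#' @export
remove_outliers <- function(expr, groups, cutoff) {
  rc <- replicate_correlations(expr, groups)
  rc$cutoff <- cutoff
  rc$decision <- "kept"
  for (g in unique(rc$group)) {
    idx <- which(rc$group == g)
    if (length(idx) <= 3) next               # small groups are kept whole
    ok <- !is.na(rc$mean_cor[idx]) & rc$mean_cor[idx] >= cutoff
    if (sum(ok) >= 3) {
      rc$decision[idx[!ok]] <- "excluded"
    } else {
      ids <- rc$sample_id[idx]
      cm <- spearman_cor(expr[, idx, drop = FALSE])
      triples <- utils::combn(order(ids), 3)  # lexicographic enumeration
      score <- apply(triples, 2, function(tr) {
        sub <- cm[tr, tr]
        mean(sub[upper.tri(sub)])
      })
      best <- triples[, which.max(score)]     # first max = lexicographic tie-break
      keep <- idx[best]
      rc$decision[setdiff(idx, keep)] <- "excluded"
      rc$decision[keep] <- ifelse(
        !is.na(rc$mean_cor[keep]) & rc$mean_cor[keep] >= cutoff, "kept", "rescued")
    }
  }
  rc
}

#' Full two-stage sample QC
#'
#' Convenience wrapper: applies [metric_filter()] when metrics are supplied,
#' then computes log2-CPM on low-expression-filtered genes and runs
#' [remove_outliers()] within replicate groups defined by genotype, cell
#' type and condition.
#'
#' @param counts genes x samples count matrix.
#' @param samples sample sheet with `sample_id`, `genotype`, `cell_type`,
#'   `condition`.
#' @param cutoff correlation cutoff (e.g. from [derive_correlation_cutoff()]).
#' @param metrics optional QC metrics table for the first stage.
#' @param assay assay type for the metric thresholds.
#' @return data.frame per sample with metric pass flag (if applicable) and
#'   outlier decision.
#' @export
qc_samples <- function(counts, samples, cutoff, metrics = NULL,
                       assay = c("rna", "atac")) {
  assay <- match.arg(assay)
  stopifnot(all(samples$sample_id %in% colnames(counts)))
  counts <- counts[, samples$sample_id, drop = FALSE]
  keep <- rep(TRUE, nrow(samples))
  mf <- NULL
  if (!is.null(metrics)) {
    mf <- metric_filter(metrics, assay)
    keep <- mf$pass[match(samples$sample_id, mf$sample_id)]
  }
  norm <- log2_cpm(counts[, keep, drop = FALSE])
  norm <- norm[filter_low_expression(norm), , drop = FALSE]
  groups <- with(samples[keep, ], paste(genotype, cell_type, condition, sep = "."))
  rep_report <- remove_outliers(norm, groups, cutoff)
  out <- data.frame(sample_id = samples$sample_id,
                    metric_pass = keep, stringsAsFactors = FALSE)
  out <- merge(out, rep_report, by = "sample_id", all.x = TRUE, sort = FALSE)
  out$decision[!out$metric_pass] <- "excluded"
  out[match(samples$sample_id, out$sample_id), ]
}
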