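#' Signature label levels
#'
#' The five assignable interaction groups, plus `minor` (significant but
#' dominated interaction) and `unassigned` (interaction not significant).
#'
#' @return character vector of the seven label levels.
#' @export
signature_levels <- function() {
  c(signature_groups(), "minor", "unassigned")
}

#' @rdname signature_levels
#' @export
signature_groups <- function() {
  c("de_novo", "mut_enhances_stim", "mut_reverts_stim",
    "stim_enhances_mut", "stim_reverts_mut")
}

#' Classify genes into the five interaction-signature groups
#'
#' Genes without a significant interaction term are `unassigned`. For the
#' rest, let `D_s` mean the interaction magnitude exceeds `ratio` times the
#' stimulation main effect and `D_m` the same against the mutant main
#' effect (strict inequalities; exact equality is "not greater"):
#'
#' * `D_s` and `D_m`: **de_novo** — the interaction dominates both mains
#'   (e.g. a response arising only in the stimulated mutant).
#' * neither: **minor** — significant but dominated interaction; kept in
#'   the significant universe but not assigned to a group.
#' * `D_m` only: the mutant modifies the stimulation response —
#'   **mut_enhances_stim** when interaction and stimulation effects share a
#'   sign, **mut_reverts_stim** otherwise (e.g. a gene induced by
#'   stimulation in wild type but not in the knockout has a negative
#'   interaction against a positive stimulation effect).
#' * `D_s` only: the stimulation modifies the mutant effect —
#'   **stim_enhances_mut** on shared sign, **stim_reverts_mut** otherwise.
#'
#' A zero interaction with significant p (pathological) lands in `minor`;
#' a zero main effect can never tie, since any nonzero interaction strictly
#' dominates it.
#'
#' @param effects data.frame with columns `beta_stim`, `beta_mut`,
#'   `beta_int` and `padj_int` (see [interaction_effects()]); extra columns
#'   are carried through.
#' @param alpha significance level on the interaction adjusted p-value.
#' @param ratio dominance factor (default 2: "twofold greater").
#' @return input data.frame with a `label` factor column
#'   (levels [signature_levels()]).
#' @export
classify_signatures <- function(effects, alpha = 0.05, ratio = 2) {
  stopifnot(alpha > 0, alpha < 1, ratio > 0)
  need <- c("beta_stim", "beta_mut", "beta_int", "padj_int")
  missing_cols <- setdiff(need, colnames(effects))
  if (length(missing_cols)) {
    stop("effects table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (cc in need) {
    if (anyNA(effects[[cc]])) {
      bad <- which(is.na(effects[[cc]]))[1]
      gene <- if ("gene" %in% colnames(effects)) effects$gene[bad] else bad
      stop("missing coefficient '", cc, "' for gene ", gene)
    }
  }
  bs <- effects$beta_stim; bm <- effects$beta_mut; bi <- effects$beta_int
  d_s <- abs(bi) > ratio * abs(bs)
  d_m <- abs(bi) > ratio * abs(bm)
  lab <- rep("unassigned", nrow(effects))
  sig <- effects$padj_int < alpha
  lab[sig & d_s & d_m] <- "de_novo"
  lab[sig & !d_s & !d_m] <- "minor"
  i2 <- sig & d_m & !d_s
  lab[i2] <- ifelse(sign(bi[i2]) == sign(bs[i2]),
                    "mut_enhances_stim", "mut_reverts_stim")
  i4 <- sig & d_s & !d_m
  lab[i4] <- ifelse(sign(bi[i4]) == sign(bm[i4]),
                    "stim_enhances_mut", "stim_reverts_mut")
  effects$label <- factor(lab, levels = signature_levels())
  effects
}

#' Prevalence of the signature groups per mutant
#'
#' Fractions of the five groups and of `minor` among the
#' interaction-significant genes (all labels except `unassigned`) of each
#' mutant; the `minor` genes stay in the denominator even though they belong
#' to no group.
#'
#' @param labels output of [classify_signatures()] (needs `label`;
#'   `genotype` used as the mutant key when present).
#' @return data.frame: `genotype`, `label`, `n`, `n_significant`,
#'   `fraction` (`NaN` with zero denominator).
#' @export
signature_prevalence <- function(labels) {
  stopifnot("label" %in% colnames(labels))
  by <- if ("genotype" %in% colnames(labels)) labels$genotype
        else rep("all", nrow(labels))
  out <- list()
  lv <- setdiff(signature_levels(), "unassigned")
  for (g in unique(by)) {
    lab <- labels$label[by == g]
    n_sig <- sum(lab != "unassigned")
    if (n_sig == 0) warning("no interaction-significant gene for mutant ", g)
    counts <- table(factor(lab[lab != "unassigned"], levels = lv))
    out[[g]] <- data.frame(
      genotype = g, label = lv, n = as.integer(counts),
      n_significant = n_sig, fraction = as.integer(counts) / n_sig,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reversion shares
#'
#' Percentage of genes whose mutant effect reverts the stimulation effect
#' (group `mut_reverts_stim`, relative to all genes with a significant
#' stimulation effect in wild-type cells), or whose stimulation reverts the
#' mutant effect (group `stim_reverts_mut`, relative to all genes with a
#' significant mutant effect in unstimulated cells). The denominator is
#' reported alongside the percentage, per mutant.
#'
#' @param labels output of [classify_signatures()]; needs `padj_stim` and
#'   `padj_mut` columns (as produced by [interaction_effects()]).
#' @param mode `"mutant_reverts_stim"` or `"stim_reverts_mut"`.
#' @param alpha significance level for the denominator main effect.
#' @return data.frame: `genotype`, `mode`, `n_reverted`, `denominator`,
#'   `share_pct` (`NA` when the denominator is zero).
#' @export
reversion_shares <- function(labels,
                             mode = c("mutant_reverts_stim", "stim_reverts_mut"),
                             alpha = 0.05) {
  mode <- match.arg(mode)
  group <- switch(mode, mutant_reverts_stim = "mut_reverts_stim",
                  stim_reverts_mut = "stim_reverts_mut")
  denom_col <- switch(mode, mutant_reverts_stim = "padj_stim",
                      stim_reverts_mut = "padj_mut")
  stopifnot(all(c("label", denom_col) %in% colnames(labels)))
  by <- if ("genotype" %in% colnames(labels)) labels$genotype
        else rep("all", nrow(labels))
  out <- list()
  for (g in unique(by)) {
    sub <- labels[by == g, ]
    denom <- sum(sub[[denom_col]] < alpha, na.rm = TRUE)
    nrev <- sum(sub$label == group)
    out[[g]] <- data.frame(
      genotype = g, mode = mode, n_reverted = nrev, denominator = denom,
      share_pct = if (denom > 0) 100 * nrev / denom else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean log2 fold change of a gene set
#'
#' Arithmetic mean of one coefficient's log2FC over the gene-set members
#' present in the fit (used e.g. for the mean stimulation response across a
#' core set of interferon-stimulated genes).
#'
#' @param fit long fit table with `gene`, `coefficient`, `logFC` (a
#'   `stimsig_fit` is accepted), or any table with `gene` plus the named
#'   coefficient's rows.
#' @param genes character vector of gene-set members.
#' @param coefficient coefficient name to average.
#' @return scalar mean log2FC with attribute `n_used` (members found).
#' @export
geneset_mean_lfc <- function(fit, genes, coefficient) {
  tab <- if (inherits(fit, "stimsig_fit")) fit$table else fit
  sub <- tab[tab$coefficient == coefficient & tab$gene %in% genes, ]
  if (!nrow(sub)) stop("no gene-set member present for coefficient '",
                       coefficient, "'")
  structure(mean(sub$logFC), n_used = nrow(sub))
}
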