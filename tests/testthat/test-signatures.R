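sig_row <- function(bs, bm, bi, padj = 0.01, gene = "g") {
  data.frame(gene = gene, beta_stim = bs, beta_mut = bm, beta_int = bi,
             padj_int = padj, stringsAsFactors = FALSE)
}

test_that("hand-worked coefficient triples land in the documented groups", {
  expect_equal(as.character(classify_signatures(sig_row(0, 0, 1.5))$label),
               "de_novo")
  # stimulation-induced gene not induced in the knockout: negative interaction
  expect_equal(as.character(classify_signatures(sig_row(2.0, 0.1, -2.0))$label),
               "mut_reverts_stim")
  expect_equal(as.character(classify_signatures(sig_row(0.1, 2.0, 1.0))$label),
               "stim_enhances_mut")
  expect_equal(as.character(classify_signatures(sig_row(1.0, 1.0, 0.5))$label),
               "minor")
  expect_equal(as.character(classify_signatures(sig_row(1.0, 0.1, 1.5))$label),
               "mut_enhances_stim")
  expect_equal(as.character(classify_signatures(sig_row(0.1, -1.0, 1.5))$label),
               "stim_reverts_mut")
  expect_equal(as.character(classify_signatures(sig_row(3, 3, 9, padj = 0.2))$label),
               "unassigned")
})

test_that("exact twofold equality falls to the not-greater branch", {
  # |int| exactly 2|stim|: stimulation is NOT dominated
  expect_equal(as.character(classify_signatures(sig_row(1, 0.1, 2))$label),
               "mut_enhances_stim")
  expect_equal(as.character(classify_signatures(sig_row(1, 1, 2))$label),
               "minor")
  # pathological zero interaction with significant p
  expect_equal(as.character(classify_signatures(sig_row(1, 1, 0))$label),
               "minor")
})

test_that("the sign x dominance grid yields exactly 5 groups plus minor, one label each", {
  grid <- expand.grid(
    bs = c(-3, -1.2, -0.6, -0.1, 0, 0.1, 0.6, 1.2, 3),
    bm = c(-3, -1.2, -0.6, -0.1, 0, 0.1, 0.6, 1.2, 3),
    bi = c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)
  )
  eff <- data.frame(gene = paste0("g", seq_len(nrow(grid))),
                    beta_stim = grid$bs, beta_mut = grid$bm,
                    beta_int = grid$bi, padj_int = 0.001)
  lab <- classify_signatures(eff)$label
  expect_false(anyNA(lab))                       # exactly one label per input
  assignable <- setdiff(unique(as.character(lab)), c("minor", "unassigned"))
  expect_setequal(assignable, signature_groups())
  expect_length(assignable, 5)
  expect_false("unassigned" %in% lab)            # all inputs were significant
})

test_that("labels are equivariant under positive rescaling of all coefficients", {
  set.seed(50)
  eff <- data.frame(gene = paste0("g", 1:200),
                    beta_stim = rnorm(200), beta_mut = rnorm(200),
                    beta_int = rnorm(200, sd = 2), padj_int = 0.01)
  base <- classify_signatures(eff)$label
  for (c_scale in c(0.2, 3, 17)) {
    scaled <- eff
    scaled[, c("beta_stim", "beta_mut", "beta_int")] <-
      scaled[, c("beta_stim", "beta_mut", "beta_int")] * c_scale
    expect_identical(classify_signatures(scaled)$label, base)
  }
})

test_that("classification errors name the offending gene", {
  eff <- sig_row(1, 1, 1, gene = "gX")
  eff$beta_mut <- NA
  expect_error(classify_signatures(eff), "gX")
  expect_error(classify_signatures(sig_row(1, 1, 1)[, -2]), "beta_stim")
})

test_that("prevalence fractions count over interaction-significant genes", {
  eff <- rbind(sig_row(0, 0, 2, gene = "a"), sig_row(0, 0, 2, gene = "b"),
               sig_row(1, 1, 0.5, gene = "c"), sig_row(1, 1, 0.5, 0.9, gene = "d"))
  prev <- signature_prevalence(classify_signatures(eff))
  expect_equal(prev$n_significant, rep(3, nrow(prev)))
  expect_equal(prev$fraction[prev$label == "de_novo"], 2 / 3)
  expect_equal(prev$fraction[prev$label == "minor"], 1 / 3)
  expect_equal(sum(prev$fraction), 1)

  # all five groups once: 1/5 each among the assignable labels
  eff5 <- rbind(sig_row(0, 0, 2, gene = "a"),
                sig_row(1, 0.1, 1.5, gene = "b"),
                sig_row(2, 0.1, -2, gene = "c"),
                sig_row(0.1, 2, 1, gene = "d"),
                sig_row(0.1, -1, 1.5, gene = "e"))
  prev5 <- signature_prevalence(classify_signatures(eff5))
  expect_true(all(prev5$fraction[prev5$label %in% signature_groups()] == 0.2))

  none <- sig_row(1, 1, 1, padj = 0.9)
  expect_warning(p0 <- signature_prevalence(classify_signatures(none)),
                 "no interaction-significant")
  expect_true(all(is.nan(p0$fraction)))
})

test_that("reversion shares divide group counts by main-effect-significant genes", {
  eff <- do.call(rbind, lapply(1:10, function(i) sig_row(2, 0.1, -2, gene = paste0("g", i))))
  eff$padj_stim <- 0.01
  eff$padj_mut <- 0.5
  lab <- classify_signatures(eff)
  lab$label[4:10] <- "minor"                    # leave 3 reverters of 10 stim-significant
  sh <- reversion_shares(lab, "mutant_reverts_stim")
  expect_equal(sh$share_pct, 30)
  expect_equal(sh$denominator, 10)

  lab$label <- factor("minor", levels = signature_levels())
  sh0 <- reversion_shares(lab, "stim_reverts_mut")
  expect_equal(sh0$denominator, 0)
  expect_true(is.na(sh0$share_pct))
  lab$padj_mut <- 0.01
  sh1 <- reversion_shares(lab, "stim_reverts_mut")
  expect_equal(sh1$share_pct, 0)
})

test_that("planted reversion shares are recovered within the binomial interval", {
  # 50 stim-responsive genes, of which a planted fraction are group-3 reverters
  set.seed(51)
  n_stim <- 50; n_rev <- 10
  rows <- lapply(seq_len(n_stim), function(i) {
    if (i <= n_rev) sig_row(2, 0.1, -2, gene = paste0("g", i))       # reverter
    else sig_row(2, 0.1, 0.2, padj = 0.9, gene = paste0("g", i))     # plain stim
  })
  eff <- do.call(rbind, rows)
  eff$padj_stim <- 0.001
  sh <- reversion_shares(classify_signatures(eff), "mutant_reverts_stim")
  expect_equal(sh$share_pct, 100 * n_rev / n_stim)
})

test_that("geneset_mean_lfc averages present members and errors on none", {
  fit <- data.frame(gene = c("a", "b", "c"), coefficient = "stim",
                    logFC = c(1, 3, 10), p = 0.1, padj = 0.2)
  m <- geneset_mean_lfc(fit, c("a", "b"), "stim")
  expect_equal(as.numeric(m), 2)
  expect_equal(attr(m, "n_used"), 2)
  m2 <- geneset_mean_lfc(fit, c("a", "b", "zz"), "stim")
  expect_equal(as.numeric(m2), 2)
  expect_equal(attr(m2, "n_used"), 2)
  expect_error(geneset_mean_lfc(fit, c("x", "y"), "stim"), "no gene-set member")
})

test_that("planted signature labels are recovered end to end", {
  # the study-style stimulation layout: several mutants sharing wild type
  rec <- sapply(1:3, function(s) {
    cfg <- simulation_config(
      n_genes = 500, n_replicates = 4, dispersion_sdlog = 0, batch_sd = 0,
      genotypes = c("WT", paste0("MUT", 1:4)), seed = s,
      archetype_fractions = setNames(rep(0.08, 5), signature_groups()))
    sim <- simulate_dataset(cfg)
    fit <- fit_expression(sim$counts, sim$design, batch = NULL)
    lab <- classify_signatures(interaction_effects(fit))
    tl <- sim$truth$genes$label[match(lab$gene, sim$truth$genes$gene_id)]
    pl <- tl != "unassigned"
    mean(as.character(lab$label[pl]) == tl[pl])
  })
  expect_gt(mean(rec), 0.75)
})
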