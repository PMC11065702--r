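test_that("simulate_design enumerates every cell with the right replication", {
  cases <- list(
    list(g = c("WT", "KO"), ct = "Tcell", cond = c("u", "s"), r = 3, rows = 12),
    list(g = paste0("g", 1:12), ct = c("Mac", "Tcell"), cond = "u", r = 4, rows = 96)
  )
  for (cs in cases) {
    cfg <- simulation_config(n_genes = 10, genotypes = cs$g, cell_types = cs$ct,
                             conditions = cs$cond, n_replicates = cs$r)
    d <- simulate_design(cfg)
    expect_equal(nrow(d), cs$rows)
    cells <- table(d$genotype, d$cell_type, d$condition)
    expect_true(all(cells == cs$r))
    expect_false(anyDuplicated(d$sample_id) > 0)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_replicates = 0), "n_replicates")
  expect_error(simulation_config(genotypes = character(0)), "non-empty")
  expect_error(simulation_config(archetype_fractions = c(de_novo = 0.7, minor = 0.6)),
               "> 1")
  expect_error(simulation_config(archetype_fractions = c(bogus = 0.1)), "unknown")
})

test_that("batches are assigned round-robin over replicates", {
  cfg <- simulation_config(n_genes = 5, n_replicates = 5, n_batches = 2)
  d <- simulate_design(cfg)
  expect_equal(d$experiment_id[d$replicate == 1], rep("batch1", sum(d$replicate == 1)))
  expect_equal(d$experiment_id[d$replicate == 2], rep("batch2", sum(d$replicate == 2)))
  expect_equal(d$experiment_id[d$replicate == 3], rep("batch1", sum(d$replicate == 3)))
})

test_that("planted effects satisfy their archetype rules (classifier as oracle)", {
  fr <- setNames(rep(0.15, 5), signature_groups())
  cfg <- simulation_config(n_genes = 400, archetype_fractions = c(fr, minor = 0.1),
                           seed = 9)
  set.seed(cfg$seed)
  truth <- simulate_effects(cfg)
  eff <- truth$effects
  eff$padj_int <- ifelse(eff$beta_int != 0, 0.001, 1)  # planted = significant
  called <- classify_signatures(eff)
  planted <- truth$genes$label[match(called$gene, truth$genes$gene_id)]
  idx <- planted != "unassigned"
  expect_true(all(as.character(called$label[idx]) == planted[idx]))
  # null genes have zero effects everywhere
  null_rows <- !idx
  expect_true(all(eff$beta_stim[null_rows] == 0 & eff$beta_mut[null_rows] == 0 &
                    eff$beta_int[null_rows] == 0))
  # magnitude bounds on the planted interaction
  expect_true(all(abs(eff$beta_int[idx]) >= cfg$effect_magnitude_low - 1e-12))
  expect_true(all(abs(eff$beta_int[idx]) <= cfg$effect_magnitude_high + 1e-12))
})

test_that("mut_reverts_stim plants opposite-signed dominant stimulation effects", {
  cfg <- simulation_config(n_genes = 200, seed = 5,
                           archetype_fractions = c(mut_reverts_stim = 0.5))
  set.seed(cfg$seed)
  eff <- simulate_effects(cfg)$effects
  pl <- eff$beta_int != 0
  expect_true(all(sign(eff$beta_int[pl]) != sign(eff$beta_stim[pl])))
  expect_true(all(abs(eff$beta_int[pl]) > 2 * abs(eff$beta_mut[pl])))
  expect_true(all(abs(eff$beta_int[pl]) <= 2 * abs(eff$beta_stim[pl])))
})

test_that("all-zero archetype fractions give an all-null truth table", {
  cfg <- test_config(archetype_fractions = numeric(0))
  set.seed(1)
  truth <- simulate_effects(cfg)
  expect_true(all(truth$genes$label == "unassigned"))
  eff <- truth$effects
  eff$padj_int <- 1
  expect_true(all(classify_signatures(eff)$label == "unassigned"))
})

test_that("simulation is deterministic given config and seed", {
  cfg <- test_config()
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$effects, b$truth$effects)
})

test_that("count means and NB variance match the generating model", {
  # near-Poisson limit, no batch noise: replicate mean within 3 SE of plan
  cfg <- simulation_config(n_genes = 60, genotypes = "WT", conditions = "u",
                           n_replicates = 1000, n_batches = 1, batch_sd = 0,
                           dispersion_meanlog = log(1e-13), dispersion_sdlog = 0,
                           lib_size_cv = 0, lib_size_mean = 1e6,
                           archetype_fractions = numeric(0), seed = 21)
  sim <- simulate_dataset(cfg)
  base <- sim$truth$genes$base_log2
  planned <- 1e6 * 2^base / sum(2^base)
  obs <- rowMeans(sim$counts)
  se <- sqrt(planned / 1000)   # Poisson SE of the mean
  expect_true(all(abs(obs - planned) <= 4 * se + 1e-9))

  # moment check at phi = 0.2: var ~= mu + phi mu^2
  cfg2 <- simulation_config(n_genes = 200, genotypes = "WT", conditions = "u",
                            n_replicates = 1000, n_batches = 1, batch_sd = 0,
                            dispersion_meanlog = log(0.2), dispersion_sdlog = 0,
                            lib_size_cv = 0, archetype_fractions = numeric(0),
                            seed = 22)
  sim2 <- simulate_dataset(cfg2)
  mu <- rowMeans(sim2$counts)
  v <- apply(sim2$counts, 1, var)
  well <- mu > 50
  ratio <- v[well] / (mu[well] + 0.2 * mu[well]^2)
  expect_gt(median(ratio), 0.9)
  expect_lt(median(ratio), 1.1)
})

test_that("an interaction of 3 log2 units gives an ~8-fold interaction ratio", {
  cfg <- simulation_config(n_genes = 50, n_replicates = 400, n_batches = 1,
                           batch_sd = 0, dispersion_meanlog = log(0.05),
                           dispersion_sdlog = 0, lib_size_cv = 0,
                           archetype_fractions = numeric(0), seed = 33)
  set.seed(cfg$seed)
  design <- simulate_design(cfg)
  truth <- simulate_effects(cfg)
  truth$effects$beta_int[1] <- 3
  counts <- simulate_counts(design, truth, cfg)
  grp <- function(g, cc) {
    rowMeans(counts[1, design$genotype == g & design$condition == cc, drop = FALSE])
  }
  # interaction ratio: (MUT.stim / MUT.unstim) / (WT.stim / WT.unstim)
  ratio <- (grp("MUT", "IFNb") / grp("MUT", "unstim")) /
    (grp("WT", "IFNb") / grp("WT", "unstim"))
  expect_gt(ratio, 8 * 0.85)
  expect_lt(ratio, 8 / 0.85)
})

test_that("inject_outliers flags and corrupts exactly the requested samples", {
  cfg <- test_config()
  sim <- simulate_dataset(cfg)
  ids <- sim$design$sample_id[c(2, 7)]
  set.seed(5)
  inj <- inject_outliers(sim$counts, ids, "shuffle_genes")
  expect_identical(names(which(inj$outliers)), ids)
  untouched <- setdiff(colnames(sim$counts), ids)
  expect_identical(inj$counts[, untouched], sim$counts[, untouched])
  expect_identical(sort(unname(inj$counts[, ids[1]])),
                   sort(unname(sim$counts[, ids[1]])))
  expect_false(identical(inj$counts[, ids[1]], sim$counts[, ids[1]]))

  # injected sample has the lowest mean replicate correlation of its group
  grp <- sim$design$sample_id[1:4]
  set.seed(6)
  inj2 <- inject_outliers(sim$counts, grp[2], "shuffle_genes")
  rc <- replicate_correlations(log2_cpm(inj2$counts[, grp]), rep("a", 4))
  expect_equal(rc$sample_id[which.min(rc$mean_cor)], grp[2])

  # no-op and error contracts
  expect_identical(inject_outliers(sim$counts, character(0))$counts, sim$counts)
  expect_error(inject_outliers(sim$counts, "nope"), "unknown sample")
  set.seed(7); f1 <- inject_outliers(sim$counts, ids, "shuffle_genes")
  set.seed(7); f2 <- inject_outliers(sim$counts, ids, "shuffle_genes")
  expect_identical(f1$counts, f2$counts)
})

test_that("swap_profile replaces a sample with another cell type's profile", {
  cfg <- simulation_config(n_genes = 500, cell_types = c("Mac", "Tcell"),
                           genotypes = "WT", conditions = "u",
                           archetype_fractions = numeric(0), seed = 8)
  sim <- simulate_dataset(cfg)
  mac_ids <- sim$design$sample_id[sim$design$cell_type == "Mac"]
  t_ids <- sim$design$sample_id[sim$design$cell_type == "Tcell"]
  set.seed(9)
  inj <- inject_outliers(sim$counts, mac_ids[1], "swap_profile",
                         design = sim$design, truth = sim$truth, config = cfg)
  norm <- log2_cpm(inj$counts)
  swapped_vs_t <- mean(cor(norm[, mac_ids[1]], norm[, t_ids], method = "spearman"))
  swapped_vs_mac <- mean(cor(norm[, mac_ids[1]], norm[, mac_ids[-1]], method = "spearman"))
  expect_gt(swapped_vs_t, swapped_vs_mac)
})
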