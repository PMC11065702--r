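#' Simulation configuration
#'
#' Builds the configuration object for the synthetic count generator. The
#' generator emulates a multi-genotype immune profiling design: several
#' genotypes (the first is the wild-type reference) by cell types by culture
#' or stimulation conditions (the first is the unstimulated baseline), with
#' replicates spread round-robin over experiment batches, negative-binomial
#' counts, and a configurable fraction of genes planted in the five
#' interaction-signature archetypes (the remainder are null).
#'
#' Planted effects are drawn so that each archetype's defining
#' magnitude-dominance and sign relations hold with a clear margin:
#' `|beta_int|` is uniform on `[effect_magnitude_low, effect_magnitude_high]`;
#' a main effect that must *not* be dominated has magnitude
#' `U[1, 1.5] * |beta_int|` (the canonical full-reversion/enhancement
#' pattern), a main effect that must be dominated has magnitude
#' `U[0, 0.2]`, and de-novo genes have exactly zero main effects.
#'
#' @param n_genes number of genes.
#' @param genotypes character vector of genotype levels; first is wild type.
#' @param cell_types character vector of cell-type levels.
#' @param conditions character vector of condition levels; first is the
#'   unstimulated baseline.
#' @param n_replicates replicates per genotype x cell type x condition cell.
#' @param n_batches number of experiment batches (round-robin over replicates).
#' @param batch_sd log2-scale SD of batch offsets shared across genes within a
#'   batch. A shared offset is a pure depth shift and is removed by CPM
#'   normalization; use `batch_gene_sd` for batch structure that survives it.
#' @param batch_gene_sd log2-scale SD of per-gene, per-batch offsets
#'   (0 disables; this is the structure a random-intercept model absorbs).
#' @param cell_type_sd log2-scale SD of per-gene offsets distinguishing cell
#'   types beyond the first; distinct lineages share housekeeping structure
#'   but diverge strongly in lineage-specific genes.
#' @param dispersion_meanlog,dispersion_sdlog log-normal parameters of the
#'   gene-wise NB dispersion phi (variance = mu + phi * mu^2).
#' @param lib_size_mean,lib_size_cv mean and coefficient of variation of the
#'   log-normal library-size distribution.
#' @param archetype_fractions named numeric vector mapping signature labels
#'   (the five groups of [signature_groups()], optionally plus `minor`) to
#'   gene fractions; must sum to at most 1, remainder are null genes.
#' @param effect_magnitude_low,effect_magnitude_high uniform bounds for the
#'   planted interaction magnitude `|beta_int|` (log2 units).
#' @param dominance_margin minimum log2 slack enforced between `|beta_int|`
#'   and twice a dominated main effect.
#' @param base_meanlog2,base_sdlog2 normal parameters of the baseline log2
#'   mean expression.
#' @param seed integer seed used by [simulate_dataset()].
#' @return object of class `simulation_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 200, n_replicates = 3, seed = 7)
#' sim <- simulate_dataset(cfg)
#' dim(sim$counts)
simulation_config <- function(n_genes = 2000,
                              genotypes = c("WT", "MUT"),
                              cell_types = "Tcell",
                              conditions = c("unstim", "IFNb"),
                              n_replicates = 4,
                              n_batches = 2,
                              batch_sd = 0.25,
                              batch_gene_sd = 0,
                              cell_type_sd = 2,
                              dispersion_meanlog = log(0.1),
                              dispersion_sdlog = 0.5,
                              lib_size_mean = 2e6,
                              lib_size_cv = 0.2,
                              archetype_fractions = c(
                                de_novo = 0.04,
                                mut_enhances_stim = 0.04,
                                mut_reverts_stim = 0.04,
                                stim_enhances_mut = 0.04,
                                stim_reverts_mut = 0.04
                              ),
                              effect_magnitude_low = 1,
                              effect_magnitude_high = 3,
                              dominance_margin = 0.1,
                              base_meanlog2 = 5,
                              base_sdlog2 = 2,
                              seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), genotypes = as.character(genotypes),
    cell_types = as.character(cell_types), conditions = as.character(conditions),
    n_replicates = as.integer(n_replicates), n_batches = as.integer(n_batches),
    batch_sd = batch_sd, batch_gene_sd = batch_gene_sd,
    cell_type_sd = cell_type_sd,
    dispersion_meanlog = dispersion_meanlog,
    dispersion_sdlog = dispersion_sdlog,
    lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
    archetype_fractions = archetype_fractions,
    effect_magnitude_low = effect_magnitude_low,
    effect_magnitude_high = effect_magnitude_high,
    dominance_margin = dominance_margin,
    base_meanlog2 = base_meanlog2, base_sdlog2 = base_sdlog2,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  for (fld in c("genotypes", "cell_types", "conditions")) {
    if (length(cfg[[fld]]) == 0 || anyNA(cfg[[fld]]) || any(cfg[[fld]] == "")) {
      stop("configuration error: '", fld, "' must be a non-empty vector of levels")
    }
    if (anyDuplicated(cfg[[fld]])) {
      stop("configuration error: duplicated levels in '", fld, "'")
    }
  }
  if (cfg$n_genes < 1) stop("configuration error: n_genes must be >= 1")
  if (cfg$n_replicates < 1) stop("configuration error: n_replicates must be >= 1")
  if (cfg$n_batches < 1) stop("configuration error: n_batches must be >= 1")
  fr <- cfg$archetype_fractions
  if (length(fr)) {
    bad <- setdiff(names(fr), c(signature_groups(), "minor"))
    if (length(bad)) {
      stop("configuration error: unknown archetype(s): ", paste(bad, collapse = ", "))
    }
    if (any(fr < 0)) stop("configuration error: archetype fractions must be >= 0")
    if (sum(fr) > 1 + 1e-12) {
      stop("configuration error: archetype fractions sum to ", sum(fr), " (> 1)")
    }
  }
  if (cfg$effect_magnitude_low <= 0 ||
      cfg$effect_magnitude_high < cfg$effect_magnitude_low) {
    stop("configuration error: effect magnitude bounds must satisfy 0 < low <= high")
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:", x$n_genes, "genes;",
      length(x$genotypes), "genotypes x", length(x$cell_types),
      "cell types x", length(x$conditions), "conditions x",
      x$n_replicates, "replicates;",
      sum(x$archetype_fractions), "planted fraction; seed", x$seed, "\n")
  invisible(x)
}

#' Sample sheet for a simulated design
#'
#' One row per sample, covering every genotype x cell type x condition cell
#' with exactly `n_replicates` rows; batches are assigned round-robin over
#' replicates. Deterministic given the configuration (no random numbers).
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns `sample_id`, `genotype`, `cell_type`,
#'   `condition`, `replicate`, `experiment_id`.
#' @export
simulate_design <- function(config) {
  validate_simulation_config(config)
  grid <- expand.grid(
    replicate = seq_len(config$n_replicates),
    condition = config$conditions,
    cell_type = config$cell_types,
    genotype = config$genotypes,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[, c("genotype", "cell_type", "condition", "replicate")]
  grid$experiment_id <- paste0(
    "batch", ((grid$replicate - 1L) %% config$n_batches) + 1L
  )
  grid$sample_id <- paste(grid$genotype, grid$cell_type, grid$condition,
                          paste0("rep", grid$replicate), sep = ".")
  rownames(grid) <- NULL
  grid[, c("sample_id", "genotype", "cell_type", "condition",
           "replicate", "experiment_id")]
}

## Draw (beta_stim, beta_mut, beta_int) obeying one archetype's sign and
## 2x-dominance relations. `big` magnitudes are comparable to or larger than
## the interaction (never dominated); `small` ones are near zero (always
## dominated, with at least `margin` slack).
draw_archetype_betas <- function(label, lo, hi, margin) {
  b_int <- sample(c(-1, 1), 1) * stats::runif(1, lo, hi)
  big <- function(sign_to) sign_to * stats::runif(1, 1, 1.5) * abs(b_int)
  small <- function() {
    cap <- min(0.2, (abs(b_int) - margin) / 2)
    sample(c(-1, 1), 1) * stats::runif(1, 0, max(cap, 0))
  }
  switch(label,
    de_novo = c(stim = 0, mut = 0, int = b_int),
    mut_enhances_stim = c(stim = big(sign(b_int)), mut = small(), int = b_int),
    mut_reverts_stim = c(stim = big(-sign(b_int)), mut = small(), int = b_int),
    stim_enhances_mut = c(stim = small(), mut = big(sign(b_int)), int = b_int),
    stim_reverts_mut = c(stim = small(), mut = big(-sign(b_int)), int = b_int),
    minor = c(stim = big(sample(c(-1, 1), 1)),
              mut = big(sample(c(-1, 1), 1)), int = b_int),
    stop("unknown archetype label: ", label)
  )
}

#' Plant per-gene effects (truth table)
#'
#' Draws baseline expression, NB dispersion and, for planted genes, the
#' coefficient triple (stimulation main effect, mutant main effect,
#' interaction) of their archetype; the triple is shared across mutant
#' genotypes because the stimulation main effect is the wild-type response.
#' Null genes have all coefficients zero. Applying
#' [classify_signatures()] to the planted coefficients reproduces the planted
#' labels by construction.
#'
#' @param config a [simulation_config()]. Uses the current RNG state; call
#'   [simulate_dataset()] (or `set.seed()`) for reproducibility.
#' @return object of class `truth_table`: list with `genes` (per-gene
#'   `gene_id`, `base_log2`, `dispersion`, `label`), `effects` (one row per
#'   gene x mutant genotype: `beta_stim`, `beta_mut`, `beta_int`), and
#'   `cell_type_offsets` (genes x cell types, first column zero).
#' @export
simulate_effects <- function(config) {
  validate_simulation_config(config)
  ng <- config$n_genes
  gene_id <- sprintf("gene%05d", seq_len(ng))

  fr <- config$archetype_fractions
  n_planted <- if (length(fr)) round(fr * ng) else integer(0)
  if (sum(n_planted) > ng) stop("configuration error: archetype fractions sum > 1")
  label <- rep("unassigned", ng)
  at <- 0L
  for (i in seq_along(n_planted)) {        # planted genes occupy the head
    if (n_planted[i] > 0) {
      label[at + seq_len(n_planted[i])] <- names(fr)[i]
      at <- at + n_planted[i]
    }
  }

  genes <- data.frame(
    gene_id = gene_id,
    base_log2 = stats::rnorm(ng, config$base_meanlog2, config$base_sdlog2),
    dispersion = stats::rlnorm(ng, config$dispersion_meanlog, config$dispersion_sdlog),
    label = label,
    stringsAsFactors = FALSE
  )

  # beta_stim is the wild-type stimulation response and is necessarily shared
  # across mutant genotypes; one coefficient triple is drawn per planted gene
  # and applied to every mutant, keeping the generating model self-consistent.
  betas <- matrix(0, ng, 3, dimnames = list(gene_id, c("stim", "mut", "int")))
  for (g in which(label != "unassigned")) {
    betas[g, ] <- draw_archetype_betas(label[g], config$effect_magnitude_low,
                                       config$effect_magnitude_high,
                                       config$dominance_margin)
  }
  mutants <- config$genotypes[-1]
  eff <- expand.grid(gene_id = gene_id, genotype = mutants,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eff$beta_stim <- rep(betas[, "stim"], length(mutants))
  eff$beta_mut <- rep(betas[, "mut"], length(mutants))
  eff$beta_int <- rep(betas[, "int"], length(mutants))

  cto <- matrix(0, ng, length(config$cell_types),
                dimnames = list(gene_id, config$cell_types))
  if (length(config$cell_types) > 1) {
    cto[, -1] <- stats::rnorm(ng * (ncol(cto) - 1), 0, config$cell_type_sd)
  }

  structure(list(genes = genes, effects = eff, cell_type_offsets = cto),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat("truth_table:", nrow(x$genes), "genes,",
      sum(x$genes$label != "unassigned"), "planted;",
      length(unique(x$effects$genotype)), "mutant genotype(s)\n")
  invisible(x)
}

#' Simulate a count matrix from a design and truth table
#'
#' Counts are negative binomial with
#' `mean = lib_s * 2^(base_g + offsets + x_s' beta_g) / normalizer` and
#' `variance = mean + phi_g * mean^2`. The normalizer is the per-cell-type
#' baseline total `sum_g 2^(base_g + celltype offset)`, so planted effects
#' and batch offsets shift library composition rather than being normalized
#' away at generation time. The stimulation/mutant/interaction coefficients
#' apply to every non-baseline condition and to each mutant genotype as
#' recorded in the truth table.
#'
#' @param design a sample sheet from [simulate_design()].
#' @param truth a `truth_table` from [simulate_effects()].
#' @param config the [simulation_config()] used to create both.
#' @return integer matrix (genes x samples) with dimnames; attributes
#'   `lib_sizes` and `batch_offsets`.
#' @export
simulate_counts <- function(design, truth, config) {
  validate_simulation_config(config)
  stopifnot(inherits(truth, "truth_table"))
  ng <- nrow(truth$genes)
  ns <- nrow(design)
  if (!all(design$genotype %in% config$genotypes)) {
    stop("design and config genotypes are inconsistent")
  }

  sdlog <- sqrt(log(1 + config$lib_size_cv^2))
  lib <- stats::rlnorm(ns, log(config$lib_size_mean) - sdlog^2 / 2, sdlog)
  batch_levels <- sort(unique(design$experiment_id))
  batch_off <- stats::setNames(
    stats::rnorm(length(batch_levels), 0, config$batch_sd), batch_levels)
  batch_gene <- NULL
  if (config$batch_gene_sd > 0) {
    batch_gene <- matrix(stats::rnorm(ng * length(batch_levels), 0,
                                      config$batch_gene_sd),
                         ng, length(batch_levels),
                         dimnames = list(truth$genes$gene_id, batch_levels))
  }

  # per-mutant coefficient lookup
  eff_split <- split(truth$effects, truth$effects$genotype)

  counts <- matrix(0L, ng, ns,
                   dimnames = list(truth$genes$gene_id, design$sample_id))
  phi <- truth$genes$dispersion
  baseline_cond <- config$conditions[1]
  wild_type <- config$genotypes[1]

  for (s in seq_len(ns)) {
    ct <- design$cell_type[s]
    logmu <- truth$genes$base_log2 + truth$cell_type_offsets[, ct]
    stim <- design$condition[s] != baseline_cond
    geno <- design$genotype[s]
    if (geno != wild_type) {
      e <- eff_split[[geno]]
      logmu <- logmu + e$beta_mut + if (stim) e$beta_int else 0
    }
    if (stim) logmu <- logmu + eff_split[[1]]$beta_stim  # shared WT response
    normalizer <- sum(2^(truth$genes$base_log2 + truth$cell_type_offsets[, ct]))
    b <- design$experiment_id[s]
    logmu <- logmu + batch_off[[b]]
    if (!is.null(batch_gene)) logmu <- logmu + batch_gene[, b]
    mu <- lib[s] * 2^logmu / normalizer
    counts[, s] <- ifelse(
      phi < 1e-12,
      stats::rpois(ng, mu),
      stats::rnbinom(ng, size = 1 / phi, mu = mu)
    )
  }
  storage.mode(counts) <- "integer"
  attr(counts, "lib_sizes") <- stats::setNames(lib, design$sample_id)
  attr(counts, "batch_offsets") <- batch_off
  counts
}

#' Simulate a complete dataset
#'
#' Seeds the RNG from the configuration and runs [simulate_design()],
#' [simulate_effects()] and [simulate_counts()]. Identical configurations
#' give identical outputs.
#'
#' @param config a [simulation_config()].
#' @return list with `design`, `truth`, `counts` and the `config`.
#' @export
simulate_dataset <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  design <- simulate_design(config)
  truth <- simulate_effects(config)
  counts <- simulate_counts(design, truth, config)
  list(design = design, truth = truth, counts = counts, config = config)
}

#' Inject outlier samples into a count matrix
#'
#' Corrupts selected samples so that QC machinery can be tested against a
#' known answer. `shuffle_genes` permutes the gene values within each target
#' column (destroying its correlation with replicates while preserving the
#' count distribution); `swap_profile` replaces the column with counts
#' simulated from a different cell type's expected profile.
#'
#' @param counts genes x samples count matrix.
#' @param sample_ids columns to corrupt.
#' @param mode `"shuffle_genes"` or `"swap_profile"`.
#' @param design,truth,config required for `swap_profile` (to locate an
#'   alternative cell type and its expected profile).
#' @return list with `counts` (modified matrix) and `outliers` (named logical
#'   flags, the test oracle).
#' @export
inject_outliers <- function(counts, sample_ids,
                            mode = c("shuffle_genes", "swap_profile"),
                            design = NULL, truth = NULL, config = NULL) {
  mode <- match.arg(mode)
  missing_ids <- setdiff(sample_ids, colnames(counts))
  if (length(missing_ids)) {
    stop("unknown sample id(s): ", paste(missing_ids, collapse = ", "))
  }
  flags <- stats::setNames(colnames(counts) %in% sample_ids, colnames(counts))
  if (length(sample_ids) == 0) {
    return(list(counts = counts, outliers = flags))
  }
  if (mode == "shuffle_genes") {
    for (id in sample_ids) {
      counts[, id] <- counts[sample(nrow(counts)), id]
    }
  } else {
    if (is.null(design) || is.null(truth) || is.null(config)) {
      stop("swap_profile requires design, truth and config")
    }
    if (length(config$cell_types) < 2) {
      stop("swap_profile requires at least two cell types in the config")
    }
    for (id in sample_ids) {
      ct <- design$cell_type[design$sample_id == id]
      other <- setdiff(config$cell_types, ct)[1]
      logmu <- truth$genes$base_log2 + truth$cell_type_offsets[, other]
      mu <- sum(counts[, id]) * 2^logmu / sum(2^logmu)
      counts[, id] <- as.integer(stats::rnbinom(
        nrow(counts), size = 1 / pmax(truth$genes$dispersion, 1e-12), mu = mu))
    }
  }
  list(counts = counts, outliers = flags)
}
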