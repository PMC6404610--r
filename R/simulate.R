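# Negative-binomial count simulator with planted coexpression modules.
#
# Each planted module has a latent eigengene whose cell means follow one of
# the reaction-norm archetypes (shared plasticity, divergent baseline,
# evolved/divergent plasticity, non-plastic divergence, null); replicate
# noise on the eigengene is standard normal, so all effect sizes are in
# replicate-SD units.  Genes load on the eigengene on the log2 scale and
# counts are drawn NB after per-sample library-size scaling.

MODULE_CATEGORIES <- c("NULL", "SHARED_PLASTICITY", "DIVERGENT_BASELINE",
                       "EVOLVED_PLASTICITY", "NON_PLASTIC_DIVERGENCE")

#' Specify a planted coexpression module
#'
#' Effects left `NULL` are filled in from the category's default archetype
#' when the design is assembled (effect size 2 replicate SD):
#' * `SHARED_PLASTICITY`: temperature effect only — all populations respond
#'   identically to the high temperature.
#' * `DIVERGENT_BASELINE`: temperature effect plus population shifts in
#'   baseline (stress populations displaced in opposite directions), no
#'   interaction.
#' * `EVOLVED_PLASTICITY`: populations respond to the high temperature in
#'   opposite directions (first half +, second half -), i.e. a pure
#'   population-by-temperature interaction.
#' * `NON_PLASTIC_DIVERGENCE`: population shifts only.
#' * `NULL`: no effects; the module is held together only by shared
#'   replicate noise on its eigengene.
#'
#' @param size Number of genes in the module (>= 1).
#' @param category One of `r paste(MODULE_CATEGORIES, collapse=", ")`.
#' @param temperature_effect Eigengene shift (replicate-SD units) added at
#'   the high temperature.
#' @param population_effects Numeric vector, one shift per population.
#' @param interaction_effects Either a vector (one value per population,
#'   applied at the high temperature) or a populations x temperatures matrix.
#' @param loading_mean,loading_sd Gene loadings on the eigengene are drawn
#'   `N(loading_mean, loading_sd)`; `loading_mean` in (0, 1].
#' @param within_module_noise_sd Log2-scale gene-level noise SD.
#' @return A `module_spec` list.
#' @export
module_spec <- function(size,
                        category = "NULL",
                        temperature_effect = NULL,
                        population_effects = NULL,
                        interaction_effects = NULL,
                        loading_mean = 0.8,
                        loading_sd = 0.1,
                        within_module_noise_sd = 0.6) {
  category <- match.arg(category, MODULE_CATEGORIES)
  if (length(size) != 1L || size < 1) fail("module size must be >= 1")
  if (loading_mean <= 0 || loading_mean > 1)
    fail("loading_mean must be in (0, 1]")
  if (loading_sd < 0) fail("loading_sd must be non-negative")
  if (within_module_noise_sd < 0) fail("within_module_noise_sd must be >= 0")
  structure(list(size = as.integer(size), category = category,
                 temperature_effect = temperature_effect,
                 population_effects = population_effects,
                 interaction_effects = interaction_effects,
                 loading_mean = loading_mean, loading_sd = loading_sd,
                 within_module_noise_sd = within_module_noise_sd),
            class = "module_spec")
}

default_populations <- function(n) {
  base <- c("ancestor", "control", "heat", "oxidative")
  if (n <= 4L) base[seq_len(n)] else c(base, sprintf("pop%d", 5:n))
}

# fill in archetype effects and validate the category invariants
resolve_module_effects <- function(spec, populations, temperatures) {
  npop <- length(populations)
  ntmp <- length(temperatures)
  e <- 2  # default archetype effect size, replicate-SD units

  pop_divergence <- function() {
    eff <- rep(0, npop)
    if (npop >= 3) {
      idx <- 3:npop
      eff[idx] <- e * (-1)^(seq_along(idx) + 1)  # +e, -e, +e, ...
    } else if (npop == 2) eff[2] <- e
    else fail("population-divergent categories need >= 2 populations")
    eff
  }

  temp <- spec$temperature_effect
  pop <- spec$population_effects
  int <- spec$interaction_effects
  if (is.null(temp)) temp <- switch(spec$category,
    "SHARED_PLASTICITY" = e, "DIVERGENT_BASELINE" = e, 0)
  if (is.null(pop)) pop <- switch(spec$category,
    "DIVERGENT_BASELINE" = pop_divergence(),
    "NON_PLASTIC_DIVERGENCE" = pop_divergence(),
    rep(0, npop))
  if (is.null(int) && spec$category == "EVOLVED_PLASTICITY") {
    half <- ceiling(npop / 2)
    int <- c(rep(e, half), rep(-e, npop - half))
  }
  if (is.null(int)) int <- rep(0, npop)
  if (is.matrix(int)) {
    if (!all(dim(int) == c(npop, ntmp)))
      fail("interaction_effects matrix must be populations x temperatures")
    intm <- int
  } else {
    if (length(int) == 1L) int <- rep(int, npop)
    if (length(int) != npop)
      fail("interaction_effects must have one value per population")
    intm <- matrix(0, npop, ntmp)
    intm[, ntmp] <- int  # applied at the high temperature
  }
  if (length(pop) == 1L) pop <- rep(pop, npop)
  if (length(pop) != npop)
    fail("population_effects must have one value per population")

  if (spec$category == "NULL" &&
      (temp != 0 || any(pop != 0) || any(intm != 0)))
    fail("a NULL module must have all effects zero")
  if (spec$category == "SHARED_PLASTICITY") {
    if (any(pop != 0) || any(intm != 0))
      fail("SHARED_PLASTICITY requires zero population and interaction effects")
    if (temp == 0) fail("SHARED_PLASTICITY requires a nonzero temperature effect")
  }
  dimnames(intm) <- list(populations, as.character(temperatures))
  list(temperature_effect = temp,
       population_effects = stats::setNames(pop, populations),
       interaction_effects = intm)
}

#' Describe a simulation design
#'
#' The default layout mirrors a 4 population x 2 temperature x 6 replicate
#' RNA-seq experiment (48 samples; populations ancestor, control, heat,
#' oxidative; rearing temperatures 20 and 30).
#'
#' @param modules List of [module_spec()] objects (at least one).
#' @param n_background_genes Genes with no module loading.
#' @param n_populations,n_temperatures,n_replicates Crossed design sizes.
#' @param library_size_range Per-sample multiplicative library-size factors
#'   are drawn uniformly from this range.
#' @param nb_dispersion NB dispersion alpha (> 0); `size = 1/alpha`.
#' @param n_batch_factors,batch_effect_sd Latent batch factors: per-sample
#'   scores centred within treatment cells and scaled to unit SD; gene
#'   loadings `N(0, batch_effect_sd)` for all genes, background included.
#' @param background_noise_sd Log2-scale noise SD of background genes.
#' @param rng_seed Master seed; all draws are deterministic given it.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(modules,
                              n_background_genes = 0,
                              n_populations = 4,
                              n_temperatures = 2,
                              n_replicates = 6,
                              library_size_range = c(0.75, 1.33),
                              nb_dispersion = 0.05,
                              n_batch_factors = 0,
                              batch_effect_sd = 0,
                              background_noise_sd = 0.6,
                              rng_seed = 1) {
  if (inherits(modules, "module_spec")) modules <- list(modules)
  if (!length(modules)) fail("module list must not be empty")
  if (!all(vapply(modules, inherits, TRUE, "module_spec")))
    fail("modules must be a list of module_spec objects")
  if (nb_dispersion <= 0) fail("nb_dispersion must be positive")
  if (length(library_size_range) != 2L || any(library_size_range <= 0) ||
      diff(library_size_range) < 0)
    fail("library_size_range must be an increasing pair of positive reals")
  if (batch_effect_sd < 0) fail("batch_effect_sd must be non-negative")
  populations <- default_populations(n_populations)
  temperatures <- if (n_temperatures == 2) c(20, 30)
                  else 20 + 10 * seq_len(n_temperatures) - 10
  structure(list(modules = modules,
                 n_background_genes = as.integer(n_background_genes),
                 n_populations = as.integer(n_populations),
                 n_temperatures = as.integer(n_temperatures),
                 n_replicates = as.integer(n_replicates),
                 populations = populations, temperatures = temperatures,
                 library_size_range = library_size_range,
                 nb_dispersion = nb_dispersion,
                 n_batch_factors = as.integer(n_batch_factors),
                 batch_effect_sd = batch_effect_sd,
                 background_noise_sd = background_noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_design")
}

#' Simulate counts with planted modules
#'
#' Draws a gene x sample count matrix under the generative model described
#' in [module_spec()] / [simulation_design()], together with sample
#' metadata and the ground-truth tables downstream stages are tested
#' against.  Each module, the background block and each global component
#' draws from its own named RNG substream, so adding a module leaves every
#' other block's draws untouched.
#'
#' @param design A [simulation_design()].
#' @return List with elements `counts` (integer matrix, genes x samples),
#'   `metadata` (data.frame: sample_id, population, temperature, replicate),
#'   `truth` (gene_labels, module_categories, batch_factors,
#'   eigengene_targets) and `design`.
#' @export
simulate_counts <- function(design) {
  if (!inherits(design, "simulation_design"))
    fail("design must come from simulation_design()")
  seed <- design$rng_seed
  pops <- design$populations
  tmps <- design$temperatures
  reps <- design$n_replicates

  meta <- expand.grid(replicate = seq_len(reps),
                      temperature = tmps, population = pops,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[, c("population", "temperature", "replicate")]
  meta$sample_id <- sprintf("%s_%d_r%d", meta$population, meta$temperature,
                            meta$replicate)
  meta$population <- factor(meta$population, levels = pops)
  meta$temperature <- factor(meta$temperature, levels = tmps)
  n <- nrow(meta)
  cell <- interaction(meta$population, meta$temperature, drop = TRUE)

  nb_size <- 1 / design$nb_dispersion
  nbatch <- design$n_batch_factors

  # latent batch factors, centred within treatment cells (identifiable
  # separately from the design) and scaled to unit SD
  batch <- matrix(0, n, max(nbatch, 0),
                  dimnames = list(meta$sample_id,
                                  if (nbatch) sprintf("batch%d", seq_len(nbatch))))
  if (nbatch > 0) with_substream(seed, "batch", {
    for (b in seq_len(nbatch)) {
      v <- stats::rnorm(n)
      v <- v - stats::ave(v, cell)
      batch[, b] <- v / stats::sd(v)
    }
  })

  libsize <- with_substream(seed, "library-sizes",
    stats::runif(n, design$library_size_range[1], design$library_size_range[2]))

  cells <- expand.grid(population = pops, temperature = tmps,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cell_names <- sprintf("%s_%s", cells$population, cells$temperature)

  nmod <- length(design$modules)
  eigengene_targets <- matrix(0, nmod, nrow(cells),
                              dimnames = list(sprintf("module_%d", seq_len(nmod)),
                                              cell_names))

  sim_block <- function(size, mu0, lambda, e, noise_sd, stream) {
    # draws happen inside the caller's substream; e may be NULL (background)
    W <- matrix(stats::rnorm(size * nbatch, 0, design$batch_effect_sd),
                size, max(nbatch, 0))
    eps <- matrix(stats::rnorm(size * n, 0, noise_sd), size, n)
    logmean <- matrix(mu0, size, n) + eps
    if (!is.null(e)) logmean <- logmean + outer(lambda, e)
    if (nbatch > 0) logmean <- logmean + W %*% t(batch)
    mu <- sweep(2^logmean, 2, libsize, "*")
    matrix(stats::rnbinom(size * n, mu = mu, size = nb_size), size, n)
  }

  blocks <- vector("list", nmod + 1L)
  labels <- integer(0)
  for (i in seq_len(nmod)) {
    spec <- design$modules[[i]]
    eff <- resolve_module_effects(spec, pops, tmps)
    target <- eff$temperature_effect * (cells$temperature == tmps[length(tmps)]) +
      eff$population_effects[cells$population] +
      eff$interaction_effects[cbind(cells$population, as.character(cells$temperature))]
    eigengene_targets[i, ] <- target
    sample_cell <- match(sprintf("%s_%s", meta$population, meta$temperature),
                         cell_names)
    blocks[[i]] <- with_substream(seed, sprintf("module-%d", i), {
      e <- target[sample_cell] + stats::rnorm(n)
      lambda <- stats::rnorm(spec$size, spec$loading_mean, spec$loading_sd)
      mu0 <- stats::runif(spec$size, 5, 9)
      sim_block(spec$size, mu0, lambda, e, spec$within_module_noise_sd)
    })
    labels <- c(labels, rep(i, spec$size))
  }
  if (design$n_background_genes > 0) {
    blocks[[nmod + 1L]] <- with_substream(seed, "background", {
      mu0 <- stats::runif(design$n_background_genes, 5, 9)
      sim_block(design$n_background_genes, mu0, NULL, NULL,
                design$background_noise_sd)
    })
    labels <- c(labels, rep(0L, design$n_background_genes))
  }

  counts <- do.call(rbind, blocks[!vapply(blocks, is.null, TRUE)])
  sizes <- vapply(design$modules, function(m) m$size, 1L)
  gene_ids <- c(unlist(lapply(seq_len(nmod), function(i)
                  sprintf("mod%d_g%04d", i, seq_len(sizes[i])))),
                if (design$n_background_genes > 0)
                  sprintf("bg_g%04d", seq_len(design$n_background_genes)))
  dimnames(counts) <- list(gene_ids, meta$sample_id)
  storage.mode(counts) <- "integer"

  truth <- list(
    gene_labels = stats::setNames(labels, gene_ids),
    module_categories = stats::setNames(
      vapply(design$modules, function(m) m$category, ""),
      sprintf("module_%d", seq_len(nmod))),
    batch_factors = batch,
    eigengene_targets = eigengene_targets)
  structure(list(counts = counts,
                 metadata = meta[, c("sample_id", "population", "temperature",
                                     "replicate")],
                 truth = truth, design = design),
            class = "coex_sim")
}

#' @export
print.coex_sim <- function(x, ...) {
  cat(sprintf("Simulated counts: %d genes x %d samples (%d modules, %d background)\n",
              nrow(x$counts), ncol(x$counts), length(x$design$modules),
              x$design$n_background_genes))
  invisible(x)
}

#' Compare an inferred module assignment with the planted truth
#'
#' @param inferred Named integer vector, gene -> module label (0 =
#'   unassigned), over the same gene universe as the truth.
#' @param truth Either the `truth` element of a [simulate_counts()] result
#'   or a named label vector of planted labels.
#' @return List with `ari` (adjusted Rand index over genes assigned in both
#'   partitions), `per_module` (precision/recall of the best-matching
#'   inferred module for every planted module), and
#'   `background_unassigned` (fraction of planted background genes left
#'   unassigned).
#' @export
evaluate_recovery <- function(inferred, truth) {
  planted <- if (is.list(truth)) truth$gene_labels else truth
  if (is.null(names(inferred)) || is.null(names(planted)))
    fail("inferred and planted labels must be named by gene")
  common <- intersect(names(inferred), names(planted))
  if (!length(common)) fail("inferred and truth gene universes are disjoint")
  inferred <- inferred[common]
  planted <- planted[common]

  both <- inferred > 0 & planted > 0
  ari <- if (any(both))
    mclust::adjustedRandIndex(inferred[both], planted[both]) else NA_real_

  mods <- sort(unique(planted[planted > 0]))
  per_module <- do.call(rbind, lapply(mods, function(m) {
    genes_m <- common[planted == m]
    hits <- inferred[genes_m]
    hits <- hits[hits > 0]
    if (!length(hits))
      return(data.frame(planted_module = m, best_inferred = NA_integer_,
                        overlap = 0L, precision = 0, recall = 0))
    tab <- table(hits)
    best <- as.integer(names(tab)[which.max(tab)])
    ov <- max(tab)
    data.frame(planted_module = m, best_inferred = best, overlap = as.integer(ov),
               precision = ov / sum(inferred == best),
               recall = ov / length(genes_m))
  }))
  bg <- planted == 0
  structure(list(ari = ari, per_module = per_module,
                 background_unassigned = if (any(bg)) mean(inferred[bg] == 0)
                                         else NA_real_,
                 n_genes = length(common)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery: ARI = %.3f (genes assigned in both partitions); background unassigned = %s\n",
              x$ari,
              ifelse(is.na(x$background_unassigned), "NA",
                     sprintf("%.1f%%", 100 * x$background_unassigned))))
  print(x$per_module)
  invisible(x)
}

#' Write a simulation to disk as plain-text tables
#'
#' Writes counts, metadata, truth labels, eigengene targets, batch factors
#' (TSV) and the planted module gene sets (GMT, for exercising enrichment
#' end to end).
#'
#' @param sim A [simulate_counts()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "coex_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             labels = file.path(dir, "truth_labels.tsv"),
             targets = file.path(dir, "truth_eigengene_targets.tsv"),
             batch = file.path(dir, "truth_batch_factors.tsv"),
             gmt = file.path(dir, "planted_modules.gmt"))
  write_tsv_matrix(sim$counts, paths["counts"], "gene")
  utils::write.table(sim$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = names(sim$truth$gene_labels),
                                module = sim$truth$gene_labels),
                     paths["labels"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_tsv_matrix(sim$truth$eigengene_targets, paths["targets"], "module")
  write_tsv_matrix(sim$truth$batch_factors, paths["batch"], "sample_id")
  sets <- split(names(sim$truth$gene_labels), sim$truth$gene_labels)
  sets <- sets[names(sets) != "0"]
  names(sets) <- sprintf("module_%s", names(sets))
  write_gene_sets(sets, paths["gmt"])
  invisible(paths)
}

write_tsv_matrix <- function(x, path, id_col) {
  df <- data.frame(rownames(x), as.data.frame(x), check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
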