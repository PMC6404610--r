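# Pipeline orchestration: input validation, configuration with study
# defaults, stage-wise artifacts and deterministic per-stage seeds.

#' Default pipeline configuration
#'
#' All stage parameters with their study defaults: 40% variance filter,
#' signed power-5 network, cut height 0.905 / deepSplit 2 / minimum
#' module size 30, 100 resamples keeping 4 of 6 replicates per cell with
#' the 10% group and 70% retention criteria, eigengene merge at r > 0.9,
#' 5-dimensional nMDS, 1000 PERMANOVA permutations, alpha 0.05.
#'
#' @param ... Overrides for individual keys (unknown keys are rejected).
#' @return Named list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(drop_fraction = 0.40, vst_dialect = "shifted-log",
              dispersion = 0.05, n_sv = "auto", include_interaction = TRUE,
              beta = 5, cor_method = "pearson", cut_height = 0.905,
              deep_split = 2, min_cluster_size = 30, pam_stage = TRUE,
              n_resamples = 100, kept_per_cell = 4, min_fraction = 0.10,
              retention_threshold = 0.70, merge_r = 0.9, nmds_k = 5,
              n_restarts = 20, n_perm = 1000, alpha = 0.05,
              include_unassigned = TRUE, seed = 1)
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) || is.null(names(over)) || any(names(over) == ""))
      fail("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

#' Read a pipeline configuration file
#'
#' YAML key-value file; keys must match [default_config()].
#'
#' @param path Path to the YAML file.
#' @return Config list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Read a counts TSV (first column gene id, header sample ids)
#' @param path Path to the file.
#' @return Integer gene x sample matrix.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read a sample-metadata TSV
#' @param path Path to the file (columns sample_id, population,
#'   temperature, replicate).
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  utils::read.delim(path, check.names = FALSE,
                    colClasses = c(sample_id = "character"))
}

#' Validate counts and metadata before running the pipeline
#'
#' Checks sample-id agreement, duplicate ids, negative and non-integer
#' counts, factor levels and replicate structure.  Never leaves partial
#' state: everything is reported, errors separated from warnings.
#'
#' @param counts Gene x sample matrix.
#' @param meta Metadata data frame.
#' @return List of class `validation_report` with `errors` and
#'   `warnings` character vectors; valid input has zero errors.
#' @export
validate_inputs <- function(counts, meta) {
  errors <- character(0); warnings_ <- character(0)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) errors <- c(errors, "counts lack gene ids")
  if (is.null(colnames(counts))) errors <- c(errors, "counts lack sample ids")
  if (!is.null(rownames(counts)) && anyDuplicated(rownames(counts)))
    errors <- c(errors, paste0("duplicated gene ids: ",
      paste(utils::head(unique(rownames(counts)[duplicated(rownames(counts))]), 5),
            collapse = ", ")))
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg))
    errors <- c(errors, paste0("negative counts at ",
      paste(sprintf("%s/%s", rownames(counts)[neg[, 1]],
                    colnames(counts)[neg[, 2]])[seq_len(min(5, nrow(neg)))],
            collapse = ", ")))
  if (any(counts %% 1 != 0))
    warnings_ <- c(warnings_, "non-integer counts present")
  need <- c("sample_id", "population", "temperature", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    errors <- c(errors, paste0("metadata lacks columns: ",
                               paste(miss, collapse = ", ")))
  } else {
    if (anyDuplicated(meta$sample_id))
      errors <- c(errors, "duplicated sample_id in metadata")
    only_counts <- setdiff(colnames(counts), meta$sample_id)
    if (length(only_counts))
      errors <- c(errors, paste0("samples in counts but not metadata: ",
                                 paste(only_counts, collapse = ", ")))
    only_meta <- setdiff(meta$sample_id, colnames(counts))
    if (length(only_meta))
      errors <- c(errors, paste0("samples in metadata but not counts: ",
                                 paste(only_meta, collapse = ", ")))
    if (length(unique(meta$temperature)) < 2)
      warnings_ <- c(warnings_, "fewer than 2 temperature levels")
    if (length(unique(meta$population)) < 2)
      warnings_ <- c(warnings_, "fewer than 2 populations")
  }
  structure(list(errors = errors, warnings = warnings_),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (!length(x$errors) && !length(x$warnings)) cat("inputs valid\n")
  for (e in x$errors) cat("error: ", e, "\n", sep = "")
  for (w in x$warnings) cat("warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Preprocess -> ordination/PERMANOVA -> network + stability filtering ->
#' eigengene statistics -> (optional) gene-set enrichment.  Every stage
#' writes TSV artifacts into `out_dir`, the configuration is echoed, and
#' per-stage seeds are derived deterministically from the global seed, so
#' re-running with identical config and inputs reproduces identical
#' artifacts.
#'
#' @param counts Gene x sample count matrix (or a TSV path).
#' @param meta Sample metadata (or a TSV path).
#' @param out_dir Output directory.
#' @param config Parameter list from [default_config()].
#' @param gene_sets Optional named list of gene-set collections (or a
#'   single GMT path).
#' @param homolog_map Optional two-column data frame (or TSV path) used
#'   to expand `gene_sets` before testing.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the stage results and the artifact
#'   `manifest`.
#' @export
run_pipeline <- function(counts, meta, out_dir, config = default_config(),
                         gene_sets = NULL, homolog_map = NULL, quiet = FALSE) {
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(meta)) meta <- read_metadata(meta)
  if (is.character(gene_sets)) gene_sets <- list(sets = read_gene_sets(gene_sets))
  if (is.character(homolog_map)) homolog_map <- utils::read.delim(homolog_map)
  say <- function(...) if (!quiet) message(...)

  rep_ <- validate_inputs(counts, meta)
  if (length(rep_$errors))
    fail("invalid inputs:\n", paste(rep_$errors, collapse = "\n"))
  for (w in rep_$warnings) warning(w, call. = FALSE)
  meta <- check_metadata(meta, counts)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  put <- function(name) {
    p <- file.path(out_dir, name)
    artifacts <<- c(artifacts, p)
    p
  }
  seed <- config$seed

  yaml::write_yaml(config, put("config.yaml"))

  say("preprocess: normalize, vst, variance filter, surrogate variables")
  prep <- preprocess(counts, meta, drop_fraction = config$drop_fraction,
                     vst_dialect = config$vst_dialect,
                     dispersion = config$dispersion, n_sv = config$n_sv,
                     include_interaction = config$include_interaction,
                     seed = derive_seed(seed, "preprocess"))
  write_tsv_matrix(prep$expr, put("expression.tsv"), "gene")
  if (!is.null(prep$sv) && ncol(prep$sv))
    write_tsv_matrix(prep$sv, put("surrogate_variables.tsv"), "sample_id")

  say("ordination: Bray-Curtis, nMDS, PERMANOVA")
  d <- bray_curtis(prep$expr)
  ord <- nmds_ordination(d, k = config$nmds_k,
                         n_restarts = config$n_restarts,
                         seed = derive_seed(seed, "nmds"))
  scores <- ord$scores
  write_tsv_matrix(scores, put("nmds_scores.tsv"), "sample_id")
  perm <- permanova(d, meta, n_perm = config$n_perm,
                    seed = derive_seed(seed, "permanova"))
  utils::write.table(data.frame(term = rownames(perm), perm),
                     put("permanova.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  say("network + stability: ", config$n_resamples, " resamples")
  stab <- stable_modules(prep$expr, meta, n_resamples = config$n_resamples,
                         kept_per_cell = config$kept_per_cell,
                         seed = derive_seed(seed, "stability"),
                         beta = config$beta, cor_method = config$cor_method,
                         cut_height = config$cut_height,
                         deep_split = config$deep_split,
                         min_cluster_size = config$min_cluster_size,
                         pam_stage = config$pam_stage,
                         min_fraction = config$min_fraction,
                         retention_threshold = config$retention_threshold,
                         merge_r = config$merge_r)
  utils::write.table(data.frame(gene = names(stab$labels),
                                module = as.integer(stab$labels)),
                     put("module_labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(stab$retention, put("retention.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(stab$plan$sample_ids, put("resample_plan.json"))

  say("eigengene statistics")
  stats_out <- NULL
  if (stab$n_modules > 0) {
    stats_out <- module_statistics(prep$expr, stab$labels, meta,
                                   alpha = config$alpha,
                                   include_unassigned = config$include_unassigned)
    write_tsv_matrix(stats_out$eigengenes, put("eigengenes.tsv"), "sample_id")
    utils::write.table(stats_out$summary, put("module_statistics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  enr <- NULL
  if (!is.null(gene_sets) && stab$n_modules > 0) {
    say("gene-set enrichment")
    if (!is.null(homolog_map))
      gene_sets <- lapply(gene_sets, expand_homologs, map = homolog_map)
    enr <- enrich_all(stab$labels, gene_sets,
                      universe = rownames(prep$expr))
    utils::write.table(enr, put("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  manifest <- data.frame(artifact = basename(artifacts), path = artifacts)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("done: ", nrow(manifest), " artifacts in ", out_dir)
  invisible(list(preprocess = prep, dissimilarity = d, ordination = ord,
                 permanova = perm, modules = stab, statistics = stats_out,
                 enrichment = enr, manifest = manifest))
}
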