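# Resampling-based module stability: rebuild the network on subsampled
# replicate sets, credit genes that land in well-supported groups of their
# full-network module, retain consistently credited genes, then merge
# correlated modules and purge undersized ones.

#' Plan replicate resamples
#'
#' Each resample keeps `kept_per_cell` replicates, drawn uniformly without
#' replacement, from every population x temperature cell (independently
#' across cells and resamples).
#'
#' @param meta Sample metadata.
#' @param n_resamples Number of resampled datasets (default 100).
#' @param kept_per_cell Replicates kept per treatment cell (default 4).
#' @param seed RNG seed; the plan is deterministic given it.
#' @return List of class `resample_plan`: `sample_ids` (list of character
#'   vectors), `n_resamples`, `kept_per_cell`, `seed`.
#' @export
make_resample_plan <- function(meta, n_resamples = 100, kept_per_cell = 4,
                               seed = 1) {
  meta <- check_metadata(meta)
  cell <- interaction(meta$population, meta$temperature, drop = TRUE)
  sizes <- table(cell)
  small <- sizes < kept_per_cell
  if (any(small))
    fail("treatment cells with fewer than ", kept_per_cell, " replicates: ",
         paste(names(sizes)[small], collapse = ", "))
  ids_by_cell <- split(meta$sample_id, cell)
  sample_ids <- with_substream(seed, "resample-plan", {
    lapply(seq_len(n_resamples), function(i) {
      unlist(lapply(ids_by_cell, function(ids)
        sample(ids, kept_per_cell)), use.names = FALSE)
    })
  })
  structure(list(sample_ids = sample_ids, n_resamples = n_resamples,
                 kept_per_cell = kept_per_cell, seed = seed),
            class = "resample_plan")
}

#' Well-supported groups of the full-network modules
#'
#' For a module `r` of a resampled network and a module `f` of the full
#' network: if the overlap holds at least `min_fraction` of `f`'s genes,
#' the genes of the overlap form a significant group of `f` and are
#' credited to it for this resample.  One resampled module may credit
#' several full modules; unassigned genes never match.
#'
#' @param resampled,full Named integer label vectors over the same genes.
#' @param min_fraction Overlap threshold as a fraction of the full
#'   module's size (default 0.10).
#' @return Named list: full-module label -> character vector of credited
#'   genes.
#' @export
significant_groups <- function(resampled, full, min_fraction = 0.10) {
  if (!setequal(names(resampled), names(full)))
    fail("resampled and full assignments cover different gene universes")
  resampled <- resampled[names(full)]
  full_sizes <- table(full[full > 0])
  both <- resampled > 0 & full > 0
  out <- lapply(names(full_sizes), function(f) character(0))
  names(out) <- names(full_sizes)
  if (!any(both)) return(out)
  genes <- names(full)[both]
  key <- paste(resampled[both], full[both])
  ov <- split(genes, key)
  for (k in names(ov)) {
    f <- sub("^\\S+ ", "", k)
    if (length(ov[[k]]) >= min_fraction * full_sizes[[f]])
      out[[f]] <- c(out[[f]], ov[[k]])
  }
  out
}

#' Apply the retention criterion
#'
#' A gene keeps its full-network label iff it was credited to that label
#' in at least `threshold * n_resamples` resamples; all other genes
#' (including genes unassigned in the full network) become unassigned.
#'
#' @param credits Named integer vector: per gene, the number of resamples
#'   in which it fell in a significant group of its full-network module.
#' @param full Named integer full-network label vector.
#' @param n_resamples Number of resamples behind `credits`.
#' @param threshold Retention fraction (default 0.70).
#' @return List: `labels` (retained assignment) and `retention` (data
#'   frame gene, full_module, credits, fraction, retained).
#' @export
apply_retention <- function(credits, full, n_resamples, threshold = 0.70) {
  if (n_resamples < 1) fail("n_resamples must be >= 1")
  credits <- credits[names(full)]
  credits[is.na(credits)] <- 0L
  retained <- full > 0 & credits >= threshold * n_resamples - 1e-9
  labels <- ifelse(retained, full, 0L)
  names(labels) <- names(full)
  retention <- data.frame(gene = names(full), full_module = as.integer(full),
                          credits = as.integer(credits),
                          fraction = as.numeric(credits) / n_resamples,
                          retained = retained, row.names = NULL)
  list(labels = labels, retention = retention)
}

#' Merge modules with highly correlated eigengenes
#'
#' Modules whose eigengene Pearson correlation exceeds `r_threshold` are
#' grouped by connected components of the thresholded correlation graph
#' (single-linkage chaining) and merged.  Because merging changes
#' eigengenes, the procedure recomputes them and iterates to a fixed
#' point by default.
#'
#' @param expr Genes x samples expression matrix.
#' @param labels Named integer label vector.
#' @param r_threshold Merge when eigengene `r > r_threshold` (default 0.9).
#' @param iterate Repeat until no pair exceeds the threshold.
#' @return Relabelled vector (numbered by decreasing size).
#' @export
merge_correlated_modules <- function(expr, labels, r_threshold = 0.9,
                                     iterate = TRUE) {
  if (!any(labels > 0)) return(labels)
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    E <- vapply(mods, function(mm)
      module_eigengene(expr, names(labels)[labels == mm])$eigengene,
      numeric(ncol(expr)))
    r <- stats::cor(E)
    adj <- r > r_threshold
    diag(adj) <- FALSE
    if (!any(adj)) break
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    new <- labels
    for (i in seq_along(mods)) new[labels == mods[i]] <- comp[i]
    labels <- new
    if (!iterate) break
  }
  out <- renumber_modules(labels)
  stats::setNames(out, names(labels))
}

#' Dissolve undersized modules
#'
#' Modules with fewer than `min_size` genes are moved to the unassigned
#' bin; the survivors are renumbered by decreasing size.
#'
#' @param labels Named integer label vector.
#' @param min_size Minimum module size (default 30).
#' @return Relabelled vector.
#' @export
enforce_min_size <- function(labels, min_size = 30) {
  mods <- unique(labels[labels > 0])
  for (mm in mods) if (sum(labels == mm) < min_size) labels[labels == mm] <- 0L
  out <- renumber_modules(labels)
  stats::setNames(out, names(labels))
}

#' Stability-filtered module detection
#'
#' Full procedure: build the network on all samples, rebuild it on each
#' planned resample with the same parameters, credit genes per
#' [significant_groups()], retain per [apply_retention()], merge
#' correlated modules and purge undersized ones.
#'
#' @param expr Genes x samples expression matrix.
#' @param meta Sample metadata.
#' @param n_resamples,kept_per_cell,seed Passed to [make_resample_plan()]
#'   (ignored when `plan` is given).
#' @param plan Optional precomputed [make_resample_plan()].
#' @param beta,cor_method,cut_height,deep_split,min_cluster_size,pam_stage
#'   Network parameters, reused for every resample.
#' @param min_fraction Significant-group threshold (default 0.10).
#' @param retention_threshold Retention fraction (default 0.70).
#' @param merge_r Eigengene merge threshold (default 0.9).
#' @param progress Emit a message per resample.
#' @return List of class `stable_modules`: `labels` (final assignment),
#'   `full_labels`, `retention` (per-gene table with final labels),
#'   `plan`, `n_modules`.
#' @export
stable_modules <- function(expr, meta, n_resamples = 100, kept_per_cell = 4,
                           seed = 1, plan = NULL, beta = 5,
                           cor_method = "pearson", cut_height = 0.905,
                           deep_split = 2, min_cluster_size = 30,
                           pam_stage = TRUE, min_fraction = 0.10,
                           retention_threshold = 0.70, merge_r = 0.9,
                           progress = FALSE) {
  meta <- check_metadata(meta, expr)
  plan <- plan %||% make_resample_plan(meta, n_resamples = n_resamples,
                                       kept_per_cell = kept_per_cell,
                                       seed = seed)
  net <- function(e) network_modules(e, beta = beta, cor_method = cor_method,
                                     cut_height = cut_height,
                                     deep_split = deep_split,
                                     min_cluster_size = min_cluster_size,
                                     pam_stage = pam_stage)
  full <- net(expr)
  credits <- stats::setNames(integer(length(full)), names(full))
  for (i in seq_along(plan$sample_ids)) {
    if (progress) message("resample ", i, "/", length(plan$sample_ids))
    res <- net(keep_log(expr[, plan$sample_ids[[i]], drop = FALSE], expr))
    groups <- significant_groups(res, full, min_fraction = min_fraction)
    credited <- unlist(groups, use.names = FALSE)
    credits[credited] <- credits[credited] + 1L
  }
  ret <- apply_retention(credits, full, length(plan$sample_ids),
                         threshold = retention_threshold)
  labels <- merge_correlated_modules(expr, ret$labels, r_threshold = merge_r)
  labels <- enforce_min_size(labels, min_size = min_cluster_size)
  retention <- ret$retention
  retention$final_label <- as.integer(labels[retention$gene])
  structure(list(labels = labels, full_labels = full, retention = retention,
                 plan = plan, n_modules = max(labels)),
            class = "stable_modules")
}

#' @export
print.stable_modules <- function(x, ...) {
  sizes <- table(x$labels[x$labels > 0])
  cat(sprintf("Stable modules: %d modules, %d genes assigned, %d unassigned\n",
              x$n_modules, sum(x$labels > 0), sum(x$labels == 0)))
  if (length(sizes)) print(sizes)
  invisible(x)
}
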