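# Gene-set handling (GMT, homolog expansion) and one-tailed Fisher
# enrichment of sets in modules with Benjamini-Hochberg FDR control.

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-delimited GMT file (set name, description,
#'   then member genes).
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description column (defaults to
#'   the set name).
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    fail("gene sets must be named")
  descriptions <- descriptions %||% names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Expand gene sets through a homolog map
#'
#' Each set's members are replaced by the union of all mapped
#' target-species genes (one-to-many maps contribute every homolog; two
#' sources sharing a target contribute it once).  Source genes with no
#' mapping are dropped; per-set mapping coverage is reported in the
#' `coverage` attribute.  Empty mapped sets are kept (flagged in the
#' coverage table), not silently dropped.
#'
#' @param sets Named list of source-species gene sets.
#' @param map Two-column data frame (source id, target id); duplicate
#'   pairs are ignored.
#' @return Named list of target-species gene sets, with attributes
#'   `coverage` (data frame) and `universe` (all mapped target genes).
#' @export
expand_homologs <- function(sets, map) {
  if (!is.data.frame(map) || ncol(map) < 2 || nrow(map) == 0)
    fail("homolog map must be a nonempty two-column data frame")
  map <- unique(data.frame(source = as.character(map[[1]]),
                           target = as.character(map[[2]])))
  by_source <- split(map$target, map$source)
  out <- lapply(sets, function(s) {
    as.character(unique(unlist(by_source[intersect(s, names(by_source))],
                               use.names = FALSE)))
  })
  coverage <- data.frame(
    set = names(sets),
    n_source = vapply(sets, length, 1L),
    n_mapped_source = vapply(sets, function(s)
      sum(s %in% names(by_source)), 1L),
    n_target = vapply(out, length, 1L), row.names = NULL)
  attr(out, "coverage") <- coverage
  attr(out, "universe") <- unique(map$target)
  out
}

#' One-tailed Fisher enrichment of a gene set in a module
#'
#' Upper-tail hypergeometric test of over-representation on the 2x2 table
#' (in module & in set, in module only, in set only, neither).  The odds
#' ratio is `a*d / (b*c)`, with `Inf` when `b*c = 0` and `a*d > 0`.
#'
#' @param module,geneset Character vectors of gene ids (clipped to the
#'   universe).
#' @param universe Character vector of testable genes (nonempty).
#' @return List: `odds_ratio`, `p`, `table` (named counts a, b, c, d).
#' @export
fisher_enrichment <- function(module, geneset, universe) {
  universe <- unique(universe)
  if (!length(universe)) fail("empty universe")
  module <- intersect(module, universe)
  geneset <- intersect(geneset, universe)
  N <- length(universe)
  a <- length(intersect(module, geneset))
  b <- length(module) - a
  cc <- length(geneset) - a
  d <- N - a - b - cc
  p <- stats::phyper(a - 1, length(geneset), N - length(geneset),
                     length(module), lower.tail = FALSE)
  or <- if (b * cc == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * cc)
  list(odds_ratio = or, p = p,
       table = c(a = a, b = b, c = cc, d = d))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment, order-preserving with the input.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    fail("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Enrichment of gene-set collections across all modules
#'
#' Runs [fisher_enrichment()] for every (module, set) pair and controls
#' the FDR within each collection (all sets of a collection across all
#' modules share one BH adjustment).
#'
#' @param labels Named integer module assignment (0 = unassigned).
#' @param collections Named list of collections, each a named list of
#'   gene sets; a single unnested collection is accepted and named
#'   `"sets"`.
#' @param universe Testable gene universe; defaults to the genes of
#'   `labels`.
#' @param include_unassigned Test the unassigned bin as a module.
#' @return Data frame with columns collection, set, module, a, b, c, d,
#'   module_size, set_size, universe_size, odds_ratio, p, q.
#' @export
enrich_all <- function(labels, collections, universe = NULL,
                       include_unassigned = FALSE) {
  if (!any(labels > 0)) fail("no modules in the assignment")
  if (!is.list(collections[[1]])) collections <- list(sets = collections)
  universe <- universe %||% names(labels)
  mods <- as.character(sort(unique(labels[labels > 0])))
  groups <- lapply(mods, function(mm)
    names(labels)[labels == as.integer(mm)])
  names(groups) <- mods
  if (include_unassigned) groups$unassigned <- names(labels)[labels == 0]
  rows <- list()
  for (coll in names(collections)) {
    for (set in names(collections[[coll]])) {
      for (mm in names(groups)) {
        fe <- fisher_enrichment(groups[[mm]], collections[[coll]][[set]],
                                universe)
        rows[[length(rows) + 1L]] <- data.frame(
          collection = coll, set = set, module = mm,
          a = fe$table[["a"]], b = fe$table[["b"]], c = fe$table[["c"]],
          d = fe$table[["d"]],
          module_size = fe$table[["a"]] + fe$table[["b"]],
          set_size = fe$table[["a"]] + fe$table[["c"]],
          universe_size = length(unique(universe)),
          odds_ratio = fe$odds_ratio, p = fe$p)
      }
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- NA_real_
  for (coll in unique(out$collection)) {
    idx <- out$collection == coll
    out$q[idx] <- bh_fdr(out$p[idx])
  }
  out
}
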