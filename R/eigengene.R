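# Module eigengenes and their statistical characterisation: variance
# explained, ancestor environment t-test, two-way ANOVA, Tukey HSD with
# compact letter display, and reaction-norm classification.

REACTION_NORM_CATEGORIES <- c("SHARED_PLASTICITY", "DIVERGENT_BASELINE",
                              "EVOLVED_OR_DIVERGENT_PLASTICITY",
                              "NON_PLASTIC_DIVERGENCE", "NO_SIGNAL")

#' Module eigengene (first principal component)
#'
#' Genes are standardised (centred, unit variance) and the first right
#' singular vector gives the per-sample eigengene scores (unit norm); the
#' sign is chosen so the eigengene correlates positively with the
#' module's mean standardised expression.
#'
#' @param expr Genes x samples matrix.
#' @param genes Character vector of module gene ids (>= 2).
#' @return List: `eigengene` (named unit-norm scores),
#'   `pct_variance_pc1`, `pct_variance_pc2` (percent of module variance),
#'   `orientation_sign`.
#' @export
module_eigengene <- function(expr, genes) {
  if (length(genes) < 2) fail("a module needs at least 2 genes")
  miss <- setdiff(genes, rownames(expr))
  if (length(miss)) fail("genes absent from expression matrix: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  x <- expr[genes, , drop = FALSE]
  sds <- row_sds(x)
  if (all(sds == 0)) fail("module is all-constant; eigengene undefined")
  if (any(sds == 0)) fail("constant genes in module: ",
                          paste(utils::head(genes[sds == 0], 5), collapse = ", "))
  xs <- (x - rowMeans(x)) / sds
  s <- svd(xs, nu = 0)
  scores <- s$v[, 1]
  pct <- 100 * s$d^2 / sum(s$d^2)
  ref <- colMeans(xs)
  orient <- sum(scores * (ref - mean(ref)))
  sign <- if (abs(orient) > 1e-12) sign(orient)
          else if (scores[which.max(abs(scores))] >= 0) 1 else -1
  scores <- scores * sign
  list(eigengene = stats::setNames(scores, colnames(expr)),
       pct_variance_pc1 = pct[1],
       pct_variance_pc2 = if (length(pct) > 1) pct[2] else 0,
       orientation_sign = sign)
}

#' Eigengenes for every module of an assignment
#'
#' @param expr Genes x samples matrix.
#' @param labels Named integer label vector (0 = unassigned).
#' @param include_unassigned Also compute an eigengene over the
#'   unassigned bin (column `"unassigned"`).
#' @return Samples x modules matrix of eigengene scores, with variance
#'   percentages in attributes `pct_variance_pc1` / `pct_variance_pc2`.
#' @export
module_eigengenes <- function(expr, labels, include_unassigned = FALSE) {
  mods <- sort(unique(labels[labels > 0]))
  groups <- lapply(mods, function(mm) names(labels)[labels == mm])
  names(groups) <- sprintf("M%d", mods)
  if (include_unassigned && sum(labels == 0) >= 2)
    groups$unassigned <- names(labels)[labels == 0]
  egs <- lapply(groups, function(g) module_eigengene(expr, g))
  out <- vapply(egs, function(e) e$eigengene, numeric(ncol(expr)))
  attr(out, "pct_variance_pc1") <- vapply(egs, `[[`, 1, "pct_variance_pc1")
  attr(out, "pct_variance_pc2") <- vapply(egs, `[[`, 1, "pct_variance_pc2")
  out
}

#' Ancestor environment t-test on an eigengene
#'
#' Two-sample t-test of eigengene scores between the two temperatures
#' within the ancestral population (pooled-variance Student's t by
#' default; Welch behind `dialect`).
#'
#' @param eigengene Named per-sample scores.
#' @param meta Sample metadata.
#' @param population Population tested (default `"ancestor"`).
#' @param dialect `"pooled"` (default) or `"welch"`.
#' @return List `t`, `df`, `p` (two-sided).
#' @export
ancestor_ttest <- function(eigengene, meta, population = "ancestor",
                           dialect = c("pooled", "welch")) {
  dialect <- match.arg(dialect)
  meta <- check_metadata(meta)
  keep <- meta$population == population
  if (!any(keep)) fail("no samples for population '", population, "'")
  e <- eigengene[meta$sample_id[keep]]
  tmp <- droplevels(meta$temperature[keep])
  if (nlevels(tmp) != 2) fail("need exactly 2 temperatures")
  if (any(table(tmp) < 2)) fail("need >= 2 samples per temperature")
  ht <- stats::t.test(e ~ tmp, var.equal = dialect == "pooled")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Two-way ANOVA on an eigengene
#'
#' Fixed-effects ANOVA of eigengene scores on population, temperature and
#' their interaction (Type-I sums of squares; identical to Type-III on
#' the balanced design).  A residual mean square of zero (exact-fit
#' degenerate input) is reported as `F = Inf`, `p = 0` with attribute
#' `degenerate = TRUE`.
#'
#' @param eigengene Named per-sample scores.
#' @param meta Sample metadata (full crossed design; empty cells are
#'   rejected).
#' @return Data frame with rows temperature, population, interaction and
#'   columns `effect`, `sum_sq`, `df_num`, `df_den`, `F`, `p`.
#' @export
eigengene_anova <- function(eigengene, meta) {
  meta <- check_metadata(meta)
  if (any(table(meta$population, meta$temperature) == 0))
    fail("empty treatment cells; full crossed design required")
  dat <- data.frame(e = as.numeric(eigengene[meta$sample_id]),
                    population = meta$population,
                    temperature = meta$temperature)
  fit <- stats::aov(e ~ population * temperature, data = dat)
  sm <- summary(fit)[[1]]
  rn <- trimws(rownames(sm))
  pick <- function(term) which(rn == term)
  df_den <- sm[pick("Residuals"), "Df"]
  ms_res <- sm[pick("Residuals"), "Mean Sq"]
  degenerate <- is.na(ms_res) || ms_res < 1e-12
  row <- function(term, label) {
    i <- pick(term)
    ss <- sm[i, "Sum Sq"]
    F <- if (degenerate) {
      if (ss > 1e-12) Inf else 0  # exact fit: effect either saturates or is absent
    } else ss / sm[i, "Df"] / ms_res
    data.frame(effect = label, sum_sq = ss, df_num = sm[i, "Df"],
               df_den = df_den, F = F,
               p = if (degenerate) {
                 if (ss > 1e-12) 0 else 1
               } else stats::pf(F, sm[i, "Df"], df_den, lower.tail = FALSE))
  }
  out <- rbind(row("temperature", "temperature"),
               row("population", "population"),
               row("population:temperature", "interaction"))
  rownames(out) <- NULL
  attr(out, "degenerate") <- degenerate
  attr(out, "sum_sq_residual") <- sm[pick("Residuals"), "Sum Sq"]
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Tukey HSD over populations with compact letter display
#'
#' Pairwise population contrasts on the eigengene using the studentized
#' range, with the residual mean square and df of the full two-way ANOVA
#' (populations pooled across temperatures).  Letters come from the
#' maximal cliques of the non-significance graph, ordered by group mean:
#' two populations share a letter iff their adjusted p exceeds `alpha`.
#'
#' @param eigengene Named per-sample scores.
#' @param meta Sample metadata.
#' @param alpha Significance level for the letters (default 0.05).
#' @return List: `comparisons` (data frame pair, estimate, p_adj),
#'   `letters` (named by population), `alpha`.
#' @export
tukey_hsd_populations <- function(eigengene, meta, alpha = 0.05) {
  meta <- check_metadata(meta)
  dat <- data.frame(e = as.numeric(eigengene[meta$sample_id]),
                    population = meta$population,
                    temperature = meta$temperature)
  fit <- stats::aov(e ~ population * temperature, data = dat)
  th <- stats::TukeyHSD(fit, which = "population")$population
  comparisons <- data.frame(pair = rownames(th), estimate = th[, "diff"],
                            p_adj = th[, "p adj"], row.names = NULL)
  pops <- levels(dat$population)
  k <- length(pops)
  nonsig <- matrix(TRUE, k, k, dimnames = list(pops, pops))
  for (i in seq_len(nrow(comparisons))) {
    pr <- strsplit(comparisons$pair[i], "-", fixed = TRUE)[[1]]
    ns <- comparisons$p_adj[i] > alpha
    nonsig[pr[1], pr[2]] <- ns
    nonsig[pr[2], pr[1]] <- ns
  }
  g <- igraph::graph_from_adjacency_matrix(nonsig, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  means <- tapply(dat$e, dat$population, mean)
  cl_mean <- vapply(cliques, function(cl) mean(means[pops[as.integer(cl)]]), 1)
  cliques <- cliques[order(cl_mean)]
  letters_out <- stats::setNames(rep("", k), pops)
  for (i in seq_along(cliques)) {
    members <- pops[as.integer(cliques[[i]])]
    letters_out[members] <- paste0(letters_out[members], letters[i])
  }
  list(comparisons = comparisons, letters = letters_out, alpha = alpha)
}

#' Classify a module's reaction norm from its ANOVA
#'
#' Decision table at level `alpha`: a significant interaction gives
#' `EVOLVED_OR_DIVERGENT_PLASTICITY`; otherwise significant temperature
#' and population give `DIVERGENT_BASELINE`; temperature only,
#' `SHARED_PLASTICITY`; population only, `NON_PLASTIC_DIVERGENCE`;
#' nothing, `NO_SIGNAL`.
#'
#' @param anova An [eigengene_anova()] result, or a named numeric vector
#'   with elements `temperature`, `population`, `interaction` (p-values).
#' @param alpha Significance level (default 0.05).
#' @return Category string with attribute `alpha`.
#' @export
classify_reaction_norm <- function(anova, alpha = 0.05) {
  p <- if (is.data.frame(anova))
    stats::setNames(anova$p, anova$effect)
  else anova
  need <- c("temperature", "population", "interaction")
  if (!all(need %in% names(p)))
    fail("need p-values named temperature, population, interaction")
  cat_out <- if (p[["interaction"]] < alpha) "EVOLVED_OR_DIVERGENT_PLASTICITY"
    else if (p[["temperature"]] < alpha && p[["population"]] < alpha)
      "DIVERGENT_BASELINE"
    else if (p[["temperature"]] < alpha) "SHARED_PLASTICITY"
    else if (p[["population"]] < alpha) "NON_PLASTIC_DIVERGENCE"
    else "NO_SIGNAL"
  structure(cat_out, alpha = alpha)
}

#' Per-module eigengene statistics table
#'
#' Assembles, for every module of an assignment (optionally plus the
#' unassigned bin): size, variance explained by PC1/PC2, the ancestor
#' environment t-test, the two-way ANOVA effects, the reaction-norm
#' category and (when the population effect is significant) Tukey HSD
#' letters.
#'
#' @param expr Genes x samples matrix.
#' @param labels Named integer label vector.
#' @param meta Sample metadata.
#' @param alpha Significance level (default 0.05).
#' @param ancestor Population used for the environment t-test.
#' @param include_unassigned Include the unassigned bin (default TRUE).
#' @return List: `summary` (one row per module x effect), `eigengenes`
#'   (samples x modules), `categories`, `tukey` (letters per module where
#'   computed).
#' @export
module_statistics <- function(expr, labels, meta, alpha = 0.05,
                              ancestor = "ancestor",
                              include_unassigned = TRUE) {
  meta <- check_metadata(meta, expr)
  egs <- module_eigengenes(expr, labels, include_unassigned = include_unassigned)
  pct1 <- attr(egs, "pct_variance_pc1")
  pct2 <- attr(egs, "pct_variance_pc2")
  mods <- colnames(egs)
  has_anc <- ancestor %in% levels(meta$population)
  rows <- list(); categories <- character(0); tukey <- list()
  for (mm in mods) {
    e <- egs[, mm]
    n_genes <- if (mm == "unassigned") sum(labels == 0)
               else sum(labels == as.integer(sub("^M", "", mm)))
    an <- eigengene_anova(e, meta)
    categories[mm] <- as.character(classify_reaction_norm(an, alpha))
    tt <- if (has_anc) ancestor_ttest(e, meta, population = ancestor)
          else list(t = NA_real_, df = NA_real_, p = NA_real_)
    if (an$p[an$effect == "population"] < alpha)
      tukey[[mm]] <- tukey_hsd_populations(e, meta, alpha = alpha)
    rows[[mm]] <- data.frame(module = mm, n_genes = n_genes,
                             pct_var_pc1 = unname(pct1[mm]),
                             pct_var_pc2 = unname(pct2[mm]),
                             effect = an$effect, F = an$F,
                             df_num = an$df_num, df_den = an$df_den,
                             p = an$p, category = unname(categories[mm]),
                             ancestor_t = tt$t, ancestor_df = tt$df,
                             ancestor_p = tt$p)
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       eigengenes = egs, categories = categories, tukey = tukey)
}
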