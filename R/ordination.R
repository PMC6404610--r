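# Ordination of samples: Bray-Curtis dissimilarity, non-metric
# multidimensional scaling, and PERMANOVA with crossed factors.

#' Bray-Curtis dissimilarity between samples
#'
#' `d(a, b) = sum |x_a - x_b| / sum (x_a + x_b)` over genes.  Residual
#' expression matrices can contain negative values; the matrix is shifted
#' by its global minimum so the smallest value is 0 (rank structure
#' preserved; the shift is recorded).
#'
#' @param expr Genes x samples matrix.
#' @return Samples x samples symmetric matrix with zero diagonal, metric
#'   name in attribute `metric` and any applied shift in `shift`.
#' @export
bray_curtis <- function(expr) {
  x <- as.matrix(expr)
  if (anyNA(x)) fail("expression matrix contains NA")
  shift <- 0
  if (min(x) < 0) {
    shift <- -min(x)
    x <- x + shift
  }
  zero <- colSums(x) == 0
  if (any(zero))
    fail("Bray-Curtis undefined for all-zero samples: ",
         paste(colnames(x)[zero], collapse = ", "))
  d <- as.matrix(vegan::vegdist(t(x), method = "bray"))
  attr(d, "metric") <- "bray-curtis"
  attr(d, "shift") <- shift
  d
}

#' Kruskal stress-1 of a configuration
#'
#' Stress of `scores` against the dissimilarities `d`, using a monotone
#' (isotonic) regression of configuration distances on the dissimilarity
#' order.  Used to verify that reported stress is invariant under rigid
#' motions of the configuration.
#'
#' @param d Dissimilarity matrix or `dist`.
#' @param scores Samples x k configuration.
#' @return Stress-1 in `[0, 1]`.
#' @export
kruskal_stress <- function(d, scores) {
  dd <- as.vector(stats::as.dist(d))
  e <- as.vector(stats::dist(scores))
  o <- order(dd, e)
  fit <- stats::isoreg(e[o])$yf
  sqrt(sum((e[o] - fit)^2) / sum(e[o]^2))
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimisation (vegan's monoMDS engine) with random
#' restarts; the best-stress configuration is returned, centred.
#'
#' @param d Dissimilarity matrix or `dist`.
#' @param k Embedding dimension (default 5).
#' @param n_restarts Random starts; the best configuration is kept.
#' @param max_iter Iteration cap per start.
#' @param seed Controls all restarts.
#' @return List with `scores` (centred samples x k), `stress`, `k`,
#'   `converged` and `n_restarts_used`.
#' @export
nmds_ordination <- function(d, k = 5, n_restarts = 20, max_iter = 500,
                            seed = 1) {
  dd <- stats::as.dist(d)
  if (k >= attr(dd, "Size")) fail("k must be below the number of samples")
  fit <- with_substream(seed, "nmds",
    vegan::metaMDS(dd, k = k, try = n_restarts, trymax = n_restarts,
                   maxit = max_iter, autotransform = FALSE, wascores = FALSE,
                   trace = 0))
  scores <- scale(fit$points, center = TRUE, scale = FALSE)
  attr(scores, "scaled:center") <- NULL
  colnames(scores) <- sprintf("NMDS%d", seq_len(k))
  structure(list(scores = scores, stress = fit$stress, k = k,
                 converged = isTRUE(fit$converged) ||
                   (is.numeric(fit$converged) && fit$converged > 0),
                 n_restarts_used = n_restarts),
            class = "nmds_ordination")
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance: sequential (Type-I)
#' partitioning of the Gower-centred dissimilarity matrix with free
#' permutation of sample labels; `p = (1 + #\{F_perm >= F_obs\}) / (1 +
#' n_perm)`.
#'
#' @param d Samples x samples dissimilarity matrix or `dist`.
#' @param meta Sample metadata (rows aligned with `d`).
#' @param formula One-sided formula over metadata columns; default
#'   `~ population * temperature`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @param permutations Optional explicit permutation matrix (rows =
#'   permutations of sample indices); overrides `n_perm`.
#' @return Data frame (terms, Residual, Total) with columns `Df`,
#'   `SumOfSqs`, `R2`, `F`, `Pr(>F)`; attributes `n_perm` and `seed`.
#' @export
permanova <- function(d, meta, formula = ~ population * temperature,
                      n_perm = 1000, seed = 1, permutations = NULL) {
  if (n_perm < 1) fail("n_perm must be >= 1")
  dst <- stats::as.dist(d)
  vars <- all.vars(formula)
  miss <- setdiff(vars, names(meta))
  if (length(miss)) fail("metadata lacks columns: ", paste(miss, collapse = ", "))
  for (v in vars) {
    x <- meta[[v]]
    if ((is.factor(x) || is.character(x)) && length(unique(x)) < 2)
      fail("factor '", v, "' has a single level")
  }
  f <- stats::update(formula, dst ~ .)
  environment(f) <- environment()
  perm <- permutations %||% n_perm
  tab <- with_substream(seed, "permanova",
    vegan::adonis2(f, data = meta, permutations = perm, by = "terms"))
  out <- as.data.frame(tab)
  attr(out, "n_perm") <- if (is.matrix(perm)) nrow(perm) else n_perm
  attr(out, "seed") <- seed
  class(out) <- c("permanova_table", "data.frame")
  out
}
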