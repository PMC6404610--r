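# Signed weighted coexpression network: adjacency, topological overlap,
# average-linkage clustering and dynamic hybrid tree cut.

#' Signed adjacency matrix
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^beta`, so anti-correlated genes get
#' adjacency near 0 and perfectly correlated genes 1.
#'
#' @param expr Genes x samples matrix (>= 3 samples; zero-variance genes
#'   are rejected, correlation being undefined for them).
#' @param beta Soft-threshold power (default 5).
#' @param cor_method `"pearson"` (default) or `"bicor"` (biweight
#'   midcorrelation; genes with zero MAD fall back to Pearson).
#' @return Genes x genes symmetric matrix in `[0, 1]`, unit diagonal;
#'   attributes `beta` and `signed = TRUE`.
#' @export
signed_adjacency <- function(expr, beta = 5, cor_method = c("pearson", "bicor")) {
  cor_method <- match.arg(cor_method)
  x <- t(as.matrix(expr))  # samples x genes
  if (nrow(x) < 3) fail("need at least 3 samples for correlations")
  v <- apply(x, 2, stats::var)
  if (any(v == 0))
    fail("zero-variance genes (correlation undefined): ",
         paste(utils::head(colnames(x)[v == 0], 10), collapse = ", "))
  r <- if (cor_method == "pearson") stats::cor(x) else bicor_matrix(x)
  a <- ((1 + r) / 2)^beta
  a[a < 0] <- 0; a[a > 1] <- 1
  diag(a) <- 1
  attr(a, "beta") <- beta
  attr(a, "signed") <- TRUE
  a
}

# biweight midcorrelation; columns with zero MAD revert to their
# standardized values (Pearson fallback for those genes)
bicor_matrix <- function(x) {
  w <- apply(x, 2, function(col) {
    med <- stats::median(col)
    madv <- stats::mad(col, constant = 1)
    if (madv == 0) return(scale(col)[, 1])
    u <- (col - med) / (9 * madv)
    wt <- (1 - u^2)^2 * (abs(u) < 1)
    z <- (col - med) * wt
    z / sqrt(sum(z^2))
  })
  r <- crossprod(w)
  # normalise in case of fallback columns (unit-norm already otherwise)
  s <- sqrt(diag(r))
  r <- r / tcrossprod(s)
  r[r > 1] <- 1; r[r < -1] <- -1
  r
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and connectivity
#' `k_i = sum_{u != i} a_iu`; `TOM_ii = 1`.  Computed with a matrix
#' product; a zero denominator (isolated pair) yields overlap 0.
#'
#' @param a Valid adjacency matrix (symmetric, unit diagonal, `[0, 1]`).
#' @return Genes x genes TOM in `[0, 1]`.
#' @export
topological_overlap <- function(a) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-12)
    fail("adjacency must be square and symmetric")
  if (any(a < 0) || any(a > 1) || any(abs(diag(a) - 1) > 1e-12))
    fail("adjacency entries must be in [0, 1] with unit diagonal")
  k <- colSums(a) - 1
  l <- a %*% a - 2 * a  # removes the u = i and u = j terms (diag = 1)
  num <- l + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- ifelse(den > 1e-12, num / den, 0)
  diag(tom) <- 1
  tom[tom < 0] <- 0; tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' TOM dissimilarity
#' @param tom Topological overlap matrix.
#' @return `1 - tom`.
#' @export
tom_dissimilarity <- function(tom) {
  d <- 1 - tom
  diag(d) <- 0
  d
}

#' Average-linkage clustering of a dissimilarity matrix
#'
#' @param diss Symmetric dissimilarity matrix with zero diagonal.
#' @return An `hclust` tree (UPGMA; merge heights non-decreasing).
#' @export
cluster_modules <- function(diss) {
  diss <- as.matrix(diss)
  if (max(abs(diss - t(diss))) > 1e-10 || any(abs(diag(diss)) > 1e-10))
    fail("dissimilarity must be symmetric with zero diagonal")
  stats::hclust(stats::as.dist(diss), method = "average")
}

# deepSplit 0..4 -> split sensitivity: maximum normalised core scatter a
# module may have, and the minimum gap between a branch's attachment
# height and its core scatter required to split it off
deep_split_params <- function(deep_split) {
  if (!deep_split %in% 0:4) fail("deep_split must be in 0..4")
  mcs <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1]
  list(max_core_scatter = mcs, min_gap = (1 - mcs) * 3 / 4)
}

#' Dynamic hybrid tree cut
#'
#' Two-stage module detection on an average-linkage dendrogram of the TOM
#' dissimilarity.  Stage 1: branches below `cut_height` are split
#' recursively at junctions whose two sub-branches both hold at least
#' `min_cluster_size` leaves and look like distinct clusters — each
#' side's core scatter (mean of its lowest merge heights, normalised by
#' the dendrogram height range) stays below the `deep_split` ceiling and
#' sits at least the `deep_split` minimum gap under the junction height.
#' Small children joining high up (outlying leaves) are peeled off during
#' the descent and rejoin their branch only if it never splits.  Terminal
#' branches qualify as modules when they hold at least
#' `min_cluster_size` leaves and their core scatter is below the ceiling.
#' Stage 2 (PAM-like, may cross branch boundaries): every unlabelled
#' leaf joins the module with the smallest average dissimilarity,
#' provided that average is at most `max_pam_dist` and inside the
#' module's diameter (the largest average within-module dissimilarity of
#' any member); ties break to the lower average, then the lower label.
#' Modules are numbered by decreasing size; label 0 marks unassigned
#' genes.
#'
#' @param dend `hclust` tree from [cluster_modules()].
#' @param diss The dissimilarity matrix the tree was built from.
#' @param cut_height Maximum merge height joining a module (default 0.905).
#' @param deep_split Split sensitivity 0 (coarse) to 4 (fine); default 2.
#' @param min_cluster_size Minimum module size (default 30).
#' @param pam_stage Run the stage-2 assignment (default TRUE).
#' @param max_pam_dist Stage-2 assignment radius (default `cut_height`).
#' @return Named integer vector of module labels (0 = unassigned).
#' @export
dynamic_tree_cut <- function(dend, diss, cut_height = 0.905, deep_split = 2,
                             min_cluster_size = 30, pam_stage = TRUE,
                             max_pam_dist = cut_height) {
  if (cut_height <= 0 || cut_height > 1 + 1e-8)
    fail("cut_height must be in (0, 1]")
  diss <- as.matrix(diss)
  n <- length(dend$order)
  labs <- dend$labels %||% as.character(seq_len(n))
  m <- dend$merge
  h <- dend$height
  nn <- nrow(m)
  ds <- deep_split_params(deep_split)
  hmin <- min(h)
  hrange <- max(h) - hmin
  if (hrange <= 0) hrange <- 1
  norm_h <- function(x) (x - hmin) / hrange

  # Per internal node: leaf set, parent height, and the lowest
  # min_cluster_size merge heights of the subtree (UPGMA heights are
  # monotone, so a node's height caps its subtree's).
  K <- max(2L, min_cluster_size)
  leafsets <- vector("list", nn)
  lowest <- vector("list", nn)
  parent_h <- rep(Inf, nn)
  for (j in seq_len(nn)) {
    a <- m[j, 1]; b <- m[j, 2]
    la <- if (a < 0) -a else leafsets[[a]]
    lb <- if (b < 0) -b else leafsets[[b]]
    leafsets[[j]] <- c(la, lb)
    cand <- c(if (a > 0) lowest[[a]], if (b > 0) lowest[[b]], h[j])
    lowest[[j]] <- sort(cand)[seq_len(min(K, length(cand)))]
    if (a > 0) parent_h[a] <- h[j]
    if (b > 0) parent_h[b] <- h[j]
  }
  node_size <- function(j) if (j < 0) 1L else length(leafsets[[j]])
  # core scatter: mean of the lowest merge heights joining the first
  # min_cluster_size members of the branch, on the normalised scale
  core_scatter <- function(j) {
    if (j < 0) return(0)
    k <- min(length(lowest[[j]]), max(1L, min(min_cluster_size, node_size(j)) - 1L))
    norm_h(mean(lowest[[j]][seq_len(k)]))
  }
  looks_distinct <- function(j, attach_h) {
    cs <- core_scatter(j)
    cs <= ds$max_core_scatter && (norm_h(attach_h) - cs) >= ds$min_gap
  }

  # maximal branches at or below the cut height
  branch_roots <- which(h <= cut_height & parent_h > cut_height)

  # Splitting of one branch.  A junction splits when both sub-branches
  # hold at least min_cluster_size leaves and each looks like a distinct
  # cluster (core-scatter/gap criteria), or when either side splits
  # further down (deeper structure proves the junction is a module
  # boundary).  Small children joining high up (outlying leaves) are
  # peeled off during the descent; they rejoin the branch if it never
  # splits, and are otherwise left to the stage-2 assignment.
  # Returns list(groups = list of (leaf vector, defining node), chaff).
  split_branch <- function(root) {
    if (root < 0)
      return(list(groups = list(), chaff = -root))
    j <- root
    peeled <- integer(0)
    repeat {
      a <- m[j, 1]; b <- m[j, 2]
      sa <- node_size(a); sb <- node_size(b)
      if (sa >= min_cluster_size && sb >= min_cluster_size) {
        ra <- split_branch(a)
        rb <- split_branch(b)
        if ((looks_distinct(a, h[j]) && looks_distinct(b, h[j])) ||
            length(ra$groups) > 1 || length(rb$groups) > 1)
          return(list(groups = c(ra$groups, rb$groups),
                      chaff = c(peeled, ra$chaff, rb$chaff)))
        # coherent branch: keep whole, peeled leaves rejoin
        return(list(groups = list(list(c(leafsets[[j]], peeled), j)),
                    chaff = integer(0)))
      }
      if (sa < min_cluster_size && sb < min_cluster_size)
        return(list(groups = list(list(c(leafsets[[j]], peeled), j)),
                    chaff = integer(0)))
      small <- if (sa < min_cluster_size) a else b
      large <- if (sa < min_cluster_size) b else a
      peeled <- c(peeled, if (small < 0) -small else leafsets[[small]])
      j <- large  # large has >= min_cluster_size leaves, so is internal
    }
  }

  labels <- integer(n)
  nxt <- 0L
  for (root in branch_roots) {
    res <- split_branch(root)
    for (g in res$groups) {
      if (length(g[[1]]) >= min_cluster_size &&
          core_scatter(g[[2]]) <= ds$max_core_scatter) {
        nxt <- nxt + 1L
        labels[g[[1]]] <- nxt
      }
    }
  }

  if (pam_stage && nxt > 0) {
    un <- which(labels == 0L)
    if (length(un)) {
      member <- outer(labels, seq_len(nxt), "==")
      sizes <- colSums(member)
      avg <- diss[un, , drop = FALSE] %*% member
      avg <- sweep(avg, 2, sizes, "/")
      # a module's diameter: largest average within-module dissimilarity
      # of any member; objects join only if they sit inside it
      within <- sweep(diss %*% member, 2, sizes, "/")
      diam <- vapply(seq_len(nxt), function(mm)
        max(within[member[, mm], mm]), numeric(1))
      best <- max.col(-avg, ties.method = "first")  # lowest avg, lowest label
      bestd <- avg[cbind(seq_along(un), best)]
      ok <- bestd <= max_pam_dist & bestd < diam[best]
      labels[un[ok]] <- best[ok]
    }
  }

  labels <- renumber_modules(labels)
  stats::setNames(labels, labs)
}

#' Build a network and detect candidate modules
#'
#' Convenience wrapper: signed adjacency, TOM, average-linkage clustering
#' and dynamic tree cut.
#'
#' @param expr Genes x samples expression matrix.
#' @param beta,cor_method Passed to [signed_adjacency()].
#' @param cut_height,deep_split,min_cluster_size,pam_stage Passed to
#'   [dynamic_tree_cut()].
#' @param keep_dendrogram Also return the dendrogram and dissimilarity.
#' @return Named integer label vector, or (with `keep_dendrogram`) a list
#'   `labels`, `dendrogram`, `diss`.
#' @export
network_modules <- function(expr, beta = 5, cor_method = "pearson",
                            cut_height = 0.905, deep_split = 2,
                            min_cluster_size = 30, pam_stage = TRUE,
                            keep_dendrogram = FALSE) {
  a <- signed_adjacency(expr, beta = beta, cor_method = cor_method)
  diss <- tom_dissimilarity(topological_overlap(a))
  dend <- cluster_modules(diss)
  labels <- dynamic_tree_cut(dend, diss, cut_height = cut_height,
                             deep_split = deep_split,
                             min_cluster_size = min_cluster_size,
                             pam_stage = pam_stage)
  if (keep_dendrogram) list(labels = labels, dendrogram = dend, diss = diss)
  else labels
}

#' Renumber module labels by decreasing size
#'
#' Label 1 is the largest module; ties break by the previous label order;
#' 0 (unassigned) is preserved.
#'
#' @param labels Integer label vector (0 = unassigned).
#' @return Relabelled integer vector (names preserved).
#' @export
renumber_modules <- function(labels) {
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) return(labels)
  sizes <- vapply(mods, function(mm) sum(labels == mm), 1L)
  ord <- mods[order(-sizes, mods)]
  out <- labels
  for (i in seq_along(ord)) out[labels == ord[i]] <- i
  out
}
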