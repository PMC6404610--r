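# Count preprocessing: median-of-ratios size factors, variance filter,
# variance-stabilising transform, residual-SVD surrogate-variable removal.
# Pipeline order is fixed: normalize -> vst -> filter -> SVA-residualize;
# each step appends itself to the matrix's transform_log.

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median, over reference genes
#' (genes with nonzero counts in every sample), of the ratio of the
#' sample's count to the gene's geometric mean across samples.
#'
#' @param counts Non-negative gene x sample count matrix.
#' @return Named vector of positive factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as_count_matrix(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    nz <- sort(colSums(counts > 0))
    fail("no gene has nonzero counts in every sample; cannot form a ",
         "median-of-ratios reference (samples with fewest expressed genes: ",
         paste(utils::head(names(nz), 5), collapse = ", "), ")")
  }
  sf <- DESeq2::estimateSizeFactorsForMatrix(counts)
  stats::setNames(as.numeric(sf), colnames(counts))
}

#' Divide counts by per-sample size factors
#'
#' @param counts Count matrix.
#' @param factors Size factors; computed by [size_factors()] if omitted.
#' @return Normalised (real-valued) matrix.
#' @export
normalize_counts <- function(counts, factors = NULL) {
  counts <- as_count_matrix(counts)
  factors <- factors %||% size_factors(counts)
  if (any(factors <= 0)) fail("size factors must be positive")
  out <- sweep(counts, 2, factors, "/")
  add_transform(out, "normalize:median-of-ratios")
}

#' Variance-stabilising transform
#'
#' Default dialect is the shifted log, `log2(count/factor + 1)`; the
#' `anscombe` dialect uses the NB first-order stabiliser
#' `log2(count/factor + 1/(2*dispersion))`.  Monotone in counts, finite
#' everywhere.
#'
#' @param counts Count matrix.
#' @param factors Positive size factors (computed if omitted).
#' @param dialect `"shifted-log"` (default) or `"anscombe"`.
#' @param dispersion NB dispersion used by the anscombe dialect.
#' @return Real-valued genes x samples matrix with a transform log.
#' @export
vst_transform <- function(counts, factors = NULL,
                          dialect = c("shifted-log", "anscombe"),
                          dispersion = 0.05) {
  dialect <- match.arg(dialect)
  counts <- as_count_matrix(counts)
  factors <- factors %||% size_factors(counts)
  if (any(factors <= 0)) fail("size factors must be positive")
  x <- sweep(counts, 2, factors, "/")
  out <- switch(dialect,
    "shifted-log" = log2(x + 1),
    "anscombe" = log2(x + 1 / (2 * dispersion)))
  out <- add_transform(out, "normalize:median-of-ratios")
  add_transform(out, sprintf("vst:%s", dialect))
}

#' Drop the lowest-variance genes
#'
#' Retains the `ceiling((1 - drop_fraction) * G)` genes with the highest
#' variance across all samples, preserving input gene order; ties at the
#' cutoff are resolved by stable gene order.
#'
#' @param expr Genes x samples matrix.
#' @param drop_fraction Fraction of genes to drop, in `[0, 1)`.
#' @return The filtered matrix.
#' @export
filter_low_variance <- function(expr, drop_fraction = 0.40) {
  if (drop_fraction < 0 || drop_fraction >= 1)
    fail("drop_fraction must be in [0, 1)")
  G <- nrow(expr)
  keep_n <- ceiling((1 - drop_fraction) * G)
  v <- row_vars(expr)
  ord <- order(-v, seq_len(G))  # stable: ties resolved by input order
  idx <- sort(ord[seq_len(keep_n)])
  out <- keep_log(expr[idx, , drop = FALSE], expr)
  add_transform(out, sprintf("filter_low_variance:drop=%.2f", drop_fraction))
}

#' Estimate surrogate variables from the residual expression matrix
#'
#' Two-step estimator: each gene is regressed on the design (population
#' and temperature, with or without their interaction) and the top left
#' singular vectors of the sample-space residual matrix are returned as
#' surrogate variables.  With `n_sv = "auto"`, the number of components is
#' chosen by permutation parallel analysis: each gene's residuals are
#' permuted independently `B` times and components whose singular value
#' exceeds the `quantile` of the permuted singular values are kept.
#'
#' @param expr Genes x samples matrix.
#' @param meta Sample metadata with `population` and `temperature`.
#' @param n_sv Number of surrogate variables, or `"auto"`.
#' @param include_interaction Include the population:temperature term in
#'   the design protected from removal.
#' @param B,quantile Parallel-analysis permutations and percentile.
#' @param seed Seed for the permutations.
#' @return Samples x n_sv matrix with orthonormal columns; attributes
#'   `singular_values` and, when residuals are numerically zero,
#'   `no_signal = TRUE` (with zero columns returned).
#' @export
estimate_surrogate_variables <- function(expr, meta, n_sv = "auto",
                                         include_interaction = TRUE,
                                         B = 20, quantile = 0.95, seed = 1) {
  meta <- check_metadata(meta, expr)
  form <- if (include_interaction) ~ population * temperature
          else ~ population + temperature
  X <- stats::model.matrix(form, meta)
  fit <- stats::lm.fit(X, t(expr))
  R <- t(fit$residuals)  # genes x samples
  model_df <- fit$rank
  max_sv <- ncol(expr) - model_df

  sv <- svd(R, nu = 0)
  d <- sv$d
  if (max(abs(R)) < 1e-10) {
    out <- matrix(numeric(0), ncol(expr), 0,
                  dimnames = list(colnames(expr), NULL))
    attr(out, "singular_values") <- d
    attr(out, "no_signal") <- TRUE
    warning("residual matrix is numerically zero; no meaningful surrogate variables")
    return(out)
  }

  if (identical(n_sv, "auto") || identical(n_sv, "AUTO")) {
    dperm <- with_substream(seed, "sva-parallel-analysis", {
      vapply(seq_len(B), function(b) {
        Rp <- t(apply(R, 1, sample))
        svd(Rp, nu = 0, nv = 0)$d
      }, numeric(length(d)))
    })
    thresh <- apply(dperm, 1, stats::quantile, probs = quantile)
    above <- d > thresh
    n_sv <- if (above[1]) max(which(cumsum(!above) == 0)) else 0L
    n_sv <- min(n_sv, max_sv)
  } else {
    n_sv <- as.integer(n_sv)
    if (n_sv >= ncol(expr) - model_df)
      fail("n_sv must be below n_samples - model df (", max_sv, ")")
  }
  out <- sv$v[, seq_len(n_sv), drop = FALSE]
  rownames(out) <- colnames(expr)
  if (n_sv > 0) colnames(out) <- sprintf("SV%d", seq_len(n_sv))
  attr(out, "singular_values") <- d
  out
}

#' Regress surrogate variables out of the expression matrix
#'
#' Per gene, ordinary least squares on an intercept plus the surrogate
#' variables; returns the residuals with the gene's intercept added back,
#' so grand means are preserved.  Re-regressing the output on the same
#' surrogate variables yields coefficients of zero (to numerical
#' precision).
#'
#' @param expr Genes x samples matrix.
#' @param sv Samples x k surrogate-variable matrix (all-zero columns are
#'   ignored; remaining columns must be of full rank).
#' @return Residualised matrix, same shape and gene order as `expr`.
#' @export
remove_latent_effects <- function(expr, sv) {
  sv <- as.matrix(sv)
  if (nrow(sv) != ncol(expr))
    fail("sv must have one row per sample")
  nz <- apply(sv, 2, function(col) any(col != 0))
  sv <- sv[, nz, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, sv)
  if (qr(X)$rank < ncol(X)) fail("surrogate-variable matrix is rank deficient")
  fit <- stats::lm.fit(X, t(expr))
  out <- t(fit$residuals) + matrix(fit$coefficients[1, ], nrow(expr),
                                   ncol(expr))
  dimnames(out) <- dimnames(expr)
  out <- keep_log(out, expr)
  add_transform(out, sprintf("remove_latent_effects:k=%d", ncol(sv)))
}

#' Preprocess a count matrix for network analysis
#'
#' Runs the fixed pipeline normalize -> vst -> variance filter ->
#' surrogate-variable residualisation and returns the transformed matrix
#' along with the intermediates.
#'
#' @param counts Gene x sample count matrix.
#' @param meta Sample metadata.
#' @param drop_fraction Passed to [filter_low_variance()].
#' @param vst_dialect,dispersion Passed to [vst_transform()].
#' @param n_sv,include_interaction Passed to
#'   [estimate_surrogate_variables()]; use `n_sv = 0` to skip SVA.
#' @param seed Seed for the SVA parallel analysis.
#' @return List with `expr` (the residual expression matrix),
#'   `size_factors`, `sv` and `transform_log`.
#' @export
preprocess <- function(counts, meta, drop_fraction = 0.40,
                       vst_dialect = "shifted-log", dispersion = 0.05,
                       n_sv = "auto", include_interaction = TRUE, seed = 1) {
  meta <- check_metadata(meta, counts)
  sf <- size_factors(counts)
  expr <- vst_transform(counts, sf, dialect = vst_dialect,
                        dispersion = dispersion)
  expr <- filter_low_variance(expr, drop_fraction)
  sv <- NULL
  if (!identical(n_sv, 0) && !identical(n_sv, 0L)) {
    sv <- estimate_surrogate_variables(expr, meta, n_sv = n_sv,
                                       include_interaction = include_interaction,
                                       seed = seed)
    if (ncol(sv) > 0) expr <- remove_latent_effects(expr, sv)
  }
  list(expr = expr, size_factors = sf, sv = sv,
       transform_log = transform_log(expr))
}
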