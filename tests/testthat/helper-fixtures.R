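# Shared fixture builders: everything is generated in code at test time.

# balanced metadata for an n_pop x 2 temperature x n_rep design
toy_metadata <- function(n_pop = 4, n_rep = 6, temps = c(20, 30)) {
  pops <- c("ancestor", "control", "heat", "oxidative")[seq_len(n_pop)]
  meta <- expand.grid(replicate = seq_len(n_rep), temperature = temps,
                      population = pops, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_%d_r%d", meta$population, meta$temperature,
                            meta$replicate)
  meta[, c("sample_id", "population", "temperature", "replicate")]
}

# small simulated dataset used across module tests
toy_simulation <- function(seed = 42, n_bg = 200, sizes = c(60, 50),
                           categories = c("SHARED_PLASTICITY",
                                          "DIVERGENT_BASELINE"), ...) {
  mods <- mapply(function(s, ctg) module_spec(s, ctg), sizes, categories,
                 SIMPLIFY = FALSE)
  simulate_counts(simulation_design(mods, n_background_genes = n_bg,
                                    rng_seed = seed, ...))
}

# deterministic expression matrix: genes x samples of pure noise
noise_expr <- function(n_genes, n_samples, seed = 1, sd = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * n_samples, sd = sd), n_genes, n_samples)
  dimnames(x) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n_samples)))
  x
}

# a numeric vector with exactly the requested mean and sd
exact_moments <- function(n, mean, sd) {
  base <- scale(seq_len(n))[, 1]
  base * sd + mean
}

# random symmetric adjacency with unit diagonal, entries in [0, 1]
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  a
}

# brute-force triple-loop TOM (independent oracle)
tom_brute <- function(a) {
  n <- nrow(a)
  k <- colSums(a) - 1
  out <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    den <- min(k[i], k[j]) + 1 - a[i, j]
    out[i, j] <- if (den > 1e-12) (l + a[i, j]) / den else 0
  }
  out
}

# PERMANOVA pseudo-F for a one-factor design from explicit group sums
permanova_f_brute <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    dg <- d[idx, idx]
    ss_within <- ss_within + sum(dg[upper.tri(dg)]^2) / length(idx)
  }
  a <- length(unique(groups))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}
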