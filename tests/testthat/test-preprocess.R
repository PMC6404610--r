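# Normalisation, variance filtering, VST and surrogate-variable removal.

test_that("median-of-ratios size factors match hand computations", {
  counts <- matrix(c(2, 4, 6, 8), 4, 2, dimnames = list(letters[1:4], c("s1", "s2")))
  counts[, 2] <- counts[, 1]
  expect_equal(unname(size_factors(counts)), c(1, 1))

  # sample 2 = 2 x sample 1: ratios to the geometric mean are 1/sqrt(2), sqrt(2)
  counts2 <- cbind(s1 = c(2, 4, 6, 8), s2 = c(4, 8, 12, 16))
  rownames(counts2) <- letters[1:4]
  expect_equal(unname(size_factors(counts2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-10)
})

test_that("scaling one sample scales its factor relative to the others", {
  set.seed(4)
  counts <- matrix(rpois(60, 50), 20, 3,
                   dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:3)))
  f0 <- size_factors(counts)
  counts[, 2] <- counts[, 2] * 3
  f1 <- size_factors(counts)
  # absolute factors shift with the geometric-mean reference; ratios obey
  # the equivariance exactly
  expect_equal(f1[2] / f1[1], 3 * f0[2] / f0[1], tolerance = 1e-10)
  expect_equal(f1[3] / f1[1], f0[3] / f0[1], tolerance = 1e-10)
})

test_that("size factors reject inputs with no all-sample reference gene", {
  counts <- cbind(s1 = c(5, 0), s2 = c(0, 7))
  rownames(counts) <- c("g1", "g2")
  expect_error(size_factors(counts), "median-of-ratios reference")
  expect_error(size_factors(counts), "s1")
})

test_that("variance filter keeps ceil((1-f)*G) top-variance genes in order", {
  x <- noise_expr(10, 8, seed = 2)
  kept <- filter_low_variance(x, 0.4)
  expect_equal(nrow(kept), 6)
  expect_equal(rownames(kept), intersect(rownames(x), rownames(kept)))

  # a constant gene is always dropped
  x["g005", ] <- 5
  expect_false("g005" %in% rownames(filter_low_variance(x, 0.4)))

  # ties at the cutoff: stable-order oracle on a 7-gene toy with 3 tied rows
  y <- rbind(a = c(0, 4), b = c(0, 2), c = c(0, 2), d = c(0, 2),
             e = c(0, 1), f = c(0, 8), g = c(0, 0.5))
  colnames(y) <- c("s1", "s2")
  v <- apply(y, 1, var)
  ord <- order(-v, seq_along(v))
  for (f_drop in c(0.2, 0.4, 0.6)) {
    keep_n <- ceiling((1 - f_drop) * 7)
    oracle <- sort(rownames(y)[ord[seq_len(keep_n)]])
    got <- filter_low_variance(y, f_drop)
    expect_equal(nrow(got), keep_n)
    expect_setequal(rownames(got), oracle)
  }
  expect_error(filter_low_variance(y, 1), "drop_fraction")
})

test_that("vst is the shifted log with recorded provenance", {
  counts <- cbind(s1 = c(0, 7), s2 = c(0, 7))
  rownames(counts) <- c("g1", "g2")
  v <- vst_transform(counts, factors = c(1, 1))
  expect_equal(unname(v["g1", "s1"]), 0)
  expect_equal(unname(v["g2", "s1"]), 3)  # log2(8)
  expect_equal(transform_log(v),
               c("normalize:median-of-ratios", "vst:shifted-log"))
  va <- vst_transform(counts, factors = c(1, 1), dialect = "anscombe",
                      dispersion = 0.05)
  expect_equal(unname(va["g1", "s1"]), log2(10))
})

test_that("vst approximately stabilises variance across NB mean bins", {
  set.seed(11)
  mu <- 2^runif(600, 5, 9)
  counts <- matrix(rnbinom(600 * 40, mu = rep(mu, 40), size = 20), 600, 40,
                   dimnames = list(sprintf("g%d", 1:600), sprintf("s%d", 1:40)))
  v <- vst_transform(counts, factors = rep(1, 40))
  gv <- apply(v, 1, var)
  gm <- rowMeans(v)
  slope <- coef(lm(gv ~ gm))[2]
  expect_lt(abs(slope), 0.05)
})

test_that("surrogate variables are orthonormal and recover a planted batch", {
  des <- simulation_design(list(module_spec(80, "SHARED_PLASTICITY")),
                           n_background_genes = 300, n_batch_factors = 1,
                           batch_effect_sd = 1, rng_seed = 2)
  sim <- simulate_counts(des)
  expr <- vst_transform(sim$counts)
  sv <- estimate_surrogate_variables(expr, sim$metadata, n_sv = 2)
  expect_equal(crossprod(sv), diag(2), ignore_attr = TRUE, tolerance = 1e-8)
  expect_gte(abs(cor(sv[, 1], sim$truth$batch_factors[, 1])), 0.9)
  # parallel analysis finds at least the planted factor and still leads
  # with it
  sva <- estimate_surrogate_variables(expr, sim$metadata, n_sv = "auto",
                                      seed = 3)
  expect_gte(ncol(sva), 1)
  expect_gte(abs(cor(sva[, 1], sim$truth$batch_factors[, 1])), 0.9)
})

test_that("zero-residual input yields a no-signal flag and n_sv bounds hold", {
  meta <- toy_metadata(n_pop = 2, n_rep = 3)
  X <- model.matrix(~ population * temperature, coexstab:::check_metadata(meta))
  set.seed(6)
  B <- matrix(rnorm(10 * ncol(X)), 10)
  expr <- B %*% t(X)  # exactly the design fit, zero residuals
  dimnames(expr) <- list(sprintf("g%02d", 1:10), meta$sample_id)
  expect_warning(sv <- estimate_surrogate_variables(expr, meta, n_sv = 1),
                 "no meaningful")
  expect_true(isTRUE(attr(sv, "no_signal")))
  expect_equal(ncol(sv), 0)
  expr2 <- expr + matrix(rnorm(length(expr), sd = 0.1), nrow(expr))
  expect_error(estimate_surrogate_variables(expr2, meta, n_sv = 50), "n_sv")
})

test_that("latent-effect removal is an exact residualisation", {
  meta <- toy_metadata(n_pop = 2, n_rep = 3)
  expr <- noise_expr(20, 12, seed = 8)
  colnames(expr) <- meta$sample_id

  # all-zero surrogate variables: identity
  out <- remove_latent_effects(expr, matrix(0, 12, 1))
  expect_equal(out, expr, ignore_attr = TRUE)

  # exact fit: gene = 3*sv + 2 leaves the constant
  sv <- matrix(scale(seq_len(12))[, 1])
  expr["g001", ] <- 3 * sv[, 1] + 2
  out <- remove_latent_effects(expr, sv)
  expect_equal(unname(out["g001", ]), rep(2, 12), tolerance = 1e-10)

  # residual property: re-regression coefficients vanish
  co <- stats::lm.fit(cbind(1, sv), t(out))$coefficients
  expect_lt(max(abs(co[2, ])), 1e-8)

  expect_error(remove_latent_effects(expr, cbind(sv, sv)), "rank deficient")
})

test_that("planted batch correlation drops by at least 5x after removal", {
  des <- simulation_design(list(module_spec(60, "SHARED_PLASTICITY")),
                           n_background_genes = 240, n_batch_factors = 1,
                           batch_effect_sd = 1, rng_seed = 13)
  sim <- simulate_counts(des)
  expr <- vst_transform(sim$counts)
  b <- sim$truth$batch_factors[, 1]
  before <- mean(abs(cor(t(expr), b)))
  sv <- estimate_surrogate_variables(expr, sim$metadata, n_sv = 1)
  after <- mean(abs(cor(t(remove_latent_effects(expr, sv)), b)))
  expect_gt(before / after, 5)
})

test_that("the preprocessing pipeline records every step in order", {
  sim <- toy_simulation(seed = 17, n_bg = 100, sizes = c(40),
                        categories = "SHARED_PLASTICITY")
  prep <- preprocess(sim$counts, sim$metadata, n_sv = 1)
  expect_equal(prep$transform_log[1:3],
               c("normalize:median-of-ratios", "vst:shifted-log",
                 "filter_low_variance:drop=0.40"))
  expect_match(prep$transform_log[4], "remove_latent_effects")
  expect_equal(nrow(prep$expr), ceiling(0.6 * nrow(sim$counts)))
})

test_that("removing a planted batch with SVA does not hurt module recovery", {
  mods <- list(module_spec(60, "SHARED_PLASTICITY"),
               module_spec(60, "SHARED_PLASTICITY", temperature_effect = -2),
               module_spec(60, "NON_PLASTIC_DIVERGENCE"))
  des <- simulation_design(mods, n_background_genes = 320,
                           n_batch_factors = 1, batch_effect_sd = 1.5,
                           rng_seed = 31)
  sim <- simulate_counts(des)
  expr <- vst_transform(sim$counts)
  sv <- estimate_surrogate_variables(expr, sim$metadata, n_sv = 1)
  clean <- remove_latent_effects(expr, sv)
  ari_raw <- evaluate_recovery(network_modules(expr), sim$truth)$ari
  ari_sva <- evaluate_recovery(network_modules(clean), sim$truth)$ari
  expect_gte(ari_sva, ari_raw)
})
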