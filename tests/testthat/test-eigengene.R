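# Eigengene extraction, ANOVA/t statistics, Tukey letters and
# reaction-norm classification.

test_that("eigengene variance explained matches closed forms", {
  meta <- toy_metadata()
  n <- nrow(meta)
  set.seed(7)
  z <- rnorm(n)
  expr <- rbind(g1 = 2 * z + 1, g2 = -3 * z, g3 = 0.5 * z + 4)
  colnames(expr) <- meta$sample_id
  eg <- module_eigengene(expr, rownames(expr))
  expect_equal(eg$pct_variance_pc1, 100)

  # two orthogonal profiles of equal variance split 50/50
  u <- c(rep(1, n / 2), rep(-1, n / 2))
  v <- rep(c(1, -1), n / 2)
  expr2 <- rbind(g1 = u, g2 = v)
  colnames(expr2) <- meta$sample_id
  expect_equal(module_eigengene(expr2, c("g1", "g2"))$pct_variance_pc1, 50)

  expr3 <- rbind(g1 = rep(1, n), g2 = rep(2, n))
  colnames(expr3) <- meta$sample_id
  expect_error(module_eigengene(expr3, c("g1", "g2")), "constant")
})

test_that("eigengene agrees with a brute-force eigendecomposition", {
  x <- noise_expr(40, 24, seed = 31)
  eg <- module_eigengene(x, rownames(x))
  xs <- t(scale(t(x)))
  ev <- eigen(tcrossprod(xs), symmetric = TRUE)$values
  expect_equal(eg$pct_variance_pc1, 100 * ev[1] / sum(ev), tolerance = 1e-8)
  expect_equal(eg$pct_variance_pc2, 100 * ev[2] / sum(ev), tolerance = 1e-8)
  expect_equal(sum(eg$eigengene^2), 1, tolerance = 1e-10)
  # orientation is deterministic and positively tracks the module mean
  eg2 <- module_eigengene(x, rownames(x))
  expect_identical(eg$eigengene, eg2$eigengene)
  expect_gte(cor(eg$eigengene, colMeans(xs)), 0)
})

test_that("ancestor t-test matches the pooled closed form", {
  meta <- toy_metadata()
  e <- setNames(numeric(nrow(meta)), meta$sample_id)
  anc20 <- meta$population == "ancestor" & meta$temperature == 20
  anc30 <- meta$population == "ancestor" & meta$temperature == 30
  e[anc20] <- exact_moments(6, 0, 0.5)
  e[anc30] <- exact_moments(6, 1, 0.5)
  tt <- ancestor_ttest(e, meta)
  expect_equal(tt$t, -1 / (0.5 * sqrt(1 / 3)), tolerance = 1e-10)  # -3.4641
  expect_equal(tt$df, 10)

  # swapping the temperature labels flips t, leaves p unchanged
  meta_sw <- meta
  meta_sw$temperature <- ifelse(meta$temperature == 20, 30, 20)
  tt_sw <- ancestor_ttest(e, meta_sw)
  expect_equal(tt_sw$t, -tt$t, tolerance = 1e-10)
  expect_equal(tt_sw$p, tt$p, tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  e[anc30] <- e[anc20]
  tt0 <- ancestor_ttest(e, meta)
  expect_equal(tt0$t, 0)
  expect_equal(tt0$p, 1)

  welch <- ancestor_ttest(e, meta, dialect = "welch")
  expect_lt(welch$df, 10 + 1e-9)
})

test_that("two-way ANOVA matches brute-force sums of squares", {
  meta <- toy_metadata()
  cellmeans <- outer(c(ancestor = 0, control = 1, heat = 3, oxidative = -1),
                     c(`20` = 0, `30` = 2), "+")
  cellmeans["heat", "30"] <- 6  # interaction
  set.seed(44)
  noise <- rnorm(nrow(meta))
  e <- setNames(cellmeans[cbind(meta$population,
                                as.character(meta$temperature))] + noise,
                meta$sample_id)
  an <- eigengene_anova(e, meta)
  expect_equal(an$df_num, c(1, 3, 3))
  expect_equal(unique(an$df_den), 40)

  # brute force from cell/marginal/grand means
  grand <- mean(e)
  pop_m <- tapply(e, meta$population, mean)
  tmp_m <- tapply(e, meta$temperature, mean)
  cell_m <- tapply(e, list(meta$population, meta$temperature), mean)
  ss_pop <- 12 * sum((pop_m - grand)^2)
  ss_tmp <- 24 * sum((tmp_m - grand)^2)
  gamma <- sweep(sweep(cell_m, 1, pop_m - grand), 2, tmp_m - grand) - grand
  ss_int <- 6 * sum(gamma^2)
  expect_equal(an$sum_sq[an$effect == "population"], ss_pop, tolerance = 1e-8)
  expect_equal(an$sum_sq[an$effect == "temperature"], ss_tmp, tolerance = 1e-8)
  expect_equal(an$sum_sq[an$effect == "interaction"], ss_int, tolerance = 1e-8)

  # permuting sample order leaves every F unchanged
  set.seed(2)
  perm <- sample(nrow(meta))
  an_p <- eigengene_anova(e[perm], meta)
  expect_equal(an_p$F, an$F, tolerance = 1e-10)
})

test_that("an exact-fit eigengene is flagged degenerate", {
  meta <- toy_metadata()
  e <- setNames(ifelse(meta$temperature == 30, 1, 0), meta$sample_id)
  an <- eigengene_anova(e, meta)
  expect_true(attr(an, "degenerate"))
  expect_equal(an$F[an$effect == "temperature"], Inf)
  expect_equal(an$p[an$effect == "temperature"], 0)
  expect_equal(an$F[an$effect == "population"], 0)
  expect_equal(an$p[an$effect == "population"], 1)

  meta_bad <- meta[!(meta$population == "heat" & meta$temperature == 30), ]
  expect_error(eigengene_anova(e[meta_bad$sample_id], meta_bad), "empty")
})

test_that("Tukey HSD letters follow the studentized range", {
  meta <- toy_metadata()
  shift <- c(ancestor = 0, control = 0, heat = 0, oxidative = 5)
  e <- setNames(numeric(nrow(meta)), meta$sample_id)
  for (p in names(shift)) for (tm in c(20, 30)) {
    idx <- meta$population == p & meta$temperature == tm
    e[idx] <- exact_moments(6, shift[[p]], 0.5)
  }
  th <- tukey_hsd_populations(e, meta)
  sig <- grepl("oxidative", th$comparisons$pair)
  expect_true(all(th$comparisons$p_adj[sig] < 0.001))
  expect_true(all(th$comparisons$p_adj[!sig] > 0.999))
  expect_equal(unname(th$letters[c("ancestor", "control", "heat")]),
               rep("a", 3))
  expect_equal(unname(th$letters[["oxidative"]]), "b")

  # hand check of one adjusted p via ptukey on the ANOVA residual scale
  fit <- aov(e ~ population * temperature,
             data = data.frame(e = e, population = factor(meta$population),
                               temperature = factor(meta$temperature)))
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  q <- abs(5) / sqrt(mse / 12)
  p_hand <- ptukey(q, nmeans = 4, df = 40, lower.tail = FALSE)
  p_got <- th$comparisons$p_adj[th$comparisons$pair == "oxidative-ancestor"]
  expect_equal(p_got, p_hand, tolerance = 1e-8)
})

test_that("letter sharing is equivalent to pairwise non-significance", {
  meta <- toy_metadata()
  for (seed in 1:5) {
    set.seed(seed)
    e <- setNames(rnorm(nrow(meta)) +
                    rep(sample(0:2, 4, replace = TRUE),
                        each = 12)[as.integer(factor(meta$population))],
                  meta$sample_id)
    th <- tukey_hsd_populations(e, meta)
    for (i in seq_len(nrow(th$comparisons))) {
      pr <- strsplit(th$comparisons$pair[i], "-", fixed = TRUE)[[1]]
      shares <- length(intersect(strsplit(th$letters[[pr[1]]], "")[[1]],
                                 strsplit(th$letters[[pr[2]]], "")[[1]])) > 0
      expect_equal(shares, th$comparisons$p_adj[i] > th$alpha)
    }
  }
})

test_that("the reaction-norm decision table covers all branches", {
  p <- function(tm, pp, ii) c(temperature = tm, population = pp, interaction = ii)
  expect_equal(as.character(classify_reaction_norm(p(0.001, 0.3, 0.6))),
               "SHARED_PLASTICITY")
  expect_equal(as.character(classify_reaction_norm(p(0.001, 0.01, 0.6))),
               "DIVERGENT_BASELINE")
  expect_equal(as.character(classify_reaction_norm(p(0.2, 0.3, 0.01))),
               "EVOLVED_OR_DIVERGENT_PLASTICITY")
  expect_equal(as.character(classify_reaction_norm(p(0.2, 0.01, 0.6))),
               "NON_PLASTIC_DIVERGENCE")
  expect_equal(as.character(classify_reaction_norm(p(0.5, 0.5, 0.5))),
               "NO_SIGNAL")
  # boundary: p exactly alpha is not significant
  expect_equal(as.character(classify_reaction_norm(p(0.05, 0.5, 0.5))),
               "NO_SIGNAL")
  expect_error(classify_reaction_norm(c(temperature = 0.1)), "p-values")
})

test_that("module statistics assemble eigengenes, tests and categories", {
  sim <- toy_simulation(seed = 37, n_bg = 120, sizes = c(50, 40),
                        categories = c("SHARED_PLASTICITY",
                                       "DIVERGENT_BASELINE"))
  expr <- vst_transform(sim$counts)
  labels <- sim$truth$gene_labels
  st <- module_statistics(expr, labels, sim$metadata)
  expect_setequal(colnames(st$eigengenes), c("M1", "M2", "unassigned"))
  expect_equal(st$categories[["M1"]], "SHARED_PLASTICITY")
  expect_equal(st$categories[["M2"]], "DIVERGENT_BASELINE")
  expect_true("M2" %in% names(st$tukey))
  sm <- st$summary
  expect_equal(sort(unique(sm$module)), sort(c("M1", "M2", "unassigned")))
  expect_true(all(sm$df_den == 40))
  expect_gt(min(sm$pct_var_pc1[sm$module != "unassigned"]), 40)
})
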