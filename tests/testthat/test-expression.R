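test_that("quantile normalization equalizes distributions", {
  set.seed(1)
  m <- matrix(rexp(30, 0.1) + 1, 10, 3)
  qn <- quantile_normalize(m)
  # identical sorted values in every column
  expect_equal(sort(qn[, 1]), sort(qn[, 2]))
  expect_equal(sort(qn[, 2]), sort(qn[, 3]))
  # permuted samples yield identical multisets
  m2 <- cbind(m[, 1], m[sample(10), 1])
  qn2 <- quantile_normalize(m2)
  expect_equal(sort(qn2[, 1]), sort(qn2[, 2]))
  # idempotent
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-12)
  # identical samples unchanged
  same <- cbind(m[, 1], m[, 1])
  expect_equal(quantile_normalize(same), same, tolerance = 1e-12)
  expect_error(quantile_normalize(matrix(c(-1, 1, 2, 3), 2)), "positive")
  expect_error(quantile_normalize(matrix(1:3, 3, 1)), ">= 2 samples")
})

test_that("quantile normalization matches a brute-force rank-average
          oracle", {
  set.seed(2)
  m <- matrix(runif(9, 1, 100), 3, 3)
  expect_equal(unname(quantile_normalize(m)), unname(qn_oracle(m)),
               tolerance = 1e-12)
  # with ties
  mt <- matrix(c(1, 1, 5, 2, 3, 4, 9, 9, 9), 3, 3) + 0.5
  expect_equal(unname(quantile_normalize(mt)), unname(qn_oracle(mt)),
               tolerance = 1e-12)
})

test_that("probe collapse keeps the brightest probe per gene", {
  m <- matrix(c(1, 2, 3, 10, 20, 30, 5, 5, 5), 3, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), NULL))
  map <- data.frame(probe = c("p1", "p2", "p3"), gene = c("g1", "g1", "g2"))
  out <- collapse_probes(m, map)
  expect_equal(rownames(out), c("g1", "g2"))
  expect_equal(unname(out["g1", ]), c(10, 20, 30)) # p2 is uniformly brighter
  # one probe per gene: identity up to renaming
  map1 <- data.frame(probe = c("p1", "p3"), gene = c("gA", "gB"))
  out1 <- collapse_probes(m, map1)
  expect_equal(unname(out1["gA", ]), unname(m["p1", ]))
  # exhaustive toy check: 5 probes, 2 genes
  set.seed(3)
  m5 <- matrix(runif(15), 5, 3,
               dimnames = list(paste0("q", 1:5), NULL))
  map5 <- data.frame(probe = paste0("q", 1:5),
                     gene = c("gx", "gx", "gx", "gy", "gy"))
  out5 <- collapse_probes(m5, map5)
  best_gx <- names(which.max(rowMeans(m5)[1:3]))
  best_gy <- names(which.max(rowMeans(m5)[4:5]))
  expect_equal(unname(out5["gx", ]), unname(m5[best_gx, ]))
  expect_equal(unname(out5["gy", ]), unname(m5[best_gy, ]))
  expect_error(collapse_probes(m, map[0, ]), "empty")
})

test_that("batch mean-centering removes additive shifts exactly", {
  set.seed(4)
  base <- matrix(rnorm(40), 4, 10)
  batches <- rep(c("a", "b"), each = 5)
  shifted <- base
  shifted[, batches == "b"] <- shifted[, batches == "b"] + 0.9
  adj <- batch_mean_center(shifted, batches)
  # per-gene batch means equal the grand mean
  for (b in c("a", "b")) {
    expect_equal(rowMeans(adj[, batches == b]), rowMeans(shifted),
                 tolerance = 1e-12)
  }
  # within-batch contrasts preserved
  expect_equal(adj[, 2] - adj[, 1], shifted[, 2] - shifted[, 1],
               tolerance = 1e-12)
  # single batch: unchanged
  expect_equal(batch_mean_center(base, rep("a", 10)), base)
  expect_warning(batch_mean_center(base, c(rep("a", 9), "solo")),
                 "singleton")
})

test_that("Holm adjustment reproduces the step-down by hand", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  set.seed(5)
  p <- runif(50)
  expect_true(all(holm_adjust(p) >= p))
  expect_true(all(holm_adjust(p) <= pmin(1, length(p) * p))) # <= Bonferroni
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the ANOVA screen F statistic matches stats::aov gene by gene", {
  st <- gen_expression_study(n_genes = 6, noise_sd = 0.3, seed = 6)
  lm2 <- log2(st$matrix)
  res <- anova_screen(lm2, samples = st$samples)
  grp <- factor(paste(st$samples$dose_gy, st$samples$day, sep = ":"))
  for (g in rownames(lm2)) {
    a <- summary(stats::aov(lm2[g, ] ~ grp))[[1]]
    expect_equal(res$f_statistic[res$gene == g], a$`F value`[1],
                 tolerance = 1e-8)
    expect_equal(res$p_value[res$gene == g], a$`Pr(>F)`[1],
                 tolerance = 1e-8)
  }
})

test_that("the screen is invariant to column order and per-gene offsets", {
  st <- gen_expression_study(n_genes = 30, noise_sd = 0.2,
                             de_genes = list(gene_00004 = c("8:6" = 1)),
                             seed = 7)
  lm2 <- log2(st$matrix)
  r1 <- anova_screen(lm2, samples = st$samples)
  perm <- sample(ncol(lm2))
  r2 <- anova_screen(lm2[, perm], samples = st$samples[perm, ])
  expect_equal(r1$f_statistic, r2$f_statistic, tolerance = 1e-10)
  r3 <- anova_screen(lm2 + 5, samples = st$samples)
  expect_equal(r1$f_statistic, r3$f_statistic, tolerance = 1e-8)
  expect_equal(r1$max_log2_fc, r3$max_log2_fc, tolerance = 1e-10)
})

test_that("identical groups are never significant and planted effects are
          found", {
  flat <- gen_expression_study(n_genes = 40, noise_sd = 0, seed = 8)
  res <- anova_screen(log2(flat$matrix), samples = flat$samples)
  expect_equal(res$p_value, rep(1, 40)) # zero variance everywhere
  expect_false(any(res$significant))

  planted <- gen_expression_study(
    n_genes = 200, noise_sd = 0.2,
    de_genes = list(gene_00010 = c("8:4" = 1, "8:6" = 1, "16:4" = 1,
                                   "16:6" = 1)),
    seed = 9)
  res2 <- de_pipeline(planted)
  expect_true(res2$significant[res2$gene == "gene_00010"])
  expect_equal(res2$gene[1], "gene_00010") # smallest p overall
  # fold-change estimate near the planted 2-fold
  expect_equal(res2$max_log2_fc[res2$gene == "gene_00010"], 1,
               tolerance = 0.35)
})

test_that("screen errors and references behave as documented", {
  st <- gen_expression_study(n_genes = 10, seed = 10)
  one_group <- st$samples
  one_group$dose_gy <- 0
  one_group$day <- 1
  expect_error(anova_screen(log2(st$matrix), samples = one_group),
               ">= 2 groups")
  no_ctrl <- st
  keep <- no_ctrl$samples$dose_gy != 0
  expect_error(
    anova_screen(log2(no_ctrl$matrix[, keep]),
                 samples = no_ctrl$samples[keep, ]),
    "control")
})

test_that("fold changes follow the 2^-ddCt rule", {
  q0 <- gen_qpcr(data.frame(condition = c("ctrl", "same"),
                            delta_ct = c(5, 5)), sd = 0, seed = 1)
  fc <- ddct_fold_change(q0)
  expect_equal(fc$fold_change, c(1, 1))
  # planted ddCt = -1 -> fold change 2 exactly
  q1 <- gen_qpcr(data.frame(condition = c("ctrl", "up"),
                            delta_ct = c(5, 4)), sd = 0, seed = 1)
  expect_equal(
    ddct_fold_change(q1)$fold_change[2], 2, tolerance = 1e-12)
  # ddCt = log2(10) -> fold change 0.1
  q2 <- gen_qpcr(data.frame(condition = c("ctrl", "down"),
                            delta_ct = c(5, 5 + log2(10))), sd = 0, seed = 1)
  expect_equal(ddct_fold_change(q2)$fold_change[2], 0.1, tolerance = 1e-9)
  # invariant to a constant added to every Ct value
  q3 <- q1
  q3$ct_target <- q3$ct_target + 7
  q3$ct_housekeeping <- q3$ct_housekeeping + 7
  expect_equal(ddct_fold_change(q3)$fold_change,
               ddct_fold_change(q1)$fold_change)
  expect_error(ddct_fold_change(q1[q1$condition != "ctrl", ]), "control")
  # noisy wells: mean fold change near planted value
  set.seed(12)
  fcs <- replicate(60, {
    q <- gen_qpcr(data.frame(condition = c("ctrl", "up"),
                             delta_ct = c(5, 4)), sd = 0.3, n = 6,
                  seed = sample.int(2^31 - 1, 1))
    ddct_fold_change(q)$fold_change[2]
  })
  expect_lt(abs(mean(log2(fcs)) - 1), 2 * sd(log2(fcs)) / sqrt(60))
})
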