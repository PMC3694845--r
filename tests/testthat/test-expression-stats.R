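test_that("quantile normalization maps columns onto the mean-sorted reference", {
  m <- cbind(a = c(2, 4, 6), b = c(1, 3, 5))
  q <- quantile_normalize(m)
  expect_equal(unname(q[, "a"]), c(1.5, 3.5, 5.5))
  expect_equal(unname(q[, "b"]), c(1.5, 3.5, 5.5))
  # single column is its own reference
  one <- matrix(c(3, 1, 2), dimnames = list(NULL, "s1"))
  expect_equal(quantile_normalize(one), one)
  expect_error(quantile_normalize(cbind(c(1, NA))), "non-finite")
})

test_that("quantile normalization equalizes multisets, preserves order, and is idempotent", {
  set.seed(11)
  for (trial in 1:5) {
    m <- matrix(rnorm(600), 100, 6)
    q <- quantile_normalize(m)
    ref <- sort(q[, 1])
    for (j in 2:6) expect_equal(sort(q[, j]), ref)          # one multiset
    for (j in 1:6) expect_equal(order(q[, j]), order(m[, j]))
    expect_equal(quantile_normalize(q), q, tolerance = 1e-12)
  }
})

test_that("ties receive the mean of the reference values at their ranks", {
  m <- cbind(a = c(2, 4, 4, 6), b = c(1, 3, 5, 7))
  q <- quantile_normalize(m)
  # reference is (1.5, 3.5, 4.5, 6.5); the tied 4s share mean(3.5, 4.5)
  expect_equal(unname(q[, "a"]), c(1.5, 4, 4, 6.5))
})

test_that("probe merging averages mapped probes and drops unmapped ones", {
  x <- rbind(p1 = c(4, 8), p2 = c(6, 10), p3 = c(1, 1), p4 = c(9, 9))
  colnames(x) <- c("s1", "s2")
  map <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    gene = c("GeneA", "GeneA", "GeneB", NA))
  g <- merge_probes_to_genes(x, map)
  expect_equal(nrow(g), 2)                         # distinct mapped symbols
  expect_equal(unname(g["GeneA", ]), c(5, 9))      # mean of (4,6), (8,10)
  expect_equal(unname(g["GeneB", ]), c(1, 1))      # single probe verbatim
  expect_false("p4" %in% rownames(g))
  expect_error(merge_probes_to_genes(x, map[0, ]), "empty")
})

test_that("merge-then-contrast is invariant to probe order", {
  sim <- simulate_timecourse_expression(tiny_config(noise_sd = 0.2, seed = 2),
                                        "immediate")
  perm <- sample(nrow(sim$exprs))
  g1 <- merge_probes_to_genes(sim$exprs, sim$probe_map)
  g2 <- merge_probes_to_genes(sim$exprs[perm, ], sim$probe_map)
  expect_equal(g1, g2)
})

test_that("moderated t behaves at its degenerate limits", {
  set.seed(21)
  x <- matrix(rnorm(40 * 6, 8, 1), 40, 6,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:6)))
  ct <- contrast_spec(c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  # equal group means for a gene -> zero fold change, t = 0, p = 1
  x[1, 4:6] <- x[1, 1:3]
  fit <- fit_moderated_t(x, ct)
  expect_equal(fit$table$log2fc[1], 0)
  expect_equal(fit$table$t_mod[1], 0)
  expect_equal(fit$table$p[1], 1)
  # identical residual variance for all genes -> d0 = Inf and the ordinary
  # pooled statistic with the common variance
  y <- matrix(8, 30, 6, dimnames = list(sprintf("g%02d", 1:30),
                                        sprintf("s%d", 1:6)))
  delta <- rnorm(30)
  y[, 4:6] <- y[, 4:6] + delta
  y[, c(1, 4)] <- y[, c(1, 4)] + 0.3   # same within-group spread everywhere
  y[, c(2, 5)] <- y[, c(2, 5)] - 0.3
  fit2 <- fit_moderated_t(y, ct)
  expect_true(is.infinite(fit2$d0))
  v <- fit2$table$s2_g[1]
  expect_equal(fit2$s0_sq, v, tolerance = 1e-12)
  expect_equal(fit2$table$t_mod,
               fit2$table$log2fc / sqrt(v * (1 / 3 + 1 / 3)),
               tolerance = 1e-9)
  # all-zero variance falls back with a warning
  z <- y; z[, 1:3] <- 5; z[, 4:6] <- 7
  expect_warning(fit3 <- fit_moderated_t(z, ct), "zero")
  expect_true(all(fit3$table$p == 0))   # nonzero fold change, no variance
})

test_that("variance-prior hyperparameters are recovered from simulated truth", {
  d0_true <- 4; s0_true <- 0.04; d <- 4; n_genes <- 200
  est <- t(sapply(1:50, function(s) {
    set.seed(s)
    sg2 <- d0_true * s0_true / rchisq(n_genes, d0_true)
    s2 <- sg2 * rchisq(n_genes, d) / d
    pr <- methgate:::fit_variance_prior(s2, d)
    c(d0 = pr$d0, s0 = pr$s0_sq)
  }))
  expect_lt(abs(median(est[, "d0"]) - d0_true) / d0_true, 0.5)
  expect_lt(abs(median(est[, "s0"]) - s0_true) / s0_true, 0.25)
})

test_that("the moderated fit matches an independent empirical-Bayes implementation", {
  set.seed(7)
  x <- matrix(rnorm(300 * 6, 8, 1), 300, 6,
              dimnames = list(sprintf("g%03d", 1:300), sprintf("s%d", 1:6)))
  x[1:30, 4:6] <- x[1:30, 4:6] + 1.5
  ct <- contrast_spec(c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  fit <- fit_moderated_t(x, ct)
  design <- cbind(intercept = 1, grp = rep(c(0, 1), each = 3))
  lfit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(fit$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(fit$s0_sq, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(fit$table$t_mod, unname(lfit$t[, "grp"]), tolerance = 1e-6)
  expect_equal(fit$table$p, unname(lfit$p.value[, "grp"]), tolerance = 1e-6)
})

test_that("fold-change selection applies strict cuts in the right direction", {
  tab <- list(table = data.frame(
    gene = c("at_cut", "above", "below_p", "down_gene", "strong_up"),
    log2fc = c(1.0, 2.5, 1.8, -2.2, 2.5),
    s2_g = 0.1, t_mod = 5, p = c(0.001, 0.001, 0.5, 0.001, 0.001)),
    label = "toy")
  class(tab) <- "contrast_result"
  up2 <- select_de_genes(tab, fc_fold = 2, p_max = 0.01, direction = "up")
  expect_false("at_cut" %in% up2$members)   # exactly 2-fold is excluded
  expect_true("above" %in% up2$members)
  expect_false("below_p" %in% up2$members)
  up4 <- select_de_genes(tab, fc_fold = 4, p_max = 0.01, direction = "up")
  expect_true("strong_up" %in% up4$members) # 2^2.5 > 4
  down2 <- select_de_genes(tab, 2, 0.01, "down")
  expect_equal(down2$members, "down_gene")
  expect_error(select_de_genes(tab, fc_fold = 1), "fc_fold")
  expect_error(select_de_genes(tab, 2, 0.01, "sideways"))
})

test_that("selection is monotone in both thresholds", {
  sim <- simulate_timecourse_expression(tiny_config(noise_sd = 0.3, seed = 8))
  g <- merge_probes_to_genes(quantile_normalize(sim$exprs), sim$probe_map)
  d <- sim$design
  ct <- contrast_spec(
    d$sample_id[d$context == "mesoderm" & d$genotype == "WT" &
                  d$treatment == "DexM" & d$time_h == 72],
    d$sample_id[d$context == "mesoderm" & d$genotype == "DKO" &
                  d$treatment == "DexM" & d$time_h == 72])
  fit <- fit_moderated_t(g, ct)
  for (dir in c("up", "down")) {
    s2 <- select_de_genes(fit, 2, 0.01, dir)$members
    s4 <- select_de_genes(fit, 4, 0.01, dir)$members
    s2tight <- select_de_genes(fit, 2, 0.001, dir)$members
    expect_true(all(s4 %in% s2))
    expect_true(all(s2tight %in% s2))
  }
})
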