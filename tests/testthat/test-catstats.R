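test_that("Kruskal-Wallis matches the hand rank-sum formula and kruskal.test", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskal_omnibus(g)
  expect_equal(kw$statistic, 7.2)           # 12/(9*10) * (12+75+192) - 30
  expect_equal(kw$epsilon_sq, 7.2 / 8)
  expect_equal(kw$p, pchisq(7.2, 2, lower.tail = FALSE))

  # identical groups: H = 0
  g0 <- rep(list(c(1, 2, 3)), 3)
  expect_equal(kruskal_omnibus(g0)$statistic, 0)
  expect_equal(kruskal_omnibus(g0)$epsilon_sq, 0)

  # agreement with stats::kruskal.test, ties included
  set.seed(4)
  for (i in 1:20) {
    gl <- lapply(1:3, function(j) round(rnorm(sample(4:10, 1)), 1))
    kw <- kruskal_omnibus(gl)
    ref <- kruskal.test(gl)
    expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw$p, ref$p.value, tolerance = 1e-12)
  }

  # two groups: p agrees with the rank-sum test (normal approx, no cc)
  a <- c(1.2, 3.1, 5.5, 7.2); b <- c(2.2, 4.4, 6.1, 8.8)
  kw2 <- kruskal_omnibus(list(a, b))
  wt <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(kw2$p, wt$p.value, tolerance = 1e-10)

  expect_error(kruskal_omnibus(list(c(1, 2), numeric(0))), "empty group")
})

test_that("Dunn Z follows the mean-rank-difference formula with sign convention", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  d <- dunn_posthoc(g)
  # hand formula: vterm = 9*10/12 = 7.5, se = sqrt(7.5 * 2/3) = sqrt(5)
  expect_equal(d$Z[d$group1 == "a" & d$group2 == "c"], -6 / sqrt(5))
  expect_equal(d$Z[d$group1 == "a" & d$group2 == "b"], -3 / sqrt(5))
  # first-listed category with larger mean rank gives positive Z
  d2 <- dunn_posthoc(list(hi = c(7, 8, 9), lo = c(1, 2, 3)))
  expect_gt(d2$Z[1], 0)
  # swapping pair order flips the sign, p unchanged
  d3 <- dunn_posthoc(list(lo = c(1, 2, 3), hi = c(7, 8, 9)))
  expect_equal(d3$Z[1], -d2$Z[1])
  expect_equal(d3$p[1], d2$p[1])
  # identical groups: Z = 0, p = 1
  d4 <- dunn_posthoc(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(d4$Z[1], 0)
  expect_equal(d4$p[1], 1)
})

test_that("ANOVA eta-squared equals the sums-of-squares identity", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  a <- anova_omnibus(g)
  expect_equal(a$eta_sq, 13.5 / 17.5)       # SSb = 13.5, SSw = 4
  # equal-mean groups: tiny eta2
  set.seed(2)
  g2 <- list(rnorm(50), rnorm(50))
  expect_lt(anova_omnibus(g2)$eta_sq, 0.1)
  # zero within-group variance, distinct means: eta2 = 1
  g3 <- list(c(1, 1, 1), c(2, 2, 2))
  # perfect separation: R warns that F is unreliable, eta2 is still exact
  expect_equal(suppressWarnings(anova_omnibus(g3))$eta_sq, 1)
})

test_that("Tukey differences match the studentized-range computation", {
  g <- list(a = c(1, 2, 3), b = c(2, 4, 6), c = c(7, 8, 9))
  tk <- tukey_posthoc(g)
  row <- tk[tk$group1 == "a" & tk$group2 == "c", ]
  expect_equal(row$diff, mean(g$a) - mean(g$c))
  # oracle: p = ptukey(|diff| / se, K, N - K) with se = sqrt(MSE/n)
  x <- unlist(g); f <- factor(rep(names(g), lengths(g)))
  mse <- sum(tapply(x, f, function(v) sum((v - mean(v))^2))) / (9 - 3)
  se <- sqrt(mse / 3)
  p_or <- ptukey(abs(row$diff) / se, 3, 6, lower.tail = FALSE)
  expect_equal(row$p_adj, p_or, tolerance = 1e-8)
  # antisymmetry and identical-group behavior
  tk2 <- tukey_posthoc(list(c = g$c, a = g$a, b = g$b))
  expect_equal(tk2$diff[tk2$group1 == "c" & tk2$group2 == "a"], -row$diff)
  tk3 <- tukey_posthoc(list(u = c(1, 2, 3), v = c(1, 2, 3)))
  expect_equal(tk3$diff[1], 0)
  expect_equal(tk3$p_adj[1], 1, tolerance = 1e-8)
})

test_that("gene scan keeps the effect-size identity and skips sparse genes", {
  sim <- simulate_study(n_tips = 25, n_genes = 30,
                        spec = shift_spec("A", multiplier = 2, fraction = 0.3),
                        seed = 6)
  mat <- build_branch_matrix(sim$genes, sim$idx, 10)
  rers <- compute_rers(mat)
  scan <- gene_scan(rers, sim$true_labels)
  expect_equal(scan$effect_size, scan$statistic / (scan$n - 1),
               tolerance = 1e-12)
  expect_equal(scan$n, rowSums(scan[, paste0("n_", c("A", "B", "C"))]))
  # post hoc table has K(K-1)/2 pairs
  expect_length(grep("^p_", names(scan)), 3L)
  # impossible per-category minimum: everything skipped, explicit error
  expect_error(gene_scan(rers, sim$true_labels, min_per_category = 1000),
               "skipped")
})

test_that("planted shifts are detected by omnibus and localized by post hoc", {
  set.seed(31)
  # direct construction: K = 3 groups of branch RERs, A shifted +3 sd
  lv <- c("A", "B", "C")
  labels <- structure(rep(lv, times = c(20, 25, 25)), levels = lv)
  n_b <- length(labels)
  rers <- cbind(shifted = rnorm(n_b) + 3 * (labels == "A"),
                null = rnorm(n_b))
  scan <- gene_scan(rers, labels)
  sh <- scan[scan$gene == "shifted", ]
  expect_lt(sh$p, 1e-3)
  expect_lt(sh[["p_A.B"]], 0.01)
  expect_lt(sh[["p_A.C"]], 0.01)
  expect_gt(sh[["p_B.C"]], 0.05)
  expect_gt(scan[scan$gene == "null", "p"], 1e-3)
})

test_that("parametric omnibus p-values are roughly calibrated on null data", {
  sim <- simulate_study(n_tips = 40, n_genes = 1000, K = 3,
                        spec = shift_spec("A", multiplier = 1, fraction = 0),
                        seed = 17)
  mat <- build_branch_matrix(sim$genes, sim$idx, 10)
  rers <- compute_rers(mat)
  fit <- fit_ctmm(sim$master, sim$pheno, "ER", seed = 2)
  rec <- marginal_reconstruction(sim$master, sim$pheno, fit)
  lab <- branch_labels(rec, sim$idx)
  scan <- gene_scan(rers, lab, posthoc = FALSE)
  frac <- mean(scan$p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.08)
})

test_that("power grows with the planted shift size", {
  set.seed(77)
  lv <- c("A", "B")
  labels <- structure(rep(lv, times = c(30, 30)), levels = lv)
  n_b <- length(labels)
  mk <- function(shift) {
    m <- vapply(1:150, function(i) rnorm(n_b) + shift * (labels == "A"),
                numeric(n_b))
    colnames(m) <- sprintf("g%03d", 1:150)
    m
  }
  p1 <- gene_scan(mk(0.5), labels, posthoc = FALSE)$p
  p2 <- gene_scan(mk(1.0), labels, posthoc = FALSE)$p
  expect_gt(mean(p2 < 0.05), mean(p1 < 0.05))
})

test_that("signed log p composes sign and magnitude", {
  expect_equal(signed_logp(0.01, 2.5), 2)
  expect_equal(signed_logp(1, -1), 0)
  expect_equal(signed_logp(0.01, -2.5), -2)
  expect_equal(signed_logp(0, 1, p_floor = 1e-4), 4)
  expect_error(signed_logp(0, 1), "p_floor")
  expect_error(signed_logp(1.2, 1), "\\[0, 1\\]")
})
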