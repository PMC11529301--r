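test_that("rate models have the right free-parameter counts", {
  expect_equal(make_rate_model(3, "ER")$n_par, 1L)
  expect_equal(make_rate_model(3, "SYM")$n_par, 3L)
  expect_equal(make_rate_model(3, "ARD")$n_par, 6L)
  expect_equal(make_rate_model(4, "ARD")$n_par, 12L)

  custom <- matrix(c(0, 1, 2, 0), 2, 2, byrow = TRUE)
  expect_equal(make_rate_model(2, custom)$n_par, 2L)
  bad_gap <- matrix(c(0, 1, 3, 0), 2, 2, byrow = TRUE)
  expect_error(make_rate_model(2, bad_gap), "no gaps")
  bad_diag <- matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE)
  expect_error(make_rate_model(2, bad_diag), "zero diagonal")
})

test_that("transition probabilities follow the ER closed form", {
  # ER stay-probability: 1/K + (1 - 1/K) exp(-K a t)
  for (K in 2:3) {
    for (a in c(0.1, 0.5, 2)) {
      Q <- build_Q_test(K, a)
      for (t in c(0, 0.3, 1, 5)) {
        P <- transition_probabilities(Q, t)
        expect_equal(rowSums(P), rep(1, K), tolerance = 1e-10)
        stay <- 1 / K + (1 - 1 / K) * exp(-K * a * t)
        off <- (1 - stay) / (K - 1)
        expect_equal(diag(P), rep(stay, K), tolerance = 1e-8)
        expect_equal(P[1, 2], off, tolerance = 1e-8)
      }
    }
  }
  Q <- build_Q_test(2, 0.5)
  expect_equal(transition_probabilities(Q, 0), diag(2))
  expect_equal(transition_probabilities(Q, 1)[1, 1], 0.5 + 0.5 * exp(-1),
               tolerance = 1e-8)
  # long-time limit: uniform rows
  expect_equal(transition_probabilities(Q, 1e4),
               matrix(0.5, 2, 2), tolerance = 1e-8)
  expect_error(transition_probabilities(Q, -1), "non-negative")
})

test_that("pruning likelihood equals brute-force enumeration", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    K <- sample(2:3, 1)
    tr <- random_tree(n, mean_branch = runif(1, 0.05, 1))
    Q <- random_Q(K)
    tip_idx <- sample.int(K, n, replace = TRUE)
    pheno <- phenotype_vector(tr$tip.label, LETTERS[tip_idx],
                              levels = LETTERS[1:K])
    prior <- rep(1 / K, K)
    ll <- pruning_loglik(tr, pheno, Q, prior)
    bf <- brute_force_loglik(tr, tip_idx, Q, prior)
    expect_lt(abs(ll - bf), 1e-9)
  }
})

test_that("degenerate branch lengths reduce to the root prior", {
  tr <- read_newick(text = "((A:0,B:0):0,C:0);")
  ph <- phenotype_vector(c("A", "B", "C"), c("x", "x", "x"),
                         levels = c("x", "y"))
  Q <- build_Q_test(2, 0.7)
  prior <- c(0.3, 0.7)
  expect_equal(pruning_loglik(tr, ph, Q, prior), log(0.3), tolerance = 1e-12)
  # grafting a zero-length root stub must not change the likelihood
  tr2 <- read_newick(text = "(((A:1,B:2):1,C:2):0);")
  tr1 <- read_newick(text = "((A:1,B:2):1,C:2);")
  ph2 <- phenotype_vector(c("A", "B", "C"), c("x", "y", "x"),
                          levels = c("x", "y"))
  expect_equal(pruning_loglik(tr1, ph2, Q, prior),
               pruning_loglik(tr2, ph2, Q, prior), tolerance = 1e-10)
})

test_that("ER rate is recovered from simulated data", {
  set.seed(21)
  alpha <- 0.3
  Q <- build_Q_test(2, alpha)
  est <- replicate(20, {
    tr <- random_tree(500, mean_branch = 0.5)
    sim <- simulate_phenotype_on_tree(tr, Q)
    if (length(unique(unclass(sim$pheno))) < 2) return(NA_real_)
    fit_ctmm(tr, sim$pheno, "ER")$rates[1]
  })
  expect_lt(abs(median(est, na.rm = TRUE) - alpha) / alpha, 0.2)
})

test_that("model nesting behaves and the LRT is calibrated", {
  set.seed(5)
  tr <- random_tree(60, mean_branch = 0.5)
  Q <- build_Q_test(3, 0.5)
  repeat {
    sim <- simulate_phenotype_on_tree(tr, Q)
    if (length(unique(unclass(sim$pheno))) == 3) break
  }
  fits <- lapply(c("ER", "SYM", "ARD"), function(m)
    fit_ctmm(tr, sim$pheno, m, seed = 2))
  ll <- vapply(fits, `[[`, 0, "loglik")
  # nested models cannot fit worse (optimizer sanity, small slack)
  expect_gte(ll[2] - ll[1], -1e-4)
  expect_gte(ll[3] - ll[2], -1e-4)
  sel <- lrt_select(fits)
  expect_equal(sel$table$df, c(2L, 3L))
  expect_true(all(sel$table$statistic >= 0))

  # chi-square reference points
  expect_equal(pchisq(11.07, 5, lower.tail = FALSE), 0.05, tolerance = 0.001)
  f2 <- fits[c(1, 1)]
  f2[[2]]$model <- make_rate_model(3, "ARD")
  f2[[2]]$loglik <- f2[[1]]$loglik   # identical likelihoods -> p = 1
  expect_equal(lrt_select(f2)$table$p, 1)

  # non-nested pair rejected: two custom 2-parameter tyings of K = 3
  m1 <- make_rate_model(3, matrix(c(0, 1, 1, 2, 0, 1, 1, 1, 0), 3, 3, TRUE))
  m2 <- make_rate_model(3, matrix(c(0, 1, 1, 1, 0, 2, 1, 1, 0), 3, 3, TRUE))
  fa <- fits[[1]]; fb <- fits[[1]]
  fa$model <- m1; fb$model <- m2
  expect_error(lrt_select(list(fa, fb)), "not nested")
})

test_that("marginal reconstruction matches brute-force posteriors", {
  set.seed(13)
  for (i in 1:15) {
    n <- sample(4:5, 1)
    K <- sample(2:3, 1)
    tr <- random_tree(n, mean_branch = runif(1, 0.2, 1))
    Q <- random_Q(K)
    tip_idx <- sample.int(K, n, replace = TRUE)
    pheno <- phenotype_vector(tr$tip.label, LETTERS[tip_idx],
                              levels = LETTERS[1:K])
    rec <- marginal_reconstruction(tr, pheno, Q)
    expect_equal(rowSums(rec$prob), rep(1, nrow(rec$prob)), tolerance = 1e-9)
    # tips are exact indicators
    expect_equal(rec$prob[cbind(seq_len(n), tip_idx)], rep(1, n))
    bf <- brute_force_marginals(tr, tip_idx, Q, rep(1 / K, K))
    expect_equal(unname(rec$prob[(n + 1):(n + tr$Nnode), , drop = FALSE]),
                 unname(bf), tolerance = 1e-8)
  }
})

test_that("slow rates make monophyletic clades certain of their state", {
  tr <- read_newick(text = "(((A:1,B:1):1,(C:1,D:1):1):1,E:2);")
  ph <- phenotype_vector(LETTERS[1:5], c("x", "x", "y", "y", "y"),
                         levels = c("x", "y"))
  Q <- build_Q_test(2, 1e-4)
  rec <- marginal_reconstruction(tr, ph, Q)
  anc_cd <- ape::getMRCA(tr, c("C", "D"))
  expect_gt(rec$prob[anc_cd, "y"], 0.99)
})

test_that("branch labels follow the child-node rule", {
  tr <- tiny_master()
  ph <- phenotype_vector(LETTERS[1:4], c("x", "x", "y", "y"))
  rec <- marginal_reconstruction(tr, ph, build_Q_test(2, 0.2))
  idx <- branch_index(tr)
  lab <- branch_labels(rec, idx)
  # pendant branches carry the observed tip state
  for (tip in LETTERS[1:4])
    expect_identical(lab[idx$keys == tip][[1]], unclass(ph)[[tip]])
  expect_length(lab, idx$n_branches)
})

test_that("transition counting equals a direct edge scan", {
  # path-like tree with forced states via near-zero rates
  tr <- read_newick(text = "((A:1,B:1):1,C:1);")
  ph <- phenotype_vector(c("A", "B", "C"), c("C1", "O1", "H1"),
                         levels = c("C1", "O1", "H1"))
  set.seed(3)
  for (i in 1:10) {
    K <- 3
    n <- 6
    tr2 <- random_tree(n, mean_branch = 0.5)
    Q <- random_Q(K)
    ph2 <- phenotype_vector(tr2$tip.label,
                            LETTERS[sample.int(K, n, replace = TRUE)],
                            levels = LETTERS[1:K])
    rec <- marginal_reconstruction(tr2, ph2, Q)
    tab <- count_transitions(rec)
    # oracle: scan edges directly
    cnt <- setNames(rep(0L, nrow(tab)), paste(tab$from, tab$to))
    for (k in seq_len(nrow(rec$edge))) {
      a <- rec$ml[rec$edge[k, 1]]; b <- rec$ml[rec$edge[k, 2]]
      if (a != b) {
        key <- paste(rec$levels[min(a, b)], rec$levels[max(a, b)])
        cnt[key] <- cnt[key] + 1L
      }
    }
    expect_equal(tab$count, unname(cnt))
  }
  # all-same-state reconstruction: all counts zero
  ph3 <- phenotype_vector(c("A", "B", "C"), c("C1", "C1", "C1"),
                          levels = c("C1", "O1"))
  rec3 <- marginal_reconstruction(tr, ph3, build_Q_test(2, 1e-5))
  expect_true(all(count_transitions(rec3)$count == 0))
})

test_that("joint reconstruction agrees with marginal in easy regimes", {
  tr <- read_newick(text = "(((A:1,B:1):1,(C:1,D:1):1):1,E:2);")
  ph <- phenotype_vector(LETTERS[1:5], c("x", "x", "y", "y", "y"),
                         levels = c("x", "y"))
  Q <- build_Q_test(2, 1e-3)
  m <- marginal_reconstruction(tr, ph, Q)
  j <- marginal_reconstruction(tr, ph, Q, type = "joint")
  expect_identical(m$ml, j$ml)
})
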