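# shared small fixture: 20-tip study with an ER fit and reconstruction
perm_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_study(n_tips = 20, n_genes = 12, K = 2,
                            spec = shift_spec("A", multiplier = 1,
                                              fraction = 0),
                            seed = 8)
      fit <- fit_ctmm(sim$master, sim$pheno, "ER", seed = 2)
      rec <- marginal_reconstruction(sim$master, sim$pheno, fit)
      cache <<- list(sim = sim, fit = fit, rec = rec)
    }
    cache
  }
})

test_that("tip-state simulation respects the CTMM and the seed", {
  # all rates ~ 0: every node inherits the root state
  tr <- random_tree(15, seed = 2)
  Q0 <- build_Q_test(2, 1e-12)
  s <- simulate_tip_states(tr, Q0, seed = 5)
  expect_length(unique(s$node_states), 1L)

  # single branch of length t: change frequency matches the closed form
  tr1 <- read_newick(text = "(A:0.8,B:0);")
  a <- 0.6
  Q <- build_Q_test(2, a)
  set.seed(11)
  flips <- replicate(10000, {
    s <- simulate_tip_states(tr1, Q)
    s$tip_states[["A"]] != s$tip_states[["B"]]
  })
  p_theory <- 0.5 - 0.5 * exp(-2 * a * 0.8)
  se <- sqrt(p_theory * (1 - p_theory) / 10000)
  expect_lt(abs(mean(flips) - p_theory), 3 * se)

  # same seed, same draw
  s1 <- simulate_tip_states(tr, Q, seed = 42)
  s2 <- simulate_tip_states(tr, Q, seed = 42)
  expect_identical(s1$node_states, s2$node_states)
})

test_that("rejection sampling enforces the (relaxed) count criterion", {
  fx <- perm_fixture()
  obs <- tabulate(match(unclass(fx$sim$pheno), categories(fx$sim$pheno)),
                  nbins = 2)
  # exact mode: every accepted draw matches the observed counts
  for (i in 1:25) {
    rs <- rejection_sample(fx$sim$master, fx$fit$Q, fx$fit$prior, obs,
                           relax = 0, max_attempts = 50000, seed = 100 + i)
    expect_identical(tabulate(rs$tip_states, nbins = 2), as.integer(obs))
  }
  # relax = 1 accepts the first draw
  rs1 <- rejection_sample(fx$sim$master, fx$fit$Q, fx$fit$prior, obs,
                          relax = 1, max_attempts = 10, seed = 1)
  expect_equal(rs1$attempts, 1L)
  # relax = 0.1 keeps counts within the ceiling tolerance
  tol <- ceiling(0.1 * obs)
  for (i in 1:10) {
    rs <- rejection_sample(fx$sim$master, fx$fit$Q, fx$fit$prior, obs,
                           relax = 0.1, max_attempts = 50000, seed = 200 + i)
    cnt <- tabulate(rs$tip_states, nbins = 2)
    expect_true(all(abs(cnt - obs) <= tol))
  }
  # impossible budget fails with advice
  expect_error(
    rejection_sample(fx$sim$master, fx$fit$Q, fx$fit$prior, obs,
                     relax = 0, max_attempts = 1, seed = 3),
    "relax")
})

test_that("internal permutation conserves the multiset and is uniform", {
  expect_identical(permute_internal(5L), 5L)
  x <- c(1L, 1L, 2L, 3L, 3L)
  for (i in 1:20)
    expect_identical(sort(permute_internal(x, seed = i)), sort(x))
  # 3 nodes, states {1,1,2}: each distinct arrangement ~ 1/3
  set.seed(9)
  draws <- replicate(10000, paste(permute_internal(c(1L, 1L, 2L)),
                                  collapse = ""))
  freq <- table(draws) / 10000
  expect_length(freq, 3L)
  se <- sqrt((1 / 3) * (2 / 3) / 10000)
  expect_true(all(abs(freq - 1 / 3) < 3 * se + 0.01))
})

test_that("annealing never worsens the labeling and finds small optima", {
  fx <- perm_fixture()
  tr <- fx$sim$master
  Q <- fx$fit$Q
  ntip <- length(tr$tip.label)

  # all internal states identical: returned unchanged
  tips <- rep(1L, ntip)
  same <- rep(2L, tr$Nnode)
  out <- anneal_internal(tr, tips, same, Q, fx$fit$prior, seed = 1)
  expect_identical(out$internal_states, same)

  # 6-tip tree, 5 internal nodes: annealed optimum matches brute force
  tr6 <- random_tree(6, seed = 14, mean_branch = 0.4)
  post6 <- reorder(tr6, "postorder")
  ntip6 <- 6L
  states_tips <- c(1L, 2L, 1L, 2L, 1L, 2L)
  internal0 <- c(1L, 1L, 2L, 2L, 2L)
  # oracle: enumerate all multiset-preserving arrangements
  perms <- unique(combinat_perms(internal0))
  Q2 <- build_Q_test(2, 0.8)
  prior <- c(0.5, 0.5)
  ll_of <- function(internal) {
    e <- post6$edge
    P <- lapply(post6$edge.length, function(t) as.matrix(Matrix::expm(Q2 * t)))
    st <- c(states_tips, internal)
    root <- e[nrow(e), 1]
    ll <- log(prior[st[root]])
    for (k in seq_len(nrow(e)))
      ll <- ll + log(P[[k]][st[e[k, 1]], st[e[k, 2]]])
    ll
  }
  best_ll <- max(vapply(perms, ll_of, 0))
  hits <- 0L
  for (s in 1:100) {
    ann <- anneal_internal(tr6, states_tips, internal0, Q2, prior, seed = s)
    expect_gte(ann$loglik, ann$loglik_init - 1e-12)
    expect_identical(sort(ann$internal_states), sort(internal0))
    if (ann$loglik >= best_ll - 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("permulation draws conserve invariants, differ, and reproduce", {
  fx <- perm_fixture()
  cfg <- permulation_config(n = 50, relax = 0, seed = 19)
  pm <- permulate(fx$sim$master, fx$fit, fx$rec, fx$sim$pheno, cfg,
                  idx = fx$sim$idx)
  obs <- tabulate(match(unclass(fx$sim$pheno), categories(fx$sim$pheno)),
                  nbins = 2)
  ntip <- length(fx$sim$master$tip.label)
  obs_int <- sort(fx$rec$ml[(ntip + 1):length(fx$rec$ml)])
  for (i in 1:50) {
    expect_identical(tabulate(pm$tip_states[, i], nbins = 2), as.integer(obs))
    expect_identical(sort(pm$internal_states[, i]), obs_int)
  }
  # draws vary: the count constraint shrinks the labeling space on a
  # 20-tip tree, so occasional repeats are expected, but most draws differ
  keys <- apply(pm$branch_states, 2, paste, collapse = "")
  expect_gt(length(unique(keys)), 30L)
  tip_keys <- apply(pm$tip_states, 2, paste, collapse = "")
  expect_gt(length(unique(tip_keys)), 30L)
  # bit-identical reproduction under the same config
  pm2 <- permulate(fx$sim$master, fx$fit, fx$rec, fx$sim$pheno, cfg,
                   idx = fx$sim$idx)
  expect_identical(pm$branch_states, pm2$branch_states)
  expect_identical(pm$tip_states, pm2$tip_states)
})

test_that("relaxation reduces rejection effort", {
  fx <- perm_fixture()
  cfg0 <- permulation_config(n = 20, relax = 0, seed = 23)
  cfg1 <- permulation_config(n = 20, relax = 0.1, seed = 23)
  p0 <- permulate(fx$sim$master, fx$fit, fx$rec, fx$sim$pheno, cfg0,
                  idx = fx$sim$idx)
  p1 <- permulate(fx$sim$master, fx$fit, fx$rec, fx$sim$pheno, cfg1,
                  idx = fx$sim$idx)
  expect_lte(mean(p1$attempts), mean(p0$attempts))
})

test_that("empirical p-values follow the proportion definition", {
  ep <- empirical_pvalues(5.5, matrix(1:10, nrow = 1))
  expect_equal(ep$p, 0.5)
  expect_false(ep$floor)
  # observed below all nulls, one-sided
  expect_equal(empirical_pvalues(0, matrix(1:10, nrow = 1))$p, 1)
  # observed above all nulls: flagged floor with < 1/N display
  ep0 <- empirical_pvalues(99, matrix(1:10, nrow = 1))
  expect_equal(ep0$p, 0)
  expect_true(ep0$floor)
  expect_match(ep0$display, "^< 0.1")
  # two-sided by absolute value
  ep2 <- empirical_pvalues(-2, matrix(c(-3, -1, 1, 3), nrow = 1),
                           sided = "two.sided")
  expect_equal(ep2$p, 0.5)
  # add-one estimator
  expect_equal(empirical_pvalues(99, matrix(1:9, nrow = 1),
                                 add_one = TRUE)$p, 0.1)
  expect_error(empirical_pvalues(1, matrix(NA_real_, nrow = 1)), "no null")
})

test_that("permulation scoring equals gene_scan statistics draw by draw", {
  fx <- perm_fixture()
  mat <- build_branch_matrix(fx$sim$genes, fx$sim$idx, 10)
  rers <- compute_rers(mat)
  cfg <- permulation_config(n = 5, relax = 0, seed = 3)
  pm <- permulate(fx$sim$master, fx$fit, fx$rec, fx$sim$pheno, cfg,
                  idx = fx$sim$idx)
  nulls <- score_permulations(rers, pm)
  for (j in 1:5) {
    lab <- structure(pm$levels[pm$branch_states[, j]], levels = pm$levels)
    sc <- gene_scan(rers, lab, posthoc = FALSE)
    expect_equal(nulls[sc$gene, j], setNames(sc$effect_size, sc$gene),
                 tolerance = 1e-12)
  }
})
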