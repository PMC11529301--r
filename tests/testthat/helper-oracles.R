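# Independent oracles used across test files. These deliberately use
# brute-force enumeration or closed forms, never the package's own
# algorithmic path.

# Brute-force CTMM likelihood: sum over all joint internal-state
# assignments of prod(edge transition probs) * root prior.
brute_force_loglik <- function(tree, tip_idx, Q, prior) {
  K <- nrow(Q)
  post <- reorder(tree, "postorder")
  e <- post$edge
  P <- lapply(post$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  ntip <- length(post$tip.label)
  nint <- post$Nnode
  internal_ids <- ntip + seq_len(nint)
  grid <- do.call(expand.grid, rep(list(seq_len(K)), nint))
  root <- e[nrow(e), 1L]
  total <- 0
  for (r in seq_len(nrow(grid))) {
    states <- integer(ntip + nint)
    states[seq_len(ntip)] <- tip_idx
    states[internal_ids] <- as.integer(grid[r, ])
    pr <- prior[states[root]]
    for (k in seq_len(nrow(e)))
      pr <- pr * P[[k]][states[e[k, 1L]], states[e[k, 2L]]]
    total <- total + pr
  }
  log(total)
}

# Brute-force marginal posteriors: enumerate joint assignments,
# marginalize per internal node.
brute_force_marginals <- function(tree, tip_idx, Q, prior) {
  K <- nrow(Q)
  post <- reorder(tree, "postorder")
  e <- post$edge
  P <- lapply(post$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  ntip <- length(post$tip.label)
  nint <- post$Nnode
  internal_ids <- ntip + seq_len(nint)
  grid <- do.call(expand.grid, rep(list(seq_len(K)), nint))
  root <- e[nrow(e), 1L]
  marg <- matrix(0, nint, K)
  for (r in seq_len(nrow(grid))) {
    states <- integer(ntip + nint)
    states[seq_len(ntip)] <- tip_idx
    states[internal_ids] <- as.integer(grid[r, ])
    pr <- prior[states[root]]
    for (k in seq_len(nrow(e)))
      pr <- pr * P[[k]][states[e[k, 1L]], states[e[k, 2L]]]
    for (j in seq_len(nint))
      marg[j, states[internal_ids[j]]] <- marg[j, states[internal_ids[j]]] + pr
  }
  marg / rowSums(marg)
}

# Equal-rates generator built directly from the definition.
build_Q_test <- function(K, a) {
  Q <- matrix(a, K, K)
  diag(Q) <- -(K - 1) * a
  Q
}

# Random valid generator under a random rate model, for property tests.
random_Q <- function(K, rate_range = c(0.2, 3)) {
  Q <- matrix(runif(K * K, rate_range[1], rate_range[2]), K, K)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# Exact one-sided rank-sum enrichment p by enumerating all placements of
# the member set among n ranks (tie-free scores assumed).
exact_rank_enrichment_p <- function(scores, member, alternative = "greater") {
  n <- length(scores)
  r <- rank(scores)
  w_obs <- sum(r[member])
  combos <- combn(n, sum(member))
  w_all <- apply(combos, 2, function(ix) sum(r[ix]))
  if (alternative == "greater") mean(w_all >= w_obs)
  else mean(pmin(mean(w_all >= w_obs), mean(w_all <= w_obs)) * 2)
}

# All permutations of a vector (small n), for exhaustive annealing oracles.
combinat_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in combinat_perms(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], p)
  out
}

# Tiny fixed fixtures
tiny_master <- function() read_newick(text = "((A:1,B:1):1,(C:1,D:1):2);")

flat3 <- rep(1 / 3, 3)
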