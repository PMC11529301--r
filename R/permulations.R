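#' Permulation settings
#'
#' @param n number of permulations (>= 1).
#' @param relax relaxation fraction r in `[0, 1]` of the count-matching
#'   rejection criterion; `0` enforces exact extant category counts, and a
#'   category with observed count c accepts simulated counts within
#'   `ceiling(r * c)` of c. A value of 0.1 gives large speedups for 4+
#'   categories with little effect on the plausibility of the permulated
#'   phenotypes.
#' @param max_attempts rejection-sampling attempt budget per draw.
#' @param t_init initial annealing temperature.
#' @param cooling geometric cooling factor per step.
#' @param steps annealing step cap; default `min(100 * n_internal, 10000)`
#'   when `NULL`.
#' @param seed integer seed; draw i uses `seed + i`.
#' @return list of class `permulation_config`.
#' @export
permulation_config <- function(n = 100L, relax = 0, max_attempts = NULL,
                               t_init = 1, cooling = 0.95, steps = NULL,
                               seed = 1L) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (relax < 0 || relax > 1) stop("relax must lie in [0, 1]")
  if (is.null(max_attempts)) max_attempts <- 100L * n
  if (max_attempts < 1L) stop("max_attempts must be >= 1")
  structure(list(n = n, relax = relax, max_attempts = as.integer(max_attempts),
                 t_init = t_init, cooling = cooling, steps = steps,
                 seed = as.integer(seed)),
            class = "permulation_config")
}

# log transition probabilities per edge, clamped away from log(0)
edge_log_probs <- function(tree, Q) {
  post <- stats::reorder(tree, "postorder")
  P <- edge_transition_probs(Q, post$edge.length)
  list(post = post, logP = lapply(P, function(m) log(pmax(m, 1e-300))))
}

# Log-likelihood of a complete node labeling (tips + internals).
labeling_loglik <- function(elp, states, prior, root) {
  e <- elp$post$edge
  ll <- log(max(prior[states[root]], 1e-300))
  for (k in seq_len(nrow(e)))
    ll <- ll + elp$logP[[k]][states[e[k, 1L]], states[e[k, 2L]]]
  ll
}

#' Simulate categorical tip states down the tree
#'
#' Draws the root state from the prior and each child state from the CTMM
#' transition probabilities over its branch; used both for permulation
#' rejection sampling and for the synthetic-data generator. The simulation
#' runs on the master tree whose branch lengths are average genome-wide
#' rates.
#'
#' @param tree a `phylo` tree.
#' @param Q K x K generator.
#' @param prior root prior (numeric vector, `"flat"` or `"stationary"`).
#' @param seed optional integer seed.
#' @return list with `tip_states` (named integer vector over tips),
#'   `node_states` (all nodes, internal included) and `levels_n` (K).
#' @export
simulate_tip_states <- function(tree, Q, prior = "flat", seed = NULL) {
  validate_phylo(tree)
  K <- nrow(Q)
  prior <- resolve_prior(prior, Q, K)
  if (!is.null(seed)) set.seed(seed)
  post <- stats::reorder(tree, "postorder")
  P <- edge_transition_probs(Q, post$edge.length)
  states <- sim_states_fast(post, P, prior, K)
  ntip <- length(tree$tip.label)
  list(tip_states = stats::setNames(states[seq_len(ntip)], post$tip.label),
       node_states = states, levels_n = K)
}

# Hot path shared by rejection sampling: edge transition matrices are
# precomputed once per (tree, Q) and reused across attempts; inverse-CDF
# draws from row-wise cumulative probabilities keep the per-node cost low.
sim_states_fast <- function(post, P, prior, K, cumP = NULL) {
  e <- post$edge
  if (is.null(cumP)) cumP <- lapply(P, function(m) t(apply(m, 1L, cumsum)))
  ne <- nrow(e)
  states <- integer(length(post$tip.label) + post$Nnode)
  root <- e[ne, 1L]
  states[root] <- 1L + sum(stats::runif(1) > cumsum(prior)[-K])
  u <- stats::runif(ne)
  for (k in rev(seq_len(ne)))   # preorder: parents before children
    states[e[k, 2L]] <- 1L +
      sum(u[k] > cumP[[k]][states[e[k, 1L]], -K])
  states
}

#' Rejection-sample a simulated phenotype matching observed counts
#'
#' Repeats [simulate_tip_states()] until, for every category c, the
#' simulated extant count is within `ceiling(relax * observed_c)` of the
#' observed count (exact equality when `relax = 0`); any other draw is
#' rejected.
#'
#' @param tree master `phylo` tree.
#' @param Q fitted generator.
#' @param prior root prior.
#' @param observed_counts integer vector of extant species per category
#'   (registry order).
#' @param relax relaxation fraction in `[0, 1]`.
#' @param max_attempts attempt budget; exhausting it is an error advising a
#'   larger `relax`.
#' @param seed optional seed.
#' @return list with `tip_states`, `node_states`, `attempts`.
#' @export
rejection_sample <- function(tree, Q, prior, observed_counts, relax = 0,
                             max_attempts = 10000L, seed = NULL) {
  K <- nrow(Q)
  stopifnot(length(observed_counts) == K)
  tol <- ceiling(relax * observed_counts)
  if (!is.null(seed)) set.seed(seed)
  prior <- resolve_prior(prior, Q, K)
  post <- stats::reorder(tree, "postorder")
  P <- edge_transition_probs(Q, post$edge.length)
  cumP <- lapply(P, function(m) t(apply(m, 1L, cumsum)))
  ntip <- length(post$tip.label)
  for (a in seq_len(max_attempts)) {
    states <- sim_states_fast(post, P, prior, K, cumP = cumP)
    cnt <- tabulate(states[seq_len(ntip)], nbins = K)
    if (all(abs(cnt - observed_counts) <= tol))
      return(list(
        tip_states = stats::setNames(states[seq_len(ntip)], post$tip.label),
        node_states = states, attempts = a))
  }
  stop("rejection sampling failed after ", max_attempts,
       " attempts; consider a larger relaxation (e.g. relax = 0.1)")
}

#' Permute the observed internal states
#'
#' Places a uniform random permutation of the observed reconstruction's
#' internal-state multiset on the internal nodes; the multiset is conserved
#' by construction.
#'
#' @param internal_states integer vector of observed internal states.
#' @param seed optional seed.
#' @return permuted integer vector of the same length.
#' @export
permute_internal <- function(internal_states, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(internal_states) <= 1L) return(internal_states)
  sample(internal_states)
}

#' Re-organize internal states by simulated annealing
#'
#' Proposal: swap the states of two internal nodes with differing states;
#' an improving swap is always accepted, a worsening one with probability
#' `exp(delta / T)` under a geometrically cooled temperature. The
#' internal-state multiset is conserved throughout and the best labeling
#' visited is returned, so the returned log-likelihood is never below the
#' initial one.
#'
#' @param tree master `phylo` tree.
#' @param tip_states integer tip states (postorder tip numbering).
#' @param internal_states integer internal states to re-organize.
#' @param Q generator.
#' @param prior root prior vector.
#' @param t_init,cooling,steps annealing schedule; `steps = NULL` uses
#'   `min(100 * n_internal, 10000)`.
#' @param seed optional seed.
#' @return list with `internal_states` (best found), `loglik`,
#'   `loglik_init`.
#' @export
anneal_internal <- function(tree, tip_states, internal_states, Q, prior,
                            t_init = 1, cooling = 0.95, steps = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(Q)
  prior <- resolve_prior(prior, Q, K)
  ntip <- length(tree$tip.label)
  nint <- length(internal_states)
  stopifnot(nint == tree$Nnode, length(tip_states) == ntip)
  elp <- edge_log_probs(tree, Q)
  e <- elp$post$edge
  root <- e[nrow(e), 1L]
  if (is.null(steps)) steps <- min(100L * nint, 10000L)

  states <- c(tip_states, internal_states)
  # edges incident to each node, for incremental delta evaluation
  inc <- vector("list", ntip + nint)
  for (k in seq_len(nrow(e))) {
    inc[[e[k, 1L]]] <- c(inc[[e[k, 1L]]], k)
    inc[[e[k, 2L]]] <- c(inc[[e[k, 2L]]], k)
  }
  local_ll <- function(states, edges) {
    s <- 0
    for (k in edges) s <- s + elp$logP[[k]][states[e[k, 1L]], states[e[k, 2L]]]
    s
  }
  ll <- labeling_loglik(elp, states, prior, root)
  ll_init <- ll
  best <- states; best_ll <- ll
  if (length(unique(internal_states)) < 2L)
    return(list(internal_states = internal_states, loglik = ll,
                loglik_init = ll_init))
  internal_ids <- ntip + seq_len(nint)
  temp <- t_init
  for (s in seq_len(steps)) {
    i <- internal_ids[sample.int(nint, 1L)]
    cand <- internal_ids[states[internal_ids] != states[i]]
    j <- cand[sample.int(length(cand), 1L)]
    edges_ij <- unique(c(inc[[i]], inc[[j]]))
    old <- local_ll(states, edges_ij)
    root_old <- if (i == root || j == root) log(max(prior[states[root]], 1e-300)) else 0
    tmp <- states[i]; states[i] <- states[j]; states[j] <- tmp
    new <- local_ll(states, edges_ij)
    root_new <- if (i == root || j == root) log(max(prior[states[root]], 1e-300)) else 0
    delta <- (new + root_new) - (old + root_old)
    if (delta > 0 || stats::runif(1) < exp(delta / temp)) {
      ll <- ll + delta
      if (ll > best_ll) { best_ll <- ll; best <- states }
    } else {
      tmp <- states[i]; states[i] <- states[j]; states[j] <- tmp
    }
    temp <- temp * cooling
  }
  list(internal_states = best[internal_ids], loglik = best_ll,
       loglik_init = ll_init)
}

#' Generate a set of categorical permulations
#'
#' Each draw composes the three permulation steps: (i) rejection-sample a
#' CTMM-simulated phenotype whose extant category counts match the observed
#' ones (within the relaxation tolerance); (ii) discard the simulated
#' internal states and place a random permutation of the observed
#' reconstruction's internal states instead; (iii) re-organize those
#' internal states by simulated annealing to improve the likelihood of the
#' full labeling against the simulated tips. Per-branch category labels
#' are then derived by the child-node rule.
#'
#' @param master master `phylo` tree (average-rate branch lengths).
#' @param fit a `ctmm_fit` for the observed phenotype.
#' @param recon the observed [marginal_reconstruction()].
#' @param pheno the observed [phenotype_vector()].
#' @param config a [permulation_config()].
#' @param idx optional [branch_index()]; built from `master` when `NULL`.
#' @return object of class `permulation_set`: `tip_states` (tips x n),
#'   `internal_states` (internals x n), `branch_states` (branches x n,
#'   integer category indices in `idx` order), `attempts`, `loglik`,
#'   `levels`, `config`.
#' @export
permulate <- function(master, fit, recon, pheno, config = permulation_config(),
                      idx = NULL) {
  stopifnot(inherits(fit, "ctmm_fit"), inherits(recon, "ancestral_recon"))
  validate_phylo(master)
  if (is.null(idx)) idx <- branch_index(master)
  lv <- fit$levels
  K <- length(lv)
  post <- idx$tree
  ntip <- length(post$tip.label)
  obs_counts <- tabulate(tip_state_indices(post, pheno), nbins = K)
  obs_internal <- recon$ml[(length(recon$tree$tip.label) + 1L):length(recon$ml)]
  # recon and idx share master node numbering (both postorder of master)
  tips_m <- matrix(0L, ntip, config$n, dimnames = list(post$tip.label, NULL))
  int_m <- matrix(0L, post$Nnode, config$n)
  br_m <- matrix(0L, idx$n_branches, config$n)
  attempts <- integer(config$n)
  lls <- numeric(config$n)
  for (i in seq_len(config$n)) {
    s <- config$seed + i
    rs <- rejection_sample(post, fit$Q, fit$prior, obs_counts,
                           relax = config$relax,
                           max_attempts = config$max_attempts, seed = s)
    perm <- permute_internal(obs_internal)
    ann <- anneal_internal(post, rs$tip_states[post$tip.label], perm,
                           fit$Q, fit$prior,
                           t_init = config$t_init, cooling = config$cooling,
                           steps = config$steps)
    states <- c(rs$tip_states[post$tip.label], ann$internal_states)
    tips_m[, i] <- states[seq_len(ntip)]
    int_m[, i] <- ann$internal_states
    br_m[, i] <- states[idx$edge[, 2L]]
    attempts[i] <- rs$attempts
    lls[i] <- ann$loglik
  }
  structure(list(tip_states = tips_m, internal_states = int_m,
                 branch_states = br_m, attempts = attempts, loglik = lls,
                 levels = lv, config = config, idx_keys = idx$keys),
            class = "permulation_set")
}

#' @export
print.permulation_set <- function(x, ...) {
  cat("Permulation set:", ncol(x$tip_states), "draws, relax =",
      x$config$relax, ", mean attempts/draw =",
      round(mean(x$attempts), 2), "\n")
  invisible(x)
}

#' Score permulations with the per-gene omnibus statistic
#'
#' Runs the same omnibus association used by [gene_scan()] on every
#' permulated branch labeling, returning the null effect-size matrix
#' (epsilon-squared for `"kw"`, eta-squared for `"anova"`). Gene ranks are
#' precomputed once per gene, so scoring scales to hundreds of draws.
#'
#' @param rers RER matrix (branches x genes) aligned with the permulation
#'   set's branch order.
#' @param perms a `permulation_set`.
#' @param method `"kw"` or `"anova"`.
#' @param min_per_category per-category branch minimum; draws where a gene
#'   fails it yield `NA` for that gene.
#' @param value `"effect"` (default) returns effect sizes; `"neglogp"`
#'   returns `-log10` of the parametric omnibus p instead (Kruskal-Wallis
#'   only), the scale used by the omnibus gene ranking.
#' @return genes x draws matrix of null statistics.
#' @export
score_permulations <- function(rers, perms, method = c("kw", "anova"),
                               min_per_category = 2L,
                               value = c("effect", "neglogp")) {
  method <- match.arg(method)
  value <- match.arg(value)
  if (value == "neglogp" && method != "kw")
    stop("value = 'neglogp' is available for method = 'kw' only")
  stopifnot(inherits(perms, "permulation_set"),
            nrow(rers) == nrow(perms$branch_states))
  G <- ncol(rers); N <- ncol(perms$branch_states)
  K <- length(perms$levels)
  obs_mask <- !is.na(rers)
  ranks <- vector("list", G)
  tiecorr <- numeric(G); nn <- integer(G)
  for (g in seq_len(G)) {
    y <- rers[obs_mask[, g], g]
    ranks[[g]] <- rank(y)
    nn[g] <- length(y)
    t_ <- table(y)
    tiecorr[g] <- 1 - sum(t_^3 - t_) / max(nn[g]^3 - nn[g], 1)
  }
  out <- matrix(NA_real_, G, N, dimnames = list(colnames(rers), NULL))
  for (j in seq_len(N)) {
    lab <- perms$branch_states[, j]
    for (g in seq_len(G)) {
      gl <- lab[obs_mask[, g]]
      cnt <- tabulate(gl, nbins = K)
      if (any(cnt < min_per_category)) next
      n <- nn[g]
      if (method == "kw") {
        Rsum <- vapply(seq_len(K), function(k) sum(ranks[[g]][gl == k]), 0)
        H <- 12 / (n * (n + 1)) * sum(Rsum^2 / cnt) - 3 * (n + 1)
        if (tiecorr[g] > 0) H <- H / tiecorr[g]
        H <- max(H, 0)
        out[g, j] <- if (value == "neglogp")
          -stats::pchisq(H, K - 1, lower.tail = FALSE, log.p = TRUE) / log(10)
        else H / (n - 1)
      } else {
        y <- rers[obs_mask[, g], g]
        m <- mean(y)
        mu_k <- vapply(seq_len(K), function(k) mean(y[gl == k]), 0)
        ssb <- sum(cnt * (mu_k - m)^2)
        sst <- sum((y - m)^2)
        out[g, j] <- if (sst > 0) ssb / sst else 0
      }
    }
  }
  out
}

#' Empirical p-values from permulation nulls
#'
#' One-sided: the proportion of null statistics at least as large as the
#' observed one. Two-sided: the proportion whose absolute value is at
#' least the observed absolute value. A p of exactly 0 (observed more
#' extreme than every null) is flagged and displayed as `< 1/N`; no
#' add-one correction is applied unless `add_one = TRUE`.
#'
#' @param observed numeric vector of observed statistics (one per item).
#' @param nulls matrix items x N of null statistics (NA nulls are ignored
#'   per item).
#' @param sided `"greater"` (one-sided, default) or `"two.sided"`.
#' @param add_one use the (b+1)/(N+1) estimator instead of b/N.
#' @return data frame with `p`, `n_null`, `floor` (logical) and `display`.
#' @export
empirical_pvalues <- function(observed, nulls,
                              sided = c("greater", "two.sided"),
                              add_one = FALSE) {
  sided <- match.arg(sided)
  if (is.vector(nulls)) nulls <- matrix(nulls, nrow = 1L)
  stopifnot(length(observed) == nrow(nulls))
  p <- n_null <- numeric(length(observed))
  for (i in seq_along(observed)) {
    z <- nulls[i, ]
    z <- z[!is.na(z)]
    if (length(z) == 0L) stop("item ", i, " has no null statistics")
    n_null[i] <- length(z)
    b <- if (sided == "greater") sum(z >= observed[i])
         else sum(abs(z) >= abs(observed[i]))
    p[i] <- if (add_one) (b + 1) / (length(z) + 1) else b / length(z)
  }
  fl <- p == 0
  data.frame(p = p, n_null = n_null, floor = fl,
             display = ifelse(fl, paste0("< ", format(1 / n_null, digits = 3)),
                              format(p, digits = 4)))
}
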