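#' Construct a rate model for the transition rate matrix
#'
#' A rate model ties the off-diagonal entries of the K x K generator Q to
#' shared free parameters through an integer index matrix with zero
#' diagonal. The standard schemes are ER (equal rates, 1 parameter), SYM
#' (symmetric, K(K-1)/2) and ARD (all rates different, K(K-1)); a custom
#' index matrix can be supplied instead of a scheme name.
#'
#' @param K number of categories (>= 2).
#' @param kind `"ER"`, `"SYM"`, `"ARD"`, or a K x K integer index matrix
#'   with zero diagonal and off-diagonal indices forming 1..max with no gaps.
#' @return an object of class `rate_model` with elements `K`, `index`,
#'   `n_par`, `name`.
#' @examples
#' make_rate_model(3, "ER")$n_par   # 1
#' make_rate_model(3, "ARD")$n_par  # 6
#' @export
make_rate_model <- function(K, kind = "ARD") {
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  if (is.matrix(kind)) {
    index <- kind
    if (!all(dim(index) == c(K, K))) stop("custom index matrix must be K x K")
    if (any(diag(index) != 0)) stop("custom index matrix must have zero diagonal")
    off <- index[row(index) != col(index)]
    if (any(off != as.integer(off)) || any(off < 1))
      stop("off-diagonal indices must be positive integers")
    m <- max(off)
    if (!setequal(unique(off), seq_len(m)))
      stop("off-diagonal indices must form 1..max with no gaps")
    name <- "custom"
  } else {
    name <- match.arg(kind, c("ER", "SYM", "ARD"))
    index <- matrix(0L, K, K)
    if (name == "ER") {
      index[row(index) != col(index)] <- 1L
    } else if (name == "SYM") {
      k <- 0L
      for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
        k <- k + 1L; index[i, j] <- k; index[j, i] <- k
      }
    } else {
      k <- 0L
      for (i in seq_len(K)) for (j in seq_len(K)) if (i != j) {
        k <- k + 1L; index[i, j] <- k
      }
    }
  }
  structure(list(K = K, index = index, n_par = as.integer(max(index)),
                 name = name),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("Rate model", x$name, "- K =", x$K, ",", x$n_par, "free parameter(s)\n")
  invisible(x)
}

# Assemble Q from a rate model and a positive rate vector.
build_Q <- function(model, rates) {
  stopifnot(inherits(model, "rate_model"), length(rates) == model$n_par)
  Q <- matrix(0, model$K, model$K)
  off <- model$index > 0
  Q[off] <- rates[model$index[off]]
  diag(Q) <- -rowSums(Q)
  Q
}

# `simple` is nested within `complex` iff every tie imposed by `complex`
# is also imposed by `simple` (then simple's parameter space is a subset).
is_nested <- function(simple, complex) {
  off <- row(simple$index) != col(simple$index)
  groups <- split(simple$index[off], complex$index[off])
  all(vapply(groups, function(g) length(unique(g)) == 1L, TRUE)) &&
    simple$n_par <= complex$n_par
}

# Transition matrices exp(Q t) for a vector of branch lengths.
# Eigendecomposition path (one decomposition, then K x K products per
# length); falls back to a Pade expm when Q is numerically defective.
edge_transition_probs <- function(Q, lens) {
  K <- nrow(Q)
  dec <- tryCatch({
    e <- eigen(Q)
    Vi <- solve(e$vectors)
    list(V = e$vectors, Vi = Vi, lam = e$values)
  }, error = function(e) NULL)
  mk <- function(t) {
    if (t == 0) return(diag(K))
    P <- if (!is.null(dec))
      Re(dec$V %*% (exp(dec$lam * t) * dec$Vi))
    else as.matrix(Matrix::expm(Q * t))
    if (any(!is.finite(P)) || max(abs(rowSums(P) - 1)) > 1e-6)
      P <- as.matrix(Matrix::expm(Q * t))
    P[P < 0] <- 0
    P / rowSums(P)
  }
  lapply(lens, mk)
}

#' Transition probability matrix of the CTMM
#'
#' Computes `exp(Q t)`, the probability of each ordered state change over a
#' branch of length `t` under generator `Q`. Rows sum to 1 and entries lie
#' in `[0, 1]`; `t = 0` gives the identity.
#'
#' @param Q K x K generator (non-negative off-diagonals, zero row sums).
#' @param t non-negative branch length.
#' @return K x K stochastic matrix.
#' @export
transition_probabilities <- function(Q, t) {
  if (t < 0) stop("t must be non-negative")
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  if (max(abs(rowSums(Q))) > 1e-8) stop("Q rows must sum to 0")
  edge_transition_probs(Q, t)[[1L]]
}

# Stationary distribution of Q (pi Q = 0, sum pi = 1).
stationary_distribution <- function(Q) {
  K <- nrow(Q)
  A <- t(Q); A[K, ] <- 1
  pi_ <- solve(A, c(rep(0, K - 1L), 1))
  pi_[pi_ < 0] <- 0
  pi_ / sum(pi_)
}

resolve_prior <- function(root_prior, Q, K) {
  if (is.numeric(root_prior)) {
    if (length(root_prior) != K || any(root_prior < 0) || sum(root_prior) <= 0)
      stop("invalid numeric root prior")
    return(root_prior / sum(root_prior))
  }
  switch(match.arg(root_prior, c("flat", "stationary")),
         flat = rep(1 / K, K),
         stationary = stationary_distribution(Q))
}

# Tip states as integer indices into the phenotype registry, in tip order.
tip_state_indices <- function(tree, pheno) {
  lv <- categories(pheno)
  miss <- setdiff(tree$tip.label, names(pheno))
  if (length(miss))
    stop("tips missing from phenotype table: ", paste(miss, collapse = ", "))
  match(unclass(pheno)[tree$tip.label], lv)
}

# Felsenstein pruning pass. Returns per-node scaled conditional likelihoods
# F (data below node | node state), per-node log scale factors, the
# postorder tree and edge transition matrices.
pruning_pass <- function(tree, tip_idx, Q, prior) {
  K <- nrow(Q)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  post <- stats::reorder(tree, "postorder")
  P <- edge_transition_probs(Q, post$edge.length)
  Fm <- matrix(1, nn, K)
  Fm[seq_len(ntip), ] <- 0
  Fm[cbind(seq_len(ntip), tip_idx)] <- 1
  logsc <- numeric(nn)
  e <- post$edge
  for (k in seq_len(nrow(e))) {
    p <- e[k, 1L]; ch <- e[k, 2L]
    msg <- as.vector(P[[k]] %*% Fm[ch, ])
    Fm[p, ] <- Fm[p, ] * msg
    logsc[p] <- logsc[p] + logsc[ch]
    mx <- max(Fm[p, ])
    if (mx <= 0) return(list(loglik = -Inf, F = Fm, logsc = logsc,
                             post = post, P = P))
    Fm[p, ] <- Fm[p, ] / mx
    logsc[p] <- logsc[p] + log(mx)
  }
  root <- e[nrow(e), 1L]
  ll <- log(sum(prior * Fm[root, ])) + logsc[root]
  list(loglik = ll, F = Fm, logsc = logsc, post = post, P = P, root = root)
}

#' Log-likelihood of tip states under a CTMM
#'
#' Felsenstein's pruning algorithm: the log of the probability of the
#' observed tip categories summed over all internal state assignments,
#' weighted at the root by `root_prior`.
#'
#' @param tree a `phylo` tree whose tips all appear in `pheno`.
#' @param pheno a [phenotype_vector()]; its registry order fixes the state
#'   order of `Q`.
#' @param Q K x K generator matrix.
#' @param root_prior `"flat"` (default), `"stationary"`, or a numeric
#'   vector of length K.
#' @return the log-likelihood (scalar).
#' @export
pruning_loglik <- function(tree, pheno, Q, root_prior = "flat") {
  validate_phylo(tree)
  tip_idx <- tip_state_indices(tree, pheno)
  prior <- resolve_prior(root_prior, Q, nrow(Q))
  pruning_pass(tree, tip_idx, Q, prior)$loglik
}

#' Fit a CTMM to observed tip categories by maximum likelihood
#'
#' Optimizes the free rates of a [make_rate_model()] on the log scale
#' (which enforces positivity) with seeded multi-start optimization; rate
#' surfaces for richer models are multimodal, so the reported optimum is
#' the best over `n_starts` starts drawn log-uniformly on
#' `[1e-3, 10] / tree height`. One-parameter models use bounded
#' one-dimensional optimization instead.
#'
#' @param tree a `phylo` tree.
#' @param pheno a [phenotype_vector()] covering the tips; at least two
#'   categories must be observed on the tree.
#' @param model a [make_rate_model()] or a scheme name (`"ER"`, `"SYM"`,
#'   `"ARD"`).
#' @param root_prior root prior policy, see [pruning_loglik()].
#' @param n_starts number of optimization starts (default 5).
#' @param seed integer seed making the starts reproducible.
#' @return an object of class `ctmm_fit`: `Q`, `rates`, `loglik`, `model`,
#'   `root_prior` (policy), `prior` (vector at the optimum), `levels`,
#'   `convergence`, `seed`.
#' @export
fit_ctmm <- function(tree, pheno, model = "ARD", root_prior = "flat",
                     n_starts = 5L, seed = 1L) {
  validate_phylo(tree)
  lv <- categories(pheno)
  K <- length(lv)
  if (K < 2L) stop("phenotype must register at least 2 categories")
  if (!is.list(model)) model <- make_rate_model(K, model)
  stopifnot(model$K == K)
  tip_idx <- tip_state_indices(tree, pheno)
  if (length(unique(tip_idx)) < 2L)
    stop("degenerate phenotype: all tree tips share one category")
  if (sum(tree$edge.length) <= 0) stop("tree must have positive total length")

  th <- max(ape::node.depth.edgelength(tree))
  numeric_prior <- is.numeric(root_prior)
  negll <- function(logr) {
    Q <- build_Q(model, exp(logr))
    prior <- resolve_prior(root_prior, Q, K)
    ll <- pruning_pass(tree, tip_idx, Q, prior)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  lo <- log(1e-8 / th); hi <- log(1e4 / th)
  best <- NULL
  if (model$n_par == 1L) {
    op <- stats::optim(log(1 / th), negll, method = "Brent",
                       lower = lo, upper = hi)
    best <- op
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    starts <- matrix(stats::runif(n_starts * model$n_par,
                                  log(1e-3 / th), log(10 / th)),
                     n_starts, model$n_par)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    for (s in seq_len(n_starts)) {
      op <- stats::optim(starts[s, ], negll, method = "Nelder-Mead",
                         control = list(maxit = 3000, reltol = 1e-10))
      if (is.null(best) || op$value < best$value) best <- op
    }
  }
  rates <- exp(best$par)
  Q <- build_Q(model, rates)
  dimnames(Q) <- list(lv, lv)
  structure(list(
    Q = Q, rates = rates, loglik = -best$value, model = model,
    root_prior = if (numeric_prior) "user" else root_prior,
    prior = resolve_prior(root_prior, Q, K),
    levels = lv, convergence = best$convergence,
    n_starts = if (model$n_par == 1L) 1L else n_starts, seed = seed
  ), class = "ctmm_fit")
}

#' @export
print.ctmm_fit <- function(x, ...) {
  cat("CTMM fit:", x$model$name, "model, K =", x$model$K,
      "| logLik =", format(x$loglik, digits = 6),
      "|", x$model$n_par, "parameter(s)\n")
  print(round(x$Q, 5))
  invisible(x)
}

#' Likelihood-ratio selection among nested rate models
#'
#' Compares consecutive fits ordered by number of free parameters; each
#' comparison uses the statistic `2 * (lnL_complex - lnL_simple)` against a
#' chi-square with df equal to the parameter-count difference. Starting
#' from the simplest model, the richer model is adopted whenever the
#' simpler one is rejected at `alpha`.
#'
#' @param fits list of `ctmm_fit` objects for nested models.
#' @param alpha rejection level (default 0.05).
#' @return list with `best` (the chosen fit) and `table` (per-comparison
#'   statistic, df and p-value).
#' @export
lrt_select <- function(fits, alpha = 0.05) {
  stopifnot(length(fits) >= 2L, all(vapply(fits, inherits, TRUE, "ctmm_fit")))
  np <- vapply(fits, function(f) f$model$n_par, 1L)
  fits <- fits[order(np)]
  rows <- list()
  cur <- fits[[1L]]
  for (i in 2L:length(fits)) {
    nxt <- fits[[i]]
    if (!is_nested(cur$model, nxt$model))
      stop("models ", cur$model$name, " and ", nxt$model$name, " are not nested")
    stat <- 2 * (nxt$loglik - cur$loglik)
    df <- nxt$model$n_par - cur$model$n_par
    stat <- max(stat, 0)
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      simple = cur$model$name, complex = nxt$model$name,
      statistic = stat, df = df, p = p)
    if (p < alpha) cur <- nxt
  }
  list(best = cur, table = do.call(rbind, rows))
}

#' Marginal ancestral state reconstruction
#'
#' Two-pass conditioning: a postorder (pruning) pass collects the
#' likelihood of the data below each node, a preorder pass propagates the
#' evidence from the rest of the tree, and the per-node marginal posterior
#' over categories is their normalized product. The ML state is the argmax
#' with ties broken toward the lowest registry index; each branch is
#' labeled with the ML state of its child node (tips keep their observed
#' state), since a branch's rate is measured on the lineage ending at the
#' child. A joint (max-product) reconstruction is available with
#' `type = "joint"`.
#'
#' @param tree a `phylo` tree.
#' @param pheno a [phenotype_vector()].
#' @param fit a `ctmm_fit`, or a K x K generator matrix `Q`.
#' @param root_prior root prior; defaults to the fit's policy when a fit is
#'   given, otherwise `"flat"`.
#' @param type `"marginal"` (default) or `"joint"`.
#' @return an object of class `ancestral_recon`: `prob` (nodes x K marginal
#'   probabilities; for `"joint"`, indicator rows of the joint ML states),
#'   `ml` (per-node state index), `levels`, `tree` (postorder), `edge`,
#'   `branch_states` (state index per edge, child rule), `root_prior`.
#' @export
marginal_reconstruction <- function(tree, pheno, fit, root_prior = NULL,
                                    type = c("marginal", "joint")) {
  type <- match.arg(type)
  validate_phylo(tree)
  if (inherits(fit, "ctmm_fit")) {
    Q <- fit$Q
    if (is.null(root_prior)) root_prior <- fit$prior
  } else {
    Q <- fit
    if (is.null(root_prior)) root_prior <- "flat"
  }
  K <- nrow(Q)
  lv <- categories(pheno)
  stopifnot(K == length(lv))
  tip_idx <- tip_state_indices(tree, pheno)
  prior <- resolve_prior(root_prior, Q, K)
  ntip <- length(tree$tip.label)

  if (type == "joint") {
    rec <- joint_reconstruction(tree, tip_idx, Q, prior)
    post <- rec$post; ml <- rec$ml
    prob <- matrix(0, length(ml), K)
    prob[cbind(seq_along(ml), ml)] <- 1
  } else {
    pp <- pruning_pass(tree, tip_idx, Q, prior)
    if (!is.finite(pp$loglik)) stop("zero-likelihood data under this model")
    post <- pp$post
    e <- post$edge
    nn <- nrow(pp$F)
    # per-edge upward message: P_k %*% F[child]
    msg <- matrix(0, nrow(e), K)
    for (k in seq_len(nrow(e))) msg[k, ] <- as.vector(pp$P[[k]] %*% pp$F[e[k, 2L], ])
    children_edges <- split(seq_len(nrow(e)), e[, 1L])
    G <- matrix(0, nn, K)
    G[pp$root, ] <- prior
    # preorder = reverse postorder over edges
    for (k in rev(seq_len(nrow(e)))) {
      p <- e[k, 1L]; ch <- e[k, 2L]
      sib <- rep(1, K)
      for (j in children_edges[[as.character(p)]])
        if (j != k) sib <- sib * msg[j, ]
      gc <- as.vector(crossprod(pp$P[[k]], G[p, ] * sib))
      s <- sum(gc)
      G[ch, ] <- if (s > 0) gc / s else rep(1 / K, K)
    }
    prob <- pp$F * G
    rs <- rowSums(prob)
    rs[rs == 0] <- 1
    prob <- prob / rs
    ml <- max.col(prob, ties.method = "first")
    ml[seq_len(ntip)] <- tip_idx[match(post$tip.label, tree$tip.label)]
  }
  colnames(prob) <- lv
  structure(list(
    prob = prob, ml = ml, levels = lv, tree = post, edge = post$edge,
    branch_states = ml[post$edge[, 2L]],
    root_prior = prior, type = type
  ), class = "ancestral_recon")
}

# Max-product (joint ML) reconstruction with backtracking.
joint_reconstruction <- function(tree, tip_idx, Q, prior) {
  K <- nrow(Q)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  post <- stats::reorder(tree, "postorder")
  P <- edge_transition_probs(Q, post$edge.length)
  e <- post$edge
  Lm <- matrix(0, nn, K)   # log max-likelihood of subtree given node state
  Lm[seq_len(ntip), ] <- -Inf
  Lm[cbind(seq_len(ntip), tip_idx)] <- 0
  back <- vector("list", nrow(e))
  for (k in seq_len(nrow(e))) {
    p <- e[k, 1L]; ch <- e[k, 2L]
    lp <- log(pmax(P[[k]], 1e-300))
    cand <- sweep(lp, 2L, Lm[ch, ], "+")   # cand[sp, sc]
    back[[k]] <- max.col(cand, ties.method = "first")
    Lm[p, ] <- Lm[p, ] + apply(cand, 1L, max)
  }
  root <- e[nrow(e), 1L]
  ml <- integer(nn)
  ml[root] <- which.max(log(pmax(prior, 1e-300)) + Lm[root, ])
  for (k in rev(seq_len(nrow(e)))) ml[e[k, 2L]] <- back[[k]][ml[e[k, 1L]]]
  list(post = post, ml = ml)
}

#' @export
print.ancestral_recon <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  cat("Ancestral reconstruction (", x$type, "): ", ntip, " tips, ",
      x$tree$Nnode, " internal nodes, K = ", length(x$levels), "\n", sep = "")
  print(table(factor(x$levels[x$ml[-seq_len(ntip)]], levels = x$levels)))
  invisible(x)
}

#' Per-branch category labels in branch-index order
#'
#' Maps a reconstruction's branch states (child-node rule) onto the
#' deterministic edge order of a [branch_index()] built from the same
#' master tree.
#'
#' @param recon an `ancestral_recon`.
#' @param idx a `branch_index` of the same tree.
#' @return character vector of category labels, one per master branch, with
#'   the registry as a `levels` attribute.
#' @export
branch_labels <- function(recon, idx) {
  stopifnot(inherits(recon, "ancestral_recon"), inherits(idx, "branch_index"))
  if (!identical(sort(recon$tree$tip.label), sort(idx$tree$tip.label)))
    stop("reconstruction and branch index are from different trees")
  rk <- vapply(clade_tip_sets(recon$tree)[recon$edge[, 2L]],
               paste, "", collapse = "|")
  pos <- match(idx$keys, rk)
  if (anyNA(pos)) stop("branch index does not match reconstruction tree")
  structure(recon$levels[recon$branch_states[pos]], levels = recon$levels)
}

#' Count state transitions along the tree
#'
#' Scans every edge of the reconstruction; when the ML states of parent and
#' child differ, the count of that unordered state pair is incremented.
#' Each such transition is a potential independent convergence event.
#'
#' @param recon an `ancestral_recon`.
#' @return data frame with columns `from`, `to` (unordered pair in registry
#'   order) and `count`, covering all K(K-1)/2 pairs.
#' @export
count_transitions <- function(recon) {
  stopifnot(inherits(recon, "ancestral_recon"))
  lv <- recon$levels
  K <- length(lv)
  cnt <- matrix(0L, K, K)
  e <- recon$edge
  for (k in seq_len(nrow(e))) {
    a <- recon$ml[e[k, 1L]]; b <- recon$ml[e[k, 2L]]
    if (a != b) {
      i <- min(a, b); j <- max(a, b)
      cnt[i, j] <- cnt[i, j] + 1L
    }
  }
  pairs <- utils::combn(K, 2)
  data.frame(from = lv[pairs[1L, ]], to = lv[pairs[2L, ]],
             count = cnt[t(pairs)])
}
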