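#' RER computation settings
#'
#' Defaults mirror the established relative-rate procedure: square-root
#' transform of branch lengths on, winsorization of the 3 most extreme
#' values per gene tail, variance-weighted regression with per-branch
#' variances estimated from cross-gene residual spread (floored at their
#' 5th percentile to avoid infinite weights), and a minimum of 10 species
#' per gene.
#'
#' @param sqrt_transform square-root transform lengths and expectations.
#' @param weighted use per-branch variance weights in the regression.
#' @param winsorize number of values clamped per gene tail (>= 0).
#' @param min_species minimum species per gene (>= 3).
#' @return a list of class `rer_config`.
#' @export
rer_config <- function(sqrt_transform = TRUE, weighted = TRUE,
                       winsorize = 3L, min_species = 10L) {
  winsorize <- as.integer(winsorize); min_species <- as.integer(min_species)
  if (winsorize < 0L) stop("winsorize must be >= 0")
  if (min_species < 3L) stop("min_species must be >= 3")
  structure(list(sqrt_transform = sqrt_transform, weighted = weighted,
                 winsorize = winsorize, min_species = min_species),
            class = "rer_config")
}

#' Branch-length matrix of a gene tree set
#'
#' Maps every gene's branch lengths onto the master branches (rows in
#' [branch_index()] order, `NA` where a gene lacks a branch). Genes with
#' fewer species than `min_species` are dropped and recorded in the
#' `dropped` attribute.
#'
#' @param genes a `gene_tree_set`.
#' @param idx a `branch_index` of the master tree.
#' @param min_species minimum tips per gene.
#' @return numeric matrix branches x genes with attributes `n_tips`
#'   (species per retained gene) and `dropped`.
#' @export
build_branch_matrix <- function(genes, idx, min_species = 10L) {
  stopifnot(inherits(genes, "gene_tree_set"), inherits(idx, "branch_index"))
  if (length(genes$trees) == 0L) stop("empty gene tree set")
  ntips <- vapply(genes$trees, function(t) length(t$tip.label), 1L)
  keep <- ntips >= min_species
  if (!any(keep)) stop("no gene has >= ", min_species, " species")
  mat <- vapply(genes$trees[keep], map_gene_branches, numeric(idx$n_branches),
                idx = idx)
  rownames(mat) <- idx$keys
  attr(mat, "n_tips") <- ntips[keep]
  attr(mat, "dropped") <- names(genes$trees)[!keep]
  mat
}

#' Genome-wide expected branch lengths
#'
#' Iteratively estimates the per-branch expectation against which gene
#' branch lengths are compared. Each iteration rescales every gene by its
#' least-squares projection onto the current expectation (removing
#' gene-level rate differences) and re-averages across genes; iteration
#' stops when the maximum relative change falls below `tol` (at most
#' `max_iter` rounds). If all genes are exact scalar multiples of one
#' vector, the fixed point is reached after one iteration.
#'
#' @param mat branch x gene matrix from [build_branch_matrix()].
#' @param max_iter iteration cap (default 20).
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @return numeric vector of expected lengths per branch (`NA` for branches
#'   present in no gene), with an `iterations` attribute.
#' @export
expected_lengths <- function(mat, max_iter = 20L, tol = 1e-6) {
  if (ncol(mat) < 2L) stop("need at least 2 genes")
  e <- rowMeans(mat, na.rm = TRUE)
  e[is.nan(e)] <- NA_real_
  it <- 0L
  for (it in seq_len(max_iter)) {
    scl <- gene_scales(mat, e)
    e_new <- rowMeans(sweep(mat, 2L, scl, "/"), na.rm = TRUE)
    e_new[is.nan(e_new)] <- NA_real_
    rel <- abs(e_new - e) / pmax(abs(e), 1e-12)
    if (max(rel, na.rm = TRUE) < tol) { e <- e_new; break }
    e <- e_new
  }
  attr(e, "iterations") <- it
  e
}

# Least-squares projection scale of each gene column onto the expectation.
gene_scales <- function(mat, e) {
  apply(mat, 2L, function(x) {
    obs <- !is.na(x) & !is.na(e)
    s <- sum(x[obs] * e[obs]) / sum(e[obs]^2)
    if (!is.finite(s) || s <= 0) 1 else s
  })
}

winsorize_vec <- function(x, n_tail) {
  if (n_tail <= 0L || length(x) <= 2L * n_tail + 1L) return(x)
  s <- sort(x)
  lo <- s[n_tail + 1L]; hi <- s[length(s) - n_tail]
  pmin(pmax(x, lo), hi)
}

#' Relative evolutionary rates
#'
#' For each gene: the column is scale-normalized by its projection onto the
#' expectation (so multiplying a gene's lengths by any positive constant
#' leaves its RERs unchanged), optionally square-root transformed together
#' with the expectation, winsorized (gene values and paired expectations
#' are each clamped at the `winsorize`-th most extreme value per tail,
#' after the transform and before the regression), and regressed on the
#' transformed expectation; the (optionally variance-weighted) regression residuals are
#' the RERs. Positive values mean the gene evolves faster than expected on
#' that branch, negative slower. Missingness propagates: the RER is `NA`
#' exactly where the branch length is.
#'
#' @param mat branch x gene matrix from [build_branch_matrix()].
#' @param expectation per-branch expectation; computed with
#'   [expected_lengths()] when `NULL`.
#' @param config an [rer_config()].
#' @return matrix of RERs with the same dimensions and dimnames as `mat`
#'   (class `rer_matrix`).
#' @export
compute_rers <- function(mat, expectation = NULL, config = rer_config()) {
  if (is.null(expectation)) expectation <- expected_lengths(mat)
  ntips <- attr(mat, "n_tips")
  if (!is.null(ntips)) {
    keep <- ntips >= config$min_species
    mat <- mat[, keep, drop = FALSE]
  }
  resid_pass <- function(weights) {
    out <- matrix(NA_real_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
    for (g in seq_len(ncol(mat))) {
      obs <- which(!is.na(mat[, g]) & !is.na(expectation))
      if (length(obs) < 3L) next
      x <- mat[obs, g]; e <- expectation[obs]
      s <- sum(x * e) / sum(e^2)
      if (!is.finite(s) || s <= 0) next
      x <- x / s
      if (config$sqrt_transform) { x <- sqrt(x); e2 <- sqrt(e) } else e2 <- e
      x <- winsorize_vec(x, config$winsorize)
      e2 <- winsorize_vec(e2, config$winsorize)
      w <- if (is.null(weights)) rep(1, length(obs)) else weights[obs]
      X <- cbind(1, e2)
      out[obs, g] <- stats::lm.wfit(X, x, w)$residuals
    }
    out
  }
  res <- resid_pass(NULL)
  if (config$weighted) {
    v <- apply(res, 1L, stats::var, na.rm = TRUE)
    v[is.na(v)] <- Inf
    fl <- stats::quantile(v[is.finite(v)], 0.05, na.rm = TRUE)
    if (is.finite(fl) && fl > 0) v <- pmax(v, fl)
    w_b <- 1 / v
    w_b[!is.finite(w_b)] <- 0
    res <- resid_pass(w_b)
  }
  class(res) <- c("rer_matrix", class(res))
  res
}

#' One-call RER pipeline from trees to an RER matrix
#' @param genes a `gene_tree_set`.
#' @param master the master `phylo` tree.
#' @param config an [rer_config()].
#' @return list with `rers`, `expectation`, `idx`.
#' @export
rer_matrix <- function(genes, master, config = rer_config()) {
  idx <- branch_index(master)
  mat <- build_branch_matrix(genes, idx, min_species = config$min_species)
  e <- expected_lengths(mat)
  list(rers = compute_rers(mat, e, config), expectation = e, idx = idx)
}

#' Write an RER matrix as TSV (rows = branch keys, columns = genes)
#' @param rers an `rer_matrix`.
#' @param file output path.
#' @export
write_rers <- function(rers, file) {
  df <- data.frame(branch = rownames(rers), unclass(rers),
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
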