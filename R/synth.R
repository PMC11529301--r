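#' Random master tree
#'
#' A random rooted topology with independent exponential branch lengths,
#' standing in for a species tree whose branch lengths are average
#' genome-wide substitution rates. The default mean branch length of 0.1
#' substitutions per site is typical of genome-average rates on mammalian
#' time scales.
#'
#' @param n_tips number of tips (>= 3).
#' @param mean_branch mean branch length (default 0.1).
#' @param seed optional integer seed.
#' @return a `phylo` tree with tips `t1..tn`.
#' @export
random_tree <- function(n_tips, mean_branch = 0.1, seed = NULL) {
  n_tips <- as.integer(n_tips)
  if (n_tips < 3L) stop("n_tips must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n_tips, br = function(n) stats::rexp(n, rate = 1 / mean_branch))
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}

#' Simulate a categorical phenotype along a tree
#'
#' CTMM simulation from root to tips; returns the observed tip phenotype
#' and the true internal states so that reconstruction accuracy can be
#' scored against the truth.
#'
#' @param tree a `phylo` tree.
#' @param Q K x K generator.
#' @param prior root prior (default flat).
#' @param labels category labels (default `LETTERS[1:K]`).
#' @param seed optional seed.
#' @return list with `pheno` (a [phenotype_vector()] over tips),
#'   `internal_states` (true integer states of internal nodes),
#'   `node_states` (all nodes).
#' @export
simulate_phenotype_on_tree <- function(tree, Q, prior = "flat",
                                       labels = NULL, seed = NULL) {
  K <- nrow(Q)
  if (is.null(labels)) labels <- LETTERS[seq_len(K)]
  stopifnot(length(labels) == K)
  sim <- simulate_tip_states(tree, Q, prior, seed = seed)
  ntip <- length(tree$tip.label)
  pheno <- phenotype_vector(names(sim$tip_states),
                            labels[sim$tip_states], levels = labels)
  list(pheno = pheno,
       internal_states = sim$node_states[(ntip + 1L):length(sim$node_states)],
       node_states = sim$node_states)
}

#' Shift specification for planted rate shifts
#'
#' @param category target category label whose branches are accelerated
#'   (or decelerated) in affected genes.
#' @param multiplier rate multiplier (> 0) applied on target-category
#'   branches of affected genes.
#' @param fraction fraction of genes affected, in `[0, 1]`.
#' @param noise_sd standard deviation (log scale) of per-branch
#'   multiplicative lognormal noise.
#' @param gene_scale_sd log-sd of the per-gene overall rate scale.
#' @return list of class `shift_spec`.
#' @export
shift_spec <- function(category, multiplier = 3, fraction = 0.1,
                       noise_sd = 0.3, gene_scale_sd = 0.2) {
  if (multiplier <= 0) stop("multiplier must be > 0")
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  structure(list(category = category, multiplier = multiplier,
                 fraction = fraction, noise_sd = noise_sd,
                 gene_scale_sd = gene_scale_sd), class = "shift_spec")
}

#' Simulate gene trees with category-linked rate shifts
#'
#' Gene g's length on branch b is
#' `master_b * scale_g * noise_gb * multiplier^[g affected and label(b) = target]`,
#' with lognormal per-branch noise (mean 1) and a lognormal per-gene
#' scale. Affected genes are a seeded random subset of the requested
#' fraction; the truth table records them.
#'
#' @param master master `phylo` tree.
#' @param labels per-branch category labels in [branch_index()] order
#'   (e.g. the truth from [simulate_phenotype_on_tree()] via
#'   [branch_labels()], or any character vector over branches).
#' @param n_genes number of genes.
#' @param spec a [shift_spec()].
#' @param seed optional seed.
#' @return list with `genes` (a `gene_tree_set`), `truth` (data frame
#'   `gene`, `affected`), `idx` (the branch index used).
#' @export
simulate_gene_trees <- function(master, labels, n_genes, spec, seed = NULL) {
  stopifnot(inherits(spec, "shift_spec"))
  idx <- branch_index(master)
  labels <- as.character(labels)
  if (length(labels) != idx$n_branches)
    stop("labels must cover all ", idx$n_branches, " master branches")
  if (!is.null(seed)) set.seed(seed)
  n_aff <- round(spec$fraction * n_genes)
  affected <- sort(sample.int(n_genes, n_aff))
  on_target <- labels == spec$category
  base <- idx$tree   # postorder master; edge order matches idx
  ids <- sprintf("g%04d", seq_len(n_genes))
  trees <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    scale_g <- exp(stats::rnorm(1, 0, spec$gene_scale_sd))
    noise <- exp(stats::rnorm(idx$n_branches, -spec$noise_sd^2 / 2,
                              spec$noise_sd))
    mult <- if (g %in% affected)
      ifelse(on_target, spec$multiplier, 1) else 1
    tr <- base
    tr$edge.length <- idx$lengths * scale_g * noise * mult
    trees[[g]] <- tr
  }
  names(trees) <- ids
  genes <- structure(list(trees = trees,
                          skipped = data.frame(gene = character(),
                                               reason = character())),
                     class = "gene_tree_set")
  list(genes = genes,
       truth = data.frame(gene = ids, affected = seq_len(n_genes) %in% affected),
       idx = idx)
}

#' Impose shared branch noise on blocks of genes
#'
#' Multiplies every gene's branch lengths by a per-block lognormal noise
#' vector shared across the block's members. This emulates coherent
#' rate variation in functionally related gene families (e.g. olfactory
#' receptors), which clusters the genes' association statistics in rank
#' without creating any true phenotype association -- the failure mode
#' that permulation-corrected enrichment is designed to absorb.
#'
#' @param genes a `gene_tree_set`.
#' @param blocks integer or character block assignment, one per gene (in
#'   `names(genes$trees)` order).
#' @param shared_sd log-sd of the shared per-branch noise.
#' @param seed optional seed.
#' @return the modified `gene_tree_set`.
#' @export
correlate_gene_blocks <- function(genes, blocks, shared_sd = 0.3,
                                  seed = NULL) {
  stopifnot(inherits(genes, "gene_tree_set"),
            length(blocks) == length(genes$trees))
  if (!is.null(seed)) set.seed(seed)
  ub <- unique(blocks)
  nb <- length(genes$trees[[1L]]$edge.length)
  noise <- lapply(ub, function(b)
    exp(stats::rnorm(nb, -shared_sd^2 / 2, shared_sd)))
  names(noise) <- as.character(ub)
  for (g in seq_along(genes$trees))
    genes$trees[[g]]$edge.length <-
      genes$trees[[g]]$edge.length * noise[[as.character(blocks[g])]]
  genes
}

#' Generate a complete synthetic study
#'
#' Master tree, CTMM-simulated phenotype with true ancestral states, and
#' gene trees with planted category-linked rate shifts -- everything the
#' pipeline consumes, plus the ground truth needed to score it.
#'
#' @param n_tips species count (default 100).
#' @param n_genes gene count (default 500).
#' @param K number of categories (default 3).
#' @param rate overall ER transition rate used to simulate the phenotype;
#'   the default 1 yields on the order of 0.1 expected changes per branch
#'   at the default mean branch length.
#' @param spec a [shift_spec()]; default plants a 3x shift on category
#'   `"A"` branches in 10% of genes.
#' @param mean_branch mean master branch length.
#' @param seed integer seed (default 1).
#' @return list with `master`, `pheno`, `internal_states`, `true_labels`
#'   (per-branch true category labels, branch-index order), `genes`,
#'   `truth`, `idx`, `Q`.
#' @export
simulate_study <- function(n_tips = 100L, n_genes = 500L, K = 3L, rate = 1,
                           spec = shift_spec("A"), mean_branch = 0.1,
                           seed = 1L) {
  set.seed(seed)
  master <- random_tree(n_tips, mean_branch = mean_branch)
  Q <- build_Q(make_rate_model(K, "ER"), rate)
  labels <- LETTERS[seq_len(K)]
  dimnames(Q) <- list(labels, labels)
  # resimulate until every category is observed at the tips
  for (try in 1:50) {
    ph <- simulate_phenotype_on_tree(master, Q, labels = labels)
    if (length(unique(unclass(ph$pheno))) == K) break
  }
  if (length(unique(unclass(ph$pheno))) < K)
    stop("failed to simulate a phenotype observing all ", K, " categories")
  idx <- branch_index(master)
  node_states <- ph$node_states
  true_labels <- structure(labels[node_states[idx$edge[, 2L]]],
                           levels = labels)
  sim <- simulate_gene_trees(master, true_labels, n_genes, spec)
  list(master = master, pheno = ph$pheno,
       internal_states = ph$internal_states, true_labels = true_labels,
       genes = sim$genes, truth = sim$truth, idx = idx, Q = Q)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC of a score against a binary truth;
#' used to summarize how well the omnibus association separates planted
#' shift genes from null genes.
#'
#' @param score numeric score, larger = more likely positive.
#' @param truth logical vector.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(score, truth) {
  stopifnot(length(score) == length(truth))
  ok <- !is.na(score) & !is.na(truth)
  score <- score[ok]; truth <- as.logical(truth[ok])
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) stop("need both positive and negative items")
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
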