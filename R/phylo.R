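#' Read a rooted Newick tree
#'
#' Parses a Newick string or file into an [ape::phylo] object and validates
#' the invariants this package relies on: branch lengths present and
#' non-negative, tip labels unique, a single root. Trees are used exactly as
#' rooted in the input; no re-rooting is performed because ancestral
#' reconstruction under a continuous-time Markov model is root-dependent.
#'
#' @param file path to a Newick file (ignored when `text` is given).
#' @param text a Newick string.
#' @return an object of class `phylo`.
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(file = NULL, text = NULL) {
  if (is.null(text) && is.null(file)) stop("supply either `file` or `text`")
  wmsg <- NULL
  tr <- withCallingHandlers(
    tryCatch(
      if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text),
      error = function(e) stop("Newick parse error: ", conditionMessage(e),
                               call. = FALSE)
    ),
    warning = function(w) {
      wmsg <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    }
  )
  if (is.null(tr))
    stop("Newick parse error: ",
         if (is.null(wmsg)) "no tree found in input" else wmsg)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1L]]
  }
  validate_phylo(tr)
  tr
}

#' Write a tree in Newick format
#'
#' Branch lengths are emitted with 10 significant digits so that
#' read/write/read round-trips are stable to printed precision. Internal
#' node labels are not emitted.
#'
#' @param tree a `phylo` object.
#' @param file optional output path; when `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  validate_phylo(tree)
  tree$node.label <- NULL
  s <- ape::write.tree(tree, digits = 10)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

# Invariant checks shared by all tree consumers.
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a `phylo` object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; lengths are required")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must be non-negative and non-missing")
  if (nrow(tree$edge) != length(tree$tip.label) + tree$Nnode - 1L)
    stop("branch count must equal node count - 1 (is the tree rooted?)")
  invisible(tree)
}

# Tip-label sets of the clade below every node, sorted for key stability.
clade_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  post <- stats::reorder(tree, "postorder")
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1L]; ch <- post$edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, function(s) sort(s))
}

#' Deterministic branch index of a master tree
#'
#' Orders the edges of the master tree in postorder and identifies each
#' branch by its child clade: the sorted set of tip labels below the edge's
#' child node. Internal nodes carry no labels in Newick input, so the
#' bipartition key is what makes gene-tree branches alignable to master
#' branches irrespective of node rotations. The ordering is deterministic
#' for identical input.
#'
#' @param master the master `phylo` tree.
#' @return an object of class `branch_index` with elements `tree` (the
#'   postorder-sorted tree), `edge`, `lengths`, `keys` (child-clade key per
#'   branch) and `clade_size`.
#' @export
branch_index <- function(master) {
  validate_phylo(master)
  post <- stats::reorder(master, "postorder")
  sets <- clade_tip_sets(post)
  child_sets <- sets[post$edge[, 2L]]
  structure(list(
    tree = post,
    edge = post$edge,
    lengths = post$edge.length,
    keys = vapply(child_sets, paste, "", collapse = "|"),
    child_sets = child_sets,
    clade_size = lengths(child_sets),
    n_branches = nrow(post$edge)
  ), class = "branch_index")
}

#' @export
print.branch_index <- function(x, ...) {
  cat("Branch index:", x$n_branches, "branches over",
      length(x$tree$tip.label), "tips\n")
  invisible(x)
}

#' Prune a tree to a set of species
#'
#' Drops all tips outside `keep`; the lengths of collapsed unary paths are
#' summed onto the surviving edge, preserving path lengths between the
#' retained species.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (at least 2, all
#'   present in the tree).
#' @return the pruned `phylo` tree.
#' @export
prune_to_species <- function(tree, keep) {
  validate_phylo(tree)
  keep <- unique(as.character(keep))
  if (!all(keep %in% tree$tip.label))
    stop("species not in tree: ", paste(setdiff(keep, tree$tip.label), collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 species to keep")
  drop <- setdiff(tree$tip.label, keep)
  if (length(drop) == 0L) return(tree)
  out <- ape::drop.tip(tree, drop, trim.internal = TRUE, collapse.singles = TRUE)
  out$root.edge <- NULL
  out
}

#' Map gene-tree branch lengths onto master branches
#'
#' Places each gene branch length at the position of the corresponding
#' master branch. A gene branch corresponds to the master branches whose
#' child clade, restricted to the gene's species, equals the gene branch's
#' child clade; where pruning collapsed a master path into one gene branch,
#' the full gene length is attributed to the child-most master edge on that
#' path and the remaining edges are marked missing. The sum of mapped
#' entries therefore equals the gene tree's total length.
#'
#' @param gene a `phylo` gene tree whose topology is the master restricted
#'   to its tips.
#' @param idx a [branch_index()] of the master tree.
#' @return numeric vector over master branches (`idx` order), `NA` where the
#'   gene lacks the branch.
#' @export
map_gene_branches <- function(gene, idx) {
  stopifnot(inherits(idx, "branch_index"))
  validate_phylo(gene)
  gtips <- gene$tip.label
  master_tips <- idx$tree$tip.label
  if (!all(gtips %in% master_tips))
    stop("gene tips not in master: ", paste(setdiff(gtips, master_tips), collapse = ", "))

  restricted <- lapply(idx$child_sets, function(s) s[s %in% gtips])
  rkey <- vapply(restricted, paste, "", collapse = "|")
  usable <- lengths(restricted) > 0L & lengths(restricted) < length(gtips)
  # child-most edge for each restricted clade = the one with the smallest
  # full clade (postorder visits children before parents, so ties cannot
  # arise: clades on a chain strictly grow toward the root)
  ord <- order(idx$clade_size)
  keys_ord <- rkey[ord]
  keep_ord <- usable[ord] & !duplicated(keys_ord)
  lookup <- ord[keep_ord]
  names(lookup) <- keys_ord[keep_ord]

  gsets <- clade_tip_sets(gene)
  gkeys <- vapply(gsets[gene$edge[, 2L]], paste, "", collapse = "|")
  pos <- lookup[gkeys]
  if (anyNA(pos)) {
    bad <- gkeys[is.na(pos)][1L]
    stop("gene topology inconsistent with master: clade {",
         gsub("\\|", ",", bad), "} not found in restricted master tree")
  }
  out <- rep(NA_real_, idx$n_branches)
  out[pos] <- gene$edge.length
  out
}

#' Read a multi-gene tree file
#'
#' One record per line, `gene_id<TAB>newick`. Every gene tree is validated
#' against the master: tips must be a subset of the master's, at least 3
#' tips are required, and the topology must equal the master restricted to
#' the gene's species. Genes failing validation are reported and skipped,
#' not fatal.
#'
#' @param file path to the gene trees file.
#' @param master the master `phylo` tree.
#' @return an object of class `gene_tree_set`: list with `trees` (named list
#'   of `phylo`) and `skipped` (data frame of gene id and reason).
#' @export
read_gene_trees <- function(file, master) {
  if (!file.exists(file)) stop("gene trees file not found: ", file)
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty gene trees file: ", file)
  idx <- branch_index(master)
  trees <- list()
  skipped <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) parts <- strsplit(ln, "[[:space:]]+")[[1L]]
    gid <- parts[1L]
    nwk <- paste(parts[-1L], collapse = " ")
    res <- tryCatch({
      tr <- read_newick(text = nwk)
      if (length(tr$tip.label) < 3L) stop("fewer than 3 tips")
      map_gene_branches(tr, idx)  # validates subset + topology consistency
      tr
    }, error = function(e) conditionMessage(e))
    if (inherits(res, "phylo")) trees[[gid]] <- res
    else skipped[[gid]] <- res
  }
  structure(list(
    trees = trees,
    skipped = data.frame(gene = names(skipped),
                         reason = unlist(skipped, use.names = FALSE),
                         row.names = NULL)
  ), class = "gene_tree_set")
}

#' Write a gene tree set to the one-record-per-line text format
#' @param genes a `gene_tree_set`.
#' @param file output path.
#' @export
write_gene_trees <- function(genes, file) {
  stopifnot(inherits(genes, "gene_tree_set"))
  lines <- vapply(names(genes$trees), function(g)
    paste0(g, "\t", write_newick(genes$trees[[g]])), "")
  writeLines(lines, file)
  invisible(file)
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat("Gene tree set:", length(x$trees), "genes accepted,",
      nrow(x$skipped), "skipped\n")
  invisible(x)
}
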