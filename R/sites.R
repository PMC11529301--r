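AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
GAP_CHARS <- c("-", ".")

#' Read a protein multiple sequence alignment (FASTA)
#'
#' @param file FASTA path.
#' @return character matrix, rows = species, columns = alignment sites,
#'   upper-case residues.
#' @export
read_alignment <- function(file) {
  aln <- ape::read.FASTA(file, type = "AA")
  ch <- lapply(as.character(aln), toupper)
  lens <- lengths(ch)
  if (length(unique(lens)) != 1L)
    stop("alignment rows have unequal lengths (", paste(unique(lens),
         collapse = ", "), ")")
  m <- do.call(rbind, ch)
  rownames(m) <- names(aln)
  m
}

#' Per-site amino-acid profiles by phenotype category
#'
#' For every alignment column, the set of amino acids observed in each
#' category's species, with gap characters excluded (a lineage with a gap
#' at a site is ignored for that site). Unknown residue characters (not
#' one of the 20 amino acids, gap, or X) trigger a warning; X is treated
#' as missing.
#'
#' @param aln character matrix from [read_alignment()]; row names must be
#'   species present in `pheno`.
#' @param pheno a [phenotype_vector()].
#' @return list of profiles, one per site: `site`, `sets` (named list of
#'   residue sets per category), `counts` (non-gap species per category).
#' @export
profile_sites <- function(aln, pheno) {
  sp <- rownames(aln)
  miss <- setdiff(sp, names(pheno))
  if (length(miss))
    stop("alignment species missing from phenotype: ",
         paste(miss, collapse = ", "))
  lv <- categories(pheno)
  cat_of <- unclass(pheno)[sp]
  bad <- setdiff(unique(as.vector(aln)), c(AA20, GAP_CHARS, "X", "*"))
  if (length(bad))
    warning("unknown residue characters treated as missing: ",
            paste(bad, collapse = " "))
  keep_res <- function(v) v[v %in% AA20]
  lapply(seq_len(ncol(aln)), function(s) {
    col <- aln[, s]
    sets <- lapply(lv, function(cc) sort(unique(keep_res(col[cat_of == cc]))))
    names(sets) <- lv
    counts <- vapply(lv, function(cc) sum(col[cat_of == cc] %in% AA20), 1L)
    list(site = s, sets = sets, counts = counts)
  })
}

#' Between-category similarity of a site profile
#'
#' The minimum (default) or mean pairwise Jaccard index between the
#' categories' residue sets; categories with no non-gap residue at the
#' site are excluded, and fewer than two non-empty sets yields `NA` (the
#' site cannot be compared).
#'
#' @param profile one element of [profile_sites()] output.
#' @param method `"min"` (default) or `"mean"`.
#' @return similarity score in `[0, 1]`, or `NA`.
#' @export
site_similarity <- function(profile, method = c("min", "mean")) {
  method <- match.arg(method)
  sets <- Filter(length, profile$sets)
  if (length(sets) < 2L) return(NA_real_)
  jac <- utils::combn(length(sets), 2, function(ij) {
    a <- sets[[ij[1L]]]; b <- sets[[ij[2L]]]
    length(intersect(a, b)) / length(union(a, b))
  })
  if (method == "min") min(jac) else mean(jac)
}

# Fitch small parsimony on a discrete character: minimum number of state
# changes on the tree. `states` is a named vector over (a subset of) tips;
# the tree is pruned to the scored tips.
fitch_changes <- function(tree, states) {
  keep <- names(states)[!is.na(states)]
  if (length(keep) < 2L) return(0L)
  tr <- if (length(keep) < length(tree$tip.label))
    prune_to_species(tree, keep) else tree
  post <- stats::reorder(tr, "postorder")
  ntip <- length(post$tip.label)
  sets <- vector("list", ntip + post$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- as.character(states[post$tip.label[i]])
  changes <- 0L
  e <- post$edge
  for (k in seq_len(nrow(e))) {
    p <- e[k, 1L]; ch <- e[k, 2L]
    if (is.null(sets[[p]])) { sets[[p]] <- sets[[ch]]; next }
    inter <- intersect(sets[[p]], sets[[ch]])
    if (length(inter)) sets[[p]] <- inter
    else { sets[[p]] <- union(sets[[p]], sets[[ch]]); changes <- changes + 1L }
  }
  changes
}

#' Screen alignment sites for category-specific composition
#'
#' Keeps sites whose between-category similarity is at or below
#' `threshold`, then asks whether the signal is independent of clade
#' membership: for the focal category (the one with the most invariant,
#' i.e. smallest, residue set) the most frequent residue is scored by
#' Fitch small parsimony as a presence/absence character on the tree, and
#' the minimum number of state changes is reported as the number of
#' independent phylogenetic origins. Sites whose composition difference
#' traces to a single clade (origins < 2) are flagged as confounded.
#'
#' @param aln character matrix from [read_alignment()].
#' @param pheno a [phenotype_vector()].
#' @param tree `phylo` tree containing the alignment species.
#' @param threshold similarity cutoff in `[0, 1]` (default 0.2).
#' @param method similarity summary, `"min"` or `"mean"`.
#' @param ref optional row name used to report reference-sequence
#'   coordinates (position among the reference's non-gap residues).
#' @return data frame with `site`, `ref_pos` (NA without `ref`),
#'   `similarity`, `focal_category`, `focal_residue`, `origins`,
#'   `confounded`.
#' @export
screen_sites <- function(aln, pheno, tree, threshold = 0.2,
                         method = c("min", "mean"), ref = NULL) {
  method <- match.arg(method)
  validate_phylo(tree)
  miss <- setdiff(rownames(aln), tree$tip.label)
  if (length(miss))
    stop("alignment species missing from tree: ", paste(miss, collapse = ", "))
  profs <- profile_sites(aln, pheno)
  sims <- vapply(profs, site_similarity, 0, method = method)
  ref_pos <- rep(NA_integer_, ncol(aln))
  if (!is.null(ref)) {
    if (!ref %in% rownames(aln)) stop("reference row not found: ", ref)
    nongap <- aln[ref, ] %in% AA20
    ref_pos[nongap] <- cumsum(nongap)[nongap]
  }
  cand <- which(!is.na(sims) & sims <= threshold)
  rows <- lapply(cand, function(s) {
    pr <- profs[[s]]
    sets <- Filter(length, pr$sets)
    sizes <- lengths(sets)
    focal <- names(sets)[which.min(sizes)]   # ties -> earliest registry order
    col <- aln[, s]
    sp_cat <- names(pheno)[unclass(pheno) == focal]
    res_tab <- table(col[intersect(rownames(aln), sp_cat)][
      col[intersect(rownames(aln), sp_cat)] %in% AA20])
    focal_res <- names(sort(res_tab, decreasing = TRUE))[1L]
    scored <- col %in% AA20
    presence <- stats::setNames(ifelse(col[scored] == focal_res, "1", "0"),
                                rownames(aln)[scored])
    orig <- fitch_changes(tree, presence)
    data.frame(site = s, ref_pos = ref_pos[s], similarity = sims[s],
               focal_category = focal, focal_residue = focal_res,
               origins = orig, confounded = orig < 2L)
  })
  if (length(rows) == 0L)
    return(data.frame(site = integer(), ref_pos = integer(),
                      similarity = numeric(), focal_category = character(),
                      focal_residue = character(), origins = integer(),
                      confounded = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
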