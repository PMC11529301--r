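#' Read gene sets in GMT format
#'
#' One pathway per line: `id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param file path to a GMT file.
#' @return named list of character vectors (pathway id -> gene set).
#' @export
read_gmt <- function(file) {
  if (!file.exists(file)) stop("GMT file not found: ", file)
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", file)
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(ln, 1, 60))
    out[[f[1L]]] <- unique(f[-(1:2)])
  }
  out
}

#' Rank genes for enrichment
#'
#' Omnibus mode scores each gene by `-log10(p)` and ranks descending (the
#' omnibus test is one-sided, so large scores mean strong association in
#' any direction). Pair mode scores by the signed `-log10` adjusted p of
#' the chosen post hoc pair and ranks from most positive to most negative,
#' so the two ends of the list hold large rate shifts in the two
#' directions. Ties are broken by gene id for determinism.
#'
#' @param results a `gene_scan` data frame.
#' @param mode `"omnibus"` or `"pair"`.
#' @param pair character vector of two category labels (pair mode).
#' @param p_floor substitution for zero p-values, see [signed_logp()].
#' @return data frame `gene`, `score`, ordered by rank (best first).
#' @export
rank_genes <- function(results, mode = c("omnibus", "pair"), pair = NULL,
                       p_floor = NULL) {
  mode <- match.arg(mode)
  stopifnot(nrow(results) > 0L)
  if (mode == "omnibus") {
    p <- results$p
    if (any(p == 0)) {
      if (is.null(p_floor)) stop("p = 0 present: supply `p_floor`")
      p[p == 0] <- p_floor
    }
    score <- -log10(p)
  } else {
    if (is.null(pair) || length(pair) != 2L) stop("pair mode needs 2 labels")
    id <- paste0(pair[1L], ".", pair[2L])
    flip <- 1
    if (!paste0("p_", id) %in% names(results)) {
      id <- paste0(pair[2L], ".", pair[1L]); flip <- -1
    }
    pcol <- paste0("p_", id); scol <- paste0("stat_", id)
    if (!pcol %in% names(results)) stop("pair not found in results: ",
                                        paste(pair, collapse = "/"))
    score <- flip * signed_logp(results[[pcol]], results[[scol]],
                                p_floor = p_floor)
  }
  ord <- order(-score, results$gene)
  data.frame(gene = results$gene[ord], score = score[ord])
}

# Tie-corrected normal z for the rank-sum of `members` scores vs the rest.
enrichment_z <- function(scores, member) {
  n <- length(scores)
  n1 <- sum(member); n2 <- n - n1
  r <- rank(scores)
  W <- sum(r[member])
  mu <- n1 * (n + 1) / 2
  ties <- table(scores)
  v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v <= 0) return(0)
  (W - mu) / sqrt(v)
}

#' Wilcoxon rank-sum pathway enrichment
#'
#' Tests whether the scores of a pathway's genes are shifted relative to
#' all other scanned genes. Omnibus scores are tested one-sided (pathway
#' shifted toward high `-log10 p`); pair-mode signed scores are tested
#' two-sided. The p-value comes from [stats::wilcox.test()] (exact for
#' small untied samples, normal approximation otherwise); the reported `z`
#' is the tie-corrected standardized rank-sum used for permulation
#' comparison.
#'
#' @param ranked data frame from [rank_genes()] (or any `gene`/`score`
#'   frame).
#' @param pathway_genes character vector of member gene ids.
#' @param min_size minimum member count after intersection (default 10).
#' @param alternative `"greater"` (omnibus) or `"two.sided"` (pair).
#' @return list with `statistic` (rank-sum W), `z`, `p`, `size`.
#' @export
wilcoxon_enrichment <- function(ranked, pathway_genes, min_size = 10L,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  member <- ranked$gene %in% pathway_genes
  n1 <- sum(member)
  if (n1 < min_size)
    stop("pathway has ", n1, " scanned genes, below min_size = ", min_size)
  if (n1 == nrow(ranked))
    return(list(statistic = sum(rank(ranked$score)[member]), z = 0, p = 1,
                size = n1))
  wt <- suppressWarnings(
    stats::wilcox.test(ranked$score[member], ranked$score[!member],
                       alternative = alternative))
  list(statistic = sum(rank(ranked$score)[member]),
       z = enrichment_z(ranked$score, member),
       p = wt$p.value, size = n1)
}

#' Fold-enrichment curve and barcode
#'
#' At each rank k, the fraction of pathway genes among the top k divided
#' by the pathway's overall fraction; the curve equals exactly 1 at
#' `k = total`. The barcode is the member rank positions.
#'
#' @param ranked data frame from [rank_genes()].
#' @param pathway_genes character vector of member gene ids.
#' @return data frame with `k`, `observed`, `expected`, `fold`; member
#'   positions in the `barcode` attribute.
#' @export
fold_curve <- function(ranked, pathway_genes) {
  member <- ranked$gene %in% pathway_genes
  total <- nrow(ranked); size <- sum(member)
  if (size == 0L) stop("no pathway genes among ranked genes")
  k <- seq_len(total)
  obs <- cumsum(member) / k
  expd <- size / total
  out <- data.frame(k = k, observed = obs, expected = expd,
                    fold = obs / expd)
  attr(out, "barcode") <- which(member)
  out
}

#' Plot a fold-enrichment curve with barcode
#' @param curve output of [fold_curve()].
#' @param main plot title.
#' @export
plot_fold_curve <- function(curve, main = "Fold enrichment") {
  graphics::plot(curve$k, curve$fold, type = "l", lwd = 2,
                 xlab = "gene rank", ylab = "fold enrichment", main = main)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  graphics::rug(attr(curve, "barcode"), col = "grey30")
  invisible(curve)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] step-up FDR control; monotone and
#' capped at 1.
#'
#' @param pvals p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Pathway enrichment with parametric and permulation p-values
#'
#' Scores every pathway against the observed gene ranking (Wilcoxon
#' rank-sum; BH correction across pathways) and, when a null score matrix
#' is supplied, against each permulation's ranking rescored by the same
#' pipeline; the permulation p is the proportion of null enrichment
#' statistics at least as extreme as the observed one, with the sidedness
#' of the parametric test.
#'
#' @param results a `gene_scan` data frame.
#' @param pathways named list of gene sets (see [read_gmt()]).
#' @param null_scores optional genes x draws matrix of null gene scores on
#'   the same scale as the observed ranking scores (e.g. the effect-size
#'   matrix from [score_permulations()] converted by `score_fun`).
#' @param mode `"omnibus"` or `"pair"`; fixes ranking and sidedness.
#' @param pair pair of labels for pair mode.
#' @param min_size,max_size pathway size bounds after intersection with
#'   scanned genes (defaults 10 and 500).
#' @param p_floor zero-p substitution for ranking.
#' @return data frame (class `pathway_enrichment`): `pathway`, `size`,
#'   `z`, `p`, `p_bh`, and with nulls `p_perm`, `perm_floor`, `n_null`.
#' @export
pathway_enrichment <- function(results, pathways, null_scores = NULL,
                               mode = c("omnibus", "pair"), pair = NULL,
                               min_size = 10L, max_size = 500L,
                               p_floor = NULL) {
  mode <- match.arg(mode)
  ranked <- rank_genes(results, mode = mode, pair = pair, p_floor = p_floor)
  alternative <- if (mode == "omnibus") "greater" else "two.sided"
  scanned <- ranked$gene
  sizes <- vapply(pathways, function(g) sum(scanned %in% g), 1L)
  use <- sizes >= min_size & sizes <= max_size
  if (!any(use)) stop("no pathway within size bounds [", min_size, ", ",
                      max_size, "] after intersection")
  pathways <- pathways[use]
  z <- p <- numeric(length(pathways))
  for (i in seq_along(pathways)) {
    w <- wilcoxon_enrichment(ranked, pathways[[i]], min_size = min_size,
                             alternative = alternative)
    z[i] <- w$z; p[i] <- w$p
  }
  out <- data.frame(pathway = names(pathways), size = sizes[use],
                    z = z, p = p, p_bh = bh_adjust(p))
  if (!is.null(null_scores)) {
    stopifnot(nrow(null_scores) == length(scanned) ||
              !is.null(rownames(null_scores)))
    ns <- if (!is.null(rownames(null_scores)))
      null_scores[scanned, , drop = FALSE] else null_scores
    N <- ncol(ns)
    member <- lapply(pathways, function(g) scanned %in% g)
    null_z <- matrix(NA_real_, length(pathways), N)
    for (j in seq_len(N)) {
      sc <- ns[, j]
      ok <- !is.na(sc)
      if (sum(ok) < 3L) next
      for (i in seq_along(pathways)) {
        m <- member[[i]][ok]
        if (sum(m) < min_size) next
        null_z[i, j] <- enrichment_z(sc[ok], m)
      }
    }
    ep <- empirical_pvalues(z, null_z,
                            sided = if (mode == "omnibus") "greater"
                                    else "two.sided")
    out$p_perm <- ep$p
    out$perm_floor <- ep$floor
    out$n_null <- ep$n_null
  }
  class(out) <- c("pathway_enrichment", class(out))
  out
}
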