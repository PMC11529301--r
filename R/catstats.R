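#' Kruskal-Wallis omnibus test with epsilon-squared effect size
#'
#' Tie-corrected Kruskal-Wallis H across K groups of RERs, p-value from a
#' chi-square with K-1 degrees of freedom, and the epsilon-squared effect
#' size `H / (n - 1)` where n is the total number of observations
#' (branches). The internal formula is used (rather than delegating) so
#' that the identical code path can score thousands of permulation nulls;
#' its agreement with `stats::kruskal.test` is unit-tested.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return list with `statistic` (H), `df`, `p`, `epsilon_sq`, `n`.
#' @examples
#' kruskal_omnibus(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$statistic  # 7.2
#' @export
kruskal_omnibus <- function(groups) {
  groups <- check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  n_i <- lengths(groups)
  g <- rep(seq_along(groups), n_i)
  n <- length(x)
  if (n < length(groups) + 1L) stop("need n >= K + 1 observations")
  r <- rank(x)
  Rsum <- vapply(split(r, g), sum, 0)
  H <- 12 / (n * (n + 1)) * sum(Rsum^2 / n_i) - 3 * (n + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- if (C > 0) H / C else 0
  H <- max(H, 0)
  df <- length(groups) - 1L
  list(statistic = H, df = df, p = stats::pchisq(H, df, lower.tail = FALSE),
       epsilon_sq = H / (n - 1), n = n)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (any(lengths(groups) == 0L)) stop("empty group after missing removal")
  invisible(groups)
}

#' Dunn post hoc pairwise tests
#'
#' Pairwise Z statistics from mean-rank differences with tie-corrected
#' variance. For the pair (i, j), Z > 0 when group i -- the first of the
#' pair in the supplied order -- has the larger mean rank (i.e. larger
#' RERs). Two-sided p-values are adjusted for the K(K-1)/2 comparisons.
#'
#' @param groups named list of >= 2 numeric vectors; the name order fixes
#'   the pair sign convention.
#' @param adjust multiple-comparison adjustment passed to
#'   [stats::p.adjust()] (default `"BH"`).
#' @return data frame with `group1`, `group2`, `Z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(groups, adjust = "BH") {
  groups <- check_groups(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  n_i <- lengths(groups)
  g <- rep(seq_along(groups), n_i)
  n <- length(x)
  r <- rank(x)
  rbar <- vapply(split(r, g), mean, 0)
  ties <- table(x)
  tiesum <- sum(ties^3 - ties)
  vterm <- n * (n + 1) / 12 - tiesum / (12 * (n - 1))
  pairs <- utils::combn(length(groups), 2)
  Z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se2 <- vterm * (1 / n_i[i] + 1 / n_i[j])
    Z[k] <- if (se2 > 0) (rbar[i] - rbar[j]) / sqrt(se2) else 0
    p[k] <- 2 * stats::pnorm(-abs(Z[k]))
  }
  data.frame(group1 = names(groups)[pairs[1L, ]],
             group2 = names(groups)[pairs[2L, ]],
             Z = Z, p = p, p_adj = stats::p.adjust(p, method = adjust))
}

#' One-way ANOVA omnibus test with eta-squared effect size
#'
#' Standard one-way F test via [stats::lm()]; eta-squared is
#' `SS_between / (SS_between + SS_within)`.
#'
#' @param groups list of >= 2 numeric vectors.
#' @return list with `statistic` (F), `df`, `p`, `eta_sq`, `n`.
#' @export
anova_omnibus <- function(groups) {
  groups <- check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  a <- stats::anova(stats::lm(x ~ g))
  ssb <- a[["Sum Sq"]][1L]; ssw <- a[["Sum Sq"]][2L]
  list(statistic = a[["F value"]][1L], df = a[["Df"]],
       p = a[["Pr(>F)"]][1L],
       eta_sq = if (ssb + ssw > 0) ssb / (ssb + ssw) else 0,
       n = length(x))
}

#' Tukey HSD post hoc pairwise tests
#'
#' Studentized-range family-wise adjusted pairwise mean differences via
#' [stats::TukeyHSD()]. For the pair (i, j), the difference is
#' `mean(i) - mean(j)` with i first in the supplied group order.
#'
#' @param groups named list of >= 2 numeric vectors.
#' @return data frame with `group1`, `group2`, `diff`, `p_adj`.
#' @export
tukey_posthoc <- function(groups) {
  groups <- check_groups(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  tk <- stats::TukeyHSD(stats::aov(x ~ g))$g
  # TukeyHSD reports "later-level minus earlier-level"; flip to (i, j) order
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- utils::combn(names(groups), 2)
  diff_ <- p_adj <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    row <- which(vapply(nm, function(v) setequal(v, c(i, j)), TRUE))[1L]
    d <- tk[row, "diff"]
    if (nm[[row]][1L] == j) d <- -d
    diff_[k] <- d; p_adj[k] <- tk[row, "p adj"]
  }
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             diff = diff_, p_adj = p_adj)
}

#' Per-gene association of RERs with branch categories
#'
#' For every gene: missing RERs are dropped, the remaining branches
#' (terminal and internal alike) are grouped by their category labels, and
#' the omnibus test plus post hoc pairwise tests are run. Genes with fewer
#' than `min_per_category` branches in any category are skipped and listed
#' in the `skipped` attribute.
#'
#' @param rers RER matrix (branches x genes), rows aligned with `labels`.
#' @param labels per-branch category labels (from [branch_labels()]), with
#'   the registry as a `levels` attribute or as a factor.
#' @param method `"kw"` (Kruskal-Wallis + Dunn, default) or `"anova"`
#'   (ANOVA + Tukey).
#' @param min_per_category minimum branches per category (default 2).
#' @param posthoc run post hoc pairwise tests (default TRUE).
#' @param adjust within-gene multiple-comparison adjustment for Dunn
#'   (default `"BH"`).
#' @return data frame (class `gene_scan`) with one row per tested gene:
#'   `gene`, `n`, per-category counts `n_<cat>`, `statistic`, `effect_size`,
#'   `p`, and per-pair columns `stat_<A>.<B>` / `p_<A>.<B>` when `posthoc`.
#'   Attributes: `method`, `adjust`, `levels`, `skipped`.
#' @export
gene_scan <- function(rers, labels, method = c("kw", "anova"),
                      min_per_category = 2L, posthoc = TRUE, adjust = "BH") {
  method <- match.arg(method)
  lv <- if (is.factor(labels)) levels(labels) else attr(labels, "levels")
  if (is.null(lv)) lv <- unique(as.character(labels))
  labels <- as.character(labels)
  if (length(labels) != nrow(rers))
    stop("labels length must equal number of RER rows")
  K <- length(lv)
  pairs <- utils::combn(lv, 2)
  npair <- ncol(pairs)
  pair_id <- paste0(pairs[1L, ], ".", pairs[2L, ])

  genes <- colnames(rers)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(rers)))
  rows <- vector("list", ncol(rers))
  skipped <- character(0)
  for (gi in seq_len(ncol(rers))) {
    y <- rers[, gi]
    obs <- !is.na(y)
    grp <- split(y[obs], factor(labels[obs], levels = lv))
    cnt <- lengths(grp)
    if (any(cnt < min_per_category)) { skipped <- c(skipped, genes[gi]); next }
    om <- tryCatch(
      if (method == "kw") kruskal_omnibus(grp) else anova_omnibus(grp),
      error = function(e) NULL)
    if (is.null(om)) { skipped <- c(skipped, genes[gi]); next }
    row <- c(list(gene = genes[gi], n = om$n),
             stats::setNames(as.list(as.integer(cnt)), paste0("n_", lv)),
             list(statistic = om$statistic,
                  effect_size = if (method == "kw") om$epsilon_sq else om$eta_sq,
                  p = om$p))
    if (posthoc) {
      ph <- if (method == "kw") dunn_posthoc(grp, adjust = adjust)
            else tukey_posthoc(grp)
      st <- if (method == "kw") ph$Z else ph$diff
      pv <- ph$p_adj
      row <- c(row, stats::setNames(as.list(st), paste0("stat_", pair_id)),
               stats::setNames(as.list(pv), paste0("p_", pair_id)))
    }
    rows[[gi]] <- as.data.frame(row, check.names = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    stop("all genes skipped (fewer than ", min_per_category,
         " branches in some category)")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "adjust") <- adjust
  attr(out, "levels") <- lv
  attr(out, "skipped") <- skipped
  class(out) <- c("gene_scan", class(out))
  out
}

#' Signed negative log10 p-value
#'
#' `-log10(p) * sign(direction)`: the bar-height statistic used to rank and
#' display pairwise results. Zero p-values (possible for empirical
#' permulation p-values when the observed statistic exceeds every null)
#' are mapped to `p_floor`, the permulation granularity `1/N`.
#'
#' @param p p-values in `[0, 1]`.
#' @param direction direction statistic (e.g. Dunn Z); its sign is used.
#' @param p_floor value substituted for `p == 0`; required if any p is 0.
#' @return numeric vector of signed `-log10` p-values.
#' @export
signed_logp <- function(p, direction, p_floor = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  if (any(p == 0, na.rm = TRUE)) {
    if (is.null(p_floor)) stop("p = 0 present: supply `p_floor` (= 1/N nulls)")
    p[p == 0] <- p_floor
  }
  -log10(p) * sign(direction)
}
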