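#' Construct a phenotype vector
#'
#' A phenotype vector maps species labels to category labels and carries an
#' ordered category registry. Registry order is first appearance, and it is
#' the order in which categories index rows/columns of the transition rate
#' matrix and the order used for post hoc pair sign conventions.
#'
#' @param species character vector of species labels (unique).
#' @param category character vector of category labels, same length.
#' @param levels optional explicit registry order; defaults to first
#'   appearance in `category`.
#' @return a named character vector of class `phenotype_vector` with a
#'   `levels` attribute.
#' @export
phenotype_vector <- function(species, category, levels = NULL) {
  species <- as.character(species); category <- as.character(category)
  if (length(species) != length(category)) stop("species/category length mismatch")
  if (anyDuplicated(species))
    stop("duplicate species: ", paste(unique(species[duplicated(species)]), collapse = ", "))
  if (any(!nzchar(category)) || anyNA(category)) stop("empty category cell")
  if (is.null(levels)) levels <- unique(category)
  if (!all(category %in% levels)) stop("category outside registry")
  structure(stats::setNames(category, species), levels = levels,
            class = "phenotype_vector")
}

#' Category registry of a phenotype vector
#' @param pheno a `phenotype_vector`.
#' @return character vector of registered category labels, in order.
#' @export
categories <- function(pheno) attr(pheno, "levels")

#' @export
print.phenotype_vector <- function(x, ...) {
  cat("Phenotype vector:", length(x), "species,",
      length(categories(x)), "categories (",
      paste(categories(x), collapse = ", "), ")\n")
  print(table(factor(unclass(x), levels = categories(x))))
  invisible(x)
}

#' Read a two-column species/category table
#'
#' Accepts TSV or CSV (`species<sep>category`). A header line is detected
#' and dropped when its first field is one of "species", "taxon" or "tip"
#' (case-insensitive). Duplicate species and empty category cells are
#' errors; the registry is the distinct labels in first-appearance order.
#'
#' @param file path to the table.
#' @param sep field separator; default auto-detects comma vs tab/whitespace.
#' @return a [phenotype_vector()].
#' @export
read_phenotypes <- function(file, sep = NULL) {
  if (!file.exists(file)) stop("phenotype file not found: ", file)
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty phenotype file: ", file)
  if (is.null(sep)) sep <- if (grepl(",", lines[1L], fixed = TRUE)) "," else "\t"
  split1 <- function(ln) {
    f <- strsplit(ln, sep, fixed = TRUE)[[1L]]
    if (length(f) < 2L && sep == "\t") f <- strsplit(ln, "[[:space:]]+")[[1L]]
    trimws(f)
  }
  fields <- lapply(lines, split1)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) stop("line ", bad[1L], ": expected 2 fields")
  if (tolower(fields[[1L]][1L]) %in% c("species", "taxon", "tip"))
    fields <- fields[-1L]
  sp <- vapply(fields, `[`, "", 1L)
  cat_ <- vapply(fields, `[`, "", 2L)
  phenotype_vector(sp, cat_)
}

#' Write a phenotype vector as TSV
#' @param pheno a `phenotype_vector`.
#' @param file output path.
#' @export
write_phenotypes <- function(pheno, file) {
  utils::write.table(
    data.frame(species = names(pheno), category = unclass(pheno)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Define a category merge rule
#'
#' A merge rule collapses two or more registered base categories into one
#' merged label (e.g. Carnivore + Piscivore -> Vertivore). The merged label
#' must not itself be a base category.
#'
#' @param label the merged category label.
#' @param constituents character vector (length >= 2) of base labels.
#' @return an object of class `merge_rule`.
#' @export
merge_rule <- function(label, constituents) {
  constituents <- as.character(constituents)
  if (length(constituents) < 2L) stop("a merge needs at least 2 constituents")
  if (label %in% constituents) stop("merged label cannot be a constituent")
  structure(list(label = as.character(label), constituents = constituents),
            class = "merge_rule")
}

#' Apply a merge rule to a phenotype vector
#'
#' Re-labels every species in the rule's constituent categories to the
#' merged label; counts of other categories are unchanged and the total
#' species count is conserved. The merged label takes the registry position
#' of its first constituent.
#'
#' @param pheno a `phenotype_vector`.
#' @param rule a [merge_rule()].
#' @return the merged `phenotype_vector`.
#' @export
merge_categories <- function(pheno, rule) {
  stopifnot(inherits(pheno, "phenotype_vector"), inherits(rule, "merge_rule"))
  lv <- categories(pheno)
  unknown <- setdiff(rule$constituents, lv)
  if (length(unknown))
    stop("unknown constituent label(s): ", paste(unknown, collapse = ", "))
  if (rule$label %in% setdiff(lv, rule$constituents))
    stop("merged label already a registered category: ", rule$label)
  v <- unclass(pheno)
  v[v %in% rule$constituents] <- rule$label
  new_lv <- lv
  new_lv[match(rule$constituents[1L], lv)] <- rule$label
  new_lv <- new_lv[!new_lv %in% rule$constituents]
  phenotype_vector(names(v), unname(v), levels = new_lv)
}

#' Enumerate valid category sets over mergeable phenotypes
#'
#' All subsets of the base labels plus merged labels, of the requested
#' sizes, excluding any set containing a merged label together with one of
#' its constituents (they describe the same species). Two merged labels may
#' co-occur when their constituent sets are disjoint. Sets are returned in
#' deterministic order: by size, then lexicographically.
#'
#' @param base character vector of base category labels.
#' @param merges list of [merge_rule()] objects.
#' @param sizes integer vector of set sizes (each >= 2).
#' @return list of character vectors (the category sets).
#' @export
enumerate_category_sets <- function(base, merges = list(), sizes) {
  base <- as.character(base)
  if (inherits(merges, "merge_rule")) merges <- list(merges)
  sizes <- as.integer(sizes)
  labels <- c(base, vapply(merges, `[[`, "", "label"))
  if (anyDuplicated(labels)) stop("duplicate labels across base and merges")
  if (any(sizes < 2L) || any(sizes > length(labels)))
    stop("sizes must lie in [2, ", length(labels), "]")
  ok <- function(set) {
    for (m in merges)
      if (m$label %in% set && any(m$constituents %in% set)) return(FALSE)
    TRUE
  }
  out <- list()
  for (s in sort(unique(sizes))) {
    combos <- utils::combn(sort(labels), s, simplify = FALSE)
    combos <- Filter(ok, combos)
    keys <- vapply(combos, paste, "", collapse = "|")
    out <- c(out, combos[order(keys)])
  }
  out
}
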