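#' Pipeline configuration
#'
#' A single declarative configuration for the whole analysis: input paths
#' (master tree, gene trees, phenotype table, optionally GMT gene sets and
#' a protein alignment), module parameter blocks, a global seed and an
#' output directory. All defaults are recorded in the run manifest so a
#' run is self-describing.
#'
#' @param out_dir output directory (created if absent).
#' @param master,genes,pheno input paths (Newick master, gene-trees file,
#'   phenotype TSV/CSV).
#' @param gmt optional GMT pathway file; enables the enrichment stage.
#' @param aln optional FASTA protein alignment; enables the site screen.
#' @param model rate model scheme or `"auto"` (LRT selection among
#'   ER/SYM/ARD).
#' @param rer an [rer_config()].
#' @param perm a [permulation_config()]; `NULL` skips permulations.
#' @param min_per_category per-category branch minimum for the gene scan.
#' @param enrich_min_size,enrich_max_size pathway size bounds.
#' @param site_threshold site-screen similarity cutoff.
#' @param seed global seed.
#' @param overwrite recompute stages whose outputs exist (default FALSE:
#'   up-to-date stages with unchanged parameters are skipped).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, master, genes, pheno, gmt = NULL, aln = NULL,
                       model = "ARD", rer = rer_config(),
                       perm = permulation_config(), min_per_category = 2L,
                       enrich_min_size = 10L, enrich_max_size = 500L,
                       site_threshold = 0.2, seed = 1L, overwrite = FALSE) {
  structure(list(out_dir = out_dir, master = master, genes = genes,
                 pheno = pheno, gmt = gmt, aln = aln, model = model,
                 rer = rer, perm = perm, min_per_category = min_per_category,
                 enrich_min_size = enrich_min_size,
                 enrich_max_size = enrich_max_size,
                 site_threshold = site_threshold, seed = as.integer(seed),
                 overwrite = overwrite),
            class = "run_config")
}

stage_params <- function(cfg, stage) {
  p <- switch(stage,
    trees = cfg[c("master", "genes")],
    rer = c(cfg[c("master", "genes")], cfg$rer),
    asr = cfg[c("master", "pheno", "model")],
    scan = c(cfg[c("master", "genes", "pheno", "model", "min_per_category")],
             cfg$rer),
    permulate = c(cfg[c("master", "pheno", "model")], cfg$perm),
    enrich = cfg[c("gmt", "enrich_min_size", "enrich_max_size")],
    sites = cfg[c("aln", "pheno", "site_threshold")])
  jsonlite::toJSON(p, auto_unbox = TRUE, null = "null", digits = NA)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order -- validate trees, compute
#' RERs, fit the CTMM and reconstruct ancestral states, scan genes,
#' permulate, enrich pathways, screen sites -- writing one artifact per
#' stage into the output directory plus a JSON manifest listing the
#' parameters, seeds and md5 hashes of every artifact. A stage is skipped
#' when its outputs already exist and its parameter block is unchanged
#' from the previous manifest (unless `overwrite`); changing, say, the
#' permulation seed regenerates only the permulation-dependent artifacts.
#'
#' @param cfg a [run_config()].
#' @return the manifest (list), invisibly; also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  man_path <- file.path(cfg$out_dir, "manifest.json")
  prev <- if (file.exists(man_path))
    jsonlite::read_json(man_path, simplifyVector = FALSE) else list()
  manifest <- list(package = "catrer",
                   version = as.character(utils::packageVersion("catrer")),
                   seed = cfg$seed, stages = list())
  t0 <- Sys.time()
  log_msg <- function(...) message(format(Sys.time(), "[%H:%M:%S] "), ...)

  outputs <- list(
    rer = "rers.tsv", asr = "asr.json", scan = "genes.tsv",
    permulate = "perm_pvalues.tsv", enrich = "pathways.tsv",
    sites = "sites.tsv")
  fresh <- character(0)   # stages recomputed in this run
  up_to_date <- function(stage) {
    if (cfg$overwrite) return(FALSE)
    f <- file.path(cfg$out_dir, outputs[[stage]])
    if (!file.exists(f)) return(FALSE)
    old <- prev$stages[[stage]]
    !is.null(old) && identical(as.character(old$params),
                               as.character(stage_params(cfg, stage)))
  }
  record <- function(stage, files, status) {
    manifest$stages[[stage]] <<- list(
      status = status, params = as.character(stage_params(cfg, stage)),
      artifacts = as.list(tools::md5sum(file.path(cfg$out_dir, files))))
    if (status == "computed") fresh <<- c(fresh, stage)
  }
  fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         "\nreproduce with run_pipeline() after fixing inputs", call. = FALSE)
  }

  # inputs needed by several stages are always loaded (cheap)
  master <- read_newick(cfg$master)
  pheno <- read_phenotypes(cfg$pheno)
  idx <- branch_index(master)

  # -- rer ------------------------------------------------------------
  rer_file <- file.path(cfg$out_dir, outputs$rer)
  if (up_to_date("rer")) {
    log_msg("rer: up to date, skipped")
    record("rer", outputs$rer, "skipped")
    tab <- utils::read.delim(rer_file, check.names = FALSE)
    rers <- as.matrix(tab[, -1, drop = FALSE])
    rownames(rers) <- tab[[1L]]
  } else {
    log_msg("rer: computing relative evolutionary rates")
    res <- tryCatch({
      genes <- read_gene_trees(cfg$genes, master)
      rer_matrix(genes, master, cfg$rer)
    }, error = function(e) fail("rer", e))
    rers <- res$rers
    write_rers(rers, rer_file)
    record("rer", outputs$rer, "computed")
  }

  # -- asr ------------------------------------------------------------
  asr_file <- file.path(cfg$out_dir, outputs$asr)
  redo_asr <- !up_to_date("asr")
  log_msg("asr: ", if (redo_asr) "fitting CTMM and reconstructing" else
          "up to date (refit in memory for downstream stages)")
  fit <- tryCatch({
    if (identical(cfg$model, "auto")) {
      fits <- lapply(c("ER", "SYM", "ARD"), function(m)
        fit_ctmm(master, pheno, m, seed = cfg$seed))
      lrt_select(fits)$best
    } else fit_ctmm(master, pheno, cfg$model, seed = cfg$seed)
  }, error = function(e) fail("asr", e))
  recon <- marginal_reconstruction(master, pheno, fit)
  labels <- branch_labels(recon, idx)
  if (redo_asr) {
    jsonlite::write_json(list(
      model = fit$model$name, loglik = fit$loglik, Q = fit$Q,
      root_prior = fit$root_prior, prior = fit$prior, seed = cfg$seed,
      levels = fit$levels,
      node_prob = recon$prob, ml_state = fit$levels[recon$ml],
      branch = idx$keys, branch_label = as.character(labels),
      transitions = count_transitions(recon)
    ), asr_file, auto_unbox = TRUE, digits = NA)
    record("asr", outputs$asr, "computed")
  } else record("asr", outputs$asr, "skipped")

  # -- gene scan ------------------------------------------------------
  scan_file <- file.path(cfg$out_dir, outputs$scan)
  if (up_to_date("scan") && !("rer" %in% fresh) && !("asr" %in% fresh)) {
    log_msg("scan: up to date, skipped")
    record("scan", outputs$scan, "skipped")
    scan <- utils::read.delim(scan_file, check.names = FALSE)
  } else {
    log_msg("scan: per-gene association tests")
    scan <- tryCatch(
      gene_scan(rers, labels, min_per_category = cfg$min_per_category),
      error = function(e) fail("scan", e))
    utils::write.table(scan, scan_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("scan", outputs$scan, "computed")
  }

  # -- permulations ---------------------------------------------------
  null_scores <- NULL
  if (!is.null(cfg$perm)) {
    perm_file <- file.path(cfg$out_dir, outputs$permulate)
    if (up_to_date("permulate") && !("rer" %in% fresh) &&
        !("asr" %in% fresh)) {
      log_msg("permulate: up to date, skipped")
      record("permulate", outputs$permulate, "skipped")
    } else {
      log_msg("permulate: ", cfg$perm$n, " draws (relax = ",
              cfg$perm$relax, ")")
      res <- tryCatch({
        perms <- permulate(master, fit, recon, pheno, cfg$perm, idx = idx)
        nulls <- score_permulations(rers, perms,
                                    min_per_category = cfg$min_per_category)
        obs <- scan$effect_size[match(rownames(nulls), scan$gene)]
        ep <- empirical_pvalues(obs, nulls, sided = "greater")
        list(perms = perms, nulls = nulls,
             tab = data.frame(gene = rownames(nulls),
                              effect_size = obs, p_perm = ep$p,
                              floor = ep$floor, n_null = ep$n_null))
      }, error = function(e) fail("permulate", e))
      null_scores <- res$nulls
      utils::write.table(res$tab, perm_file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record("permulate", outputs$permulate, "computed")
    }
  }

  # -- enrichment -----------------------------------------------------
  if (!is.null(cfg$gmt)) {
    enr_file <- file.path(cfg$out_dir, outputs$enrich)
    if (up_to_date("enrich") && !length(fresh)) {
      log_msg("enrich: up to date, skipped")
      record("enrich", outputs$enrich, "skipped")
    } else {
      log_msg("enrich: pathway enrichment")
      enr <- tryCatch({
        pw <- read_gmt(cfg$gmt)
        ns <- if (!is.null(null_scores))
          score_via_logp(null_scores, scan) else NULL
        pathway_enrichment(scan, pw, null_scores = ns,
                           min_size = cfg$enrich_min_size,
                           max_size = cfg$enrich_max_size)
      }, error = function(e) fail("enrich", e))
      utils::write.table(enr, enr_file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record("enrich", outputs$enrich, "computed")
    }
  }

  # -- site screen ----------------------------------------------------
  if (!is.null(cfg$aln)) {
    site_file <- file.path(cfg$out_dir, outputs$sites)
    if (up_to_date("sites")) {
      log_msg("sites: up to date, skipped")
      record("sites", outputs$sites, "skipped")
    } else {
      log_msg("sites: screening alignment columns")
      sc <- tryCatch({
        aln <- read_alignment(cfg$aln)
        screen_sites(aln, pheno, master, threshold = cfg$site_threshold)
      }, error = function(e) fail("sites", e))
      utils::write.table(sc, site_file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record("sites", outputs$sites, "computed")
    }
  }

  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  log_msg("done (", round(manifest$elapsed_sec, 1), " s)")
  invisible(manifest)
}

# Convert a null effect-size matrix to the -log10 p scale of the observed
# omnibus ranking (chi-square with K-1 df; per-gene n from the scan).
score_via_logp <- function(null_effects, scan) {
  m <- match(rownames(null_effects), scan$gene)
  n <- scan$n[m]
  K <- length(attr(scan, "levels"))
  if (is.null(K) || K == 0) K <- sum(grepl("^n_", names(scan))) + 0L
  H <- null_effects * (n - 1)
  -stats::pchisq(H, K - 1, lower.tail = FALSE, log.p = TRUE) / log(10)
}
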