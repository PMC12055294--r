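# End-to-end orchestration: filter -> coverage -> tree -> alpha -> PD ->
# beta -> MRM, with one root seed expanded per stage so a rerun with the same
# configuration is byte-identical.

write_stage_tsv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metadiv %s seed=%s",
                     as.character(utils::packageVersion("metadiv")),
                     seed %||% "none"), con)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full diversity workflow
#'
#' Stages run in order: singleton filter, per-sample coverage, tree assembly
#' (when sequence inputs are supplied), coverage-standardized taxonomic
#' diversity, phylogenetic diversity (skipped with a warning when no tree
#' inputs exist), beta dissimilarity matrices and, when an environmental
#' table is supplied, MRM per Hill order. Output TSVs carry a header comment
#' with the package version and the root seed. No stage mutates its inputs.
#'
#' @param table community matrix or path to one.
#' @param outdir output directory (created if absent).
#' @param backbone,alignments,taxonomy,calibrations tree-stage inputs
#'   (objects or `NULL` to skip the tree and PD stages).
#' @param env environmental data.frame (or `NULL` to skip MRM); all numeric
#'   columns are used as one Euclidean predictor and all factor columns as
#'   one Gower predictor.
#' @param coverage coverage target (default 0.996; 0.98 is the usual
#'   robustness alternative).
#' @param q Hill orders.
#' @param B Monte-Carlo subsamples for rarefied estimates.
#' @param n_perm MRM permutations.
#' @param seed root seed; stage seeds derive from it deterministically.
#' @param extrap_cap extrapolation cap (multiplier of n).
#' @return invisible list with every stage result.
#' @export
run_pipeline <- function(table, outdir, backbone = NULL, alignments = NULL,
                         taxonomy = NULL, calibrations = NULL, env = NULL,
                         coverage = 0.996, q = c(0, 1, 2), B = 200,
                         n_perm = 999, seed = 42, extrap_cap = 2) {
  if (is.character(table)) table <- read_otu_table(table)
  table <- validate_otu_table(table)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(seed = seed)

  filt <- apply_singleton_filter(table, seed = seed)
  res$filter <- filt
  write_stage_tsv(filt$corrections, file.path(outdir, "corrections.tsv"), seed)
  write_otu_table(filt$table, file.path(outdir, "filtered.tsv"))

  cov <- coverage_table(filt$table)
  res$coverage <- cov
  write_stage_tsv(cov, file.path(outdir, "coverage.tsv"), seed)

  tree <- NULL
  if (!is.null(backbone) && !is.null(alignments)) {
    mt <- build_megatree(backbone, alignments, taxonomy, calibrations)
    tree <- mt$tree
    res$tree <- mt
    write_newick(tree, file.path(outdir, "megatree.nwk"))
    write_stage_tsv(mt$report, file.path(outdir, "tree_report.tsv"), seed)
  }

  alpha <- alpha_diversity(filt$table, q = q, coverage = coverage,
                           seed = seed + 1000, B = B, extrap_cap = extrap_cap)
  res$alpha <- alpha
  write_stage_tsv(alpha, file.path(outdir, "alpha.tsv"), seed)

  if (!is.null(tree)) {
    keep <- intersect(colnames(filt$table), tree$tip.label)
    pd_tab <- pd_diversity(filt$table[, keep, drop = FALSE], tree, q = q,
                           coverage = coverage, seed = seed + 2000, B = B,
                           extrap_cap = extrap_cap)
    res$pd <- pd_tab
    write_stage_tsv(pd_tab, file.path(outdir, "pd.tsv"), seed)
  } else {
    warning("no tree inputs; phylogenetic diversity skipped", call. = FALSE)
  }

  res$beta <- list()
  for (qq in q) {
    D <- community_distance_matrix(filt$table, qq, C_target = coverage,
                                   seed = seed + 3000 + qq, B = B,
                                   extrap_cap = extrap_cap)
    res$beta[[as.character(qq)]] <- D
    utils::write.table(D, file.path(outdir, sprintf("beta_q%d.tsv", qq)),
                       sep = "\t", quote = FALSE, col.names = NA)
  }

  if (!is.null(env)) {
    num <- vapply(env, is.numeric, logical(1))
    preds <- list()
    if (any(num)) preds$env_euclid <- env_distance(env, colnames(env)[num], "euclidean", scale = TRUE)
    if (any(!num)) preds$env_gower <- env_distance(env, colnames(env)[!num], "gower")
    res$mrm <- list()
    for (qq in q) {
      D <- res$beta[[as.character(qq)]]
      if (anyNA(D)) {
        warning("beta matrix for q = ", qq, " has excluded pairs; MRM skipped",
                call. = FALSE)
        next
      }
      fit <- mrm(D, preds, n_perm = n_perm, seed = seed + 4000 + qq)
      res$mrm[[as.character(qq)]] <- fit
      write_stage_tsv(data.frame(term = names(fit$coefficients),
                                 coefficient = fit$coefficients,
                                 p = fit$p.values,
                                 r_squared = fit$r.squared,
                                 p_r_squared = fit$p.r.squared),
                      file.path(outdir, sprintf("mrm_q%d.tsv", qq)), seed)
    }
  }
  invisible(res)
}
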