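#' Run the full integrative methylation/copy-number analysis
#'
#' Chains all stages on a cohort: LINE-1 summary, HMM copy-number-state
#' calling (when only log ratios are available), per-tumor burden, RPMM
#' methylation classing, the global permutation Kruskal-Wallis burden test,
#' the locus- and gene-level correlation screens, tumor-vs-normal alteration
#' tests stratified by the RPMM root split, Ward/Hamming CNA clustering with
#' high/low dichotomization, covariate tests, and the LINE-1 group
#' comparison.  All result tables are written as TSV under \code{out_dir}
#' together with a JSON run manifest (seed, parameters, stage row counts);
#' rerunning with the same config and seed reproduces the tables
#' byte-identically.
#'
#' @param config an [analysis_config()]; its \code{paths} element may name
#'   \code{beta}, \code{cn_state} and/or \code{log_ratio}, \code{cpg_annot},
#'   \code{snp_annot}, \code{metadata}, \code{line1} TSV files.
#' @param out_dir output directory (created if missing); NULL writes nothing.
#' @param cohort optionally a [simulate_cohort()] object used directly
#'   instead of reading \code{config$paths}.
#' @return list with all stage results (\code{burden}, \code{classing},
#'   \code{global_test}, \code{local_locus}, \code{local_gene},
#'   \code{volcano}, \code{cna_groups}, \code{covariates}, \code{line1_diff},
#'   \code{orderings}, \code{manifest}).
#' @export
run_pipeline <- function(config, out_dir = NULL, cohort = NULL) {
  stopifnot(inherits(config, "methcna_config"))
  stage <- "load_inputs"
  res <- tryCatch({
    if (is.null(cohort)) {
      p <- config$paths
      beta <- read_matrix(p$beta, "beta")
      cpg_annot <- read_annotation(p$cpg_annot)
      snp_annot <- read_annotation(p$snp_annot)
      metadata <- utils::read.delim(p$metadata, stringsAsFactors = FALSE)
      line1 <- if (!is.null(p$line1)) {
        utils::read.delim(p$line1, stringsAsFactors = FALSE)
      } else NULL
      cn <- if (!is.null(p$cn_state)) read_matrix(p$cn_state, "cn_state") else NULL
      log_ratio <- if (!is.null(p$log_ratio)) {
        read_matrix(p$log_ratio, "log_ratio")
      } else NULL
    } else {
      beta <- cohort$beta; cpg_annot <- cohort$cpg_annot
      snp_annot <- cohort$snp_annot; metadata <- cohort$metadata
      line1 <- cohort$line1; cn <- cohort$cn; log_ratio <- cohort$log_ratio
    }
    tumors <- metadata$sample[metadata$tissue == "tumor"]
    normals <- metadata$sample[metadata$tissue == "normal"]

    stage <- "preprocess"
    line1_means <- if (!is.null(line1)) line1_summary(line1) else NULL

    stage <- "cn_hmm"
    if (is.null(cn)) {
      if (is.null(log_ratio)) stop("need cn_state or log_ratio input")
      ord <- snp_annot$locus[snp_annot$locus %in% colnames(log_ratio)]
      model <- cn_hmm_model(config$hmm_emission_sd, config$hmm_stay_prob)
      cn <- call_cn_states(log_ratio[, ord, drop = FALSE],
                           snp_annot$chrom[match(ord, snp_annot$locus)], model)
    }
    burden <- cn_burden(cn[tumors, , drop = FALSE])

    stage <- "rpmm"
    classing <- rpmm_fit(beta[tumors, , drop = FALSE],
                         max_depth = config$rpmm_max_depth,
                         min_node_weight = config$rpmm_min_node_weight,
                         seed = config$seed, tol = config$rpmm_tol)

    stage <- "global_association"
    gt <- permutation_test_global(burden, classing$leaf_class[tumors],
                                  n_perm = config$n_perm_global,
                                  seed = config$seed)

    stage <- "local_integration"
    pairs <- match_loci(cpg_annot, snp_annot, config$match_max_distance)
    mp <- pairs[pairs$matched, , drop = FALSE]
    x_loc <- t(cn[tumors, mp$snp, drop = FALSE])
    y_loc <- t(beta[tumors, mp$cpg, drop = FALSE])
    rownames(x_loc) <- rownames(y_loc) <- mp$cpg
    local_locus <- correlation_screen(x_loc, y_loc,
                                      n_perm = config$n_perm_local,
                                      seed = config$seed, level = "locus")
    agg <- gene_aggregate(beta, cn, cpg_annot, snp_annot)
    common_genes <- intersect(colnames(agg$meth), colnames(agg$cn))
    local_gene <- correlation_screen(
      t(agg$cn[tumors, common_genes, drop = FALSE]),
      t(agg$meth[tumors, common_genes, drop = FALSE]),
      n_perm = config$n_perm_local, seed = config$seed, level = "gene")

    stage <- "alteration_stats"
    volcano <- stratified_volcano(
      t(agg$meth[tumors, , drop = FALSE]),
      t(agg$meth[normals, , drop = FALSE]),
      t(agg$cn[tumors, common_genes, drop = FALSE]),
      classing, q_threshold = config$q_threshold)

    stage <- "cluster_groups"
    cn_dend <- ward_cluster(hamming_matrix(cn[tumors, , drop = FALSE]))
    groups <- dichotomize_cna(cn_dend, burden)
    covar <- covariate_tests(groups$label[tumors],
                             metadata[match(tumors, metadata$sample), ],
                             seed = config$seed)
    line1_diff <- if (!is.null(line1_means)) {
      l1 <- stats::setNames(line1_means$line1, line1_means$sample)
      line1_group_difference(l1, groups)
    } else NULL
    orderings <- heatmap_orderings(beta[tumors, , drop = FALSE],
                                   cn[tumors, , drop = FALSE], classing,
                                   cn_dend)

    manifest <- list(
      package = "methcna",
      version = as.character(utils::packageVersion("methcna")),
      seed = config$seed,
      parameters = config[setdiff(names(config), "paths")],
      n_tumors = length(tumors), n_normals = length(normals),
      n_cpg = ncol(beta), n_snp = ncol(cn),
      n_matched_loci = nrow(mp),
      n_genes_meth = ncol(agg$meth), n_genes_cn = ncol(agg$cn))

    list(burden = burden, cn_states = cn, classing = classing,
         global_test = gt, matched_pairs = pairs,
         local_locus = local_locus, local_gene = local_gene,
         volcano = volcano, cna_groups = groups, covariates = covar,
         line1_means = line1_means, line1_diff = line1_diff,
         orderings = orderings, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(data.frame(sample = names(res$burden), burden = res$burden), "burden.tsv")
  write_matrix(res$cn_states, file.path(out_dir, "cn_states.tsv"), "sample")
  tsv(data.frame(sample = res$classing$sample_ids,
                 leaf_class = res$classing$leaf_class,
                 root_side = res$classing$root_side), "classes.tsv")
  tsv(data.frame(H = res$global_test$H, p = res$global_test$p,
                 n_perm = res$global_test$n_perm), "global_test.tsv")
  tsv(res$global_test$class_summary, "global_class_summary.tsv")
  tsv(res$matched_pairs, "matched_pairs.tsv")
  tsv(res$local_locus, "local_corr_locus.tsv")
  tsv(res$local_gene, "local_corr_gene.tsv")
  tsv(do.call(rbind, res$volcano$tables), "volcano.tsv")
  tsv(data.frame(sample = names(res$cna_groups$label),
                 cna_group = res$cna_groups$label), "cna_groups.tsv")
  tsv(res$covariates, "covariates.tsv")
  if (!is.null(res$line1_diff)) {
    ci <- if (res$line1_diff$ci_available) res$line1_diff$conf_int else c(NA, NA)
    tsv(data.frame(difference = res$line1_diff$difference,
                   ci_lo = ci[1], ci_hi = ci[2]), "line1_difference.tsv")
  }
  tsv(res$orderings$meth_table, "meth_ordering.tsv")
  tsv(data.frame(sample = res$orderings$cn_order,
                 position = seq_along(res$orderings$cn_order)),
      "cn_ordering.tsv")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
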