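# End-to-end orchestration: a single configuration object holding every
# threshold, a seeded pipeline run writing all stage outputs to disk, and a
# machine-readable run report whose tallies are recomputed from the files.

#' Pipeline configuration
#'
#' All thresholds of the screening pipeline with their standard defaults:
#' retention-time floor 30 s, 70% prevalence, detection fraction 0.5 for
#' outlier samples, FDR cut-off 0.05, 4-fold top-differing rule, quadrant
#' cut-offs FC 2 and |r| 0.3, 12 ppm mass tolerance, acceptance thresholds
#' 47/50 (HMDB) and 50/40 (METLIN), EBIC gamma 0.5.
#'
#' @param min_rt,min_prevalence,min_detection preprocessing thresholds.
#' @param q_cut FDR cut-off used by every filter step.
#' @param fold_top top-differing fold threshold.
#' @param fc_cut,r_cut quadrant-group cut-offs.
#' @param tol_ppm annotation mass tolerance (ppm).
#' @param hmdb_qi,hmdb_frag,metlin_qi,metlin_frag acceptance thresholds.
#' @param ebic_gamma EBIC hyperparameter for network selection.
#' @param network_max_nodes cap on network size (top-differing metabolites
#'   ranked by |log2 fold change|).
#' @param n_lambda penalty-grid size for the network stage.
#' @param permutations global-test permutation count for the pipeline run.
#' @param include_cord include cord samples in the age correlation.
#' @param seed integer seed for every stochastic stage.
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(min_rt = 30, min_prevalence = 0.70,
                            min_detection = 0.5, q_cut = 0.05, fold_top = 4,
                            fc_cut = 2, r_cut = 0.3, tol_ppm = 12,
                            hmdb_qi = 47, hmdb_frag = 50, metlin_qi = 50,
                            metlin_frag = 40, ebic_gamma = 0.5,
                            network_max_nodes = 56, n_lambda = 100,
                            permutations = 999, include_cord = TRUE,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

check_config <- function(config) {
  req <- names(formals(pipeline_config))
  missing <- setdiff(req, names(config))
  if (length(missing)) {
    stop("pipeline config is missing field(s): ", paste(missing, collapse = ", "))
  }
  invisible(config)
}

#' Read / write a pipeline configuration
#' @param config a [pipeline_config()]
#' @param path JSON file path
#' @return the configuration (reader) or `path` invisibly (writer)
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  check_config(cfg)
  cfg
}

stage_msg <- function(...) message("[cordmetab] ", sprintf(...))

#' Run the full screening pipeline
#'
#' Executes, in order: preprocessing (RT filter, prevalence filter, outlier
#' sample removal, injection aggregation, per-batch median normalization),
#' annotation with class exclusion, per-metabolite statistics with the
#' two-step antiaging filter and its pro-aging mirror, the partial-correlation
#' network of the top-differing set, pathway enrichment (global test, ORA,
#' impact, activity) and ordination (sample PCA, metabolite MDS). All stage
#' outputs are written to `out_dir` as TSV/JSON; identical inputs, config and
#' seed give byte-identical outputs.
#'
#' @param features raw [feature_table()] (per-injection columns).
#' @param samples matching [sample_table()]
#' @param library a [compound_library()]
#' @param pathways a [pathway_db()]
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if needed).
#' @return the run report (also written as `run_report.json`), a nested list
#'   of stage counts.
#' @export
run_pipeline <- function(features, samples, library, pathways,
                         config = pipeline_config(), out_dir) {
  check_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  stage_msg("preprocess: %d features x %d columns in", n_features(features),
            n_samples(features))
  pp <- preprocess_pipeline(features, samples, min_rt = config$min_rt,
                            min_prevalence = config$min_prevalence,
                            min_detection = config$min_detection)
  counts$preprocess <- pp$report$counts
  write_feature_table(pp$table, file.path(out_dir, "normalized_features.tsv"))
  write_sample_table(pp$samples, file.path(out_dir, "samples_clean.tsv"))
  stage_msg("preprocess: %d features x %d biological samples out",
            n_features(pp$table), n_samples(pp$table))

  hits <- annotate_features(pp$table, library, tol_ppm = config$tol_ppm,
                            hmdb_qi = config$hmdb_qi,
                            hmdb_frag = config$hmdb_frag,
                            metlin_qi = config$metlin_qi,
                            metlin_frag = config$metlin_frag)
  acc <- hits[hits$accepted, , drop = FALSE]
  excl <- exclude_classes(acc, library)
  kept <- excl$kept
  counts$annotate <- list(n_hits_scored = nrow(hits),
                          n_features_annotated = nrow(acc),
                          n_excluded_class = excl$n_removed,
                          n_metabolites = nrow(kept))
  utils::write.table(hits, file.path(out_dir, "annotation_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_msg("annotate: %d accepted, %d removed as exogenous/steroid, %d kept",
            nrow(acc), excl$n_removed, nrow(kept))

  # compound-level table: one row per annotated, non-excluded metabolite
  ridx <- match(kept$feature_id, pp$table$features$feature_id)
  met_tab <- feature_table(
    data.frame(feature_id = kept$compound_id,
               rt = pp$table$features$rt[ridx],
               mz = pp$table$features$mz[ridx], stringsAsFactors = FALSE),
    pp$table$intensities[ridx, , drop = FALSE],
    normalized = TRUE
  )

  stats <- metabolite_stats(met_tab, pp$samples, q_cut = config$q_cut,
                            fold = config$fold_top, fc_cut = config$fc_cut,
                            r_cut = config$r_cut,
                            include_cord = config$include_cord)
  counts$diffstats <- list(
    n_metabolites = nrow(stats),
    n_significant = sum(stats$q_diff < config$q_cut, na.rm = TRUE),
    n_top_differing = sum(stats$is_top_differing),
    n_top_cord_enriched = sum(stats$direction == "cord_enriched"),
    n_top_adult_enriched = sum(stats$direction == "adult_enriched"),
    n_antiaging = sum(stats$antiaging),
    n_group = as.list(stats::setNames(
      vapply(1:4, function(g) sum(stats$group == g, na.rm = TRUE), 0L),
      paste0("g", 1:4))),
    n_proaging = sum(stats$proaging)
  )
  utils::write.table(stats, file.path(out_dir, "metabolite_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  anti <- stats[stats$antiaging, , drop = FALSE]
  anti <- anti[order(anti$composite_rank), , drop = FALSE]
  utils::write.table(anti, file.path(out_dir, "antiaging_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  pro <- stats[stats$proaging, , drop = FALSE]
  utils::write.table(pro, file.path(out_dir, "proaging_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  stage_msg("diffstats: %d significant, %d top-differing (%d up / %d down), %d antiaging, %d proaging",
            counts$diffstats$n_significant, counts$diffstats$n_top_differing,
            counts$diffstats$n_top_cord_enriched,
            counts$diffstats$n_top_adult_enriched,
            counts$diffstats$n_antiaging, counts$diffstats$n_proaging)

  top <- stats[stats$is_top_differing, , drop = FALSE]
  top <- top[order(-abs(top$log2fc)), , drop = FALSE]
  net_ids <- utils::head(top$metabolite_id, config$network_max_nodes)
  if (length(net_ids) >= 3) {
    net <- metabolite_network(met_tab, pp$samples, metabolite_ids = net_ids,
                              gamma = config$ebic_gamma,
                              n_lambda = config$n_lambda)
    counts$network <- list(n_nodes = length(net$nodes),
                           n_edges = n_edges(net),
                           lambda = net$lambda)
    utils::write.table(edge_list(net), file.path(out_dir, "network_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(net$centralities,
                       file.path(out_dir, "network_centralities.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage_msg("network: %d nodes, %d edges at lambda %.4g",
              length(net$nodes), n_edges(net), net$lambda)
  } else {
    counts$network <- list(n_nodes = 0L, n_edges = 0L, lambda = NA)
    stage_msg("network: skipped (<3 top-differing metabolites)")
  }

  gt <- enrich_global(met_tab, pp$samples, pathways, outcome = "group",
                      B = config$permutations, seed = config$seed)
  ora <- ora_all(anti$metabolite_id, stats$metabolite_id, pathways)
  ora$impact <- vapply(ora$pathway_id, function(pid) {
    pathway_impact(pathways$sets[[pid]], pathways$edges[[pid]],
                   intersect(anti$metabolite_id, pathways$sets[[pid]]))
  }, 0)
  act <- pathway_activity(met_tab, pp$samples, pathways)
  counts$enrichment <- list(
    n_pathways = length(pathways$sets),
    n_global_significant = sum(gt$q < config$q_cut, na.rm = TRUE),
    n_ora_antiaging_significant = sum(ora$q < config$q_cut, na.rm = TRUE)
  )
  utils::write.table(gt, file.path(out_dir, "enrichment_global.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(ora, file.path(out_dir, "enrichment_ora.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(act, file.path(out_dir, "pathway_activity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  stage_msg("enrichment: %d/%d pathways significant (global test)",
            counts$enrichment$n_global_significant, length(pathways$sets))

  emb <- pca(t(log2_missing(met_tab$intensities[, !pp$samples$is_qc,
                                                drop = FALSE])),
             n_components = 2)
  pca_out <- data.frame(sample_id = emb$ids, pc1 = emb$coords[, 1],
                        pc2 = emb$coords[, 2], stringsAsFactors = FALSE)
  utils::write.table(pca_out, file.path(out_dir, "pca_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mds <- mds_metabolites(met_tab, pp$samples)
  mds_out <- data.frame(metabolite_id = mds$ids, dim1 = mds$coords[, 1],
                        dim2 = mds$coords[, 2], stringsAsFactors = FALSE)
  utils::write.table(mds_out, file.path(out_dir, "mds_metabolites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$ordination <- list(
    pca_variance_explained = as.numeric(emb$variance_explained),
    mds_stress = mds$stress
  )

  report <- list(package_version = as.character(utils::packageVersion("cordmetab")),
                 seed = config$seed, counts = counts)
  check_report_consistency(report)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

check_report_consistency <- function(report) {
  d <- report$counts$diffstats
  if (!is.null(d)) {
    if (sum(unlist(d$n_group)) != d$n_antiaging) {
      stop("inconsistent tallies: group counts do not sum to antiaging count")
    }
    if (d$n_top_cord_enriched + d$n_top_adult_enriched != d$n_top_differing) {
      stop("inconsistent tallies: top-differing split does not sum")
    }
  }
  invisible(report)
}

#' Recompute the run report from stage output files
#'
#' Re-reads the pipeline's on-disk outputs and tallies them independently of
#' any in-memory state, so serialization bugs surface as count mismatches.
#'
#' @param out_dir directory written by [run_pipeline()]
#' @param q_cut FDR cut-off used to re-count significant rows (default 0.05).
#' @return nested list of recomputed counts.
#' @export
summarize_counts <- function(out_dir, q_cut = 0.05) {
  need <- c("metabolite_stats.tsv", "antiaging_candidates.tsv",
            "proaging_candidates.tsv", "enrichment_global.tsv")
  for (f in need) {
    if (!file.exists(file.path(out_dir, f))) {
      stop("missing stage output file: ", f)
    }
  }
  stats <- utils::read.table(file.path(out_dir, "metabolite_stats.tsv"),
                             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  anti <- utils::read.table(file.path(out_dir, "antiaging_candidates.tsv"),
                            header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  pro <- utils::read.table(file.path(out_dir, "proaging_candidates.tsv"),
                           header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  gt <- utils::read.table(file.path(out_dir, "enrichment_global.tsv"),
                          header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  counts <- list(
    n_metabolites = nrow(stats),
    n_significant = sum(stats$q_diff < q_cut, na.rm = TRUE),
    n_top_differing = sum(stats$is_top_differing),
    n_antiaging = nrow(anti),
    n_group = as.list(stats::setNames(
      vapply(1:4, function(g) sum(anti$group == g, na.rm = TRUE), 0L),
      paste0("g", 1:4))),
    n_proaging = nrow(pro),
    n_global_significant = sum(gt$q < q_cut, na.rm = TRUE)
  )
  if (sum(unlist(counts$n_group)) != counts$n_antiaging) {
    stop("inconsistent tallies: group counts do not sum to antiaging count")
  }
  counts
}
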