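#' Default pipeline configuration
#'
#' Collects every stage parameter with its default, the five input paths and
#' an output directory. One global seed fans out to per-stage sub-seeds by
#' fixed offsets so stages are individually reproducible.
#'
#' @param matrix_path,metadata_path,network_path,annotation_path,disease_path
#'   input file paths (TSV dialects of the reader functions). `network_path`,
#'   `annotation_path` and `disease_path` may be `NULL` to skip those stages.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @param exclusive_min_present,min_present_per_group,max_total_na
#'   missingness-stage thresholds.
#' @param p_cutoff,d_cutoff,outlier_k differential-stage thresholds.
#' @param edge_min_score,hub_threshold network-stage thresholds.
#' @param disease_min_score gene-disease threshold.
#' @param n_sim Monte-Carlo chi-squared simulations.
#' @param kmeans_k clusters for the QC stage.
#' @param test `"welch"` or `"student"`.
#' @param seed global integer seed.
#' @return a named list (class `pipeline_config`).
#' @export
pipeline_config <- function(matrix_path, metadata_path,
                            network_path = NULL, annotation_path = NULL,
                            disease_path = NULL, out_dir = NULL,
                            exclusive_min_present = 3L,
                            min_present_per_group = 4L, max_total_na = 3L,
                            p_cutoff = 0.05, d_cutoff = 2.0, outlier_k = 2.0,
                            edge_min_score = 0.9, hub_threshold = 2,
                            disease_min_score = 2.0, n_sim = 2000L,
                            kmeans_k = 2L, test = "welch", seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Fixed stage order: read inputs -> group-exclusive detection (on the raw
#' matrix) -> missingness filter -> per-sample mean imputation -> per-protein
#' differential statistics and DEP classification -> LFC outliers ->
#' clustering / PCA quality control -> category association per ontology ->
#' PPI hub consensus -> gene-disease filter. Any stage failure aborts with
#' the stage name. Identical config and inputs give an identical report.
#'
#' @param config a [pipeline_config()].
#' @return the report: a nested list with one section per stage, every
#'   threshold echoed, and provenance fields recording which matrix each
#'   stage consumed. Written to `<out_dir>/report.json` (plus per-stage
#'   TSVs) when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline aborted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  log_msg <- function(...) message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "),
                                   ...)

  log_msg("stage input: reading abundance matrix")
  raw <- stage("input", read_abundance_matrix(config$matrix_path,
                                              config$metadata_path))

  log_msg("stage exclusive: raw matrix, min_present = ",
          config$exclusive_min_present)
  exclusive <- stage("exclusive",
                     detect_exclusive(raw, config$exclusive_min_present))

  log_msg("stage filter: min_present_per_group = ",
          config$min_present_per_group, ", max_total_na = ",
          config$max_total_na)
  filt <- stage("filter",
                filter_missingness(raw, config$min_present_per_group,
                                   config$max_total_na))

  log_msg("stage impute: per-sample mean")
  imp <- stage("impute", impute_sample_mean(filt$dataset))

  log_msg("stage differential: ", config$test, " t-test")
  records <- stage("differential", {
    rec <- dep_statistics(imp$dataset, imp$imputation_counts,
                          test = config$test)
    classify_deps(rec, config$p_cutoff, config$d_cutoff)
  })
  n_up <- sum(records$direction == "up")
  n_down <- sum(records$direction == "down")

  outliers <- stage("outliers", {
    if (n_up + n_down >= 2L) detect_outliers(records, config$outlier_k)
    else list(cutoff = NA_real_, n_deps = n_up + n_down,
              outliers_up = character(0), outliers_down = character(0))
  })

  log_msg("stage multivariate: k-means (k = ", config$kmeans_k, ") + PCA")
  ordination <- stage("multivariate",
                      kmeans_pca(imp$dataset, k = config$kmeans_k,
                                 seed = config$seed + 1L))

  association <- NULL
  if (!is.null(config$annotation_path)) {
    log_msg("stage association: Monte-Carlo chi-squared, n_sim = ",
            config$n_sim)
    association <- stage("association", {
      ann <- read_annotation_table(config$annotation_path)
      onts <- intersect(.ONTOLOGIES, unique(ann$ontology))
      lapply(stats::setNames(onts, onts), function(o)
        test_category_association(records, ann, o, n_sim = config$n_sim,
                                  seed = config$seed + 2L))
    })
  }

  hubs <- NULL
  if (!is.null(config$network_path)) {
    log_msg("stage hubs: edge score > ", config$edge_min_score,
            ", centrality threshold >= ", config$hub_threshold)
    hubs <- stage("hubs", {
      net <- filter_edges(read_edge_list(config$network_path),
                          config$edge_min_score)
      scores <- hub_scores(net)
      c(list(scores = scores),
        consensus_hubs(scores, config$hub_threshold))
    })
  }

  disease <- NULL
  if (!is.null(config$disease_path)) {
    log_msg("stage disease: confidence score > ", config$disease_min_score)
    disease <- stage("disease",
                     filter_associations(read_disease_table(config$disease_path),
                                         config$disease_min_score))
  }

  report <- list(
    parameters = unclass(config)[setdiff(names(config),
                                         c("matrix_path", "metadata_path",
                                           "network_path", "annotation_path",
                                           "disease_path", "out_dir"))],
    provenance = list(
      exclusive_input = "raw matrix",
      differential_input = "filtered and imputed matrix",
      n_proteins_raw = nrow(raw$values),
      n_proteins_filtered = nrow(filt$dataset$values)),
    counts = list(
      proteins_raw = nrow(raw$values),
      proteins_excluded = filt$report$n_excluded,
      proteins_analyzed = filt$report$n_kept,
      deps_up = n_up, deps_down = n_down,
      deps_total = n_up + n_down,
      exclusive = stats::setNames(
        as.list(as.integer(table(factor(exclusive$present_group,
                                        levels = raw$group_levels)))),
        raw$group_levels)),
    per_sample = filt$report$per_sample,
    exclusive = exclusive,
    dep_records = records,
    outliers = outliers,
    multivariate = list(
      explained_variance_fraction = ordination$explained_variance_fraction,
      kmeans_labels = as.list(ordination$kmeans_labels),
      dendrogram_heights = ordination$dendrogram$height),
    association = lapply(association, function(a)
      a[c("ontology", "contingency", "chi2_statistic", "mc_p_value",
          "n_sim", "residuals", "bands", "significant")]),
    hubs = hubs,
    disease = disease)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(records, file.path(config$out_dir, "dep_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(exclusive,
                       file.path(config$out_dir, "exclusive_proteins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(volcano_table(records),
                       file.path(config$out_dir, "volcano.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(hubs))
      utils::write.table(hubs$scores,
                         file.path(config$out_dir, "hub_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      report[setdiff(names(report), "dep_records")],
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = 10, force = TRUE, pretty = TRUE)
  }
  invisible(report)
}
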