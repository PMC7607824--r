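# End-to-end orchestration: read -> filter -> dissimilarity -> cluster ->
# quality/summary, with optional expression mapping and annotation
# composition, writing all reports plus a run manifest.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the clustering pipeline end-to-end
#'
#' Executes the full analysis from a configuration (a named list or the
#' path of a YAML file): read and validate the phenotype table, keep the
#' complete records, build the weighted Gower dissimilarity, cluster
#' (PAM, Ward's or complete linkage), compute the quality report,
#' guideline verdict and majority-phenotype summary; optionally scan a
#' weight-by-k grid, map K-means expression profiles onto the phenotypic
#' clusters, and compute composition tables for annotation attributes.
#' Every output is written to \code{outDir} along with a
#' \code{manifest.json} echoing the parameters, seeds, package version
#' and the file list.  Re-running an unchanged config overwrites the
#' outputs identically; any stage failure aborts with a message naming
#' the stage.
#'
#' Recognized config fields: \code{phenotypes} (path, required),
#' \code{weights} (preset name or 10 numbers, default "NoWeight"),
#' \code{k} (required), \code{method} ("pam"/"ward"/"complete"),
#' \code{scan} (list: \code{presets}, \code{k_values}),
#' \code{expression} (list: \code{path}, \code{k}, \code{seed},
#' \code{restarts}), \code{annotations} (list: \code{path},
#' \code{attributes}), \code{thresholds} (list: \code{min_size},
#' \code{max_k}, \code{rsd_limit}, \code{consensus_min},
#' \code{varied_threshold}, \code{dominance}, \code{min_genes}).
#'
#' @param config named list or YAML file path.
#' @param outDir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopIfNot(is.list(config), "config must be a named list or a YAML path")
  stopIfNot(!is.null(config$phenotypes), "config needs a 'phenotypes' path")
  stopIfNot(!is.null(config$k), "config needs 'k'")
  thr <- config$thresholds %||% list()
  min.size <- thr$min_size %||% 3
  max.k <- thr$max_k %||% 40
  rsd.limit <- thr$rsd_limit %||% 15
  consensus.min <- thr$consensus_min %||% 95
  varied <- thr$varied_threshold %||% 50
  dominance <- thr$dominance %||% 0.40
  min.genes <- thr$min_genes %||% 3
  method <- config$method %||% "pam"
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(outDir, name)
    writer(path)
    outputs <<- c(outputs, name)
    path
  }

  tab <- .stage("phenotype_data", {
    stopIfNot(file.exists(config$phenotypes),
              "phenotype file not found: %s", config$phenotypes)
    readPhenotypeTable(config$phenotypes)
  })
  complete <- .stage("phenotype_data", suppressMessages(filterComplete(tab)))
  emit("validated_phenotypes.csv",
       function(p) writePhenotypeTable(complete, p))

  d <- .stage("dissimilarity",
              gowerMatrix(complete, config$weights %||% "NoWeight"))
  asg <- .stage("partition_clustering", {
    if (method == "pam") pamCluster(d, config$k)
    else agglomerativeCluster(d, method, config$k)
  })
  emit("assignment.csv", function(p)
    writeAssignment(asg, p, parameters = list(
      weights = config$weights %||% "NoWeight", method = method)))
  outputs <- c(outputs, "assignment.json")

  quality <- .stage("cluster_quality", runQuality(asg, complete))
  verdict <- guidelineCheck(quality, min.size, max.k, rsd.limit,
                            consensus.min)
  emit("quality_per_cluster.csv", function(p)
    utils::write.csv(quality@perCluster, p, row.names = FALSE))
  emit("quality_per_trait.csv", function(p)
    utils::write.csv(quality@perTrait, p, row.names = FALSE))
  emit("cluster_summary.csv", function(p)
    utils::write.csv(clusterSummary(asg, complete, varied), p,
                     row.names = FALSE))

  if (!is.null(config$scan)) {
    presets <- config$scan$presets %||% names(weightPreset())
    scan <- .stage("cluster_quality",
                   weightScan(complete, weightPreset()[presets],
                              config$scan$k_values, method))
    emit("weight_scan.csv", function(p)
      utils::write.csv(scan, p, row.names = FALSE))
  }

  profile.summary <- NULL
  if (!is.null(config$expression)) {
    ex <- config$expression
    map <- .stage("expression_profiles", {
      expr <- standardizeRows(readExpressionMatrix(ex$path))
      prof <- kmeansProfiles(expr, ex$k, ex$seed %||% 1L,
                             ex$restarts %||% 10L)
      mapProfiles(asg, prof, min.genes, dominance)
    })
    emit("profile_map.csv", function(p)
      utils::write.csv(map@perCluster, p, row.names = FALSE))
    emit("profile_crosstab.csv", function(p)
      utils::write.csv(as.data.frame.matrix(map@crossTab), p))
    profile.summary <- map@summary
  }

  if (!is.null(config$annotations)) {
    an <- config$annotations
    ann <- .stage("cluster_annotation", readAnnotationTable(an$path))
    for (attr in an$attributes %||% character(0)) {
      comp <- .stage("cluster_annotation", composition(asg, ann, attr))
      emit(sprintf("composition_%s.csv", attr), function(p)
        utils::write.csv(comp$perCluster, p, row.names = FALSE))
    }
  }

  manifest <- list(
    package = "phenoPAM",
    version = as.character(utils::packageVersion("phenoPAM")),
    parameters = config[setdiff(names(config), NULL)],
    thresholds = list(min_size = min.size, max_k = max.k,
                      rsd_limit = rsd.limit, consensus_min = consensus.min,
                      varied_threshold = varied, dominance = dominance,
                      min_genes = min.genes),
    n_input = nrow(tab), n_complete = nrow(complete),
    guideline_verdict = verdict[c("min_size_ok", "max_clusters_ok",
                                  "rsd_ok", "consensus_ok", "pass")],
    composite_consensus = quality@compositeConsensus,
    composite_rsd = quality@compositeRSD,
    profile_summary = profile.summary,
    outputs = sort(outputs))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
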