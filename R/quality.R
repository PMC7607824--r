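# Cluster-quality statistics: per-cluster relative standard deviation for
# the continuous traits, percent consensus for the categorical traits,
# run-level composites, guideline checks, the weight-by-k selection scan
# and majority-phenotype cluster summaries.

#' Relative standard deviation, in per cent
#'
#' 100 times the sample standard deviation (n-1 denominator) divided by
#' the mean.  A singleton has no spread and returns 0 by convention.  A
#' mean at or below the 1e-9 guard is undefined and aborts.
#'
#' @param values numeric vector of positive measurements, length >= 1.
#' @return numeric scalar (per cent).
#' @examples
#' relativeSD(c(10, 20))  # 47.14
#' @export
relativeSD <- function(values) {
  stopIfNot(is.numeric(values) && length(values) >= 1L && !anyNA(values),
            "values must be a non-empty numeric vector without NAs")
  if (length(values) == 1L) return(0)
  m <- mean(values)
  stopIfNot(m > 1e-9, "undefined relative SD: mean is not positive")
  100 * stats::sd(values) / m
}

#' Percent consensus of a set of categorical labels
#'
#' The share (per cent) of the most prevalent label.  Ties between
#' equally frequent labels are broken by \code{vocabulary} order and
#' flagged.
#'
#' @param labels character vector, length >= 1.
#' @param vocabulary ordered label vector used for tie-breaking; defaults
#'   to first-appearance order.
#' @return list with \code{percent}, \code{majority} and \code{tie}.
#' @examples
#' percentConsensus(c(rep("Reduced", 6), rep("Normal", 4)))  # 60%
#' @export
percentConsensus <- function(labels, vocabulary = NULL) {
  stopIfNot(length(labels) >= 1L, "labels must be non-empty")
  labels <- as.character(labels)
  if (!is.null(vocabulary)) {
    extra <- setdiff(labels, vocabulary)
    stopIfNot(length(extra) == 0L, "label(s) outside the vocabulary: %s",
              paste(extra, collapse = ", "))
  }
  m <- modalLabel(labels, vocabulary)
  list(percent = 100 * m$count / length(labels), majority = m$label,
       tie = m$tie)
}

#' Quality report for a clustering run
#'
#' Computes, for every cluster, the relative SD of each continuous trait
#' and the percent consensus (with majority label) of each categorical
#' trait; then run-level per-trait averages over clusters (each cluster
#' weighted equally, regardless of size) and the two composites: the mean
#' of the two continuous per-trait averages (composite relative SD) and
#' the mean of the eight categorical per-trait averages (composite
#' consensus).
#'
#' @param assignment a [ClusterAssignment-class] whose ids are all present
#'   in \code{table}.
#' @param table a complete [PhenotypeTable-class].
#' @return a [QualityReport-class].
#' @export
runQuality <- function(assignment, table) {
  pos <- match(assignment@ids, geneIds(table))
  stopIfNot(!anyNA(pos), "gene(s) in assignment missing from table: %s",
            paste(assignment@ids[is.na(pos)], collapse = ", "))
  sc <- table@schema
  d <- table@data[pos, , drop = FALSE]
  ord <- order(sc@traits$position)
  k <- assignment@k
  per.cluster <- data.frame(cluster = seq_len(k),
                            size = tabulate(assignment@labels, k))
  trait.avg <- numeric(0)
  for (i in ord) {
    nm <- sc@traits$name[i]
    if (sc@traits$kind[i] == "continuous") {
      v <- vapply(seq_len(k), function(cl)
        relativeSD(d[[nm]][assignment@labels == cl]), numeric(1))
      per.cluster[[paste0("rsd_", nm)]] <- v
    } else {
      pc <- lapply(seq_len(k), function(cl)
        percentConsensus(d[[nm]][assignment@labels == cl],
                         sc@vocabulary[[nm]]))
      v <- vapply(pc, `[[`, numeric(1), "percent")
      per.cluster[[paste0("consensus_", nm)]] <- v
      per.cluster[[paste0("majority_", nm)]] <-
        vapply(pc, `[[`, character(1), "majority")
    }
    trait.avg[nm] <- mean(v)
  }
  names.ord <- sc@traits$name[ord]
  kinds <- sc@traits$kind[ord]
  per.trait <- data.frame(trait = names.ord, kind = kinds,
                          average = unname(trait.avg[names.ord]),
                          stringsAsFactors = FALSE)
  new("QualityReport", perCluster = per.cluster, perTrait = per.trait,
      compositeRSD = mean(per.trait$average[kinds == "continuous"]),
      compositeConsensus = mean(per.trait$average[kinds == "categorical"]),
      run = list(method = assignment@method, k = k))
}

#' Check a quality report against the clustering guidelines
#'
#' The four guidelines: at least \code{minSize} genes in every cluster, at
#' most \code{maxK} clusters, composite relative SD strictly below
#' \code{rsdLimit} per cent, and composite consensus no less than
#' \code{consensusMin} per cent.  The run passes iff all four hold.
#'
#' @param report a [QualityReport-class].
#' @param minSize minimum genes per cluster (default 3).
#' @param maxK maximum number of clusters (default 40).
#' @param rsdLimit relative-SD ceiling, per cent (default 15).
#' @param consensusMin consensus floor, per cent (default 95).
#' @return list with the four booleans, \code{pass} and the thresholds.
#' @export
guidelineCheck <- function(report, minSize = 3, maxK = 40, rsdLimit = 15,
                           consensusMin = 95) {
  v <- list(
    min_size_ok = all(report@perCluster$size >= minSize),
    max_clusters_ok = nrow(report@perCluster) <= maxK,
    rsd_ok = report@compositeRSD < rsdLimit,
    consensus_ok = report@compositeConsensus >= consensusMin)
  v$pass <- all(unlist(v))
  v$thresholds <- list(minSize = minSize, maxK = maxK, rsdLimit = rsdLimit,
                       consensusMin = consensusMin)
  v
}

#' Weight-by-k selection scan
#'
#' Clusters the table once per (weight preset, k) combination and reports
#' the per-trait averages, the two composites and the guideline verdict
#' for every run --- the model-selection table for choosing the weighting
#' and the number of clusters.  The "best" run is flagged by the
#' lexicographic criterion: maximal composite consensus, then minimal
#' composite relative SD.
#'
#' @param table a complete [PhenotypeTable-class].
#' @param presets named list of weight vectors (default all of
#'   [weightPreset()]).
#' @param kValues integer vector of cluster counts to scan.
#' @param method \code{"pam"} (default), \code{"ward"} or
#'   \code{"complete"}.
#' @return data.frame, one row per (preset, k) in scan order, with a
#'   logical \code{best} column.
#' @export
weightScan <- function(table, presets = weightPreset(), kValues,
                       method = c("pam", "ward", "complete")) {
  method <- match.arg(method)
  stopIfNot(length(presets) >= 1L && length(kValues) >= 1L,
            "presets and kValues must be non-empty")
  if (is.null(names(presets)) || any(names(presets) == ""))
    stop("presets must be a named list", call. = FALSE)
  rows <- list()
  for (w in names(presets)) {
    d <- gowerMatrix(table, presets[[w]])
    for (k in kValues) {
      asg <- if (method == "pam") pamCluster(d, k)
             else agglomerativeCluster(d, method, k)
      rep <- runQuality(asg, table)
      verdict <- guidelineCheck(rep)
      row <- data.frame(weights = w, k = as.integer(k),
                        stringsAsFactors = FALSE)
      for (i in seq_len(nrow(rep@perTrait))) {
        pref <- if (rep@perTrait$kind[i] == "continuous") "avg_rsd_"
                else "avg_consensus_"
        row[[paste0(pref, rep@perTrait$trait[i])]] <- rep@perTrait$average[i]
      }
      row$composite_consensus <- rep@compositeConsensus
      row$composite_rsd <- rep@compositeRSD
      row$min_size_ok <- verdict$min_size_ok
      row$max_clusters_ok <- verdict$max_clusters_ok
      row$rsd_ok <- verdict$rsd_ok
      row$consensus_ok <- verdict$consensus_ok
      row$pass <- verdict$pass
      rows[[length(rows) + 1L]] <- row
    }
  }
  scan <- do.call(rbind, rows)
  rownames(scan) <- NULL
  best <- order(-scan$composite_consensus, scan$composite_rsd)[1L]
  scan$best <- seq_len(nrow(scan)) == best
  scan
}

#' Majority-phenotype summary per cluster
#'
#' For every cluster and every trait, the majority phenotype with its
#' share, formatted as e.g. \code{"75\% Normal Average"}.  Continuous
#' traits are first binned with [binContinuous()].  When no single
#' phenotype exceeds \code{variedThreshold} per cent of the cluster the
#' cell reads \code{"Varied"}.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param table a complete [PhenotypeTable-class].
#' @param variedThreshold per-cent share a majority must strictly exceed
#'   (default 50).
#' @return data.frame: \code{cluster}, \code{size}, one column per trait.
#' @export
clusterSummary <- function(assignment, table, variedThreshold = 50) {
  pos <- match(assignment@ids, geneIds(table))
  stopIfNot(!anyNA(pos), "gene(s) in assignment missing from table: %s",
            paste(assignment@ids[is.na(pos)], collapse = ", "))
  sc <- table@schema
  d <- table@data[pos, , drop = FALSE]
  k <- assignment@k
  out <- data.frame(cluster = seq_len(k),
                    size = tabulate(assignment@labels, k))
  for (i in order(sc@traits$position)) {
    nm <- sc@traits$name[i]
    if (sc@traits$kind[i] == "continuous") {
      lv <- .BIN_LEVELS
      vals <- binContinuous(d[[nm]],
                            if (nm == "growth_rate") "growth" else "aerial")
    } else {
      lv <- sc@vocabulary[[nm]]
      vals <- d[[nm]]
    }
    out[[nm]] <- vapply(seq_len(k), function(cl) {
      pc <- percentConsensus(vals[assignment@labels == cl], lv)
      if (pc$percent <= variedThreshold) "Varied"
      else sprintf("%.0f%% %s", pc$percent, pc$majority)
    }, character(1))
  }
  out
}
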