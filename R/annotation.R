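# Cluster composition against gene annotations, multi-pathway MAPK
# target counting and the chromosome goodness-of-fit test.

.ANNOTATION_FLAGS <- c("yeast_ortholog", "has_TM", "is_GPCR", "is_ST_kinase",
                       "is_phosphatase", "is_TF", "is_metabolic",
                       "is_phosphoprotein", "target_MAK1", "target_MAK2",
                       "target_OS2")

#' Read and validate a gene annotation table
#'
#' One row per gene: \code{gene_id}, any subset of the boolean attribute
#' columns (yeast_ortholog, has_TM, is_GPCR, is_ST_kinase, is_phosphatase,
#' is_TF, is_metabolic, is_phosphoprotein, target_MAK1, target_MAK2,
#' target_OS2) and optionally \code{linkage_group} (1..7).  Booleans may
#' be coded TRUE/FALSE or 0/1.  A predicted GPCR is by definition a
#' transmembrane protein, so \code{is_GPCR} implies \code{has_TM}.
#'
#' @param file CSV path, or a data.frame to validate directly.
#' @return validated data.frame.
#' @export
readAnnotationTable <- function(file) {
  df <- if (is.data.frame(file)) file
        else utils::read.csv(file, stringsAsFactors = FALSE)
  stopIfNot("gene_id" %in% names(df), "annotation table needs a gene_id column")
  df$gene_id <- as.character(df$gene_id)
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  stopIfNot(length(dup) == 0L, "duplicate gene_id in annotations: %s",
            paste(dup, collapse = ", "))
  for (nm in intersect(.ANNOTATION_FLAGS, names(df))) {
    v <- df[[nm]]
    if (!is.logical(v)) v <- as.logical(as.integer(v))
    stopIfNot(!anyNA(v), "attribute '%s' has unparseable values", nm)
    df[[nm]] <- v
  }
  if (all(c("is_GPCR", "has_TM") %in% names(df)))
    stopIfNot(all(df$has_TM[df$is_GPCR]),
              "is_GPCR implies has_TM; violated for %s",
              paste(df$gene_id[df$is_GPCR & !df$has_TM], collapse = ", "))
  if ("linkage_group" %in% names(df)) {
    lg <- as.integer(df$linkage_group)
    stopIfNot(all(lg %in% 1:7), "linkage_group must be in 1..7")
    df$linkage_group <- lg
  }
  df
}

#' Per-cluster composition for a boolean gene attribute
#'
#' For every cluster, the count and percentage (one decimal) of genes
#' carrying the attribute, plus the dataset-level percentage.  Genes in
#' the assignment but absent from the annotation table count as FALSE
#' (with a warning), so the denominator is always the cluster size.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param annotations annotation data.frame (see [readAnnotationTable()]).
#' @param attribute name of a boolean column.
#' @return list: \code{perCluster} data.frame (cluster, size, count,
#'   percent) and \code{dataset} (count, size, percent).
#' @examples
#' ann <- data.frame(gene_id = paste0("g", 1:28),
#'                   is_GPCR = rep(c(TRUE, FALSE), c(17, 11)),
#'                   has_TM = rep(c(TRUE, FALSE), c(17, 11)))
#' asg <- new("ClusterAssignment", ids = ann$gene_id,
#'            labels = rep(1L, 28), medoids = character(0),
#'            method = "manual", k = 1L, totalCost = 0,
#'            centers = matrix(numeric(0), 0, 0))
#' composition(asg, ann, "is_GPCR")$perCluster$percent  # 60.7
#' @export
composition <- function(assignment, annotations, attribute) {
  annotations <- readAnnotationTable(annotations)
  stopIfNot(attribute %in% names(annotations),
            "unknown attribute '%s'", attribute)
  flag <- stats::setNames(annotations[[attribute]], annotations$gene_id)
  v <- flag[assignment@ids]
  if (anyNA(v)) {
    warning(sprintf("%d gene(s) missing from the annotation table counted as FALSE",
                    sum(is.na(v))), call. = FALSE)
    v[is.na(v)] <- FALSE
  }
  k <- assignment@k
  size <- tabulate(assignment@labels, k)
  count <- vapply(seq_len(k), function(cl)
    sum(v[assignment@labels == cl]), integer(1))
  list(perCluster = data.frame(cluster = seq_len(k), size = size,
                               count = count,
                               percent = round(100 * count / size, 1)),
       dataset = list(count = sum(v), size = length(v),
                      percent = round(100 * sum(v) / length(v), 1)))
}

#' Multi-pathway MAPK target counts
#'
#' Counts, per gene, how many of the three MAPK pathways (MAK-1, MAK-2,
#' OS-2) list it as a target (0--3), then tabulates single, double and
#' triple targets per cluster and overall.
#'
#' @param annotations annotation data.frame with the three
#'   \code{target_*} flags.
#' @param assignment a [ClusterAssignment-class]; genes without
#'   annotation rows count as non-targets.
#' @return list: \code{perGene} (gene_id, nPathways), \code{perCluster}
#'   (cluster, single, double, triple), \code{overall} named counts.
#' @export
multiPathwayTargets <- function(annotations, assignment) {
  annotations <- readAnnotationTable(annotations)
  flags <- c("target_MAK1", "target_MAK2", "target_OS2")
  stopIfNot(all(flags %in% names(annotations)),
            "annotations must contain the three target flags: %s",
            paste(flags, collapse = ", "))
  np <- rowSums(annotations[, flags])
  np <- stats::setNames(as.integer(np), annotations$gene_id)
  v <- np[assignment@ids]
  v[is.na(v)] <- 0L
  per.cluster <- do.call(rbind, lapply(seq_len(assignment@k), function(cl) {
    x <- v[assignment@labels == cl]
    data.frame(cluster = cl, single = sum(x == 1L), double = sum(x == 2L),
               triple = sum(x == 3L))
  }))
  list(perGene = data.frame(gene_id = assignment@ids, nPathways = unname(v)),
       perCluster = per.cluster,
       overall = c(single = sum(v == 1L), double = sum(v == 2L),
                   triple = sum(v == 3L)))
}

#' Chromosome goodness-of-fit test
#'
#' Pearson chi-square test of whether the distribution of dataset genes
#' across the seven linkage groups matches the genome-wide distribution:
#' \eqn{E_i = n \cdot g_i / \sum g}, \eqn{X^2 = \sum (O_i - E_i)^2 /
#' E_i}, df = 6, upper-tail p-value.
#'
#' @param datasetCounts integer vector of length 7 (observed genes per
#'   linkage group in the dataset).
#' @param genomeCounts integer vector of length 7 (genome-wide genes per
#'   linkage group), all positive.
#' @return list: \code{statistic}, \code{df}, \code{p.value},
#'   \code{expected}.
#' @export
chromosomeGof <- function(datasetCounts, genomeCounts) {
  stopIfNot(length(datasetCounts) == 7L && length(genomeCounts) == 7L,
            "both count vectors must have length 7 (one per linkage group)")
  stopIfNot(all(genomeCounts > 0), "all genome counts must be positive")
  n <- sum(datasetCounts)
  stopIfNot(n > 0, "dataset total must be positive")
  expected <- n * genomeCounts / sum(genomeCounts)
  stopIfNot(all(expected > 0), "zero expected cell")
  x2 <- sum((datasetCounts - expected)^2 / expected)
  list(statistic = x2, df = 6L,
       p.value = stats::pchisq(x2, df = 6L, lower.tail = FALSE),
       expected = expected)
}
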