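# Generics and accessor/show methods for the core containers.

#' Gene identifiers of an object
#' @param x a phenoPAM container.
#' @return character vector of gene ids, in stable object order.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "PhenotypeTable", function(x) x@data$gene_id)

#' @rdname geneIds
#' @export
setMethod("geneIds", "DissimilarityMatrix", function(x) x@ids)

#' @rdname geneIds
#' @export
setMethod("geneIds", "ClusterAssignment", function(x) x@ids)

#' @rdname geneIds
#' @export
setMethod("geneIds", "ExpressionTimeCourse", function(x) rownames(x@values))

#' Trait schema of a phenotype table
#' @param x a [PhenotypeTable-class].
#' @return the [TraitSchema-class].
#' @export
setGeneric("traitSchema", function(x) standardGeneric("traitSchema"))

#' @rdname traitSchema
#' @export
setMethod("traitSchema", "PhenotypeTable", function(x) x@schema)

#' Completeness flags of a phenotype table
#'
#' A record is complete iff all ten traits are present (non-missing).
#' @param x a [PhenotypeTable-class].
#' @return logical vector parallel to [geneIds()].
#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))

#' @rdname isComplete
#' @export
setMethod("isComplete", "PhenotypeTable", function(x) {
  cols <- x@schema@traits$name
  stats::complete.cases(x@data[, cols, drop = FALSE])
})

#' Cluster labels of a partition
#' @param x a [ClusterAssignment-class].
#' @return named integer vector (names = gene ids), values in 1..k.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "ClusterAssignment",
          function(x) stats::setNames(x@labels, x@ids))

#' Medoid gene ids of a PAM partition
#' @param x a [ClusterAssignment-class].
#' @return character vector of medoid ids (cluster order), empty for
#'   methods without medoids.
#' @export
setGeneric("medoids", function(x) standardGeneric("medoids"))

#' @rdname medoids
#' @export
setMethod("medoids", "ClusterAssignment", function(x) x@medoids)

#' Number of rows (mutants / genes) in a container
#' @param x a phenoPAM container.
#' @export
setMethod("nrow", "PhenotypeTable", function(x) base::nrow(x@data))

#' Matrix view of a dissimilarity object
#' @param x a [DissimilarityMatrix-class].
#' @param ... ignored.
#' @export
setMethod("as.matrix", "DissimilarityMatrix", function(x, ...) x@values)

#' @rdname as.matrix-DissimilarityMatrix-method
#' @export
setMethod("as.matrix", "ExpressionTimeCourse", function(x, ...) x@values)

#' dist view of a dissimilarity object
#' @param m a [DissimilarityMatrix-class].
#' @param ... ignored.
#' @export
as.dist.DissimilarityMatrix <- function(m, ...) stats::as.dist(m@values)

setMethod("show", "TraitSchema", function(object) {
  tr <- object@traits[order(object@traits$position), ]
  cat("TraitSchema with 10 traits\n")
  for (i in seq_len(nrow(tr)))
    cat(sprintf("  %2d %-26s %-11s %s\n", tr$position[i], tr$name[i],
                tr$kind[i], tr$unit[i]))
  invisible(object)
})

setMethod("show", "PhenotypeTable", function(object) {
  n <- nrow(object@data)
  nc <- sum(isComplete(object))
  cat(sprintf("PhenotypeTable: %d mutants x 10 traits (%d complete, %d incomplete)\n",
              n, nc, n - nc))
  invisible(object)
})

setMethod("show", "DissimilarityMatrix", function(object) {
  v <- object@values[upper.tri(object@values)]
  cat(sprintf("DissimilarityMatrix: %d genes; range [%.4g, %.4g]\n",
              length(object@ids), if (length(v)) min(v) else 0,
              if (length(v)) max(v) else 0))
  invisible(object)
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %s, k = %d, n = %d, total cost = %.4f\n",
              object@method, object@k, length(object@ids), object@totalCost))
  sz <- tabulate(object@labels, object@k)
  cat(sprintf("  cluster sizes: min %d, median %g, max %d\n",
              min(sz), stats::median(sz), max(sz)))
  invisible(object)
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport: %s, k = %d\n",
              object@run$method %||% "?", nrow(object@perCluster)))
  cat(sprintf("  composite consensus: %.2f%%  composite RSD: %.2f%%\n",
              object@compositeConsensus, object@compositeRSD))
  invisible(object)
})

setMethod("show", "ExpressionTimeCourse", function(object) {
  cat(sprintf("ExpressionTimeCourse: %d genes x %d time points%s\n",
              nrow(object@values), ncol(object@values),
              if (isTRUE(object@standardized))
                sprintf(" (standardized, row SD %g)", object@targetSd) else ""))
  invisible(object)
})

setMethod("show", "ProfileMapReport", function(object) {
  s <- object@summary
  cat(sprintf("ProfileMapReport: %d clusters analyzed, %d excluded (< %d genes with expression)\n",
              nrow(object@perCluster), nrow(object@excluded), s$minGenes))
  cat(sprintf("  mean profiles/cluster: %.2f; clusters with a dominant profile: %d\n",
              s$avgProfilesPerCluster, s$nWithDominant))
  invisible(object)
})
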