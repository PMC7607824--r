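#' @import methods
NULL

#' Trait schema for a mixed phenotype table
#'
#' Describes the ten traits scored for every knockout mutant: eight
#' categorical developmental traits (positions 1--8, in the canonical
#' order conidia number/morphology, protoperithecia number/morphology,
#' perithecia number/morphology, ascospore number/morphology) followed by
#' two continuous traits (position 9, basal hyphal growth rate in mm/day;
#' position 10, aerial hyphae height in mm).  The position order fixes the
#' index of every weight vector used downstream.
#'
#' @slot traits data.frame with columns \code{name}, \code{kind}
#'   (\code{"categorical"} or \code{"continuous"}), \code{unit} and
#'   \code{position}.
#' @slot vocabulary named list; for each categorical trait, the ordered
#'   vector of permitted labels (order is also the tie-break order for
#'   consensus statistics).
#'
#' @seealso [defaultTraitSchema()]
#' @export
setClass("TraitSchema",
         representation(traits = "data.frame", vocabulary = "list"))

setValidity("TraitSchema", function(object) {
  tr <- object@traits
  msg <- character(0)
  need <- c("name", "kind", "unit", "position")
  if (!all(need %in% names(tr)))
    return(paste("traits must have columns:", paste(need, collapse = ", ")))
  if (nrow(tr) != 10L)
    msg <- c(msg, "a schema must describe exactly 10 traits")
  if (!identical(sort(tr$position), 1:10))
    msg <- c(msg, "positions must be a permutation of 1..10")
  ord <- tr[order(tr$position), ]
  if (nrow(tr) == 10L) {
    if (!all(ord$kind[1:8] == "categorical"))
      msg <- c(msg, "positions 1..8 must be categorical traits")
    if (!all(ord$kind[9:10] == "continuous"))
      msg <- c(msg, "positions 9..10 must be continuous traits")
  }
  if (anyDuplicated(tr$name))
    msg <- c(msg, "trait names must be unique")
  cat.names <- tr$name[tr$kind == "categorical"]
  if (!all(cat.names %in% names(object@vocabulary)))
    msg <- c(msg, "every categorical trait needs a vocabulary entry")
  for (nm in intersect(cat.names, names(object@vocabulary))) {
    v <- object@vocabulary[[nm]]
    if (length(v) == 0L || anyDuplicated(v) || anyNA(v))
      msg <- c(msg, sprintf("vocabulary for '%s' must be non-empty and duplicate-free", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Mixed-trait phenotype table
#'
#' One row per knockout mutant: a unique gene identifier plus the ten
#' traits of a [TraitSchema-class].  Missing observations are \code{NA};
#' a record is \emph{complete} iff all ten traits are present.  Row order
#' is stable and drives deterministic tie-breaking downstream.
#'
#' @slot schema the [TraitSchema-class] the columns conform to.
#' @slot data data.frame with column \code{gene_id} plus one column per
#'   trait, named by trait name.
#' @export
setClass("PhenotypeTable",
         representation(schema = "TraitSchema", data = "data.frame"))

setValidity("PhenotypeTable", function(object) {
  d <- object@data
  sc <- object@schema
  msg <- character(0)
  if (!"gene_id" %in% names(d)) return("data must have a 'gene_id' column")
  dup <- unique(d$gene_id[duplicated(d$gene_id)])
  if (length(dup))
    msg <- c(msg, sprintf("duplicate gene_id: %s", paste(dup, collapse = ", ")))
  missing.col <- setdiff(sc@traits$name, names(d))
  if (length(missing.col))
    return(sprintf("missing trait columns: %s", paste(missing.col, collapse = ", ")))
  for (i in seq_len(nrow(sc@traits))) {
    nm <- sc@traits$name[i]
    if (sc@traits$kind[i] == "continuous") {
      v <- d[[nm]]
      if (!is.numeric(v))
        msg <- c(msg, sprintf("trait '%s' must be numeric", nm))
      else if (any(v < 0, na.rm = TRUE))
        msg <- c(msg, sprintf("trait '%s' has negative values", nm))
    } else {
      v <- as.character(d[[nm]])
      bad <- !is.na(v) & !(v %in% sc@vocabulary[[nm]])
      if (any(bad)) {
        k <- which(bad)[1]
        msg <- c(msg, sprintf(
          "gene '%s', trait '%s': label '%s' is not in the vocabulary",
          d$gene_id[k], nm, v[k]))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Symmetric pairwise dissimilarity matrix
#'
#' Gene-by-gene dissimilarities with a zero diagonal.  Gower entries live
#' in [0, 1]; one-minus-Pearson entries in [0, 2].
#'
#' @slot ids ordered character vector of gene identifiers.
#' @slot values symmetric numeric matrix, \code{dimnames} equal to
#'   \code{ids}.
#' @export
setClass("DissimilarityMatrix",
         representation(ids = "character", values = "matrix"))

setValidity("DissimilarityMatrix", function(object) {
  v <- object@values
  n <- length(object@ids)
  msg <- character(0)
  if (!is.numeric(v) || nrow(v) != n || ncol(v) != n)
    return("values must be a numeric n x n matrix matching ids")
  if (anyDuplicated(object@ids)) msg <- c(msg, "ids must be unique")
  if (any(abs(diag(v)) > 0)) msg <- c(msg, "diagonal must be exactly 0")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12)))
    msg <- c(msg, "matrix must be symmetric")
  if (any(v < 0)) msg <- c(msg, "entries must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Partition of genes into clusters
#'
#' Result of PAM, hierarchical agglomeration or K-means.  Labels are
#' integers 1..k; every cluster is non-empty.  For PAM, \code{medoids}
#' holds the k medoid gene ids (one per cluster, each labeled with its own
#' cluster); for K-means, \code{centers} holds the centroid matrix.
#' \code{totalCost} is the summed dissimilarity (or squared Euclidean
#' distance) of each point to its medoid (centroid).
#'
#' @slot ids character, gene identifiers.
#' @slot labels integer, parallel to \code{ids}, values in 1..k.
#' @slot medoids character, length k (PAM) or 0.
#' @slot method character scalar.
#' @slot k integer scalar.
#' @slot totalCost numeric scalar.
#' @slot centers numeric matrix (K-means centroids; 0 x 0 otherwise).
#' @export
setClass("ClusterAssignment",
         representation(ids = "character", labels = "integer",
                        medoids = "character", method = "character",
                        k = "integer", totalCost = "numeric",
                        centers = "matrix"))

setValidity("ClusterAssignment", function(object) {
  msg <- character(0)
  n <- length(object@ids)
  k <- object@k
  if (length(object@labels) != n)
    return("labels must be parallel to ids")
  if (anyDuplicated(object@ids)) msg <- c(msg, "ids must be unique")
  if (n > 0) {
    if (any(is.na(object@labels)) || any(object@labels < 1L | object@labels > k))
      msg <- c(msg, "labels must lie in 1..k")
    else if (!all(seq_len(k) %in% object@labels))
      msg <- c(msg, "every cluster must be non-empty")
  }
  if (length(object@medoids)) {
    if (length(object@medoids) != k)
      msg <- c(msg, "medoids must have length k")
    else {
      pos <- match(object@medoids, object@ids)
      if (anyNA(pos))
        msg <- c(msg, "medoids must be among ids")
      else if (!identical(object@labels[pos], seq_len(k)))
        msg <- c(msg, "medoid i must be labeled with cluster i")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Cluster-quality report
#'
#' Per-cluster and run-level quality statistics: relative standard
#' deviation (per cent, continuous traits) and percent consensus (share of
#' the modal label, categorical traits).  Run-level per-trait values
#' average clusters without size weighting; the two composites are the
#' unweighted means of the continuous and the categorical per-trait
#' averages respectively.
#'
#' @slot perCluster data.frame: one row per cluster, columns \code{cluster},
#'   \code{size}, then \code{rsd_<trait>} for the two continuous traits and
#'   \code{consensus_<trait>} / \code{majority_<trait>} for each
#'   categorical trait.
#' @slot perTrait data.frame: \code{trait}, \code{kind}, \code{average}.
#' @slot compositeRSD numeric scalar (per cent).
#' @slot compositeConsensus numeric scalar (per cent).
#' @slot run list describing the run (method, k, weights label, ...).
#' @export
setClass("QualityReport",
         representation(perCluster = "data.frame", perTrait = "data.frame",
                        compositeRSD = "numeric",
                        compositeConsensus = "numeric", run = "list"))

setValidity("QualityReport", function(object) {
  msg <- character(0)
  if (object@compositeRSD < 0) msg <- c(msg, "compositeRSD must be >= 0")
  if (object@compositeConsensus <= 0 || object@compositeConsensus > 100)
    msg <- c(msg, "compositeConsensus must lie in (0, 100]")
  if (length(msg)) msg else TRUE
})

#' Expression time course
#'
#' A genes-by-time-points numeric matrix.  Once standardized, every row
#' has mean 0 and sample standard deviation \code{targetSd} (default 2)
#' to within 1e-9.
#'
#' @slot values numeric matrix, rownames = gene ids, colnames = time
#'   point labels.
#' @slot standardized logical scalar.
#' @slot targetSd numeric scalar, the row SD after standardization.
#' @export
setClass("ExpressionTimeCourse",
         representation(values = "matrix", standardized = "logical",
                        targetSd = "numeric"))

setValidity("ExpressionTimeCourse", function(object) {
  v <- object@values
  msg <- character(0)
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "rows must carry unique gene ids")
  if (is.null(colnames(v)))
    msg <- c(msg, "columns must carry time-point labels")
  if (isTRUE(object@standardized) && ncol(v) >= 2 && nrow(v) > 0) {
    m <- rowMeans(v)
    s <- apply(v, 1, stats::sd)
    if (max(abs(m)) > 1e-9 || max(abs(s - object@targetSd)) > 1e-9)
      msg <- c(msg, sprintf("standardized rows must have mean 0 and SD %g within 1e-9",
                            object@targetSd))
  }
  if (length(msg)) msg else TRUE
})

#' Expression-profile to phenotypic-cluster map
#'
#' Cross-tabulation of K-means expression profiles against phenotypic
#' clusters, with the dominance rule: a profile is dominant in a cluster
#' when it covers at least \code{dominance} (default 40\%) of the genes of
#' that cluster that have expression data.  Clusters with fewer than
#' \code{minGenes} expression-covered genes are excluded and counted
#' separately.
#'
#' @slot perCluster data.frame: \code{cluster}, \code{nGenes} (with
#'   expression data), \code{nProfiles}, \code{dominantProfile} (NA when
#'   none), \code{dominantShare}.
#' @slot excluded data.frame: clusters below the gene floor.
#' @slot crossTab integer matrix, phenotypic cluster x profile counts.
#' @slot summary list: \code{avgProfilesPerCluster}, \code{nWithDominant},
#'   \code{modalDominantProfile}, \code{modalDominantShare}, thresholds.
#' @export
setClass("ProfileMapReport",
         representation(perCluster = "data.frame", excluded = "data.frame",
                        crossTab = "matrix", summary = "list"))

setValidity("ProfileMapReport", function(object) {
  pc <- object@perCluster
  thr <- object@summary$dominance
  if (!is.null(thr) && nrow(pc)) {
    has <- !is.na(pc$dominantProfile)
    if (any(pc$dominantShare[has] < thr - 1e-12))
      return("a reported dominant profile must meet the dominance threshold")
  }
  TRUE
})
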