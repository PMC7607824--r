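# Hierarchical agglomeration on a dissimilarity matrix and seeded
# K-means on a numeric matrix.

#' Hierarchical agglomerative clustering cut at k clusters
#'
#' Lance-Williams agglomeration via [stats::hclust()] on the dissimilarity
#' matrix, cut at \code{k} clusters.  \code{"ward"} uses the ward.D2
#' convention (Ward's minimum variance on squared dissimilarities);
#' \code{"complete"} is complete-linkage HAC.  Deterministic, with hclust's
#' index-order tie handling.  The reported medoid of each cluster is the
#' member minimizing the within-cluster dissimilarity sum, and
#' \code{totalCost} is the summed dissimilarity to those medoids.
#'
#' @param d a [DissimilarityMatrix-class].
#' @param method \code{"ward"} or \code{"complete"}.
#' @param k number of clusters, 1 <= k <= n.
#' @return a [ClusterAssignment-class].
#' @export
agglomerativeCluster <- function(d, method = c("ward", "complete"), k) {
  method <- match.arg(method)
  n <- length(d@ids)
  stopIfNot(is.numeric(k) && length(k) == 1L && k == round(k) &&
              k >= 1 && k <= n,
            "parameter error: k must lie in 1..n (n = %d)", n)
  k <- as.integer(k)
  hc <- stats::hclust(stats::as.dist(d@values),
                      method = if (method == "ward") "ward.D2" else "complete")
  labels <- as.integer(stats::cutree(hc, k = k))
  meds <- vapply(seq_len(k), function(cl) {
    idx <- which(labels == cl)
    idx[which.min(rowSums(d@values[idx, idx, drop = FALSE]))]
  }, integer(1))
  cost <- sum(d@values[cbind(seq_len(n), meds[labels])])
  new("ClusterAssignment", ids = d@ids, labels = labels,
      medoids = character(0), method = method, k = k, totalCost = cost,
      centers = matrix(numeric(0), 0, 0))
}

# Draw k distinct (as rows) initial centers from x using the current RNG,
# with k-means++ seeding: the first center uniform, each next drawn with
# probability proportional to the squared distance to the nearest center
# already chosen.  Spreads the seeds over all well-separated groups.
.drawCenters <- function(x, k) {
  n <- nrow(x)
  for (try in 1:100) {
    idx <- integer(k)
    idx[1L] <- sample.int(n, 1L)
    d2 <- rowSums((x - rep(x[idx[1L], ], each = n))^2)
    for (i in seq_len(k - 1L)) {
      if (all(d2 == 0)) d2 <- rep(1, n)
      idx[i + 1L] <- sample.int(n, 1L, prob = d2)
      d2 <- pmin(d2, rowSums((x - rep(x[idx[i + 1L], ], each = n))^2))
    }
    ctr <- x[idx, , drop = FALSE]
    if (!anyDuplicated(ctr)) return(ctr)
  }
  stop("could not draw k distinct initial centers (too many duplicate rows)",
       call. = FALSE)
}

#' Seeded K-means with restarts
#'
#' Lloyd iterations ([stats::kmeans()], \code{algorithm = "Lloyd"}) from
#' seeded random initial centers drawn from the rows of \code{x} with
#' k-means++ weighting; the best of \code{restarts} runs by
#' within-cluster sum of squares is returned.
#' Fully deterministic given \code{(seed, restarts)}.  A degenerate
#' initialization (duplicate centers or an emptied cluster) is handled by
#' deterministically redrawing the initial centers from the seeded RNG
#' stream.
#'
#' @param x numeric matrix (observations in rows; rownames used as ids).
#' @param k number of clusters, 1 <= k <= nrow(x).
#' @param seed integer seed.
#' @param restarts number of random restarts (>= 1).
#' @return a [ClusterAssignment-class] with \code{centers} and
#'   \code{totalCost} = total within-cluster sum of squares.
#' @export
kmeansCluster <- function(x, k, seed, restarts = 10L) {
  stopIfNot(is.matrix(x) && is.numeric(x), "x must be a numeric matrix")
  n <- nrow(x)
  stopIfNot(is.numeric(k) && length(k) == 1L && k == round(k) &&
              k >= 1 && k <= n,
            "parameter error: k must lie in 1..n (n = %d)", n)
  stopIfNot(restarts >= 1, "restarts must be >= 1")
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(n))
  k <- as.integer(k)
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(restarts)) {
      fit <- NULL
      for (attempt in 1:100) {
        ctr <- .drawCenters(x, k)
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(x, centers = ctr, iter.max = 100L,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit) && any(fit$size == 0L)) fit <- NULL
        if (!is.null(fit)) break
      }
      stopIfNot(!is.null(fit), "k-means failed to initialize after 100 redraws")
      if (is.null(best) || fit$tot.withinss < best$tot.withinss - 1e-12)
        best <- fit
    }
  })
  new("ClusterAssignment", ids = rownames(x),
      labels = as.integer(best$cluster), medoids = character(0),
      method = "kmeans", k = k, totalCost = best$tot.withinss,
      centers = best$centers)
}

#' Write a cluster assignment to disk
#'
#' Emits a two-column CSV (\code{gene_id, cluster}) plus a JSON sidecar
#' recording method, k, medoids, total cost and any extra parameters.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param file CSV path; the sidecar replaces the extension with
#'   \code{.json}.
#' @param parameters optional named list echoed into the sidecar.
#' @return the CSV path, invisibly.
#' @export
writeAssignment <- function(assignment, file, parameters = list()) {
  utils::write.csv(
    data.frame(gene_id = assignment@ids, cluster = assignment@labels),
    file, row.names = FALSE)
  side <- sub("\\.[^.]+$", ".json", file)
  jsonlite::write_json(
    list(method = assignment@method, k = assignment@k,
         medoids = assignment@medoids, total_cost = assignment@totalCost,
         parameters = parameters),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
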