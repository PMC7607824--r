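# Deterministic Partitioning Around Medoids (BUILD + best-improvement
# SWAP) on a precomputed dissimilarity matrix.

#' Total cost of a medoid set
#'
#' Sum over all points of the dissimilarity to the nearest medoid --- the
#' objective PAM minimizes.  Shared by [pamCluster()] and the exhaustive
#' enumeration used to verify it.
#'
#' @param d a [DissimilarityMatrix-class].
#' @param medoids character vector of medoid gene ids (subset of
#'   \code{geneIds(d)}).
#' @return numeric scalar.
#' @export
totalCost <- function(d, medoids) {
  pos <- match(medoids, d@ids)
  stopIfNot(!anyNA(pos), "unknown medoid id(s): %s",
            paste(medoids[is.na(pos)], collapse = ", "))
  m <- d@values[, pos, drop = FALSE]
  sum(do.call(pmin, as.data.frame(m)))
}

# Nearest and second-nearest medoid for every point.  Returns list with
# grp (index into `med` of the nearest medoid, first-index ties), dn, ds.
.nearestTwo <- function(dm, med) {
  m <- dm[, med, drop = FALSE]
  n <- nrow(m)
  g1 <- max.col(-m, ties.method = "first")
  dn <- m[cbind(seq_len(n), g1)]
  if (length(med) == 1L) {
    ds <- rep(Inf, n)
  } else {
    m[cbind(seq_len(n), g1)] <- Inf
    g2 <- max.col(-m, ties.method = "first")
    ds <- m[cbind(seq_len(n), g2)]
  }
  list(grp = g1, dn = dn, ds = ds)
}

#' Partitioning Around Medoids on a dissimilarity matrix
#'
#' Deterministic PAM in the classic two-phase form.  BUILD: the first
#' medoid minimizes the total dissimilarity to all points; each
#' subsequent medoid maximizes the total cost reduction.  SWAP: all
#' (medoid, non-medoid) exchanges are evaluated and the single best
#' improving swap is applied, repeating until no swap improves the cost.
#' Ties are broken by the smallest index in table order, so the result is
#' reproducible across platforms.  Points are then labeled by their
#' nearest medoid (clusters numbered by ascending medoid index).
#'
#' @param d a [DissimilarityMatrix-class].
#' @param k number of clusters, 1 <= k <= n.
#' @return a [ClusterAssignment-class] with medoids and
#'   \code{totalCost = sum_i d(i, medoid(i))}.
#' @references Kaufman & Rousseeuw (1990), Finding Groups in Data.
#' @export
pamCluster <- function(d, k) {
  n <- length(d@ids)
  stopIfNot(is.numeric(k) && length(k) == 1L && k == round(k),
            "parameter error: k must be a single integer")
  stopIfNot(k >= 1 && k <= n, "parameter error: k must lie in 1..n (n = %d)", n)
  k <- as.integer(k)
  dm <- d@values

  # BUILD
  med <- which.min(colSums(dm))
  dn <- dm[, med]
  while (length(med) < k) {
    gain <- colSums(pmax(dn - dm, 0))
    gain[med] <- -Inf
    j <- which.max(gain)
    med <- c(med, j)
    dn <- pmin(dn, dm[, j])
  }

  # SWAP (best improvement, lexicographic tie-break on candidate then medoid)
  if (k < n) {
    for (iter in seq_len(10000L)) {
      nt <- .nearestTwo(dm, med)
      nonmed <- setdiff(seq_len(n), med)
      dh <- dm[, nonmed, drop = FALSE]
      a <- pmin(dh - nt$dn, 0)             # gain if j's nearest medoid stays
      b <- pmin(dh, nt$ds) - nt$dn         # change if j's nearest medoid leaves
      sum.a <- colSums(a)
      g <- matrix(0, k, ncol(dh))          # k x |nonmed|, rows = medoid slots
      rs <- rowsum(b - a, nt$grp)
      g[as.integer(rownames(rs)), ] <- rs
      tmat <- sweep(g, 2, sum.a, "+")      # tmat[m, h]: cost change of swap
      best <- min(tmat)
      if (best >= -1e-12) break
      hit <- which(tmat == best, arr.ind = TRUE)
      pick <- hit[order(hit[, 2L], hit[, 1L])[1L], ]
      med[pick[1L]] <- nonmed[pick[2L]]
    }
  }

  med <- sort(med)
  m <- dm[, med, drop = FALSE]
  labels <- max.col(-m, ties.method = "first")
  labels[med] <- seq_len(k)   # a medoid always anchors its own cluster
  cost <- sum(m[cbind(seq_len(n), labels)])
  new("ClusterAssignment", ids = d@ids, labels = as.integer(labels),
      medoids = d@ids[med], method = "pam", k = k, totalCost = cost,
      centers = matrix(numeric(0), 0, 0))
}
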