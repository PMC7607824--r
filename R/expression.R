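# Expression time-course profiling: row standardization, K-means
# profiles, cluster-count diagnostics (within-SS, gap statistic,
# Davies-Bouldin) and the dominant-profile map onto phenotypic clusters.

#' Construct an expression time course
#'
#' @param values numeric matrix, genes in rows (unique rownames), time
#'   points in columns (colnames; defaults to \code{t1..tT}).
#' @param standardized logical; set by [standardizeRows()].
#' @param targetSd row SD after standardization.
#' @return an [ExpressionTimeCourse-class].
#' @export
expressionTimeCourse <- function(values, standardized = FALSE, targetSd = 2) {
  stopIfNot(is.matrix(values) && is.numeric(values),
            "values must be a numeric matrix")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("t", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  new("ExpressionTimeCourse", values = values, standardized = standardized,
      targetSd = targetSd)
}

#' Read an expression matrix from CSV/TSV
#'
#' Genes in rows, time points in columns, first column the gene id.
#'
#' @param file path; separator inferred from the extension (tab for
#'   \code{.tsv}/\code{.txt}) unless given.
#' @param sep field separator override.
#' @return an [ExpressionTimeCourse-class] (not standardized).
#' @export
readExpressionMatrix <- function(file, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", file, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE, quote = "\"")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  expressionTimeCourse(m)
}

#' Standardize each gene's time course
#'
#' Linearly transforms every row to mean 0 and sample standard deviation
#' \code{targetSd} (default 2), giving comparable relative expression per
#' gene.  Constant rows have no shape and are dropped with a warning.
#' Idempotent on already-standardized input.
#'
#' @param expr an [ExpressionTimeCourse-class] with >= 2 time points.
#' @param targetSd target row SD (default 2).
#' @return a standardized [ExpressionTimeCourse-class].
#' @examples
#' e <- expressionTimeCourse(rbind(g1 = c(1, 2, 3)))
#' as.matrix(standardizeRows(e))   # -2 0 2
#' @export
standardizeRows <- function(expr, targetSd = 2) {
  v <- expr@values
  stopIfNot(ncol(v) >= 2L, "standardization needs >= 2 time points")
  s <- apply(v, 1, stats::sd)
  flat <- s == 0
  if (any(flat)) {
    warning(sprintf("dropping %d constant row(s): %s", sum(flat),
                    paste(utils::head(rownames(v)[flat], 10), collapse = ", ")),
            call. = FALSE)
    v <- v[!flat, , drop = FALSE]
    s <- s[!flat]
  }
  out <- (v - rowMeans(v)) / s * targetSd
  expressionTimeCourse(out, standardized = TRUE, targetSd = targetSd)
}

#' K-means expression profiles
#'
#' Partitions standardized time courses into \code{k} expression profiles
#' via [kmeansCluster()]; the per-profile centroid curves are stored in
#' \code{centers} for reporting.
#'
#' @param expr a standardized [ExpressionTimeCourse-class].
#' @param k number of profiles.
#' @param seed integer seed.
#' @param restarts random restarts (default 10).
#' @return a [ClusterAssignment-class] (method \code{"kmeans"}).
#' @export
kmeansProfiles <- function(expr, k, seed, restarts = 10L) {
  stopIfNot(isTRUE(expr@standardized),
            "kmeansProfiles requires a standardized matrix; run standardizeRows() first")
  fit <- kmeansCluster(expr@values, k, seed, restarts)
  fit@method <- "kmeans"
  fit
}

# Davies-Bouldin index from a fitted partition.
.daviesBouldin <- function(x, labels, centers) {
  k <- nrow(centers)
  if (k < 2L) return(NA_real_)
  s <- vapply(seq_len(k), function(cl) {
    rows <- x[labels == cl, , drop = FALSE]
    mean(sqrt(rowSums((rows - rep(centers[cl, ], each = nrow(rows)))^2)))
  }, numeric(1))
  m <- as.matrix(stats::dist(centers))
  r <- outer(s, s, "+") / m
  diag(r) <- -Inf
  mean(apply(r, 1, max))
}

#' Cluster-count diagnostics for expression profiling
#'
#' For every k in \code{kRange}, fits seeded K-means and reports three
#' complementary quality measures: the within-cluster sum of squares, the
#' gap statistic (observed log within-SS against \code{B} uniform
#' reference datasets sampled within the per-time-point ranges, with its
#' standard error) and the Davies-Bouldin index.  Recommendations: the
#' gap rule picks the smallest k with \code{gap(k) >= gap(k+1) -
#' SE(k+1)}; Davies-Bouldin picks the argmin; the within-SS elbow is left
#' to the user.
#'
#' @param expr a standardized [ExpressionTimeCourse-class].
#' @param kRange integer vector within [2, n-1].
#' @param B number of gap-statistic reference datasets (default 50).
#' @param seed integer seed governing fits and reference sampling.
#' @param restarts K-means restarts per fit (default 10).
#' @return list: \code{table} (data.frame with k, withinSS, gap, gapSE,
#'   daviesBouldin), \code{gapK}, \code{dbK}.
#' @export
kDiagnostics <- function(expr, kRange, B = 50L, seed, restarts = 10L) {
  stopIfNot(isTRUE(expr@standardized),
            "kDiagnostics requires a standardized matrix")
  x <- expr@values
  n <- nrow(x)
  stopIfNot(all(kRange >= 2L & kRange <= n - 1L),
            "kRange must lie within [2, n-1] (n = %d)", n)
  kRange <- as.integer(sort(kRange))
  all.seeds <- subSeeds(seed, length(kRange) * (B + 1L) + 1L)
  ref.seed <- all.seeds[1L]
  seeds <- matrix(all.seeds[-1L], nrow = length(kRange))
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  refs <- withSeed(ref.seed, lapply(seq_len(B), function(b) {
    m <- vapply(seq_along(lo), function(j) stats::runif(n, lo[j], hi[j]),
                numeric(n))
    rownames(m) <- rownames(x)
    m
  }))
  rows <- lapply(seq_along(kRange), function(i) {
    k <- kRange[i]
    fit <- kmeansCluster(x, k, seeds[i, 1L], restarts)
    w <- fit@totalCost
    logw.ref <- vapply(seq_len(B), function(b)
      log(kmeansCluster(refs[[b]], k, seeds[i, b + 1L], restarts)@totalCost),
      numeric(1))
    data.frame(k = k, withinSS = w,
               gap = mean(logw.ref) - log(w),
               gapSE = stats::sd(logw.ref) * sqrt(1 + 1 / B),
               daviesBouldin = .daviesBouldin(x, fit@labels, fit@centers))
  })
  tab <- do.call(rbind, rows)
  gap.k <- NA_integer_
  if (nrow(tab) >= 2L) {
    ok <- which(tab$gap[-nrow(tab)] >=
                  tab$gap[-1L] - tab$gapSE[-1L])
    if (length(ok)) gap.k <- tab$k[ok[1L]]
  }
  list(table = tab, gapK = gap.k, dbK = tab$k[which.min(tab$daviesBouldin)])
}

#' Map expression profiles onto phenotypic clusters
#'
#' Intersects the two gene universes, cross-tabulates expression profiles
#' against phenotypic clusters and applies the dominance rule: a profile
#' is dominant in a cluster when it covers at least \code{dominance}
#' (default 0.40, i.e. 40 per cent) of that cluster's expression-covered
#' genes.  Phenotypic clusters with fewer than \code{minGenes} covered
#' genes are excluded from the analysis and listed separately.
#'
#' @param pheno phenotypic [ClusterAssignment-class].
#' @param profiles expression-profile [ClusterAssignment-class].
#' @param minGenes minimum expression-covered genes per analyzed cluster
#'   (default 3).
#' @param dominance dominance threshold as a fraction (default 0.40).
#' @return a [ProfileMapReport-class].
#' @export
mapProfiles <- function(pheno, profiles, minGenes = 3L, dominance = 0.40) {
  common <- intersect(pheno@ids, profiles@ids)
  stopIfNot(length(common) > 0L,
            "empty intersection between phenotype and expression gene ids")
  n.unmatched <- length(pheno@ids) - length(common)
  pl <- clusterLabels(pheno)[common]
  el <- clusterLabels(profiles)[common]
  cross <- table(factor(pl, levels = seq_len(pheno@k)),
                 factor(el, levels = seq_len(profiles@k)))
  cross <- unclass(cross)
  dimnames(cross) <- list(cluster = rownames(cross), profile = colnames(cross))
  covered <- rowSums(cross)
  analyzed <- covered >= minGenes
  per <- lapply(which(analyzed), function(cl) {
    cnt <- cross[cl, ]
    share <- cnt / covered[cl]
    top <- which.max(share)   # ties: smallest profile id
    data.frame(cluster = cl, nGenes = covered[cl],
               nProfiles = sum(cnt > 0),
               dominantProfile = if (share[top] >= dominance)
                 as.integer(top) else NA_integer_,
               dominantShare = unname(share[top]))
  })
  per <- if (length(per)) do.call(rbind, per)
         else data.frame(cluster = integer(0), nGenes = integer(0),
                         nProfiles = integer(0),
                         dominantProfile = integer(0),
                         dominantShare = numeric(0))
  rownames(per) <- NULL
  excluded <- data.frame(cluster = which(!analyzed),
                         nGenes = unname(covered[!analyzed]))
  dom <- per$dominantProfile[!is.na(per$dominantProfile)]
  modal <- if (length(dom)) modalLabel(as.character(dom)) else NULL
  summ <- list(
    avgProfilesPerCluster = if (nrow(per)) mean(per$nProfiles) else NA_real_,
    nWithDominant = length(dom),
    modalDominantProfile = if (length(dom)) as.integer(modal$label) else NA_integer_,
    modalDominantShare = if (length(dom)) modal$count / length(dom) else NA_real_,
    minGenes = as.integer(minGenes), dominance = dominance,
    nUnmatchedPhenotypeGenes = n.unmatched)
  new("ProfileMapReport", perCluster = per, excluded = excluded,
      crossTab = cross, summary = summ)
}
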