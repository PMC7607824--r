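# Pairwise dissimilarities: weighted Gower for the mixed table, one minus
# Pearson correlation for the converted numeric pipeline.

.WEIGHT_PRESETS <- list(
  NoWeight = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
  W1 = c(1, 1, 1, 1, 1, 1, 1, 1, 2, 2),
  W2 = c(1, 0.5, 1, 0.5, 1, 0.5, 1, 0.5, 2, 2),
  W3 = c(2, 2, 1, 1, 1, 1, 1, 1, 6, 2),
  W4 = c(0.5, 0.5, 1, 1, 1, 1, 1, 1, 6, 5),
  W5 = c(1, 1, 1, 1, 1, 1, 1, 1, 6, 4),
  W6 = c(1, 1, 1, 1, 1, 1, 1, 1, 6, 6))

#' Named trait-weight presets
#'
#' The seven weight vectors explored in the weight-by-k selection scan,
#' indexed by schema position (eight categorical traits, then growth rate
#' and aerial height): NoWeight = all ones; W1 = (1,1,1,1,1,1,1,1,2,2);
#' W2 = (1,0.5,1,0.5,1,0.5,1,0.5,2,2); W3 = (2,2,1,1,1,1,1,1,6,2);
#' W4 = (0.5,0.5,1,1,1,1,1,1,6,5); W5 = (1,1,1,1,1,1,1,1,6,4);
#' W6 = (1,1,1,1,1,1,1,1,6,6).  W6 up-weights both continuous traits
#' six-fold and is the preset that selected the production clustering.
#'
#' @param name preset name; omit to get the full named list.
#' @return numeric weight vector of length 10 (or the list of all presets).
#' @examples
#' weightPreset("W6")
#' @export
weightPreset <- function(name) {
  if (missing(name)) return(.WEIGHT_PRESETS)
  stopIfNot(name %in% names(.WEIGHT_PRESETS),
            "unknown weight preset '%s' (have: %s)", name,
            paste(names(.WEIGHT_PRESETS), collapse = ", "))
  .WEIGHT_PRESETS[[name]]
}

.resolveWeights <- function(weights) {
  if (is.character(weights) && length(weights) == 1L)
    weights <- weightPreset(weights)
  stopIfNot(is.numeric(weights) && length(weights) == 10L,
            "weights must be a numeric vector of length 10 or a preset name")
  stopIfNot(all(weights >= 0), "weights must be non-negative")
  stopIfNot(sum(weights) > 0, "at least one weight must be positive")
  weights
}

#' Weighted Gower dissimilarity matrix for a mixed phenotype table
#'
#' For mutants i and j, \eqn{d(i,j) = \sum_t w_t \delta_t(i,j) / \sum_t
#' w_t}, where for a continuous trait \eqn{\delta_t = |x_i - x_j| /
#' range_t} (range taken over the analyzed table) and for a categorical
#' trait \eqn{\delta_t} is the 0/1 match/mismatch indicator (labels are
#' treated as nominal).  Weights are indexed by schema position; scaling
#' all weights by a constant leaves the matrix unchanged.  A continuous
#' trait with zero range contributes 0 to every pair, with a warning.
#'
#' @param table a complete [PhenotypeTable-class].
#' @param weights numeric vector of length 10 (schema-position order) or
#'   a preset name for [weightPreset()].
#' @return a [DissimilarityMatrix-class] with entries in [0, 1].
#' @examples
#' sim <- simulatePhenotypes(phenotypeSimConfig(
#'   nClusters = 2, sizes = c(3, 3), seed = 1))
#' gowerMatrix(sim$table, "W6")
#' @export
gowerMatrix <- function(table, weights = "NoWeight") {
  w <- .resolveWeights(weights)
  stopIfNot(all(isComplete(table)),
            "gowerMatrix requires a complete table; run filterComplete() first")
  sc <- table@schema
  d <- table@data
  n <- nrow(d)
  ord <- order(sc@traits$position)
  acc <- matrix(0, n, n)
  for (pos in 1:10) {
    tr <- sc@traits[ord[pos], ]
    if (w[pos] == 0) next
    v <- d[[tr$name]]
    if (tr$kind == "continuous") {
      rng <- diff(range(v))
      if (rng == 0) {
        warning(sprintf("continuous trait '%s' has zero range; it contributes 0",
                        tr$name), call. = FALSE)
        next
      }
      delta <- abs(outer(v, v, "-")) / rng
    } else {
      delta <- outer(v, v, "!=") * 1
    }
    acc <- acc + w[pos] * delta
  }
  vals <- acc / sum(w)
  vals <- (vals + t(vals)) / 2
  diag(vals) <- 0
  dimnames(vals) <- list(d$gene_id, d$gene_id)
  new("DissimilarityMatrix", ids = d$gene_id, values = vals)
}

#' One-minus-Pearson distance matrix for a numeric matrix
#'
#' \eqn{d(i,j) = 1 - r(x_i, x_j)} between rows, in [0, 2].  A row with
#' zero variance has no defined correlation and aborts with the offending
#' gene ids.
#'
#' @param x numeric matrix with at least two columns; rownames are gene
#'   ids (row indices are used if absent).
#' @return a [DissimilarityMatrix-class].
#' @export
pearsonDistanceMatrix <- function(x) {
  stopIfNot(is.matrix(x) && is.numeric(x), "x must be a numeric matrix")
  stopIfNot(ncol(x) >= 2L, "pearsonDistanceMatrix needs >= 2 columns")
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  sds <- apply(x, 1, stats::sd)
  flat <- rownames(x)[sds == 0]
  stopIfNot(length(flat) == 0L,
            "zero-variance row(s): correlation undefined for %s",
            paste(flat, collapse = ", "))
  vals <- 1 - stats::cor(t(x))
  vals <- pmax((vals + t(vals)) / 2, 0)
  diag(vals) <- 0
  new("DissimilarityMatrix", ids = rownames(x), values = vals)
}

#' Write / read a dissimilarity matrix as square CSV
#'
#' Gene ids appear as both row and column headers; round-trips exactly at
#' full double precision.
#'
#' @param d a [DissimilarityMatrix-class].
#' @param file path.
#' @return the path (write) or a [DissimilarityMatrix-class] (read).
#' @export
writeDissimilarity <- function(d, file) {
  df <- data.frame(gene_id = d@ids,
                   format(d@values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeDissimilarity
#' @export
readDissimilarity <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, colClasses = "character")
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(ids, ids)
  diag(vals) <- 0
  vals <- (vals + t(vals)) / 2
  new("DissimilarityMatrix", ids = ids, values = vals)
}
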