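# Shared fixtures: all built in code at test time.

# A complete wild-type-like record; override any trait by name.
baseRecord <- function(gene_id, ...) {
  rec <- list(gene_id = gene_id,
              conidia_number = "Normal", conidia_morphology = "Normal",
              protoperithecia_number = "Normal",
              protoperithecia_morphology = "Normal",
              perithecia_number = "Normal", perithecia_morphology = "Normal",
              ascospore_number = "Normal", ascospore_morphology = "Normal",
              growth_rate = 80, aerial_height = 37)
  over <- list(...)
  rec[names(over)] <- over
  as.data.frame(rec, stringsAsFactors = FALSE)
}

makeTable <- function(...) {
  phenotypeTable(do.call(rbind, list(...)))
}

# Dissimilarity matrix from points on the line, absolute difference.
lineDiss <- function(x, ids = paste0("g", seq_along(x))) {
  m <- abs(outer(x, x, "-"))
  dimnames(m) <- list(ids, ids)
  new("DissimilarityMatrix", ids = ids, values = m)
}

# Brute-force PAM oracle: enumerate every k-subset of medoids.
bruteForcePam <- function(d, k) {
  ids <- geneIds(d)
  combs <- utils::combn(length(ids), k)
  costs <- apply(combs, 2, function(s) totalCost(d, ids[s]))
  best <- which(costs <= min(costs) + 1e-12)
  list(cost = min(costs),
       medoidSets = lapply(best, function(j) combs[, j]))
}

# Partition induced by a medoid set (nearest medoid, first-index ties).
medoidPartition <- function(d, medoidIdx) {
  m <- as.matrix(d)[, medoidIdx, drop = FALSE]
  max.col(-m, ties.method = "first")
}

# Adjusted Rand index between two label vectors.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Scalar-by-scalar weighted Gower oracle, independent of gowerMatrix().
gowerOracle <- function(table, w) {
  sc <- traitSchema(table)
  d <- table@data
  ord <- order(sc@traits$position)
  n <- nrow(d)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0
    for (pos in 1:10) {
      tr <- sc@traits[ord[pos], ]
      v <- d[[tr$name]]
      delta <- if (tr$kind == "continuous") {
        rng <- max(v) - min(v)
        if (rng == 0) 0 else abs(v[i] - v[j]) / rng
      } else as.numeric(v[i] != v[j])
      num <- num + w[pos] * delta
    }
    out[i, j] <- num / sum(w)
  }
  dimnames(out) <- list(d$gene_id, d$gene_id)
  out
}

# Manual ClusterAssignment for composition-style tests.
manualAssignment <- function(ids, labels) {
  new("ClusterAssignment", ids = ids, labels = as.integer(labels),
      medoids = character(0), method = "manual",
      k = max(as.integer(labels)), totalCost = 0,
      centers = matrix(numeric(0), 0, 0))
}
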