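# Seeded synthetic-data generators with planted structure: phenotype
# tables, expression time courses and annotation tables.  All generators
# are pure functions of (config, seed).

.TABLE2_SIZES <- c(28, 10, 171, 82, 73, 23, 130, 38, 82, 8, 8, 8, 12, 9,
                   77, 21, 12, 8, 25, 19, 42, 32, 11, 13, 11, 15, 15, 15,
                   9, 7, 36, 9, 6, 12, 10, 33, 13, 9, 5, 21)

#' Configuration for the phenotype-table generator
#'
#' Defines the planted cluster structure: per-cluster archetypes for the
#' two continuous traits (mean and SD, SD defaulting to
#' \code{continuousSdFrac} times the mean) and, for each categorical
#' trait, a modal label reproduced with probability \code{consensus}
#' (otherwise a uniform draw over the remaining vocabulary).  Default
#' archetypes place the clusters on a growth-rate-by-aerial-height grid
#' spanning realistic ranges (20--90 mm/day, 5--50 mm) and cycle the
#' modal labels through each trait's vocabulary, so both continuous and
#' categorical traits carry cluster signal.
#'
#' @param nClusters number of planted clusters.
#' @param sizes integer vector of cluster sizes (length nClusters).
#' @param consensus modal-label probability; scalar or nClusters x 8
#'   matrix.  Must exceed 1/|vocabulary| for every trait.
#' @param continuousSdFrac per-cluster SD as a fraction of the mean
#'   (default 0.05); ignored when \code{continuousSds} is given.
#' @param continuousMeans optional nClusters x 2 matrix (growth, aerial).
#' @param continuousSds optional nClusters x 2 matrix of SDs (>= 0).
#' @param modalLabels optional nClusters x 8 character matrix of modal
#'   labels (columns in schema position order 1..8).
#' @param missingRate per-cell missingness probability (default 0).
#' @param nIncomplete alternatively, exact number of records to receive
#'   one missing cell each (overrides missingRate).
#' @param schema a [TraitSchema-class].
#' @param seed integer seed.
#' @return a validated config (list, class \code{"PhenotypeSimConfig"}).
#' @seealso [simulatePhenotypes()], [publishedCohortConfig()]
#' @export
phenotypeSimConfig <- function(nClusters, sizes, consensus = 0.95,
                               continuousSdFrac = 0.05,
                               continuousMeans = NULL, continuousSds = NULL,
                               modalLabels = NULL, missingRate = 0,
                               nIncomplete = 0L,
                               schema = defaultTraitSchema(), seed) {
  k <- as.integer(nClusters)
  stopIfNot(k >= 1L, "nClusters must be >= 1")
  sizes <- as.integer(sizes)
  stopIfNot(length(sizes) == k && all(sizes >= 1L),
            "sizes must give a positive size for each of the %d clusters", k)
  ord <- order(schema@traits$position)
  cat.names <- schema@traits$name[ord][1:8]
  if (is.null(continuousMeans)) {
    ng <- ceiling(sqrt(k))
    na <- ceiling(k / ng)
    g <- seq(20, 90, length.out = ng)
    a <- seq(5, 50, length.out = na)
    idx <- seq_len(k) - 1L
    continuousMeans <- cbind(growth = g[idx %% ng + 1L],
                             aerial = a[idx %/% ng + 1L])
  }
  continuousMeans <- matrix(as.numeric(continuousMeans), k, 2L)
  if (is.null(continuousSds))
    continuousSds <- continuousSdFrac * continuousMeans
  continuousSds <- matrix(as.numeric(continuousSds), k, 2L)
  stopIfNot(all(continuousSds >= 0), "continuous SDs must be >= 0")
  if (is.null(modalLabels)) {
    modalLabels <- vapply(seq_along(cat.names), function(t) {
      v <- schema@vocabulary[[cat.names[t]]]
      v[(seq_len(k) - 1L + t) %% length(v) + 1L]
    }, character(k))
    modalLabels <- matrix(modalLabels, k, 8L)
  }
  modalLabels <- matrix(as.character(modalLabels), k, 8L,
                        dimnames = list(NULL, cat.names))
  if (length(consensus) == 1L) consensus <- matrix(consensus, k, 8L)
  consensus <- matrix(as.numeric(consensus), k, 8L)
  for (t in seq_along(cat.names)) {
    v <- schema@vocabulary[[cat.names[t]]]
    stopIfNot(all(modalLabels[, t] %in% v),
              "modal label outside the vocabulary of '%s'", cat.names[t])
    stopIfNot(all(consensus[, t] > 1 / length(v) & consensus[, t] <= 1),
              "consensus for '%s' must lie in (1/|vocab|, 1]", cat.names[t])
  }
  stopIfNot(missingRate >= 0 && missingRate < 1, "missingRate must be in [0, 1)")
  nIncomplete <- as.integer(nIncomplete)
  stopIfNot(nIncomplete >= 0L && nIncomplete <= sum(sizes),
            "nIncomplete must be in [0, n]")
  structure(list(nClusters = k, sizes = sizes, consensus = consensus,
                 continuousMeans = continuousMeans,
                 continuousSds = continuousSds, modalLabels = modalLabels,
                 missingRate = missingRate, nIncomplete = nIncomplete,
                 schema = schema, seed = as.integer(seed)),
            class = "PhenotypeSimConfig")
}

#' Published-cohort-style simulation config
#'
#' The bundled configuration mimicking the marginal structure of the real
#' knockout cohort: 1168 mutants in 40 clusters whose sizes are the
#' published per-cluster gene counts (range 5--171, mean 29.2, median
#' 14), categorical consensus probability 0.95 and continuous SD equal to
#' 5 per cent of each cluster's mean.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [phenotypeSimConfig()].
#' @return a \code{"PhenotypeSimConfig"}.
#' @export
publishedCohortConfig <- function(seed, ...) {
  phenotypeSimConfig(nClusters = 40L, sizes = .TABLE2_SIZES,
                     consensus = 0.95, continuousSdFrac = 0.05,
                     seed = seed, ...)
}

#' Generate a phenotype table with planted clusters
#'
#' Continuous values are drawn from the per-cluster normal (clipped at 0,
#' growth and height being physical quantities); each categorical value
#' is the cluster's modal label with its consensus probability, otherwise
#' uniform over the remaining vocabulary.  Record order is a seeded
#' permutation of the cluster blocks; missingness is applied last.
#' Deterministic for a given config (the seed lives in the config).
#'
#' @param config a \code{"PhenotypeSimConfig"} from [phenotypeSimConfig()].
#' @return list: \code{table} (a [PhenotypeTable-class]), \code{labels}
#'   (named integer vector of true clusters, in table order).
#' @export
simulatePhenotypes <- function(config) {
  stopIfNot(inherits(config, "PhenotypeSimConfig"),
            "config must come from phenotypeSimConfig()")
  sc <- config$schema
  ord <- order(sc@traits$position)
  cat.names <- sc@traits$name[ord][1:8]
  cont.names <- sc@traits$name[ord][9:10]
  n <- sum(config$sizes)
  truth <- rep.int(seq_len(config$nClusters), config$sizes)
  withSeed(config$seed, {
    d <- data.frame(gene_id = sprintf("NCU%05d", seq_len(n)),
                    stringsAsFactors = FALSE)
    for (t in 1:8) {
      nm <- cat.names[t]
      v <- sc@vocabulary[[nm]]
      modal <- config$modalLabels[truth, t]
      p <- config$consensus[truth, t]
      take.modal <- stats::runif(n) < p
      val <- modal
      flip <- which(!take.modal)
      if (length(flip))
        val[flip] <- vapply(flip, function(i)
          sample(setdiff(v, modal[i]), 1L), character(1))
      d[[nm]] <- val
    }
    for (j in 1:2) {
      nm <- cont.names[j]
      d[[nm]] <- pmax(stats::rnorm(n, config$continuousMeans[truth, j],
                                   config$continuousSds[truth, j]), 0)
    }
    perm <- sample.int(n)
    d <- d[perm, , drop = FALSE]
    truth <- truth[perm]
    trait.cols <- sc@traits$name
    if (config$nIncomplete > 0L) {
      rows <- sample.int(n, config$nIncomplete)
      cols <- sample(trait.cols, config$nIncomplete, replace = TRUE)
      for (i in seq_along(rows)) d[rows[i], cols[i]] <- NA
    } else if (config$missingRate > 0) {
      for (nm in trait.cols) {
        hit <- stats::runif(n) < config$missingRate
        d[[nm]][hit] <- NA
      }
    }
  })
  rownames(d) <- NULL
  list(table = phenotypeTable(d, sc),
       labels = stats::setNames(truth, d$gene_id))
}

#' Default expression-profile templates
#'
#' \code{nProfiles} (2--8) distinct curve shapes over \code{nTimePoints}
#' samples of the unit interval --- monotone rise, monotone fall,
#' mid-course peak, one-cycle cosine, one-cycle sine, mid-course valley,
#' late peak and early peak --- each scaled to mean 0 and sample SD 2
#' (the standardized expression scale).  The shapes are ordered so that
#' every prefix of the list is mutually well separated, keeping planted
#' cluster numbers identifiable by the k diagnostics.
#'
#' @param nProfiles number of templates (2--8).
#' @param nTimePoints number of time points (>= 4).
#' @return numeric matrix, profiles x time points.
#' @export
defaultProfileTemplates <- function(nProfiles, nTimePoints) {
  stopIfNot(nProfiles >= 2L && nProfiles <= 8L, "nProfiles must be in 2..8")
  stopIfNot(nTimePoints >= 4L, "nTimePoints must be >= 4")
  t <- seq(0, 1, length.out = nTimePoints)
  shapes <- list(
    rising = t,
    falling = 1 - t,
    mid_peak = exp(-((t - 0.5) / 0.12)^2),
    cycle_cos = cos(2 * pi * t),
    cycle_sin = sin(2 * pi * t),
    mid_valley = -exp(-((t - 0.5) / 0.12)^2),
    late_peak = exp(-((t - 0.92) / 0.10)^2),
    early_peak = exp(-((t - 0.08) / 0.10)^2))
  m <- do.call(rbind, shapes[seq_len(nProfiles)])
  m <- (m - rowMeans(m)) / apply(m, 1, stats::sd) * 2
  colnames(m) <- paste0("t", seq_len(nTimePoints))
  m
}

#' Configuration for the expression-time-course generator
#'
#' @param templates profiles x time-points matrix of mean curves
#'   (default [defaultProfileTemplates()]); pairwise correlations must
#'   stay below 0.9 so the planted profiles are distinct.
#' @param genesPerProfile integer vector (recycled) of genes per profile.
#' @param noiseSd SD of the i.i.d. normal noise added to each curve.
#' @param nProfiles,nTimePoints used when \code{templates} is NULL.
#' @param seed integer seed.
#' @return a validated config (list, class \code{"ExpressionSimConfig"}).
#' @export
expressionSimConfig <- function(templates = NULL, genesPerProfile,
                                noiseSd = 0.25, nProfiles = 6L,
                                nTimePoints = 8L, seed) {
  if (is.null(templates))
    templates <- defaultProfileTemplates(nProfiles, nTimePoints)
  stopIfNot(is.matrix(templates) && nrow(templates) >= 2L,
            "templates must be a matrix with >= 2 profiles")
  cc <- stats::cor(t(templates))
  stopIfNot(max(cc[upper.tri(cc)]) < 0.9,
            "templates are not distinct (pairwise correlation >= 0.9)")
  genesPerProfile <- rep_len(as.integer(genesPerProfile), nrow(templates))
  stopIfNot(all(genesPerProfile >= 1L), "genesPerProfile must be >= 1")
  stopIfNot(noiseSd >= 0, "noiseSd must be >= 0")
  structure(list(templates = templates, genesPerProfile = genesPerProfile,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "ExpressionSimConfig")
}

#' Generate an expression time course with planted profiles
#'
#' Each gene's curve is its profile template plus i.i.d. normal noise.
#'
#' @param config an \code{"ExpressionSimConfig"}.
#' @return list: \code{expr} (an [ExpressionTimeCourse-class], not
#'   standardized), \code{labels} (named integer vector of true
#'   profiles).
#' @export
simulateExpression <- function(config) {
  stopIfNot(inherits(config, "ExpressionSimConfig"),
            "config must come from expressionSimConfig()")
  truth <- rep.int(seq_len(nrow(config$templates)), config$genesPerProfile)
  n <- length(truth)
  tp <- ncol(config$templates)
  m <- withSeed(config$seed,
    config$templates[truth, , drop = FALSE] +
      matrix(stats::rnorm(n * tp, sd = config$noiseSd), n, tp))
  rownames(m) <- sprintf("NCU%05d", seq_len(n))
  colnames(m) <- colnames(config$templates)
  list(expr = expressionTimeCourse(m),
       labels = stats::setNames(truth, rownames(m)))
}

#' Generate an annotation table conditioned on planted clusters
#'
#' Boolean attributes are Bernoulli draws whose probability depends on
#' the gene's cluster (per-cluster enrichment); \code{has_TM} is forced
#' TRUE wherever \code{is_GPCR} is TRUE.  Linkage groups are a
#' multinomial draw with the supplied genome proportions.
#'
#' @param labels named integer vector of cluster labels (names = gene
#'   ids), as returned by [simulatePhenotypes()].
#' @param enrichment named list: attribute name -> per-cluster
#'   probability vector (scalars are recycled over clusters).
#' @param genomeProportions length-7 positive vector of linkage-group
#'   proportions (default mildly uneven, chromosome-1-heavy).
#' @param seed integer seed.
#' @return annotation data.frame (see [readAnnotationTable()]).
#' @export
simulateAnnotations <- function(labels, enrichment,
                                genomeProportions = c(0.20, 0.15, 0.15,
                                                      0.14, 0.13, 0.12,
                                                      0.11),
                                seed) {
  stopIfNot(!is.null(names(labels)), "labels must be named by gene id")
  stopIfNot(length(genomeProportions) == 7L && all(genomeProportions > 0),
            "genomeProportions must be 7 positive numbers")
  k <- max(labels)
  n <- length(labels)
  stopIfNot(is.list(enrichment) && !is.null(names(enrichment)),
            "enrichment must be a named list")
  bad <- setdiff(names(enrichment), .ANNOTATION_FLAGS)
  stopIfNot(length(bad) == 0L, "unknown attribute(s): %s",
            paste(bad, collapse = ", "))
  withSeed(seed, {
    df <- data.frame(gene_id = names(labels), stringsAsFactors = FALSE)
    for (nm in names(enrichment)) {
      p <- rep_len(as.numeric(enrichment[[nm]]), k)
      stopIfNot(all(p >= 0 & p <= 1),
                "enrichment probabilities for '%s' must lie in [0, 1]", nm)
      df[[nm]] <- stats::runif(n) < p[labels]
    }
    if (all(c("is_GPCR", "has_TM") %in% names(df)))
      df$has_TM <- df$has_TM | df$is_GPCR
    df$linkage_group <- sample.int(7L, n, replace = TRUE,
                                   prob = genomeProportions / sum(genomeProportions))
    rownames(df) <- NULL
    readAnnotationTable(df)
  })
}
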