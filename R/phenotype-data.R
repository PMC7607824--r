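# Phenotype table model: schema, I/O, completeness filtering, continuous
# binning, ordinal conversion and global phenotype classification.

.ABUNDANCE_VOCAB <- c("Not Formed", "Severely Reduced", "Reduced",
                      "Slightly Reduced", "Normal", "Increased")
.MORPHOLOGY_VOCAB <- c("Not Formed", "Abnormal", "Normal")
.NORMAL_BINS <- c("Normal Low", "Normal Average", "Normal High")
.BIN_LEVELS <- c("Severely Reduced", "Reduced", "Slightly Reduced",
                 "Normal Low", "Normal Average", "Normal High", "Increased")

#' Default ten-trait schema
#'
#' The canonical schema for the knockout phenotype table: eight categorical
#' developmental traits in the standard column order (conidia
#' number/morphology, protoperithecia number/morphology, perithecia
#' number/morphology, ascospore number/morphology) followed by the two
#' continuous traits, basal hyphal growth rate (mm/day) and aerial hyphae
#' height (mm).  Abundance ("number") traits use the six-level severity
#' vocabulary Not Formed < Severely Reduced < Reduced < Slightly Reduced <
#' Normal < Increased; morphology traits use Not Formed / Abnormal /
#' Normal (perithecia morphology additionally admits "Abnormal Beaks").
#' Vocabulary order doubles as the deterministic tie-break order for
#' consensus statistics.
#'
#' @return a [TraitSchema-class].
#' @examples
#' defaultTraitSchema()
#' @export
defaultTraitSchema <- function() {
  cat.names <- c("conidia_number", "conidia_morphology",
                 "protoperithecia_number", "protoperithecia_morphology",
                 "perithecia_number", "perithecia_morphology",
                 "ascospore_number", "ascospore_morphology")
  traits <- data.frame(
    name = c(cat.names, "growth_rate", "aerial_height"),
    kind = c(rep("categorical", 8L), rep("continuous", 2L)),
    unit = c(rep("none", 8L), "mm/day", "mm"),
    position = 1:10,
    stringsAsFactors = FALSE)
  vocab <- stats::setNames(rep(list(.ABUNDANCE_VOCAB), 4L),
                           cat.names[c(1, 3, 5, 7)])
  vocab <- c(vocab, stats::setNames(rep(list(.MORPHOLOGY_VOCAB), 4L),
                                    cat.names[c(2, 4, 6, 8)]))
  vocab$perithecia_morphology <-
    c("Not Formed", "Abnormal Beaks", "Abnormal", "Normal")
  new("TraitSchema", traits = traits, vocabulary = vocab[cat.names])
}

#' Construct a phenotype table from a data.frame
#'
#' @param data data.frame with a \code{gene_id} column and one column per
#'   schema trait.  Categorical columns are coerced to character.
#' @param schema a [TraitSchema-class] (default [defaultTraitSchema()]).
#' @return a validated [PhenotypeTable-class]; row order is preserved.
#' @export
phenotypeTable <- function(data, schema = defaultTraitSchema()) {
  stopIfNot(is.data.frame(data), "data must be a data.frame")
  for (nm in schema@traits$name[schema@traits$kind == "categorical"]) {
    if (nm %in% names(data)) data[[nm]] <- as.character(data[[nm]])
  }
  data$gene_id <- as.character(data$gene_id)
  rownames(data) <- NULL
  new("PhenotypeTable", schema = schema,
      data = data[, c("gene_id", schema@traits$name), drop = FALSE])
}

#' Read a phenotype table from a delimited text file
#'
#' Expects a header row naming the gene-id column and all ten trait
#' columns.  Blank cells become missing values; a non-blank cell that
#' cannot be parsed as a number (continuous traits) or is outside its
#' trait's vocabulary (categorical traits) aborts with a report naming
#' every offending gene, trait and value.
#'
#' @param file path to a CSV/TSV file (UTF-8, one mutant per row).
#' @param schema a [TraitSchema-class].
#' @param sep field separator; by default inferred from the file
#'   extension (tab for \code{.tsv}/\code{.txt}, comma otherwise).
#' @param geneColumn name of the gene-id column in the file.
#' @param columnMap optional named character vector mapping trait names to
#'   file column names, for files whose headers differ from the schema.
#' @return a [PhenotypeTable-class], records in file order.
#' @seealso [writePhenotypeTable()], [filterComplete()]
#' @export
readPhenotypeTable <- function(file, schema = defaultTraitSchema(),
                               sep = NULL, geneColumn = "gene_id",
                               columnMap = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", file, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(file, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, na.strings = c("", "NA"),
                           quote = "\"", comment.char = "")
  wanted <- stats::setNames(schema@traits$name, schema@traits$name)
  if (!is.null(columnMap)) wanted[names(columnMap)] <- columnMap
  need <- c(geneColumn, unname(wanted))
  absent <- setdiff(need, names(raw))
  stopIfNot(length(absent) == 0L,
            "schema error: required column(s) missing from '%s': %s",
            file, paste(absent, collapse = ", "))
  out <- data.frame(gene_id = raw[[geneColumn]], stringsAsFactors = FALSE)
  dup <- unique(out$gene_id[duplicated(out$gene_id)])
  stopIfNot(length(dup) == 0L, "validation error: duplicate gene_id: %s",
            paste(dup, collapse = ", "))
  problems <- character(0)
  for (i in seq_len(nrow(schema@traits))) {
    nm <- schema@traits$name[i]
    v <- raw[[wanted[[nm]]]]
    if (schema@traits$kind[i] == "continuous") {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        problems <- c(problems, sprintf(
          "gene '%s', trait '%s': unparseable numeric value '%s'",
          out$gene_id[bad], nm, v[bad]))
      out[[nm]] <- num
    } else {
      bad <- which(!is.na(v) & !(v %in% schema@vocabulary[[nm]]))
      if (length(bad))
        problems <- c(problems, sprintf(
          "gene '%s', trait '%s': label '%s' is not in the vocabulary",
          out$gene_id[bad], nm, v[bad]))
      out[[nm]] <- v
    }
  }
  stopIfNot(length(problems) == 0L, "validation error in '%s':\n  %s",
            file, paste(problems, collapse = "\n  "))
  phenotypeTable(out, schema)
}

#' Write a phenotype table as CSV
#'
#' Round-trips with [readPhenotypeTable()] field-for-field.
#'
#' @param table a [PhenotypeTable-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writePhenotypeTable <- function(table, file) {
  utils::write.csv(table@data, file, row.names = FALSE, na = "")
  invisible(file)
}

#' Keep only complete records
#'
#' Retains records with all ten traits present, in original order, and
#' reports the retained/dropped counts.  Clustering operates on complete
#' records only.
#'
#' @param table a [PhenotypeTable-class].
#' @return a [PhenotypeTable-class] of the complete records.
#' @export
filterComplete <- function(table) {
  keep <- isComplete(table)
  message(sprintf("filterComplete: retained %d complete records, dropped %d incomplete",
                  sum(keep), sum(!keep)))
  if (!any(keep)) warning("no complete records remain", call. = FALSE)
  phenotypeTable(table@data[keep, , drop = FALSE], table@schema)
}

#' Bin a continuous trait value into its reported severity class
#'
#' Applies the published bin boundaries for basal hyphal growth rate
#' (normal range 75--85 mm/day: 75--77.5 Normal Low, 77.6--82.5 Normal
#' Average, 82.6--85 Normal High; 65--74.9 Slightly Reduced, 40--64.9
#' Reduced, < 40 Severely Reduced, > 85 Increased) and aerial hyphae
#' height (normal range 30--45 mm: 30--35 Normal Low, 35.1--39.9 Normal
#' Average, 40--45 Normal High; 25--29 Slightly Reduced, 15--24.9 Reduced,
#' < 15 Severely Reduced, > 45 Increased).  Values are rounded to one
#' decimal before comparison (the precision the boundaries are stated at)
#' and each printed range is treated as inclusive; the one residual gap
#' this leaves (aerial 29.1--29.9 mm) is assigned to the neighboring bin
#' above (Normal Low), so binning is total on [0, Inf).
#'
#' @param value numeric vector of non-negative measurements.
#' @param trait \code{"growth"} (mm/day) or \code{"aerial"} (mm).
#' @return character vector of bin labels.
#' @examples
#' binContinuous(c(80, 39), "growth")   # Normal Average, Severely Reduced
#' binContinuous(46, "aerial")          # Increased
#' @export
binContinuous <- function(value, trait = c("growth", "aerial")) {
  trait <- match.arg(trait)
  stopIfNot(is.numeric(value), "value must be numeric")
  stopIfNot(all(value >= 0, na.rm = TRUE),
            "domain error: negative %s value", trait)
  r <- round(value, 1)
  if (trait == "growth") {
    cuts <- c(40, 65, 75, 77.6, 82.6, 85 + 0.05)
  } else {
    cuts <- c(15, 25, 29.1, 35.1, 40, 45 + 0.05)
  }
  idx <- findInterval(r, cuts) + 1L
  out <- .BIN_LEVELS[idx]
  out[is.na(value)] <- NA_character_
  out
}

#' Default severity-to-number mapping for abundance traits
#'
#' The ordinal conversion scale used by the numeric (Pearson / K-means)
#' pipeline: increments of 0.25 across six severity categories, from Not
#' Formed (0) through Severely Reduced (0.25), Reduced (0.5), Slightly
#' Reduced (0.75) and Normal (1.0) to Increased (1.5).
#'
#' @return named numeric vector.
#' @export
defaultOrdinalMapping <- function() {
  c("Not Formed" = 0, "Severely Reduced" = 0.25, "Reduced" = 0.5,
    "Slightly Reduced" = 0.75, "Normal" = 1.0, "Increased" = 1.5)
}

#' Convert a phenotype table to the numeric matrix used by Pearson/K-means
#'
#' Only the four abundance ("number") traits are amenable to ordinal
#' conversion; morphology traits are excluded.  The output has one row
#' per mutant and six columns: the two continuous traits, z-scored over
#' the table so the mm-scale measurements are commensurable with the
#' 0--1.5 ordinal scale, followed by the four converted abundance traits.
#'
#' @param table a complete [PhenotypeTable-class].
#' @param mapping named numeric vector covering every label of the four
#'   abundance traits (default [defaultOrdinalMapping()]).
#' @return numeric matrix with gene ids as rownames.
#' @export
toOrdinal <- function(table, mapping = defaultOrdinalMapping()) {
  stopIfNot(all(isComplete(table)),
            "toOrdinal requires a complete table; run filterComplete() first")
  sc <- table@schema
  abundance <- sc@traits$name[sc@traits$position %in% c(1, 3, 5, 7)]
  continuous <- sc@traits$name[order(sc@traits$position)][9:10]
  d <- table@data
  out <- matrix(0, nrow(d), 6L,
                dimnames = list(d$gene_id, c(continuous, abundance)))
  for (nm in continuous) {
    v <- d[[nm]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning(sprintf("trait '%s' has zero variance; z-scores set to 0", nm),
              call. = FALSE)
      out[, nm] <- 0
    } else out[, nm] <- (v - mean(v)) / s
  }
  for (nm in abundance) {
    v <- d[[nm]]
    unmapped <- setdiff(unique(v), names(mapping))
    stopIfNot(length(unmapped) == 0L,
              "conversion error: trait '%s' has label(s) outside the mapping: %s",
              nm, paste(unmapped, collapse = ", "))
    out[, nm] <- unname(mapping[v])
  }
  out
}

#' Classify mutants into the three global phenotype classes
#'
#' Flags each complete record for the three broad defect classes: growth
#' rate (growth bin outside the normal range; "Increased" counts as a
#' defect), asexual development (aerial-height bin abnormal, or conidia
#' number or morphology not Normal) and sexual development (any of the six
#' protoperithecia/perithecia/ascospore traits not Normal).  Returns the
#' per-mutant flags, the per-class counts, the total number of global
#' phenotypes (their sum) and the Venn partition of the three flags.
#'
#' @param table a complete [PhenotypeTable-class].
#' @return list with elements \code{flags} (data.frame), \code{counts}
#'   (named integer: growth, asexual, sexual), \code{totalGlobalPhenotypes},
#'   \code{nWithPhenotype}, \code{nNoPhenotype} and \code{venn} (named
#'   counts for the seven regions).
#' @export
classifyGlobalPhenotypes <- function(table) {
  stopIfNot(all(isComplete(table)),
            "precondition error: classifyGlobalPhenotypes requires complete records")
  d <- table@data
  growth.bin <- binContinuous(d$growth_rate, "growth")
  aerial.bin <- binContinuous(d$aerial_height, "aerial")
  growth <- !(growth.bin %in% .NORMAL_BINS)
  asexual <- !(aerial.bin %in% .NORMAL_BINS) |
    d$conidia_number != "Normal" | d$conidia_morphology != "Normal"
  sexual.traits <- c("protoperithecia_number", "protoperithecia_morphology",
                     "perithecia_number", "perithecia_morphology",
                     "ascospore_number", "ascospore_morphology")
  sexual <- Reduce(`|`, lapply(sexual.traits, function(nm) d[[nm]] != "Normal"))
  any.defect <- growth | asexual | sexual
  flags <- data.frame(gene_id = d$gene_id, growth_defect = growth,
                      asexual_defect = asexual, sexual_defect = sexual,
                      any_defect = any.defect, stringsAsFactors = FALSE)
  counts <- c(growth = sum(growth), asexual = sum(asexual),
              sexual = sum(sexual))
  venn <- c(
    growth_only = sum(growth & !asexual & !sexual),
    asexual_only = sum(!growth & asexual & !sexual),
    sexual_only = sum(!growth & !asexual & sexual),
    growth_asexual = sum(growth & asexual & !sexual),
    growth_sexual = sum(growth & !asexual & sexual),
    asexual_sexual = sum(!growth & asexual & sexual),
    all_three = sum(growth & asexual & sexual))
  list(flags = flags, counts = counts,
       totalGlobalPhenotypes = sum(counts),
       nWithPhenotype = sum(any.defect),
       nNoPhenotype = sum(!any.defect),
       venn = venn)
}
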