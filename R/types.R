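#' OTU count table
#'
#' An `otu_table` is an integer matrix of read counts with samples as rows and
#' OTUs (taxa) as columns.  Row and column names carry the sample and taxon
#' ids and must be unique; counts must be finite, non-negative integers.
#'
#' @param counts numeric matrix (samples x taxa) of non-negative integers.
#' @param sample_ids optional character vector of row ids (defaults to
#'   existing rownames).
#' @param taxon_ids optional character vector of column ids.
#' @return a validated `otu_table` (integer matrix with class attribute).
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      taxon_ids = colnames(counts)) {
  .assert(is.matrix(counts), "counts must be a matrix")
  .assert(!is.null(sample_ids) && !is.null(taxon_ids),
          "sample and taxon ids are required")
  .assert(length(sample_ids) == nrow(counts) &&
          length(taxon_ids) == ncol(counts),
          "id lengths must match matrix dimensions")
  .assert(!anyDuplicated(sample_ids), "duplicate sample ids")
  .assert(!anyDuplicated(taxon_ids), "duplicate taxon ids")
  .assert(all(is.finite(counts)), "counts must be finite")
  .assert(all(counts >= 0), "counts must be non-negative")
  .assert(all(counts == round(counts)), "counts must be integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(as.character(sample_ids), as.character(taxon_ids))
  class(counts) <- c("otu_table", "matrix", "array")
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d taxa, %s total reads\n",
              nrow(x), ncol(x), format(sum(as.double(x)), big.mark = ",")))
  invisible(x)
}

#' Test/access helpers for otu_table
#' @param x object to test.
#' @return `is_otu_table` returns a logical scalar.
#' @export
is_otu_table <- function(x) inherits(x, "otu_table")

# drop the class for plain-matrix math
.unclass_counts <- function(t) {
  m <- unclass(t)
  class(m) <- NULL
  attr(m, "class") <- NULL
  storage.mode(m) <- "double"
  m
}

#' Sample metadata for the two-factor design
#'
#' A data frame with columns `sample`, `species` (chinstrap/gentoo) and
#' `stage` (feeding/moulting).  The crossing of the two factors defines the
#' four study groups.
#'
#' @param sample character vector of unique sample ids.
#' @param species factor/character, levels `chinstrap`, `gentoo`.
#' @param stage factor/character, levels `feeding`, `moulting`.
#' @return a validated `sample_metadata` data frame.
#' @export
sample_metadata <- function(sample, species, stage) {
  .assert(length(sample) > 0, "metadata is empty")
  .assert(!anyDuplicated(sample), "duplicate sample ids in metadata")
  .assert(length(species) == length(sample) && length(stage) == length(sample),
          "metadata columns must have equal length")
  species <- as.character(species); stage <- as.character(stage)
  bad_sp <- setdiff(unique(species), c("chinstrap", "gentoo"))
  .assert(length(bad_sp) == 0,
          paste0("unknown species level(s): ", paste(bad_sp, collapse = ", ")))
  bad_st <- setdiff(unique(stage), c("feeding", "moulting"))
  .assert(length(bad_st) == 0,
          paste0("unknown stage level(s): ", paste(bad_st, collapse = ", ")))
  .assert(!anyNA(species) && !anyNA(stage), "missing factor values")
  out <- data.frame(sample = as.character(sample),
                    species = factor(species, c("chinstrap", "gentoo")),
                    stage = factor(stage, c("feeding", "moulting")),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_metadata", "data.frame")
  out
}

#' Group label (species.stage) per sample
#' @param meta a `sample_metadata` object.
#' @return named character vector of "species.stage" labels.
#' @export
group_labels <- function(meta) {
  setNames(paste(meta$species, meta$stage, sep = "."), meta$sample)
}

#' Taxonomy map with six fixed ranks
#'
#' Stores one ranked lineage per taxon (domain, phylum, class, order, family,
#' genus); missing ranks are the literal string `"unclassified"`.
#'
#' @param taxon_ids character vector of unique taxon ids.
#' @param lineage character matrix or data frame with 6 columns (domain,
#'   phylum, class, order, family, genus), one row per taxon.
#' @return a `taxonomy_map` data frame keyed by `taxon`.
#' @export
taxonomy_map <- function(taxon_ids, lineage) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  lineage <- as.data.frame(lineage, stringsAsFactors = FALSE)
  .assert(ncol(lineage) == 6L, "lineage must have exactly 6 ranks")
  .assert(nrow(lineage) == length(taxon_ids),
          "one lineage row per taxon required")
  .assert(!anyDuplicated(taxon_ids), "duplicate taxon ids in taxonomy")
  names(lineage) <- ranks
  lineage[] <- lapply(lineage, function(col) {
    col <- as.character(col)
    col[is.na(col) | col == ""] <- "unclassified"
    col
  })
  out <- cbind(data.frame(taxon = as.character(taxon_ids),
                          stringsAsFactors = FALSE), lineage)
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

#' Symmetric sample dissimilarity matrix
#'
#' @param d symmetric numeric matrix with zero diagonal.
#' @param ids optional ids (defaults to rownames).
#' @return a `dist_matrix` (numeric matrix with class attribute).
#' @export
dist_matrix <- function(d, ids = rownames(d)) {
  .assert(is.matrix(d) && nrow(d) == ncol(d), "d must be square")
  .assert(!is.null(ids) && !anyDuplicated(ids), "ids must be unique")
  .assert(all(is.finite(d)), "distances must be finite")
  .assert(max(abs(d - t(d))) < 1e-9, "d must be symmetric")
  .assert(max(abs(diag(d))) < 1e-12, "diagonal must be zero")
  .assert(all(d >= -1e-12), "distances must be non-negative")
  d <- (d + t(d)) / 2
  d[d < 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  class(d) <- c("dist_matrix", "matrix", "array")
  d
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix: %d x %d, range [%.4g, %.4g]\n", nrow(x), ncol(x),
              min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

# check that every id in `need` is present in `have`; error naming the missing
.check_ids <- function(need, have, what) {
  missing <- setdiff(need, have)
  .assert(length(missing) == 0,
          sprintf("%s missing: %s%s", what,
                  paste(head(missing, 5), collapse = ", "),
                  if (length(missing) > 5)
                    sprintf(" (+%d more)", length(missing) - 5) else ""))
  invisible(TRUE)
}
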