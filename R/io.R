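#' Read a shared-style OTU count table
#'
#' Accepts two tab-separated dialects, auto-detected from the header:
#' \itemize{
#'   \item mothur shared layout with leading `label`, `Group`, `numOtus`
#'     columns followed by one column per OTU;
#'   \item a bare layout whose first column holds sample ids and remaining
#'     columns hold OTU counts.
#' }
#'
#' @param path path to a TSV file.
#' @return an [otu_table()].
#' @export
read_shared <- function(path) {
  .assert(file.exists(path), paste0("file not found: ", path))
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", blank.lines.skip = TRUE)
  .assert(nrow(raw) > 0 && ncol(raw) >= 2, "malformed shared table: no data")
  hdr <- names(raw)
  if (tolower(hdr[1]) == "label" && tolower(hdr[2]) %in% c("group", "sample") &&
      tolower(hdr[3]) == "numotus") {
    samples <- raw[[2]]
    counts_chr <- raw[, -(1:3), drop = FALSE]
  } else {
    samples <- raw[[1]]
    counts_chr <- raw[, -1, drop = FALSE]
  }
  .assert(ncol(counts_chr) >= 1, "malformed shared table: no OTU columns")
  .assert(!anyDuplicated(samples),
          paste0("duplicate sample id(s): ",
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  counts <- matrix(NA_real_, nrow(counts_chr), ncol(counts_chr),
                   dimnames = list(samples, names(counts_chr)))
  for (j in seq_len(ncol(counts_chr))) {
    v <- suppressWarnings(as.numeric(counts_chr[[j]]))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    .assert(length(bad) == 0,
            sprintf("invalid count at sample '%s', OTU '%s': '%s'",
                    samples[bad[1]], names(counts_chr)[j],
                    counts_chr[[j]][bad[1]]))
    counts[, j] <- v
  }
  otu_table(counts)
}

#' Write an OTU table as a mothur-style shared TSV
#'
#' @param t an [otu_table()].
#' @param path output path.
#' @param dialect `"mothur"` (label/Group/numOtus prefix) or `"bare"`.
#' @return `path`, invisibly.
#' @export
write_shared <- function(t, path, dialect = c("mothur", "bare")) {
  dialect <- match.arg(dialect)
  .assert(is_otu_table(t), "t must be an otu_table")
  df <- as.data.frame(unclass(t), check.names = FALSE)
  if (dialect == "mothur") {
    df <- cbind(data.frame(label = "0.03", Group = rownames(t),
                           numOtus = ncol(t), stringsAsFactors = FALSE), df)
  } else {
    df <- cbind(data.frame(sample = rownames(t), stringsAsFactors = FALSE), df)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a consensus-taxonomy TSV
#'
#' Expects at least two tab-separated columns: OTU id and a
#' semicolon-delimited lineage.  mothur-style bootstrap suffixes `"(NN)"` are
#' stripped; lineages shorter than six ranks are right-padded with
#' `"unclassified"`; lineages longer than six ranks are truncated.
#'
#' @param path path to a TSV file (a `Size` column between id and lineage is
#'   tolerated, as written by mothur's classify.otu).
#' @return a [taxonomy_map()].
#' @export
read_taxonomy <- function(path) {
  .assert(file.exists(path), paste0("file not found: ", path))
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  .assert(ncol(raw) >= 2, "taxonomy file needs >= 2 columns")
  .assert(nrow(raw) > 0, "taxonomy file is empty")
  ids <- raw[[1]]
  lin_col <- ncol(raw)  # lineage is the last column (Size may sit between)
  lineage <- vapply(raw[[lin_col]], function(s) {
    s <- gsub("\\([0-9.]+\\)", "", s)          # strip bootstrap confidences
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    parts <- parts[parts != ""]
    length(parts) <- 6L                         # pad with NA / truncate
    parts
  }, character(6), USE.NAMES = FALSE)
  taxonomy_map(ids, t(lineage))
}

#' Write a taxonomy map as TSV
#' @param tax a [taxonomy_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  lineage <- apply(tax[, -1, drop = FALSE], 1, paste, collapse = ";")
  df <- data.frame(OTU = tax$taxon, Taxonomy = lineage,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted newick phylogeny
#'
#' @param path newick file.
#' @param strict if `TRUE` (default) a tree without branch lengths is an
#'   error, because nearest-taxon distances are undefined without them; if
#'   `FALSE` missing lengths are set to 0.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path, strict = TRUE) {
  .assert(file.exists(path), paste0("file not found: ", path))
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed newick: ",
                                            conditionMessage(e), call. = FALSE))
  .assert(!is.null(tree), "malformed newick file")
  if (is.null(tree$edge.length)) {
    .assert(!strict, "tree has no branch lengths (strict mode)")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  .assert(!anyNA(tree$edge.length) || !strict,
          "tree has missing branch lengths (strict mode)")
  tree$edge.length[is.na(tree$edge.length)] <- 0
  .assert(all(tree$edge.length >= 0), "negative branch lengths")
  .assert(!anyDuplicated(tree$tip.label), "duplicate tip labels")
  tree
}

#' Write a phylogeny to newick
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read sample metadata (sample, species, stage)
#'
#' @param path TSV with header columns `sample`, `species`, `stage`.
#' @return a [sample_metadata()] data frame.
#' @export
read_metadata <- function(path) {
  .assert(file.exists(path), paste0("file not found: ", path))
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  .assert(nrow(raw) > 0, "metadata file is empty")
  need <- c("sample", "species", "stage")
  .check_ids(need, names(raw), "metadata column(s)")
  sample_metadata(raw$sample, raw$species, raw$stage)
}

#' Write sample metadata as TSV
#' @param meta a [sample_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  df <- data.frame(sample = meta$sample, species = as.character(meta$species),
                   stage = as.character(meta$stage), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# all result TSVs go through here: UTF-8, tab-delimited, header, 6 sig. digits
.write_result_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

# square numeric matrix (possibly with NA diagonal / signed values) as TSV
.write_square_tsv <- function(m, path) {
  df <- cbind(data.frame(id = rownames(m), stringsAsFactors = FALSE),
              as.data.frame(signif(m, 6), check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' Write a square distance matrix as TSV with an id header column
#' @param d a [dist_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(d, path) {
  df <- cbind(data.frame(id = rownames(d), stringsAsFactors = FALSE),
              as.data.frame(signif(unclass(d), 6), check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
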