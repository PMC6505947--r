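#' Remove singleton OTUs
#'
#' Drops every taxon whose total count across all samples equals exactly 1,
#' the usual guard against spurious OTUs from sequencing error.
#'
#' @param t an [otu_table()].
#' @return an [otu_table()] without singleton taxa.
#' @export
remove_singletons <- function(t) {
  .assert(is_otu_table(t), "t must be an otu_table")
  totals <- colSums(.unclass_counts(t))
  keep <- totals != 1
  if (!any(keep)) warning("all taxa were singletons; empty table returned")
  otu_table(unclass(t)[, keep, drop = FALSE])
}

#' Rarefy samples to a fixed depth
#'
#' Each sample is subsampled uniformly without replacement to exactly `depth`
#' reads (a multivariate hypergeometric draw).  Samples whose total is below
#' `depth` are dropped with a warning reporting how many.  The draw is carried
#' out in canonical (sorted taxon id) order so the result is invariant to the
#' column order of the input.
#'
#' @param t an [otu_table()].
#' @param depth target reads per sample (default 13415).
#' @param seed integer seed; per-sample substreams are derived from it.
#' @return an [otu_table()] in which every row sums to `depth`.
#' @export
rarefy <- function(t, depth = 13415L, seed = 1L) {
  .assert(is_otu_table(t), "t must be an otu_table")
  .assert(depth > 0, "depth must be positive")
  m <- .unclass_counts(t)
  keep <- rowSums(m) >= depth
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(rownames(t)[!keep], collapse = ", ")))
  }
  m <- m[keep, , drop = FALSE]
  .assert(nrow(m) > 0, "no samples at or above rarefaction depth")
  ord <- order(colnames(m))          # canonical taxon order
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    set.seed(substream_seed(seed, paste0("rarefy/", rownames(m)[i])))
    cnt <- m[i, ord]
    if (sum(cnt) == depth) {
      out[i, ord] <- cnt
    } else {
      reads <- rep.int(seq_along(cnt), cnt)
      drawn <- sample(reads, depth, replace = FALSE)
      out[i, ord] <- tabulate(drawn, nbins = length(cnt))
    }
  }
  otu_table(out)
}

#' Hellinger transform
#'
#' Square root of within-sample relative abundances:
#' `y[i,t] = sqrt(x[i,t] / rowsum_i)`.  Every transformed row has unit sum of
#' squares, which makes Bray-Curtis/Euclidean analyses robust to double zeros.
#'
#' @param t an [otu_table()] (or non-negative numeric matrix).
#' @return numeric matrix of the same shape.
#' @export
hellinger <- function(t) {
  m <- if (is_otu_table(t)) .unclass_counts(t) else as.matrix(t)
  rs <- rowSums(m)
  zero <- which(rs == 0)
  .assert(length(zero) == 0,
          paste0("all-zero sample row(s): ",
                 paste(rownames(m)[zero], collapse = ", ")))
  sqrt(m / rs)
}

#' Bray-Curtis dissimilarity between all sample pairs
#'
#' `d(i,j) = sum_t |x_it - x_jt| / sum_t (x_it + x_jt)`.
#'
#' @param m numeric matrix (samples x taxa), non-negative values.
#' @return a [dist_matrix()].
#' @export
bray_curtis <- function(m) {
  m <- if (is_otu_table(m)) .unclass_counts(m) else as.matrix(m)
  .assert(nrow(m) >= 2, "need at least 2 samples")
  .assert(all(m >= 0), "values must be non-negative")
  rs <- rowSums(m)
  # |x-y| summed = manhattan distance; denominator = rowsum_i + rowsum_j
  num <- as.matrix(dist(m, method = "manhattan"))
  den <- outer(rs, rs, "+")
  zero_pair <- num == 0 & den == 0
  .assert(!any(zero_pair[upper.tri(zero_pair)]),
          "Bray-Curtis undefined for a pair of all-zero samples")
  d <- num / den
  diag(d) <- 0
  dist_matrix(d, rownames(m))
}

#' Shannon diversity and richness per sample
#'
#' `H_i = -sum_t p log(p)` over taxa with positive counts, with
#' `p = count / rowsum`; richness is the number of taxa with positive counts.
#'
#' @param t an [otu_table()].
#' @param base logarithm base, `"e"` (natural, default) or `"2"`.
#' @return data frame with columns `sample`, `shannon`, `richness`.
#' @export
shannon <- function(t, base = c("e", "2")) {
  base <- match.arg(as.character(base)[1], c("e", "2"))
  m <- .unclass_counts(t)
  rs <- rowSums(m)
  .assert(all(rs > 0), "all-zero sample row")
  logf <- if (base == "e") log else log2
  H <- vapply(seq_len(nrow(m)), function(i) {
    p <- m[i, ][m[i, ] > 0] / rs[i]
    -sum(p * logf(p))
  }, numeric(1))
  data.frame(sample = rownames(m), shannon = H,
             richness = as.integer(rowSums(m > 0)),
             stringsAsFactors = FALSE)
}

#' Aggregate OTU counts to a taxonomic rank
#'
#' Columns are summed by their label at `rank`.  `"unclassified"` labels are
#' kept as distinct bins suffixed by the nearest classified parent rank so
#' unrelated unclassified lineages are not pooled.
#'
#' @param t an [otu_table()].
#' @param tax a [taxonomy_map()] covering every taxon in `t`.
#' @param rank one of `"phylum"`, `"family"`, `"genus"` (any of the six ranks
#'   is accepted).
#' @return an [otu_table()] whose columns are rank labels.
#' @export
aggregate_taxonomy <- function(t, tax,
                               rank = c("phylum", "family", "genus",
                                        "domain", "class", "order")) {
  rank <- match.arg(rank)
  .assert(inherits(tax, "taxonomy_map"), "tax must be a taxonomy_map")
  .check_ids(colnames(t), tax$taxon, "taxonomy for OTU(s)")
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  ri <- match(rank, ranks)
  idx <- match(colnames(t), tax$taxon)
  labels <- tax[[rank]][idx]
  unc <- labels == "unclassified"
  if (any(unc)) {
    # walk up to the nearest classified rank for a disambiguating suffix
    parent <- rep("root", sum(unc))
    if (ri > 1) {
      anc <- as.matrix(tax[idx[unc], 1 + seq_len(ri - 1), drop = FALSE])
      for (k in rev(seq_len(ri - 1))) {
        take <- parent == "root" & anc[, k] != "unclassified"
        parent[take] <- anc[take, k]
      }
    }
    labels[unc] <- paste0("unclassified_", parent)
  }
  m <- .unclass_counts(t)
  agg <- rowsum(base::t(m), group = labels)   # taxa x samples -> labels
  otu_table(base::t(agg))
}

#' Per-sample relative abundances
#'
#' @param t an [otu_table()] (or numeric matrix) with positive row sums.
#' @param percent if `TRUE`, rows sum to 100 instead of 1.
#' @return numeric matrix of proportions.
#' @export
relative_abundance <- function(t, percent = FALSE) {
  m <- if (is_otu_table(t)) .unclass_counts(t) else as.matrix(t)
  rs <- rowSums(m)
  .assert(all(rs > 0), "all-zero sample row")
  (m / rs) * if (percent) 100 else 1
}

#' Group-mean relative abundances
#'
#' Group-level values are the mean of per-sample proportions (not pooled
#' counts), matching the per-sample testing convention used downstream.
#'
#' @param t an [otu_table()] (typically rank-aggregated).
#' @param meta a [sample_metadata()] covering the table's samples.
#' @param percent report percentages (default `TRUE`).
#' @return matrix groups x taxa of mean proportions.
#' @export
group_mean_abundance <- function(t, meta, percent = TRUE) {
  .check_ids(rownames(t), meta$sample, "metadata for sample(s)")
  rel <- relative_abundance(t, percent = percent)
  grp <- group_labels(meta)[rownames(rel)]
  out <- rowsum(rel, grp) / as.vector(table(grp)[sort(unique(grp))])
  out[order(rownames(out)), , drop = FALSE]
}
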