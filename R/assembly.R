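#' Patristic (cophenetic) distances between all tree tips
#'
#' `d(a, b)` is the sum of branch lengths on the path between tips `a` and
#' `b`.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return symmetric numeric matrix with tip labels as dimnames.
#' @export
cophenetic_distances <- function(tree) {
  .assert(!anyDuplicated(tree$tip.label), "duplicate tip labels")
  .assert(!is.null(tree$edge.length), "tree has no branch lengths")
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label]
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For each taxon present in one community, the patristic distance to its
#' nearest taxon in the other community is found; betaMNTD is the average of
#' these nearest-taxon distances over both directions,
#' abundance-weighted by within-sample relative abundances (or equal weights
#' `1/richness` when `weighted = FALSE`).
#'
#' @param x_i,x_j non-negative abundance vectors named by (or aligned to) the
#'   taxa of `td`.
#' @param td patristic distance matrix over the taxa (see
#'   [cophenetic_distances()]).
#' @param weighted abundance-weight the taxon contributions (default `TRUE`).
#' @return a single numeric value.
#' @export
beta_mntd <- function(x_i, x_j, td, weighted = TRUE) {
  if (!is.null(names(x_i))) x_i <- x_i[rownames(td)]
  if (!is.null(names(x_j))) x_j <- x_j[rownames(td)]
  pi <- which(x_i > 0); pj <- which(x_j > 0)
  .assert(length(pi) > 0 && length(pj) > 0, "empty community")
  min_ij <- apply(td[pi, pj, drop = FALSE], 1, min)  # i-taxa to nearest in j
  min_ji <- apply(td[pj, pi, drop = FALSE], 1, min)
  if (weighted) {
    wi <- x_i[pi] / sum(x_i[pi]); wj <- x_j[pj] / sum(x_j[pj])
  } else {
    wi <- rep(1 / length(pi), length(pi)); wj <- rep(1 / length(pj), length(pj))
  }
  0.5 * (sum(wi * min_ij) + sum(wj * min_ji))
}

#' Beta nearest taxon index (betaNTI) for all sample pairs
#'
#' betaNTI standardizes the observed betaMNTD of each sample pair against a
#' null distribution obtained by shuffling taxon labels across the tips of
#' the phylogeny pruned to the taxa observed anywhere in the table (the
#' regional pool): `betaNTI = (obs - mean_null) / sd_null`.  One shuffle per
#' null iteration is shared by all pairs.  `|betaNTI| > 2` indicates
#' deterministic selection (+ variable, - homogeneous).
#'
#' @param t an [otu_table()] (typically rarefied counts).
#' @param tree an [ape::phylo] tree containing every table taxon as a tip.
#' @param n_null number of null shuffles (default 999).
#' @param weighted abundance-weighted betaMNTD (default `TRUE`).
#' @param seed integer seed.
#' @return a `bnti_matrix` list: `sample_ids`, `bnti` (symmetric matrix, NA
#'   diagonal; NaN where the null SD is 0), `bmntd_obs`, `null_mean`,
#'   `null_sd`, `n_null`, `weighted`.
#' @export
beta_nti <- function(t, tree, n_null = 999L, weighted = TRUE, seed = 1L) {
  .assert(is_otu_table(t), "t must be an otu_table")
  .assert(n_null >= 2, "n_null must be >= 2")
  m <- .unclass_counts(t)
  m <- m[, colSums(m) > 0, drop = FALSE]
  .check_ids(colnames(m), tree$tip.label, "tree tip(s) for taxon(s)")
  pruned <- ape::keep.tip(tree, colnames(m))
  D <- cophenetic_distances(pruned)
  taxa <- rownames(D)
  m <- m[, taxa, drop = FALSE]
  n <- nrow(m); T_n <- length(taxa)

  comm <- lapply(seq_len(n), function(i) which(m[i, ] > 0) - 1L)
  wts <- lapply(seq_len(n), function(i) {
    x <- m[i, m[i, ] > 0]
    if (weighted) x / sum(x) else rep(1 / length(x), length(x))
  })
  pairs <- base::t(combn(n, 2)) - 1L
  set.seed(substream_seed(seed, "bnti"))
  perms <- matrix(0L, n_null, T_n)
  for (k in seq_len(n_null)) perms[k, ] <- sample.int(T_n) - 1L

  res <- cpp_bnti(D, comm, wts, pairs, perms)
  # a degenerate null (e.g. star phylogeny) leaves only floating-point dust
  # in the variance (relative sd ~ sqrt(machine eps)); flag against the null
  # mean's magnitude with head-room above that dust level
  sd0 <- res[, 3] <= 1e-6 * pmax(abs(res[, 2]), 1e-12)
  if (any(sd0)) {
    warning(sprintf("%d pair(s) with null SD = 0 flagged NaN", sum(sd0)))
  }
  bnti_v <- ifelse(sd0, NaN, (res[, 1] - res[, 2]) / res[, 3])

  to_mat <- function(v, diag_val = NA_real_) {
    M <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
    M[lower.tri(M)] <- NA  # filled below
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1] + 1L; j <- pairs[p, 2] + 1L
      M[i, j] <- M[j, i] <- v[p]
    }
    diag(M) <- diag_val
    M
  }
  structure(list(sample_ids = rownames(m),
                 bnti = to_mat(bnti_v),
                 bmntd_obs = to_mat(res[, 1], 0),
                 null_mean = to_mat(res[, 2]),
                 null_sd = to_mat(res[, 3]),
                 n_null = as.integer(n_null), weighted = weighted),
            class = "bnti_matrix")
}

# Efraimidis-Spirakis weighted sampling without replacement: the k items with
# the smallest Exp(1)/w keys are a sequential weighted draw.
.weighted_subset <- function(n_items, k, w) {
  keys <- rexp(n_items) / w
  order(keys)[seq_len(k)]
}

# one null community: preserve richness and total reads of the template
.rc_null_community <- function(richness, depth, occ_prob, meta_prob) {
  sel <- .weighted_subset(length(occ_prob), richness, occ_prob)
  x <- integer(length(occ_prob))
  x[sel] <- 1L                                    # each selected taxon seeded
  extra <- depth - richness
  if (extra > 0) {
    p <- meta_prob[sel]
    x[sel] <- x[sel] + rmultinom(1, extra, p / sum(p))[, 1]
  }
  x
}

#' Bray-Curtis Raup-Crick (RC-bray) for all sample pairs
#'
#' For each pair, the observed Bray-Curtis dissimilarity is located within a
#' null distribution of dissimilarities between probabilistically reassembled
#' communities.  Each null community preserves its sample's observed richness
#' and total reads: taxa are drawn without replacement with probability
#' proportional to occupancy (number of samples containing the taxon), each
#' drawn taxon receives one read, and the remaining reads are assigned
#' multinomially with probability proportional to metacommunity relative
#' abundance restricted to the drawn taxa.
#' `RC = 2 * ((#\{null < obs\} + 0.5 #\{null = obs\}) / n_null - 0.5)`,
#' in `[-1, +1]`; `|RC| > 0.95` signals dispersal-driven turnover.
#'
#' Null communities are generated per sample per iteration and paired across
#' samples, so results do not depend on the order pairs are evaluated.
#'
#' @param t an [otu_table()] (typically rarefied counts) with >= 2 samples
#'   and positive row sums.
#' @param n_null number of null draws (default 999).
#' @param seed integer seed.
#' @return an `rc_matrix` list: `sample_ids`, `rc` (symmetric matrix, NA
#'   diagonal), `n_null`.
#' @export
raup_crick_bray <- function(t, n_null = 999L, seed = 1L) {
  .assert(is_otu_table(t), "t must be an otu_table")
  m <- .unclass_counts(t)
  m <- m[, colSums(m) > 0, drop = FALSE]
  n <- nrow(m)
  .assert(n >= 2, "need >= 2 samples")
  .assert(all(rowSums(m) > 0), "sample with zero reads")
  occ <- colSums(m > 0)
  meta_p <- colSums(m) / sum(m)
  rich <- rowSums(m > 0)
  depth <- rowSums(m)
  .assert(all(rich <= ncol(m)), "sample richness exceeds taxon pool")

  obs <- as.matrix(dist(m, method = "manhattan")) /
    outer(depth, depth, "+")
  less <- matrix(0, n, n); equal <- matrix(0, n, n)
  set.seed(substream_seed(seed, "rcbray"))
  for (k in seq_len(n_null)) {
    nullm <- matrix(0L, n, ncol(m))
    for (s in seq_len(n)) {
      nullm[s, ] <- .rc_null_community(rich[s], depth[s], occ, meta_p)
    }
    bc <- as.matrix(dist(nullm, method = "manhattan")) /
      outer(depth, depth, "+")
    less <- less + (bc < obs - 1e-12)
    equal <- equal + (abs(bc - obs) <= 1e-12)
  }
  rc <- 2 * ((less + 0.5 * equal) / n_null - 0.5)
  rc <- (rc + base::t(rc)) / 2
  diag(rc) <- NA_real_
  dimnames(rc) <- list(rownames(m), rownames(m))
  structure(list(sample_ids = rownames(m), rc = rc,
                 n_null = as.integer(n_null)),
            class = "rc_matrix")
}

#' Classify a sample pair into one of five assembly processes
#'
#' Decision tree on the pair's betaNTI and RC-bray values:
#' `bnti > +2` variable selection; `bnti < -2` homogeneous selection;
#' otherwise `rc > +0.95` dispersal limitation, `rc < -0.95` homogenizing
#' dispersal, else drift.  Boundary ties (exactly 2 or 0.95) fall to the
#' stochastic side; non-finite betaNTI gives `"undetermined"`.
#'
#' @param bnti,rc numeric vectors (recycled to common length).
#' @param th_bnti,th_rc thresholds (defaults 2 and 0.95).
#' @return character vector of process labels.
#' @export
classify_pair <- function(bnti, rc, th_bnti = 2, th_rc = 0.95) {
  k <- max(length(bnti), length(rc))
  bnti <- rep_len(bnti, k); rc <- rep_len(rc, k)
  out <- rep("drift", k)
  out[rc > th_rc] <- "dispersal_limitation"
  out[rc < -th_rc] <- "homogenizing_dispersal"
  out[bnti > th_bnti] <- "variable_selection"
  out[bnti < -th_bnti] <- "homogeneous_selection"
  out[!is.finite(bnti)] <- "undetermined"
  out
}

#' Process labels in canonical order
#' @export
process_levels <- function() {
  c("variable_selection", "homogeneous_selection", "dispersal_limitation",
    "homogenizing_dispersal", "drift")
}

#' Per-group percentages of assembly processes
#'
#' Classifies every within-group sample pair via [classify_pair()] and
#' reports, per group, the percentage of its `choose(n, 2)` pairwise
#' comparisons assigned to each process.  Percentages are taken over valid
#' (finite-betaNTI) pairs; undetermined pairs are counted and reported.
#'
#' @param bnti a `bnti_matrix` from [beta_nti()].
#' @param rc an `rc_matrix` from [raup_crick_bray()].
#' @param meta a [sample_metadata()] covering the samples.
#' @param th_bnti,th_rc classification thresholds.
#' @return a `process_summary` data frame: group, process, percent, n_pairs
#'   (valid pairs in the group); attribute `n_undetermined`.
#' @export
summarize_processes <- function(bnti, rc, meta, th_bnti = 2, th_rc = 0.95) {
  .assert(inherits(bnti, "bnti_matrix"), "bnti must be a bnti_matrix")
  .assert(inherits(rc, "rc_matrix"), "rc must be an rc_matrix")
  ids <- bnti$sample_ids
  .check_ids(ids, rc$sample_ids, "RC value(s) for sample(s)")
  .check_ids(ids, meta$sample, "metadata for sample(s)")
  grp <- group_labels(meta)[ids]
  out <- list(); n_undet <- 0L
  for (g in sort(unique(grp))) {
    members <- ids[grp == g]
    if (length(members) < 2) {
      warning(sprintf("group '%s' has < 2 samples; skipped", g))
      next
    }
    prs <- combn(members, 2)
    b <- bnti$bnti[cbind(prs[1, ], prs[2, ])]
    r <- rc$rc[cbind(prs[1, ], prs[2, ])]
    cls <- classify_pair(b, r, th_bnti, th_rc)
    undet <- cls == "undetermined"
    n_undet <- n_undet + sum(undet)
    valid <- sum(!undet)
    .assert(valid > 0, sprintf("group '%s' has no valid pairs", g))
    pct <- 100 * vapply(process_levels(),
                        function(p) sum(cls[!undet] == p), numeric(1)) / valid
    out[[g]] <- data.frame(group = g, process = process_levels(),
                           percent = unname(pct), n_pairs = valid,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "n_undetermined") <- n_undet
  class(res) <- c("process_summary", "data.frame")
  res
}

#' Long-format pair classification table
#'
#' One row per sample pair (within-group pairs flagged) with betaNTI, RC and
#' the assigned process, mirroring the per-pair audit trail behind a process
#' summary.
#'
#' @inheritParams summarize_processes
#' @return data frame: sample_i, sample_j, group (NA for between-group
#'   pairs), bnti, rc, class.
#' @export
pair_classes <- function(bnti, rc, meta, th_bnti = 2, th_rc = 0.95) {
  ids <- bnti$sample_ids
  grp <- group_labels(meta)[ids]
  prs <- combn(ids, 2)
  b <- bnti$bnti[cbind(prs[1, ], prs[2, ])]
  r <- rc$rc[cbind(prs[1, ], prs[2, ])]
  g1 <- grp[prs[1, ]]; g2 <- grp[prs[2, ]]
  data.frame(sample_i = prs[1, ], sample_j = prs[2, ],
             group = ifelse(g1 == g2, g1, NA_character_),
             bnti = b, rc = r,
             class = classify_pair(b, r, th_bnti, th_rc),
             stringsAsFactors = FALSE)
}
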