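test_that("cophenetic_distances: hand values, zero diagonal, graph oracle", {
  D <- cophenetic_distances(toy_tree())
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)
  expect_true(all(diag(D) == 0))

  skip_if_not_installed("igraph")
  tr <- simulate_tree(50, 13)
  D <- cophenetic_distances(tr)
  # independent oracle: shortest paths on the tree's weighted edge graph
  n_tip <- length(tr$tip.label)
  g <- igraph::graph_from_data_frame(
    data.frame(from = tr$edge[, 1], to = tr$edge[, 2],
               weight = tr$edge.length), directed = FALSE)
  sp <- igraph::distances(g, v = as.character(seq_len(n_tip)),
                          to = as.character(seq_len(n_tip)))
  dimnames(sp) <- list(tr$tip.label, tr$tip.label)
  expect_equal(D, sp[rownames(D), colnames(D)], tolerance = 1e-12)
})

test_that("beta_mntd equals the brute-force oracle and its closed forms", {
  td <- cophenetic_distances(toy_tree())
  # singleton communities: betaMNTD is the patristic distance itself
  expect_equal(beta_mntd(c(A = 1, B = 0, C = 0), c(A = 0, B = 1, C = 0), td),
               2)
  # identical communities: all nearest-taxon distances are zero
  x <- c(A = 3, B = 1, C = 2)
  expect_equal(beta_mntd(x, x, td), 0)

  for (seed in 1:20) {
    set.seed(seed)
    tr <- simulate_tree(8, seed + 100)
    td <- cophenetic_distances(tr)
    x_i <- setNames(rpois(8, 2), rownames(td))
    x_j <- setNames(rpois(8, 2), rownames(td))
    if (sum(x_i) == 0 || sum(x_j) == 0) next
    for (w in c(TRUE, FALSE)) {
      expect_equal(beta_mntd(x_i, x_j, td, weighted = w),
                   bmntd_oracle(x_i, x_j, td, weighted = w),
                   tolerance = 1e-12)
    }
  }
})

test_that("beta_nti agrees with an all-R null reimplementation on a tiny case", {
  set.seed(21)
  tr <- simulate_tree(12, 21)
  tab <- simulate_neutral(metacommunity(12, 0.8,
                                        taxon_ids = tr$tip.label),
                          4, 60, 21)
  res <- suppressWarnings(beta_nti(tab, tr, n_null = 199, seed = 5))

  # reimplement the null in plain R with the same permutation stream
  m <- unclass(tab); storage.mode(m) <- "double"
  keep <- colSums(m) > 0
  m <- m[, keep, drop = FALSE]
  pruned <- ape::keep.tip(tr, colnames(m))
  D <- cophenetic_distances(pruned)
  m <- m[, rownames(D), drop = FALSE]
  T_n <- ncol(m)
  set.seed(substream_seed(5, "bnti"))
  perms <- matrix(0L, 199, T_n)
  for (k in 1:199) perms[k, ] <- sample.int(T_n)
  pair <- c(1, 3)
  obs <- beta_mntd(m[pair[1], ], m[pair[2], ], D)
  nulls <- vapply(1:199, function(k) {
    Dp <- D[perms[k, ], perms[k, ]]
    dimnames(Dp) <- dimnames(D)
    beta_mntd(m[pair[1], ], m[pair[2], ], Dp)
  }, numeric(1))
  expect_equal(res$bmntd_obs[pair[1], pair[2]], obs, tolerance = 1e-12)
  expect_equal(res$bnti[pair[1], pair[2]],
               (obs - mean(nulls)) / sd(nulls), tolerance = 1e-9)
})

test_that("beta_nti flags zero-SD nulls on a star phylogeny", {
  tr <- star_tree(5)
  m <- matrix(c(3L, 1L, 0L, 0L, 0L,
                0L, 0L, 2L, 1L, 0L), 2, 5, byrow = TRUE,
              dimnames = list(c("s1", "s2"), tr$tip.label))
  expect_warning(res <- beta_nti(otu_table(m), tr, n_null = 19, seed = 1),
                 "SD = 0")
  expect_true(is.nan(res$bnti["s1", "s2"]))
})

test_that("raup_crick_bray stays in [-1, 1] and hits its limiting values", {
  # two identical samples whose taxa occupy every sample of a bigger table
  set.seed(30)
  base <- c(500L, 300L, 150L, 50L)
  m <- rbind(s1 = base, s2 = base,
             s3 = c(10L, 700L, 80L, 210L), s4 = c(400L, 100L, 400L, 100L),
             s5 = c(30L, 40L, 800L, 130L), s6 = c(250L, 250L, 250L, 250L))
  colnames(m) <- paste0("t", 1:4)
  rc <- raup_crick_bray(otu_table(m), n_null = 199, seed = 2)
  expect_true(all(abs(rc$rc) <= 1, na.rm = TRUE))
  expect_lt(rc$rc["s1", "s2"], -0.9)

  # disjoint taxa from a shared rich pool push RC towards +1
  set.seed(31)
  pool <- 40
  m2 <- matrix(0L, 6, pool,
               dimnames = list(paste0("s", 1:6), paste0("t", 1:pool)))
  for (i in 1:4) m2[i, sample(pool, 15)] <- rpois(15, 20) + 1L
  m2[5, 1:12] <- 50L
  m2[6, 29:40] <- 50L   # s5, s6 disjoint
  rc2 <- raup_crick_bray(otu_table(m2), n_null = 199, seed = 3)
  expect_gt(rc2$rc["s5", "s6"], 0.9)

  expect_identical(raup_crick_bray(otu_table(m), 99, 7)$rc,
                   raup_crick_bray(otu_table(m), 99, 7)$rc)
})

test_that("classify_pair implements the five-way decision tree with ties to drift", {
  expect_equal(classify_pair(2.5, 0.1), "variable_selection")
  expect_equal(classify_pair(-2.5, 0.99), "homogeneous_selection")
  expect_equal(classify_pair(0.3, 0.97), "dispersal_limitation")
  expect_equal(classify_pair(0.3, -0.97), "homogenizing_dispersal")
  expect_equal(classify_pair(0.3, 0.2), "drift")
  # boundaries fall to the stochastic side
  expect_equal(classify_pair(2.0, 0.2), "drift")
  expect_equal(classify_pair(2.0, 0.97), "dispersal_limitation")
  expect_equal(classify_pair(-2.0, -0.95), "drift")
  expect_equal(classify_pair(0.1, 0.95), "drift")
  expect_equal(classify_pair(NaN, 0.5), "undetermined")
})

test_that("summarize_processes yields the pair-count percentage grid", {
  # build synthetic bnti/rc matrices with known classes: a 6-sample group has
  # 15 pairs; 7 drift pairs give exactly 46.67%
  md <- toy_metadata(c(0, 6, 0, 0), ids = paste0("m", 1:6))
  n <- 6
  b <- matrix(0, n, n, dimnames = list(md$sample, md$sample))
  r <- matrix(0, n, n, dimnames = list(md$sample, md$sample))
  prs <- combn(n, 2)
  cls <- c(rep("drift", 7), rep("variable_selection", 5),
           rep("homogenizing_dispersal", 3))
  for (q in seq_len(ncol(prs))) {
    i <- prs[1, q]; j <- prs[2, q]
    if (cls[q] == "variable_selection") b[i, j] <- b[j, i] <- 3
    if (cls[q] == "homogenizing_dispersal") r[i, j] <- r[j, i] <- -0.99
  }
  bnti <- structure(list(sample_ids = md$sample, bnti = b, n_null = 999L),
                    class = "bnti_matrix")
  rc <- structure(list(sample_ids = md$sample, rc = r, n_null = 999L),
                  class = "rc_matrix")
  ps <- summarize_processes(bnti, rc, md)
  expect_equal(ps$percent[ps$process == "drift"], 100 * 7 / 15)
  expect_equal(round(ps$percent[ps$process == "drift"], 2), 46.67)
  expect_equal(ps$percent[ps$process == "variable_selection"], 100 * 5 / 15)
  expect_equal(sum(ps$percent), 100, tolerance = 1e-9)
  expect_equal(unique(ps$n_pairs), 15L)

  # all pairs one class
  bnti$bnti[upper.tri(b) | lower.tri(b)] <- 5
  ps2 <- summarize_processes(bnti, rc, md)
  expect_equal(ps2$percent[ps2$process == "variable_selection"], 100)
  expect_equal(sum(ps2$percent), 100)
})

test_that("pair_classes reports within-group labels and matches summarize", {
  set.seed(40)
  tr <- simulate_tree(30, 40)
  tab <- simulate_neutral(metacommunity(30, 1, taxon_ids = tr$tip.label),
                          8, 400, 40)
  md <- toy_metadata(c(4, 4, 0, 0), ids = rownames(tab))
  b <- suppressWarnings(beta_nti(tab, tr, n_null = 99, seed = 2))
  r <- raup_crick_bray(tab, n_null = 99, seed = 2)
  pc <- pair_classes(b, r, md)
  expect_equal(nrow(pc), choose(8, 2))
  expect_equal(sum(!is.na(pc$group)), 2 * choose(4, 2))
  ps <- summarize_processes(b, r, md)
  for (g in unique(ps$group)) {
    sub <- pc[!is.na(pc$group) & pc$group == g & pc$class != "undetermined", ]
    for (p in process_levels()) {
      expect_equal(ps$percent[ps$group == g & ps$process == p],
                   100 * sum(sub$class == p) / nrow(sub))
    }
  }
})
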