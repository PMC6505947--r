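test_that("isotonic_fit is PAVA: identity on monotone input, pooling on violations", {
  expect_equal(isotonic_fit(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(isotonic_fit(c(3, 1, 2)), c(2, 2, 2))
  expect_equal(isotonic_fit(c(1, 3, 2, 4)), c(1, 2.5, 2.5, 4))

  # against stats::isoreg (independent base-R implementation)
  for (seed in 1:5) {
    set.seed(seed)
    e <- rnorm(25)
    expect_equal(isotonic_fit(e), isoreg(e)$yf, tolerance = 1e-12)
    expect_true(all(diff(isotonic_fit(e)) >= -1e-12))
  }

  # weighted solution minimizes weighted SSE among monotone candidates
  e <- c(2, 1); w <- c(3, 1)
  expect_equal(isotonic_fit(e, w), rep((3 * 2 + 1 * 1) / 4, 2))
})

test_that("nmds recovers embeddable configurations with near-zero stress", {
  # 5 collinear points are perfectly embeddable at k = 1
  x <- c(0, 1, 2, 4, 7)
  d <- dist_matrix(as.matrix(dist(x)), ids = paste0("p", 1:5))
  res <- nmds(d, k = 1, n_starts = 10, seed = 1)
  expect_lt(res$stress, 1e-3)

  # unit square with diagonals embeds exactly at k = 2 (grid-search optimum
  # stress is 0 by construction)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  d2 <- dist_matrix(as.matrix(dist(sq)), ids = paste0("q", 1:4))
  res2 <- nmds(d2, k = 2, n_starts = 10, seed = 2)
  expect_lt(res2$stress, 1e-3)
  expect_true(res2$converged)
  # scores are centred
  expect_equal(colMeans(res2$scores), c(NMDS1 = 0, NMDS2 = 0),
               tolerance = 1e-8)
})

test_that("stress is invariant to rotation, translation and scaling", {
  set.seed(3)
  n <- 7
  dobs <- as.matrix(dist(matrix(rnorm(n * 2), n, 2)))
  dv <- dobs[lower.tri(dobs)]
  ord <- order(dv)
  tie <- cumsum(c(1, diff(dv[ord]) > 1e-12))
  jj <- rep.int(seq_len(n - 1), (n - 1):1)
  ii <- unlist(lapply(seq_len(n - 1), function(j) seq.int(j + 1, n)))
  X <- matrix(rnorm(n * 2), n, 2)
  s0 <- penguinproc:::.stress1(as.vector(X), n, 2, ord, tie, ii, jj)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  X2 <- (X %*% R) * 3.1 + 5
  s1 <- penguinproc:::.stress1(as.vector(X2), n, 2, ord, tie, ii, jj)
  expect_equal(s0, s1, tolerance = 1e-10)
})

test_that("nmds flags degenerate all-equal distance input", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  dm <- dist_matrix(d, ids = letters[1:4])
  expect_warning(res <- nmds(dm, seed = 1), "arbitrary")
  expect_false(res$converged)
})

test_that("permanova matches vegan::adonis2 and decomposes SS", {
  skip_if_not_installed("vegan")
  set.seed(8)
  tab <- random_table(n = 16, t = 30, lambda = 8, seed = 8)
  md <- toy_metadata(c(4, 4, 4, 4), ids = rownames(tab))
  bc <- bray_curtis(relative_abundance(tab))
  pm <- permanova(bc, md, n_perm = 99, seed = 1)

  ad <- vegan::adonis2(stats::as.dist(unclass(bc)) ~ species * stage,
                       data = data.frame(species = md$species,
                                         stage = md$stage),
                       permutations = 99, by = "terms")
  expect_equal(pm$SS[1:4], ad$SumOfSqs[1:4], tolerance = 1e-10)
  expect_equal(pm$pseudo_F[1:3], ad$F[1:3], tolerance = 1e-10)
  expect_equal(pm$df, c(1L, 1L, 1L, 12L, 15L))

  # additive decomposition and F-invariance under distance scaling
  expect_equal(sum(pm$SS[1:4]), pm$SS[5], tolerance = 1e-9)
  pm2 <- permanova(dist_matrix(unclass(bc) * 3.7), md, n_perm = 9, seed = 1)
  expect_equal(pm2$pseudo_F[1:3], pm$pseudo_F[1:3], tolerance = 1e-9)

  # degenerate single-level factor
  md_one <- sample_metadata(md$sample, rep("gentoo", 16), md$stage)
  expect_error(permanova(bc, md_one, n_perm = 9, seed = 1), "single level")
})

test_that("permanova permutation p is close to exact enumeration at n = 6", {
  # structured fixture: real species signal keeps exact p small so the
  # Monte-Carlo error of the permutation estimate stays inside the band
  set.seed(9)
  m <- rbind(matrix(rpois(18, 20), 3, 6), matrix(rpois(18, 1), 3, 6))
  m <- cbind(m, rbind(matrix(rpois(18, 1), 3, 6),
                      matrix(rpois(18, 20), 3, 6))) + 1L
  dimnames(m) <- list(sprintf("S%02d", 1:6), sprintf("Otu%03d", 1:12))
  tab <- otu_table(m)
  md <- toy_metadata(c(3, 0, 3, 0), ids = rownames(tab))
  bc <- bray_curtis(relative_abundance(tab))

  pm <- permanova(bc, md, terms = "species", n_perm = 999, seed = 4)

  # exact p over all 6! relabelings, via the same projection algebra
  A <- -0.5 * unclass(bc)^2
  C <- diag(6) - matrix(1 / 6, 6, 6)
  G <- C %*% A %*% C
  X <- cbind(1, as.numeric(md$species == "gentoo"))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  H0 <- matrix(1 / 6, 6, 6)
  fstat <- function(p) {
    Gp <- G[p, p]
    ss <- sum((H - H0) * Gp)
    ssr <- sum((diag(6) - H) * Gp)
    (ss / 1) / (ssr / 4)
  }
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  f_obs <- fstat(1:6)
  f_all <- apply(perms, 1, fstat)
  p_exact <- mean(f_all >= f_obs - 1e-12)
  expect_lt(abs(pm$p[1] - p_exact), 0.02)
})

test_that("welch_t matches stats::t.test to high precision", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  r <- welch_t(x, y)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  # equal variances and sizes reduce df to n1 + n2 - 2
  r2 <- welch_t(c(1, 2, 3), c(11, 12, 13))
  expect_equal(r2$df, 4)

  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(5 + seed %% 4); y <- rnorm(7, 0.4, 1.6)
    mine <- welch_t(x, y)
    ref <- t.test(x, y)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
  }
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("differential_abundance: power, nulls and BH monotonicity", {
  md <- toy_metadata(c(6, 6, 0, 0))
  # identical proportions in both stages -> p = 1
  rel <- matrix(0.5, 12, 2, dimnames = list(md$sample, c("tA", "tB")))
  da <- differential_abundance(rel, md, "chinstrap")
  expect_equal(da$p, c(1, 1))

  # simulated shift delta = 0.3, sd = 0.05: raw p < 0.01 nearly always
  hits <- 0L
  for (r in 1:200) {
    set.seed(r)
    a <- pmin(pmax(rnorm(6, 0.2, 0.05), 0), 1)
    b <- pmin(pmax(rnorm(6, 0.5, 0.05), 0), 1)
    rel <- cbind(tA = c(a, b), tB = 1 - c(a, b))
    rownames(rel) <- md$sample
    da <- differential_abundance(rel, md, "chinstrap")
    if (da$p[da$taxon == "tA"] < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 190L)  # >= 95% of 200

  # BH adjusted p never below raw p
  set.seed(10)
  rel <- matrix(abs(rnorm(12 * 8, 0.2, 0.1)), 12, 8,
                dimnames = list(md$sample, paste0("t", 1:8)))
  rel <- rel / rowSums(rel)
  da <- differential_abundance(rel, md, "chinstrap")
  expect_true(all(da$p_adj >= da$p - 1e-12, na.rm = TRUE))
})

test_that("group_ellipses: centroids, zero-SD groups, isotropic clouds", {
  md <- toy_metadata(c(4, 3, 3, 5))
  sc <- matrix(rnorm(30), 15, 2, dimnames = list(md$sample, NULL))
  sc[1:4, ] <- matrix(c(2, 3), 4, 2, byrow = TRUE)  # identical points
  ell <- group_ellipses(sc, md)
  cf <- ell[ell$group == "chinstrap.feeding", ]
  expect_equal(c(cf$centroid_1, cf$centroid_2), c(2, 3))
  expect_equal(c(cf$sd_1, cf$sd_2), c(0, 0))
  expect_equal(ell$centroid_1[ell$group == "gentoo.moulting"],
               mean(sc[11:15, 1]))

  # isotropic gaussian: both axis SDs near sigma at n = 1000
  set.seed(11)
  big_md <- sample_metadata(sprintf("B%04d", 1:1000), rep("gentoo", 1000),
                            rep("feeding", 1000))
  cloud <- matrix(rnorm(2000, 0, 0.7), 1000, 2,
                  dimnames = list(big_md$sample, NULL))
  e2 <- group_ellipses(cloud, big_md)
  expect_lt(abs(e2$sd_1 - 0.7) / 0.7, 0.15)
  expect_lt(abs(e2$sd_2 - 0.7) / 0.7, 0.15)

  md_small <- toy_metadata(c(2, 13, 0, 0))
  expect_warning(group_ellipses(sc, md_small), "skipped")
})
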