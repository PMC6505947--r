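#' Isotonic regression by pool-adjacent-violators
#'
#' Least-squares non-decreasing fit to `e` (already ordered by the observed
#' dissimilarity ranks), the monotone-regression step inside NMDS.
#'
#' @param e numeric vector.
#' @param w optional positive weights (default 1).
#' @return non-decreasing numeric vector of the same length.
#' @export
isotonic_fit <- function(e, w = rep(1, length(e))) {
  n <- length(e)
  .assert(n > 0, "empty input")
  .assert(length(w) == n && all(w > 0), "weights must be positive")
  # blocks as (value, weight, size) triples; pool while a violator remains
  val <- numeric(n); wt <- numeric(n); size <- integer(n)
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    val[nb] <- e[i]; wt[nb] <- w[i]; size[nb] <- 1L
    while (nb > 1L && val[nb - 1L] > val[nb]) {
      wsum <- wt[nb - 1L] + wt[nb]
      val[nb - 1L] <- (wt[nb - 1L] * val[nb - 1L] + wt[nb] * val[nb]) / wsum
      wt[nb - 1L] <- wsum
      size[nb - 1L] <- size[nb - 1L] + size[nb]
      nb <- nb - 1L
    }
  }
  rep.int(val[seq_len(nb)], size[seq_len(nb)])
}

# Kruskal stress-1 machinery.  ord orders pairs by observed dissimilarity;
# tie_grp holds the tie-block id per ordered position.  Within a tie block the
# fitted values need not follow the configuration order (Kruskal's primary
# approach), implemented by re-sorting the configuration distances within each
# block before the monotone fit.
.stress_parts <- function(par, n, k, ord, tie_grp) {
  X <- matrix(par, n, k)
  e <- as.vector(dist(X))
  perm <- ord
  for (g in unique(tie_grp[duplicated(tie_grp)])) {
    idx <- which(tie_grp == g)
    perm[idx] <- ord[idx][order(e[ord[idx]])]
  }
  dhat_o <- isotonic_fit(e[perm])
  dhat <- numeric(length(e))
  dhat[perm] <- dhat_o
  ss <- sum(e^2)
  stress <- if (ss == 0) 1 else sqrt(sum((dhat - e)^2) / ss)
  list(X = X, e = e, dhat = dhat, ss = ss, stress = stress)
}

.stress1 <- function(par, n, k, ord, tie_grp, ii, jj) {
  .stress_parts(par, n, k, ord, tie_grp)$stress
}

# analytic gradient with the monotone fit held fixed (Kruskal's scheme):
# dS/de = ((e - dhat) - S^2 e) / (S * sum(e^2)); de/dx follows the chain rule
.stress1_gr <- function(par, n, k, ord, tie_grp, ii, jj) {
  sp <- .stress_parts(par, n, k, ord, tie_grp)
  if (sp$ss == 0 || sp$stress == 0) return(numeric(length(par)))
  g_e <- ((sp$e - sp$dhat) - sp$stress^2 * sp$e) / (sp$stress * sp$ss)
  coef <- ifelse(sp$e > 0, g_e / sp$e, 0)
  diffs <- (sp$X[ii, , drop = FALSE] - sp$X[jj, , drop = FALSE]) * coef
  dX <- matrix(0, n, k)
  add_i <- rowsum(diffs, ii)
  add_j <- rowsum(diffs, jj)
  dX[as.integer(rownames(add_i)), ] <- dX[as.integer(rownames(add_i)), ] +
    add_i
  dX[as.integer(rownames(add_j)), ] <- dX[as.integer(rownames(add_j)), ] -
    add_j
  as.vector(dX)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Minimizes stress-1 = sqrt(sum (dhat - e)^2 / sum e^2), where `e` are
#' configuration distances and `dhat` their isotonic regression on the
#' observed dissimilarity ranks, over `n_starts` starting configurations (one
#' metric start from classical scaling plus random starts).  The best
#' configuration is centred and rotated to its principal axes.
#'
#' @param d a [dist_matrix()].
#' @param k embedding dimension (default 2).
#' @param n_starts number of starts (default 20).
#' @param max_iter maximum optimizer iterations per start (default 300).
#' @param tol relative stress-change convergence tolerance (default 1e-7).
#' @param seed integer seed for the random starts.
#' @return an `nmds_result` list: `scores` (n x k matrix), `stress`,
#'   `converged`, `n_starts_used`.
#' @export
nmds <- function(d, k = 2L, n_starts = 20L, max_iter = 300L, tol = 1e-7,
                 seed = 1L) {
  .assert(inherits(d, "dist_matrix"), "d must be a dist_matrix")
  n <- nrow(d)
  .assert(n >= k + 1, "need at least k+1 samples")
  dv <- unclass(d)[lower.tri(d)]
  degenerate <- diff(range(dv)) < 1e-12
  ord <- order(dv)
  tie_grp <- cumsum(c(1, diff(dv[ord]) > 1e-12))
  # pair indices in dist() element order: (i, j), i > j, column-wise
  jj <- rep.int(seq_len(n - 1), (n - 1):1)
  ii <- unlist(lapply(seq_len(n - 1), function(j) seq.int(j + 1, n)))

  cmd <- suppressWarnings(cmdscale(unclass(d), k = k))
  if (ncol(cmd) < k) cmd <- cbind(cmd, matrix(0, n, k - ncol(cmd)))
  if (degenerate) {
    warning("all dissimilarities equal; configuration is arbitrary")
    scores <- scale(cmd, scale = FALSE)
    dimnames(scores) <- list(rownames(d), paste0("NMDS", seq_len(k)))
    return(structure(list(scores = scores,
                          stress = .stress1(as.vector(cmd), n, k, ord,
                                            tie_grp, ii, jj),
                          converged = FALSE, n_starts_used = 0L),
                     class = "nmds_result"))
  }

  set.seed(substream_seed(seed, "nmds"))
  best <- NULL
  scale0 <- mean(dv)
  for (s in seq_len(n_starts)) {
    par0 <- if (s == 1) as.vector(cmd) else rnorm(n * k, 0, scale0)
    fit <- optim(par0, .stress1, .stress1_gr, n = n, k = k, ord = ord,
                 tie_grp = tie_grp, ii = ii, jj = jj, method = "BFGS",
                 control = list(maxit = max_iter, reltol = tol))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  X <- matrix(best$par, n, k)
  X <- scale(X, scale = FALSE)
  if (k > 1) X <- X %*% svd(X)$v   # principal-axis rotation
  dimnames(X) <- list(rownames(d), paste0("NMDS", seq_len(k)))
  structure(list(scores = X, stress = best$value,
                 converged = best$convergence == 0L,
                 n_starts_used = as.integer(n_starts)),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points, k = %d, stress = %.4f (%s, %d starts)\n",
              nrow(x$scores), ncol(x$scores), x$stress,
              if (x$converged) "converged" else "not converged",
              x$n_starts_used))
  invisible(x)
}

#' Per-group standard-deviation ellipses in ordination space
#'
#' For each group with at least 3 samples: the centroid (coordinate-wise
#' mean), the 1-SD half-axis lengths (square roots of the covariance
#' eigenvalues) and the orientation (first principal axis angle, radians).
#'
#' @param res an [nmds()] result (or any matrix of scores).
#' @param meta a [sample_metadata()] covering the scored samples.
#' @return data frame: group, centroid per axis, sd per axis, angle, n.
#' @export
group_ellipses <- function(res, meta) {
  scores <- if (inherits(res, "nmds_result")) res$scores else as.matrix(res)
  k <- ncol(scores)
  .check_ids(rownames(scores), meta$sample, "metadata for sample(s)")
  grp <- group_labels(meta)[rownames(scores)]
  out <- list()
  for (g in sort(unique(grp))) {
    pts <- scores[grp == g, , drop = FALSE]
    if (nrow(pts) < 3) {
      warning(sprintf("group '%s' has < 3 samples; ellipse skipped", g))
      next
    }
    ctr <- colMeans(pts)
    eg <- eigen(cov(pts), symmetric = TRUE)
    sds <- sqrt(pmax(eg$values, 0))
    ang <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
    row <- data.frame(group = g, t(ctr), t(sds), angle = ang, n = nrow(pts),
                      stringsAsFactors = FALSE)
    names(row) <- c("group", paste0("centroid_", seq_len(k)),
                    paste0("sd_", seq_len(k)), "angle", "n")
    out[[g]] <- row
  }
  .assert(length(out) > 0, "no group with >= 3 samples")
  do.call(rbind, c(out, make.row.names = FALSE))
}
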