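# dummy-coded design columns for one factor (treatment contrasts, no intercept)
.factor_dummies <- function(f) {
  lev <- levels(f)
  .assert(length(lev) >= 2, "factor with a single level")
  X <- vapply(lev[-1], function(l) as.numeric(f == l), numeric(length(f)))
  matrix(X, nrow = length(f))
}

#' Permutational multivariate ANOVA (two crossed factors with interaction)
#'
#' Distance-based linear model in the Anderson style: the squared
#' dissimilarity matrix is Gower-centred into an inner-product matrix `G`, and
#' sequential (Type I) sums of squares are obtained by projecting `G` on the
#' nested factor designs in the order given by `terms`, then the interaction.
#' `pseudo-F = MS_term / MS_residual`; p-values come from unrestricted
#' permutation of sample rows with the add-one convention
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`, so the smallest attainable
#' p at 999 permutations is 0.001.
#'
#' @param d a [dist_matrix()].
#' @param meta a [sample_metadata()] covering the samples in `d`.
#' @param terms main-effect factor names, columns of `meta` (default
#'   species then stage; Type I order matters for unbalanced designs).
#' @param interaction include the two-way interaction (default `TRUE`;
#'   ignored when a single term is given).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return a `permanova_table` data frame: Source, df, SS, MS, pseudo_F, p.
#' @export
permanova <- function(d, meta, terms = c("species", "stage"),
                      interaction = TRUE, n_perm = 999L, seed = 1L) {
  .assert(inherits(d, "dist_matrix"), "d must be a dist_matrix")
  .assert(n_perm >= 1, "n_perm must be >= 1")
  .check_ids(rownames(d), meta$sample, "metadata for sample(s)")
  n <- nrow(d)
  idx <- match(rownames(d), meta$sample)
  facs <- lapply(terms, function(tm) {
    .assert(tm %in% names(meta), paste0("unknown term: ", tm))
    droplevels(factor(meta[[tm]][idx]))
  })
  names(facs) <- terms
  use_int <- interaction && length(terms) == 2

  # Gower-centred inner-product matrix: G = -(1/2) C d^2 C
  A <- -0.5 * unclass(d)^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  ss_total <- sum(diag(G))

  # sequential projections
  dummies <- lapply(facs, .factor_dummies)
  if (use_int) {
    Xa <- dummies[[1]]; Xb <- dummies[[2]]
    Xab <- matrix(apply(expand.grid(seq_len(ncol(Xa)), seq_len(ncol(Xb))), 1,
                        function(ij) Xa[, ij[1]] * Xb[, ij[2]]), nrow = n)
    dummies <- c(dummies, list(Xab))
    names(dummies)[length(dummies)] <- paste(terms, collapse = " x ")
  }
  proj <- function(X) {
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  cum_X <- matrix(1, n, 1)
  H_prev <- proj(cum_X)
  Hdiff <- list(); dfs <- integer(0)
  for (j in seq_along(dummies)) {
    cum_X <- cbind(cum_X, dummies[[j]])
    H_cur <- proj(cum_X)
    Hdiff[[j]] <- H_cur - H_prev
    dfs[j] <- qr(cum_X)$rank - sum(dfs) - 1L
    H_prev <- H_cur
  }
  R <- diag(n) - H_prev                      # residual projector
  df_res <- n - 1L - sum(dfs)
  .assert(df_res >= 1, "no residual degrees of freedom")

  term_ss <- function(Gm) vapply(Hdiff, function(H) sum(H * Gm), numeric(1))
  ss_obs <- term_ss(G)
  ss_res <- sum(R * G)
  F_obs <- (ss_obs / dfs) / (ss_res / df_res)

  set.seed(substream_seed(seed, "permanova"))
  exceed <- numeric(length(F_obs))
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    Gp <- G[p, p]
    ssp <- term_ss(Gp)
    Fp <- (ssp / dfs) / (sum(R * Gp) / df_res)
    exceed <- exceed + (Fp >= F_obs - 1e-12)
  }
  pvals <- (1 + exceed) / (1 + n_perm)

  src <- c(names(dummies), "Residual", "Total")
  out <- data.frame(Source = src,
                    df = c(dfs, df_res, n - 1L),
                    SS = c(ss_obs, ss_res, ss_total),
                    MS = c(ss_obs / dfs, ss_res / df_res, NA),
                    pseudo_F = c(F_obs, NA, NA),
                    p = c(pvals, NA, NA),
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- as.integer(n_perm)
  class(out) <- c("permanova_table", "data.frame")
  out
}

#' Welch's two-sample t-test
#'
#' `t = (mean(x) - mean(y)) / sqrt(s2x/n1 + s2y/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value from the t distribution.
#'
#' @param x,y numeric vectors, each with at least 2 values.
#' @return list: `t`, `df`, `p`, `mean_diff`.
#' @export
welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  .assert(n1 >= 2 && n2 >= 2, "need >= 2 observations per group")
  v1 <- var(x); v2 <- var(y)
  md <- mean(x) - mean(y)
  if (v1 == 0 && v2 == 0) {
    .assert(md == 0, "both groups have zero variance and unequal means")
    return(list(t = 0, df = n1 + n2 - 2, p = 1, mean_diff = 0))
  }
  se2 <- v1 / n1 + v2 / n2
  tstat <- md / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df), mean_diff = md)
}

#' Per-taxon differential relative abundance between stages within a species
#'
#' Welch t-tests on per-sample proportions (feeding vs moulting) for every
#' taxon of a rank-aggregated table, with Benjamini-Hochberg correction.
#' Taxa present in fewer than `min_prevalence` of the species' samples are
#' skipped (reported in the `tested` column).
#'
#' @param rel matrix of per-sample proportions (samples x taxa), e.g.
#'   [relative_abundance()] of an [aggregate_taxonomy()] table.
#' @param meta a [sample_metadata()].
#' @param species which species to test within (`"chinstrap"` or `"gentoo"`).
#' @param min_prevalence minimum fraction of samples with the taxon present
#'   (default 0.25).
#' @return data frame: taxon, mean_feeding, mean_moulting, t, df, p, p_adj,
#'   tested.
#' @export
differential_abundance <- function(rel, meta, species = "chinstrap",
                                   min_prevalence = 0.25) {
  .assert(species %in% c("chinstrap", "gentoo"), "unknown species")
  .check_ids(rownames(rel), meta$sample, "metadata for sample(s)")
  md <- meta[match(rownames(rel), meta$sample), ]
  in_sp <- md$species == species
  .assert(sum(in_sp & md$stage == "feeding") >= 2 &&
          sum(in_sp & md$stage == "moulting") >= 2,
          "need >= 2 samples per stage within the species")
  sub <- rel[in_sp, , drop = FALSE]
  stage <- md$stage[in_sp]
  res <- lapply(colnames(sub), function(tx) {
    v <- sub[, tx]
    tested <- mean(v > 0) >= min_prevalence
    x <- v[stage == "feeding"]; y <- v[stage == "moulting"]
    if (!tested || (var(x) == 0 && var(y) == 0 && mean(x) != mean(y))) {
      return(data.frame(taxon = tx, mean_feeding = mean(x),
                        mean_moulting = mean(y), t = NA_real_, df = NA_real_,
                        p = NA_real_, tested = FALSE,
                        stringsAsFactors = FALSE))
    }
    wt <- welch_t(x, y)
    data.frame(taxon = tx, mean_feeding = mean(x), mean_moulting = mean(y),
               t = wt$t, df = wt$df, p = wt$p, tested = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  out$p_adj[out$tested] <- p.adjust(out$p[out$tested], method = "BH")
  out
}
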