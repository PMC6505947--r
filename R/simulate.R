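#' Regional species pool (metacommunity)
#'
#' Relative abundances follow a configurable power-law rank-abundance curve,
#' `p_r` proportional to `r^-rank_exponent`, giving the strong unevenness
#' typical of gut communities dominated by a handful of taxa.
#'
#' @param n_taxa number of taxa in the pool.
#' @param rank_exponent skew of the rank-abundance curve (default 1.2; 0 =
#'   even pool).
#' @param taxon_ids optional ids (default `Otu0001..`).
#' @return a `metacommunity` list with `taxon_ids`, `abundance` (simplex
#'   vector) and `occupancy` weights.
#' @export
metacommunity <- function(n_taxa, rank_exponent = 1.2,
                          taxon_ids = sprintf("Otu%04d", seq_len(n_taxa))) {
  .assert(n_taxa >= 1, "need at least one taxon")
  .assert(rank_exponent >= 0, "rank_exponent must be >= 0")
  p <- seq_len(n_taxa)^(-rank_exponent)
  p <- p / sum(p)
  structure(list(taxon_ids = as.character(taxon_ids), abundance = p,
                 occupancy = p), class = "metacommunity")
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Rooted binary ultrametric tree with `n_tips` labelled tips, simulated under
#' a constant birth rate.  Deterministic given `seed`.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @param tip_ids optional tip labels (default `Otu0001..`).
#' @return an [ape::phylo] tree.
#' @export
simulate_tree <- function(n_tips, seed,
                          tip_ids = sprintf("Otu%04d", seq_len(n_tips))) {
  .assert(n_tips >= 2, "n_tips must be >= 2")
  set.seed(substream_seed(seed, "tree"))
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- as.character(tip_ids)
  tree$edge.length <- pmax(tree$edge.length, 1e-8)  # strictly positive
  tree
}

#' Evolve a continuous trait by Brownian motion along a tree
#'
#' Root value 0; each child value is the parent value plus a
#' `Normal(0, sigma^2 * branch_length)` increment.  The resulting tip values
#' carry phylogenetic signal by construction: close relatives have similar
#' niches, which is the premise that makes selection detectable by betaNTI.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param sigma Brownian rate (>= 0), trait units per sqrt(branch length).
#' @param seed integer seed.
#' @return named numeric vector of tip trait values.
#' @export
evolve_trait <- function(tree, sigma, seed) {
  .assert(sigma >= 0, "sigma must be >= 0")
  set.seed(substream_seed(seed, "trait"))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  val <- numeric(n_node)
  # preorder over edges: parents are assigned before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  incr <- rnorm(nrow(ord$edge), 0, sigma * sqrt(ord$edge.length))
  for (e in seq_len(nrow(ord$edge))) {
    val[ord$edge[e, 2]] <- val[ord$edge[e, 1]] + incr[e]
  }
  setNames(val[seq_len(n_tip)], tree$tip.label)
}

# per-sample multinomial draw, optionally with host-level Dirichlet
# overdispersion: finite `dispersion` perturbs the sampling probabilities as
# p ~ Dirichlet(dispersion * w) before the multinomial, modelling the
# compositional drift between individual hosts; Inf = pure multinomial.
.draw_community <- function(w, depth, dispersion) {
  w <- w / sum(w)
  if (is.finite(dispersion)) {
    w <- rgamma(length(w), shape = dispersion * w)
    if (sum(w) == 0) w[] <- 1
    w <- w / sum(w)
  }
  rmultinom(1, depth, w)[, 1]
}

#' Neutral (drift-dominated) community table
#'
#' Each sample is an independent multinomial draw of `depth` reads from the
#' metacommunity relative abundances: purely stochastic assembly.  A finite
#' `dispersion` adds host-level compositional drift by drawing each sample's
#' probabilities from `Dirichlet(dispersion * abundance)` first; the default
#' (`Inf`) is the pure multinomial model.
#'
#' @param meta a [metacommunity()].
#' @param n_samples number of samples.
#' @param depth reads per sample.
#' @param seed integer seed.
#' @param dispersion Dirichlet concentration for host-level overdispersion
#'   (default `Inf` = none).
#' @param sample_ids optional sample ids.
#' @return an [otu_table()].
#' @export
simulate_neutral <- function(meta, n_samples, depth, seed, dispersion = Inf,
                             sample_ids = sprintf("S%02d", seq_len(n_samples))) {
  .assert(inherits(meta, "metacommunity"), "meta must be a metacommunity")
  .assert(length(meta$taxon_ids) >= 1, "empty metacommunity")
  .assert(depth >= 1, "depth must be >= 1")
  set.seed(substream_seed(seed, "neutral"))
  counts <- t(vapply(seq_len(n_samples),
                     function(i) .draw_community(meta$abundance, depth,
                                                 dispersion),
                     integer(length(meta$taxon_ids))))
  dimnames(counts) <- list(sample_ids, meta$taxon_ids)
  otu_table(counts)
}

#' Selection-structured community table (environmental filtering)
#'
#' Sample `i` with environment `env[i]` draws `depth` reads multinomially with
#' per-taxon weight `meta_t * exp(-(trait_t - env_i)^2 / (2 sigma_f^2))`,
#' renormalized: a Gaussian niche filter of width `sigma_f` over a
#' phylogenetically conserved trait.  Identical `env` across samples gives the
#' homogeneous-selection regime; divergent `env` gives variable selection.
#'
#' @param meta a [metacommunity()] (taxa must match `traits` names).
#' @param traits named trait vector from [evolve_trait()].
#' @param env numeric vector, one environment value per sample.
#' @param sigma_f niche filter width (> 0).
#' @param depth reads per sample.
#' @param seed integer seed.
#' @param dispersion host-level Dirichlet overdispersion (default `Inf`).
#' @param sample_ids optional sample ids.
#' @return an [otu_table()].
#' @export
simulate_selection <- function(meta, traits, env, sigma_f, depth, seed,
                               dispersion = Inf,
                               sample_ids = sprintf("S%02d", seq_along(env))) {
  .assert(sigma_f > 0, "sigma_f must be > 0")
  .check_ids(meta$taxon_ids, names(traits), "trait for taxon(s)")
  tr <- traits[meta$taxon_ids]
  set.seed(substream_seed(seed, "selection"))
  counts <- matrix(0L, length(env), length(tr),
                   dimnames = list(sample_ids, meta$taxon_ids))
  for (i in seq_along(env)) {
    w <- meta$abundance * exp(-(tr - env[i])^2 / (2 * sigma_f^2))
    .assert(sum(w) > 0,
            sprintf("degenerate filter: env %.3g too far from all traits",
                    env[i]))
    counts[i, ] <- .draw_community(w, depth, dispersion)
  }
  otu_table(counts)
}

#' Dispersal-limited community table (patch structure)
#'
#' Taxa are partitioned into `n_patches` disjoint subpools; each sample is
#' assigned a patch (round-robin) and draws reads from a mixture
#' `patch_mix * metacommunity + (1 - patch_mix) * patch-restricted pool`.
#' `patch_mix = 1` recovers neutral sampling; `patch_mix = 0` is fully
#' patch-restricted, driving between-patch Bray-Curtis towards 1.
#'
#' @param meta a [metacommunity()].
#' @param n_patches number of disjoint patches (>= 1).
#' @param patch_mix mixing weight in `[0, 1]` towards the full pool.
#' @param n_samples number of samples.
#' @param depth reads per sample.
#' @param seed integer seed.
#' @param dispersion host-level Dirichlet overdispersion (default `Inf`).
#' @param sample_ids optional sample ids.
#' @return an [otu_table()] with a `"patch"` attribute giving each sample's
#'   patch index.
#' @export
simulate_dispersal_limited <- function(meta, n_patches, patch_mix, n_samples,
                                       depth, seed, dispersion = Inf,
                                       sample_ids = sprintf("S%02d",
                                                            seq_len(n_samples))) {
  .assert(n_patches >= 1, "n_patches must be >= 1")
  .assert(patch_mix >= 0 && patch_mix <= 1, "patch_mix must be in [0, 1]")
  n_taxa <- length(meta$taxon_ids)
  .assert(n_patches <= n_taxa, "more patches than taxa")
  set.seed(substream_seed(seed, "dispersal"))
  patch_of_taxon <- rep_len(seq_len(n_patches), n_taxa)[sample.int(n_taxa)]
  for (p in seq_len(n_patches)) {
    .assert(any(patch_of_taxon == p), "patch with zero taxa")
  }
  patch_of_sample <- rep_len(seq_len(n_patches), n_samples)
  counts <- matrix(0L, n_samples, n_taxa,
                   dimnames = list(sample_ids, meta$taxon_ids))
  for (i in seq_len(n_samples)) {
    in_patch <- patch_of_taxon == patch_of_sample[i]
    local <- meta$abundance * in_patch
    local <- local / sum(local)
    w <- patch_mix * meta$abundance + (1 - patch_mix) * local
    counts[i, ] <- .draw_community(w, depth, dispersion)
  }
  out <- otu_table(counts)
  attr(out, "patch") <- setNames(patch_of_sample, sample_ids)
  out
}

#' Scenario configuration for a synthetic 2x2 study
#'
#' Defaults emulate a two-penguin-species, feeding-vs-moulting design with
#' group sizes 7/6/7/5, 500 taxa and 20,000 reads per sample (above the
#' default 13,415 rarefaction depth so the subsampling stage is exercised).
#' Feeding groups default to the `variable_selection` regime (divergent
#' environments, narrow niche filter); moulting groups default to `neutral`.
#'
#' @param n_per_group named integer vector of group sizes in the order
#'   chinstrap.feeding, chinstrap.moulting, gentoo.feeding, gentoo.moulting.
#' @param n_taxa taxa in the regional pool.
#' @param depth reads per sample.
#' @param regimes named character vector per group, each one of `neutral`,
#'   `variable_selection`, `homogeneous_selection`, `dispersal_limited`.
#' @param trait_sigma Brownian rate of the niche trait.
#' @param sigma_f niche filter width (trait units).
#' @param env_spread half-width of the environment gradient used by
#'   variable-selection groups, as a multiple of the tip-trait SD.
#' @param rank_exponent metacommunity skew (see [metacommunity()]).
#' @param n_patches,patch_mix dispersal-limited regime parameters.
#' @param host_dispersion Dirichlet concentration for between-host
#'   compositional drift, applied to every sample regardless of regime
#'   (default 100, giving within-group Bray-Curtis around 0.4 as seen in real
#'   faecal microbiota; `Inf` disables it).
#' @param seed master integer seed.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n_per_group = c(chinstrap.feeding = 7L,
                                            chinstrap.moulting = 6L,
                                            gentoo.feeding = 7L,
                                            gentoo.moulting = 5L),
                            n_taxa = 500L, depth = 20000L,
                            regimes = c(chinstrap.feeding = "variable_selection",
                                        chinstrap.moulting = "neutral",
                                        gentoo.feeding = "variable_selection",
                                        gentoo.moulting = "neutral"),
                            trait_sigma = 1, sigma_f = 0.4, env_spread = 1.5,
                            rank_exponent = 1.2, n_patches = 4L,
                            patch_mix = 0, host_dispersion = 100,
                            seed = 1L) {
  groups <- c("chinstrap.feeding", "chinstrap.moulting",
              "gentoo.feeding", "gentoo.moulting")
  .check_ids(groups, names(n_per_group), "group size(s)")
  .check_ids(groups, names(regimes), "regime(s)")
  .assert(all(n_per_group >= 1), "group sizes must be positive")
  allowed <- c("neutral", "variable_selection", "homogeneous_selection",
               "dispersal_limited")
  bad <- setdiff(regimes, allowed)
  .assert(length(bad) == 0, paste0("unknown regime(s): ",
                                   paste(bad, collapse = ", ")))
  .assert(n_taxa >= 2 && depth >= 1 && trait_sigma >= 0 && sigma_f > 0,
          "invalid scenario parameters")
  structure(list(n_per_group = as.integer(n_per_group[groups]),
                 groups = groups, n_taxa = as.integer(n_taxa),
                 depth = as.integer(depth), regimes = regimes[groups],
                 trait_sigma = trait_sigma, sigma_f = sigma_f,
                 env_spread = env_spread, rank_exponent = rank_exponent,
                 n_patches = as.integer(n_patches), patch_mix = patch_mix,
                 host_dispersion = host_dispersion, seed = as.integer(seed)),
            class = "scenario_config")
}

# assign pseudo-taxonomy by cutting an ultrametric tree at increasing depths
.clade_taxonomy <- function(tree) {
  n_tip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)   # distance from root
  total <- max(depths[seq_len(n_tip)])
  ranks <- c("phylum", "class", "order", "family", "genus")
  fracs <- c(0.15, 0.30, 0.45, 0.60, 0.75)     # cut times as root fraction
  lineage <- matrix("unclassified", n_tip, 6)
  lineage[, 1] <- "Bacteria"
  for (r in seq_along(ranks)) {
    cut_t <- fracs[r] * total
    # clade id per tip: the most rootward ancestor whose depth exceeds cut_t;
    # iterative preorder to avoid deep recursion on big trees
    grp <- integer(n_tip)
    counter <- 0L
    root <- n_tip + 1L
    stack <- list(list(node = root, crossed = FALSE))
    while (length(stack)) {
      fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      node <- fr$node; crossed <- fr$crossed
      if (isFALSE(crossed) && depths[node] >= cut_t) {
        counter <- counter + 1L
        crossed <- counter
      }
      if (node <= n_tip) {
        grp[node] <- if (isFALSE(crossed)) { counter <- counter + 1L; counter
                     } else crossed
      } else {
        for (child in tree$edge[tree$edge[, 1] == node, 2]) {
          stack[[length(stack) + 1L]] <- list(node = child, crossed = crossed)
        }
      }
    }
    lineage[, r + 1] <- sprintf("%s%03d", c("Phy", "Cls", "Ord", "Fam",
                                            "Gen")[r], grp)
  }
  taxonomy_map(tree$tip.label, lineage)
}

#' Simulate a full 2x2 synthetic study
#'
#' Generates one phylogeny and metacommunity, evolves a niche trait, then
#' simulates each group's samples under its configured assembly regime and
#' assembles consistent outputs: one OTU table over all samples, the tree,
#' per-sample metadata, and a pseudo-taxonomy obtained by clading the tree.
#'
#' @param cfg a [scenario_config()].
#' @return list with elements `table` ([otu_table()]), `tree` (phylo),
#'   `metadata` ([sample_metadata()]), `taxonomy` ([taxonomy_map()]),
#'   `traits`, `env` (named per-sample environment values).
#' @export
simulate_study <- function(cfg) {
  .assert(inherits(cfg, "scenario_config"), "cfg must be a scenario_config")
  meta_pool <- metacommunity(cfg$n_taxa, cfg$rank_exponent)
  tree <- simulate_tree(cfg$n_taxa, cfg$seed, meta_pool$taxon_ids)
  traits <- evolve_trait(tree, cfg$trait_sigma, cfg$seed)
  trait_sd <- sd(traits)
  trait_mid <- stats::median(traits)

  tabs <- list(); metas <- list(); envs <- list()
  for (g in seq_along(cfg$groups)) {
    grp <- cfg$groups[g]
    n_g <- cfg$n_per_group[g]
    ids <- sprintf("%s_%02d", gsub("\\.", "_", grp), seq_len(n_g))
    gseed <- substream_seed(cfg$seed, paste0("group/", grp))
    regime <- cfg$regimes[[g]]
    if (regime == "neutral") {
      tab <- simulate_neutral(meta_pool, n_g, cfg$depth, gseed,
                              cfg$host_dispersion, ids)
      env <- rep(NA_real_, n_g)
    } else if (regime == "variable_selection") {
      # divergent environments: evenly spaced across the trait gradient
      env <- trait_mid + seq(-1, 1, length.out = n_g) * cfg$env_spread * trait_sd
      tab <- simulate_selection(meta_pool, traits, env, cfg$sigma_f * trait_sd,
                                cfg$depth, gseed, cfg$host_dispersion, ids)
    } else if (regime == "homogeneous_selection") {
      env <- rep(trait_mid, n_g)
      tab <- simulate_selection(meta_pool, traits, env, cfg$sigma_f * trait_sd,
                                cfg$depth, gseed, cfg$host_dispersion, ids)
    } else {  # dispersal_limited
      tab <- simulate_dispersal_limited(meta_pool, cfg$n_patches,
                                        cfg$patch_mix, n_g, cfg$depth, gseed,
                                        cfg$host_dispersion, ids)
      env <- rep(NA_real_, n_g)
    }
    sp_st <- strsplit(grp, ".", fixed = TRUE)[[1]]
    tabs[[grp]] <- unclass(tab)[, meta_pool$taxon_ids, drop = FALSE]
    metas[[grp]] <- data.frame(sample = ids, species = sp_st[1],
                               stage = sp_st[2], stringsAsFactors = FALSE)
    envs[[grp]] <- setNames(env, ids)
  }
  counts <- do.call(rbind, tabs)
  md <- do.call(rbind, metas)
  list(table = otu_table(counts),
       tree = tree,
       metadata = sample_metadata(md$sample, md$species, md$stage),
       taxonomy = .clade_taxonomy(tree),
       traits = traits,
       env = unlist(unname(envs)))
}
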