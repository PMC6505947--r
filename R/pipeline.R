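#' Pipeline configuration
#'
#' Exactly one of `inputs` (paths to shared/tree/taxonomy/metadata files) or
#' `scenario` (a [scenario_config()] to simulate) must be given.  Defaults:
#' rarefaction depth 13,415 reads, 999 permutations and 999 null iterations,
#' classification thresholds 2 (betaNTI) and 0.95 (RC-bray).
#'
#' @param inputs named list with elements `shared`, `tree`, `taxonomy`,
#'   `metadata` (file paths), or `NULL`.
#' @param scenario a [scenario_config()], or `NULL`.
#' @param depth rarefaction depth.
#' @param n_perm PERMANOVA permutations.
#' @param n_null null-model iterations for betaNTI and RC-bray.
#' @param th_bnti,th_rc process-classification thresholds.
#' @param log_base Shannon log base ("e" or "2").
#' @param seed master seed; all stages derive substreams from it.
#' @param outdir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(inputs = NULL, scenario = NULL, depth = 13415L,
                            n_perm = 999L, n_null = 999L, th_bnti = 2,
                            th_rc = 0.95, log_base = "e", seed = 1L,
                            outdir = "penguinproc_out") {
  .assert(xor(is.null(inputs), is.null(scenario)),
          "give exactly one of inputs or scenario")
  if (!is.null(inputs)) {
    .check_ids(c("shared", "tree", "taxonomy", "metadata"), names(inputs),
               "input path(s)")
  }
  .assert(depth > 0 && n_perm >= 1 && n_null >= 2 && th_bnti > 0 &&
          th_rc > 0, "numeric parameters must be positive")
  structure(list(inputs = inputs, scenario = scenario,
                 depth = as.integer(depth), n_perm = as.integer(n_perm),
                 n_null = as.integer(n_null), th_bnti = th_bnti,
                 th_rc = th_rc, log_base = log_base, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Cross-check the four pipeline inputs
#'
#' Reports taxa missing from the tree or taxonomy, samples missing metadata
#' (all fatal) and tree tips absent from the table (pruned downstream, a
#' warning only), plus the per-group sample counts.
#'
#' @param table an [otu_table()].
#' @param tree an [ape::phylo] tree.
#' @param tax a [taxonomy_map()].
#' @param meta a [sample_metadata()].
#' @return list: `fatal` (character vector of fatal problems, empty when
#'   consistent), `warnings`, `group_sizes`.
#' @export
validate_inputs <- function(table, tree, tax, meta) {
  fatal <- character(0); warns <- character(0)
  miss_tree <- setdiff(colnames(table), tree$tip.label)
  if (length(miss_tree)) {
    fatal <- c(fatal, paste0("taxa missing from tree: ",
                             paste(head(miss_tree, 5), collapse = ", ")))
  }
  miss_tax <- setdiff(colnames(table), tax$taxon)
  if (length(miss_tax)) {
    fatal <- c(fatal, paste0("taxa missing from taxonomy: ",
                             paste(head(miss_tax, 5), collapse = ", ")))
  }
  miss_meta <- setdiff(rownames(table), meta$sample)
  if (length(miss_meta)) {
    fatal <- c(fatal, paste0("samples missing metadata: ",
                             paste(head(miss_meta, 5), collapse = ", ")))
  }
  extra_tips <- setdiff(tree$tip.label, colnames(table))
  if (length(extra_tips)) {
    warns <- c(warns, sprintf("%d tree tip(s) not in table will be pruned",
                              length(extra_tips)))
  }
  gs <- table(group_labels(meta))
  list(fatal = fatal, warnings = warns,
       group_sizes = setNames(as.integer(gs), names(gs)))
}

#' Run the full analysis pipeline
#'
#' simulate/read -> validate -> singleton removal -> rarefaction ->
#' (Hellinger + Bray-Curtis -> NMDS + ellipses + PERMANOVA),
#' (Shannon + Welch tests), (rank aggregation + differential abundance),
#' (betaNTI + RC-bray -> pair classification -> process summary).
#' All outputs are tab-separated text in `cfg$outdir`; a JSON manifest
#' records parameters, versions, per-stage dimensions and dropped samples.
#' Identical config and seed give byte-identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest, invisibly (list).
#' @export
run_pipeline <- function(cfg) {
  .assert(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # ---- inputs ----
  if (!is.null(cfg$scenario)) {
    study <- stage("simulate", simulate_study(cfg$scenario))
  } else {
    study <- stage("read", list(
      table = read_shared(cfg$inputs$shared),
      tree = read_newick(cfg$inputs$tree),
      taxonomy = read_taxonomy(cfg$inputs$taxonomy),
      metadata = read_metadata(cfg$inputs$metadata)))
  }
  rep0 <- validate_inputs(study$table, study$tree, study$taxonomy,
                          study$metadata)
  .assert(length(rep0$fatal) == 0,
          paste0("input validation failed: ",
                 paste(rep0$fatal, collapse = "; ")))
  for (w in rep0$warnings) warning(w)
  log_stage("inputs", "%d samples x %d taxa; groups: %s",
            nrow(study$table), ncol(study$table),
            paste(sprintf("%s=%d", names(rep0$group_sizes),
                          rep0$group_sizes), collapse = ", "))

  # ---- preprocessing ----
  tab1 <- stage("singletons", remove_singletons(study$table))
  n_singletons <- ncol(study$table) - ncol(tab1)
  dropped <- character(0)
  tab2 <- stage("rarefy", withCallingHandlers(
    rarefy(tab1, cfg$depth, cfg$seed),
    warning = function(w) {
      dropped <<- c(dropped, conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  meta2 <- study$metadata[study$metadata$sample %in% rownames(tab2), ]
  log_stage("preprocess", "removed %d singleton(s); rarefied to %d (%d of %d samples kept)",
            n_singletons, cfg$depth, nrow(tab2), nrow(tab1))

  out <- function(f) file.path(cfg$outdir, f)
  files <- character(0)
  emit <- function(name, writer) { writer(out(name)); files <<- c(files, name) }

  # ---- ordination / PERMANOVA ----
  bc <- stage("distance", bray_curtis(hellinger(tab2)))
  emit("bray_curtis.tsv", function(p) write_dist_tsv(bc, p))
  ord <- stage("ordinate", nmds(bc, seed = cfg$seed))
  sc <- data.frame(sample = rownames(ord$scores), ord$scores,
                   stringsAsFactors = FALSE)
  emit("nmds_scores.tsv", function(p) .write_result_tsv(sc, p))
  ell <- stage("ellipses", group_ellipses(ord, meta2))
  emit("nmds_ellipses.tsv", function(p) .write_result_tsv(ell, p))
  pm <- stage("permanova", permanova(bc, meta2, n_perm = cfg$n_perm,
                                     seed = cfg$seed))
  emit("permanova.tsv", function(p) .write_result_tsv(as.data.frame(pm), p))
  log_stage("multivariate", "NMDS stress %.4f; PERMANOVA interaction p = %.3g",
            ord$stress, pm$p[3])

  # ---- diversity ----
  div <- stage("diversity", shannon(tab2, cfg$log_base))
  emit("diversity.tsv", function(p) .write_result_tsv(div, p))
  gl <- group_labels(meta2)[div$sample]
  sp_tests <- lapply(c("chinstrap", "gentoo"), function(sp) {
    x <- div$shannon[gl == paste0(sp, ".feeding")]
    y <- div$shannon[gl == paste0(sp, ".moulting")]
    if (length(x) >= 2 && length(y) >= 2) {
      wt <- welch_t(x, y)
      data.frame(species = sp, t = wt$t, df = wt$df, p = wt$p,
                 mean_feeding = mean(x), mean_moulting = mean(y),
                 stringsAsFactors = FALSE)
    }
  })
  emit("diversity_tests.tsv",
       function(p) .write_result_tsv(do.call(rbind, sp_tests), p))

  # ---- taxonomy / differential abundance ----
  diff_all <- list()
  for (rk in c("phylum", "family")) {
    agg <- stage("aggregate", aggregate_taxonomy(tab2, study$taxonomy, rk))
    gm <- group_mean_abundance(agg, meta2)
    gm_df <- data.frame(group = rownames(gm), gm, check.names = FALSE,
                        stringsAsFactors = FALSE)
    emit(sprintf("abundance_%s.tsv", rk),
         function(p) .write_result_tsv(gm_df, p))
    rel <- relative_abundance(agg)
    for (sp in c("chinstrap", "gentoo")) {
      da <- stage("diffabund", differential_abundance(rel, meta2, sp))
      da <- cbind(data.frame(rank = rk, species = sp,
                             stringsAsFactors = FALSE), da)
      diff_all[[paste(rk, sp)]] <- da
    }
  }
  emit("differential_abundance.tsv",
       function(p) .write_result_tsv(do.call(rbind, c(diff_all,
                                                      make.row.names = FALSE)),
                                     p))

  # ---- assembly processes ----
  bnti <- stage("processes", beta_nti(tab2, study$tree, cfg$n_null,
                                      seed = cfg$seed))
  rc <- stage("processes", raup_crick_bray(tab2, cfg$n_null,
                                           seed = cfg$seed))
  emit("bnti.tsv", function(p) .write_square_tsv(bnti$bnti, p))
  emit("rc.tsv", function(p) .write_square_tsv(rc$rc, p))
  pc <- stage("processes", pair_classes(bnti, rc, meta2, cfg$th_bnti,
                                        cfg$th_rc))
  emit("pair_classes.tsv", function(p) .write_result_tsv(pc, p))
  ps <- stage("processes", summarize_processes(bnti, rc, meta2, cfg$th_bnti,
                                               cfg$th_rc))
  emit("process_summary.tsv",
       function(p) .write_result_tsv(as.data.frame(ps), p))
  log_stage("processes", "%d within-group pairs classified",
            sum(!is.na(pc$group)))

  manifest <- list(
    parameters = list(depth = cfg$depth, n_perm = cfg$n_perm,
                      n_null = cfg$n_null, th_bnti = cfg$th_bnti,
                      th_rc = cfg$th_rc, log_base = cfg$log_base,
                      seed = cfg$seed,
                      simulated = !is.null(cfg$scenario)),
    versions = list(penguinproc = as.character(utils::packageVersion("penguinproc")),
                    r = paste(R.version$major, R.version$minor, sep = ".")),
    dimensions = list(input = dim(study$table), rarefied = dim(tab2)),
    singletons_removed = n_singletons,
    dropped_samples = dropped,
    group_sizes = as.list(rep0$group_sizes),
    nmds_stress = ord$stress,
    files = files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
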