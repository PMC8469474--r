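# Result-table writer: every output carries the run seed and settings in
# comment lines above the header so a table is self-describing.
write_result <- function(df, path, seed, note = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed: ", seed), con)
  if (!is.null(note)) writeLines(paste0("# ", note), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_matrix_result <- function(m, path, seed, note = NULL) {
  df <- data.frame(sample_id = rownames(m), unclass(m), check.names = FALSE)
  write_result(df, path, seed, note)
}

#' Assemble a pipeline run configuration
#'
#' Either point `otu_table`/`tree`/`metadata`/`group_map` at input files, or
#' supply `simulate` (a list of [simulation_config()] arguments) to run on a
#' synthetic transect.
#'
#' @param otu_table,tree,metadata,group_map input file paths (all or none).
#' @param simulate list of arguments for [simulation_config()], or `NULL`.
#' @param depth rarefaction depth; `NULL` = smallest sample total.
#' @param abundant_min,rare_max abundance-partition thresholds.
#' @param bnti_cut,rc_cut process-classification thresholds.
#' @param n_rand null-model randomizations (default 999).
#' @param n_perm permutations for the group/Mantel/slope tests (default 999).
#' @param classes community classes analysed per layer; subset of
#'   `c("overall", "abundant", "rare")`.
#' @param stages stages to run, in order; subset of
#'   `c("rarefy", "partition", "betadiv", "grouptests", "ddr", "varpart",
#'   "nullmodels", "rf", "niche")`.
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(otu_table = NULL, tree = NULL, metadata = NULL,
                       group_map = NULL, simulate = NULL, depth = NULL,
                       abundant_min = 0.001, rare_max = 0.0001,
                       bnti_cut = 2, rc_cut = 0.95, n_rand = 999,
                       n_perm = 999,
                       classes = c("overall", "abundant", "rare"),
                       stages = c("rarefy", "partition", "betadiv",
                                  "grouptests", "ddr", "varpart",
                                  "nullmodels", "rf", "niche"),
                       seed = 1L) {
  if (is.null(simulate) &&
      (is.null(otu_table) || is.null(tree) || is.null(metadata) ||
       is.null(group_map))) {
    stop("provide either all four input paths or a `simulate` block")
  }
  if (!(abundant_min > 0 && abundant_min < 1 && rare_max > 0 &&
        abundant_min > rare_max)) {
    stop("thresholds must satisfy 0 < rare_max < abundant_min < 1")
  }
  cfg <- list(otu_table = otu_table, tree = tree, metadata = metadata,
              group_map = group_map, simulate = simulate, depth = depth,
              abundant_min = abundant_min, rare_max = rare_max,
              bnti_cut = bnti_cut, rc_cut = rc_cut,
              n_rand = as.integer(n_rand), n_perm = as.integer(n_perm),
              classes = match.arg(classes, several.ok = TRUE),
              stages = match.arg(stages, several.ok = TRUE),
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full community-assembly analysis
#'
#' Orchestrates the analysis sequence on one dataset: rarefaction ->
#' abundant/rare partition -> beta-diversity (Bray-Curtis and weighted
#' UniFrac) -> between-layer group tests -> distance-decay -> variation
#' partitioning -> betaNTI/RC_Bray null models with process classification ->
#' random-forest driver importance -> niche breadth. Pairwise stages are
#' stratified by soil layer (no cross-layer pairs); abundant/rare
#' sub-communities keep their original rarefied counts. Deterministic given
#' the config seed; a manifest lists every file written with its stage and
#' md5 checksum.
#'
#' @param config a [run_config()] (or YAML path).
#' @param out_dir results directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- data.frame(file = character(), stage = character())
  emit <- function(path, stage) {
    manifest <<- rbind(manifest,
                       data.frame(file = basename(path), stage = stage))
  }
  fail <- function(stage, e) {
    stop("stage `", stage, "` failed: ", conditionMessage(e), call. = FALSE)
  }

  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_cfg <- do.call(simulation_config,
                       c(config$simulate,
                         if (is.null(config$simulate$seed)) list(seed = seed)))
    dat <- simulate_dataset(sim_cfg)
    table <- dat$table; tree <- dat$tree; md <- dat$metadata
  } else {
    table <- read_otu_table(config$otu_table)
    tree <- read_newick(config$tree)
    md <- read_metadata(config$metadata, config$group_map)
  }
  md <- md[match(rownames(table), md$sample_id), ]
  if (anyNA(md$sample_id)) stop("stage `inputs` failed: samples missing from metadata")
  table <- match_table_tree(table, tree)

  on <- function(stage) stage %in% config$stages
  layers <- intersect(c("topsoil", "subsoil"), unique(md$layer))

  # --- rarefy ---------------------------------------------------------------
  if (on("rarefy")) {
    depth <- if (is.null(config$depth)) min(rowSums(table)) else config$depth
    table <- tryCatch(rarefy(table, depth, seed = seed + 10L),
                      error = function(e) fail("rarefy", e))
    # OTUs zeroed out by rarefaction are no longer community members
    table <- table[, colSums(table) > 0, drop = FALSE]
    write_otu_table(table, file.path(out_dir, "otu_table_rarefied.tsv"))
    emit("otu_table_rarefied.tsv", "rarefy")
  }

  # --- partition ------------------------------------------------------------
  class_otus <- list(overall = colnames(table))
  if (on("partition")) {
    part <- tryCatch(
      partition_by_abundance(table, config$abundant_min, config$rare_max),
      error = function(e) fail("partition", e))
    class_otus$abundant <- part$abundant_ids
    class_otus$rare <- part$rare_ids
    cls <- rep("intermediate", ncol(table))
    names(cls) <- colnames(table)
    cls[part$abundant_ids] <- "abundant"; cls[part$rare_ids] <- "rare"
    write_result(data.frame(otu_id = names(cls), class = unname(cls)),
                 file.path(out_dir, "abundance_partition.tsv"), seed,
                 note = sprintf("abundant_min=%g rare_max=%g mode=%s",
                                config$abundant_min, config$rare_max, part$mode))
    emit("abundance_partition.tsv", "partition")
  }
  # a class is analysable only if it has >= 2 OTUs with reads and leaves
  # >= 3 non-empty samples in every layer
  classes <- intersect(config$classes, names(class_otus))
  classes <- classes[vapply(classes, function(cl) {
    ids <- class_otus[[cl]]
    if (length(ids) < 2L) return(FALSE)
    all(vapply(layers, function(layer) {
      t0 <- table[md$sample_id[md$layer == layer], ids, drop = FALSE]
      sum(rowSums(t0) > 0) >= 3L
    }, logical(1)))
  }, logical(1))]

  # per-layer, per-class tables + beta matrices, computed once, reused
  sub_table <- function(layer, cl) {
    t0 <- table[md$sample_id[md$layer == layer], class_otus[[cl]], drop = FALSE]
    t0[, colSums(t0) >= 0, drop = FALSE]
  }
  beta_of <- list()
  get_beta <- function(layer, cl, metric) {
    key <- paste(layer, cl, metric, sep = ".")
    if (is.null(beta_of[[key]])) {
      t0 <- sub_table(layer, cl)
      keep <- rowSums(t0) > 0
      t0 <- t0[keep, , drop = FALSE]
      beta_of[[key]] <<- if (metric == "braycurtis") bray_curtis(t0)
                         else weighted_unifrac(t0, tree)
    }
    beta_of[[key]]
  }

  # --- betadiv --------------------------------------------------------------
  if (on("betadiv")) {
    for (layer in layers) for (cl in classes) for (metric in c("braycurtis", "wunifrac")) {
      b <- tryCatch(get_beta(layer, cl, metric),
                    error = function(e) fail("betadiv", e))
      fn <- sprintf("beta_%s_%s_%s.tsv", metric, layer, cl)
      write_matrix_result(b, file.path(out_dir, fn), seed)
      emit(fn, "betadiv")
    }
  }

  # --- grouptests (topsoil vs subsoil, overall community) -------------------
  if (on("grouptests") && length(layers) == 2L) {
    rows <- list()
    for (metric in c("braycurtis", "wunifrac")) {
      b <- if (metric == "braycurtis") bray_curtis(table)
           else weighted_unifrac(table, tree)
      grouping <- md$layer
      for (f in list(permanova, anosim, mrpp, permdisp)) {
        r <- tryCatch(f(b, grouping, n_perm = config$n_perm, seed = seed + 20L),
                      error = function(e) fail("grouptests", e))
        r$metric <- metric
        rows[[length(rows) + 1L]] <- r
      }
    }
    write_result(do.call(rbind, rows), file.path(out_dir, "group_tests.tsv"), seed)
    emit("group_tests.tsv", "grouptests")
  }

  # --- ddr ------------------------------------------------------------------
  if (on("ddr")) {
    rows <- list()
    for (layer in layers) {
      md_l <- md[md$layer == layer, ]
      attr(md_l, "group_map") <- attr(md, "group_map")
      sp <- spatial_distance(md_l)
      en <- environmental_distance(md_l)
      for (cl in classes) for (metric in c("braycurtis", "wunifrac")) {
        b <- tryCatch(get_beta(layer, cl, metric),
                      error = function(e) fail("ddr", e))
        if (!identical(rownames(b), rownames(sp))) next  # dropped empty samples
        sim <- to_similarity(b)
        for (dn in c("spatial", "environment")) {
          d <- if (dn == "spatial") sp else en
          fit <- tryCatch(
            fit_distance_decay(sim, d, n_perm = config$n_perm, seed = seed + 30L),
            error = function(e) fail("ddr", e))
          rows[[length(rows) + 1L]] <- data.frame(
            layer = layer, class = cl, metric = metric, distance = dn,
            slope = fit$slope, intercept = fit$intercept,
            pearson_r = fit$pearson_r, mantel_r = fit$mantel_r,
            mantel_p = fit$mantel_p, n_pairs = fit$n_pairs)
        }
      }
    }
    write_result(do.call(rbind, rows), file.path(out_dir, "distance_decay.tsv"), seed)
    emit("distance_decay.tsv", "ddr")
  }

  # --- varpart --------------------------------------------------------------
  if (on("varpart")) {
    rows <- list()
    for (layer in layers) {
      md_l <- md[md$layer == layer, ]
      attr(md_l, "group_map") <- attr(md, "group_map")
      sp <- spatial_distance(md_l)
      en <- environmental_distance(md_l)
      for (cl in classes) for (metric in c("braycurtis", "wunifrac")) {
        b <- tryCatch(get_beta(layer, cl, metric),
                      error = function(e) fail("varpart", e))
        if (!identical(rownames(b), rownames(sp))) next
        vp <- tryCatch(variation_partition(b, en, sp),
                       error = function(e) fail("varpart", e))
        rows[[length(rows) + 1L]] <- data.frame(
          layer = layer, class = cl, metric = metric,
          a_env = vp$a, b_shared = vp$b, c_spatial = vp$c, d_resid = vp$d,
          r2_full = vp$r2_full, deterministic_pct = vp$deterministic_pct,
          stochastic_pct = vp$stochastic_pct,
          a_env_adj = vp$adjusted$a, c_spatial_adj = vp$adjusted$c)
      }
    }
    write_result(do.call(rbind, rows), file.path(out_dir, "varpart.tsv"), seed)
    emit("varpart.tsv", "varpart")
  }

  # --- nullmodels (overall community per layer) -----------------------------
  if (on("nullmodels")) {
    frac_rows <- list(); pair_rows <- list()
    for (layer in layers) {
      t0 <- sub_table(layer, "overall")
      bn <- tryCatch(bnti(t0, tree, n_rand = config$n_rand, seed = seed + 40L),
                     error = function(e) fail("nullmodels", e))
      rc <- tryCatch(raup_crick_bray(t0, n_rand = config$n_rand, seed = seed + 41L),
                     error = function(e) fail("nullmodels", e))
      ps <- classify_processes(bn, rc, config$bnti_cut, config$rc_cut)
      pr <- ps$pairs
      pr$bmntd_obs <- pair_values(bn$obs)
      pr$bc_obs <- pair_values(rc$obs)
      pr$layer <- layer
      pair_rows[[layer]] <- pr
      frac_rows[[layer]] <- data.frame(layer = layer,
                                       process = names(ps$fractions),
                                       fraction = unname(ps$fractions),
                                       n_pairs = ps$n_pairs,
                                       n_excluded = ps$n_excluded)
    }
    write_result(do.call(rbind, pair_rows),
                 file.path(out_dir, "null_model_pairs.tsv"), seed,
                 note = sprintf("n_rand=%d", config$n_rand))
    write_result(do.call(rbind, frac_rows),
                 file.path(out_dir, "process_fractions.tsv"), seed)
    emit("null_model_pairs.tsv", "nullmodels")
    emit("process_fractions.tsv", "nullmodels")
  }

  # --- rf (overall community per layer) -------------------------------------
  if (on("rf")) {
    rows <- list()
    for (layer in layers) {
      md_l <- md[md$layer == layer, ]
      attr(md_l, "group_map") <- attr(md, "group_map")
      preds <- c(list(spatial = spatial_distance(md_l)),
                 setNames(lapply(env_group_names(), function(g)
                   environmental_distance(md_l, groups = g)),
                   env_group_names()))
      for (metric in c("braycurtis", "wunifrac")) {
        b <- tryCatch(get_beta(layer, "overall", metric),
                      error = function(e) fail("rf", e))
        imp <- tryCatch(rf_importance(b, preds, seed = seed + 50L),
                        error = function(e) fail("rf", e))
        imp$layer <- layer; imp$metric <- metric
        rows[[length(rows) + 1L]] <- imp
      }
    }
    write_result(do.call(rbind, rows), file.path(out_dir, "rf_importance.tsv"), seed)
    emit("rf_importance.tsv", "rf")
  }

  # --- niche ----------------------------------------------------------------
  if (on("niche")) {
    vals <- list()
    for (layer in layers) {
      t0 <- sub_table(layer, "overall")
      for (cl in classes) {
        sb <- tryCatch(sample_breadths(t0, class_otus[[cl]]),
                       error = function(e) fail("niche", e))
        vals[[paste(layer, cl)]] <- data.frame(
          site = md$site_id[match(names(sb), md$sample_id)],
          layer = layer, class = cl, value = unname(sb))
      }
    }
    breadths <- do.call(rbind, vals)
    breadths <- breadths[!is.na(breadths$value), ]
    cmp <- tryCatch(compare_breadths(breadths),
                    error = function(e) fail("niche", e))
    write_result(breadths, file.path(out_dir, "niche_breadth_samples.tsv"), seed)
    cls_tab <- merge(cmp$classes, cmp$paired, by = "class")
    write_result(cls_tab, file.path(out_dir, "niche_breadth_summary.tsv"), seed)
    emit("niche_breadth_samples.tsv", "niche")
    emit("niche_breadth_summary.tsv", "niche")
  }

  manifest$md5 <- unname(tools::md5sum(file.path(out_dir, manifest$file)))
  manifest$seed <- seed
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
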