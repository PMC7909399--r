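# End-to-end orchestration: from a counts table + metadata (read from
# disk or simulated) to a report directory of plain-text tables, driven by
# one configuration and one master seed.

#' Pipeline configuration
#'
#' Either supply input paths (`counts`, `metadata`, optionally `taxonomy`,
#' `mapping`) or a [sim_config()] via `sim` to analyse a simulated
#' dataset.
#'
#' @param counts,taxonomy,metadata input file paths (ignored when `sim`
#'   is given).
#' @param sim optional [sim_config()].
#' @param mapping path to a taxon-to-function mapping TSV; defaults to the
#'   demonstration mapping shipped with the package.
#' @param out_dir report directory.
#' @param min_total_reads,exclude_patterns preprocessing parameters
#'   (see [preprocess_community()]).
#' @param depth rarefaction depth: `"min"` (smallest sample total) or an
#'   integer.
#' @param rules habitat rules (see [habitat_rules()]).
#' @param env_vars metadata columns used as environmental predictors;
#'   default: all numeric columns except coordinates.
#' @param n_perm_select,n_perm_tests,n_perm_mantel,n_rand permutation and
#'   randomization counts per stage (defaults 999 / 999 / 9999 / 1000; all
#'   must be at least 99).
#' @param alpha,sr_alpha significance levels for group tests (0.05) and
#'   the SR compact letters (0.01).
#' @param seed master seed; every stage derives its own stream from it.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, taxonomy = NULL, metadata = NULL,
                            sim = NULL, mapping = NULL,
                            out_dir = "aquassembly_report",
                            min_total_reads = 10,
                            exclude_patterns = "Chloroplast",
                            depth = "min", rules = habitat_rules(),
                            env_vars = NULL,
                            n_perm_select = 999, n_perm_tests = 999,
                            n_perm_mantel = 9999, n_rand = 1000,
                            alpha = 0.05, sr_alpha = 0.01, seed = 1) {
  if (is.null(sim) && (is.null(counts) || is.null(metadata)))
    stop("supply either input paths or a sim_config")
  for (np in c(n_perm_select, n_perm_tests, n_perm_mantel, n_rand)) {
    if (np < 99) stop("permutation/randomization counts must be >= 99")
  }
  if (!identical(depth, "min") && (!is.numeric(depth) || depth < 1))
    stop("depth must be \"min\" or a positive integer")
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata,
                 sim = sim, mapping = mapping, out_dir = out_dir,
                 min_total_reads = min_total_reads,
                 exclude_patterns = exclude_patterns, depth = depth,
                 rules = rules, env_vars = env_vars,
                 n_perm_select = n_perm_select, n_perm_tests = n_perm_tests,
                 n_perm_mantel = n_perm_mantel, n_rand = n_rand,
                 alpha = alpha, sr_alpha = sr_alpha, seed = seed),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' The file holds flat key-value pairs matching the arguments of
#' [pipeline_config()]; a `sim:` block, when present, is passed to
#' [sim_config()].
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  do.call(pipeline_config, raw)
}

write_num_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate; preprocess (low-abundance filter,
#' taxonomy exclusion); rarefy; assign habitat groups; alpha diversity
#' with Kruskal-Wallis letters; Bray-Curtis matrix, UPGMA dendrograms and
#' within-group beta summary; group OTU overlap; function profile and
#' pairwise group comparisons; Mantel correlations among community,
#' function, geographic and single-variable environmental distances;
#' ANOSIM/PERMANOVA on habitat groups; RDA with permutation-based forward
#' selection for community and function profiles; distance-decay overall
#' and per group (groups with at least 4 samples); PCNM + three-set
#' variation partitioning; null-model stochasticity ratio and assembly
#' significance; and a machine-readable manifest (versions, seeds, output
#' hashes).  Every stage derives its seed from the master seed, so a
#' rerun with the same configuration is byte-identical.  A stage failure
#' aborts the run naming the stage.
#'
#' @param cfg a [pipeline_config()].
#' @return the report directory path, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  seeds <- list()
  seed_for <- function(label) {
    s <- derive_seed(cfg$seed, label)
    seeds[[label]] <<- s
    s
  }

  # --- input ---------------------------------------------------------
  if (!is.null(cfg$sim)) {
    stage("simulate", {
      md <- simulate_metadata(cfg$sim)
      cm_raw <- simulate_communities(cfg$sim, md)$community
      note("simulated dataset: nu = %g, sim seed = %d", cfg$sim$nu,
           cfg$sim$seed)
    })
  } else {
    stage("load", {
      cm_raw <- read_community(cfg$counts, cfg$taxonomy)
      md <- read_metadata(cfg$metadata)
      md <- md[match(sample_ids(cm_raw), md$sample_id), ]
      if (any(is.na(md$sample_id)))
        stop("metadata does not cover all samples")
    })
  }

  # --- preprocessing -------------------------------------------------
  stage("preprocess", {
    cm_f <- preprocess_community(cm_raw, cfg$min_total_reads,
                                 cfg$exclude_patterns)
    depth <- if (identical(cfg$depth, "min"))
      min(rowSums(cm_f$counts)) else as.integer(cfg$depth)
    cm <- rarefy_community(cm_f, depth, seed = seed_for("rarefy"))
    note("preprocess: %d -> %d OTUs (min total %d; patterns: %s)",
         ncol(cm_raw$counts), ncol(cm_f$counts), cfg$min_total_reads,
         paste(cfg$exclude_patterns, collapse = ","))
    note("rarefied to %d reads per sample", depth)
  })
  if (!("habitat_group" %in% names(md)))
    md <- stage("groups", assign_habitat_groups(md, cfg$rules))
  groups <- md$habitat_group

  # --- alpha diversity ----------------------------------------------
  stage("alpha", {
    alpha <- alpha_diversity(cm)
    alpha$habitat_group <- groups
    write_num_csv(alpha, file.path(out, "alpha_diversity.csv"))
    kl_tab <- do.call(rbind, lapply(
      c("chao1", "shannon", "invsimpson"), function(idx) {
        kl <- kruskal_letters(alpha[[idx]], groups, alpha = cfg$alpha)
        data.frame(index = idx, H = kl$H, p = kl$p,
                   group = names(kl$letters), letter = unname(kl$letters))
      }))
    write_num_csv(kl_tab, file.path(out, "alpha_kruskal_letters.csv"))
  })

  # --- beta diversity ------------------------------------------------
  bc <- stage("beta", bray_curtis(cm))
  stage("beta", {
    write_dist_matrix(bc, file.path(out, "bray_curtis.tsv"))
    upgma_tree(bc, file = file.path(out, "upgma_bcc.nwk"))
    write_num_csv(within_group_beta(bc, groups),
                  file.path(out, "within_group_beta.csv"))
    ov <- group_overlap(cm, groups)
    write_num_csv(
      data.frame(group = names(ov$per_group), n_otus = ov$per_group,
                 exclusive = ov$exclusive,
                 exclusive_pct = ov$exclusive_pct),
      file.path(out, "group_overlap.csv"))
    note("group overlap: %d/%d OTUs shared by all groups", ov$shared_all,
         ov$total_otus)
  })

  # --- function profile ---------------------------------------------
  ft <- stage("functions", {
    map_path <- cfg$mapping %||%
      system.file("extdata", "function_mapping_demo.tsv",
                  package = "aquassembly")
    apply_mapping(cm, read_function_mapping(map_path))
  })
  bfc_rel <- t(ft$relative)                      # samples x functions
  stage("functions", {
    write_num_csv(data.frame(func = rownames(ft$relative), ft$relative,
                             check.names = FALSE),
                  file.path(out, "function_profile.csv"))
    note("functions: %d/%d OTUs (%.0f%%) assigned", ft$assigned_otus,
         ncol(cm$counts), 100 * ft$assigned_fraction)
    lv <- unique(groups)
    cmp <- do.call(rbind, lapply(utils::combn(lv, 2, simplify = FALSE),
      function(pr) {
        sel <- groups %in% pr
        sub <- ft
        sub$relative <- ft$relative[, sel, drop = FALSE]
        res <- compare_profiles(sub, groups[sel], alpha = cfg$alpha,
                                n_perm = cfg$n_perm_tests,
                                seed = seed_for(paste(pr, collapse = "-")))
        res$comparison <- paste(pr, collapse = " vs ")
        res
      }))
    write_num_csv(cmp, file.path(out, "function_comparisons.csv"))
  })
  bfc_bc <- stage("functions", {
    keep <- rowSums(bfc_rel) > 0
    if (!all(keep)) stop("sample(s) with no annotated reads")
    bray_curtis(bfc_rel)
  })
  stage("functions",
        upgma_tree(bfc_bc, file = file.path(out, "upgma_bfc.nwk")))

  # --- spatial setup -------------------------------------------------
  xy <- project_coordinates(md)
  geo <- geographic_distance(xy)
  env_vars <- cfg$env_vars %||%
    setdiff(names(md)[vapply(md, is.numeric, TRUE)],
            c("latitude", "longitude"))
  env <- as.matrix(md[, env_vars, drop = FALSE])
  rownames(env) <- md$sample_id

  # --- Mantel correlation structure ---------------------------------
  stage("mantel", {
    mats <- c(list(BFC = bfc_bc, geographic = geo),
              stats::setNames(lapply(env_vars, function(v) {
                dist_matrix(stats::dist(scale(md[[v]])), kind = "geographic",
                            ids = md$sample_id)
              }), env_vars))
    rows <- lapply(names(mats), function(nm2) {
      mt <- mantel_test(bc, mats[[nm2]], n_perm = cfg$n_perm_mantel,
                        seed = seed_for(paste0("mantel_bcc_", nm2)))
      data.frame(d1 = "BCC", d2 = nm2, r = mt$statistic, p = mt$p)
    })
    mt <- mantel_test(bfc_bc, geo, n_perm = cfg$n_perm_mantel,
                      seed = seed_for("mantel_bfc_geo"))
    rows[[length(rows) + 1]] <- data.frame(d1 = "BFC", d2 = "geographic",
                                           r = mt$statistic, p = mt$p)
    write_num_csv(do.call(rbind, rows), file.path(out, "mantel_tests.csv"))
  })

  # --- group separation ---------------------------------------------
  stage("group_tests", {
    an <- anosim_test(bc, groups, n_perm = cfg$n_perm_tests,
                      seed = seed_for("anosim"))
    pm <- permanova_test(bc, groups, n_perm = cfg$n_perm_tests,
                         seed = seed_for("permanova"))
    an_f <- anosim_test(bfc_bc, groups, n_perm = cfg$n_perm_tests,
                        seed = seed_for("anosim_bfc"))
    pm_f <- permanova_test(bfc_bc, groups, n_perm = cfg$n_perm_tests,
                           seed = seed_for("permanova_bfc"))
    write_num_csv(data.frame(
      profile = c("BCC", "BCC", "BFC", "BFC"),
      test = c("ANOSIM", "PERMANOVA", "ANOSIM", "PERMANOVA"),
      statistic = c(an$statistic, pm$statistic, an_f$statistic,
                    pm_f$statistic),
      r2 = c(NA, pm$r2, NA, pm_f$r2),
      p = c(an$p, pm$p, an_f$p, pm_f$p)),
      file.path(out, "group_separation.csv"))
  })

  # --- RDA with forward selection ------------------------------------
  hel <- hellinger(cm)
  fs_bcc <- stage("rda", forward_select(
    hel, env, alpha = cfg$alpha, n_perm = cfg$n_perm_select,
    seed = seed_for("fs_bcc")))
  stage("rda", {
    write_num_csv(fs_bcc$steps, file.path(out, "rda_selection_bcc.csv"))
    fs_bfc <- forward_select(hellinger(bfc_rel), env,
                             alpha = cfg$alpha, n_perm = cfg$n_perm_select,
                             seed = seed_for("fs_bfc"))
    write_num_csv(fs_bfc$steps, file.path(out, "rda_selection_bfc.csv"))
    if (length(fs_bcc$selected)) {
      fit <- rda_fit(hel, env[, fs_bcc$selected, drop = FALSE],
                     n_perm = cfg$n_perm_tests, seed = seed_for("rda_bcc"))
      scores <- data.frame(sample_id = md$sample_id, fit$site_scores,
                           check.names = FALSE)
      utils::write.table(scores, file.path(out, "rda_site_scores_bcc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("RDA (BCC): %s | R2 = %.3f (adj %.3f), p = %.4g",
           paste(fs_bcc$selected, collapse = "+"), fit$r2, fit$adj_r2,
           fit$p)
    }
  })

  # --- distance decay ------------------------------------------------
  stage("distance_decay", {
    sim_bc <- dm_complement(bc)
    rows <- list()
    dd <- distance_decay(sim_bc, geo, n_perm = cfg$n_perm_tests,
                         seed = seed_for("dd_all"))
    rows[[1]] <- data.frame(scope = "all", slope = dd$slope,
                            intercept = dd$intercept, r2 = dd$r2, p = dd$p,
                            n_pairs = dd$n_pairs)
    for (g in unique(groups)) {
      idx <- which(groups == g)
      if (length(idx) < 4) {
        note("distance decay: group %s skipped (n = %d < 4)", g,
             length(idx))
        next
      }
      sub_s <- dist_matrix(as.matrix(sim_bc)[idx, idx], "similarity")
      sub_g <- dist_matrix(as.matrix(geo)[idx, idx], "geographic")
      ddg <- distance_decay(sub_s, sub_g, n_perm = cfg$n_perm_tests,
                            seed = seed_for(paste0("dd_", g)))
      rows[[length(rows) + 1]] <- data.frame(
        scope = g, slope = ddg$slope, intercept = ddg$intercept,
        r2 = ddg$r2, p = ddg$p, n_pairs = ddg$n_pairs)
    }
    write_num_csv(do.call(rbind, rows), file.path(out, "distance_decay.csv"))
  })

  # --- variation partitioning ---------------------------------------
  stage("varpart", {
    pcnm <- pcnm_axes(geo)
    sel_env <- if (length(fs_bcc$selected))
      env[, fs_bcc$selected, drop = FALSE] else env
    s_axes <- pcnm$vectors
    # keep the partition estimable: total predictors must stay below n - 1
    max_s <- nrow(hel) - 2 - ncol(sel_env) - 2 - 1
    if (ncol(s_axes) > max_s)
      s_axes <- s_axes[, seq_len(max_s), drop = FALSE]
    vp <- variation_partition(hel, E = sel_env, S = s_axes,
                              T_ = scale(xy, scale = FALSE),
                              n_perm = cfg$n_perm_tests,
                              seed = seed_for("varpart"))
    write_num_csv(data.frame(fraction = names(vp$fractions),
                             adj_r2 = unname(vp$fractions)),
                  file.path(out, "variation_partitioning.csv"))
    write_num_csv(vp$tests, file.path(out, "variation_partitioning_tests.csv"))
  })

  # --- assembly null model ------------------------------------------
  stage("assembly", {
    ens <- expected_similarity(cm, n_rand = cfg$n_rand,
                               seed = seed_for("null_ensemble"))
    sr <- stochasticity_ratio(dm_complement(bc), ens, groups,
                              alpha = cfg$sr_alpha)
    write_num_csv(sr$per_pair, file.path(out, "stochasticity_pairs.csv"))
    write_num_csv(data.frame(group = names(sr$sr), sr_percent = sr$sr,
                             letter = unname(sr$letters[names(sr$sr)])),
                  file.path(out, "stochasticity_ratio.csv"))
    asg <- assembly_significance(cm, groups, n_rand = cfg$n_rand,
                                 seed = seed_for("assembly_f"))
    write_num_csv(data.frame(f_null = asg$f_null),
                  file.path(out, "assembly_null_f.csv"))
    note("assembly: observed PERMANOVA F = %.3f vs null (p = %.4g); %s",
         asg$f_obs, asg$p,
         paste(names(sr$sr), sprintf("SR=%.1f%%", sr$sr), collapse = "  "))
  })

  # --- manifest ------------------------------------------------------
  stage("manifest", {
    writeLines(log_lines, file.path(out, "pipeline_log.txt"))
    files <- sort(setdiff(list.files(out), "run_manifest.json"))
    manifest <- list(
      package = "aquassembly",
      package_version = as.character(utils::packageVersion("aquassembly")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      master_seed = cfg$seed,
      stage_seeds = seeds,
      n_perm = list(select = cfg$n_perm_select, tests = cfg$n_perm_tests,
                    mantel = cfg$n_perm_mantel, n_rand = cfg$n_rand),
      files = stats::setNames(
        as.list(unname(tools::md5sum(file.path(out, files)))), files))
    jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(out)
}
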