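pipeline_defaults <- function() {
  list(
    seed = 1L, out_dir = NULL,
    # synthetic brain and studies
    grid_shape = c(24L, 24L, 24L), voxel_size_mm = 2, mask_kind = "ellipsoid",
    n_studies = 8L, noise_sd = 0.1, pooled_effect = c(0.8, -0.8),
    cluster_centers_mm = rbind(c(-10, 0, 0), c(10, 4, 4)),
    # meta-analysis
    fwhm_mm = 20, p_voxel = 0.005, extent = 20L, run_jackknife = TRUE,
    # synthetic expression
    n_donors = 6L, n_samples_per_donor = 40L, n_genes = 120L,
    probes_per_gene = 2L, n_true_genes = 20L, target_r = 0.6,
    autocorr_length_mm = 15, decoy_frac = 0.1,
    # expression processing
    min_frac = 0.5, min_r = 0.2, top_frac_ds = 0.5,
    # association and permutation test
    radius_mm = 3, alpha = 0.05, n_perm = 250L,
    surrogate_mode = "map_surrogate", k_grid = NULL, rank_match = TRUE,
    # annotation assets
    n_sets = 20L, edge_density = 0.05, n_terms = 3L, min_score = 0.9,
    hub_top_frac = 0.10, behavior_threshold = 0.2
  )
}

#' Assemble and validate a pipeline configuration
#'
#' Starts from the documented defaults and overrides them with the named
#' arguments; unknown keys are rejected. The defaults run the full chain at
#' demonstration scale (a 24-voxel ellipsoid mask, 8 studies with the
#' first-episode psychosis group sizes, 6 donors, 120 genes, 250
#' map-surrogate permutations); per-operation defaults (20 mm FWHM,
#' p = 0.005 / 20 voxels, 50 percent intensity filter, r = 0.2 probe rule,
#' top-50 percent DS, 3 mm spheres, q <= 0.05) are the analysis settings of
#' the study the pipeline reproduces.
#'
#' @param ... named overrides of the defaults.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all config overrides must be named")
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$noise_sd >= 0, cfg$fwhm_mm > 0,
            cfg$p_voxel > 0, cfg$p_voxel < 1, cfg$extent >= 1,
            cfg$min_frac >= 0, cfg$min_frac <= 1,
            cfg$top_frac_ds > 0, cfg$top_frac_ds <= 1,
            cfg$radius_mm > 0, cfg$alpha > 0, cfg$alpha < 1,
            cfg$n_perm >= 1,
            cfg$surrogate_mode %in% c("map_surrogate", "per_gene_surrogates"),
            abs(cfg$target_r) < 1, cfg$n_true_genes <= cfg$n_genes)
  class(cfg) <- "pipeline_config"
  cfg
}

config_lines <- function(cfg) {
  vapply(names(cfg), function(k)
    paste0(k, " = ", paste(format(cfg[[k]]), collapse = " ")), "")
}

#' Run the full synthetic-data pipeline
#'
#' Executes the stages in analysis order: synthetic study generation,
#' coordinate-based random-effects meta-analysis (with heterogeneity,
#' small-study and optional jackknife diagnostics), synthetic expression
#' generation against the meta-analytic z map, expression preprocessing,
#' sphere-sampled gene-wise association with BH control, the spatially
#' constrained permutation test, and gene-set / hub / behavioral
#' characterization. All randomness derives from `config$seed`. When
#' `config$out_dir` is set, every artifact is written there (NIfTI maps,
#' CSV/TSV tables, GMT sets, a JSON ground-truth sidecar, a timestamped
#' log) and a manifest of content hashes is returned.
#'
#' @param config a [pipeline_config()].
#' @return list with the stage results (`grid`, `studies`, `meta`,
#'   `clusters`, `heterogeneity`, `small_study`, `jackknife`, `expression`,
#'   `association`, `perm_test`, `enrichment`, `hubs`, `behavior`, `truth`)
#'   and, when writing, `manifest` (data frame `artifact`, `path`, `md5`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    log <<- c(log, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           "\nconfig:\n", paste(config_lines(config), collapse = "\n"),
           call. = FALSE))
  }
  say("config: ", paste(config_lines(config), collapse = "; "))

  # --- synthetic brain, truth, studies ---------------------------------
  res <- list()
  stage("simulate", {
    spec <- toy_brain_spec(config$grid_shape, config$voxel_size_mm,
                           config$mask_kind, seed = config$seed)
    res$grid <- gen_brain_grid(spec)
    gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
    res$truth <- synthetic_truth(
      true_gene_ids = gene_ids[seq_len(config$n_true_genes)],
      target_r = config$target_r,
      pooled_effect = config$pooled_effect,
      cluster_centers_mm = config$cluster_centers_mm,
      autocorr_length_mm = config$autocorr_length_mm)
    res$studies <- gen_study_peaks(config$n_studies, res$truth, res$grid,
                                   config$noise_sd, seed = config$seed + 1L)
    say("simulate: ", length(res$studies), " studies, ",
        sum(res$grid$mask), " mask voxels")
  })

  # --- meta-analysis ----------------------------------------------------
  stage("meta", {
    res$study_maps <- lapply(res$studies, reconstruct_study_map,
                             grid = res$grid, fwhm_mm = config$fwhm_mm)
    res$meta <- random_effects_combine(res$study_maps)
    res$clusters <- threshold_clusters(res$meta, config$p_voxel, config$extent)
    res$heterogeneity <- heterogeneity_report(res$meta, res$clusters)
    res$small_study <- small_study_tests(res$study_maps, res$meta, res$clusters)
    if (config$run_jackknife)
      res$jackknife <- jackknife_consistency(res$study_maps, config$p_voxel,
                                             config$extent)
    say("meta: ", nrow(res$clusters), " clusters above threshold")
  })

  # --- synthetic expression against the z map --------------------------
  z_map <- volume_map(values_to_array(res$meta$z, res$grid),
                      res$grid$affine, res$grid$mask)
  stage("expression", {
    ds <- gen_expression_dataset(
      res$grid, z_map, n_donors = config$n_donors,
      n_samples_per_donor = config$n_samples_per_donor,
      n_genes = config$n_genes, probes_per_gene = config$probes_per_gene,
      truth = res$truth, seed = config$seed + 2L,
      decoy_frac = config$decoy_frac)
    res$dataset <- ds
    res$expression <- process_expression(
      ds$probes, ds$rnaseq, res$grid, min_frac = config$min_frac,
      min_r = config$min_r, top_frac_ds = config$top_frac_ds)
    say("expression: ", paste(names(attr(res$expression, "log")),
                              attr(res$expression, "log"),
                              sep = "=", collapse = ", "))
  })

  # --- association + permutation test ----------------------------------
  stage("associate", {
    coords <- as.matrix(res$expression$samples[, c("x", "y", "z")])
    zvec <- extract_sphere_values(z_map, coords, config$radius_mm)
    res$association <- genewise_correlation(res$expression$expr, zvec,
                                            config$alpha)
    say("associate: ", sum(res$association$significant), " of ",
        nrow(res$association), " genes significant at q <= ", config$alpha)
    res$perm_test <- permutation_test_gene_count(
      res$expression$expr, zvec, coords = coords, n_perm = config$n_perm,
      mode = config$surrogate_mode, alpha = config$alpha,
      k_grid = config$k_grid, rank_match = config$rank_match,
      seed = config$seed + 3L)
    say("surrogate test: observed = ", res$perm_test$observed,
        ", p = ", signif(res$perm_test$p, 4))
  })

  # --- annotation -------------------------------------------------------
  stage("annotate", {
    universe <- res$association$gene_id
    sig <- res$association$gene_id[res$association$significant]
    res$assets <- gen_annotation_assets(
      universe, n_sets = config$n_sets, edge_density = config$edge_density,
      n_terms = config$n_terms, grid = res$grid, seed = config$seed + 4L,
      target_list = sig)
    res$enrichment <- enrich_collection(sig, res$assets$gene_sets, universe,
                                        config$alpha)
    edges_f <- filter_edges(res$assets$edges, config$min_score, sig)
    res$edges_filtered <- edges_f
    res$hubs <- hub_genes(edges_f, config$hub_top_frac)
    res$behavior <- if (length(sig) >= 1 && nrow(res$expression$expr) >= 4)
      behavioral_relevance(
        res$expression$expr[, sig, drop = FALSE], res$assets$term_maps,
        as.matrix(res$expression$samples[, c("x", "y", "z")]),
        config$radius_mm, config$behavior_threshold)
    say("annotate: ", sum(res$enrichment$significant), " enriched sets, ",
        nrow(res$hubs), " hubs, ",
        if (is.null(res$behavior)) 0 else sum(res$behavior$selected),
        " behavioral terms selected")
  })

  res$log <- log
  if (is.null(config$out_dir)) return(res)

  # --- persist artifacts ------------------------------------------------
  stage("write", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(config$out_dir, f)
    put_vol <- function(vals, f) {
      write_volume(volume_map(values_to_array(vals, res$grid),
                              res$grid$affine, res$grid$mask), fp(f))
    }
    put_vol(res$meta$z, "meta_z.nii")
    put_vol(res$meta$p, "meta_p.nii")
    put_vol(res$meta$I2, "meta_I2.nii")
    write_volume(volume_map(array(as.numeric(res$grid$mask),
                                  dim(res$grid$mask)),
                            res$grid$affine, res$grid$mask), fp("mask.nii"))
    write_peak_table(res$studies, fp("peaks.csv"))
    utils::write.csv(res$clusters, fp("clusters.csv"), row.names = FALSE)
    utils::write.csv(res$association, fp("association.csv"), row.names = FALSE)
    utils::write.csv(data.frame(null_count = res$perm_test$null_counts),
                     fp("null_counts.csv"), row.names = FALSE)
    utils::write.csv(data.frame(sample_id = res$expression$samples$sample_id,
                                res$expression$expr, check.names = FALSE),
                     fp("expression.csv"), row.names = FALSE)
    utils::write.csv(res$expression$samples, fp("samples.csv"), row.names = FALSE)
    utils::write.csv(data.frame(gene_id = names(res$expression$ds),
                                ds = res$expression$ds),
                     fp("ds.csv"), row.names = FALSE)
    write_gmt(res$assets$gene_sets, fp("gene_sets.gmt"))
    write_edges(res$assets$edges, fp("edges.tsv"))
    utils::write.csv(res$enrichment, fp("enrichment.csv"), row.names = FALSE)
    utils::write.csv(res$hubs, fp("hubs.csv"), row.names = FALSE)
    if (!is.null(res$behavior))
      utils::write.csv(res$behavior, fp("behavior.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(true_gene_ids = res$truth$true_gene_ids,
           target_r = res$truth$target_r,
           pooled_effect = res$truth$pooled_effect,
           autocorr_length_mm = res$truth$autocorr_length_mm,
           seed = config$seed),
      fp("truth.json"), auto_unbox = TRUE, digits = NA)
    writeLines(log, fp("pipeline.log"))
    # the timestamped log is excluded from the manifest so that identical
    # config + seed gives hash-identical manifests
    files <- setdiff(list.files(config$out_dir), c("manifest.csv", "pipeline.log"))
    res$manifest <- data.frame(
      artifact = files, path = file.path(config$out_dir, files),
      md5 = unname(tools::md5sum(file.path(config$out_dir, files))),
      stringsAsFactors = FALSE)
    utils::write.csv(res$manifest, fp("manifest.csv"), row.names = FALSE)
  })
  res
}
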