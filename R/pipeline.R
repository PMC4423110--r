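# YAML-configured pipeline runner with a reproducibility manifest.
# One master seed drives every stage through named substreams
# (substream_seed), so re-running a manifest reproduces all stochastic
# results bit-identically.

pipeline_schema <- function() {
  list(
    seed = "scalar",
    simulate = list(
      genome = names(formals(genome_config)),
      n_per_group = "scalar", noise_sd = "scalar",
      wgbs_n_per_group = "scalar", mean_coverage = "scalar",
      target_r2 = "scalar"),
    array_blocks = list(
      comparison = "vector", covariates = "vector", threshold = "scalar",
      min_width_bp = "scalar", window_bp = "scalar", max_gap = "scalar",
      min_regions = "scalar", n_perm = "scalar", alpha = "scalar"),
    dmrs = list(
      comparison = "vector", covariates = "vector", threshold = "scalar",
      cluster_gap = "scalar", min_probes = "scalar", n_perm = "scalar",
      alpha = "scalar"),
    wgbs = list(
      comparison = "vector", reference_group = "scalar", preset = "scalar",
      min_cov = "scalar", mode = "scalar", t_cut = "scalar",
      min_width_bp = "scalar", min_meandiff = "scalar",
      max_gap_bp = "scalar", min_cpgs = "scalar"),
    enrichment = list(
      reference_bed = "scalar", n_sets = "scalar"),
    summaries = list(
      comparison = "vector", target_r2 = "scalar"))
}

validate_config <- function(config, schema = pipeline_schema(), path = "") {
  for (key in names(config)) {
    here <- if (path == "") key else paste0(path, ".", key)
    if (!(key %in% names(schema) ||
          (is.character(schema) && key %in% schema)))
      stop_mb(sprintf("unknown configuration key: '%s'", here), "bad_config")
    sub <- if (is.list(schema)) schema[[key]] else NULL
    if (is.list(sub) || (is.character(sub) && length(sub) > 1))
      if (is.list(config[[key]]))
        validate_config(config[[key]], sub, here)
  }
  invisible(config)
}

#' Run the configured analysis pipeline
#'
#' Executes the configured stages in dependency order: `simulate` ->
#' `array_blocks` -> `dmrs` -> `wgbs` -> `enrichment` -> `summaries`.
#' Partial pipelines are allowed (any later stage requires the simulate
#' stage in this desk-scale runner). All outputs plus a `manifest.json`
#' (parameters, seed, input digests, package version, timestamp) are
#' written under `out_dir`. Unknown configuration keys are rejected.
#'
#' @param config YAML file path or an equivalent nested list. Top-level
#'   keys: `seed` plus one block per stage to run.
#' @param out_dir output directory (created).
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  seed <- config$seed %||% 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  if (!is.null(config$simulate)) {
    sc <- config$simulate
    gcfg <- do.call(genome_config, sc$genome %||% list())
    sim <- simulate_genome(gcfg, substream_seed(seed, "simulate_genome"))
    design <- make_design(sc$n_per_group %||% 10)
    betas <- simulate_array_cohort(sim$annotation, sim$truth, design,
                                   noise_sd = sc$noise_sd %||% 0.05,
                                   seed = substream_seed(seed, "simulate_array"))
    wdesign <- do.call(rbind, lapply(split(design, design$group),
                                     head, sc$wgbs_n_per_group %||% 3))
    wgbs <- simulate_wgbs_cohort(sim$truth, wdesign,
                                 mean_coverage = sc$mean_coverage %||% 6,
                                 seed = substream_seed(seed, "simulate_wgbs"))
    write_simulation(file.path(out_dir, "simulate"), sim$annotation,
                     sim$truth, design, betas, wgbs)
    res$simulate <- list(sim = sim, design = design, betas = betas,
                         wgbs = wgbs)
    message("stage simulate: done")
  }

  need_sim <- function(stage) {
    if (is.null(res$simulate))
      stop_mb(sprintf("stage '%s' requires the 'simulate' stage output", stage),
              "missing_dependency")
  }

  if (!is.null(config$array_blocks)) {
    need_sim("array_blocks")
    ac <- config$array_blocks
    bc <- find_blocks_array(
      res$simulate$betas, res$simulate$sim$annotation, res$simulate$design,
      comparison = unlist(ac$comparison) %||% c("O-exp", "Y-pro"),
      covariates = unlist(ac$covariates),
      threshold = ac$threshold %||% 0.05,
      min_width_bp = ac$min_width_bp %||% 200000,
      window_bp = ac$window_bp %||% 250000,
      max_gap = ac$max_gap %||% 1500,
      min_regions = ac$min_regions %||% 5,
      n_perm = ac$n_perm %||% 400, alpha = ac$alpha %||% 0.05,
      seed = substream_seed(seed, "array_blocks"))
    dir.create(file.path(out_dir, "blocks"), showWarnings = FALSE)
    write_calls_bed(bc$blocks, file.path(out_dir, "blocks", "blocks.bed"),
                    paste(bc$comparison, collapse = "_vs_"))
    res$array_blocks <- bc
    message(sprintf("stage array_blocks: %d block(s)", nrow(bc$blocks)))
  }

  if (!is.null(config$dmrs)) {
    need_sim("dmrs")
    dc <- config$dmrs
    dm <- find_dmrs(
      res$simulate$betas, res$simulate$sim$annotation, res$simulate$design,
      comparison = unlist(dc$comparison) %||% c("O-exp", "Y-pro"),
      covariates = unlist(dc$covariates) %||% c("sex", "body_site"),
      cluster_gap = dc$cluster_gap %||% 500,
      threshold = dc$threshold %||% 0.1,
      min_probes = dc$min_probes %||% 2,
      n_perm = dc$n_perm %||% 400, alpha = dc$alpha %||% 0.1,
      seed = substream_seed(seed, "dmrs"))
    dir.create(file.path(out_dir, "dmrs"), showWarnings = FALSE)
    write_calls_bed(dm$dmrs, file.path(out_dir, "dmrs", "dmrs.bed"),
                    paste(dm$comparison, collapse = "_vs_"))
    res$dmrs <- dm
    message(sprintf("stage dmrs: %d DMR(s)", nrow(dm$dmrs)))
  }

  if (!is.null(config$wgbs)) {
    need_sim("wgbs")
    wc <- config$wgbs
    wb <- find_blocks_wgbs(
      res$simulate$wgbs,
      comparison = unlist(wc$comparison) %||% c("O-exp", "Y-pro"),
      reference_group = wc$reference_group %||% "Y-pro",
      preset = wc$preset %||% "large",
      min_cov = wc$min_cov %||% 2, mode = wc$mode %||% "group_total",
      t_cut = wc$t_cut %||% 2, min_width_bp = wc$min_width_bp %||% 10000,
      min_meandiff = wc$min_meandiff %||% 0.05,
      max_gap_bp = wc$max_gap_bp %||% 1000, min_cpgs = wc$min_cpgs %||% 10)
    dir.create(file.path(out_dir, "wgbs"), showWarnings = FALSE)
    write_calls_bed(wb$blocks, file.path(out_dir, "wgbs", "blocks.bed"), "wgbs")
    dens <- methylation_density(wb$smoothed, wb$blocks)
    data.table::fwrite(dens, file.path(out_dir, "wgbs", "density.tsv"), sep = "\t")
    res$wgbs <- wb
    message(sprintf("stage wgbs: %d block(s)", nrow(wb$blocks)))
  }

  if (!is.null(config$enrichment)) {
    if (is.null(res$array_blocks))
      stop_mb("stage 'enrichment' requires the 'array_blocks' stage output",
              "missing_dependency")
    ec <- config$enrichment
    genome <- res$simulate$sim$truth$genome
    reference <- if (!is.null(ec$reference_bed)) read_bed(ec$reference_bed)
                 else res$simulate$sim$truth$blocks
    universe <- interval_set(names(genome), rep(0, length(genome)),
                             unname(genome), genome)
    query <- calls_to_granges(res$array_blocks$blocks, genome)
    orr <- bp_odds_ratio(query, reference, universe)
    rs <- matched_random_sets(query, res$simulate$sim$annotation,
                              n_sets = ec$n_sets %||% 1000,
                              seed = substream_seed(seed, "enrichment"))
    pt <- permutation_overlap_test(query, reference, rs)
    dir.create(file.path(out_dir, "enrichment"), showWarnings = FALSE)
    jsonlite::write_json(
      list(odds_ratio = orr$odds_ratio, contingency = as.vector(orr$contingency),
           corrected = orr$corrected, chisq_p = orr$chisq_p,
           observed = pt$observed, empirical_p = pt$empirical_p,
           significant = pt$significant, n_sets = length(rs),
           unit = "bp", seed = substream_seed(seed, "enrichment")),
      file.path(out_dir, "enrichment", "enrichment.json"),
      auto_unbox = TRUE, digits = NA)
    res$enrichment <- list(odds_ratio = orr, test = pt)
    message(sprintf("stage enrichment: OR %.2f, p %.4g",
                    orr$odds_ratio, pt$empirical_p))
  }

  if (!is.null(config$summaries)) {
    if (is.null(res$array_blocks))
      stop_mb("stage 'summaries' requires the 'array_blocks' stage output",
              "missing_dependency")
    sc <- config$summaries
    comparison <- unlist(sc$comparison) %||% c("O-exp", "Y-pro")
    bm <- block_mean_matrix(res$simulate$betas, res$simulate$sim$annotation,
                            res$array_blocks$blocks, res$simulate$design,
                            comparison)
    grades <- simulate_clinical_grades(
      rowMeans(bm), target_r2 = sc$target_r2 %||% 0.8,
      seed = substream_seed(seed, "grades"))
    reg <- clinical_regression(rowMeans(bm), grades)
    trend <- group_trend_check(bm, res$simulate$design)
    xy <- mds_embed(res$simulate$betas)
    dir.create(file.path(out_dir, "summaries"), showWarnings = FALSE)
    write.csv(data.frame(sample_id = rownames(bm), bm),
              file.path(out_dir, "summaries", "block_means.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(regression = reg, trend_verdict = trend$verdict,
           group_means = as.list(trend$group_means)),
      file.path(out_dir, "summaries", "clinical.json"),
      auto_unbox = TRUE, digits = NA)
    write.csv(data.frame(sample_id = rownames(xy), xy),
              file.path(out_dir, "summaries", "mds.csv"), row.names = FALSE)
    res$summaries <- list(block_means = bm, regression = reg, trend = trend,
                          mds = xy)
    message("stage summaries: done")
  }

  manifest <- list(
    command = "run_pipeline",
    config = config,
    config_file = cfg_path,
    input_digests = if (!is.null(cfg_path))
      as.list(tools::md5sum(cfg_path)) else list(),
    seed = seed,
    version = as.character(utils::packageVersion("methblocks")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}
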