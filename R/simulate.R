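#' Configuration for the synthetic methylome generator
#'
#' Desk-scale defaults emulate the structure (not the size) of a 450k +
#' WGBS skin-aging study: a 3 x 20 Mb genome, ~6,000 array probes split
#' into CpG islands, shores and open sea, hypomethylated blocks of
#' 202 kb-1.3 Mb with per-block methylation drops drawn from 5.2-16%
#' (mean ~9%), and small DMRs of ~460 bp with |delta| 0.37 carried by
#' dense probe clusters.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param n_probes total array probes.
#' @param island_fraction,shore_fraction fraction of probes in islands /
#'   shores; the remainder (minus DMR probes) is open sea.
#' @param probes_per_island probes per simulated island cluster.
#' @param n_blocks planted hypomethylated blocks.
#' @param block_size_range block width range (bp).
#' @param block_delta methylation drop per block: scalar for a fixed
#'   effect or length-2 range to draw from.
#' @param block_min_gap minimum separation between planted blocks (bp).
#' @param edge_taper linear taper width at block edges (bp); 0 for a flat
#'   profile.
#' @param n_dmrs planted small DMRs (half hyper-, half hypomethylated).
#' @param dmr_size DMR width (bp).
#' @param dmr_delta absolute methylation change of DMRs.
#' @param dmr_probes probes per DMR cluster.
#' @param snp_rate Bernoulli rate of SNP-flagged probes.
#' @param baseline named baseline methylation per relation class.
#' @param cpg_spacing WGBS CpG spacing (bp).
#' @return a `genome_config` list.
#' @export
genome_config <- function(n_chrom = 3, chrom_length = 2e7, n_probes = 6000,
                          island_fraction = 0.15, shore_fraction = 0.15,
                          probes_per_island = 6,
                          n_blocks = 15, block_size_range = c(202e3, 1.3e6),
                          block_delta = c(0.052, 0.16), block_min_gap = 3e5,
                          edge_taper = 1e4,
                          n_dmrs = 20, dmr_size = 460, dmr_delta = 0.37,
                          dmr_probes = 4, snp_rate = 0.036,
                          baseline = c(island = 0.15, shore = 0.5, open_sea = 0.8),
                          cpg_spacing = 300) {
  cfg <- as.list(environment())
  stopifnot(n_chrom >= 1, chrom_length > 0, n_probes > 0,
            island_fraction >= 0, shore_fraction >= 0,
            island_fraction + shore_fraction < 1,
            all(block_delta > 0), all(block_delta < 1))
  if (n_blocks > 0 &&
      max(cfg$block_size_range) + 2 * cfg$block_min_gap > chrom_length)
    stop_mb("block sizes exceed chromosome length", "bad_config")
  class(cfg) <- "genome_config"
  cfg
}

draw_disjoint <- function(n, sizes, chrom_len, chroms, min_gap, avoid = NULL) {
  # rejection-sample disjoint (chrom, start) placements with min_gap spacing
  placed <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  chrom_of <- sample(chroms, n, replace = TRUE)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:500) {
      ch <- if (try <= 250) chrom_of[i] else sample(chroms, 1)
      s <- floor(runif(1, min_gap, chrom_len - sizes[i] - min_gap))
      e <- s + sizes[i] - 1
      clash <- placed$chrom == ch & placed$start - min_gap <= e & placed$end + min_gap >= s
      if (!is.null(avoid)) {
        av <- avoid[avoid$chrom == ch, , drop = FALSE]
        clash <- c(clash, av$start <= e & av$end >= s)
      }
      if (!any(clash)) { ok <- TRUE; break }
    }
    if (!ok) stop_mb("could not place disjoint regions; genome too crowded", "bad_config")
    placed <- rbind(placed, data.frame(chrom = ch, start = s, end = e))
  }
  placed[order(placed$chrom, placed$start), , drop = FALSE]
}

#' Simulate a genome layout with planted truth
#'
#' Places disjoint hypomethylated blocks (avoiding islands), CpG-island
#' probe clusters with shore probes on their flanks, dense probe clusters
#' marking planted DMRs, and sparse open-sea probes genome-wide.
#' Deterministic given `seed`.
#'
#' @param config a [genome_config()].
#' @param seed integer seed.
#' @return list with `annotation` (probe table, see
#'   [read_probe_annotation()]) and `truth` (a `sim_truth` list: `genome`,
#'   `blocks` / `dmrs` GRanges with `delta` metadata, `islands`, `config`,
#'   `seed`).
#' @export
simulate_genome <- function(config = genome_config(), seed = 1) {
  stopifnot(inherits(config, "genome_config"))
  with_rng(seed, {
    genome <- stats::setNames(rep(config$chrom_length, config$n_chrom),
                              paste0("chr", seq_len(config$n_chrom)))
    chroms <- names(genome)

    sizes <- round(runif(config$n_blocks, config$block_size_range[1],
                         config$block_size_range[2]))
    blocks <- draw_disjoint(config$n_blocks, sizes, config$chrom_length,
                            chroms, config$block_min_gap)
    blocks$delta <- if (length(config$block_delta) == 1) {
      rep(config$block_delta, nrow(blocks))
    } else {
      runif(nrow(blocks), config$block_delta[1], config$block_delta[2])
    }

    n_isl_probes <- round(config$island_fraction * config$n_probes)
    n_islands <- max(1L, ceiling(n_isl_probes / config$probes_per_island))
    islands <- draw_disjoint(n_islands, rep(1000, n_islands), config$chrom_length,
                             chroms, 5e3, avoid = blocks)

    dmrs <- NULL
    if (config$n_dmrs > 0) {
      dmrs <- draw_disjoint(config$n_dmrs, rep(config$dmr_size, config$n_dmrs),
                            config$chrom_length, chroms, 1e4,
                            avoid = rbind(blocks[1:3], islands[1:3]))
      dmrs$delta <- rep(c(1, -1), length.out = config$n_dmrs) * config$dmr_delta
    }

    probe_rows <- list()
    for (i in seq_len(nrow(islands))) {
      k <- config$probes_per_island
      at <- round(seq(islands$start[i], islands$end[i], length.out = k))
      probe_rows[[length(probe_rows) + 1L]] <-
        data.frame(chrom = islands$chrom[i], pos = at, relation = "island")
    }
    n_shore <- round(config$shore_fraction * config$n_probes)
    sh_isl <- rep(seq_len(nrow(islands)), length.out = n_shore)
    sh_side <- rep(c(-1, 1), length.out = n_shore)
    sh_pos <- ifelse(sh_side < 0,
                     islands$start[sh_isl] - round(runif(n_shore, 300, 1900)),
                     islands$end[sh_isl] + round(runif(n_shore, 300, 1900)))
    probe_rows[[length(probe_rows) + 1L]] <-
      data.frame(chrom = islands$chrom[sh_isl], pos = sh_pos, relation = "shore")
    if (!is.null(dmrs)) {
      for (i in seq_len(nrow(dmrs))) {
        at <- round(seq(dmrs$start[i], dmrs$end[i], length.out = config$dmr_probes))
        probe_rows[[length(probe_rows) + 1L]] <-
          data.frame(chrom = dmrs$chrom[i], pos = at, relation = "shore")
      }
    }
    n_sea <- config$n_probes - sum(vapply(probe_rows, nrow, 1L))
    if (n_sea < 0) stop_mb("island/shore/DMR probes exceed n_probes", "bad_config")
    sea_chrom <- sample(chroms, n_sea, replace = TRUE)
    sea_pos <- floor(runif(n_sea, 1, config$chrom_length))
    probe_rows[[length(probe_rows) + 1L]] <-
      data.frame(chrom = sea_chrom, pos = sea_pos, relation = "open_sea")

    ann <- do.call(rbind, probe_rows)
    ann$pos <- pmin(pmax(ann$pos, 1), config$chrom_length)
    ann <- ann[!duplicated(ann[, c("chrom", "pos")]), , drop = FALSE]
    ann <- ann[order(ann$chrom, ann$pos), , drop = FALSE]
    ann$probe_id <- sprintf("cg%06d", seq_len(nrow(ann)))
    ann$snp_flag <- runif(nrow(ann)) < config$snp_rate
    ann <- ann[, c("probe_id", "chrom", "pos", "relation", "snp_flag")]
    rownames(ann) <- NULL

    to_gr <- function(df) {
      if (is.null(df) || nrow(df) == 0) return(GenomicRanges::GRanges())
      gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
      if (!is.null(df$delta)) gr$delta <- df$delta
      GenomeInfoDb::seqlevels(gr) <- chroms
      GenomeInfoDb::seqlengths(gr) <- unname(genome)
      GenomicRanges::sort(gr)
    }
    truth <- structure(list(genome = genome, blocks = to_gr(blocks),
                            dmrs = to_gr(dmrs), islands = to_gr(islands),
                            config = config, seed = seed),
                       class = "sim_truth")
    list(annotation = ann, truth = truth)
  })
}

# per-position planted effect: block drop (positive) and signed DMR change,
# with a linear taper over `edge_taper` bp at block edges
planted_effect <- function(chrom, pos, truth) {
  cfg <- truth$config
  site <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  eff_in <- function(gr, taper_bp) {
    delta <- numeric(length(pos))
    taper <- numeric(length(pos))
    if (length(gr) == 0) return(list(delta = delta, taper = taper))
    hit <- GenomicRanges::findOverlaps(site, gr)
    qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
    delta[qi] <- gr$delta[si]
    d_edge <- pmin(pos[qi] - GenomicRanges::start(gr)[si],
                   GenomicRanges::end(gr)[si] - pos[qi])
    taper[qi] <- if (taper_bp > 0) pmin(1, d_edge / taper_bp) else 1
    list(delta = delta, taper = taper)
  }
  b <- eff_in(truth$blocks, cfg$edge_taper)   # blocks taper at their edges
  d <- eff_in(truth$dmrs, 0)                  # DMRs are flat (hundreds of bp)
  list(block = b$delta * b$taper, dmr = d$delta * d$taper)
}

#' Default group gradient of the planted block effect
#'
#' O-exp carries the full planted drop; the intermediate groups (O-pro,
#' Y-exp) carry a configurable fraction of it, reproducing the observed
#' progressive hypomethylation ordering; Y-pro is the unaffected baseline.
#'
#' @param intermediate fraction of the full effect in O-pro and Y-exp.
#' @return named numeric vector over the four groups.
#' @export
group_gradient <- function(intermediate = 0.4) {
  c("Y-pro" = 0, "O-pro" = intermediate, "Y-exp" = intermediate, "O-exp" = 1)
}

#' Simulate an array cohort (beta matrix) over a planted truth
#'
#' Per-probe baselines come from the relation class; samples in affected
#' groups lose the planted block delta (scaled by the group gradient) and
#' gain/lose the signed DMR delta; probe noise is truncated Gaussian on
#' the beta scale (or logit-normal).
#'
#' @param annotation probe table from [simulate_genome()].
#' @param truth matching `sim_truth`.
#' @param design cohort design ([make_design()]).
#' @param noise_sd probe noise standard deviation (beta scale).
#' @param gradient group gradient, see [group_gradient()].
#' @param noise_model "gaussian" (truncated at 0/1) or "logit".
#' @param seed integer seed.
#' @return beta matrix, probes x samples.
#' @export
simulate_array_cohort <- function(annotation, truth, design, noise_sd = 0.05,
                                  gradient = group_gradient(),
                                  noise_model = c("gaussian", "logit"),
                                  seed = 1) {
  noise_model <- match.arg(noise_model)
  if (noise_sd < 0) stop_mb("noise_sd must be non-negative", "bad_config")
  stopifnot(all(design$group %in% names(gradient)))
  with_rng(seed, {
    base <- truth$config$baseline[annotation$relation]
    eff <- planted_effect(annotation$chrom, annotation$pos, truth)
    grad <- gradient[design$group]
    mu <- outer(base, rep(1, nrow(design))) +
      outer(-eff$block + eff$dmr, grad)
    noise <- matrix(rnorm(length(mu), 0, noise_sd), nrow(mu))
    beta <- if (noise_model == "gaussian") {
      clip01(mu + noise)
    } else {
      # logit-normal alternative; sd scaled to match the beta-scale sd at 0.5
      eps <- 1e-4
      stats::plogis(stats::qlogis(pmin(1 - eps, pmax(eps, mu))) + 4 * noise)
    }
    dimnames(beta) <- list(annotation$probe_id, design$sample_id)
    beta
  })
}

#' Simulate a WGBS cohort over a planted truth
#'
#' CpG sites are placed on a jittered grid; each site/sample has a
#' methylation probability from the same planted model as the array arm
#' (plus site-level Gaussian noise), coverage is Poisson and methylated
#' reads are Binomial(coverage, p).
#'
#' @param truth `sim_truth` from [simulate_genome()].
#' @param design cohort design (typically a 3 vs 3 subset).
#' @param mean_coverage scalar or per-sample Poisson mean; must be > 0.
#' @param noise_sd site-level noise sd on the methylation fraction.
#' @param gradient group gradient.
#' @param seed integer seed.
#' @return a `wgbs_cohort`: list with `chrom`, `pos`, matrices `meth` and
#'   `cov` (sites x samples), and the `design`.
#' @export
simulate_wgbs_cohort <- function(truth, design, mean_coverage = 6,
                                 noise_sd = 0.05,
                                 gradient = group_gradient(), seed = 1) {
  if (any(mean_coverage <= 0)) stop_mb("mean_coverage must be positive", "bad_config")
  lam <- rep(mean_coverage, length.out = nrow(design))
  cfg <- truth$config
  with_rng(seed, {
    pos_l <- lapply(names(truth$genome), function(ch) {
      grid <- seq(cfg$cpg_spacing, truth$genome[[ch]] - cfg$cpg_spacing,
                  by = cfg$cpg_spacing)
      sort(unique(pmax(1, grid + sample(-50:50, length(grid), replace = TRUE))))
    })
    chrom <- rep(names(truth$genome), lengths(pos_l))
    pos <- unlist(pos_l, use.names = FALSE)
    n <- length(pos)

    site <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    base <- rep(cfg$baseline[["open_sea"]], n)
    base[IRanges::overlapsAny(site, truth$islands)] <- cfg$baseline[["island"]]
    if (length(truth$dmrs))
      base[IRanges::overlapsAny(site, truth$dmrs)] <- cfg$baseline[["shore"]]
    eff <- planted_effect(chrom, pos, truth)
    grad <- gradient[design$group]

    ns <- nrow(design)
    p <- clip01(outer(base, rep(1, ns)) + outer(-eff$block + eff$dmr, grad) +
                matrix(rnorm(n * ns, 0, noise_sd), n))
    cov <- matrix(rpois(n * ns, rep(lam, each = n)), n)
    meth <- matrix(rbinom(n * ns, as.vector(cov), as.vector(p)), n)
    dimnames(meth) <- dimnames(cov) <- list(NULL, design$sample_id)
    structure(list(chrom = chrom, pos = pos, meth = meth, cov = cov,
                   design = design, genome = truth$genome),
              class = "wgbs_cohort")
  })
}

#' Extract per-sample CpG count tables from a WGBS cohort
#' @param wgbs a `wgbs_cohort`.
#' @return named list of `data.frame`s (`chrom`, `pos`, `meth`, `total`).
#' @export
cpg_tables <- function(wgbs) {
  stats::setNames(lapply(seq_len(ncol(wgbs$meth)), function(j) {
    data.frame(chrom = wgbs$chrom, pos = wgbs$pos,
               meth = wgbs$meth[, j], total = wgbs$cov[, j])
  }), colnames(wgbs$meth))
}

#' Assemble per-sample CpG count tables into a WGBS cohort
#'
#' Aligns tables on the union of (chrom, pos) sites; absent sites get
#' zero coverage.
#'
#' @param tables named list of count tables (see [read_cpg_counts()]).
#' @param design cohort design whose `sample_id` matches the list names.
#' @return a `wgbs_cohort`.
#' @export
bind_cpg_tables <- function(tables, design) {
  stopifnot(!is.null(names(tables)), all(design$sample_id %in% names(tables)))
  tables <- tables[design$sample_id]
  key <- unique(do.call(rbind, lapply(tables, function(t) t[, c("chrom", "pos")])))
  key <- key[order(key$chrom, key$pos), ]
  id <- paste(key$chrom, key$pos)
  n <- nrow(key); ns <- length(tables)
  meth <- cov <- matrix(0L, n, ns, dimnames = list(NULL, names(tables)))
  for (j in seq_len(ns)) {
    m <- match(paste(tables[[j]]$chrom, tables[[j]]$pos), id)
    meth[m, j] <- as.integer(tables[[j]]$meth)
    cov[m, j] <- as.integer(tables[[j]]$total)
  }
  structure(list(chrom = key$chrom, pos = key$pos, meth = meth, cov = cov,
                 design = design, genome = NULL),
            class = "wgbs_cohort")
}

#' Simulate clinical photoage grades from block methylation
#'
#' Grades are an affine function of per-sample mean block methylation
#' (lower methylation, higher grade) plus Gaussian noise scaled so the
#' population R-squared equals `target_r2`, then rounded to the integer
#' 0-8 photoage scale. Rounding/clipping slightly attenuates the realized
#' R-squared.
#'
#' @param block_means per-sample mean methylation within blocks.
#' @param target_r2 in (0, 1].
#' @param grade_range integer grade scale limits.
#' @param seed integer seed.
#' @return integer grades, same length as `block_means`.
#' @export
simulate_clinical_grades <- function(block_means, target_r2 = 0.8,
                                     grade_range = c(0, 8), seed = 1) {
  stopifnot(target_r2 > 0, target_r2 <= 1)
  if (stats::sd(block_means) == 0 || any(is.na(block_means)))
    stop_mb("block means are constant or missing; grades undefined", "bad_input")
  with_rng(seed, {
    b <- (grade_range[1] - grade_range[2]) / (max(block_means) - min(block_means))
    a <- grade_range[2] - b * min(block_means)
    sig <- a + b * block_means
    noise_sd <- abs(b) * stats::sd(block_means) * sqrt(1 / target_r2 - 1)
    raw <- sig + rnorm(length(block_means), 0, noise_sd)
    as.integer(round(pmin(grade_range[2], pmax(grade_range[1], raw))))
  })
}

#' Write a simulated dataset and its truth to disk
#'
#' Emits the same formats the readers consume: probe annotation TSV, beta
#' matrix TSV, sample sheet CSV, per-sample bedGraph-like count tables,
#' truth BED files and a JSON sidecar with deltas and the seed.
#'
#' @param dir output directory (created).
#' @param annotation,truth,design,betas,wgbs components; `betas`/`wgbs`
#'   optional.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(dir, annotation, truth, design,
                             betas = NULL, wgbs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_probe_annotation(annotation, file.path(dir, "probes.tsv"))
  write.csv(design, file.path(dir, "samples.csv"), row.names = FALSE)
  if (!is.null(betas)) write_beta_matrix(betas, file.path(dir, "betas.tsv"))
  if (!is.null(wgbs)) {
    wdir <- file.path(dir, "wgbs"); dir.create(wdir, showWarnings = FALSE)
    tabs <- cpg_tables(wgbs)
    for (s in names(tabs))
      write_cpg_counts(tabs[[s]], file.path(wdir, paste0(s, ".bedgraph")))
  }
  write_bed(truth$blocks, file.path(dir, "truth_blocks.bed"))
  if (length(truth$dmrs)) write_bed(truth$dmrs, file.path(dir, "truth_dmrs.bed"))
  jsonlite::write_json(
    list(seed = truth$seed,
         genome = as.list(truth$genome),
         block_deltas = if (length(truth$blocks)) truth$blocks$delta else numeric(0),
         dmr_deltas = if (length(truth$dmrs)) truth$dmrs$delta else numeric(0)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
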