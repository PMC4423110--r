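#' Remove SNP-affected probes
#'
#' Drops every probe with an annotated SNP at the single-base extension
#' or CpG site. The number removed is recorded in attribute `n_removed`
#' and messaged.
#'
#' @param annotation probe annotation `data.frame`.
#' @return filtered annotation.
#' @export
filter_probes <- function(annotation) {
  n0 <- nrow(annotation)
  out <- annotation[!annotation$snp_flag, , drop = FALSE]
  message(sprintf("filter_probes: removed %d of %d SNP-flagged probes",
                  n0 - nrow(out), n0))
  attr(out, "n_removed") <- n0 - nrow(out)
  out
}

#' Collapse open-sea probes into gap-delimited regions
#'
#' Consecutive open-sea probes whose inter-probe gap is at most `max_gap`
#' form one region; each region's per-sample value is the arithmetic mean
#' of its member probe beta values (missing values ignored per probe).
#' Other relation classes are not used.
#'
#' @param annotation filtered probe annotation.
#' @param betas beta matrix, probes x samples (rownames = probe ids).
#' @param max_gap maximum intra-region inter-probe gap (bp).
#' @return a `collapsed_regions` list: `chrom`, `start`, `end`, `mid`,
#'   `n_probes`, `probe_idx` (list of annotation row indices), and
#'   `values` (regions x samples).
#' @export
collapse_open_sea <- function(annotation, betas, max_gap = 1500) {
  sea <- which(annotation$relation == "open_sea")
  if (length(sea) == 0) {
    warning("no open-sea probes; returning empty region set")
    return(structure(list(chrom = character(0), start = numeric(0),
                          end = numeric(0), mid = numeric(0),
                          n_probes = integer(0), probe_idx = list(),
                          values = matrix(0, 0, ncol(betas),
                                          dimnames = list(NULL, colnames(betas)))),
                     class = "collapsed_regions"))
  }
  ann <- annotation[sea, , drop = FALSE]
  ord <- order(ann$chrom, ann$pos)
  ann <- ann[ord, , drop = FALSE]; sea <- sea[ord]
  new_region <- c(TRUE, ann$chrom[-1] != ann$chrom[-nrow(ann)] |
                    diff(ann$pos) > max_gap)
  rid <- cumsum(new_region)
  B <- betas[ann$probe_id, , drop = FALSE]
  grp <- split(seq_len(nrow(ann)), rid)
  vals <- rowsum(ifelse(is.na(B), 0, B), rid) /
    pmax(1L, rowsum((!is.na(B)) + 0L, rid))
  vals[rowsum((!is.na(B)) + 0L, rid) == 0] <- NA
  structure(list(
    chrom = vapply(grp, function(i) ann$chrom[i[1]], character(1)),
    start = vapply(grp, function(i) ann$pos[i[1]], numeric(1)),
    end = vapply(grp, function(i) ann$pos[i[length(i)]], numeric(1)),
    mid = vapply(grp, function(i) round(mean(range(ann$pos[i]))), numeric(1)),
    n_probes = lengths(grp),
    probe_idx = lapply(grp, function(i) sea[i]),
    values = vals), class = "collapsed_regions")
}

#' Per-region group difference with precision weights
#'
#' The least-squares coefficient of the group indicator per region
#' (equal to `mean(groupA) - mean(groupB)` without covariates), weighted
#' by the number of member probes.
#'
#' @param regions a `collapsed_regions` object.
#' @param design cohort design.
#' @param comparison `c(groupA, groupB)`; positive differences mean A is
#'   more methylated.
#' @param covariates optional design column names to adjust for.
#' @return list with `d`, `weight`, `sel` (selected sample indices) and
#'   `g` (group indicator over `sel`).
#' @export
region_group_difference <- function(regions, design,
                                    comparison = c("O-exp", "Y-pro"),
                                    covariates = NULL) {
  ci <- comparison_index(design, comparison)
  if (min(sum(ci$g), sum(1 - ci$g)) < 2)
    stop_mb("each comparison group needs at least 2 samples", "bad_comparison")
  X0 <- covariate_matrix(design, ci$sel, covariates)
  d <- drop(group_coef_mat(regions$values[, ci$sel, drop = FALSE],
                           matrix(ci$g, ncol = 1), X0))
  list(d = d, weight = regions$n_probes, sel = ci$sel, g = ci$g)
}

#' Smooth region differences over a large window
#'
#' Weighted running mean of the per-region difference over all regions
#' within `window_bp / 2` of each region's midpoint (weights = member
#' probe counts); never crosses chromosome boundaries. Regions whose
#' window holds fewer than `min_regions` regions are flagged
#' unsmoothable and excluded from candidacy.
#'
#' @param regions a `collapsed_regions` object.
#' @param d per-region raw differences.
#' @param window_bp full smoothing window width (bp).
#' @param min_regions minimum regions per window.
#' @return list with `smoothed` and logical `smoothable`.
#' @export
smooth_differences <- function(regions, d, window_bp = 250000, min_regions = 5) {
  stopifnot(window_bp > 0, min_regions > 0)
  wi <- window_index(regions$chrom, regions$mid, window_bp)
  sm <- drop(smooth_mat(matrix(d, ncol = 1), regions$n_probes, wi$lo, wi$hi))
  list(smoothed = sm, smoothable = wi$count >= min_regions)
}

#' Threshold and segment smoothed differences into candidate blocks
#'
#' Maximal runs of consecutive smoothable regions whose smoothed
#' difference shares one sign and exceeds `threshold` in absolute value;
#' runs spanning `min_width_bp` or less are discarded. Block boundaries
#' are the span from the first to the last member region. `area` is the
#' sum of |smoothed difference| over member regions.
#'
#' @param regions a `collapsed_regions` object.
#' @param smoothing result of [smooth_differences()].
#' @param threshold minimum |smoothed difference| (beta units).
#' @param min_width_bp minimum block span (strict).
#' @return candidate `data.frame`.
#' @export
find_candidate_blocks <- function(regions, smoothing, threshold = 0.05,
                                  min_width_bp = 200000) {
  segment_runs(smoothing$smoothed, smoothing$smoothable, regions$chrom,
               regions$start, regions$end, threshold, min_width_bp)
}

# raw probe-level group mean difference within each candidate span
raw_span_diff <- function(cand, annotation, betas, sel, g, open_sea_only = TRUE) {
  if (nrow(cand) == 0) return(numeric(0))
  ann <- annotation
  if (open_sea_only) ann <- ann[ann$relation == "open_sea", , drop = FALSE]
  B <- betas[ann$probe_id, sel, drop = FALSE]
  mA <- rowMeans(B[, g == 1, drop = FALSE], na.rm = TRUE)
  mB <- rowMeans(B[, g == 0, drop = FALSE], na.rm = TRUE)
  pd <- mA - mB
  vapply(seq_len(nrow(cand)), function(k) {
    i <- ann$chrom == cand$chrom[k] & ann$pos >= cand$start[k] &
      ann$pos <= cand$end[k]
    mean(pd[i], na.rm = TRUE)
  }, numeric(1))
}

#' Permutation family-wise inference for candidate blocks
#'
#' For each null label assignment (shuffled within covariate strata when
#' covariates are supplied) the full difference, smoothing and
#' segmentation pipeline is re-run and the genome-wide maximum candidate
#' area recorded. `fwer_p = (1 + #\{null max >= area\}) / (1 + n_perm)`;
#' with fewer distinct assignments than `n_perm`, all are enumerated and
#' the count is exact.
#'
#' @param candidates observed candidates from [find_candidate_blocks()].
#' @param regions a `collapsed_regions` object.
#' @param design,comparison,covariates as in [region_group_difference()].
#' @param threshold,min_width_bp,window_bp,min_regions pipeline
#'   parameters (must match the observed call).
#' @param n_perm permutations (>= 20).
#' @param seed integer seed.
#' @return `candidates` with an `fwer_p` column; attribute `null_max`
#'   holds the null max-area distribution, attribute `exact` whether it
#'   was enumerated.
#' @export
block_fwer <- function(candidates, regions, design,
                       comparison = c("O-exp", "Y-pro"), covariates = NULL,
                       threshold = 0.05, min_width_bp = 200000,
                       window_bp = 250000, min_regions = 5,
                       n_perm = 400, seed = 1) {
  ci <- comparison_index(design, comparison)
  X0 <- covariate_matrix(design, ci$sel, covariates)
  strata <- perm_strata(design, ci$sel, covariates)
  pg <- perm_groups(ci$g, strata, n_perm, seed)
  Y <- regions$values[, ci$sel, drop = FALSE]
  D <- group_coef_mat(Y, pg$G, X0)
  wi <- window_index(regions$chrom, regions$mid, window_bp)
  SM <- smooth_mat(D, regions$n_probes, wi$lo, wi$hi)
  usable <- wi$count >= min_regions
  null_max <- vapply(seq_len(ncol(SM)), function(k) {
    cand <- segment_runs(SM[, k], usable, regions$chrom, regions$start,
                         regions$end, threshold, min_width_bp)
    if (nrow(cand) == 0) 0 else max(cand$area)
  }, numeric(1))
  candidates$fwer_p <- fwer_pvalues(candidates$area, null_max)
  attr(candidates, "null_max") <- null_max
  attr(candidates, "exact") <- pg$exact
  candidates
}

#' Find differentially methylated blocks in array data
#'
#' End-to-end 450k-style block finder: SNP-probe filtering, open-sea
#' collapsing, group differences (optionally covariate-adjusted),
#' large-window smoothing, thresholded segmentation, and permutation
#' family-wise inference. Defaults follow the published analysis: 5%
#' smoothed difference, blocks > 200 kb, FWER < 0.05.
#'
#' @param betas beta matrix, probes x samples.
#' @param annotation probe annotation (unfiltered; SNP probes dropped
#'   here).
#' @param design cohort design.
#' @param comparison `c(groupA, groupB)`.
#' @param covariates optional covariate column names.
#' @param max_gap open-sea collapsing gap (bp).
#' @param window_bp smoothing window (bp).
#' @param min_regions minimum regions per smoothing window.
#' @param threshold smoothed-difference threshold (beta units).
#' @param min_width_bp minimum block span (strict).
#' @param n_perm permutations.
#' @param alpha family-wise error cutoff for reported blocks.
#' @param seed integer seed.
#' @return a `block_calls` list: `blocks` (reported calls with
#'   `mean_diff`, `area`, `fwer_p`, `n_regions`), `candidates` (all, with
#'   p-values), `comparison`, `params`.
#' @export
find_blocks_array <- function(betas, annotation, design,
                              comparison = c("O-exp", "Y-pro"),
                              covariates = NULL, max_gap = 1500,
                              window_bp = 250000, min_regions = 5,
                              threshold = 0.05, min_width_bp = 200000,
                              n_perm = 400, alpha = 0.05, seed = 1) {
  ann <- suppressMessages(filter_probes(annotation))
  regions <- collapse_open_sea(ann, betas, max_gap)
  gd <- region_group_difference(regions, design, comparison, covariates)
  sm <- smooth_differences(regions, gd$d, window_bp, min_regions)
  cand <- find_candidate_blocks(regions, sm, threshold, min_width_bp)
  cand <- block_fwer(cand, regions, design, comparison, covariates,
                     threshold, min_width_bp, window_bp, min_regions,
                     n_perm, seed)
  cand$mean_diff <- raw_span_diff(cand, ann, betas, gd$sel, gd$g)
  cand$n_regions <- cand$n_units
  blocks <- cand[cand$fwer_p < alpha, , drop = FALSE]
  structure(list(
    blocks = blocks, candidates = cand, comparison = comparison,
    params = list(max_gap = max_gap, window_bp = window_bp,
                  min_regions = min_regions, threshold = threshold,
                  min_width_bp = min_width_bp, n_perm = n_perm,
                  alpha = alpha, seed = seed,
                  covariates = covariates,
                  exact_null = attr(cand, "exact"))),
    class = "block_calls")
}

#' @export
print.block_calls <- function(x, ...) {
  cat(sprintf("block_calls: %s vs %s - %d reported block(s) of %d candidate(s)\n",
              x$comparison[1], x$comparison[2], nrow(x$blocks),
              nrow(x$candidates)))
  if (nrow(x$blocks))
    print(x$blocks[, c("chrom", "start", "end", "width", "direction",
                       "mean_diff", "area", "fwer_p")], row.names = FALSE)
  invisible(x)
}
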