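#' Coverage filter for WGBS CpG sites
#'
#' A CpG is retained when every sample group passes the coverage
#' criterion at that site. Default interpretation (`mode =
#' "group_total"`): the group's summed coverage is at least `min_cov` and
#' at least one sample in the group covers the site. The strict
#' alternative (`mode = "per_sample"`) requires every sample of every
#' group to reach `min_cov`. The retained set is shared by all samples.
#'
#' @param wgbs a `wgbs_cohort`.
#' @param min_cov minimum coverage (reads).
#' @param mode "group_total" or "per_sample".
#' @return logical vector over sites.
#' @export
filter_cpgs <- function(wgbs, min_cov = 2, mode = c("group_total", "per_sample")) {
  mode <- match.arg(mode)
  groups <- unique(wgbs$design$group)
  keep <- rep(TRUE, length(wgbs$pos))
  for (gp in groups) {
    j <- wgbs$design$group == gp
    cv <- wgbs$cov[, j, drop = FALSE]
    keep <- keep & if (mode == "group_total") {
      rowSums(cv) >= min_cov & rowSums(cv > 0) >= 1
    } else {
      rowSums(cv >= min_cov) == sum(j)
    }
  }
  if (!any(keep))
    stop_mb(sprintf(
      "no CpG passes the coverage filter (min_cov = %d, mode = %s, %d sites)",
      min_cov, mode, length(keep)), "empty_filter")
  keep
}

#' Smoothing presets for WGBS methylomes
#'
#' `local` reproduces fine-scale smoothing (70 CpGs / >= 1 kb); `large`
#' is the block-hunting scale (500 CpGs / >= 20 kb).
#'
#' @param preset "large" or "local".
#' @return list with `min_cpgs` and `min_window_bp`.
#' @export
smoothing_preset <- function(preset = c("large", "local")) {
  preset <- match.arg(preset)
  if (preset == "large") list(min_cpgs = 500, min_window_bp = 20000)
  else list(min_cpgs = 70, min_window_bp = 1000)
}

# per-chromosome dispatch of the compiled local-linear smoother
smooth_one <- function(chrom, pos, y, wt, min_cpgs, min_window_bp) {
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (length(i) < min_cpgs) {
      warning(sprintf(
        "chromosome %s has %d < %d retained CpGs; using chromosome-wide weighted mean",
        ch, length(i), min_cpgs))
      w <- wt[i]
      out[i] <- if (sum(w) > 0) sum(y[i] * w, na.rm = TRUE) / sum(w)
                else mean(y[i], na.rm = TRUE)
    } else {
      out[i] <- .smooth_llin_cpp(as.numeric(pos[i]), as.numeric(y[i]),
                                 as.numeric(wt[i]), as.integer(min_cpgs),
                                 as.numeric(min_window_bp))
    }
  }
  out
}

#' Smooth per-sample methylation fractions
#'
#' At each retained CpG a coverage- and distance-weighted (tricube) local
#' linear trend of the methylation fraction is fit over the smallest
#' symmetric window holding at least `min_cpgs` CpGs and spanning at
#' least `min_window_bp`; the fitted value, clipped to [0, 1], is the
#' smoothed estimate. Smoothing never crosses chromosomes.
#'
#' @param wgbs a `wgbs_cohort`.
#' @param keep logical retained-site index from [filter_cpgs()].
#' @param min_cpgs minimum CpGs per window.
#' @param min_window_bp minimum window span (bp).
#' @return a `smoothed_methylome`: list with `chrom`, `pos` (retained
#'   sites), `smooth` (sites x samples), `raw` fractions, `cov`, `design`
#'   and the window metadata.
#' @export
smooth_methylation <- function(wgbs, keep = NULL, min_cpgs = 500,
                               min_window_bp = 20000) {
  stopifnot(min_cpgs > 0, min_window_bp > 0)
  if (is.null(keep)) keep <- rep(TRUE, length(wgbs$pos))
  chrom <- wgbs$chrom[keep]; pos <- wgbs$pos[keep]
  cov <- wgbs$cov[keep, , drop = FALSE]
  frac <- wgbs$meth[keep, , drop = FALSE] / ifelse(cov == 0, NA, cov)
  sm <- matrix(NA_real_, nrow(frac), ncol(frac),
               dimnames = dimnames(frac))
  for (j in seq_len(ncol(frac)))
    sm[, j] <- clip01(smooth_one(chrom, pos, frac[, j], cov[, j],
                                 min_cpgs, min_window_bp))
  structure(list(chrom = chrom, pos = pos, smooth = sm, raw = frac,
                 cov = cov, design = wgbs$design,
                 window = list(min_cpgs = min_cpgs,
                               min_window_bp = min_window_bp)),
            class = "smoothed_methylome")
}

#' Per-CpG t-statistics with reference-group variance
#'
#' `t = (mean_A - mean_B) / (sd_ref + floor)`, where `sd_ref` is the
#' standard deviation of the smoothed methylation across reference-group
#' samples, itself smoothed over the same window, and `floor` is the
#' 75th percentile of the genome-wide smoothed `sd_ref` (a variance
#' floor against near-constant sites).
#'
#' @param sm a `smoothed_methylome`.
#' @param comparison `c(groupA, groupB)`.
#' @param reference_group group supplying the variance (default Y-pro);
#'   needs >= 2 samples.
#' @param floor_quantile quantile of `sd_ref` used as the floor.
#' @return list with `t`, `sd_ref`, `floor`, `mean_a`, `mean_b`.
#' @export
group_tstat <- function(sm, comparison = c("O-exp", "Y-pro"),
                        reference_group = "Y-pro", floor_quantile = 0.75) {
  des <- sm$design
  jr <- which(des$group == reference_group)
  if (length(jr) < 2)
    stop_mb("reference group needs at least 2 samples", "bad_comparison")
  ja <- which(des$group == comparison[1])
  jb <- which(des$group == comparison[2])
  if (!length(ja) || !length(jb))
    stop_mb("comparison group absent from design", "bad_comparison")
  mean_a <- rowMeans(sm$smooth[, ja, drop = FALSE])
  mean_b <- rowMeans(sm$smooth[, jb, drop = FALSE])
  sd_raw <- apply(sm$smooth[, jr, drop = FALSE], 1, stats::sd)
  wt <- rowSums(sm$cov[, jr, drop = FALSE])
  sd_ref <- pmax(0, smooth_one(sm$chrom, sm$pos, sd_raw, wt,
                               sm$window$min_cpgs, sm$window$min_window_bp))
  floor <- stats::quantile(sd_ref, floor_quantile, na.rm = TRUE, names = FALSE)
  list(t = (mean_a - mean_b) / (sd_ref + floor), sd_ref = sd_ref,
       floor = floor, mean_a = mean_a, mean_b = mean_b)
}

# pooled raw group methylation fractions (sum meth / sum coverage)
pooled_group_frac <- function(wgbs_or_sm, keep, design, group) {
  j <- which(design$group == group)
  if (inherits(wgbs_or_sm, "wgbs_cohort")) {
    m <- rowSums(wgbs_or_sm$meth[keep, j, drop = FALSE])
    cv <- rowSums(wgbs_or_sm$cov[keep, j, drop = FALSE])
    m / ifelse(cv == 0, NA, cv)
  } else stop("expects a wgbs_cohort")
}

#' Call WGBS methylation blocks from t-statistics
#'
#' Maximal same-sign runs of retained CpGs with `|t| >= t_cut`, broken
#' where consecutive CpGs are more than `max_gap_bp` apart; a run is
#' reported when it spans more than `min_width_bp`, holds at least
#' `min_cpgs` CpGs and its raw pooled group difference exceeds
#' `min_meandiff` in absolute value. Defaults follow the published
#' cutoffs: t in (-2, 2), blocks > 10 kb, mean difference > 5%.
#'
#' @param tt result of [group_tstat()].
#' @param sm the `smoothed_methylome` the t-statistics came from.
#' @param wgbs the underlying `wgbs_cohort` (for raw pooled fractions).
#' @param keep retained-site index used to build `sm`.
#' @param comparison `c(groupA, groupB)`.
#' @param t_cut t-statistic cutoff.
#' @param min_width_bp minimum block span (strict).
#' @param min_meandiff minimum |raw mean difference| (strict).
#' @param max_gap_bp maximum intra-block CpG gap.
#' @param min_cpgs minimum CpGs per block.
#' @return `data.frame` of blocks with `mean_diff` (A - B, raw), `mean_t`
#'   and `n_cpgs`; never self-overlapping.
#' @export
call_wgbs_blocks <- function(tt, sm, wgbs, keep, comparison = c("O-exp", "Y-pro"),
                             t_cut = 2, min_width_bp = 10000,
                             min_meandiff = 0.05, max_gap_bp = 1000,
                             min_cpgs = 10) {
  t <- tt$t
  state <- ifelse(is.na(t) | abs(t) < t_cut, 0, sign(t))
  gap_break <- c(TRUE, sm$chrom[-1] != sm$chrom[-length(sm$chrom)] |
                   diff(sm$pos) > max_gap_bp)
  seg <- cumsum(gap_break)
  key <- paste(seg, state)
  r <- rle(key)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  sel <- state[idx_start] != 0
  if (!any(sel)) return(empty_wgbs_blocks())
  first <- idx_start[sel]; last <- idx_end[sel]
  fa <- pooled_group_frac(wgbs, keep, wgbs$design, comparison[1])
  fb <- pooled_group_frac(wgbs, keep, wgbs$design, comparison[2])
  out <- data.frame(
    chrom = sm$chrom[first], start = sm$pos[first], end = sm$pos[last],
    width = sm$pos[last] - sm$pos[first] + 1,
    n_cpgs = last - first + 1L,
    direction = ifelse(state[first] > 0, "hyper", "hypo"),
    mean_t = vapply(seq_along(first), function(k)
      mean(t[first[k]:last[k]]), numeric(1)),
    mean_diff = vapply(seq_along(first), function(k)
      mean(fa[first[k]:last[k]] - fb[first[k]:last[k]], na.rm = TRUE),
      numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[out$width > min_width_bp & out$n_cpgs >= min_cpgs &
               abs(out$mean_diff) > min_meandiff, , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(!self_overlapping(out))   # structural guarantee, asserted
  out
}

empty_wgbs_blocks <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             width = numeric(0), n_cpgs = integer(0), direction = character(0),
             mean_t = numeric(0), mean_diff = numeric(0),
             stringsAsFactors = FALSE)
}

self_overlapping <- function(calls) {
  if (nrow(calls) < 2) return(FALSE)
  gr <- calls_to_granges(calls)
  any(GenomicRanges::countOverlaps(gr, gr) > 1)
}

#' End-to-end WGBS block finder
#'
#' Coverage filtering, large-scale smoothing, reference-variance
#' t-statistics and block calling in one call.
#'
#' @param wgbs a `wgbs_cohort` (or named list of count tables plus a
#'   design via [bind_cpg_tables()]).
#' @param comparison `c(groupA, groupB)`.
#' @param reference_group variance reference group.
#' @param preset smoothing preset ("large" for block hunting).
#' @param min_cov coverage filter threshold.
#' @param mode coverage filter interpretation.
#' @param ... passed to [call_wgbs_blocks()].
#' @return a `wgbs_block_calls` list: `blocks`, `keep`, `smoothed`,
#'   `tstat`, `params`.
#' @export
find_blocks_wgbs <- function(wgbs, comparison = c("O-exp", "Y-pro"),
                             reference_group = "Y-pro",
                             preset = "large", min_cov = 2,
                             mode = "group_total", ...) {
  ps <- smoothing_preset(preset)
  keep <- filter_cpgs(wgbs, min_cov, mode)
  sm <- smooth_methylation(wgbs, keep, ps$min_cpgs, ps$min_window_bp)
  tt <- group_tstat(sm, comparison, reference_group)
  blocks <- call_wgbs_blocks(tt, sm, wgbs, keep, comparison, ...)
  structure(list(blocks = blocks, keep = keep, smoothed = sm, tstat = tt,
                 comparison = comparison,
                 params = c(ps, list(min_cov = min_cov, mode = mode,
                                     reference_group = reference_group))),
            class = "wgbs_block_calls")
}

#' Methylation density inside and outside blocks
#'
#' Histograms of smoothed methylation on a fixed [0, 1] bin grid, per
#' sample group, for all retained CpGs, CpGs inside blocks and CpGs
#' outside blocks. Masses sum to 1 within each non-empty partition.
#'
#' @param sm a `smoothed_methylome`.
#' @param blocks block `data.frame` (chrom/start/end).
#' @param breaks histogram bin edges on [0, 1].
#' @return long `data.frame`: `group`, `partition`, `bin_left`,
#'   `bin_right`, `mass`.
#' @export
methylation_density <- function(sm, blocks, breaks = seq(0, 1, by = 0.05)) {
  site <- GenomicRanges::GRanges(sm$chrom, IRanges::IRanges(sm$pos, sm$pos))
  inside <- if (nrow(blocks) == 0) rep(FALSE, length(sm$pos))
            else IRanges::overlapsAny(site, calls_to_granges(blocks))
  if (nrow(blocks) == 0)
    warning("empty block set: 'inside' partition is empty")
  parts <- list(all = rep(TRUE, length(sm$pos)), inside = inside,
                outside = !inside)
  out <- list()
  for (gp in unique(sm$design$group)) {
    v <- rowMeans(sm$smooth[, sm$design$group == gp, drop = FALSE])
    for (pn in names(parts)) {
      x <- v[parts[[pn]]]
      x <- x[!is.na(x)]
      cnt <- if (length(x)) {
        h <- hist(pmin(x, max(breaks) - 1e-9), breaks = breaks, plot = FALSE)
        h$counts / length(x)
      } else rep(NA_real_, length(breaks) - 1)
      out[[length(out) + 1L]] <- data.frame(
        group = gp, partition = pn, bin_left = head(breaks, -1),
        bin_right = breaks[-1], mass = cnt, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
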