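#' Per-sample mean methylation within each block
#'
#' Entry (s, b) is the mean methylation of sample s over the measured
#' sites inside block b. Blocks containing no measured site are dropped
#' with a warning. Ordering metadata for heatmap-style display is
#' attached: `sample_order` (rows by row mean) and `block_order`
#' (columns by group mean difference when a design and comparison are
#' supplied, else by column mean).
#'
#' @param betas beta matrix, probes x samples.
#' @param annotation probe annotation.
#' @param blocks block `data.frame` (chrom/start/end, 1-based closed).
#' @param design optional cohort design for the block ordering.
#' @param comparison optional `c(groupA, groupB)` for the block ordering.
#' @return samples x blocks matrix with ordering attributes.
#' @export
block_mean_matrix <- function(betas, annotation, blocks, design = NULL,
                              comparison = c("O-exp", "Y-pro")) {
  if (nrow(blocks) == 0)
    return(matrix(0, ncol(betas), 0, dimnames = list(colnames(betas), NULL)))
  ann <- annotation[order(annotation$chrom, annotation$pos), , drop = FALSE]
  B <- betas[ann$probe_id, , drop = FALSE]
  cols <- lapply(seq_len(nrow(blocks)), function(k) {
    i <- ann$chrom == blocks$chrom[k] & ann$pos >= blocks$start[k] &
      ann$pos <= blocks$end[k]
    if (!any(i)) return(NULL)
    colMeans(B[i, , drop = FALSE], na.rm = TRUE)
  })
  empty <- vapply(cols, is.null, logical(1))
  if (any(empty))
    warning(sprintf("%d block(s) contain no measured site and were dropped",
                    sum(empty)))
  m <- do.call(cbind, cols[!empty])
  colnames(m) <- sprintf("block_%d", which(!empty))
  attr(m, "sample_order") <- order(rowMeans(m))
  attr(m, "block_order") <- if (!is.null(design)) {
    da <- colMeans(m[design$group == comparison[1], , drop = FALSE])
    db <- colMeans(m[design$group == comparison[2], , drop = FALSE])
    order(da - db)
  } else order(colMeans(m))
  attr(m, "kept_blocks") <- which(!empty)
  m
}

#' Regress a clinical grade on block methylation
#'
#' Ordinary least squares of grade on per-sample mean block methylation,
#' with an optional subset filter (e.g. excluding face samples, the
#' published variant analysis). The reported R-squared is verified to
#' equal the squared Pearson correlation of fitted and observed values.
#'
#' @param block_means per-sample mean methylation within blocks.
#' @param grades clinical grades (same order).
#' @param subset optional logical filter over samples.
#' @return list: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
clinical_regression <- function(block_means, grades, subset = NULL) {
  if (!is.null(subset)) {
    block_means <- block_means[subset]
    grades <- grades[subset]
  }
  ok <- !is.na(block_means) & !is.na(grades)
  block_means <- block_means[ok]; grades <- grades[ok]
  if (length(grades) < 3)
    stop_mb("need at least 3 samples after filtering", "bad_input")
  if (stats::sd(block_means) == 0)
    stop_mb("constant block methylation; regression undefined", "bad_input")
  fit <- stats::lm(grades ~ block_means)
  s <- summary(fit)
  r2 <- s$r.squared
  stopifnot(abs(r2 - stats::cor(stats::fitted(fit), grades)^2) < 1e-8)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, p_value = s$coefficients[2, 4], n = length(grades))
}

#' Classical multidimensional scaling of samples
#'
#' Classical MDS on Euclidean pairwise distances between per-sample
#' methylation vectors. Axis signs are fixed by the
#' largest-magnitude-coordinate-positive convention so embeddings are
#' reproducible.
#'
#' @param betas beta matrix, probes x samples.
#' @param samples optional sample names / indices to embed.
#' @param n_dims embedding dimension.
#' @return samples x n_dims coordinate matrix.
#' @export
mds_embed <- function(betas, samples = NULL, n_dims = 2) {
  m <- if (is.null(samples)) betas else betas[, samples, drop = FALSE]
  if (ncol(m) < n_dims + 1)
    stop_mb("need more samples than embedding dimensions", "bad_input")
  d <- dist(t(m))
  xy <- cmdscale(d, k = n_dims)
  for (j in seq_len(ncol(xy))) {
    i <- which.max(abs(xy[, j]))
    if (xy[i, j] < 0) xy[, j] <- -xy[, j]
  }
  colnames(xy) <- paste0("MDS", seq_len(ncol(xy)))
  xy
}

#' Check the progressive-hypomethylation group ordering
#'
#' True when Y-pro has the highest mean block methylation, O-exp the
#' lowest, and both intermediates (O-pro, Y-exp) lie strictly between.
#'
#' @param block_matrix samples x blocks matrix from
#'   [block_mean_matrix()].
#' @param design cohort design (all four groups required for a verdict).
#' @return list: `group_means` (named, decreasing order expected
#'   Y-pro, intermediates, O-exp), `verdict` (logical or NA when a group
#'   is missing).
#' @export
group_trend_check <- function(block_matrix, design) {
  sample_means <- rowMeans(block_matrix)
  gm <- tapply(sample_means, design$group, mean)
  want <- c("Y-pro", "O-pro", "Y-exp", "O-exp")
  if (!all(want %in% names(gm))) {
    warning("missing group(s): partial report, no verdict")
    return(list(group_means = gm, verdict = NA))
  }
  verdict <- gm["Y-pro"] > gm["O-pro"] && gm["Y-pro"] > gm["Y-exp"] &&
    gm["O-exp"] < gm["O-pro"] && gm["O-exp"] < gm["Y-exp"]
  list(group_means = gm[want], verdict = unname(verdict))
}

#' Apply a frozen block set to a new cohort
#'
#' Computes the block methylation matrix and inside/outside-of-block
#' density summaries for a new cohort measured on the same probe
#' annotation, without re-discovering blocks (the block definitions are
#' hash-checked to prove they are unchanged).
#'
#' @param new_betas beta matrix of the new cohort.
#' @param annotation shared probe annotation; every probe of the new
#'   matrix must be annotated.
#' @param blocks frozen block `data.frame`.
#' @param new_design design of the new cohort (a `group` column drives
#'   the densities).
#' @param open_sea_only restrict densities to open-sea probes.
#' @param breaks density bin edges.
#' @return list: `block_means` (samples x blocks), `density` (long
#'   data.frame as in [methylation_density()]), `blocks_digest`.
#' @export
apply_blocks_to_cohort <- function(new_betas, annotation, blocks, new_design,
                                   open_sea_only = FALSE,
                                   breaks = seq(0, 1, by = 0.05)) {
  if (!all(rownames(new_betas) %in% annotation$probe_id))
    stop_mb("new cohort probes are not all present in the annotation",
            "annotation_mismatch")
  digest_in <- block_digest(blocks)
  ann <- annotation[annotation$probe_id %in% rownames(new_betas), , drop = FALSE]
  if (open_sea_only) ann <- ann[ann$relation == "open_sea", , drop = FALSE]
  m <- block_mean_matrix(new_betas[ann$probe_id, , drop = FALSE], ann, blocks)
  site <- GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$pos, ann$pos))
  inside <- IRanges::overlapsAny(site, calls_to_granges(blocks))
  B <- new_betas[ann$probe_id, , drop = FALSE]
  parts <- list(all = rep(TRUE, nrow(ann)), inside = inside, outside = !inside)
  dens <- list()
  for (gp in unique(new_design$group)) {
    v <- rowMeans(B[, new_design$group == gp, drop = FALSE], na.rm = TRUE)
    for (pn in names(parts)) {
      x <- v[parts[[pn]]]; x <- x[!is.na(x)]
      cnt <- if (length(x)) {
        h <- hist(pmin(x, max(breaks) - 1e-9), breaks = breaks, plot = FALSE)
        h$counts / length(x)
      } else rep(NA_real_, length(breaks) - 1)
      dens[[length(dens) + 1L]] <- data.frame(
        group = gp, partition = pn, bin_left = head(breaks, -1),
        bin_right = breaks[-1], mass = cnt, stringsAsFactors = FALSE)
    }
  }
  stopifnot(identical(block_digest(blocks), digest_in))  # frozen blocks
  list(block_means = m, density = do.call(rbind, dens),
       n_probes_used = nrow(ann), blocks_digest = digest_in)
}

block_digest <- function(blocks) {
  paste(blocks$chrom, blocks$start, blocks$end, collapse = ";")
}
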