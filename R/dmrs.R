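#' Per-probe group coefficients from a covariate-adjusted linear model
#'
#' Fits, per probe, least squares of beta on the group indicator plus
#' covariates (default sex and body site) and returns the group
#' coefficient and residual variance. Probes from all relation classes
#' are used.
#'
#' @param betas beta matrix, probes x samples.
#' @param annotation probe annotation (row order defines probe order).
#' @param design cohort design.
#' @param comparison `c(groupA, groupB)`.
#' @param covariates design columns to adjust for; NULL for none.
#' @return list with `coef`, `resid_var`, `sel`, `g` and the probe order
#'   used (`annotation` reordered by chrom, pos).
#' @export
probe_model_differences <- function(betas, annotation, design,
                                    comparison = c("O-exp", "Y-pro"),
                                    covariates = c("sex", "body_site")) {
  ann <- annotation[order(annotation$chrom, annotation$pos), , drop = FALSE]
  ci <- comparison_index(design, comparison)
  X0 <- covariate_matrix(design, ci$sel, covariates)
  Y <- betas[ann$probe_id, ci$sel, drop = FALSE]
  cf <- drop(group_coef_mat(Y, matrix(ci$g, ncol = 1), X0))
  # residual variance of the full fit (group + covariates)
  n <- length(ci$sel)
  if (is.null(X0)) X0 <- matrix(1, n, 1)
  X <- cbind(X0, g = ci$g)
  qx <- qr(X)
  res <- t(qr.resid(qx, t(as.matrix(Y))))
  rv <- rowSums(res^2) / max(1L, n - qx$rank)
  list(coef = cf, resid_var = rv, sel = ci$sel, g = ci$g, annotation = ann)
}

#' Segment per-probe coefficients into candidate small DMRs
#'
#' Probes are clustered by inter-probe gap; within a cluster, maximal
#' same-sign runs of probes with |coefficient| at or above `threshold`
#' and at least `min_probes` probes become candidates. `area` is the sum
#' of |coefficient| over member probes.
#'
#' @param fit result of [probe_model_differences()].
#' @param cluster_gap maximum intra-cluster inter-probe gap (bp).
#' @param threshold minimum |coefficient| (beta units).
#' @param min_probes minimum probes per DMR.
#' @return candidate `data.frame` with `n_probes` and `mean_change`.
#' @export
find_candidate_dmrs <- function(fit, cluster_gap = 500, threshold = 0.1,
                                min_probes = 2) {
  ann <- fit$annotation
  cand <- dmr_segment(fit$coef, ann, cluster_gap, threshold, min_probes)
  cand
}

# run scanner shared by the observed and the permuted passes
dmr_segment <- function(coefs, ann, cluster_gap, threshold, min_probes) {
  new_cluster <- c(TRUE, ann$chrom[-1] != ann$chrom[-nrow(ann)] |
                     diff(ann$pos) > cluster_gap)
  cl <- cumsum(new_cluster)
  state <- ifelse(is.na(coefs) | abs(coefs) < threshold, 0, sign(coefs))
  key <- paste(cl, state)
  r <- rle(key)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  keep <- state[idx_start] != 0 & r$lengths >= min_probes
  if (!any(keep)) return(empty_candidates())
  first <- idx_start[keep]; last <- idx_end[keep]
  data.frame(chrom = ann$chrom[first], start = ann$pos[first],
             end = ann$pos[last], width = ann$pos[last] - ann$pos[first] + 1,
             first = first, last = last, n_units = last - first + 1L,
             n_probes = last - first + 1L,
             direction = ifelse(state[first] > 0, "hyper", "hypo"),
             area = vapply(seq_along(first), function(k)
               sum(abs(coefs[first[k]:last[k]])), numeric(1)),
             mean_change = vapply(seq_along(first), function(k)
               mean(coefs[first[k]:last[k]]), numeric(1)),
             stringsAsFactors = FALSE)
}

#' Permutation family-wise inference for small DMRs
#'
#' Same contract as [block_fwer()] with the DMR candidate generator: per
#' null label assignment the probe-level model and run scanner are
#' re-run and the genome-wide maximum area recorded.
#'
#' @param candidates observed candidates from [find_candidate_dmrs()].
#' @param betas beta matrix.
#' @param fit result of [probe_model_differences()].
#' @param design,comparison,covariates as in
#'   [probe_model_differences()].
#' @param cluster_gap,threshold,min_probes candidate parameters (must
#'   match the observed pass).
#' @param n_perm permutations (>= 20).
#' @param seed integer seed.
#' @return `candidates` with `fwer_p`; attributes `null_max`, `exact`.
#' @export
dmr_fwer <- function(candidates, betas, fit, design,
                     comparison = c("O-exp", "Y-pro"),
                     covariates = c("sex", "body_site"),
                     cluster_gap = 500, threshold = 0.1, min_probes = 2,
                     n_perm = 400, seed = 1) {
  ann <- fit$annotation
  ci <- comparison_index(design, comparison)
  X0 <- covariate_matrix(design, ci$sel, covariates)
  strata <- perm_strata(design, ci$sel, covariates)
  pg <- perm_groups(ci$g, strata, n_perm, seed)
  Y <- betas[ann$probe_id, ci$sel, drop = FALSE]
  D <- group_coef_mat(Y, pg$G, X0)
  null_max <- vapply(seq_len(ncol(D)), function(k) {
    cand <- dmr_segment(D[, k], ann, cluster_gap, threshold, min_probes)
    if (nrow(cand) == 0) 0 else max(cand$area)
  }, numeric(1))
  candidates$fwer_p <- fwer_pvalues(candidates$area, null_max)
  attr(candidates, "null_max") <- null_max
  attr(candidates, "exact") <- pg$exact
  candidates
}

#' Find small differentially methylated regions in array data
#'
#' Probe-level bump hunting across all relation classes with covariate
#' adjustment and permutation family-wise inference. Defaults follow the
#' published analysis: 0.1 beta difference, sex and body-site
#' covariates, FWER < 0.1.
#'
#' @inheritParams probe_model_differences
#' @param cluster_gap probe clustering gap (bp).
#' @param threshold coefficient threshold (beta units).
#' @param min_probes minimum probes per DMR.
#' @param n_perm permutations.
#' @param alpha family-wise error cutoff.
#' @param seed integer seed.
#' @return a `dmr_calls` list: `dmrs` (reported, with `mean_diff` alias
#'   of the probe-mean change), `candidates`, `comparison`, `params`.
#' @export
find_dmrs <- function(betas, annotation, design,
                      comparison = c("O-exp", "Y-pro"),
                      covariates = c("sex", "body_site"), cluster_gap = 500,
                      threshold = 0.1, min_probes = 2, n_perm = 400,
                      alpha = 0.1, seed = 1) {
  ann <- suppressMessages(filter_probes(annotation))
  fit <- probe_model_differences(betas, ann, design, comparison, covariates)
  cand <- find_candidate_dmrs(fit, cluster_gap, threshold, min_probes)
  cand <- dmr_fwer(cand, betas, fit, design, comparison, covariates,
                   cluster_gap, threshold, min_probes, n_perm, seed)
  cand$mean_diff <- cand$mean_change
  dmrs <- cand[cand$fwer_p < alpha, , drop = FALSE]
  structure(list(
    dmrs = dmrs, candidates = cand, comparison = comparison,
    params = list(cluster_gap = cluster_gap, threshold = threshold,
                  min_probes = min_probes, n_perm = n_perm, alpha = alpha,
                  covariates = covariates, seed = seed,
                  exact_null = attr(cand, "exact"))),
    class = "dmr_calls")
}

#' @export
print.dmr_calls <- function(x, ...) {
  cat(sprintf("dmr_calls: %s vs %s - %d reported DMR(s) (%d hyper, %d hypo)\n",
              x$comparison[1], x$comparison[2], nrow(x$dmrs),
              sum(x$dmrs$direction == "hyper"),
              sum(x$dmrs$direction == "hypo")))
  invisible(x)
}
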