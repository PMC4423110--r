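#' Base-pair odds ratio of overlap between two interval sets
#'
#' Builds the 2x2 contingency of base pairs over a finite universe,
#' crossing membership in the query with membership in the reference,
#' and reports `OR = (a d) / (b c)`. When any cell is zero the Haldane
#' 0.5 correction is applied and flagged. A chi-square p-value on the bp
#' table is reported as a secondary, approximate statistic (base pairs
#' are autocorrelated).
#'
#' @param query,reference `GRanges` (clipped to the universe and merged
#'   internally).
#' @param universe `GRanges` defining the background; must be non-empty.
#' @return list: `odds_ratio`, `contingency` (2x2 bp counts), `corrected`
#'   flag, `chisq_p`.
#' @export
bp_odds_ratio <- function(query, reference, universe) {
  uni <- merge_intervals(universe)
  if (length(uni) == 0) stop_mb("empty universe", "bad_universe")
  q <- suppressWarnings(GenomicRanges::intersect(merge_intervals(query), uni,
                                                 ignore.strand = TRUE))
  r <- suppressWarnings(GenomicRanges::intersect(merge_intervals(reference), uni,
                                                 ignore.strand = TRUE))
  n <- total_width(uni)
  a <- overlap_bp(q, r)                       # in query, in reference
  b <- total_width(q) - a                     # in query, out of reference
  c_ <- total_width(r) - a                    # out of query, in reference
  d <- n - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(query = c("in", "out"),
                                reference = c("in", "out")))
  corrected <- any(tab == 0)
  tt <- if (corrected) tab + 0.5 else tab
  or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  chisq_p <- tryCatch(
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
    error = function(e) NA_real_)
  list(odds_ratio = unname(or), contingency = tab, corrected = corrected,
       chisq_p = chisq_p)
}

#' Width- and probe-matched random region sets
#'
#' For each template region (width w, holding k probes) draws a
#' probe-anchored start whose width-w window contains exactly k probes
#' where feasible, else the closest achievable count (logged in the
#' `relaxed` attribute). Regions within one random set never overlap
#' each other. Deterministic given `seed`.
#'
#' @param template `GRanges` of observed regions (e.g. called DMRs).
#' @param annotation probe annotation supplying the probe universe.
#' @param n_sets number of random sets.
#' @param seed integer seed.
#' @return list of `n_sets` `GRanges`, each with one region per template
#'   region.
#' @export
matched_random_sets <- function(template, annotation, n_sets = 1000, seed = 1) {
  ann <- annotation[order(annotation$chrom, annotation$pos), , drop = FALSE]
  probes <- GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$pos, ann$pos))
  widths <- GenomicRanges::width(template)
  k_target <- GenomicRanges::countOverlaps(template, probes)
  chroms <- split(seq_len(nrow(ann)), ann$chrom)
  chrom_max <- vapply(chroms, function(i) max(ann$pos[i]), numeric(1))

  # feasible anchor probes per template region, computed once
  anchors <- lapply(seq_along(widths), function(t) {
    w <- widths[t]
    feas <- list()
    for (ch in names(chroms)) {
      p <- ann$pos[chroms[[ch]]]
      cnt <- findInterval(p + w - 1 + 0.5, p) - seq_along(p) + 1L
      ok <- p + w - 1 <= chrom_max[ch]
      feas[[ch]] <- data.frame(chrom = rep(ch, sum(ok)), pos = p[ok],
                               count = cnt[ok])
    }
    feas <- do.call(rbind, feas)
    if (nrow(feas) == 0) {
      # region wider than any probe span: anchor anywhere, width-matched
      feas <- data.frame(chrom = ann$chrom, pos = ann$pos,
                         count = NA_integer_)
      feas$count <- -1L
    }
    hit <- feas[feas$count == k_target[t], , drop = FALSE]
    relaxed <- FALSE
    if (nrow(hit) == 0) {
      relaxed <- TRUE
      best <- min(abs(feas$count - k_target[t]))
      hit <- feas[abs(feas$count - k_target[t]) == best, , drop = FALSE]
    }
    list(chrom = hit$chrom, pos = hit$pos, relaxed = relaxed)
  })
  relaxed <- vapply(anchors, `[[`, logical(1), "relaxed")
  if (any(relaxed))
    warning(sprintf(
      "%d template region(s) had no exactly probe-matched window; width-matched with closest probe count",
      sum(relaxed)))

  with_rng(seed, {
    sets <- vector("list", n_sets)
    for (s in seq_len(n_sets)) {
      ch <- character(length(widths)); st <- en <- numeric(length(widths))
      for (t in order(widths, decreasing = TRUE)) {
        a <- anchors[[t]]
        for (try in seq_len(200)) {
          j <- sample.int(length(a$pos), 1)
          p <- a$pos[j]; cj <- a$chrom[j]
          e <- p + widths[t] - 1
          if (!any(ch == cj & st <= e & en >= p)) break
        }
        ch[t] <- cj; st[t] <- p; en[t] <- e
      }
      sets[[s]] <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, st + widths - 1))
    }
    attr(sets, "relaxed") <- relaxed
    sets
  })
}

#' Permutation overlap test against matched random regions
#'
#' Observed statistic: number of query regions overlapping the reference
#' by at least 1 bp; the null is the same count for each random set.
#' `empirical_p = (1 + #\{null >= observed\}) / (1 + n_sets)`; the query
#' is called significant when the observed count strictly exceeds the
#' 95th percentile of the null counts.
#'
#' @param query `GRanges` of called regions.
#' @param reference `GRanges` of reference marks.
#' @param random_sets list of `GRanges` from [matched_random_sets()]
#'   (generated with the query as template).
#' @return an `enrichment_result` list: `observed`, `null`, `empirical_p`,
#'   `significant`, `threshold` (null 95th percentile).
#' @export
permutation_overlap_test <- function(query, reference, random_sets) {
  if (length(random_sets) < 100)
    warning("fewer than 100 random sets: p-value resolution is coarse")
  ref <- merge_intervals(reference)
  count_hits <- function(gr) sum(IRanges::overlapsAny(gr, ref))
  observed <- count_hits(query)
  null <- vapply(random_sets, count_hits, numeric(1))
  thr <- stats::quantile(null, 0.95, type = 1, names = FALSE)
  structure(list(observed = observed, null = null,
                 empirical_p = (1 + sum(null >= observed)) / (1 + length(null)),
                 significant = observed > thr, threshold = thr),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: observed %d overlapping regions; null 95th pct %.1f; p = %.4g; %s\n",
    x$observed, x$threshold, x$empirical_p,
    if (x$significant) "SIGNIFICANT" else "not significant"))
  invisible(x)
}
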