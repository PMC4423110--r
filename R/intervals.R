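#' Construct a genomic interval set
#'
#' Builds a strand-less `GRanges` from 0-based half-open coordinates (the
#' BED convention used by all on-disk interval files in this package).
#' Internally intervals follow the Bioconductor 1-based closed convention;
#' conversion happens only here and in the BED reader/writer, so a single
#' convention holds on each side of the file boundary.
#'
#' @param chrom character chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end exclusive end positions; must satisfy `end > start`.
#' @param genome optional named vector of chromosome lengths.
#' @return a sorted `GRanges`.
#' @export
#' @examples
#' interval_set("chr1", c(0, 500), c(100, 900), genome = c(chr1 = 1000))
interval_set <- function(chrom, start, end, genome = NULL) {
  if (any(end <= start)) stop_mb("all intervals must have end > start", "bad_interval")
  if (any(start < 0)) stop_mb("starts must be non-negative", "bad_interval")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  if (!is.null(genome)) suppressWarnings({
    # bounds violations raise a classed error in check_bounds() instead
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- unname(genome)
  })
  check_bounds(gr)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

check_bounds <- function(gr) {
  sl <- GenomeInfoDb::seqlengths(gr)
  if (all(is.na(sl))) return(invisible(gr))
  lim <- sl[as.character(GenomeInfoDb::seqnames(gr))]
  bad <- !is.na(lim) & (GenomicRanges::end(gr) > lim | GenomicRanges::start(gr) < 1L)
  if (any(bad))
    stop_mb(sprintf("%d interval(s) outside chromosome bounds", sum(bad)),
            "interval_out_of_bounds")
  invisible(gr)
}

#' Merge an interval set into disjoint intervals
#'
#' Returns the minimal sorted set of disjoint, non-abutting intervals
#' covering the same base pairs. Idempotent.
#'
#' @param gr a `GRanges`.
#' @return merged `GRanges`.
#' @export
merge_intervals <- function(gr) {
  check_bounds(gr)
  GenomicRanges::reduce(GenomicRanges::sort(gr, ignore.strand = TRUE),
                        ignore.strand = TRUE)
}

#' Total base pairs covered by an interval set
#' @param gr a `GRanges`.
#' @return integer bp count of the merged set.
#' @export
total_width <- function(gr) sum(as.numeric(GenomicRanges::width(merge_intervals(gr))))

check_same_genome <- function(a, b) {
  sla <- GenomeInfoDb::seqlengths(a); slb <- GenomeInfoDb::seqlengths(b)
  shared <- intersect(names(sla)[!is.na(sla)], names(slb)[!is.na(slb)])
  if (length(shared) && !identical(sla[shared], slb[shared]))
    stop_mb("interval sets carry conflicting chromosome lengths", "genome_mismatch")
  invisible(TRUE)
}

#' Shared base pairs between two interval sets
#'
#' @param a,b `GRanges` (merged internally).
#' @return numeric bp of overlap; `overlap_bp(a, b) <= min(total_width(a),
#'   total_width(b))`.
#' @export
overlap_bp <- function(a, b) {
  check_same_genome(a, b)
  a <- merge_intervals(a); b <- merge_intervals(b)
  ov <- suppressWarnings(GenomicRanges::intersect(a, b, ignore.strand = TRUE))
  sum(as.numeric(GenomicRanges::width(ov)))
}

#' Jaccard similarity of two interval sets (bp units)
#'
#' `|a intersect b| / |a union b|` in base pairs; 0 when both sets are
#' empty. Symmetric.
#'
#' @param a,b `GRanges`.
#' @return fraction in `[0, 1]`.
#' @export
interval_jaccard <- function(a, b) {
  check_same_genome(a, b)
  a <- merge_intervals(a); b <- merge_intervals(b)
  un <- sum(as.numeric(GenomicRanges::width(
    suppressWarnings(GenomicRanges::union(a, b, ignore.strand = TRUE)))))
  if (un == 0) return(0)
  overlap_bp(a, b) / un
}

#' Read a BED3 file as an interval set
#' @param path BED file path.
#' @param genome optional named chromosome lengths.
#' @return `GRanges`.
#' @export
read_bed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::strand(gr) <- "*"
  S4Vectors::mcols(gr) <- NULL
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr), names(genome))
    GenomeInfoDb::seqlengths(gr) <- unname(genome[GenomeInfoDb::seqlevels(gr)])
    check_bounds(gr)
  }
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write an interval set as BED3
#' @param gr `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  out <- gr
  S4Vectors::mcols(out) <- NULL
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}
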