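#' Read a probe annotation table
#'
#' Tab-separated with columns `probe_id`, `chrom`, `pos` (1-based position
#' of the interrogated CpG), `relation` (one of `island`, `shore`,
#' `open_sea`) and `snp_flag` (TRUE for probes with an annotated SNP at the
#' single-base extension or CpG site).
#'
#' @param path TSV path.
#' @return a `data.frame` sorted by (chrom, pos), probe ids unique.
#' @export
read_probe_annotation <- function(path) {
  ann <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  validate_probe_annotation(ann)
}

validate_probe_annotation <- function(ann) {
  need <- c("probe_id", "chrom", "pos", "relation", "snp_flag")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop_mb(paste("probe annotation lacks columns:", paste(miss, collapse = ", ")),
            "bad_annotation")
  if (anyDuplicated(ann$probe_id))
    stop_mb("probe ids are not unique", "bad_annotation")
  bad <- setdiff(unique(ann$relation), c("island", "shore", "open_sea"))
  if (length(bad))
    stop_mb(paste("unknown relation class:", paste(bad, collapse = ", ")),
            "bad_annotation")
  ann$snp_flag <- as.logical(ann$snp_flag)
  ann[order(ann$chrom, ann$pos), , drop = FALSE]
}

#' Write a probe annotation table
#' @param ann annotation `data.frame`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(ann, path) {
  data.table::fwrite(ann, path, sep = "\t")
  invisible(path)
}

#' Read a beta-value matrix
#'
#' TSV with probes as rows (first column `probe_id`) and samples as
#' columns; values are methylation fractions in `[0, 1]` or NA.
#'
#' @param path TSV path.
#' @return numeric matrix, probes x samples, rownames = probe ids.
#' @export
read_beta_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  validate_beta_matrix(m)
  m
}

validate_beta_matrix <- function(m) {
  rng <- range(m, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop_mb("beta values outside [0, 1]", "bad_beta")
  invisible(m)
}

#' Write a beta-value matrix
#' @param m probes x samples matrix with rownames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path) {
  dt <- data.table::data.table(probe_id = rownames(m))
  for (s in colnames(m)) dt[[s]] <- m[, s]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with per-sample metadata: `sample_id`, `tissue` (epidermis/dermis),
#' `age_group` (younger/older), `exposure` (protected/exposed),
#' `body_site` (arm/face), `sex` (F/M), and optional integer
#' `griffiths_grade` / `helfrich_grade` photoaging scores. A `group`
#' column (Y-pro/Y-exp/O-pro/O-exp) is derived, never read.
#'
#' @param path CSV path.
#' @return a cohort design `data.frame` with the derived `group` column.
#' @export
read_sample_sheet <- function(path) {
  validate_design(read.csv(path, stringsAsFactors = FALSE))
}

#' Group label from age group and exposure
#' @param age_group "younger"/"older".
#' @param exposure "protected"/"exposed".
#' @return character vector like "Y-pro", "O-exp".
#' @export
group_label <- function(age_group, exposure) {
  paste0(ifelse(age_group == "younger", "Y", "O"),
         "-", ifelse(exposure == "protected", "pro", "exp"))
}

validate_design <- function(design) {
  need <- c("sample_id", "tissue", "age_group", "exposure", "body_site", "sex")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop_mb(paste("sample sheet lacks columns:", paste(miss, collapse = ", ")),
            "bad_design")
  stopifnot(all(design$age_group %in% c("younger", "older")),
            all(design$exposure %in% c("protected", "exposed")))
  design$group <- group_label(design$age_group, design$exposure)
  design
}

#' Read a per-sample CpG count table
#'
#' Accepts the 5-column bedGraph-like dialect (`chrom`, `start`, `end`,
#' `meth`, `total`; 0-based half-open, the writer's format) or the
#' 4-column dialect (`chrom`, `pos`, `meth`, `total`; 0-based CpG
#' position). Dialect is auto-detected from the column count unless
#' forced.
#'
#' @param path TSV path (no header).
#' @param format "auto", "bedgraph5" or "pos4".
#' @return `data.frame` with `chrom`, `pos` (1-based), `meth`, `total`.
#' @export
read_cpg_counts <- function(path, format = c("auto", "bedgraph5", "pos4")) {
  format <- match.arg(format)
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
  if (format == "auto")
    format <- if (ncol(dt) >= 5) "bedgraph5" else "pos4"
  tab <- if (format == "bedgraph5") {
    data.frame(chrom = dt[[1]], pos = dt[[2]] + 1L, meth = dt[[4]], total = dt[[5]])
  } else {
    data.frame(chrom = dt[[1]], pos = dt[[2]] + 1L, meth = dt[[3]], total = dt[[4]])
  }
  validate_cpg_counts(tab)
}

validate_cpg_counts <- function(tab) {
  if (any(tab$meth > tab$total))
    stop_mb("methylated counts exceed total counts", "bad_counts")
  if (any(tab$total < 0) || any(tab$meth < 0))
    stop_mb("negative read counts", "bad_counts")
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  if (any(stats::ave(tab$pos, tab$chrom, FUN = function(p) c(1, diff(p))) <= 0))
    stop_mb("duplicate CpG positions within a chromosome", "bad_counts")
  tab
}

#' Write a CpG count table in bedGraph-like form
#' @param tab `data.frame` with `chrom`, `pos` (1-based), `meth`, `total`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cpg_counts <- function(tab, path) {
  out <- data.table::data.table(chrom = tab$chrom, start = tab$pos - 1L,
                                end = tab$pos, meth = tab$meth, total = tab$total)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a block or DMR call set as BED6 plus a statistics TSV
#'
#' BED6 columns: chrom, start, end, name (comparison label), score
#' (`round(1000 * |mean_diff|)` capped at 1000), strand ".". The companion
#' `<path>.stats.tsv` carries the full per-region statistics.
#'
#' @param calls call-set `data.frame` with `chrom`, `start`, `end`,
#'   `mean_diff` and any extra statistic columns.
#' @param path BED output path.
#' @param name region name stem (e.g. the comparison label).
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path, name = "region") {
  bed <- data.table::data.table(
    chrom = calls$chrom, start = calls$start - 1L, end = calls$end,
    name = sprintf("%s_%d", name, seq_len(nrow(calls))),
    score = pmin(1000L, as.integer(round(1000 * abs(calls$mean_diff)))),
    strand = ".")
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  data.table::fwrite(calls, paste0(path, ".stats.tsv"), sep = "\t")
  invisible(path)
}

#' Convert a call-set data frame to a GRanges
#' @param calls `data.frame` with `chrom`, `start`, `end` (1-based closed).
#' @param genome optional named chromosome lengths.
#' @return `GRanges` with the remaining columns as metadata.
#' @export
calls_to_granges <- function(calls, genome = NULL) {
  if (nrow(calls) == 0) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$start, calls$end))
  extra <- setdiff(names(calls), c("chrom", "start", "end"))
  S4Vectors::mcols(gr) <- calls[, extra, drop = FALSE]
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr), names(genome))
    GenomeInfoDb::seqlengths(gr) <- unname(genome[GenomeInfoDb::seqlevels(gr)])
  }
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}
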