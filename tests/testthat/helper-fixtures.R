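# Shared fixtures, built in code. The cache avoids re-simulating the
# same cohort across test files; everything is seeded and deterministic.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

# small planted-truth array cohort used by several modules
std_sim <- function() fixture("std_sim", function() {
  cfg <- genome_config(block_delta = 0.09)
  sim <- simulate_genome(cfg, seed = 1)
  design <- make_design(10)
  betas <- simulate_array_cohort(sim$annotation, sim$truth, design, seed = 101)
  list(cfg = cfg, sim = sim, design = design, betas = betas)
})

# hand-built probe annotation on one toy chromosome
toy_annotation <- function(pos = c(1000, 1400, 2200, 6000, 9000),
                           relation = rep("open_sea", length(pos)),
                           snp = rep(FALSE, length(pos))) {
  data.frame(probe_id = sprintf("p%02d", seq_along(pos)), chrom = "chr1",
             pos = pos, relation = relation, snp_flag = snp,
             stringsAsFactors = FALSE)
}

toy_betas <- function(ann, values) {
  m <- matrix(values, nrow = nrow(ann))
  rownames(m) <- ann$probe_id
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  m
}

toy_design <- function(groups) {
  n <- length(groups)
  parts <- strsplit(groups, "-")
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             tissue = "epidermis",
             age_group = ifelse(vapply(parts, `[`, "", 1) == "Y", "younger", "older"),
             exposure = ifelse(vapply(parts, `[`, "", 2) == "pro", "protected", "exposed"),
             body_site = rep(c("arm", "arm", "face", "face"), length.out = n),
             sex = rep(c("F", "M"), length.out = n),
             group = groups, stringsAsFactors = FALSE)
}

# exhaustive per-bp membership mask over a single toy chromosome
bp_mask <- function(gr, chrom_len) {
  mask <- logical(chrom_len)
  for (i in seq_along(gr)) {
    s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
    mask[s:e] <- TRUE
  }
  mask
}

random_interval_set <- function(n, chrom_len, genome = c(chr1 = chrom_len)) {
  st <- sample.int(chrom_len - 1000, n)
  w <- sample.int(900, n)
  interval_set("chr1", st - 1, st - 1 + w, genome = genome)
}
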