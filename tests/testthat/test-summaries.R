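test_that("block mean matrix equals brute-force per-block averages", {
  s <- std_sim()
  tr <- s$sim$truth$blocks
  blocks <- data.frame(chrom = as.character(GenomicRanges::seqnames(tr)),
                       start = GenomicRanges::start(tr),
                       end = GenomicRanges::end(tr))
  m <- block_mean_matrix(s$betas, s$sim$annotation, blocks, s$design)
  expect_equal(dim(m), c(40, 15))
  expect_true(all(m >= 0 & m <= 1))
  ann <- s$sim$annotation
  for (k in c(1, 7, 15)) {
    ids <- ann$probe_id[ann$chrom == blocks$chrom[k] &
                          ann$pos >= blocks$start[k] & ann$pos <= blocks$end[k]]
    expect_equal(unname(m[, k]), unname(colMeans(s$betas[ids, , drop = FALSE])),
                 tolerance = 1e-12)
  }

  # one block, one probe: the matrix is that probe's betas
  one <- data.frame(chrom = ann$chrom[5], start = ann$pos[5], end = ann$pos[5])
  m1 <- block_mean_matrix(s$betas, ann, one)
  expect_equal(unname(m1[, 1]), unname(s$betas[ann$probe_id[5], ]))

  # empty block dropped with a warning
  gap <- data.frame(chrom = "chr1", start = 2, end = 3)
  expect_warning(m2 <- block_mean_matrix(s$betas, ann, rbind(blocks, gap)),
                 "dropped")
  expect_equal(ncol(m2), 15)

  # commutes with sample subsetting
  sub <- s$design$group %in% c("O-exp", "Y-pro")
  m_sub <- block_mean_matrix(s$betas[, sub], ann, blocks)
  expect_equal(unname(m_sub), unname(m[sub, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("clinical regression matches its definition and guards input", {
  x <- seq(0.6, 0.9, length.out = 20)
  g <- 8 - 20 * (x - 0.6)
  out <- suppressWarnings(clinical_regression(x, g))  # perfect-fit lm warning
  expect_gt(out$r_squared, 1 - 1e-12)   # perfectly affine relation

  set.seed(3)
  g2 <- sample(0:8, 20, replace = TRUE)
  out2 <- clinical_regression(x, g2)
  fit <- lm(g2 ~ x)
  expect_equal(out2$r_squared, summary(fit)$r.squared, tolerance = 1e-12)
  expect_equal(out2$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(out2$p_value, summary(fit)$coefficients[2, 4], tolerance = 1e-12)

  # subset filter
  keep <- rep(c(TRUE, FALSE), 10)
  out3 <- clinical_regression(x, g2, subset = keep)
  expect_equal(out3$n, 10)

  expect_error(clinical_regression(rep(0.5, 10), g2[1:10]), class = "bad_input")
  expect_error(clinical_regression(x[1:2], g2[1:2]), class = "bad_input")
})

test_that("null regression R-squared scales like 1/(n-1)", {
  set.seed(5)
  r2s <- replicate(200, {
    x <- runif(50); y <- rnorm(50)
    clinical_regression(x, y)$r_squared
  })
  expect_lt(abs(mean(r2s) - 1 / 49), 0.01)
})

test_that("MDS embedding is reproducible and metric-faithful", {
  # intrinsically 2-D configuration: exact distance recovery
  set.seed(7)
  xy0 <- cbind(runif(12), runif(12))
  basis <- qr.Q(qr(matrix(rnorm(50 * 2), 50)))
  m <- t(xy0 %*% t(basis))            # 50 "probes" x 12 samples
  colnames(m) <- sprintf("s%02d", 1:12)
  emb <- mds_embed(m, n_dims = 2)
  expect_equal(as.matrix(dist(emb)), as.matrix(dist(t(m))), tolerance = 1e-8)

  # identical samples coincide
  m2 <- cbind(m, s99 = m[, 1])
  emb2 <- mds_embed(m2)
  expect_lt(max(abs(emb2["s99", ] - emb2["s01", ])), 1e-8)

  # deterministic sign convention
  expect_identical(mds_embed(m), mds_embed(m))
  expect_error(mds_embed(m[, 1:2], n_dims = 2), class = "bad_input")
})

test_that("groups separate in MDS for planted effects, not for nulls", {
  s <- std_sim()
  emb <- mds_embed(s$betas)
  d <- s$design
  sep <- function(e) {
    mu <- rowsum(e, d$group) / as.vector(table(d$group))
    between <- mean(dist(mu))
    within <- mean(vapply(unique(d$group), function(g)
      mean(dist(e[d$group == g, ])), numeric(1)))
    between / within
  }
  b0 <- simulate_array_cohort(s$sim$annotation, s$sim$truth, d,
                              gradient = group_gradient(0) * 0, seed = 99)
  expect_gt(sep(emb), 2 * sep(mds_embed(b0)))
})

test_that("group trend verdict follows the planted gradient", {
  s <- std_sim()
  tr <- s$sim$truth$blocks
  blocks <- data.frame(chrom = as.character(GenomicRanges::seqnames(tr)),
                       start = GenomicRanges::start(tr),
                       end = GenomicRanges::end(tr))
  m <- block_mean_matrix(s$betas, s$sim$annotation, blocks, s$design)
  out <- group_trend_check(m, s$design)
  expect_true(out$verdict)
  expect_equal(names(out$group_means), c("Y-pro", "O-pro", "Y-exp", "O-exp"))
  expect_gt(out$group_means[["Y-pro"]], out$group_means[["O-exp"]])

  # equal group means: strict inequality fails
  m_eq <- matrix(0.5, nrow(m), ncol(m), dimnames = dimnames(m))
  out_eq <- group_trend_check(m_eq, s$design)
  expect_false(out_eq$verdict)

  # missing group: partial report, NA verdict
  sub <- s$design$group != "O-pro"
  expect_warning(out_na <- group_trend_check(m[sub, ], s$design[sub, ]),
                 "missing")
  expect_true(is.na(out_na$verdict))
})

test_that("frozen blocks applied to a new cohort", {
  s <- std_sim()
  tr <- s$sim$truth$blocks
  blocks <- data.frame(chrom = as.character(GenomicRanges::seqnames(tr)),
                       start = GenomicRanges::start(tr),
                       end = GenomicRanges::end(tr))
  # identity: same cohort gives the same matrix
  ap <- apply_blocks_to_cohort(s$betas, s$sim$annotation, blocks, s$design)
  m <- block_mean_matrix(s$betas, s$sim$annotation, blocks)
  expect_equal(unname(ap$block_means), unname(m), tolerance = 1e-12)

  # a "tumor" group with deeper in-block loss lowers in-block means only
  tumor_truth <- s$sim$truth
  tumor_truth$blocks$delta <- pmin(0.45, tr$delta + 0.25)
  des_t <- s$design
  b_t <- simulate_array_cohort(s$sim$annotation, tumor_truth, des_t, seed = 55)
  ap_t <- apply_blocks_to_cohort(b_t, s$sim$annotation, blocks, des_t)
  oexp <- des_t$group == "O-exp"
  frac_lower <- mean(colMeans(ap_t$block_means[oexp, , drop = FALSE]) <
                       colMeans(ap$block_means[oexp, , drop = FALSE]))
  expect_gte(frac_lower, 1)             # every block drops further
  out_cmp <- merge(
    ap$density[ap$density$partition == "outside" & ap$density$group == "O-exp", ],
    ap_t$density[ap_t$density$partition == "outside" & ap_t$density$group == "O-exp", ],
    by = c("bin_left", "bin_right"))
  expect_lt(max(abs(out_cmp$mass.x - out_cmp$mass.y)), 0.05)

  # open-sea restriction uses only open-sea probes
  ap_os <- apply_blocks_to_cohort(s$betas, s$sim$annotation, blocks, s$design,
                                  open_sea_only = TRUE)
  expect_equal(ap_os$n_probes_used,
               sum(s$sim$annotation$relation == "open_sea"))

  # annotation mismatch rejected
  bad <- s$betas
  rownames(bad)[1] <- "cg_unknown"
  expect_error(apply_blocks_to_cohort(bad, s$sim$annotation, blocks, s$design),
               class = "annotation_mismatch")
})
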