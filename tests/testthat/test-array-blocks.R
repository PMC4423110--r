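test_that("SNP-flagged probes are removed and counted", {
  ann <- toy_annotation(pos = seq(1000, 100000, length.out = 100),
                        snp = rep(c(TRUE, rep(FALSE, 9)), 10))
  expect_message(out <- filter_probes(ann), "removed 10 of 100")
  expect_equal(nrow(out), 90)
  expect_equal(attr(out, "n_removed"), 10)
  ann2 <- toy_annotation()
  expect_equal(nrow(suppressMessages(filter_probes(ann2))), nrow(ann2))
})

test_that("open-sea collapsing follows the gap rule", {
  ann <- toy_annotation(pos = c(1000, 1400, 2200))
  b <- toy_betas(ann, c(0.8, 0.6, 0.7, 0.9, 0.7, 0.8))
  r <- collapse_open_sea(ann, b, max_gap = 1500)
  expect_equal(length(r$chrom), 1)          # gaps 400, 800 merge
  expect_equal(r$n_probes, c(`1` = 3L))

  ann2 <- toy_annotation(pos = c(1000, 3000))
  r2 <- collapse_open_sea(ann2, toy_betas(ann2, runif(4)), max_gap = 1500)
  expect_equal(length(r2$chrom), 2)         # gap 2000 splits

  # island/shore probes never enter
  ann3 <- toy_annotation(relation = c("island", "open_sea", "open_sea",
                                      "shore", "open_sea"))
  r3 <- collapse_open_sea(ann3, toy_betas(ann3, runif(10)), max_gap = 1e6)
  expect_equal(sum(r3$n_probes), 3)
})

test_that("collapsed region means equal brute-force per-region averages", {
  set.seed(7)
  pos <- sort(sample.int(5e5, 300))
  ann <- toy_annotation(pos = pos, relation = rep("open_sea", 300))
  b <- toy_betas(ann, runif(300 * 8))
  r <- collapse_open_sea(ann, b, max_gap = 1500)
  for (k in sample(length(r$chrom), 20)) {
    ids <- ann$probe_id[ann$pos >= r$start[k] & ann$pos <= r$end[k]]
    expect_equal(unname(r$values[k, ]), unname(colMeans(b[ids, , drop = FALSE])),
                 tolerance = 1e-12)
  }
  expect_equal(sum(r$n_probes), 300)
})

test_that("region group differences equal the least-squares oracle", {
  ann <- toy_annotation(pos = c(1000, 1400, 5000, 9000))
  des <- toy_design(c("O-exp", "O-exp", "Y-pro", "Y-pro"))
  b <- toy_betas(ann, rep(c(0.8, 0.8, 0.7, 0.7), each = 4))
  r <- collapse_open_sea(ann, b)
  gd <- region_group_difference(r, des, c("O-exp", "Y-pro"))
  expect_equal(unname(gd$d), rep(0.10, length(gd$d)), tolerance = 1e-12)

  # identical groups give zero
  b2 <- toy_betas(ann, rep(0.5, 16))
  gd2 <- region_group_difference(collapse_open_sea(ann, b2), des,
                                 c("O-exp", "Y-pro"))
  expect_equal(unname(gd2$d), rep(0, length(gd2$d)))

  # with a binary covariate the coefficient matches lm()
  set.seed(3)
  des8 <- toy_design(c("O-exp", "O-exp", "O-exp", "O-exp",
                       "Y-pro", "Y-pro", "Y-pro", "Y-pro"))
  b8 <- toy_betas(ann, runif(32))
  r8 <- collapse_open_sea(ann, b8)
  gd8 <- region_group_difference(r8, des8, c("O-exp", "Y-pro"),
                                 covariates = "sex")
  for (k in seq_along(gd8$d)) {
    fit <- lm(r8$values[k, ] ~ I(des8$group == "O-exp") + des8$sex)
    expect_equal(unname(gd8$d[k]), unname(coef(fit)[2]), tolerance = 1e-10)
  }

  des_small <- toy_design(c("O-exp", "Y-pro", "Y-pro"))
  expect_error(region_group_difference(r, des_small, c("O-exp", "Y-pro")),
               class = "bad_comparison")
})

test_that("smoothing matches a brute-force windowed weighted mean", {
  set.seed(9)
  pos <- sort(sample.int(3e6, 400))
  ann <- toy_annotation(pos = pos, relation = rep("open_sea", 400))
  b <- toy_betas(ann, runif(400 * 4))
  r <- collapse_open_sea(ann, b, max_gap = 2000)
  d <- rnorm(length(r$chrom), 0, 0.05)
  sm <- smooth_differences(r, d, window_bp = 250000, min_regions = 5)
  w <- r$n_probes
  half <- 125000
  for (i in seq_along(d)) {
    j <- which(r$chrom == r$chrom[i] & abs(r$mid - r$mid[i]) <= half)
    expect_equal(sm$smoothed[i], sum(d[j] * w[j]) / sum(w[j]),
                 tolerance = 1e-10)
    expect_equal(sm$smoothable[i], length(j) >= 5)
  }

  # constant differences are preserved exactly
  smc <- smooth_differences(r, rep(0.09, length(d)))
  expect_equal(smc$smoothed, rep(0.09, length(d)), tolerance = 1e-12)
})

test_that("an isolated region is flagged unsmoothable", {
  ann <- toy_annotation(pos = c(1e4, 2e6, 2.002e6, 2.004e6, 2.006e6, 2.008e6))
  b <- toy_betas(ann, runif(12))
  r <- collapse_open_sea(ann, b, max_gap = 1500)
  sm <- smooth_differences(r, rnorm(length(r$chrom)), window_bp = 250000,
                           min_regions = 5)
  expect_false(sm$smoothable[1])
  expect_true(all(sm$smoothable[-1]))
})

test_that("candidate blocks respect threshold and width filters", {
  # synthetic smoothed landscape: one 150 kb run and one 400 kb run
  mk_regions <- function(pos) {
    structure(list(chrom = rep("chr1", length(pos)), start = pos, end = pos,
                   mid = pos, n_probes = rep(1L, length(pos)),
                   probe_idx = as.list(seq_along(pos)),
                   values = matrix(0, length(pos), 2)),
              class = "collapsed_regions")
  }
  pos <- seq(1e5, 3e6, by = 1e4)
  r <- mk_regions(pos)
  x <- rep(0, length(pos))
  x[pos >= 5e5 & pos <= 6.5e5] <- -0.08    # 150 kb: too narrow
  x[pos >= 1.5e6 & pos <= 1.9e6] <- -0.08  # 400 kb: kept
  sm <- list(smoothed = x, smoothable = rep(TRUE, length(x)))
  cand <- find_candidate_blocks(r, sm, threshold = 0.05, min_width_bp = 2e5)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$width, 4e5 + 1)
  expect_equal(cand$direction, "hypo")

  # |smoothed| below threshold is never a candidate
  sm2 <- list(smoothed = rep(-0.04, length(x)), smoothable = rep(TRUE, length(x)))
  expect_equal(nrow(find_candidate_blocks(r, sm2, 0.05, 2e5)), 0)

  # at threshold 0 and min width 0 candidates partition same-sign runs
  set.seed(1)
  x3 <- rnorm(length(pos))
  sm3 <- list(smoothed = x3, smoothable = rep(TRUE, length(x3)))
  cand3 <- find_candidate_blocks(r, sm3, threshold = 0, min_width_bp = 0)
  expect_equal(sum(cand3$n_units), length(x3))
  expect_false(any(duplicated(unlist(
    mapply(seq, cand3$first, cand3$last, SIMPLIFY = FALSE)))))
})

test_that("noiseless planted block yields exactly one spanning candidate", {
  cfg <- genome_config(n_chrom = 1, chrom_length = 5e6, n_probes = 600,
                       n_blocks = 1, block_size_range = c(4e5, 4e5),
                       block_delta = 0.09, n_dmrs = 0, snp_rate = 0,
                       edge_taper = 0)
  sim <- simulate_genome(cfg, seed = 5)
  des <- make_design(3)
  b <- simulate_array_cohort(sim$annotation, sim$truth, des, noise_sd = 0,
                             seed = 6)
  reg <- collapse_open_sea(sim$annotation, b)
  gd <- region_group_difference(reg, des, c("Y-pro", "O-exp"))
  sm <- smooth_differences(reg, gd$d)
  cand <- find_candidate_blocks(reg, sm)
  expect_equal(nrow(cand), 1)
  tr <- sim$truth$blocks
  expect_gte(cand$start, GenomicRanges::start(tr) - 1)
  expect_lte(cand$end, GenomicRanges::end(tr) + 1)
  expect_equal(cand$direction, "hyper")  # Y-pro minus O-exp is positive
})

test_that("direction bookkeeping: swapping groups negates, calls unchanged", {
  s <- std_sim()
  bc1 <- find_blocks_array(s$betas, s$sim$annotation, s$design,
                           comparison = c("O-exp", "Y-pro"), n_perm = 50,
                           seed = 21)
  bc2 <- find_blocks_array(s$betas, s$sim$annotation, s$design,
                           comparison = c("Y-pro", "O-exp"), n_perm = 50,
                           seed = 21)
  expect_equal(bc1$candidates$start, bc2$candidates$start)
  expect_equal(bc1$candidates$end, bc2$candidates$end)
  expect_equal(bc1$candidates$mean_smoothed, -bc2$candidates$mean_smoothed,
               tolerance = 1e-12)
  expect_equal(bc1$candidates$mean_diff, -bc2$candidates$mean_diff,
               tolerance = 1e-12)
})

test_that("permutation null is exact for tiny cohorts and seeded", {
  pg <- perm_groups(c(1, 1, 1, 0, 0, 0), n_perm = 100, seed = 1)
  expect_true(pg$exact)
  expect_equal(ncol(pg$G), choose(6, 3) - 1)         # identity excluded
  expect_false(any(colSums(pg$G != c(1, 1, 1, 0, 0, 0)) == 0))

  pg2 <- perm_groups(rep(c(1, 0), each = 10), n_perm = 50, seed = 4)
  pg3 <- perm_groups(rep(c(1, 0), each = 10), n_perm = 50, seed = 4)
  expect_identical(pg2$G, pg3$G)
  expect_false(pg2$exact)
  expect_error(perm_groups(c(1, 1, 0, 0), n_perm = 10), class = "bad_config")
})

test_that("fwer p-values depend only on the null multiset and are seeded", {
  s <- std_sim()
  bc1 <- find_blocks_array(s$betas, s$sim$annotation, s$design, n_perm = 80,
                           seed = 31)
  bc2 <- find_blocks_array(s$betas, s$sim$annotation, s$design, n_perm = 80,
                           seed = 31)
  expect_identical(bc1$candidates$fwer_p, bc2$candidates$fwer_p)
  nm <- attr(bc1$candidates, "null_max")
  expect_equal(bc1$candidates$fwer_p,
               (1 + vapply(bc1$candidates$area,
                           function(a) sum(sort(nm) >= a), numeric(1))) /
                 (1 + length(nm)))
  expect_true(all(bc1$candidates$fwer_p > 0 & bc1$candidates$fwer_p <= 1))
})
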