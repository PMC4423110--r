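# small synthetic wgbs_cohort built directly from matrices
mk_wgbs <- function(pos, meth, cov, groups, chrom = "chr1") {
  des <- toy_design(groups)
  colnames(meth) <- colnames(cov) <- des$sample_id
  structure(list(chrom = rep(chrom, length(pos)), pos = pos, meth = meth,
                 cov = cov, design = des, genome = NULL),
            class = "wgbs_cohort")
}

test_that("coverage filter implements both interpretations", {
  set.seed(2)
  groups <- c("O-exp", "O-exp", "Y-pro", "Y-pro")
  cov <- matrix(rpois(400, 3), 100, 4)
  cov[1, 1:2] <- 0                      # O-exp uncovered at site 1
  cov[2, ] <- c(1, 1, 5, 5)            # group total 2, no sample >= 2
  meth <- matrix(rbinom(400, cov, 0.5), 100, 4)
  w <- mk_wgbs(seq(1000, by = 500, length.out = 100), meth, cov, groups)

  keep <- filter_cpgs(w, min_cov = 2, mode = "group_total")
  expect_false(keep[1])
  expect_true(keep[2])
  # brute-force oracle
  oracle <- vapply(seq_len(100), function(i) {
    all(vapply(unique(groups), function(g) {
      cv <- cov[i, groups == g]
      sum(cv) >= 2 && any(cv > 0)
    }, TRUE))
  }, TRUE)
  expect_equal(keep, oracle)

  keep_s <- filter_cpgs(w, min_cov = 2, mode = "per_sample")
  oracle_s <- vapply(seq_len(100), function(i) all(cov[i, ] >= 2), TRUE)
  expect_equal(keep_s, oracle_s)

  w0 <- mk_wgbs(c(100, 200), matrix(0L, 2, 4), matrix(0L, 2, 4), groups)
  expect_error(filter_cpgs(w0), class = "empty_filter")
})

test_that("smoothing preserves constants and tracks steps monotonically", {
  pos <- seq(100, by = 100, length.out = 500)
  groups <- c("O-exp", "Y-pro")
  cov <- matrix(5L, 500, 2)
  meth <- matrix(4L, 500, 2)            # constant 0.8
  w <- mk_wgbs(pos, meth, cov, groups)
  sm <- smooth_methylation(w, min_cpgs = 30, min_window_bp = 1000)
  expect_equal(unname(sm$smooth[, 1]), rep(0.8, 500), tolerance = 1e-9)

  meth2 <- meth; meth2[251:500, ] <- 2L  # step 0.8 -> 0.4
  w2 <- mk_wgbs(pos, meth2, cov, groups)
  sm2 <- smooth_methylation(w2, min_cpgs = 30, min_window_bp = 1000)
  v <- sm2$smooth[, 1]
  expect_lt(max(abs(v[1:200] - 0.8)), 0.05)
  expect_lt(max(abs(v[301:500] - 0.4)), 0.05)
  expect_true(all(diff(v[150:350]) <= 0.01))  # essentially monotone across the step
})

test_that("smoothed values equal a direct weighted local regression", {
  set.seed(4)
  n <- 120
  pos <- sort(sample.int(20000, n))
  cov <- matrix(rpois(n, 6) + 1L, n, 2)
  meth <- matrix(rbinom(2 * n, cov, 0.6), n, 2)
  w <- mk_wgbs(pos, meth, cov, c("O-exp", "Y-pro"))
  min_cpgs <- 11; min_window <- 500
  sm <- smooth_methylation(w, min_cpgs = min_cpgs, min_window_bp = min_window)
  frac <- meth / cov
  half <- (min_cpgs - 1) %/% 2
  for (i in sample(n, 25)) {
    j0 <- max(1, i - half); j1 <- min(n, i + half)
    if (j0 == 1) j1 <- min(n, j0 + min_cpgs - 1)
    if (j1 == n) j0 <- max(1, j1 - min_cpgs + 1)
    while (pos[j1] - pos[j0] < min_window && (j0 > 1 || j1 < n)) {
      dl <- if (j0 > 1) pos[i] - pos[j0 - 1] else Inf
      dr <- if (j1 < n) pos[j1 + 1] - pos[i] else Inf
      if (dl <= dr) j0 <- j0 - 1 else j1 <- j1 + 1
    }
    h <- max(pos[i] - pos[j0], pos[j1] - pos[i]) * 1.0001
    jj <- j0:j1
    tri <- (1 - (abs(pos[jj] - pos[i]) / h)^3)^3
    fit <- lm(frac[jj, 1] ~ I(pos[jj] - pos[i]), weights = tri * cov[jj, 1])
    expect_equal(unname(sm$smooth[i, 1]), unname(coef(fit)[1]),
                 tolerance = 1e-8)
  }
})

test_that("smoothing is shift-equivariant away from the clip bounds", {
  set.seed(6)
  n <- 200
  pos <- seq(50, by = 75, length.out = n)
  cov <- matrix(rpois(n, 8) + 1L, n, 2)
  meth <- matrix(rbinom(2 * n, cov, 0.4), n, 2)
  w1 <- mk_wgbs(pos, meth, cov, c("O-exp", "Y-pro"))
  sm1 <- smooth_methylation(w1, min_cpgs = 21, min_window_bp = 500)
  # shift every fraction by +0.2 via a direct call to the smoother core
  frac <- meth[, 1] / cov[, 1]
  a <- methblocks:::smooth_one(w1$chrom, pos, frac, cov[, 1], 21, 500)
  b <- methblocks:::smooth_one(w1$chrom, pos, frac + 0.2, cov[, 1], 21, 500)
  expect_equal(b, a + 0.2, tolerance = 1e-9)
  expect_equal(unname(sm1$smooth[, 1]), clip01(a), tolerance = 1e-12)
})

test_that("t-statistics: zero under equality, exact antisymmetry, arithmetic", {
  set.seed(8)
  n <- 300
  pos <- seq(100, by = 100, length.out = n)
  cov <- matrix(rpois(4 * n, 6) + 1L, n, 4)
  meth <- matrix(rbinom(4 * n, cov, 0.7), n, 4)
  groups <- c("O-exp", "O-exp", "Y-pro", "Y-pro")
  w <- mk_wgbs(pos, meth, cov, groups)
  sm <- smooth_methylation(w, min_cpgs = 31, min_window_bp = 500)

  # identical groups: compare a group against itself via relabeling
  sm_eq <- sm
  sm_eq$smooth[, 3:4] <- sm$smooth[, 1:2]
  sm_eq$cov[, 3:4] <- sm$cov[, 1:2]
  tt_eq <- group_tstat(sm_eq, c("O-exp", "Y-pro"), reference_group = "Y-pro")
  expect_equal(tt_eq$t, rep(0, n), tolerance = 1e-12)

  tt1 <- group_tstat(sm, c("O-exp", "Y-pro"))
  tt2 <- group_tstat(sm, c("Y-pro", "O-exp"))
  expect_equal(tt1$t, -tt2$t, tolerance = 1e-12)

  # arithmetic oracle at individual sites
  sd_raw <- apply(sm$smooth[, 3:4], 1, sd)
  sd_ref <- pmax(0, methblocks:::smooth_one(sm$chrom, sm$pos, sd_raw,
                                            rowSums(sm$cov[, 3:4]), 31, 500))
  fl <- quantile(sd_ref, 0.75, names = FALSE)
  expect_equal(tt1$floor, fl)
  ma <- rowMeans(sm$smooth[, 1:2]); mb <- rowMeans(sm$smooth[, 3:4])
  expect_equal(tt1$t, (ma - mb) / (sd_ref + fl), tolerance = 1e-12)

  des1 <- sm$design; des1$group[4] <- "O-pro"
  sm_bad <- sm; sm_bad$design <- des1
  expect_error(group_tstat(sm_bad, c("O-exp", "Y-pro")),
               class = "bad_comparison")
})

wgbs_calls_fixture <- function() fixture("wgbs_calls", function() {
  s <- std_sim()
  wdes <- do.call(rbind, lapply(split(s$design, s$design$group), head, 3))
  w <- simulate_wgbs_cohort(s$sim$truth, wdes, mean_coverage = 6, seed = 71)
  find_blocks_wgbs(w)
})

test_that("wgbs block calls respect all three filters by construction", {
  s <- std_sim()
  wb <- wgbs_calls_fixture()
  expect_true(all(wb$blocks$width > 10000))
  expect_true(all(abs(wb$blocks$mean_diff) > 0.05))
  expect_true(all(wb$blocks$n_cpgs >= 10))
  expect_false(methblocks:::self_overlapping(wb$blocks))
  # recovery of the planted truth
  cg <- calls_to_granges(wb$blocks, s$sim$truth$genome)
  expect_gte(interval_jaccard(s$sim$truth$blocks, cg), 0.7)
})

test_that("narrow or weak runs are filtered out of block calls", {
  # construct a t landscape directly: an 8 kb run and a weak-effect run
  n <- 400
  pos <- seq(500, by = 500, length.out = n)
  sm <- list(chrom = rep("chr1", n), pos = pos,
             design = toy_design(c("O-exp", "Y-pro")))
  t <- rep(0, n)
  t[11:26] <- -3     # 7.5 kb span: below the 10 kb width filter
  t[101:200] <- -3   # 49.5 kb span, but weak raw difference
  cov <- matrix(10L, n, 2)
  meth <- cbind(as.integer(round(10 * (0.8 - 0.04 * (t < 0)))),
                rep(8L, n))   # raw diff only -0.04 in the long run
  w <- mk_wgbs(pos, meth, cov, c("O-exp", "Y-pro"))
  out <- call_wgbs_blocks(list(t = t), sm, w, rep(TRUE, n))
  expect_equal(nrow(out), 0)
  # raising the raw difference recovers exactly the long run
  meth2 <- cbind(as.integer(round(10 * (0.8 - 0.3 * (t < 0)))), rep(8L, n))
  w2 <- mk_wgbs(pos, meth2, cov, c("O-exp", "Y-pro"))
  out2 <- call_wgbs_blocks(list(t = t), sm, w2, rep(TRUE, n))
  expect_equal(nrow(out2), 1)
  expect_equal(out2$start, pos[101])
  expect_equal(out2$end, pos[200])
})

test_that("methylation densities are normalized and shift inside blocks", {
  wb <- wgbs_calls_fixture()
  dens <- methylation_density(wb$smoothed, wb$blocks)
  sums <- tapply(dens$mass, interaction(dens$group, dens$partition), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  inside <- function(g) {
    d <- dens[dens$group == g & dens$partition == "inside", ]
    sum(d$mass * (d$bin_left + d$bin_right) / 2)
  }
  expect_lt(inside("O-exp"), inside("Y-pro") - 0.05)  # mass shifted left
  outside <- function(g) {
    d <- dens[dens$group == g & dens$partition == "outside", ]
    sum(d$mass * (d$bin_left + d$bin_right) / 2)
  }
  expect_lt(abs(outside("O-exp") - outside("Y-pro")), 0.03)

  # empty block set: all == outside, inside empty
  expect_warning(d0 <- methylation_density(wb$smoothed, wb$blocks[0, ]),
                 "empty")
  a <- d0[d0$partition == "all", "mass"]
  o <- d0[d0$partition == "outside", "mass"]
  expect_equal(a, o, tolerance = 1e-12)
  expect_true(all(is.na(d0[d0$partition == "inside", "mass"])))
})
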