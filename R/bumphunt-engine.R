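# Shared machinery for bump-style region finding: windowed weighted
# smoothing of a per-unit difference statistic, segmentation of
# thresholded same-sign runs, and the label-permutation null.
# "Units" are collapsed open-sea regions (blocks) or single probes (DMRs).

# first/last unit index within +-window_bp/2 of each unit, never crossing
# a chromosome boundary; positions must be sorted within chrom
window_index <- function(chrom, pos, window_bp) {
  n <- length(pos)
  lo <- hi <- integer(n)
  half <- window_bp / 2
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    p <- pos[i]
    lo[i] <- i[1] - 1L + findInterval(p - half - 0.5, p) + 1L
    hi[i] <- i[1] - 1L + findInterval(p + half + 0.5, p)
  }
  list(lo = lo, hi = hi, count = hi - lo + 1L)
}

# weighted running mean of each column of D over [lo, hi]
smooth_mat <- function(D, w, lo, hi) {
  D <- as.matrix(D)
  cw <- c(0, cumsum(w))
  csum <- apply(D * w, 2, function(x) c(0, cumsum(x)))
  num <- csum[hi + 1L, , drop = FALSE] - csum[lo, , drop = FALSE]
  num / (cw[hi + 1L] - cw[lo])
}

# maximal same-sign runs with |x| >= threshold among usable units;
# returns first/last unit index, span, direction and area per run
segment_runs <- function(x, usable, chrom, start, end, threshold, min_width_bp) {
  state <- ifelse(!usable | is.na(x) | abs(x) < threshold, 0, sign(x))
  key <- paste(chrom, state)
  r <- rle(key)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  keep <- state[idx_start] != 0
  if (!any(keep)) return(empty_candidates())
  first <- idx_start[keep]; last <- idx_end[keep]
  span_start <- start[first]; span_end <- end[last]
  width <- span_end - span_start + 1
  area <- vapply(seq_along(first), function(k)
    sum(abs(x[first[k]:last[k]])), numeric(1))
  out <- data.frame(chrom = chrom[first], start = span_start, end = span_end,
                    width = width, first = first, last = last,
                    n_units = last - first + 1L,
                    direction = ifelse(state[first] > 0, "hyper", "hypo"),
                    area = area,
                    mean_smoothed = area / (last - first + 1L) *
                      ifelse(state[first] > 0, 1, -1),
                    stringsAsFactors = FALSE)
  out[out$width > min_width_bp, , drop = FALSE]
}

empty_candidates <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             width = numeric(0), first = integer(0), last = integer(0),
             n_units = integer(0), direction = character(0), area = numeric(0),
             mean_smoothed = numeric(0), stringsAsFactors = FALSE)
}

# Null label assignments for the permutation FWER.
# Returns a 0/1 matrix (selected samples x permutations); when the number
# of distinct assignments (within strata) is small, enumerates them all
# (minus the observed one) for an exact null.
perm_groups <- function(g, strata = NULL, n_perm = 400, seed = 1) {
  if (n_perm < 20) stop_mb("n_perm < 20 gives too coarse a p-value", "bad_config")
  n <- length(g)
  if (is.null(strata)) strata <- rep(1L, n)
  strata <- as.integer(factor(strata))
  with_rng(seed, {
    n_distinct <- prod(vapply(split(g, strata), function(gs)
      choose(length(gs), sum(gs)), numeric(1)))
    if (is.finite(n_distinct) && n_distinct - 1 <= n_perm) {
      G <- enumerate_assignments(g, strata)
      G <- G[, colSums(G != g) > 0, drop = FALSE]      # drop identity
      list(G = G, exact = TRUE)
    } else {
      G <- matrix(0, n, n_perm)
      for (k in seq_len(n_perm)) {
        repeat {
          gk <- g
          for (s in unique(strata)) {
            i <- which(strata == s)
            gk[i] <- gk[sample(i)]
          }
          if (any(gk != g)) break                      # exclude identity
        }
        G[, k] <- gk
      }
      list(G = G, exact = FALSE)
    }
  })
}

enumerate_assignments <- function(g, strata) {
  per_stratum <- lapply(sort(unique(strata)), function(s) {
    i <- which(strata == s)
    ch <- utils::combn(length(i), sum(g[i]))
    lapply(seq_len(ncol(ch)), function(k) {
      v <- numeric(length(i)); v[ch[, k]] <- 1; v
    })
  })
  combos <- expand.grid(lapply(per_stratum, seq_along))
  G <- matrix(0, length(g), nrow(combos))
  for (r in seq_len(nrow(combos))) {
    gk <- numeric(length(g))
    for (s in seq_along(per_stratum))
      gk[strata == sort(unique(strata))[s]] <- per_stratum[[s]][[combos[r, s]]]
    G[, r] <- gk
  }
  G
}

# Group-difference coefficient of every unit (row of Y) under every label
# assignment (column of G), optionally adjusting for covariates X0 by
# Frisch-Waugh residualization. Equals the lm() group coefficient.
group_coef_mat <- function(Y, G, X0 = NULL) {
  Y <- as.matrix(Y); G <- as.matrix(G)
  if (anyNA(Y)) {                                    # mean-impute per unit
    rm <- rowMeans(Y, na.rm = TRUE)
    Y[is.na(Y)] <- rm[row(Y)[is.na(Y)]]
  }
  if (is.null(X0)) {
    nA <- colSums(G); nB <- nrow(G) - nA
    C <- sweep(G, 2, nA, "/") - sweep(1 - G, 2, nB, "/")
    Y %*% C
  } else {
    qx <- qr(X0)
    if (qx$rank < ncol(X0))
      stop_mb("covariate design is rank deficient", "rank_deficient")
    RG <- G - X0 %*% qr.coef(qx, G)
    denom <- colSums(RG^2)
    if (any(denom < 1e-12))
      stop_mb("a covariate is perfectly confounded with the comparison groups",
              "rank_deficient")
    RY <- Y - t(qr.fitted(qx, t(Y)))
    sweep(RY %*% RG, 2, denom, "/")
  }
}

# covariate model matrix (no intercept redundancy) for selected samples
covariate_matrix <- function(design, sel, covariates) {
  if (is.null(covariates) || length(covariates) == 0) return(NULL)
  miss <- setdiff(covariates, names(design))
  if (length(miss))
    stop_mb(paste("unknown covariate(s):", paste(miss, collapse = ", ")),
            "bad_covariate")
  df <- design[sel, covariates, drop = FALSE]
  df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
  X0 <- stats::model.matrix(~ ., data = df)
  qx <- qr(X0)
  if (qx$rank < ncol(X0)) {
    # name the offending covariate for the error message
    drop_col <- colnames(X0)[qx$pivot[(qx$rank + 1):ncol(X0)]]
    stop_mb(paste("rank-deficient covariate design; offending term(s):",
                  paste(drop_col, collapse = ", ")), "rank_deficient")
  }
  X0
}

# strata for label shuffling: joint covariate levels, or one stratum
perm_strata <- function(design, sel, covariates) {
  if (is.null(covariates) || length(covariates) == 0) return(NULL)
  interaction(design[sel, covariates, drop = FALSE], drop = TRUE)
}

# permutation FWER by the genome-wide max-area null: for each label
# assignment the full difference -> smooth -> segment pipeline is re-run
# and the maximum candidate area recorded; ties count as exceedances
fwer_pvalues <- function(obs_area, null_max) {
  vapply(obs_area, function(a) (1 + sum(null_max >= a)) / (1 + length(null_max)),
         numeric(1))
}
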