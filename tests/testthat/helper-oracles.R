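# Independent brute-force oracles and small fixture builders. These are
# deliberately written as plain scalar loops / full enumerations, separate
# from the vectorized implementation paths they check.

# Build a small DCE study from an explicit 4D array (or a generator fn).
make_test_study <- function(volumes, phase_times = c(-10, 60, 150, 420),
                            spacing = c(1, 1, 1), id = "T1", tp = "BL") {
  dce_study(volumes, phase_times, spacing, patient_id = id, timepoint = tp)
}

# Random study: uniform background s0 plus noise, optional enhancing blob.
random_study <- function(shape = c(8, 8, 4), n_phase = 4, s0 = 100,
                         noise = 20) {
  vols <- array(s0 + stats::runif(prod(shape) * n_phase, -noise, noise),
                dim = c(shape, n_phase))
  make_test_study(vols, phase_times = c(-10, 60, 150, 420)[seq_len(n_phase)])
}

# Scalar per-voxel PE/SER oracle (loops, one voxel at a time).
oracle_pe_ser <- function(study, early, late) {
  pre_idx <- max(which(study$phase_times <= 0))
  d <- dim(study$volumes)[1:3]
  eps <- 1e-6 * diff(range(study$volumes))
  pe <- ser <- array(NA_real_, dim = d)
  valid_pe <- valid_ser <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    s_pre <- study$volumes[i, j, k, pre_idx]
    s_e <- study$volumes[i, j, k, early]
    s_l <- study$volumes[i, j, k, late]
    if (s_pre > 0) {
      valid_pe[i, j, k] <- TRUE
      pe[i, j, k] <- (s_e - s_pre) / s_pre * 100
    }
    if (s_e - s_pre > 0) {
      valid_ser[i, j, k] <- TRUE
      ser[i, j, k] <- if (s_l - s_pre <= eps) SER_CAP else
        (s_e - s_pre) / (s_l - s_pre)
    }
  }
  list(pe = pe, ser = ser, valid_pe = valid_pe, valid_ser = valid_ser)
}

# Per-voxel FTV count oracle.
oracle_ftv_count <- function(mask, maps, pe_thr, ser_thr) {
  n <- 0L
  d <- dim(mask)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] && maps$valid[i, j, k] &&
        maps$pe[i, j, k] > pe_thr && maps$ser[i, j, k] > ser_thr)
      n <- n + 1L
  }
  n
}

# Pairwise AUC oracle (positives vs negatives, double loop).
oracle_auc <- function(pos, neg) {
  s <- 0
  for (x in pos) for (y in neg)
    s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p by full enumeration of label assignments
# (no ties assumed).
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_obs <- sum(outer(a, b, ">"))
  combs <- utils::combn(n, na)
  u_all <- apply(combs, 2, function(idx)
    sum(outer(pooled[idx], pooled[-idx], ">")))
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Classical two-sided Fisher p for a 2x2 table by hypergeometric
# enumeration; also returns the total probability over all tables with the
# observed margins (should be 1).
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  ks <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(ks, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  list(p = sum(probs[probs <= p_obs * (1 + 1e-7)]), total = sum(probs))
}

# Brute-force Otsu: try every split point of the sorted sample, compute
# between-class variance from group means directly.
oracle_otsu <- function(x) {
  xs <- sort(x)
  best_bcv <- -Inf
  best_thr <- NA_real_
  for (i in seq_len(length(xs) - 1)) {
    if (xs[i] == xs[i + 1]) next
    lo <- xs[1:i]
    hi <- xs[(i + 1):length(xs)]
    bcv <- (length(lo) / length(xs)) * (length(hi) / length(xs)) *
      (mean(lo) - mean(hi))^2
    if (bcv > best_bcv + 1e-12) {
      best_bcv <- bcv
      best_thr <- xs[i]
    }
  }
  best_thr
}

# Brute-force Youden cutoff search over observed scores.
oracle_youden <- function(scores, labels) {
  cand <- sort(unique(scores))
  best_j <- -Inf
  best_c <- NA_real_
  for (cc in cand) {
    sens <- mean(scores[labels == 1] >= cc)
    spec <- mean(scores[labels == 0] < cc)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_c <- cc
    }
  }
  best_c
}

# Small enhancing-blob patient for pipeline tests: studies + masks for all
# three timepoints built from a tiny zero-noise config.
tiny_config <- function(n = 8, seed = 11, noise = 2, ...) {
  cohort_config(n_patients = n, grid_shape = c(16, 16, 12),
                spacing_mm = c(2, 2, 2.5), radius_mm_mean = 6,
                radius_mm_sd = 1, noise_sd = noise, seed = seed, ...)
}
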