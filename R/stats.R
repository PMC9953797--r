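# Statistical layer: Mann-Whitney, Fisher's exact (r x c), ROC AUC with
# DeLong CI, and Youden best-cutoff selection. The AUC/DeLong/Youden
# machinery is implemented here; rank-test and exact-table p-values delegate
# to the standard stats routines.

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Returns the U statistic (number of `(a_i > b_j)` pairs plus half the
#' tied pairs) and a two-sided p-value: exact by enumeration when the
#' combined sample size is at most 20 and there are no ties, otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param a,b numeric vectors, both nonempty.
#' @return list with `U` and `p_value`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be nonempty")
  U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 20L) && !ties
  p <- stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  list(U = U, p_value = min(p, 1))
}

check_two_classes <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
  labels
}

#' ROC AUC from labeled scores
#'
#' The probability that a randomly chosen positive case outscores a random
#' negative case, ties counted 0.5 (the Mann-Whitney estimator
#' `U / (n1 * n0)`). When the positive class is expected to have *lower*
#' scores, set `positive_high = FALSE` to fix the orientation rather than
#' taking `max(AUC, 1 - AUC)`.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector aligned with `scores`; 1 = positive class.
#' @param positive_high logical: TRUE if higher scores indicate the positive
#'   class.
#' @return AUC in `[0, 1]`.
#' @export
auc_from_scores <- function(scores, labels, positive_high = TRUE) {
  labels <- check_two_classes(scores, labels)
  if (!positive_high) scores <- -scores
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong confidence interval and test for the AUC
#'
#' Nonparametric (DeLong) variance of the Mann-Whitney AUC from the
#' per-case placement values, a normal-approximation confidence interval
#' clipped to `[0, 1]`, and a two-sided p-value for AUC = 0.5. With
#' perfectly separated classes the variance degenerates to zero; the CI
#' then collapses to a point, `degenerate` is TRUE and a warning is issued
#' (the p-value is 1 when the AUC is exactly 0.5, otherwise NA).
#'
#' @inheritParams auc_from_scores
#' @param conf_level confidence level (default 0.95).
#' @return list with `auc`, `ci_low`, `ci_high`, `p_value`, `se`,
#'   `degenerate`.
#' @export
auc_ci_delong <- function(scores, labels, positive_high = TRUE,
                          conf_level = 0.95) {
  labels <- check_two_classes(scores, labels)
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L)
    stop("DeLong CI needs at least 2 cases in each class")
  if (!positive_high) scores <- -scores
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  auc <- mean(psi)
  var_auc <- stats::var(v10) / length(x) + stats::var(v01) / length(y)
  se <- sqrt(var_auc)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (se == 0) {
    warning("degenerate DeLong variance (perfect separation or all ties); ",
            "CI collapses to a point")
    p <- if (auc == 0.5) 1 else NA_real_
    return(list(auc = auc, ci_low = auc, ci_high = auc, p_value = p,
                se = 0, degenerate = TRUE))
  }
  p <- 2 * stats::pnorm(-abs(auc - 0.5) / se)
  list(auc = auc,
       ci_low = max(0, auc - z * se),
       ci_high = min(1, auc + z * se),
       p_value = min(max(p, .Machine$double.xmin), 1),
       se = se, degenerate = FALSE)
}

#' Best ROC cutoff by Youden's J
#'
#' Maximizes sensitivity + specificity - 1 over the observed scores as
#' candidate cutoffs. A case is called positive when its score is `>=` the
#' cutoff (`<=` when `positive_high = FALSE`). Ties in J are broken toward
#' the smaller cutoff.
#'
#' @inheritParams auc_from_scores
#' @return the selected cutoff, in score units.
#' @export
youden_cutoff <- function(scores, labels, positive_high = TRUE) {
  labels <- check_two_classes(scores, labels)
  cand <- sort(unique(scores))
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  j <- vapply(cand, function(cc) {
    if (positive_high) {
      sens <- mean(pos >= cc); spec <- mean(neg < cc)
    } else {
      sens <- mean(pos <= cc); spec <- mean(neg > cc)
    }
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]   # which.max takes the first (smallest) maximizer
}

#' Fisher's exact test for r x c contingency tables
#'
#' Freeman-Halton generalization: the two-sided p-value is the total
#' probability of all tables with the observed margins whose hypergeometric
#' probability does not exceed that of the observed table (computed by the
#' network algorithm of [stats::fisher.test()]). Tables with a large total
#' count must opt into Monte-Carlo estimation.
#'
#' @param counts matrix of nonnegative integer counts, at least 2 x 2.
#' @param monte_carlo logical; estimate the p-value by table simulation
#'   instead of exact enumeration.
#' @param B number of Monte-Carlo replicates when `monte_carlo = TRUE`.
#' @param budget maximum total count for exact enumeration.
#' @return two-sided p-value.
#' @export
fisher_exact_rxc <- function(counts, monte_carlo = FALSE, B = 1e5,
                             budget = 1000) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("`counts` must be at least a 2 x 2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be nonnegative integers")
  if (!monte_carlo && sum(counts) > budget)
    stop("table total ", sum(counts), " exceeds the exact-enumeration ",
         "budget (", budget, "); rerun with monte_carlo = TRUE")
  stats::fisher.test(counts, simulate.p.value = monte_carlo, B = B,
                     workspace = 2e6)$p.value
}
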