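#' Confusion-matrix metrics
#'
#' Standard binary-classification metrics from confusion counts, reported
#' as percentages. Zero-denominator cases (e.g. no predicted positives)
#' return 0 with a warning.
#'
#' @param tp,tn,fp,fn non-negative counts, at least one positive.
#' @return Named numeric vector: counts plus \code{accuracy},
#'   \code{precision}, \code{recall}, \code{specificity}, \code{fpr},
#'   \code{fnr}, \code{f1}, all in percent.
#' @export
metricsFromConfusion <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be >= 0")
  n <- sum(counts)
  if (n == 0) stop("confusion counts are all zero")
  safeDiv <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting 0")
      return(0)
    }
    num / den
  }
  precision <- safeDiv(tp, tp + fp, "precision")
  recall <- safeDiv(tp, tp + fn, "recall")
  specificity <- safeDiv(tn, tn + fp, "specificity")
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  100 * c(counts / 100,  # keep counts unscaled
          accuracy = (tp + tn) / n, precision = precision, recall = recall,
          specificity = specificity, fpr = 1 - specificity,
          fnr = 1 - recall, f1 = f1)
}

#' F1 score from precision and recall (percent scale)
#'
#' Harmonic mean of precision and recall, both given in percent.
#'
#' @param precision,recall percentages in [0, 100].
#' @return F1 in percent.
#' @export
f1FromPrecisionRecall <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve computed from midranks (equal to the
#' normalized Mann-Whitney U statistic), handling score ties.
#'
#' @param scores numeric decision scores.
#' @param labels 0/1 labels (1 = positive).
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)  # midranks
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Seen-minus-unseen performance drop
#'
#' Simple subtraction of the unseen accuracy from the seen accuracy, in
#' percentage points.
#'
#' @param seenAcc,unseenAcc accuracies in percent, in [0, 100].
#' @return Performance drop in percentage points.
#' @export
performanceDrop <- function(seenAcc, unseenAcc) {
  stopifnot(seenAcc >= 0, seenAcc <= 100, unseenAcc >= 0, unseenAcc <= 100)
  seenAcc - unseenAcc
}

#' Group aggregation: mean and population SD
#'
#' Aggregates a group of per-model (or per-fold) percentages the way the
#' report tables do: arithmetic mean and the population standard deviation
#' (denominator n), both rounded to 2 decimals for reporting.
#'
#' @param values numeric vector (>= 1 value).
#' @param digits rounding for the reported values (default 2).
#' @return Named numeric vector \code{c(mean =, sd =)}.
#' @export
groupAggregate <- function(values, digits = 2) {
  if (length(values) == 0L) stop("empty input")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))  # population convention
  c(mean = round(m, digits), sd = round(s, digits))
}

#' Reliability statistics between two per-fold score vectors
#'
#' Paired t-test, Wilcoxon signed-rank test (zero differences dropped,
#' exact distribution for n <= 25) and Mann-Whitney U test (exact for small
#' samples without ties, normal approximation with tie correction
#' otherwise), comparing e.g. per-fold accuracies of two models.
#' Degenerate cases (all differences zero, or zero-variance differences in
#' the paired t-test) return p = 1 with a warning.
#'
#' @param a,b numeric vectors; the paired tests require equal lengths >= 2.
#' @return data.frame with rows \code{paired_t}, \code{wilcoxon},
#'   \code{mann_whitney} and columns \code{statistic}, \code{p}.
#' @export
reliabilityTests <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("paired tests require equal lengths >= 2")
  d <- a - b
  if (stats::sd(d) == 0) {
    warning("zero-variance paired differences; paired t-test p set to 1")
    tstat <- 0; tp <- 1
  } else {
    tt <- t.test(a, b, paired = TRUE)
    tstat <- unname(tt$statistic); tp <- tt$p.value
  }
  dnz <- d[d != 0]
  if (length(dnz) == 0L) {
    warning("all paired differences are zero; Wilcoxon p set to 1")
    wstat <- 0; wp <- 1
  } else if (length(dnz) <= 25L) {
    sr <- exactSignedRank(dnz)
    wstat <- sr$statistic; wp <- sr$p
  } else {
    wt <- suppressWarnings(wilcox.test(dnz, exact = FALSE))
    wstat <- unname(wt$statistic); wp <- wt$p.value
  }
  if (length(a) <= 8L && length(b) <= 8L) {
    mwRes <- exactMannWhitney(a, b)
  } else {
    mw <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    mwRes <- list(statistic = unname(mw$statistic), p = mw$p.value)
  }
  data.frame(
    test = c("paired_t", "wilcoxon", "mann_whitney"),
    statistic = c(tstat, wstat, mwRes$statistic),
    p = c(tp, wp, mwRes$p),
    row.names = c("paired_t", "wilcoxon", "mann_whitney"))
}

# Exact two-sided signed-rank test on nonzero differences, tie-tolerant:
# the null distribution of V (sum of midranks of positive differences) is
# built by convolution over the 2^n equally likely sign assignments.
exactSignedRank <- function(dnz) {
  r <- rank(abs(dnz))
  v <- sum(r[dnz > 0])
  ri <- as.integer(round(2 * r))  # doubled midranks are integers
  total <- sum(ri)
  dist <- c(1, rep(0, total))     # dist[k + 1] = #assignments with 2V = k
  for (x in ri) {
    shifted <- c(rep(0, x), dist[seq_len(length(dist) - x)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  v2 <- as.integer(round(2 * v))
  pLow <- sum(dist[seq_len(v2 + 1L)])
  pHigh <- sum(dist[(v2 + 1L):length(dist)])
  list(statistic = v, p = min(1, 2 * min(pLow, pHigh)))
}

# Exact two-sided Mann-Whitney test by full enumeration of group
# assignments over pooled midranks (tie-tolerant); feasible for the small
# per-fold vectors it is used on.
exactMannWhitney <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  u <- w - na * (na + 1) / 2
  sums <- combn(r, na, sum)
  pLow <- mean(sums <= w + 1e-9)
  pHigh <- mean(sums >= w - 1e-9)
  list(statistic = u, p = min(1, 2 * min(pLow, pHigh)))
}
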