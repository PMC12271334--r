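#' Confusion-matrix metrics for binary predictions
#'
#' Precision is undefined (NA) when there are no positive predictions,
#' recall when there are no positive labels; an undefined component makes F1
#' undefined too. Undefined values are propagated, never coerced to 0 — a
#' model that predicts no positives has no F1, not a zero one.
#'
#' @param labels,preds Equal-length binary 0/1 vectors.
#' @return List: `tp`, `fp`, `tn`, `fn`, `precision`, `recall`, `f1`.
#' @export
score <- function(labels, preds) {
  if (length(labels) != length(preds)) stop("length mismatch")
  tp <- sum(labels == 1 & preds == 1)
  fp <- sum(labels == 0 & preds == 1)
  tn <- sum(labels == 0 & preds == 0)
  fn <- sum(labels == 1 & preds == 0)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
  else if (precision + recall == 0) 0
  else 2 * precision * recall / (precision + recall)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       precision = precision, recall = recall, f1 = f1)
}

#' F1 of the always-positive baseline classifier
#'
#' The base-rate reference an informative model must beat: predicting every
#' observation positive yields precision = positive rate p and recall = 1,
#' hence F1 = 2p / (1 + p).
#'
#' @param labels Binary 0/1 vector.
#' @return F1 of the constant-positive predictor (NA if no labels).
#' @export
base_rate_f1 <- function(labels) {
  if (!length(labels)) return(NA_real_)
  p <- mean(labels == 1)
  if (p == 0) return(NA_real_)
  2 * p / (1 + p)
}

#' Pick the better of the low- and high-burden models
#'
#' Defined-F1 maximum: if only one F1 is defined that one wins; exact ties
#' report schema `"tie"`; both undefined reports `"incomparable"` (excluded
#' from best-model summaries).
#'
#' @param f1_low,f1_high F1 values (NA = undefined).
#' @return List with `best_schema` and `best_f1`.
#' @export
best_of_two <- function(f1_low, f1_high) {
  if (is.na(f1_low) && is.na(f1_high)) {
    return(list(best_schema = "incomparable", best_f1 = NA_real_))
  }
  if (is.na(f1_high) || (!is.na(f1_low) && f1_low > f1_high)) {
    return(list(best_schema = "low_burden", best_f1 = f1_low))
  }
  if (is.na(f1_low) || f1_high > f1_low) {
    return(list(best_schema = "high_burden", best_f1 = f1_high))
  }
  list(best_schema = "tie", best_f1 = f1_low)
}

#' Paired Wilcoxon signed-rank test, normal approximation
#'
#' Two-sided test on paired differences `x - y`: zero differences are
#' dropped, absolute differences receive average ranks under ties, the
#' positive-rank sum W is compared with its null mean n(n+1)/4, and the
#' z statistic uses the tie-corrected variance and a 0.5 continuity
#' correction. The normal approximation is used throughout (matching
#' reported Z values); for small n it agrees with exact sign enumeration to
#' within about 0.02 in p.
#'
#' @param x,y Paired numeric vectors.
#' @return List: `n` (non-zero pairs), `W` (positive-rank sum), `z`, `p`,
#'   `median_x`, `median_y`. All NA when no non-zero pairs remain.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(n = 0L, W = NA_real_, z = NA_real_, p = NA_real_,
                median_x = stats::median(x, na.rm = TRUE),
                median_y = stats::median(y, na.rm = TRUE)))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 == 0) 0 else {
    cc <- 0.5 * sign(W - mu)
    (W - mu - cc) / sqrt(sigma2)
  }
  p <- 2 * stats::pnorm(-abs(z))
  list(n = n, W = W, z = z, p = min(p, 1),
       median_x = stats::median(x, na.rm = TRUE),
       median_y = stats::median(y, na.rm = TRUE))
}

#' Subgroup the cohort by model preference and test each subgroup
#'
#' Participants with both F1s defined are assigned to `low_better`,
#' `high_better` or `tie` by the sign of `f1_low - f1_high`; pairs with an
#' undefined member are `incomparable`. Within each non-tie subgroup a
#' paired two-sided Wilcoxon signed-rank test compares the two schemas and
#' subgroup medians are reported. Note the circularity caveat: testing a
#' difference within a subgroup selected by the sign of that difference is
#' confirmatory by construction; the subgroup statistics describe effect
#' size, not independent evidence.
#'
#' @param pairs Data frame with `participant_id`, `f1_low`, `f1_high`.
#' @return List of class `ppg_comparison`: `pairs` (with `best_schema`,
#'   `best_f1`, `subgroup` columns), `subgroup_sizes`, `tests` (per
#'   subgroup: n, W, z, p, medians), `best_f1_summary` (mean/median/sd over
#'   defined best F1s), `caveat`.
#' @export
subgroup_and_test <- function(pairs) {
  stopifnot(nrow(pairs) >= 1)
  bs <- t(vapply(seq_len(nrow(pairs)), function(i) {
    b <- best_of_two(pairs$f1_low[i], pairs$f1_high[i])
    c(b$best_schema, as.character(b$best_f1))
  }, character(2)))
  pairs$best_schema <- bs[, 1]
  pairs$best_f1 <- suppressWarnings(as.numeric(bs[, 2]))
  d <- pairs$f1_low - pairs$f1_high
  pairs$subgroup <- ifelse(is.na(d), "incomparable",
                           ifelse(d > 0, "low_better",
                                  ifelse(d < 0, "high_better", "tie")))
  sizes <- table(factor(pairs$subgroup,
                        levels = c("low_better", "high_better", "tie",
                                   "incomparable")))
  tests <- list()
  for (sg in c("low_better", "high_better")) {
    sub <- pairs[pairs$subgroup == sg, ]
    if (nrow(sub) == 0L) next
    wt <- wilcoxon_signed_rank(sub$f1_low, sub$f1_high)
    tests[[sg]] <- list(
      n = wt$n, W = wt$W, z = wt$z, p = wt$p,
      median_low = stats::median(sub$f1_low),
      median_high = stats::median(sub$f1_high),
      median_diff = stats::median(sub$f1_low) - stats::median(sub$f1_high))
  }
  bf <- pairs$best_f1[!is.na(pairs$best_f1)]
  structure(
    list(pairs = pairs,
         subgroup_sizes = as.list(sizes),
         tests = tests,
         best_f1_summary = list(n = length(bf), mean = mean(bf),
                                median = stats::median(bf),
                                sd = stats::sd(bf)),
         caveat = paste("Subgroup tests condition on the sign of the",
                        "difference they test; they describe, not confirm.")),
    class = "ppg_comparison")
}
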