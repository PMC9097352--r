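#' @title Screening-style evaluation
#' @description
#' Evaluates predicted MCI probabilities the way a screening test is
#' evaluated: confusion-matrix metrics (sensitivity, specificity, PPV, NPV,
#' F1) across a grid of probability cutoffs, the ROC curve and its area
#' computed as the midrank Mann-Whitney statistic, bootstrap confidence
#' intervals, and the analytic dependence of predictive values on disease
#' prevalence. A patient is classified positive when the predicted
#' probability is greater than or equal to the cutoff. Undefined ratios
#' (0/0) are reported as `NA`, never silently replaced by 0.
#' @name evaluation
NULL

#' Confusion-matrix metrics at one probability cutoff
#'
#' @param probs Predicted probabilities in `[0, 1]`.
#' @param labels Binary 0/1 outcomes of the same length.
#' @param cutoff Classification threshold; positive iff `prob >= cutoff`.
#' @return A one-row tibble: `cutoff`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `f1`. F1 is derived from
#'   PPV and sensitivity: `2 * ppv * sens / (ppv + sens)`.
#' @examples
#' confusion_at_cutoff(c(0.2, 0.8, 0.6), c(0, 1, 1), 0.5)
#' @export
confusion_at_cutoff <- function(probs, labels, cutoff) {
  if (!length(probs)) stop("empty input")
  stopifnot(length(probs) == length(labels),
            all(probs >= 0 & probs <= 1), all(labels %in% c(0, 1)))
  pos <- probs >= cutoff
  tp <- sum(pos & labels == 1); fp <- sum(pos & labels == 0)
  fn <- sum(!pos & labels == 1); tn <- sum(!pos & labels == 0)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  f1 <- if (is.na(ppv) || is.na(sens) || ppv + sens == 0) NA_real_ else
    2 * ppv * sens / (ppv + sens)
  tibble::tibble(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec, ppv = ppv,
                 npv = npv, f1 = f1)
}

#' Metrics across a grid of cutoffs
#'
#' @inheritParams confusion_at_cutoff
#' @param cutoffs Probability thresholds (default `c(0.3, 0.4, 0.5, 0.6)`,
#'   the operating points usually reported for this screening problem).
#' @return A tibble with one row per cutoff (see [confusion_at_cutoff()]).
#' @export
cutoff_sweep <- function(probs, labels, cutoffs = c(0.3, 0.4, 0.5, 0.6)) {
  do.call(rbind, lapply(cutoffs, function(ct)
    confusion_at_cutoff(probs, labels, ct)))
}

#' ROC curve and AUC with a bootstrap confidence interval
#'
#' AUC is the midrank Mann-Whitney statistic — the probability that a
#' random positive outranks a random negative, ties counting 1/2 — which
#' equals the trapezoidal area under the ROC curve. The confidence
#' interval is a stratified (within-class) bootstrap percentile interval;
#' a DeLong-style analytic interval is available via `ci_method`.
#'
#' @inheritParams confusion_at_cutoff
#' @param ci_method `"bootstrap"` (default) or `"delong"`.
#' @param boot_reps Bootstrap replicates (default 2000).
#' @param conf_level Interval coverage (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return A list of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `points` (tibble `fpr`, `tpr`, ordered), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(probs, labels, ci_method = c("bootstrap", "delong"),
                    boot_reps = 2000L, conf_level = 0.95, seed = 1L) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) stop("both outcome classes must be present")
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  auc <- auc_rank(pos, neg)

  # ROC points: threshold sweep over unique scores, (FPR, TPR) ascending
  thr <- sort(unique(probs), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  points <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))

  if (ci_method == "bootstrap") {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    reps <- vapply(seq_len(boot_reps), function(i) {
      auc_rank(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
    }, numeric(1))
    qs <- quantile(reps, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                   names = FALSE)
  } else {
    # DeLong variance from placement values
    v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)), numeric(1))
    v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)), numeric(1))
    v <- var(v10) / length(pos) + var(v01) / length(neg)
    z <- qnorm(1 - (1 - conf_level) / 2)
    qs <- c(auc - z * sqrt(v), auc + z * sqrt(v))
  }
  structure(list(auc = auc, ci_low = max(0, qs[1]), ci_high = min(1, qs[2]),
                 ci_method = ci_method, points = points,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}

# midrank Mann-Whitney AUC
auc_rank <- function(pos, neg) {
  r <- rank(c(pos, neg), ties.method = "average")
  n1 <- length(pos); n0 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%.3f, %.3f) [%s], %d pos / %d neg\n",
              x$auc, x$ci_low, x$ci_high, x$ci_method, x$n_pos, x$n_neg))
  invisible(x)
}

#' Predictive values implied by sensitivity, specificity and prevalence
#'
#' Bayes' rule: a test with fixed sensitivity and specificity yields a
#' higher PPV (and lower NPV) in a higher-prevalence population. Degenerate
#' denominators give `NA`.
#'
#' @param sensitivity,specificity,prevalence Values in `[0, 1]` (vectors
#'   recycle).
#' @return Tibble `prevalence`, `ppv`, `npv`.
#' @examples
#' ppv_npv_at_prevalence(0.87, 0.32, c(0.1, 0.3, 0.5))
#' @export
ppv_npv_at_prevalence <- function(sensitivity, specificity, prevalence) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1),
            all(prevalence >= 0 & prevalence <= 1))
  num_p <- sensitivity * prevalence
  den_p <- num_p + (1 - specificity) * (1 - prevalence)
  num_n <- specificity * (1 - prevalence)
  den_n <- num_n + (1 - sensitivity) * prevalence
  tibble::tibble(prevalence = prevalence,
                 ppv = ifelse(den_p == 0, NA_real_, num_p / den_p),
                 npv = ifelse(den_n == 0, NA_real_, num_n / den_n))
}
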