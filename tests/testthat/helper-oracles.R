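# Independent oracles used by the tests. These deliberately re-derive results
# by brute force / first principles and never call the implementation paths
# they check.

# enumerate EVERY increasing token subsequence matching the pattern under the
# gap rule, then apply leftmost-start / shortest-end / non-overlapping
# selection with resume-after-end
oracle_match <- function(lower, forms, max_gap) {
  cand_s <- integer(0); cand_e <- integer(0)
  rec <- function(j, pos, start) {
    if (j > length(forms)) {
      cand_s <<- c(cand_s, start); cand_e <<- c(cand_e, pos)
      return(invisible())
    }
    lo <- pos + 1L
    hi <- min(length(lower), pos + 1L + max_gap)
    if (lo > hi) return(invisible())
    for (p in lo:hi) {
      if (lower[p] %in% forms[[j]]) rec(j + 1L, p, start)
    }
  }
  for (i in seq_along(lower)) {
    if (lower[i] %in% forms[[1]]) rec(2L, i, i)
  }
  if (!length(cand_s)) return(data.frame(start_token = integer(0),
                                         end_token = integer(0)))
  ord <- order(cand_s, cand_e)
  cand_s <- cand_s[ord]; cand_e <- cand_e[ord]
  sel_s <- integer(0); sel_e <- integer(0)
  last_end <- 0L
  repeat {
    ok <- which(cand_s > last_end)
    if (!length(ok)) break
    i <- ok[1]  # smallest start, then smallest end (sorted)
    sel_s <- c(sel_s, cand_s[i]); sel_e <- c(sel_e, cand_e[i])
    last_end <- cand_e[i]
  }
  data.frame(start_token = sel_s, end_token = sel_e)
}

# plain iteratively-reweighted least squares for unpenalized logistic
# regression
irls_logistic <- function(X, y, tol = 1e-12, maxit = 200L) {
  X1 <- cbind(`(Intercept)` = 1, X)
  b <- rep(0, ncol(X1))
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    bn <- drop(solve(crossprod(X1, w * X1), crossprod(X1, w * z)))
    if (max(abs(bn - b)) < tol) return(bn)
    b <- bn
  }
  b
}

# explicit-count confusion metrics
oracle_confusion <- function(probs, labels, cutoff) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(probs)) {
    pred <- probs[i] >= cutoff
    if (pred && labels[i] == 1) tp <- tp + 1L
    if (pred && labels[i] == 0) fp <- fp + 1L
    if (!pred && labels[i] == 1) fn <- fn + 1L
    if (!pred && labels[i] == 0) tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# concordant-pair AUC by full enumeration
oracle_auc <- function(probs, labels) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

toy_dictionary <- function() {
  load_dictionary(system.file("extdata", "toy-dictionary.yaml",
                              package = "mcitext"),
                  quiet = TRUE)
}

bundled_dictionary <- function() {
  load_dictionary(bundled_dictionary_path(), quiet = TRUE)
}
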