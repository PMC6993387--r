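# Brute-force oracles, deliberately written as explicit loops independent of
# the package's vectorized implementations.

# Empirical p by counting; BH by the textbook step-up (sort, i/m scaling,
# cumulative minimum from the largest p).
oracle_fdr <- function(test, null, q, tail) {
  m <- length(test)
  p <- sapply(test, function(s) {
    hits <- 0
    for (x in null) {
      if ((tail == "lower" && x <= s) || (tail == "upper" && x >= s)) {
        hits <- hits + 1
      }
    }
    (hits + 1) / (length(null) + 1)
  })
  ord <- order(p)
  qv <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    qv[ord[i]] <- running
  }
  disc <- qv <= q
  thr <- if (!any(disc)) {
    NA_real_
  } else if (tail == "lower") max(test[disc]) else min(test[disc])
  list(p = p, q_values = qv, threshold = thr, discovery = disc)
}

# Precision-recall with explicit confusion counts at every threshold.
oracle_pr <- function(scores, labels) {
  thr <- sort(unique(scores))
  prec <- rec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    tp <- fp <- fn <- 0
    for (j in seq_along(scores)) {
      pred <- scores[j] <= thr[i]
      if (pred && labels[j]) tp <- tp + 1
      if (pred && !labels[j]) fp <- fp + 1
      if (!pred && labels[j]) fn <- fn + 1
    }
    prec[i] <- tp / (tp + fp)
    rec[i] <- tp / (tp + fn)
  }
  auprc <- 0
  prev <- 0
  for (i in seq_along(thr)) {
    auprc <- auprc + (rec[i] - prev) * prec[i]
    prev <- rec[i]
  }
  list(precision = prec, recall = rec, auprc = auprc)
}

# Spearman rho from first principles: average ranks by explicit tie
# handling, then the Pearson formula on the ranks.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      less <- sum(v < v[i])
      tied <- sum(v == v[i])
      r[i] <- less + (tied + 1) / 2
    }
    r
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Tail LLR by explicit counting with add-one smoothing.
oracle_llr <- function(s, pos, neg) {
  np <- 0
  for (x in pos) if (x <= s) np <- np + 1
  nn <- 0
  for (x in neg) if (x >= s) nn <- nn + 1
  log10(((np + 1) / (length(pos) + 1)) / ((nn + 1) / (length(neg) + 1)))
}
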