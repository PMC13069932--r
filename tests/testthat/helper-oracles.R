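# Independent brute-force oracles. These recompute quantities from first
# principles (exhaustive enumeration, per-pixel loops) and stay deliberately
# separate from the package's code paths.

# AUC by exhaustive concordant/discordant/tied pair counting:
# (#concordant + 1/2 #tied) / (n_pos * n_neg)
auc_pairs_oracle <- function(scores, labels01) {
  pos <- scores[labels01]
  neg <- scores[!labels01]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Field quantification by per-pixel recomputation
quantify_oracle <- function(img) {
  v <- as.vector(unclass(img))
  thr <- (min(v) + max(v)) / 2
  st <- v[v < thr]
  list(threshold = thr,
       mean_intensity = if (length(st) > 0) mean(st) else NA_real_,
       pct_area = 100 * length(st) / length(v),
       n_stained = length(st))
}

# Youden cutoff by exhaustive search over all observed cutoffs
# (ties broken toward the smallest cutoff)
youden_oracle <- function(scores, labels01) {
  cuts <- sort(unique(scores))
  j <- vapply(cuts, function(c) {
    mean(scores[labels01] >= c) + mean(scores[!labels01] < c) - 1
  }, numeric(1))
  cuts[which(j >= max(j) - 1e-12)[1]]
}

# A random small score/label set with ties (both classes guaranteed)
random_tied_case <- function(n) {
  scores <- round(runif(n, 0, 5) * 2) / 2
  labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)[sample(n)]
  list(scores = scores, labels = labels)
}
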