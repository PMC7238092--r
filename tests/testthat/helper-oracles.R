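# Independent brute-force oracles used to pin expected values.

# AUC as the tie-corrected pairwise comparison over all pos x neg pairs.
brute_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exhaustive Youden search over every midpoint between adjacent distinct
# score levels; ties resolved toward the cutoff with higher sensitivity.
brute_youden <- function(scores, truth) {
  pos <- scores[truth == "malignant"]
  neg <- scores[truth == "benign"]
  lv <- sort(unique(scores))
  cuts <- (lv[-length(lv)] + lv[-1]) / 2
  j <- vapply(cuts, function(ct) {
    mean(pos > ct) + mean(neg <= ct) - 1
  }, numeric(1))
  best <- which(j == max(j))
  # lower cutoff = higher sensitivity
  list(cutoff = cuts[min(best)], j = max(j))
}

# Exact two-sided McNemar p by direct binomial-mass summation.
brute_mcnemar_exact <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  lo <- min(b, c)
  min(1, 2 * sum(vapply(0:lo, function(x) dbinom(x, n, 0.5), numeric(1))))
}

# Direct substitution of the Hanley-McNeil variance formula.
direct_hm_se <- function(A, n_pos, n_neg) {
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  sqrt((A * (1 - A) + (n_pos - 1) * (Q1 - A^2) +
          (n_neg - 1) * (Q2 - A^2)) / (n_pos * n_neg))
}

# All 2^n plane-call patterns as a character matrix.
all_call_patterns <- function(n_planes) {
  g <- expand.grid(rep(list(c("B", "M")), n_planes),
                   stringsAsFactors = FALSE)
  as.matrix(g)
}

random_roc_instance <- function(max_n = 50, n_levels = 5) {
  n_pos <- sample(1:max_n, 1)
  n_neg <- sample(1:max_n, 1)
  list(pos = sample(0:(n_levels - 1), n_pos, replace = TRUE),
       neg = sample(0:(n_levels - 1), n_neg, replace = TRUE))
}
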