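# Independent oracles used to check the implementation by a second route.
# These deliberately use brute-force enumeration / simulation, never the
# package's own code paths.

# AUC by exhaustive cross-class pair counting (concordant + half ties).
auc_brute <- function(scores, labels) {
  y <- if (is.character(labels)) as.integer(labels == "BA") else as.integer(labels)
  ca <- scores[y == 1]; ct <- scores[y == 0]
  tot <- 0
  for (a in ca) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ca) * length(ct))
}

# DeLong variance of a single AUC from structural components, small n:
# V10_i = mean_j psi(case_i, ctrl_j), V01_j = mean_i psi(case_i, ctrl_j),
# var(AUC) = s10/m + s01/n with sample variances.
delong_var_brute <- function(scores, labels) {
  y <- as.integer(labels)
  ca <- scores[y == 1]; ct <- scores[y == 0]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(ca, function(a) mean(vapply(ct, function(b) psi(a, b),
                                            numeric(1))), numeric(1))
  v01 <- vapply(ct, function(b) mean(vapply(ca, function(a) psi(a, b),
                                            numeric(1))), numeric(1))
  stats::var(v10) / length(ca) + stats::var(v01) / length(ct)
}

# Paired two-sided permutation test for the AUC difference of two score
# vectors on the same patients: under the null the two modalities are
# exchangeable within a patient, so scores are swapped per patient.
perm_test_auc_diff <- function(scores_a, scores_b, labels, n_perm = 20000,
                               seed = 1) {
  auc_rank <- function(s, y) {
    r <- rank(s)
    m <- sum(y == 1)
    (sum(r[y == 1]) - m * (m + 1) / 2) / (m * sum(y == 0))
  }
  y <- as.integer(labels)
  obs <- abs(auc_rank(scores_a, y) - auc_rank(scores_b, y))
  set.seed(seed)
  n <- length(y)
  hits <- 0
  for (k in seq_len(n_perm)) {
    swap <- runif(n) < 0.5
    a <- ifelse(swap, scores_b, scores_a)
    b <- ifelse(swap, scores_a, scores_b)
    if (abs(auc_rank(a, y) - auc_rank(b, y)) >= obs - 1e-12) hits <- hits + 1
  }
  hits / n_perm
}

# Exact two-sided Wilcoxon rank-sum p-value by enumerating every assignment
# of the pooled sample to the two groups (tiny n only).
wilcoxon_exact_enum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# Youden-optimal threshold by brute force over all cutpoints (calls are
# score > t); returns the maximal Youden index and the best thresholds.
youden_brute <- function(scores, labels) {
  y <- as.integer(labels)
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2)
  j <- sapply(cand, function(t) {
    sens <- sum(scores > t & y == 1) / sum(y == 1)
    spec <- sum(scores <= t & y == 0) / sum(y == 0)
    sens + spec - 1
  })
  list(max_j = max(j), thresholds = cand[j >= max(j) - 1e-12])
}

# Discretized ellipse area by brute-force pixel counting at a given center.
ellipse_area_brute <- function(a, b, center, nr, nc) {
  count <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if ((r - center[1])^2 / b^2 + (cc - center[2])^2 / a^2 <= 1)
      count <- count + 1L
  }
  count
}
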