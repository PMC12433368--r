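# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: AUC by all-pairs concordance, Youden by an
# exhaustive threshold scan.

# Mann-Whitney concordance: fraction of (positive, negative) pairs where the
# positive scores higher, ties counted one half.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  grid <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(grid)
}

# Exhaustive scan over every candidate threshold (each distinct score plus
# -Inf), positive call = score >= threshold; returns the maximal J and the
# set of thresholds attaining it.
oracle_youden_scan <- function(scores, labels) {
  thresholds <- c(-Inf, sort(unique(scores)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  sens <- vapply(thresholds, function(t) sum(scores >= t & labels == 1) / n_pos,
                 numeric(1))
  spec <- vapply(thresholds, function(t) sum(scores < t & labels == 0) / n_neg,
                 numeric(1))
  j <- sens + spec - 1
  list(j_max = max(j),
       argmax = thresholds[j == max(j)],
       sens = sens[j == max(j)], spec = spec[j == max(j)])
}

# A flat one-sample peak table with every core peptide at the given areas.
core_sample <- function(sample_id = "s1", area = 500, is_area = 500,
                        noise = NA_real_) {
  tibble::tibble(
    sample_id = sample_id,
    peptide_id = c("aT1", "aT3", "bT1", "bT2", "gT10", "dT2", "zT8"),
    area = area, is_area = is_area, noise = noise
  )
}
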